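# FASTA / BLAST-tabular readers and the global pairwise aligner shared by
# all pipeline stages. Sequence sets are plain data frames (class
# "protein_records") with columns id, sequence, length, flagged.

protein_records <- function(id, sequence, flagged = logical(length(id))) {
  stopifnot(length(id) == length(sequence))
  df <- data.frame(id = as.character(id), sequence = as.character(sequence),
                   length = nchar(sequence), flagged = flagged,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("protein_records", "data.frame"))
}

#' Read a protein FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a
#' `protein_records` data frame. Sequences are uppercased. Characters outside
#' the standard 20-letter alphabet plus the tolerated ambiguity set
#' ([AA_AMBIGUITY]) are always a parse error. Records containing ambiguity
#' codes raise an error under `alphabet_policy = "strict"` and are returned
#' with `flagged = TRUE` under `"tolerant"`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet_policy `"strict"` or `"tolerant"`.
#' @return A `protein_records` data frame with columns `id`, `sequence`,
#'   `length` and `flagged`, one row per FASTA entry in file order.
#' @export
read_fasta <- function(path, alphabet_policy = c("tolerant", "strict")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("malformed FASTA file '", path, "': no records")
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("malformed FASTA record '", ids[!nzchar(seqs)][1L],
         "': empty sequence")
  }
  flagged <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[i], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, c(AA20, AA_AMBIGUITY))
    if (length(bad) > 0L) {
      stop("parse error in record '", ids[i], "': invalid residue code(s) ",
           paste(bad, collapse = ", "))
    }
    amb <- intersect(chars, AA_AMBIGUITY)
    if (length(amb) > 0L) {
      if (alphabet_policy == "strict") {
        stop("parse error in record '", ids[i],
             "': non-standard residue(s) ", paste(amb, collapse = ", "),
             " not allowed under strict alphabet policy")
      }
      flagged[i] <- TRUE
    }
  }
  protein_records(ids, seqs, flagged)
}

#' Write protein records to FASTA
#'
#' @param records A `protein_records` data frame (or anything with `id` and
#'   `sequence` columns).
#' @param path Output file path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read BLAST tabular output
#'
#' Reads the standard 12-column BLAST tabular dialect (`-outfmt 6`:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Two optional trailing columns are interpreted as query
#' and subject sequence lengths. Percent similarity (positives) is not part
#' of the standard dialect and is returned as `NA`.
#'
#' @param path Path to a tab-separated hit file.
#' @return A data frame of hits in file order (class `blast_hits`).
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bit_score")
  empty <- data.frame(matrix(nrow = 0, ncol = 15))
  names(empty) <- c(cols, "query_length", "subject_length",
                    "percent_similarity")
  if (length(lines) == 0L) {
    return(structure(empty, class = c("blast_hits", "data.frame")))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 12L & nfield != 14L)
  if (length(bad) > 0L) {
    stop("parse error at line ", bad[1L], ": expected 12 or 14 columns, got ",
         nfield[bad[1L]])
  }
  num <- function(k) as.numeric(vapply(parts, `[`, character(1), k))
  chr <- function(k) vapply(parts, `[`, character(1), k)
  hits <- data.frame(
    query_id = chr(1), subject_id = chr(2), percent_identity = num(3),
    alignment_length = as.integer(num(4)), mismatches = as.integer(num(5)),
    gap_opens = as.integer(num(6)), q_start = as.integer(num(7)),
    q_end = as.integer(num(8)), s_start = as.integer(num(9)),
    s_end = as.integer(num(10)), evalue = num(11), bit_score = num(12),
    stringsAsFactors = FALSE)
  if (all(nfield == 14L)) {
    hits$query_length <- as.integer(num(13))
    hits$subject_length <- as.integer(num(14))
  } else {
    hits$query_length <- NA_integer_
    hits$subject_length <- NA_integer_
  }
  hits$percent_similarity <- NA_real_
  if (any(hits$evalue < 0, na.rm = TRUE)) {
    stop("parse error: negative e-value at line ",
         which(hits$evalue < 0)[1L])
  }
  structure(hits, class = c("blast_hits", "data.frame"))
}

#' Globally align two protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gap
#' penalties (defaults 11/1, matching BLAST's default protein scoring).
#' Identity is the fraction of identical columns among aligned columns
#' (columns where neither row is a gap); set
#' `identity_denominator = "shorter"` to divide by the shorter sequence
#' length instead.
#'
#' @param a,b Single rows of a `protein_records` data frame, or plain lists
#'   with `id` and `sequence` entries.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param substitution_matrix Name of a scoring matrix bundled with
#'   Biostrings, or a numeric matrix.
#' @param identity_denominator `"aligned"` or `"shorter"`.
#' @return An object of class `pairwise_alignment`: gapped rows, score,
#'   aligned/identical column counts and `identity_fraction`.
#' @export
align_pair <- function(a, b, gap_open = 11, gap_extend = 1,
                       substitution_matrix = "BLOSUM62",
                       identity_denominator = c("aligned", "shorter")) {
  identity_denominator <- match.arg(identity_denominator)
  seq_a <- if (is.character(a)) a else a$sequence
  seq_b <- if (is.character(b)) b else b$sequence
  id_a <- if (is.character(a)) "seq_a" else as.character(a$id)
  id_b <- if (is.character(b)) "seq_b" else as.character(b$id)
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("align_pair(): sequences must be non-empty")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(ga, "", fixed = TRUE)[[1L]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1L]]
  aligned <- ca != "-" & cb != "-"
  identical_cols <- sum(aligned & ca == cb)
  denom <- if (identity_denominator == "aligned") sum(aligned) else
    min(nchar(seq_a), nchar(seq_b))
  structure(list(
    id_a = id_a, id_b = id_b,
    seq_a_gapped = ga, seq_b_gapped = gb,
    score = Biostrings::score(aln),
    aligned_columns = sum(aligned),
    identical_columns = identical_cols,
    identity_fraction = if (denom > 0) identical_cols / denom else NA_real_
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment ", x$id_a, " / ", x$id_b,
      sprintf(": score %.1f, identity %.1f%% over %d aligned columns\n",
              x$score, 100 * x$identity_fraction, x$aligned_columns),
      sep = "")
  invisible(x)
}

#' Write a pairwise alignment as aligned FASTA
#'
#' @param alignment A `pairwise_alignment` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  writeLines(c(paste0(">", alignment$id_a), alignment$seq_a_gapped,
               paste0(">", alignment$id_b), alignment$seq_b_gapped), path)
  invisible(path)
}
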