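# Construction of the non-redundant AP-NP ortholog pair set: reciprocal
# best hits, length-difference and similarity filters, membrane-protein
# removal, blastclust-style redundancy clustering and the final length
# window. Stage counts are collected in a pipeline report whose counts are
# monotonically non-increasing through the filter stages.

#' Reciprocal best hits
#'
#' A pair (a, b) is returned iff b is a's best hit in `hits_ab` and a is b's
#' best hit in `hits_ba`, with both e-values below `evalue_max`. Best =
#' smallest e-value; ties are broken by higher percent identity, then by
#' lexically smallest subject id (so the best hit is always unique). When
#' e-values are absent (internally aligned candidates) a `score` column is
#' used instead, largest first, and the e-value threshold is skipped.
#'
#' @param hits_ab,hits_ba Hit data frames (see [read_blast_tabular()]); at
#'   minimum columns `query_id`, `subject_id` and `evalue` (or `score`).
#' @param evalue_max Reciprocal e-value threshold (default 1e-10).
#' @return Data frame with columns `id_a`, `id_b`, `evalue_ab`, `evalue_ba`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_max = 1e-10) {
  best_of <- function(hits) {
    if (nrow(hits) == 0L) return(hits)
    use_score <- (is.null(hits$evalue) || all(is.na(hits$evalue))) &&
      !is.null(hits$score)
    key <- if (use_score) -hits$score else hits$evalue
    pid <- if (!is.null(hits$percent_identity)) hits$percent_identity else 0
    ord <- order(hits$query_id, key, -pid, hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    hits[!duplicated(hits$query_id), , drop = FALSE]
  }
  ba <- best_of(hits_ab)
  bb <- best_of(hits_ba)
  if (nrow(ba) == 0L || nrow(bb) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      evalue_ab = numeric(0), evalue_ba = numeric(0)))
  }
  j <- match(ba$subject_id, bb$query_id)
  ok <- !is.na(j) & bb$subject_id[j] == ba$query_id
  ev_ab <- if (!is.null(ba$evalue)) ba$evalue else rep(NA_real_, nrow(ba))
  ev_ba <- if (!is.null(bb$evalue)) bb$evalue[j] else rep(NA_real_, nrow(ba))
  if (!all(is.na(ev_ab))) {
    ok <- ok & ev_ab < evalue_max & ev_ba < evalue_max
  }
  out <- data.frame(id_a = ba$query_id[ok], id_b = ba$subject_id[ok],
                    evalue_ab = ev_ab[ok], evalue_ba = ev_ba[ok],
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Filter candidate pairs on length difference and similarity
#'
#' Keeps pairs whose absolute length difference is strictly less than
#' `max_len_diff_frac` times the shorter length and whose percent similarity
#' is strictly greater than `min_similarity`.
#'
#' @param candidates Data frame with columns `len_ap`, `len_np` and
#'   `similarity` (percent).
#' @param max_len_diff_frac Length-difference fraction (default 0.05).
#' @param min_similarity Similarity threshold in percent (default 30).
#' @return The surviving rows.
#' @export
filter_pairs <- function(candidates, max_len_diff_frac = 0.05,
                         min_similarity = 30) {
  if (nrow(candidates) == 0L) return(candidates)
  shorter <- pmin(candidates$len_ap, candidates$len_np)
  keep <- abs(candidates$len_ap - candidates$len_np) <
    max_len_diff_frac * shorter &
    candidates$similarity > min_similarity
  candidates[keep, , drop = FALSE]
}

#' Remove pairs containing membrane proteins
#'
#' Drops every pair whose AP or NP member id appears in `membrane_ids`
#' (typically parsed from TMHMM output or a plain id list).
#'
#' @param pairs Data frame with columns `id_ap` and `id_np`.
#' @param membrane_ids Character vector of transmembrane protein ids.
#' @return The surviving rows.
#' @export
remove_membrane_proteins <- function(pairs, membrane_ids) {
  if (nrow(pairs) == 0L || length(membrane_ids) == 0L) return(pairs)
  keep <- !(pairs$id_ap %in% membrane_ids | pairs$id_np %in% membrane_ids)
  pairs[keep, , drop = FALSE]
}

#' Apply the length window to protein records
#'
#' Keeps sequences strictly longer than `min_len` and strictly shorter than
#' `max_len`.
#'
#' @param records A `protein_records` data frame.
#' @param min_len,max_len Window bounds (defaults 50 and 600, both
#'   exclusive).
#' @return The surviving rows.
#' @export
length_window <- function(records, min_len = 50L, max_len = 600L) {
  records[records$length > min_len & records$length < max_len, ,
          drop = FALSE]
}

# Single-linkage components over sequences: two sequences link when their
# global-alignment identity >= max_identity and the aligned columns cover
# >= min_coverage of BOTH sequences (blastclust-style, emulated with the
# internal aligner).
.sequence_components <- function(seqs, min_coverage, max_identity, ...) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (identical(seqs[i], seqs[j])) {
          union2(i, j)
          next
        }
        aln <- align_pair(seqs[i], seqs[j], ...)
        cov_i <- aln$aligned_columns / nchar(seqs[i])
        cov_j <- aln$aligned_columns / nchar(seqs[j])
        if (aln$identity_fraction >= max_identity &&
            cov_i >= min_coverage && cov_j >= min_coverage) {
          union2(i, j)
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Remove redundant pairs by single-linkage sequence clustering
#'
#' Emulates blastclust: all AP and NP sequences of all pairs are clustered
#' by single linkage, linking two sequences when their pairwise identity is
#' at least `max_identity` (default 0.25) with alignment coverage of at
#' least `min_coverage` (default 0.5) of both sequences. Pairs whose members
#' fall in connected sequence clusters form one pair cluster, from which a
#' single representative is retained: the pair with the smallest RBH
#' e-value (largest alignment score when e-values are absent), ties broken
#' by the lexically smallest AP id.
#'
#' @param pairs Data frame with columns `id_ap`, `id_np`, `seq_ap`,
#'   `seq_np`, and `evalue_ab`/`evalue_ba` (or `score`).
#' @param min_coverage,max_identity Clustering thresholds.
#' @param ... Passed to [align_pair()].
#' @return The retained rows.
#' @export
cluster_redundancy <- function(pairs, min_coverage = 0.5,
                               max_identity = 0.25, ...) {
  if (nrow(pairs) <= 1L) return(pairs)
  seqs <- c(pairs$seq_ap, pairs$seq_np)
  comp <- .sequence_components(seqs, min_coverage, max_identity, ...)
  n <- nrow(pairs)
  # merge the two members of each pair, then group pairs by component
  parent <- seq_along(comp)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_along(comp)) link(i, comp[i])
  for (k in seq_len(n)) link(k, k + n)
  cluster <- vapply(seq_len(n), find, integer(1))
  ev <- if (!is.null(pairs$evalue_ab) && !all(is.na(pairs$evalue_ab))) {
    pmin(pairs$evalue_ab, pairs$evalue_ba, na.rm = TRUE)
  } else if (!is.null(pairs$score)) {
    -pairs$score
  } else {
    rep(0, n)
  }
  keep <- logical(n)
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    ord <- idx[order(ev[idx], pairs$id_ap[idx])]
    keep[ord[1L]] <- TRUE
  }
  pairs[keep, , drop = FALSE]
}

# Internal all-vs-all candidate hits from the package aligner: one hit per
# (query, subject) with the alignment score as the ranking key.
.internal_hits <- function(qrecords, srecords, ...) {
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(qrecords))) {
    for (j in seq_len(nrow(srecords))) {
      aln <- align_pair(qrecords[i, ], srecords[j, ], ...)
      k <- k + 1L
      rows[[k]] <- data.frame(
        query_id = qrecords$id[i], subject_id = srecords$id[j],
        evalue = NA_real_, percent_identity = 100 * aln$identity_fraction,
        score = aln$score, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build the non-redundant AP-NP ortholog pair set
#'
#' Runs the full pipeline: reciprocal best hits (from supplied BLAST tabular
#' hits, or from internal all-vs-all global alignments when none are given),
#' the length-difference (< 5% of the shorter sequence) and similarity
#' (> 30%) filters, membrane-protein removal, blastclust-style redundancy
#' clustering (identity 0.25, coverage 0.5) and the 50/600 length window.
#' Similarity is BLAST percent positives when hits carry them, otherwise the
#' percent identity of the pair alignment.
#'
#' @param ap,np `protein_records` data frames for the AP and NP proteomes.
#' @param hits_ab,hits_ba Optional precomputed hit tables (AP query vs NP
#'   subject, and the reverse).
#' @param membrane_ids Character vector of transmembrane protein ids.
#' @param evalue_max,max_len_diff_frac,min_similarity,min_coverage,max_identity,min_len,max_len
#'   Stage thresholds (defaults as stated above).
#' @param ... Passed to [align_pair()].
#' @return List of class `ortholog_pairs`: `pairs` (data frame with ids,
#'   sequences, lengths, identity, similarity, e-values), `alignments`
#'   (list of [align_pair()] results, AP row `"a"`), and `report` (a
#'   `pipeline_report` of stage counts).
#' @export
build_ortholog_pairs <- function(ap, np, hits_ab = NULL, hits_ba = NULL,
                                 membrane_ids = character(0),
                                 evalue_max = 1e-10,
                                 max_len_diff_frac = 0.05,
                                 min_similarity = 30,
                                 min_coverage = 0.5, max_identity = 0.25,
                                 min_len = 50L, max_len = 600L, ...) {
  report <- list(n_ap = nrow(ap), n_np = nrow(np))
  if (is.null(hits_ab) || is.null(hits_ba)) {
    hits_ab <- .internal_hits(ap, np, ...)
    hits_ba <- .internal_hits(np, ap, ...)
  }
  rbh <- reciprocal_best_hits(hits_ab, hits_ba, evalue_max = evalue_max)
  report$n_rbh <- nrow(rbh)

  if (nrow(rbh) > 0L) {
    i_ap <- match(rbh$id_a, ap$id)
    i_np <- match(rbh$id_b, np$id)
    if (anyNA(i_ap) || anyNA(i_np)) {
      stop("build_ortholog_pairs(): hit ids not found in the FASTA records")
    }
    alns <- lapply(seq_len(nrow(rbh)), function(k) {
      align_pair(ap[i_ap[k], ], np[i_np[k], ], ...)
    })
    identity <- vapply(alns, function(a) a$identity_fraction, numeric(1))
    ppos <- rep(NA_real_, nrow(rbh))
    if (!is.null(hits_ab$percent_similarity)) {
      key <- paste(hits_ab$query_id, hits_ab$subject_id)
      ppos <- hits_ab$percent_similarity[
        match(paste(rbh$id_a, rbh$id_b), key)]
    }
    pairs <- data.frame(
      id_ap = rbh$id_a, id_np = rbh$id_b,
      seq_ap = ap$sequence[i_ap], seq_np = np$sequence[i_np],
      len_ap = ap$length[i_ap], len_np = np$length[i_np],
      identity = identity,
      similarity = ifelse(is.na(ppos), 100 * identity, ppos),
      evalue_ab = rbh$evalue_ab, evalue_ba = rbh$evalue_ba,
      score = vapply(alns, function(a) a$score, numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(id_ap = character(0), id_np = character(0),
                        seq_ap = character(0), seq_np = character(0),
                        len_ap = integer(0), len_np = integer(0),
                        identity = numeric(0), similarity = numeric(0),
                        evalue_ab = numeric(0), evalue_ba = numeric(0),
                        score = numeric(0), stringsAsFactors = FALSE)
    alns <- list()
  }

  pairs <- filter_pairs(pairs, max_len_diff_frac, min_similarity)
  report$n_filtered <- nrow(pairs)
  pairs <- remove_membrane_proteins(pairs, membrane_ids)
  report$n_membrane_removed <- nrow(pairs)
  pairs <- cluster_redundancy(pairs, min_coverage, max_identity, ...)
  report$n_clustered <- nrow(pairs)
  keep <- pairs$len_ap > min_len & pairs$len_ap < max_len &
    pairs$len_np > min_len & pairs$len_np < max_len
  pairs <- pairs[keep, , drop = FALSE]
  report$n_final <- nrow(pairs)
  rownames(pairs) <- NULL

  alignments <- lapply(seq_len(nrow(pairs)), function(k) {
    align_pair(list(id = pairs$id_ap[k], sequence = pairs$seq_ap[k]),
               list(id = pairs$id_np[k], sequence = pairs$seq_np[k]), ...)
  })
  structure(list(pairs = pairs, alignments = alignments,
                 report = structure(report, class = "pipeline_report")),
            class = "ortholog_pairs")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Ortholog pipeline stage counts:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Write an ortholog pair set
#'
#' Writes mate-paired FASTA files (the i-th records of the two files are an
#' ortholog pair), a TSV pair table and a JSON pipeline report.
#'
#' @param result An `ortholog_pairs` object.
#' @param prefix Output path prefix; files `<prefix>_ap.fa`,
#'   `<prefix>_np.fa`, `<prefix>_pairs.tsv`, `<prefix>_report.json` are
#'   created.
#' @return Character vector of the written paths, invisibly.
#' @export
write_ortholog_pairs <- function(result, prefix) {
  p <- result$pairs
  fa_ap <- paste0(prefix, "_ap.fa")
  fa_np <- paste0(prefix, "_np.fa")
  write_fasta(protein_records(p$id_ap, p$seq_ap), fa_ap)
  write_fasta(protein_records(p$id_np, p$seq_np), fa_np)
  tsv <- paste0(prefix, "_pairs.tsv")
  utils::write.table(
    p[, c("id_ap", "id_np", "len_ap", "len_np", "identity", "similarity",
          "evalue_ab", "evalue_ba")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- paste0(prefix, "_report.json")
  jsonlite::write_json(unclass(result$report), js, auto_unbox = TRUE)
  invisible(c(fa_ap, fa_np, tsv, js))
}
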