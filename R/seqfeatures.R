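# The sequence feature catalogue: 889 named features per protein, of which
# 871 are computed natively from the sequence and 18 are placeholders for
# structure-predictor output (secondary structure, burial, disorder, RSA,
# Z-fit) that can be supplied externally but is never computed here.
#
# Naming scheme: c_<k> is an absolute count, x_<k> the same quantity
# normalized by chain length (length - 1 for dipeptides). Ambiguity codes are
# skipped in numerators; denominators always use the full chain length so
# compositions stay comparable across records.

DIPEPTIDES <- paste0(rep(AA20, each = 20L), AA20)

CATALOGUE_GROUPS <- list(
  list(group = "Sequence length", names = "length", external = FALSE),
  list(group = "Amino acid counts and composition",
       names = c(paste0("c_", AA20), paste0("x_", AA20)), external = FALSE),
  list(group = "Dipeptide counts and composition",
       names = c(paste0("c_", DIPEPTIDES), paste0("x_", DIPEPTIDES)),
       external = FALSE),
  list(group = "Charged residues and net charge",
       names = c("c_positive", "x_positive", "c_negative", "x_negative",
                 "c_charged", "x_charged", "net_charge", "x_net_charge"),
       external = FALSE),
  list(group = "Small, tiny, aromatic, aliphatic, hydrophobic and polar residues",
       names = as.vector(t(outer(c("c_", "x_"),
                                 c("small", "tiny", "aromatic", "aliphatic",
                                   "hydrophobic", "polar"), paste0))),
       external = FALSE),
  list(group = "Side-chain hydrogen-bond capable residues",
       names = c("c_hbond", "x_hbond"), external = FALSE),
  list(group = "Sulfur atoms", names = "c_sulfide", external = FALSE),
  list(group = "Mean maximum solvent-accessible surface area",
       names = "asa_max_mean", external = FALSE),
  list(group = "Isoelectric point", names = c("pI", "pIa"), external = FALSE),
  list(group = "Instability index and class",
       names = c("instability_index", "instability_class"), external = FALSE),
  list(group = "Aliphatic index", names = "aliphatic_index", external = FALSE),
  list(group = "GRAVY hydropathy index", names = "gravy", external = FALSE),
  list(group = "Predicted secondary structure residues",
       names = c("c_helix", "x_helix", "c_sheet", "x_sheet",
                 "c_coil", "x_coil"), external = TRUE),
  list(group = "Predicted buried/exposed residues",
       names = c("c_buried", "x_buried", "c_exposed", "x_exposed"),
       external = TRUE),
  list(group = "Predicted disorder (coils, rem465, hot loops)",
       names = c("len_coils", "x_coils", "len_rem465", "x_rem465",
                 "len_hotloops", "x_hotloops"), external = TRUE),
  list(group = "Mean relative surface accessibility",
       names = "rsa_mean", external = TRUE),
  list(group = "Mean Z-fit score", names = "zfit_mean", external = TRUE)
)

#' The sequence feature catalogue
#'
#' Deterministically ordered catalogue of all 889 features: 871 natively
#' computable from sequence and 18 external predictor-derived entries
#' (secondary structure, burial, disorder, RSA, Z-fit) that are ingested,
#' never computed.
#'
#' @return A data frame with columns `name`, `group` and `computable`
#'   (`"native"` or `"external"`).
#' @export
feature_catalogue <- function() {
  parts <- lapply(CATALOGUE_GROUPS, function(g) {
    data.frame(name = g$names, group = g$group,
               computable = if (g$external) "external" else "native",
               stringsAsFactors = FALSE)
  })
  cat_df <- do.call(rbind, parts)
  rownames(cat_df) <- NULL
  cat_df
}

.seq_chars <- function(p) {
  s <- if (is.character(p)) p else p$sequence
  if (is.null(s) || !nzchar(s)) stop("empty sequence")
  strsplit(toupper(s), "", fixed = TRUE)[[1L]]
}

.aa_counts <- function(chars) {
  tab <- table(factor(chars, levels = AA20))
  stats::setNames(as.integer(tab), AA20)
}

#' Residue category features
#'
#' Counts and length-normalized fractions for the residue category sets
#' (positive, negative, all-charged, small, tiny, aromatic, aliphatic,
#' hydrophobic, polar, hydrogen-bond capable side chains), the net charge
#' (K+R minus D+E; His excluded), the sulfur-atom count (Cys + Met) and the
#' mean per-residue maximum solvent-accessible surface area.
#'
#' @param p A protein record (row of a `protein_records` data frame, a list
#'   with a `sequence` entry, or a plain string).
#' @param sets Residue category sets; see [residue_sets()].
#' @param max_asa Named per-residue maximum-ASA table.
#' @return Named numeric vector.
#' @export
category_features <- function(p, sets = residue_sets(),
                              max_asa = MAX_ASA_DEFAULT) {
  chars <- .seq_chars(p)
  L <- length(chars)
  cnt <- .aa_counts(chars)
  in_set <- function(res) sum(cnt[res])
  c_pos <- in_set(sets$positive); c_neg <- in_set(sets$negative)
  n_std <- sum(cnt)
  out <- c(
    c_positive = c_pos, x_positive = c_pos / L,
    c_negative = c_neg, x_negative = c_neg / L,
    c_charged = c_pos + c_neg, x_charged = (c_pos + c_neg) / L,
    net_charge = c_pos - c_neg, x_net_charge = (c_pos - c_neg) / L)
  for (nm in c("small", "tiny", "aromatic", "aliphatic", "hydrophobic",
               "polar")) {
    k <- in_set(sets[[nm]])
    out[paste0("c_", nm)] <- k
    out[paste0("x_", nm)] <- k / L
  }
  hb <- in_set(sets$hbond)
  out["c_hbond"] <- hb
  out["x_hbond"] <- hb / L
  out["c_sulfide"] <- cnt["C"] + cnt["M"]
  out["asa_max_mean"] <- if (n_std > 0)
    sum(cnt * max_asa[AA20]) / n_std else NA_real_
  out
}

.net_charge_at_ph <- function(cnt, ph) {
  pos <- c(Nterm = 1, cnt[c("K", "R", "H")])
  neg <- c(Cterm = 1, cnt[c("D", "E", "C", "Y")])
  pks_pos <- PKA_POSITIVE[c("Nterm", "K", "R", "H")]
  pks_neg <- PKA_NEGATIVE[c("Cterm", "D", "E", "C", "Y")]
  sum(pos / (1 + 10^(ph - pks_pos))) - sum(neg / (1 + 10^(pks_neg - ph)))
}

.isoelectric_point <- function(cnt, tol = 1e-4) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.net_charge_at_ph(cnt, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' ProtParam-style global indices
#'
#' Isoelectric point by bisection on the Henderson-Hasselbalch net-charge
#' curve with the Bjellqvist pKa set; residue-averaged pI; the
#' dipeptide-weight instability index (unstable above 40); the aliphatic
#' index; and the GRAVY hydropathy index (mean Kyte-Doolittle hydropathy).
#' Ambiguity codes are skipped in all sums; the instability index and
#' aliphatic index are scaled by the full chain length.
#'
#' @param p A protein record (see [category_features()]).
#' @return A list with elements `pI`, `pI_average`, `instability_index`,
#'   `instability_class` (`"stable"` or `"unstable"`), `aliphatic_index` and
#'   `gravy`.
#' @export
protparam_indices <- function(p) {
  chars <- .seq_chars(p)
  L <- length(chars)
  std <- chars[chars %in% AA20]
  if (length(std) == 0L) {
    stop("protparam_indices(): sequence contains no standard residues")
  }
  cnt <- .aa_counts(chars)
  ii <- 0
  if (L >= 2L) {
    a <- chars[-L]; b <- chars[-1L]
    keep <- a %in% AA20 & b %in% AA20
    if (any(keep)) ii <- sum(DIWV_TABLE[cbind(a[keep], b[keep])])
  }
  ii <- 10 * ii / L
  ai <- 100 * (cnt["A"] + 2.9 * cnt["V"] + 3.9 * (cnt["I"] + cnt["L"])) / L
  list(
    pI = .isoelectric_point(cnt),
    pI_average = mean(RESIDUE_PI[std]),
    instability_index = ii,
    instability_class = if (ii > 40) "unstable" else "stable",
    aliphatic_index = unname(ai),
    gravy = mean(KYTE_DOOLITTLE[std]))
}

#' Compute the feature vector for one protein
#'
#' Computes all 871 native catalogue features. External predictor-derived
#' entries are filled from `external` when supplied and are `NA` otherwise.
#'
#' @param p A protein record (see [category_features()]).
#' @param external Optional named numeric vector covering only catalogue
#'   entries marked external; unknown names are an error.
#' @param sets,max_asa Passed to [category_features()].
#' @return Named numeric vector of length 889 in catalogue order
#'   (`instability_class` encoded 0 = stable, 1 = unstable).
#' @export
compute_features <- function(p, external = NULL, sets = residue_sets(),
                             max_asa = MAX_ASA_DEFAULT) {
  cat_df <- feature_catalogue()
  chars <- .seq_chars(p)
  L <- length(chars)
  cnt <- .aa_counts(chars)
  vals <- stats::setNames(rep(NA_real_, nrow(cat_df)), cat_df$name)
  vals["length"] <- L
  vals[paste0("c_", AA20)] <- cnt
  vals[paste0("x_", AA20)] <- cnt / L
  dp_cnt <- stats::setNames(integer(400L), DIPEPTIDES)
  if (L >= 2L) {
    a <- chars[-L]; b <- chars[-1L]
    keep <- a %in% AA20 & b %in% AA20
    if (any(keep)) {
      tab <- table(factor(paste0(a[keep], b[keep]), levels = DIPEPTIDES))
      dp_cnt[] <- as.integer(tab)
    }
  }
  vals[paste0("c_", DIPEPTIDES)] <- dp_cnt
  vals[paste0("x_", DIPEPTIDES)] <- if (L >= 2L) dp_cnt / (L - 1L) else 0
  catf <- category_features(p, sets = sets, max_asa = max_asa)
  vals[names(catf)] <- catf
  pp <- protparam_indices(p)
  vals["pI"] <- pp$pI
  vals["pIa"] <- pp$pI_average
  vals["instability_index"] <- pp$instability_index
  vals["instability_class"] <- as.numeric(pp$instability_class == "unstable")
  vals["aliphatic_index"] <- pp$aliphatic_index
  vals["gravy"] <- pp$gravy
  if (!is.null(external)) {
    ext_names <- cat_df$name[cat_df$computable == "external"]
    unknown <- setdiff(names(external), ext_names)
    if (length(unknown) > 0L) {
      stop("compute_features(): unknown external feature name(s): ",
           paste(unknown, collapse = ", "))
    }
    vals[names(external)] <- as.numeric(external)
  }
  vals
}

#' Compute the feature matrix for a set of proteins
#'
#' @param records A `protein_records` data frame.
#' @param external Optional list of per-record external feature vectors,
#'   indexed by record id.
#' @inheritParams compute_features
#' @return Numeric matrix, one row per record (rownames = ids), columns in
#'   catalogue order.
#' @export
compute_feature_matrix <- function(records, external = NULL,
                                   sets = residue_sets(),
                                   max_asa = MAX_ASA_DEFAULT) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    ext <- if (!is.null(external)) external[[records$id[i]]] else NULL
    compute_features(records[i, ], external = ext, sets = sets,
                     max_asa = max_asa)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- records$id
  m
}

#' Write a feature matrix as TSV
#'
#' One row per sequence, columns in catalogue order, missing (external)
#' values as empty cells.
#'
#' @param m Feature matrix from [compute_feature_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
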