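# Directional amino-acid substitution propensity matrix and the per-residue
# composition comparison between AP (acid-stable) and NP (neutral-cytoplasm)
# ortholog sets.
#
# Matrix convention: counts[r, c] is the number of aligned, non-gap,
# standard-residue columns with AP residue r and NP residue c, i.e. the
# forward (NP -> AP) substitution c -> r. The ratio line of a row divides
# each cell by its transpose, so values above 1 mark substitutions favored
# in the forward direction.

new_substitution_matrix <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            !is.null(rownames(counts)),
            identical(rownames(counts), colnames(counts)))
  structure(list(
    counts = counts,
    total = sum(counts),
    total_offdiag = sum(counts) - sum(diag(counts)),
    ratios = NULL, pvalues = NULL, calls = NULL,
    construction = NULL, alpha = NULL
  ), class = "substitution_matrix")
}

#' Count directional substitutions from AP-NP alignments
#'
#' Walks every column of each pairwise alignment and increments
#' `counts[ap_residue, np_residue]`. Columns containing a gap or an
#' ambiguity code in either row are skipped.
#'
#' @param alignments List of [align_pair()] results.
#' @param ap_row For each alignment, `"a"` or `"b"`: which row is the AP
#'   member. Recycled if length 1. Missing labels are an error.
#' @return A `substitution_matrix` with counts filled (residues in
#'   alphabetical order).
#' @export
count_substitutions <- function(alignments, ap_row) {
  if (missing(ap_row) || is.null(ap_row) || any(is.na(ap_row))) {
    stop("count_substitutions(): every alignment must be labeled with its ",
         "AP row ('a' or 'b')")
  }
  ap_row <- rep_len(as.character(ap_row), length(alignments))
  if (!all(ap_row %in% c("a", "b"))) {
    stop("count_substitutions(): ap_row entries must be 'a' or 'b'")
  }
  counts <- matrix(0L, 20L, 20L, dimnames = list(AA20, AA20))
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    ca <- strsplit(aln$seq_a_gapped, "", fixed = TRUE)[[1L]]
    cb <- strsplit(aln$seq_b_gapped, "", fixed = TRUE)[[1L]]
    ap <- if (ap_row[i] == "a") ca else cb
    np <- if (ap_row[i] == "a") cb else ca
    keep <- ap %in% AA20 & np %in% AA20
    if (any(keep)) {
      tab <- table(factor(ap[keep], levels = AA20),
                   factor(np[keep], levels = AA20))
      counts <- counts + matrix(as.integer(tab), 20L, 20L)
    }
  }
  new_substitution_matrix(counts)
}

#' Read a substitution count matrix from TSV
#'
#' Expects a header line of residue codes (NP side) and one row per AP
#' residue, first column the residue code. The bundled published count
#' matrix is available via
#' `system.file("extdata", "apnp_substitution_counts.tsv", package = "acidostab")`.
#'
#' @param path TSV file path.
#' @return A `substitution_matrix` with counts filled, preserving the file's
#'   residue order.
#' @export
read_substitution_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  colnames(m) <- colnames(df)
  new_substitution_matrix(m)
}

#' Half-up decimal rounding
#'
#' Rounds to `digits` decimals with ties away from zero, the convention used
#' for the displayed substitution ratios (base `round()` rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Fill directional substitution ratios
#'
#' `ratios[r, c] = counts[r, c] / counts[c, r]`. A positive count over a
#' zero count is `Inf`; 0/0 is `NaN`; the diagonal is reported as 1 by
#' convention.
#'
#' @param m A `substitution_matrix` with counts filled.
#' @return The matrix with `ratios` filled.
#' @export
substitution_ratios <- function(m) {
  stopifnot(inherits(m, "substitution_matrix"))
  cnt <- m$counts
  ratios <- cnt / t(cnt)
  ratios[cnt > 0 & t(cnt) == 0] <- Inf
  diag(ratios) <- 1
  m$ratios <- ratios
  m
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (with the customary 1e-7
#' relative tolerance for ties).
#'
#' @param a,b,c,d Cell counts of the table `[[a, b], [c, d]]`.
#' @return The two-sided p-value.
#' @export
fisher_exact2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

.fisher_table <- function(counts, r, c, construction) {
  n_rc <- counts[r, c]
  n_cr <- counts[c, r]
  switch(construction,
    ap_conditional = {
      occ <- rowSums(counts)
      c(n_rc, occ[r] - n_rc, n_cr, occ[c] - n_cr)
    },
    equal_margins = {
      total <- sum(counts) - sum(diag(counts))
      c(n_rc, total - n_rc, n_cr, total - n_cr)
    },
    equal_margins_diag = {
      total <- sum(counts)
      c(n_rc, total - n_rc, n_cr, total - n_cr)
    },
    source_rate = {
      occ <- colSums(counts)
      c(n_rc, occ[c] - n_rc, n_cr, occ[r] - n_cr)
    },
    stop("unknown Fisher construction: ", construction))
}

#' Fisher exact significance calls for substitution bias
#'
#' For each unordered residue pair a two-sided Fisher exact test compares the
#' two opposite directional counts. The 2x2 construction is configurable
#' because the underlying study does not state it:
#'
#' * `"ap_conditional"` (default): each directed count against the AP-side
#'   abundance of its target residue,
#'   `[[n(c->r), occAP(r) - n(c->r)], [n(r->c), occAP(c) - n(r->c)]]` --
#'   does gaining r from c outweigh gaining c from r, relative to how common
#'   r and c are among AP residues? This is the candidate construction that
#'   comes closest to reproducing the published bias-call totals.
#' * `"equal_margins"` / `"equal_margins_diag"`: the two directed counts
#'   against the total (off-diagonal / all) substitution count.
#' * `"source_rate"`: each directed count against the NP-side abundance of
#'   its source residue.
#'
#' Cells with `p < alpha` are called `"forward"` when their count exceeds
#' the transposed count (the NP -> AP direction into the row residue is
#' favored) and `"reverse"` otherwise; everything else, including the
#' diagonal, is `"ns"`.
#'
#' @param m A `substitution_matrix` with counts filled.
#' @param alpha Significance cutoff (default 1e-10).
#' @param construction One of the constructions above.
#' @return The matrix with `pvalues` and `calls` filled.
#' @export
substitution_significance <- function(m, alpha = 1e-10,
                                      construction = c("ap_conditional",
                                                       "equal_margins",
                                                       "equal_margins_diag",
                                                       "source_rate")) {
  stopifnot(inherits(m, "substitution_matrix"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("substitution_significance(): alpha must be in (0, 1)")
  }
  construction <- match.arg(construction)
  cnt <- m$counts
  n <- nrow(cnt)
  pvals <- matrix(NA_real_, n, n, dimnames = dimnames(cnt))
  calls <- matrix("ns", n, n, dimnames = dimnames(cnt))
  for (r in seq_len(n - 1L)) {
    for (c in (r + 1L):n) {
      tab <- .fisher_table(cnt, r, c, construction)
      p <- fisher_exact2x2(tab[1L], tab[2L], tab[3L], tab[4L])
      pvals[r, c] <- p
      pvals[c, r] <- p
      if (p < alpha) {
        if (cnt[r, c] > cnt[c, r]) {
          calls[r, c] <- "forward"; calls[c, r] <- "reverse"
        } else if (cnt[c, r] > cnt[r, c]) {
          calls[c, r] <- "forward"; calls[r, c] <- "reverse"
        }
      }
    }
  }
  m$pvalues <- pvals
  m$calls <- calls
  m$construction <- construction
  m$alpha <- alpha
  m
}

#' Summarize significance calls
#'
#' @param m A `substitution_matrix` with calls filled.
#' @return List with `n_significant` (significant cells), `n_forward` and
#'   `n_reverse`.
#' @export
substitution_summary <- function(m) {
  stopifnot(inherits(m, "substitution_matrix"), !is.null(m$calls))
  nf <- sum(m$calls == "forward")
  nr <- sum(m$calls == "reverse")
  list(n_significant = nf + nr, n_forward = nf, n_reverse = nr)
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("Directional substitution matrix (", nrow(x$counts), " residues, ",
      x$total, " columns counted, ", x$total_offdiag, " off-diagonal)\n",
      sep = "")
  if (!is.null(x$calls)) {
    s <- substitution_summary(x)
    cat("  ", s$n_significant, " significant cells (",
        s$n_forward, " forward, ", s$n_reverse, " reverse) at alpha ",
        format(x$alpha), ", construction '", x$construction, "'\n", sep = "")
  }
  invisible(x)
}

#' Write the substitution matrix in the two-line-per-residue layout
#'
#' Mirrors the published presentation: for each residue row, a line of
#' counts followed by a line of half-up two-decimal ratios (diagonal as
#' `-`).
#'
#' @param m A `substitution_matrix` with ratios filled.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(m, path) {
  stopifnot(!is.null(m$ratios))
  res <- rownames(m$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("ap", res), collapse = "\t"), con)
  for (r in seq_along(res)) {
    writeLines(paste(c(res[r], m$counts[r, ]), collapse = "\t"), con)
    ratio <- sprintf("%.2f", round_half_up(m$ratios[r, ], 2L))
    ratio[r] <- "-"
    writeLines(paste(c("", ratio), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the substitution matrix in long format
#'
#' One row per ordered residue pair with the count, reverse count, ratio,
#' p-value and call.
#'
#' @param m A `substitution_matrix` (significance optional).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_substitution_long <- function(m, path) {
  res <- rownames(m$counts)
  grid <- expand.grid(ap = res, np = res, stringsAsFactors = FALSE)
  grid <- grid[grid$ap != grid$np, c("np", "ap")]
  idx <- cbind(match(grid$ap, res), match(grid$np, res))
  df <- data.frame(
    from_np = grid$np, to_ap = grid$ap,
    count = m$counts[idx], reverse_count = t(m$counts)[idx],
    ratio = if (!is.null(m$ratios)) round_half_up(m$ratios[idx], 2L)
            else NA_real_,
    p = if (!is.null(m$pvalues)) m$pvalues[idx] else NA_real_,
    call = if (!is.null(m$calls)) m$calls[idx] else NA_character_,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-residue composition comparison between AP and NP members
#'
#' For each of the 20 residues: the mean and standard deviation of the
#' composition over the AP members and over the NP members, the two-sided
#' unpaired (Welch) and paired t-test p-values, and the direction call.
#' Degenerate inputs (zero variance of the paired differences) are flagged;
#' by convention their paired p is 1 when all differences are 0 and 0
#' otherwise.
#'
#' @param ap_comp,np_comp Numeric matrices, one row per ortholog pair and
#'   one column per residue composition feature (same column order). Row i
#'   of the two matrices must belong to the same pair.
#' @param alpha Significance level for the direction call.
#' @return Data frame with one row per residue (class
#'   `composition_comparison`).
#' @export
composition_tests <- function(ap_comp, np_comp, alpha = 0.05) {
  stopifnot(is.matrix(ap_comp), is.matrix(np_comp),
            identical(dim(ap_comp), dim(np_comp)))
  if (nrow(ap_comp) < 2L) {
    stop("composition_tests(): at least 2 pairs required")
  }
  residues <- colnames(ap_comp)
  if (is.null(residues)) residues <- as.character(seq_len(ncol(ap_comp)))
  rows <- lapply(seq_len(ncol(ap_comp)), function(j) {
    a <- ap_comp[, j]; b <- np_comp[, j]
    d <- a - b
    degenerate <- stats::sd(d) == 0
    p_paired <- if (degenerate) {
      if (all(d == 0)) 1 else 0
    } else {
      stats::t.test(a, b, paired = TRUE)$p.value
    }
    p_unpaired <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b, paired = FALSE)$p.value
    }
    direction <- if (p_paired < alpha) {
      if (mean(d) > 0) "increased-in-AP" else "decreased-in-AP"
    } else "ns"
    data.frame(residue = residues[j],
               mean_ap = mean(a), sd_ap = stats::sd(a),
               mean_np = mean(b), sd_np = stats::sd(b),
               p_unpaired = p_unpaired, p_paired = p_paired,
               degenerate = degenerate, direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("composition_comparison", "data.frame")
  out
}

#' Write a composition comparison table
#'
#' @param x A `composition_comparison` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
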