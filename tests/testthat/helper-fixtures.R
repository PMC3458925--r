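# Shared helpers: in-code fixtures and independent oracles.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

# Independent two-sided Fisher oracle: explicit enumeration of every 2x2
# table with the observed margins, probabilities from binomial
# coefficients (not dhyper), summing those not exceeding the observed
# table's probability (1e-7 relative tolerance for ties).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  probs <- exp(vapply(support, logp, numeric(1)))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Trapezoidal area under the empirical ROC curve (independent of the
# rank-sum implementation).
auc_trapezoid <- function(pos, neg) {
  pts <- roc_points(pos, neg)
  fpr <- c(0, pts$fpr)
  tpr <- c(0, pts$tpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Toy gapped alignment object for substitution counting.
toy_alignment <- function(a, b, id_a = "ap1", id_b = "np1") {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  both <- ca != "-" & cb != "-"
  structure(list(
    id_a = id_a, id_b = id_b, seq_a_gapped = a, seq_b_gapped = b,
    score = NA_real_, aligned_columns = sum(both),
    identical_columns = sum(both & ca == cb),
    identity_fraction = sum(both & ca == cb) / max(1, sum(both))),
    class = "pairwise_alignment")
}

# Random protein sequence from a uniform residue distribution.
random_seq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                collapse = "")

published_counts_path <- function() {
  system.file("extdata", "apnp_substitution_counts.tsv",
              package = "acidostab")
}
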