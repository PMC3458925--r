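# Synthetic AP/NP ortholog-pair generator. Emulates the statistical
# structure of real AP-NP ortholog sets -- paired sequences of 30-90%
# identity with controllable directional substitution biases and the
# resulting composition shifts -- so every pipeline stage is testable
# without external downloads. The mutation model is site-independent: a
# single global substitution rate plus multiplicative directional biases.

# Default background: the mean NP amino-acid composition observed across
# real AP-NP ortholog sets, normalized to sum to 1.
NP_BACKGROUND <- local({
  x <- c(A = 0.106, C = 0.010, D = 0.056, E = 0.066, F = 0.032, G = 0.083,
         H = 0.024, I = 0.059, K = 0.043, L = 0.098, M = 0.025, N = 0.029,
         P = 0.048, Q = 0.036, R = 0.073, S = 0.051, T = 0.046, V = 0.076,
         W = 0.011, Y = 0.027)
  x / sum(x)
})

#' Configuration for the synthetic ortholog-pair generator
#'
#' Defaults mirror the conditions of real non-redundant AP-NP ortholog
#' sets: 393 pairs, lengths drawn uniformly within the open (50, 600)
#' window, background composition equal to the observed mean NP
#' composition, and a per-site substitution rate of 0.3 (giving roughly
#' 70% identity, inside the 30-90% identity range of real pairs). Indels
#' are off by default.
#'
#' @param n_pairs Number of ortholog pairs.
#' @param length_range Inclusive integer bounds for NP sequence lengths.
#' @param background_composition Named 20-vector of residue probabilities
#'   summing to 1.
#' @param substitution_rate Per-site probability that the AP residue is
#'   redrawn.
#' @param bias_map Data frame with columns `from`, `to`, `multiplier`:
#'   multiplicative weights applied to the target-residue distribution in
#'   the NP -> AP direction (empty by default).
#' @param indel_rate Per-site single-indel probability (applied after
#'   substitutions; geometric extension).
#' @param indel_ext Geometric extension probability of an indel.
#' @param seed Integer seed.
#' @return Validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs = 393L,
                             length_range = c(51L, 599L),
                             background_composition = NP_BACKGROUND,
                             substitution_rate = 0.3,
                             bias_map = NULL,
                             indel_rate = 0, indel_ext = 0.3,
                             seed = 1L) {
  stopifnot(n_pairs >= 0L, length(length_range) == 2L)
  if (length_range[1L] > length_range[2L] || length_range[1L] < 1L) {
    stop("synthetic_config(): degenerate length range")
  }
  bg <- background_composition[AA20]
  if (anyNA(bg) || abs(sum(bg) - 1) > 1e-9 || any(bg < 0)) {
    stop("synthetic_config(): background composition must be a named ",
         "20-vector over the standard residues summing to 1")
  }
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1) {
    stop("synthetic_config(): rates must lie in [0, 1]")
  }
  if (!is.null(bias_map)) {
    stopifnot(all(c("from", "to", "multiplier") %in% names(bias_map)),
              all(bias_map$from %in% AA20), all(bias_map$to %in% AA20),
              all(bias_map$multiplier >= 0))
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 length_range = as.integer(length_range),
                 background_composition = bg,
                 substitution_rate = substitution_rate,
                 bias_map = bias_map,
                 indel_rate = indel_rate, indel_ext = indel_ext,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# 20x20 matrix of target-draw weights: row = NP (source) residue, col =
# candidate AP (target) residue. Background composition reweighted by the
# bias multipliers; the source residue itself is excluded so every
# substitution event changes the residue.
.target_weights <- function(cfg) {
  w <- matrix(rep(cfg$background_composition, each = 20L), 20L, 20L,
              dimnames = list(AA20, AA20))
  if (!is.null(cfg$bias_map)) {
    for (k in seq_len(nrow(cfg$bias_map))) {
      w[cfg$bias_map$from[k], cfg$bias_map$to[k]] <-
        w[cfg$bias_map$from[k], cfg$bias_map$to[k]] *
        cfg$bias_map$multiplier[k]
    }
  }
  diag(w) <- 0
  w / rowSums(w)
}

#' Generate synthetic AP-NP ortholog pairs
#'
#' Each NP sequence is drawn i.i.d. from the background composition; its AP
#' ortholog is derived by redrawing each site with probability
#' `substitution_rate` from the bias-reweighted background (the source
#' residue excluded, so every substitution event changes the residue).
#' Optional single-residue indels with geometric extension are applied
#' afterwards. The truth record stores, per pair, the true alignment and
#' the realized substitution counts, plus the realized per-residue
#' composition deltas.
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `synthetic_pairs`: `ap` and `np`
#'   (`protein_records`), and `truth` with `counts` (20x20 realized
#'   substitution matrix, AP rows x NP columns), `alignments` (true gapped
#'   alignments, AP row `"a"`), `composition_delta` (mean AP minus NP
#'   composition per residue) and `config`.
#' @export
generate_pairs <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  tw <- .target_weights(cfg)
  n <- cfg$n_pairs
  ap_seqs <- character(n)
  np_seqs <- character(n)
  counts <- matrix(0L, 20L, 20L, dimnames = list(AA20, AA20))
  alignments <- vector("list", n)
  comp_delta <- stats::setNames(numeric(20L), AA20)
  for (i in seq_len(n)) {
    L <- sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
    np <- sample(AA20, L, replace = TRUE,
                 prob = cfg$background_composition)
    ap <- np
    mut <- stats::runif(L) < cfg$substitution_rate
    for (s in which(mut)) {
      ap[s] <- sample(AA20, 1L, prob = tw[np[s], ])
    }
    ap_gapped <- ap
    np_gapped <- np
    if (cfg$indel_rate > 0) {
      res <- .apply_indels(ap, np, cfg)
      ap <- res$ap
      ap_gapped <- res$ap_gapped
      np_gapped <- res$np_gapped
    }
    both <- ap_gapped != "-" & np_gapped != "-"
    tab <- table(factor(ap_gapped[both], levels = AA20),
                 factor(np_gapped[both], levels = AA20))
    counts <- counts + matrix(as.integer(tab), 20L, 20L)
    ap_seqs[i] <- paste(ap, collapse = "")
    np_seqs[i] <- paste(np, collapse = "")
    alignments[[i]] <- structure(list(
      id_a = sprintf("AP_%04d", i), id_b = sprintf("NP_%04d", i),
      seq_a_gapped = paste(ap_gapped, collapse = ""),
      seq_b_gapped = paste(np_gapped, collapse = ""),
      score = NA_real_,
      aligned_columns = sum(ap_gapped != "-" & np_gapped != "-"),
      identical_columns = sum(ap_gapped == np_gapped & ap_gapped != "-"),
      identity_fraction = NA_real_), class = "pairwise_alignment")
    al <- alignments[[i]]
    alignments[[i]]$identity_fraction <-
      al$identical_columns / al$aligned_columns
    comp_delta <- comp_delta +
      (table(factor(ap, levels = AA20)) / length(ap) -
       table(factor(np, levels = AA20)) / length(np)) / n
  }
  structure(list(
    ap = protein_records(sprintf("AP_%04d", seq_len(n)), ap_seqs),
    np = protein_records(sprintf("NP_%04d", seq_len(n)), np_seqs),
    truth = list(counts = counts, alignments = alignments,
                 composition_delta = as.numeric(comp_delta),
                 config = cfg)
  ), class = "synthetic_pairs")
}

# Single-residue indels on the AP copy with geometric extension: deletions
# gap the AP row, insertions gap the NP row of the true alignment.
.apply_indels <- function(ap, np, cfg) {
  ap_g <- ap
  np_g <- np
  L <- length(ap)
  events <- which(stats::runif(L) < cfg$indel_rate)
  offset <- 0L
  for (s in events) {
    len <- 1L + stats::rgeom(1L, 1 - cfg$indel_ext)
    pos <- s + offset
    if (pos > length(ap_g)) break
    if (stats::runif(1) < 0.5) {
      span <- pos:min(pos + len - 1L, length(ap_g))
      ap_g[span] <- "-"
    } else {
      ins <- sample(AA20, len, replace = TRUE,
                    prob = cfg$background_composition)
      ap_g <- append(ap_g, ins, after = pos)
      np_g <- append(np_g, rep("-", len), after = pos)
      offset <- offset + len
    }
  }
  list(ap = ap_g[ap_g != "-"], ap_gapped = ap_g, np_gapped = np_g)
}

#' Write synthetic pairs to mate-paired FASTA plus a truth JSON
#'
#' @param sim A `synthetic_pairs` object.
#' @param prefix Output path prefix (`<prefix>_ap.fa`, `<prefix>_np.fa`,
#'   `<prefix>_truth.json`).
#' @return Written paths, invisibly.
#' @export
write_synthetic_pairs <- function(sim, prefix) {
  fa_ap <- paste0(prefix, "_ap.fa")
  fa_np <- paste0(prefix, "_np.fa")
  write_fasta(sim$ap, fa_ap)
  write_fasta(sim$np, fa_np)
  js <- paste0(prefix, "_truth.json")
  truth <- list(
    counts = as.data.frame(sim$truth$counts),
    composition_delta = stats::setNames(
      as.list(sim$truth$composition_delta), AA20),
    config = unclass(sim$truth$config)[
      c("n_pairs", "length_range", "substitution_rate", "indel_rate",
        "seed")])
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(fa_ap, fa_np, js))
}

#' Generate linearly separable scoring deltas
#'
#' Draws delta vectors over the ten scoring features such that a known
#' (planted) weight vector scores every oriented pair at least `margin`
#' before noise; Gaussian noise is then added and the deltas are clamped to
#' \[-1, 1\]. Used to exercise the hill-climbing trainer.
#'
#' @param n Number of pairs (0 gives an empty set).
#' @param margin Minimum planted score (> 0).
#' @param noise_sd Standard deviation of the additive noise.
#' @param seed Integer seed.
#' @param planted_weights The separating weight vector (default
#'   [published_weights()]).
#' @return An n x 10 delta matrix with attribute `planted_weights`.
#' @export
generate_separable_deltas <- function(n, margin = 0.2, noise_sd = 0.05,
                                      seed = 1L,
                                      planted_weights = published_weights()) {
  if (margin <= 0) stop("generate_separable_deltas(): margin must be > 0")
  set.seed(as.integer(seed))
  nf <- length(planted_weights)
  out <- matrix(numeric(0), 0L, nf,
                dimnames = list(NULL, names(planted_weights)))
  while (nrow(out) < n) {
    d <- stats::runif(nf, -1, 1)
    s <- sum(planted_weights * d)
    if (s < 0) {
      d <- -d
      s <- -s
    }
    if (s >= margin) {
      d <- pmin(1, pmax(-1, d + stats::rnorm(nf, 0, noise_sd)))
      out <- rbind(out, d)
    }
  }
  rownames(out) <- NULL
  attr(out, "planted_weights") <- planted_weights
  out
}
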