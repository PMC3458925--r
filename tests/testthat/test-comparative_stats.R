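test_that("substitution counting walks columns, skipping gaps and ambiguity", {
  m <- count_substitutions(list(toy_alignment("AC-T", "ADGT")), ap_row = "a")
  expect_equal(m$counts["A", "A"], 1L)
  expect_equal(m$counts["C", "D"], 1L)
  expect_equal(m$counts["T", "T"], 1L)
  expect_equal(m$total, 3L)

  empty <- count_substitutions(list(), ap_row = character(0))
  expect_true(all(empty$counts == 0L))

  amb <- count_substitutions(list(toy_alignment("AXC", "AAC")), ap_row = "a")
  expect_equal(amb$total, 2L) # X column skipped

  # role labels flip the matrix orientation
  flipped <- count_substitutions(list(toy_alignment("AC", "AD")), ap_row = "b")
  expect_equal(flipped$counts["D", "C"], 1L)
  expect_error(count_substitutions(list(toy_alignment("AC", "AD"))),
               "labeled")
})

test_that("conservation invariant: totals and marginals account for every column", {
  sim <- generate_pairs(synthetic_config(n_pairs = 8L,
                                         length_range = c(80L, 120L),
                                         substitution_rate = 0.3,
                                         seed = 2L))
  m <- count_substitutions(sim$truth$alignments, ap_row = "a")
  expect_equal(m$total, sum(vapply(sim$truth$alignments,
                                   function(a) a$aligned_columns,
                                   numeric(1))))
  # row marginal of r = AP occurrences of r; column marginal = NP occurrences
  ap_chars <- table(factor(strsplit(paste(sim$ap$sequence, collapse = ""),
                                    "")[[1]], levels = AA20))
  np_chars <- table(factor(strsplit(paste(sim$np$sequence, collapse = ""),
                                    "")[[1]], levels = AA20))
  expect_equal(unname(rowSums(m$counts)), as.numeric(ap_chars))
  expect_equal(unname(colSums(m$counts)), as.numeric(np_chars))
})

test_that("ratios are transpose-reciprocal with documented edge cases", {
  cnt <- matrix(0L, 20, 20, dimnames = list(AA20, AA20))
  cnt["A", "C"] <- 8L; cnt["C", "A"] <- 2L
  cnt["D", "E"] <- 5L; cnt["E", "D"] <- 5L
  cnt["F", "G"] <- 3L # reverse zero
  m <- substitution_ratios(structure(
    list(counts = cnt, total = sum(cnt), total_offdiag = sum(cnt)),
    class = "substitution_matrix"))
  expect_equal(m$ratios["A", "C"], 4)
  expect_equal(m$ratios["C", "A"], 0.25)
  expect_equal(m$ratios["D", "E"], 1)
  expect_true(is.infinite(m$ratios["F", "G"]))
  expect_equal(m$ratios["G", "F"], 0)
  expect_true(is.nan(m$ratios["H", "K"])) # 0/0 undefined
  expect_equal(unname(diag(m$ratios)), rep(1, 20))
  # antisymmetry wherever both counts positive
  pos <- cnt > 0 & t(cnt) > 0
  expect_equal(unname(m$ratios[pos] * t(m$ratios)[pos]), rep(1, sum(pos)))
})

test_that("Fisher p-values equal brute-force hypergeometric enumeration", {
  set.seed(31)
  cases <- cbind(a = sample(0:500, 40, TRUE), b = sample(0:500, 40, TRUE),
                 c = sample(0:500, 40, TRUE), d = sample(0:500, 40, TRUE))
  cases <- rbind(cases, c(8, 992, 2, 998), c(0, 10, 10, 0), c(0, 0, 0, 5),
                 c(1, 1, 1, 1))
  for (i in seq_len(nrow(cases))) {
    p_pkg <- fisher_exact2x2(cases[i, 1], cases[i, 2], cases[i, 3],
                             cases[i, 4])
    p_oracle <- fisher_oracle(cases[i, 1], cases[i, 2], cases[i, 3],
                              cases[i, 4])
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  }
  # and against the stock R implementation
  for (i in 1:10) {
    tab <- matrix(cases[i, ], 2, byrow = TRUE)
    expect_equal(fisher_exact2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("significance calls are symmetric, directional, and vanish for symmetric counts", {
  cnt <- matrix(50L, 20, 20, dimnames = list(AA20, AA20))
  m <- substitution_ratios(structure(
    list(counts = cnt, total = sum(cnt), total_offdiag = sum(cnt) - 1000L),
    class = "substitution_matrix"))
  for (cons in c("ap_conditional", "equal_margins", "source_rate")) {
    ms <- substitution_significance(m, construction = cons)
    expect_equal(substitution_summary(ms)$n_significant, 0L)
    expect_true(all(ms$calls == "ns"))
  }

  # strong asymmetry is called in the direction of the larger count
  cnt2 <- cnt
  cnt2["D", "N"] <- 2000L; cnt2["N", "D"] <- 50L
  m2 <- structure(list(counts = cnt2, total = sum(cnt2),
                       total_offdiag = sum(cnt2) - sum(diag(cnt2))),
                  class = "substitution_matrix")
  ms2 <- substitution_significance(m2, construction = "equal_margins")
  expect_equal(ms2$calls["D", "N"], "forward")
  expect_equal(ms2$calls["N", "D"], "reverse")
  expect_equal(unname(ms2$pvalues["D", "N"]), unname(ms2$pvalues["N", "D"]))
  expect_true(all(diag(ms2$calls) == "ns"))
  expect_error(substitution_significance(m2, alpha = 2), "alpha")
})

test_that("matrix writers reproduce the two-line layout and long format", {
  m <- read_substitution_counts(published_counts_path())
  m <- substitution_ratios(m)
  m <- substitution_significance(m)
  f <- tempfile(fileext = ".tsv")
  write_substitution_matrix(m, f)
  lines <- readLines(f)
  expect_equal(length(lines), 1 + 2 * 20)
  expect_match(lines[1], "^ap\t")
  t_row <- strsplit(lines[which(startsWith(lines, "T\t"))], "\t")[[1]]
  t_ratio <- strsplit(lines[which(startsWith(lines, "T\t")) + 1], "\t")[[1]]
  a_col <- which(strsplit(lines[1], "\t")[[1]] == "A")
  expect_equal(t_row[a_col], "488")
  expect_equal(t_ratio[a_col], "1.16")

  f2 <- tempfile(fileext = ".tsv")
  write_substitution_long(m, f2)
  long <- utils::read.delim(f2)
  expect_equal(nrow(long), 380L)
  row <- long[long$to_ap == "T" & long$from_np == "A", ]
  expect_equal(row$count, 488L)
  expect_equal(row$reverse_count, 420L)
  expect_equal(row$ratio, 1.16)
})

test_that("composition tests recover the paired t-test and its degeneracies", {
  # paired differences (1, 2, 3): t = mean/(sd/sqrt(n)) = 3.4641, df = 2
  ap <- matrix(c(1, 3, 6), ncol = 1, dimnames = list(NULL, "x_A"))
  np <- matrix(c(0, 1, 3), ncol = 1, dimnames = list(NULL, "x_A"))
  res <- composition_tests(ap, np)
  t_hand <- mean(c(1, 2, 3)) / (sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(res$p_paired, 2 * stats::pt(-t_hand, df = 2))
  expect_equal(res$p_paired, 0.0742, tolerance = 1e-3)
  expect_false(res$degenerate)

  # constant shift: all differences equal -> degenerate, p 0
  ap2 <- matrix(c(1, 2, 3), ncol = 1)
  np2 <- matrix(c(0, 1, 2), ncol = 1)
  res2 <- composition_tests(ap2, np2)
  expect_true(res2$degenerate)
  expect_equal(res2$p_paired, 0)

  # identical vectors -> degenerate, p 1, ns
  res3 <- composition_tests(ap2, ap2)
  expect_equal(res3$p_paired, 1)
  expect_equal(res3$direction, "ns")

  expect_error(composition_tests(ap[1, , drop = FALSE],
                                 np[1, , drop = FALSE]), "at least 2")
})

test_that("composition comparison on simulated shifted pairs finds the shift", {
  # D enriched and N depleted as substitution targets across all sources
  up <- expand.grid(from = AA20, to = "D", stringsAsFactors = FALSE)
  up$multiplier <- 8
  down <- expand.grid(from = AA20, to = "N", stringsAsFactors = FALSE)
  down$multiplier <- 0.1
  bias <- rbind(up, down)
  bias <- bias[bias$from != bias$to, ]
  sim <- generate_pairs(synthetic_config(
    n_pairs = 60L, length_range = c(150L, 250L), substitution_rate = 0.25,
    bias_map = bias, seed = 9L))
  ap_m <- compute_feature_matrix(sim$ap)
  np_m <- compute_feature_matrix(sim$np)
  cols <- paste0("x_", AA20)
  res <- composition_tests(ap_m[, cols], np_m[, cols])
  d_row <- res[res$residue == "x_D", ]
  n_row <- res[res$residue == "x_N", ]
  expect_equal(d_row$direction, "increased-in-AP")
  expect_equal(n_row$direction, "decreased-in-AP")
  expect_true(all(res$mean_ap >= 0 & res$mean_ap <= 1))
  expect_true(all(res$sd_ap >= 0))
  f <- tempfile(fileext = ".tsv")
  write_composition_table(res, f)
  expect_equal(nrow(utils::read.delim(f)), 20L)
})
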