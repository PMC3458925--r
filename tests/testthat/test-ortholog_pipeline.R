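hits_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               evalue = as.numeric(r[[3]]),
               percent_identity = if (length(r) > 3) as.numeric(r[[4]]) else 50,
               stringsAsFactors = FALSE)
  }))
}

test_that("reciprocal best hits require mutual best and the e-value cutoff", {
  ab <- hits_df(list("a1", "b1", 1e-50), list("a1", "b2", 1e-20))
  ba <- hits_df(list("b1", "a1", 1e-48))
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(rbh$id_a, "a1")
  expect_equal(rbh$id_b, "b1")
  expect_equal(rbh$evalue_ab, 1e-50)

  # non-reciprocal
  ba2 <- hits_df(list("b1", "a2", 1e-60))
  expect_equal(nrow(reciprocal_best_hits(ab, ba2)), 0L)

  # both e-values must beat the threshold
  ab3 <- hits_df(list("a1", "b1", 1e-5))
  ba3 <- hits_df(list("b1", "a1", 1e-5))
  expect_equal(nrow(reciprocal_best_hits(ab3, ba3, evalue_max = 1e-10)), 0L)
  expect_equal(nrow(reciprocal_best_hits(ab3, ba3, evalue_max = 1e-3)), 1L)

  expect_equal(nrow(reciprocal_best_hits(ab[0, ], ba[0, ])), 0L)
})

test_that("best-hit ties break by identity then lexical subject id", {
  ab <- hits_df(list("a1", "b2", 1e-50, 40), list("a1", "b1", 1e-50, 60))
  ba <- hits_df(list("b1", "a1", 1e-50, 60))
  expect_equal(reciprocal_best_hits(ab, ba)$id_b, "b1") # higher identity
  ab2 <- hits_df(list("a1", "b2", 1e-50, 50), list("a1", "b1", 1e-50, 50))
  ba2 <- hits_df(list("b1", "a1", 1e-50, 50))
  expect_equal(reciprocal_best_hits(ab2, ba2)$id_b, "b1") # lexical
})

test_that("length and similarity filters use strict inequalities", {
  cand <- data.frame(id_ap = c("a", "b", "c"), id_np = c("x", "y", "z"),
                     len_ap = c(100L, 100L, 100L),
                     len_np = c(106L, 104L, 104L),
                     similarity = c(45, 45, 30))
  kept <- filter_pairs(cand)
  expect_equal(kept$id_ap, "b") # 6 >= 5.0 rejected; sim 30 not > 30 rejected
})

test_that("membrane removal drops a pair when either member matches", {
  pairs <- data.frame(id_ap = c("a1", "a2"), id_np = c("n1", "n2"),
                      stringsAsFactors = FALSE)
  expect_equal(remove_membrane_proteins(pairs, character(0)), pairs)
  expect_equal(nrow(remove_membrane_proteins(pairs, "a1")), 1L)
  expect_equal(remove_membrane_proteins(pairs, "n2")$id_ap, "a1")
})

test_that("length window keeps strictly inside (50, 600)", {
  recs <- protein_records(
    c("short", "edge50", "ok51", "ok599", "edge600"),
    vapply(c(10L, 50L, 51L, 599L, 600L),
           function(n) strrep("A", n), character(1)))
  kept <- length_window(recs)
  expect_equal(kept$id, c("ok51", "ok599"))
})

test_that("redundancy clustering collapses duplicate groups via single linkage", {
  set.seed(21)
  s1 <- random_seq(80); s2 <- random_seq(80); s3 <- random_seq(80)
  # two pairs with identical AP sequences -> one survivor
  pairs <- data.frame(
    id_ap = c("a1", "a2"), id_np = c("n1", "n2"),
    seq_ap = c(s1, s1), seq_np = c(s2, s3),
    evalue_ab = c(1e-40, 1e-60), evalue_ba = c(1e-40, 1e-60),
    stringsAsFactors = FALSE)
  kept <- cluster_redundancy(pairs)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$id_ap, "a2") # smaller e-value retained

  # all-dissimilar pairs -> both retained
  pairs2 <- pairs
  pairs2$seq_ap <- c(s1, random_seq(80))
  expect_equal(nrow(cluster_redundancy(pairs2)), 2L)

  # chaining: pair1-pair2 share a sequence, pair2-pair3 share one, 1 and 3
  # do not -> one cluster, one survivor (single-linkage transitivity)
  s4 <- random_seq(80)
  pairs3 <- data.frame(
    id_ap = c("a1", "a2", "a3"), id_np = c("n1", "n2", "n3"),
    seq_ap = c(s1, s1, s4), seq_np = c(s2, s4, s3),
    evalue_ab = c(1e-10, 1e-20, 1e-30),
    evalue_ba = c(1e-10, 1e-20, 1e-30), stringsAsFactors = FALSE)
  kept3 <- cluster_redundancy(pairs3)
  expect_equal(nrow(kept3), 1L)
  expect_equal(kept3$id_ap, "a3")
})

test_that("the full pipeline runs on synthetic proteomes and reports monotone counts", {
  sim <- generate_pairs(synthetic_config(n_pairs = 6L,
                                         length_range = c(60L, 90L),
                                         substitution_rate = 0.25,
                                         seed = 33L))
  res <- build_ortholog_pairs(sim$ap, sim$np)
  counts <- unlist(res$report[c("n_rbh", "n_filtered",
                                "n_membrane_removed", "n_clustered",
                                "n_final")])
  expect_true(all(diff(counts) <= 0))
  expect_gt(res$report$n_final, 0L)
  p <- res$pairs
  # final pairs satisfy all pair invariants simultaneously
  expect_true(all(abs(p$len_ap - p$len_np) < 0.05 * pmin(p$len_ap, p$len_np)))
  expect_true(all(p$similarity > 30))
  expect_true(all(p$len_ap > 50 & p$len_ap < 600))
  # with distinct random pairs, the true mates should be recovered
  expect_true(all(sub("AP", "", p$id_ap) == sub("NP", "", p$id_np)))

  # input order does not change the surviving set
  res2 <- build_ortholog_pairs(sim$ap[rev(seq_len(6)), ], sim$np)
  expect_equal(sort(res2$pairs$id_ap), sort(p$id_ap))

  # writer produces mate-paired FASTA + TSV + JSON report
  prefix <- tempfile()
  files <- write_ortholog_pairs(res, prefix)
  expect_true(all(file.exists(files)))
  ap_back <- read_fasta(files[1])
  expect_equal(ap_back$id, p$id_ap)
  rep_back <- jsonlite::read_json(files[4])
  expect_equal(rep_back$n_final, res$report$n_final)
})

test_that("membrane ids and precomputed hits are honored end to end", {
  sim <- generate_pairs(synthetic_config(n_pairs = 3L,
                                         length_range = c(60L, 70L),
                                         substitution_rate = 0.2,
                                         seed = 5L))
  res_all <- build_ortholog_pairs(sim$ap, sim$np)
  res_mem <- build_ortholog_pairs(sim$ap, sim$np,
                                  membrane_ids = res_all$pairs$id_ap[1])
  expect_equal(res_mem$report$n_membrane_removed,
               res_all$report$n_membrane_removed - 1L)
})
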