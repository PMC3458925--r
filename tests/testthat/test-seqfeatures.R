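test_that("catalogue has the documented size, groups and native subset", {
  cat_df <- feature_catalogue()
  expect_equal(nrow(cat_df), 889L)
  expect_equal(sum(cat_df$computable == "native"), 871L)
  expect_equal(sum(cat_df$computable == "external"), 18L)
  expect_false(anyDuplicated(cat_df$name) > 0)
  sizes <- as.integer(table(factor(cat_df$group, levels = unique(cat_df$group))))
  expect_equal(sizes, c(1L, 40L, 800L, 8L, 12L, 2L, 1L, 1L, 2L, 2L, 1L, 1L,
                        6L, 4L, 6L, 1L, 1L))
  expect_equal(sum(sizes), 889L)
  # dipeptide group is 400 counts + 400 compositions
  dip <- cat_df$name[cat_df$group == "Dipeptide counts and composition"]
  expect_equal(sum(startsWith(dip, "c_")), 400L)
  expect_equal(sum(startsWith(dip, "x_")), 400L)
})

test_that("feature values on tiny sequences match direct computation", {
  fv <- compute_features("AAA")
  expect_equal(unname(fv["x_A"]), 1.0)
  expect_equal(unname(fv["c_AA"]), 2)
  expect_equal(unname(fv["x_AA"]), 1.0)
  expect_equal(unname(fv["gravy"]), 1.8)

  fv2 <- compute_features("ACDC")
  expect_equal(unname(fv2["c_sulfide"]), 2) # two Cys, no Met
  expect_equal(unname(fv2["net_charge"]), -1)

  cf <- category_features("TD")
  expect_equal(unname(cf["c_small"]), 2)
  expect_equal(unname(cf["x_small"]), 1.0)
  cf2 <- category_features("GASP")
  expect_equal(unname(cf2["c_tiny"]), 4)
  expect_equal(unname(cf2["x_tiny"]), 1.0)
  cf3 <- category_features("FHYW")
  expect_equal(unname(cf3["x_aromatic"]), 1.0)
  expect_equal(unname(cf3["x_hbond"]), 0.75) # H, Y, W but not F
})

test_that("composition features sum to 1 and tie counts to fractions", {
  set.seed(11)
  for (L in c(2, 17, 120)) {
    s <- random_seq(L)
    fv <- compute_features(s)
    expect_equal(sum(fv[paste0("x_", AA20)]), 1, tolerance = 1e-9)
    dip <- paste0("x_", paste0(rep(AA20, each = 20), AA20))
    expect_equal(sum(fv[dip]), 1, tolerance = 1e-9)
    # every c_ feature equals x_ times its denominator
    expect_equal(unname(fv[paste0("c_", AA20)]),
                 unname(fv[paste0("x_", AA20)]) * L)
    cdip <- sub("x_", "c_", dip)
    expect_equal(unname(fv[cdip]), unname(fv[dip]) * (L - 1))
    expect_true(all(fv[c(paste0("x_", AA20), dip)] >= 0 &
                    fv[c(paste0("x_", AA20), dip)] <= 1))
  }
})

test_that("concatenation adds counts plus one boundary dipeptide", {
  set.seed(12)
  s <- random_seq(25); t <- random_seq(31)
  fs <- compute_features(s); ft <- compute_features(t)
  fst <- compute_features(paste0(s, t))
  expect_equal(fst[paste0("c_", AA20)],
               fs[paste0("c_", AA20)] + ft[paste0("c_", AA20)])
  cdip <- paste0("c_", paste0(rep(AA20, each = 20), AA20))
  boundary <- paste0("c_", substr(s, 25, 25), substr(t, 1, 1))
  expected <- fs[cdip] + ft[cdip]
  expected[boundary] <- expected[boundary] + 1
  expect_equal(fst[cdip], expected)
})

test_that("permuting a sequence changes only dipeptide and order-dependent features", {
  set.seed(13)
  s <- random_seq(60)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  f1 <- compute_features(s); f2 <- compute_features(perm)
  single <- c("length", paste0("c_", AA20), paste0("x_", AA20),
              "c_positive", "net_charge", "c_small", "x_tiny", "c_sulfide",
              "asa_max_mean", "pI", "pIa", "aliphatic_index", "gravy")
  expect_equal(f1[single], f2[single])
})

test_that("ProtParam-style indices match reference values", {
  # frozen against an independent implementation of the same published
  # formulas (sequences avoid residue-specific terminal pKa adjustments)
  pp <- protparam_indices("KLVANMWGRLCDEHYTQFISPG")
  expect_equal(pp$instability_index, 35.531818, tolerance = 1e-6)
  expect_equal(pp$gravy, -0.290909, tolerance = 1e-6)
  expect_equal(pp$pI, 6.742, tolerance = 1e-2)
  expect_equal(pp$instability_class, "stable")

  pp2 <- protparam_indices("GAVLIPFMWSTCYNQDEKRH")
  expect_equal(pp2$instability_index, 45.235, tolerance = 1e-6)
  expect_equal(pp2$instability_class, "unstable")

  expect_equal(protparam_indices(strrep("A", 10))$aliphatic_index, 100)
  expect_equal(protparam_indices(strrep("V", 10))$aliphatic_index, 290)
  expect_error(protparam_indices("XXX"), "standard residues")
})

test_that("ambiguity codes are skipped in numerators but kept in length", {
  fv <- compute_features("ACXDE")
  expect_equal(unname(fv["length"]), 5)
  expect_equal(unname(fv["c_A"]), 1)
  expect_equal(unname(fv["x_A"]), 1 / 5)
  # dipeptides AC and DE only; CX and XD skipped
  expect_equal(unname(fv["c_AC"]), 1)
  expect_equal(unname(fv["c_DE"]), 1)
  cdip <- paste0("c_", paste0(rep(AA20, each = 20), AA20))
  expect_equal(sum(fv[cdip]), 2)
})

test_that("external features are ingested, never computed", {
  fv <- compute_features("ACDEF")
  expect_true(all(is.na(fv[c("c_helix", "rsa_mean", "zfit_mean")])))
  fv2 <- compute_features("ACDEF", external = c(rsa_mean = 0.37))
  expect_equal(unname(fv2["rsa_mean"]), 0.37)
  expect_error(compute_features("ACDEF", external = c(x_A = 1)),
               "unknown external")
})

test_that("feature matrix writer preserves values and empty externals", {
  recs <- read_fasta(write_tmp_fasta(c(">p1", "MKVLYAANDE", ">p2", "GGHHWWTT")))
  m <- compute_feature_matrix(recs)
  expect_equal(rownames(m), c("p1", "p2"))
  f <- tempfile(fileext = ".tsv")
  write_feature_matrix(m, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$x_M[1], unname(m["p1", "x_M"]))
  expect_true(is.na(back$rsa_mean[1]))
})
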