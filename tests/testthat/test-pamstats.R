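# Weighted PFMs, PCV tables, the heat-map grid and the wobble comparison.

test_that("read weights shape the PFM as hand-computed", {
  sites <- make_sites(flank3 = c("AGGTACGTAC", "TGGTACGTAC"), reads = c(1, 3))
  pfm <- weighted_pfm(sites, "three_prime", "all", "reads")
  expect_equal(pfm$matrix["A", 1], 0.25)
  expect_equal(pfm$matrix["T", 1], 0.75)
  expect_true(all(abs(colSums(pfm$matrix) - 1) < 1e-9))
  # equal weights reduce to the unweighted flank PFM
  eq <- make_sites(flank3 = c("AGGTACGTAC", "TGGTACGTAC"), reads = c(2, 2))
  expect_equal(weighted_pfm(eq, "three_prime", "all", "reads")$matrix,
               flank_diversity(eq$flank3)$pfm,
               ignore_attr = TRUE)
  # identical flanks are one-hot whatever the weights
  oh <- make_sites(flank3 = rep("AGGTACGTAC", 3), reads = c(1, 10, 100))
  expect_true(all(weighted_pfm(oh, "three_prime")$matrix %in% c(0, 1)))
  expect_error(weighted_pfm(make_sites("AGGTACGTAC", 2), "three_prime",
                            "mismatch"), "mismatch")
})

test_that("site-count and read weighting agree when all reads are equal", {
  fl <- rand_flanks(11, 30)
  a <- make_sites(fl, reads = rep(5, 30))
  expect_equal(weighted_pfm(a, "three_prime", weight_mode = "reads")$matrix,
               weighted_pfm(a, "three_prime", weight_mode = "sites")$matrix)
})

test_that("PCV reproduces the hand-worked enrichment example", {
  # captured 75% AG / 25% AA against a uniform background over 4 dinucleotides
  sites <- make_sites(flank3 = c("AGGGGGGGGG", "AAGGGGGGGG"), reads = c(3, 1))
  bg <- c("AA", "AG", "CA", "GT")
  pcv <- pcv_table(sites, bg, L = 2, orientation = "three_prime")
  expect_equal(pcv$pcv[pcv$pam == "AG"], 3.0)
  expect_equal(pcv$pcv[pcv$pam == "AA"], 1.0)
  expect_equal(pcv$relative_pcv[pcv$pam == "AG"], 0)
  expect_equal(pcv$relative_pcv[pcv$pam == "AA"], log2(1 / 3))
  # uncaptured background PAMs get zero captured fraction and -Inf relative
  expect_equal(pcv$captured_fraction[pcv$pam == "CA"], 0)
  expect_identical(pcv$relative_pcv[pcv$pam == "CA"], -Inf)
})

test_that("PCV is the identity when capture mirrors the background", {
  fl <- c("AAGGGGGGGG", "ACGGGGGGGG", "AGGGGGGGGG", "ATGGGGGGGG")
  sites <- make_sites(fl, reads = c(2, 2, 2, 2))
  bg <- substr(fl, 1, 2)
  pcv <- pcv_table(sites, bg, L = 2, orientation = "three_prime")
  expect_true(all(abs(pcv$pcv - 1) < 1e-12))
  expect_true(all(pcv$relative_pcv == 0))
})

test_that("PCV table invariants hold on simulated capture", {
  cfg <- sim_config(seed = 41, n_perfect_targets = 1500,
                    n_mismatch_targets = 0)
  truth <- sim_truth(cfg)
  sites <- sim_capture(truth, cfg)
  tpl <- sim_templates(truth)
  pcv <- pcv_table(sites, pam_flank(tpl, "three_prime"), L = 3,
                   orientation = "three_prime")
  expect_equal(sum(pcv$captured_fraction), 1)
  expect_equal(sum(pcv$background_fraction), 1)
  defined <- !pcv$undefined
  expect_equal(sum(pcv$background_fraction[defined] * pcv$pcv[defined]), 1,
               tolerance = 1e-6)
  expect_equal(max(pcv$relative_pcv[defined & is.finite(pcv$relative_pcv)]), 0)
  # read-scale invariance
  scaled <- sites
  scaled$read_count <- scaled$read_count * 7L
  pcv2 <- pcv_table(scaled, pam_flank(tpl, "three_prime"), L = 3,
                    orientation = "three_prime")
  expect_equal(pcv$pcv, pcv2$pcv)
  # planted NGG: the top-PCV 3-mers are exactly the NGG quartet
  top <- pcv$pam[defined][order(-pcv$pcv[defined])][1:4]
  expect_setequal(top, c("AGG", "CGG", "GGG", "TGG"))
})

test_that("the 4-base heat map reshapes the PCV table bijectively", {
  fl <- rand_flanks(17, 600)
  sites <- make_sites(fl, reads = rep(1, 600))
  pcv <- pcv_table(sites, fl, L = 4, orientation = "three_prime")
  hm <- heatmap_matrix(pcv)
  expect_identical(dim(hm), c(16L, 16L))
  # identity capture: every defined cell is 0
  expect_true(all(hm[!is.na(hm)] == 0))
  # round-trip: each table row lands in its (pos12, pos34) cell
  for (i in sample(nrow(pcv), 25)) {
    r <- substr(pcv$pam[i], 1, 2)
    cc <- substr(pcv$pam[i], 3, 4)
    if (!pcv$undefined[i])
      expect_identical(hm[r, cc], pcv$relative_pcv[i])
  }
  # a single dominant PAM owns the unique zero
  dom <- make_sites(rep("AGGTACGTAC", 5), reads = rep(10, 5))
  pcv2 <- pcv_table(dom, fl, L = 4, orientation = "three_prime")
  hm2 <- heatmap_matrix(pcv2)
  expect_identical(hm2["AG", "GT"], 0)
  expect_true(all(hm2[is.finite(hm2) & !is.na(hm2)] <= 0))
  expect_error(heatmap_matrix(pcv_table(dom, fl, L = 3, "three_prime")),
               "L = 4")
})

test_that("wobble comparison matches the textbook 2x2 chi-square", {
  # identical composition across strata: equal fractions, p = 1
  fl <- rep(c("AGGTACGTAC", "AGGTACGTAC", "TGGTACGTAC", "TGGTACGTAC"), 2)
  s <- make_sites(fl, reads = rep(2, 8),
                  n_mismatch = c(rep(0, 4), rep(1, 4)))
  w <- wobble_comparison(s, position = 1, base = "A", "three_prime")
  expect_equal(w$perfect_frac, w$mismatch_frac)
  expect_gt(w$p_value, 0.99)
  # 10/100 vs 60/100 G at position 1: strong enrichment
  f_perf <- c(rep("GAAAAAAAAA", 10), rep("CAAAAAAAAA", 90))
  f_mm <- c(rep("GAAAAAAAAA", 60), rep("CAAAAAAAAA", 40))
  s2 <- make_sites(c(f_perf, f_mm), reads = rep(1, 200),
                   n_mismatch = c(rep(0, 100), rep(1, 100)))
  s2$start <- seq_len(200) * 60L   # keep keys unique
  s2$end <- s2$start + 20L
  s2 <- site_table(as.data.frame(s2))
  w2 <- wobble_comparison(s2, position = 1, base = "G", "three_prime")
  M <- rbind(c(10, 90), c(60, 40))
  orc <- oracle_chisq(M)
  expect_equal(w2$chi2, orc$chi2)
  expect_equal(w2$p_value, orc$p)
  expect_lt(w2$p_value, 0.01)
  expect_error(wobble_comparison(make_sites("AGGTACGTAC", 1), 2, "G"),
               "strata")
})
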