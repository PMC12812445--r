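# The edited-value statistic, the window chi-square, printed percentages,
# and the iterative seed-extension motif table.

test_that("edited values blend reads into the site-count range", {
  # reads proportional to sites carry no extra contrast: values = site counts
  ev <- edited_value(c(10, 40), c(1000, 4000))
  expect_equal(attr(ev, "scale_factor"), 0.01)
  expect_equal(max(ev$scaled_reads), max(ev$site_count))
  expect_equal(ev$value, c(10, 40))
  expect_equal(max(ev$value), max(ev$site_count))
  # anti-proportional reads pull the low-site motif up to the cap
  ev1 <- edited_value(c(10, 40), c(4000, 1000))
  expect_equal(ev1$value, c(40, 40))
  # reads numerically equal to sites reduce to the site counts
  ev2 <- edited_value(c(3, 7), c(3, 7))
  expect_equal(ev2$value, c(3, 7))
  # degenerate single motif
  ev3 <- edited_value(5, 50)
  expect_equal(attr(ev3, "scale_factor"), 0.1)
  expect_equal(ev3$value, 5)
  expect_warning(ev4 <- edited_value(c(4, 2), c(0, 0)), "zero")
  expect_equal(ev4$value, c(4, 2))
})

test_that("window chi-square agrees with the textbook oracle", {
  # null: edited proportional to background
  null <- window_chi_square(c(10, 20, 30, 40), c(100, 200, 300, 400))
  expect_lt(null$chi2, 1e-9)
  expect_gt(null$p_value, 0.999)
  # randomized tables up to 2 x 6
  set.seed(99)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    bg <- sample(50:500, k)
    ed <- vapply(bg, function(b) sample.int(b, 1), integer(1))
    wc <- window_chi_square(ed, bg)
    orc <- oracle_chisq(rbind(ed, bg))
    expect_equal(wc$chi2, orc$chi2, tolerance = 1e-10)
    expect_equal(wc$p_value, orc$p, tolerance = 1e-10)
    expect_equal(wc$df, orc$df, ignore_attr = TRUE)
  }
  # sharp contrast on two motifs is significant
  sharp <- window_chi_square(c(10, 0), c(10, 10))
  expect_lt(sharp$p_value, 0.05)
  expect_true(is.finite(sharp$chi2))
  # all-zero columns are dropped with a warning
  expect_warning(dropped <- window_chi_square(c(5, 0, 8), c(10, 0, 10)),
                 "dropped")
  expect_identical(dropped$dropped, 2L)
  expect_identical(ncol(dropped$table), 2L)
})

test_that("printed percentages use half-up rounding to one decimal", {
  expect_identical(percent_edited(1103, 1681), 65.6)
  expect_identical(percent_edited(449, 477), 94.1)
  expect_identical(percent_edited(0, 100), 0)
  expect_identical(percent_edited(1, 16), 6.3)   # 6.25 rounds up, not to even
  expect_error(percent_edited(1, 0), "positive")
  expect_error(percent_edited(5, 4), "exceed")
})

test_that("a planted 3' GG PAM is recovered as GG at positions 2-3", {
  cfg <- sim_config(seed = 5, n_perfect_targets = 2000,
                    n_mismatch_targets = 500)
  truth <- sim_truth(cfg)
  sites <- sim_capture(truth, cfg)
  tab <- seed_extend(sites, sim_templates(truth), "three_prime")
  ret <- tab$retained
  expect_gte(nrow(ret), 2)
  expect_identical(ret$motif[1], "G")
  expect_true(ret$pos_lo[1] %in% 2:3)
  expect_identical(ret$motif[2], "GG")
  expect_identical(c(ret$pos_lo[2], ret$pos_hi[2]), c(2L, 3L))
  # no later step is retained: GG saturates the edited percentage
  expect_identical(nrow(ret), 2L)
})

test_that("uniform random flanks retain essentially nothing", {
  set.seed(77)
  fl <- rand_flanks(77, 1000)
  sites <- make_sites(fl, reads = rpois(1000, 50) + 1)
  bg <- make_templates(rand_flanks(78, 4000))
  tab <- seed_extend(sites, bg, "three_prime")
  expect_lte(nrow(tab$retained), 1)
  # the trace itself is still complete
  expect_identical(nrow(tab$steps), 10L)
})

test_that("a planted interior 4-mer grows to the full window", {
  # ACAC at PAM positions 5-8 of the 3' flank
  set.seed(31)
  n_bg <- 12000
  bg_fl <- rand_flanks(31, n_bg)
  hit <- substr(bg_fl, 5, 8) == "ACAC"
  # capture 90% of matching targets
  cap <- which(hit)[runif(sum(hit)) < 0.9]
  sites <- make_sites(bg_fl[cap], reads = rpois(length(cap), 80) + 1)
  tab <- seed_extend(sites, make_templates(bg_fl), "three_prime")
  ret <- tab$retained
  final <- ret[nrow(ret), ]
  expect_identical(final$motif, "ACAC")
  expect_identical(c(final$pos_lo, final$pos_hi), c(5L, 8L))
})

test_that("the trace is deterministic and respects containment/monotonicity", {
  cfg <- sim_config(seed = 9, n_perfect_targets = 1200,
                    n_mismatch_targets = 300)
  truth <- sim_truth(cfg)
  sites <- sim_capture(truth, cfg)
  tpl <- sim_templates(truth)
  t1 <- seed_extend(sites, tpl, "three_prime")
  t2 <- seed_extend(sites, tpl, "three_prime")
  expect_identical(t1$steps, t2$steps)
  # retained percentages strictly increase
  if (nrow(t1$retained) > 1)
    expect_true(all(diff(t1$retained$percent_edited) > 0))
  # each step's motif contains its predecessor at identical positions
  steps <- t1$steps
  for (r in 2:nrow(steps)) {
    prev <- steps[r - 1, ]; cur <- steps[r, ]
    expect_identical(cur$pos_hi - cur$pos_lo, prev$pos_hi - prev$pos_lo + 1L)
    expect_true(cur$pos_lo == prev$pos_lo - 1L || cur$pos_hi == prev$pos_hi + 1L)
    off <- prev$pos_lo - cur$pos_lo
    expect_identical(substr(cur$motif, off + 1, off + nchar(prev$motif)),
                     prev$motif)
  }
  # the full trace spans the whole PAM window
  expect_identical(nrow(steps), 10L)
  expect_identical(c(steps$pos_lo[10], steps$pos_hi[10]), c(1L, 10L))
})

test_that("adding reads to sites matching the best motif never lowers its value", {
  s <- c(40, 10, 5, 2)
  r <- c(4000, 900, 300, 100)
  v0 <- edited_value(s, r)$value
  best <- which.max(v0)
  r2 <- r
  r2[best] <- r2[best] + 500
  v1 <- edited_value(s, r2)$value
  expect_gte(v1[best], v0[best])
})

test_that("motif-table JSON serialization carries the trace and metadata", {
  cfg <- sim_config(seed = 15, n_perfect_targets = 800, n_mismatch_targets = 0)
  truth <- sim_truth(cfg)
  tab <- seed_extend(sim_capture(truth, cfg), sim_templates(truth))
  f <- withr::local_tempfile(fileext = ".json")
  write_genomepam_table(tab, f, meta = list(seed = 15))
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$meta$seed, 15L)
  expect_identical(back$steps$motif, tab$steps$motif)
  expect_equal(back$retained$percent_edited, tab$retained$percent_edited)
})
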