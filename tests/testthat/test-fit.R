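test_that("noiseless piecewise profiles are refit to machine precision", {
  # breaks placed on bin centres so the piecewise truth is in the model class
  for (geom in list(c(fcp = 300500, sl = 5e-7, sr = 5e-7),
                    c(fcp = 420500, sl = 4e-7, sr = 6e-7),
                    c(fcp = 650500, sl = 8e-7, sr = 3e-7))) {
    prof <- piecewise_v_profile(1e6, 1000, geom[["fcp"]],
                                geom[["sl"]], geom[["sr"]])
    seg <- replicon_segments(origin("chrV", 0), prof$replicon)
    fit <- fit_breakpoint(prof, seg[1, ])
    expect_lte(abs(fit$fcp_arc - geom[["fcp"]]), 500)  # half a bin
    expect_lt(abs(fit$left_slope + geom[["sl"]]), 1e-9)
    expect_lt(abs(fit$right_slope - geom[["sr"]]), 1e-9)
    expect_lt(fit$sse, 1e-12)
  }
})

test_that("symmetric V profiles put the fcp at the midpoint", {
  prof <- piecewise_v_profile(1e6, 1000, 500000, 5e-7, 5e-7)
  seg <- replicon_segments(origin("chrV", 0), prof$replicon)
  fit <- fit_breakpoint(prof, seg[1, ])
  expect_lte(abs(fit$fcp_arc - fit$mp_arc), 500)
  expect_lt(fit$fcp_mp_pct, 0.05001)
})

test_that("the scan matches an independent per-candidate lm oracle", {
  set.seed(99)
  rep <- replicon("chrV", 2e5)
  seg <- replicon_segments(origin("chrV", 0), rep)
  for (i in 1:5) {
    y <- ifelse(seq(500, 199500, by = 1000) <= 80000,
                0.4 - 2e-6 * seq(500, 199500, by = 1000),
                0.4 - 2e-6 * 80000 +
                  1.5e-6 * (seq(500, 199500, by = 1000) - 80000)) +
      rnorm(200, 0, 0.03)
    prof <- mk_profile(rep, 1000, y)
    fit <- fit_breakpoint(prof, seg[1, ])
    bins <- seq(500, 199500, by = 1000)
    idx <- which(bins > 5000 & bins < 195000 &
                 seq_along(bins) >= 5 & seq_along(bins) <= 196)
    orc <- oracle_two_piece(bins, y, idx)
    expect_equal(fit$fcp_arc, orc$break_x)
    expect_equal(fit$sse, orc$sse, tolerance = 1e-9)
  }
})

test_that("mirroring a profile mirrors the fitted fcp", {
  set.seed(21)
  rep <- replicon("chrV", 5e5)
  s <- seq(500, 499500, by = 1000)
  y <- ifelse(s <= 180000, 0.5 - 1.5e-6 * s,
              0.5 - 1.5e-6 * 180000 + 1.2e-6 * (s - 180000)) +
    rnorm(length(s), 0, 0.02)
  seg <- replicon_segments(origin("chrV", 0), rep)
  f <- fit_breakpoint(mk_profile(rep, 1000, y), seg[1, ])
  f_m <- fit_breakpoint(mk_profile(rep, 1000, rev(y)), seg[1, ])
  expect_lte(abs((5e5 - f_m$fcp_arc) - f$fcp_arc), 1000)
})

test_that("breakpoint preconditions are enforced", {
  prof <- piecewise_v_profile(1e6, 1000, 500000, 5e-7, 5e-7)
  tiny_seg <- list(left_origin = "a", right_origin = "b", left_pos = 0,
                   right_pos = 5000, arc_length = 5000, mp = 2500)
  expect_error(fit_breakpoint(prof, tiny_seg), "shorter than 10 bins")
  sparse <- prof
  sparse$mask[4:998] <- TRUE
  seg <- replicon_segments(origin("chrV", 0), prof$replicon)
  expect_error(fit_breakpoint(sparse, seg[1, ]), "too few")
})

test_that("gaussian width recovery is exact in class and degenerate at zero", {
  gm <- genome_map(list(replicon("chrS", 1e6)))
  par <- replication_parameters(40, 1 / (40 * 5e-7))
  ors <- list(origin("chrS", 0, name = "ori"))
  seg <- replicon_segments(ors, gm$replicons$chrS)

  # noiseless mixture with sigma = 50 kb: recovered within 1%
  sp <- synthetic_spec(gm, ors, par, 1000, 200, sigma_map = 50000)
  e <- expected_profile(sp)$chrS
  g <- fit_gaussian_width(e, fit_breakpoint(e, seg[1, ]))
  expect_lt(abs(g$sigma - 50000) / 50000, 0.01)
  expect_equal(g$s95 / g$sigma, 3.919928, tolerance = 1e-9)
  expect_identical(g$sigma_flag, "ok")

  # data generated with sigma = 0: fitted sigma pinned at the lower bound
  sp0 <- synthetic_spec(gm, ors, par, 1000, 200, sigma_map = 0)
  e0 <- expected_profile(sp0)$chrS
  g0 <- fit_gaussian_width(e0, fit_breakpoint(e0, seg[1, ]))
  expect_identical(g0$sigma_flag, "lower_bound")
  expect_lte(g0$s95, 1000)
})

test_that("origin localisation finds noiseless apexes, honouring the wrap", {
  par <- replication_parameters(40, 25000)
  # apex away from the seam
  gm <- genome_map(list(replicon("c", 2e6)))
  prof <- theoretical_log2_profile(gm, origin("c", 1200000), par, 1000)$c
  loc <- localize_origin(prof, windows = c(2e5, 4e5))
  expect_equal(nrow(loc), 2L)
  expect_lt(max(abs(loc$apex - 1200000)), 1000)

  # apex at position 0: circular wrap
  prof0 <- theoretical_log2_profile(gm, origin("c", 0), par, 1000)$c
  loc0 <- localize_origin(prof0, windows = c(2e5, 4e5))
  d0 <- pmin(loc0$apex %% 2e6, 2e6 - loc0$apex %% 2e6)
  expect_lt(max(d0), 1000)

  # flat profile: no peak
  flat <- mk_profile(replicon("c", 1e5), 1000, rep(0.2, 100))
  expect_error(localize_origin(flat, windows = 5e4), "no peak")
  expect_error(localize_origin(prof, windows = 5000), "at least 20 bins")
})

test_that("slope asymmetry across a shared origin is flagged strictly", {
  mk_fit <- function(lo, ro, ls, rs) {
    structure(list(replicon = "chr1", left_origin = lo, right_origin = ro,
                   left_slope = ls, right_slope = rs),
              class = "segment_fit")
  }
  a <- mk_fit("oriA", "oriB", -4e-7, 4e-7)
  b <- mk_fit("oriB", "oriA", -4e-7, 4e-7)
  sym <- slope_asymmetry(a, b)
  expect_equal(sym$ratio, 1)
  expect_false(sym$flag)
  expect_identical(sym$shared_origin, "oriB")

  # perturbed arm: ratio beyond 1.25 flags
  b2 <- mk_fit("oriB", "oriA", -6e-7, 4e-7)
  expect_true(slope_asymmetry(a, b2)$ratio < 1 / 1.25)
  expect_true(slope_asymmetry(a, b2)$flag)

  # ratio exactly at the threshold is NOT flagged (strict inequality)
  b3 <- mk_fit("oriB", "oriA", -5e-7, 4e-7)
  expect_equal(slope_asymmetry(a, b3)$ratio, 1 / 1.25)
  expect_false(slope_asymmetry(a, b3)$flag)
  expect_error(slope_asymmetry(a, mk_fit("oriB", "oriA", 0, 1e-7)), "zero slope")
  expect_error(slope_asymmetry(a, mk_fit("oriX", "oriY", 1e-7, 1e-7)),
               "do not share")
})

test_that("termination synchrony classifies by the log2 difference at the fcps", {
  rep1 <- replicon("chr1", 1e5); rep2 <- replicon("chr2", 1e5)
  mkp <- function(rep, level) mk_profile(rep, 1000, rep(level, 100), reference = "chr1")
  mkf <- function(repn, fcp) structure(list(replicon = repn, fcp = fcp),
                                       class = "segment_fit")
  f1 <- mkf("chr1", 50000); f2 <- mkf("chr2", 50000)
  profs_ahead <- list(chr1 = mkp(rep1, 0), chr2 = mkp(rep2, 0.2))
  expect_identical(termination_synchrony(profs_ahead, f1, f2)$classification,
                   "chr2 ahead")
  profs_behind <- list(chr1 = mkp(rep1, 0.2), chr2 = mkp(rep2, 0))
  expect_identical(termination_synchrony(profs_behind, f1, f2)$classification,
                   "chr2 behind")
  profs_sync <- list(chr1 = mkp(rep1, 0.02), chr2 = mkp(rep2, 0))
  expect_identical(termination_synchrony(profs_sync, f1, f2)$classification,
                   "synchronous")

  # masked fcp bin: nearest unmasked bin within 5 bins, else error
  p_masked <- mkp(rep1, 0)
  p_masked$mask[48:53] <- TRUE
  expect_identical(termination_synchrony(list(chr1 = p_masked,
                                              chr2 = mkp(rep2, 0.2)),
                                         f1, f2)$classification, "chr2 ahead")
  p_wide <- mkp(rep1, 0)
  p_wide$mask[40:62] <- TRUE
  expect_error(termination_synchrony(list(chr1 = p_wide,
                                          chr2 = mkp(rep2, 0.2)), f1, f2),
               "no unmasked bin")
})

test_that("segment reports carry fcp-mp arithmetic and locus distances", {
  gm <- genome_map(list(replicon("chr1", 2960000)),
                   data.frame(name = "dif1", replicon = "chr1",
                              position = 1438000))
  fit <- structure(list(
    replicon = "chr1", left_origin = "oriC1", right_origin = "oriC1",
    left_pos = 0, right_pos = 0, arc_length = 2960000, bin_size = 1000,
    fcp = 1483000, fcp_arc = 1483000, mp = 1480000, mp_arc = 1480000,
    fcp_mp_bp = 3000, fcp_mp_pct = 100 * 3000 / 2960000,
    left_slope = -4e-7, left_intercept = 0.6,
    right_slope = 4e-7, right_intercept = -0.6,
    sse = 0.1, n_bins = 2960, sigma = 10000, s95 = 39199.28,
    sigma_flag = "ok"), class = "segment_fit")
  rep <- segment_report(fit, gm)
  expect_equal(rep$fcp_mp_bp, 3000)
  expect_equal(rep$fcp_mp_pct, 0.1013514, tolerance = 1e-6)
  expect_equal(rep$fcp, 1483001)  # 1-based report coordinates
  expect_equal(rep$dist_to_dif1, 45000)

  fit0 <- fit; fit0$fcp <- 1480000; fit0$fcp_mp_bp <- 0; fit0$fcp_mp_pct <- 0
  rep0 <- segment_report(fit0, gm)
  expect_equal(rep0$fcp_mp_bp, 0)
  expect_equal(rep0$fcp_mp_pct, 0)
})
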