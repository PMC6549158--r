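test_that("replication age is the minimum over origins and fork directions", {
  rep <- replicon("c", 1e6)
  par <- replication_parameters(tau = 40, v = 1000)
  o0 <- origin("c", 0)
  expect_equal(replication_age(250000, o0, par, rep), 250)
  # antipode is the last-replicated position
  ages <- replication_age(seq(0, 999999, by = 500), o0, par, rep)
  expect_equal(max(ages), replication_age(500000, o0, par, rep))

  # two synchronous origins: exhaustive min over 4 origin-direction paths
  o2 <- list(origin("c", 0), origin("c", 600000))
  expect_equal(replication_age(800000, o2, par, rep), 200)
  x <- 123456
  paths <- c((x - 0) %% 1e6, (0 - x) %% 1e6,
             (x - 6e5) %% 1e6, (6e5 - x) %% 1e6) / 1000
  expect_equal(replication_age(x, o2, par, rep), min(paths))
  expect_error(replication_age(1, list(origin("other", 0)), par, rep),
               "no origins")
})

test_that("theoretical fcps sit at midpoints, shifted by firing offsets", {
  rep <- replicon("c", 1e6)
  par <- replication_parameters(40, 1000)
  f1 <- theoretical_fcps(origin("c", 0), par, rep)
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$fcp, 500000)

  f2 <- theoretical_fcps(list(origin("c", 0), origin("c", 600000)), par, rep)
  expect_equal(sort(f2$fcp), c(300000, 800000))

  # 100 min late origin at 600 kb: clockwise fcp moves to 350 kb
  f3 <- theoretical_fcps(list(origin("c", 0),
                              origin("c", 600000, firing_offset = 100)),
                         par, rep)
  expect_equal(f3$fcp[f3$left_origin == "ori@0"], 350000)
})

test_that("fcp geometry is rotation equivariant and obeys the midpoint law", {
  par <- replication_parameters(30, 800)
  rep <- replicon("c", 2e6)
  set.seed(5)
  for (i in 1:10) {
    pos <- sort(sample.int(2e6, 3L) - 1L)
    ors <- lapply(pos, function(p) origin("c", p))
    f <- theoretical_fcps(ors, par, rep)
    # midpoint law under synchrony
    expect_equal(f$fcp, f$mp)
    # rotation by a constant shifts every fcp by that constant (mod L)
    shift <- sample.int(2e6, 1L)
    ors_s <- lapply(pos, function(p) origin("c", (p + shift) %% 2e6))
    f_s <- theoretical_fcps(ors_s, par, rep)
    expect_setequal(round(f_s$fcp), round((f$fcp + shift) %% 2e6))
  }
})

test_that("theoretical log2 profile is affine with slope 1/(v*tau)", {
  gm <- genome_map(list(replicon("c", 1e6)))
  par <- replication_parameters(tau = 40, v = 25000)  # v*tau = 1 Mb
  prof <- theoretical_log2_profile(gm, origin("c", 0), par, 1000)$c
  # closed form 0.5 at the origin, minus one-bin discretisation (centres sit
  # 500 bp off the origin and antipode)
  expect_equal(max(prof$log2mf), 0.499, tolerance = 1e-12)
  expect_equal(min(prof$log2mf), 0)
  # affine on the first replichore, slope -1/(v*tau), to 1e-12
  s <- bin_centers(prof)
  half <- s < 500000
  slopes <- diff(prof$log2mf[half]) / diff(s[half])
  expect_lt(max(abs(slopes + 1 / (25000 * 40))), 1e-12)

  # doubling v halves every log2 difference
  prof2 <- theoretical_log2_profile(gm, origin("c", 0),
                                    replication_parameters(40, 50000), 1000)$c
  expect_equal(max(prof2$log2mf) - min(prof2$log2mf),
               (max(prof$log2mf) - min(prof$log2mf)) / 2, tolerance = 1e-9)
})

test_that("gaussian-corrected MF matches its degenerate and mixture limits", {
  li <- 0.5; ls <- -5e-7; ri <- -0.3; rs <- 4e-7
  fcp <- 400000
  # sigma = 0: exactly the piecewise model
  expect_equal(gaussian_corrected_mf(100000, fcp, 0, li, ls, ri, rs),
               2^(li + ls * 100000))
  expect_equal(gaussian_corrected_mf(700000, fcp, 0, li, ls, ri, rs),
               2^(ri + rs * 700000))
  # at the fcp the mixture is the average of the two lines
  expect_equal(gaussian_corrected_mf(fcp, fcp, 10000, li, ls, ri, rs),
               (2^(li + ls * fcp) + 2^(ri + rs * fcp)) / 2)
  expect_error(gaussian_corrected_mf(1, fcp, -1, li, ls, ri, rs), "sigma")
})

test_that("gaussian-corrected MF agrees with the Monte-Carlo mixture oracle", {
  li <- 0.35; ls <- -7e-7; ri <- -0.35; rs <- 7e-7
  fcp <- 500000; sigma <- 10000
  s <- c(470000, 490000, 500000, 505000, 530000)
  got <- gaussian_corrected_mf(s, fcp, sigma, li, ls, ri, rs)
  mc <- mc_gaussian_mf(s, fcp, sigma, li, ls, ri, rs, n_draws = 1e6)
  expect_equal(got, mc, tolerance = 1e-3)
})

test_that("the sigma -> 0 mixture converges uniformly to the piecewise model", {
  li <- 0.5; ls <- -5e-7; ri <- -0.34; rs <- 4.2e-7
  fcp <- 400000; arc <- 1e6
  s <- seq(500, arc - 500, by = 1000)
  piecewise <- ifelse(s < fcp, 2^(li + ls * s), 2^(ri + rs * s))
  piecewise[s == fcp] <- (2^(li + ls * fcp) + 2^(ri + rs * fcp)) / 2
  tiny <- gaussian_corrected_mf(s, fcp, arc / 1e6, li, ls, ri, rs)
  expect_lt(max(abs(tiny - piecewise)), 1e-9)
})

test_that("crtS coupling sets the oriC2 firing offset from chr1 progression", {
  gm <- vcholerae_like_genome()
  par <- replication_parameters(40, 60000)
  ors1 <- list(origin("chr1", 0, name = "oriC1"))

  # co-termination construction: chr1 and chr2 termination ages equal
  delay <- co_termination_delay(gm, ors1, par)
  ori2 <- crts_coupled_offset(gm, ors1, par, extra_delay = delay)
  end1 <- max(theoretical_fcps(ors1, par, gm$replicons$chr1)$fcp_age)
  end2 <- max(theoretical_fcps(ori2, par, gm$replicons$chr2)$fcp_age)
  expect_equal(end1, end2, tolerance = 1e-9)

  # ectopic origin 40 kb from crtS: oriC2 fires early
  ors_l <- list(origin("chr1", 0, name = "oriC1"),
                origin("chr1", locus_position(gm, "oriL3")$position,
                       name = "oriL3"))
  ori2_l <- crts_coupled_offset(gm, ors_l, par, extra_delay = delay)
  expect_equal(ori2_l$firing_offset, 40000 / 60000 + delay, tolerance = 1e-9)
  expect_error(crts_coupled_offset(gm, ors1, par, crts_locus = "nope"),
               "not found")
})
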