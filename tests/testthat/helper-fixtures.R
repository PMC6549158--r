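# Shared fixtures and independent oracles, built in code at test time.

# Minimal mf_profile constructor for engineered (already-normalised) data.
mk_profile <- function(replicon, bin_size, log2mf, mask = NULL,
                       reference = replicon$name) {
  mask <- mask %||% rep(FALSE, length(log2mf))
  structure(list(replicon = replicon, bin_size = bin_size,
                 mf = 2^log2mf, log2mf = log2mf, mask = mask,
                 normalization_reference = reference),
            class = "mf_profile")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free piecewise log-linear V profile on a circular replicon:
# descends from the origin (bin arc 0) at -slope_l, breaks at fcp_arc,
# ascends at +slope_r back to the origin.
piecewise_v_profile <- function(L, bin_size, fcp_arc, slope_l, slope_r,
                                top = 0.6, name = "chrV") {
  rep <- replicon(name, L)
  s <- (seq_len(ceiling(L / bin_size)) - 0.5) * bin_size
  y <- ifelse(s <= fcp_arc, top - slope_l * s,
              top - slope_l * fcp_arc + slope_r * (s - fcp_arc))
  mk_profile(rep, bin_size, y)
}

# Independent breakpoint oracle: per-candidate lm() fits, no prefix sums.
oracle_two_piece <- function(s, y, candidate_idx) {
  n <- length(s)
  sse <- vapply(candidate_idx, function(i) {
    fl <- stats::lm(y[1:i] ~ s[1:i])
    fr <- stats::lm(y[i:n] ~ s[i:n])
    sum(stats::residuals(fl)^2) + sum(stats::residuals(fr)^2)
  }, numeric(1L))
  k <- which.min(sse)
  list(break_x = s[candidate_idx[k]], sse = sse[k], sse_all = sse)
}

# Monte-Carlo oracle for the Gaussian-corrected marker frequency: draws
# convergence points p ~ N(fcp, sigma^2); a position s is replicated by
# the left fork (left line) in the cells with p > s, by the right fork
# otherwise.
mc_gaussian_mf <- function(s, fcp, sigma, li, ls, ri, rs, n_draws = 1e6,
                           seed = 42) {
  set.seed(seed)
  p <- stats::rnorm(n_draws, fcp, sigma)
  vapply(s, function(si)
    mean(ifelse(p > si, 2^(li + ls * si), 2^(ri + rs * si))), numeric(1L))
}

# Ten-read SAM fixture on a 5 kb replicon (1 kb bins): 5 starts in bin 0,
# one exactly at the bin-1 boundary, two in bin 3, two unmapped.
write_sam_fixture <- function(sam_path) {
  pos1 <- c(1, 50, 100, 900, 1000, 1001, 3500, 3600)  # 1-based mapped starts
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:5000",
    vapply(seq_along(pos1), function(i)
      sprintf("r%d\t0\tchrT\t%d\t60\t10M\t*\t0\t0\tACGTACGTAC\t*", i, pos1[i]),
      character(1L)),
    "u1\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*",
    "u2\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*")
  writeLines(lines, sam_path)
  list(expected_counts = c(5, 1, 0, 2, 0), n_mapped = length(pos1))
}

# Quartiles by explicit sort + linear interpolation (independent of
# stats::quantile internals).
sorted_quartiles <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  q_at <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  c(q1 = q_at(0.25), q3 = q_at(0.75))
}

# One-stop pipeline for simulated fixtures: trim + normalise + fit every
# chr1/chr2 segment.
fit_fixture <- function(fx, reference = "chr1", gaussian = FALSE) {
  profs <- normalize_profiles(lapply(fx$coverages, trim_outlier_bins),
                              reference)
  fits <- lapply(names(profs), function(nm) {
    segs <- replicon_segments(fx$origins, fx$genome$replicons[[nm]])
    lapply(seq_len(nrow(segs)), function(k) {
      f <- fit_breakpoint(profs[[nm]], segs[k, ])
      if (gaussian) f <- fit_gaussian_width(profs[[nm]], f)
      f
    })
  })
  names(fits) <- names(profs)
  list(profiles = profs, fits = fits)
}
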