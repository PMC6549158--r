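#' Inter-origin segments of a replicon
#'
#' Splits a circular replicon into its `n` inter-origin segments (clockwise
#' adjacent origin pairs; a single origin yields one segment spanning the
#' whole circle).  Geometry only — no replication parameters involved.
#'
#' @param origins List of [origin()]s on the replicon.
#' @param replicon A [replicon()].
#' @return `data.frame` with columns `left_origin`, `right_origin`,
#'   `left_pos`, `right_pos`, `arc_length`, `mp`.
#' @export
replicon_segments <- function(origins, replicon) {
  stopifnot(inherits(replicon, "replicon"))
  ors <- .origins_on(origins, replicon$name)
  if (!length(ors)) stop("no origins on replicon ", replicon$name)
  L <- replicon$length
  pos <- vapply(ors, `[[`, numeric(1L), "position")
  ord <- order(pos)
  ors <- ors[ord]; pos <- pos[ord]
  n <- length(ors)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    left <- ors[[i]]
    right <- ors[[if (i == n) 1L else i + 1L]]
    arc <- if (n == 1L) L else (right$position - left$position) %% L
    if (arc == 0 && n > 1L) stop("coincident origins at ", left$position)
    out[[i]] <- data.frame(
      left_origin = left$name, right_origin = right$name,
      left_pos = left$position, right_pos = right$position,
      arc_length = arc, mp = (left$position + arc / 2) %% L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Exhaustive two-piece OLS scan.  x must be sorted ascending; for each
# candidate index i the data are split into [1..i] and [i..n] (the break
# bin belongs to both sides) and each side is fitted by ordinary least
# squares; returns the candidate minimising the total SSE (ties: smallest
# x).  Closed-form OLS via prefix sums makes the full scan O(n).
.two_piece_scan <- function(x, y, candidate_idx) {
  n <- length(x)
  xc <- x - mean(x)  # guard against cancellation in the moment sums
  cx <- cumsum(xc); cy <- cumsum(y)
  cxx <- cumsum(xc * xc); cxy <- cumsum(xc * y); cyy <- cumsum(y * y)
  side_sse <- function(Sx, Sy, Sxx, Sxy, Syy, m) {
    vx <- Sxx - Sx * Sx / m
    vy <- Syy - Sy * Sy / m
    vxy <- Sxy - Sx * Sy / m
    sse <- ifelse(vx > 0, vy - vxy * vxy / vx, vy)
    pmax(sse, 0)
  }
  i <- candidate_idx
  sseL <- side_sse(cx[i], cy[i], cxx[i], cxy[i], cyy[i], i)
  j <- i - 1L
  m <- n - j
  sseR <- side_sse(cx[n] - cx[j], cy[n] - cy[j], cxx[n] - cxx[j],
                   cxy[n] - cxy[j], cyy[n] - cyy[j], m)
  tot <- sseL + sseR
  best <- candidate_idx[which.min(tot)]  # which.min takes the first tie
  ols <- function(idx) {
    fit_x <- x[idx]; fit_y <- y[idx]
    mx <- mean(fit_x); my <- mean(fit_y)
    vx <- sum((fit_x - mx)^2)
    b <- if (vx > 0) sum((fit_x - mx) * (fit_y - my)) / vx else 0
    a <- my - b * mx
    c(intercept = a, slope = b)
  }
  left <- ols(seq_len(best))
  right <- ols(best:n)
  list(break_idx = best, break_x = x[best], sse = min(tot),
       sse_by_candidate = tot,
       left_intercept = left[["intercept"]], left_slope = left[["slope"]],
       right_intercept = right[["intercept"]], right_slope = right[["slope"]])
}

# Map profile bins onto a segment's clockwise arc coordinate.
# Returns unmasked bins with 0 <= s <= arc_length, sorted by s.
.segment_bins <- function(profile, seg) {
  L <- profile$replicon$length
  ctr <- bin_centers(profile)
  s <- if (profile$replicon$circular) (ctr - seg$left_pos) %% L else ctr - seg$left_pos
  keep <- !profile$mask & s >= 0 & s <= seg$arc_length & is.finite(profile$log2mf)
  ord <- order(s[keep])
  list(s = s[keep][ord], log2mf = profile$log2mf[keep][ord],
       mf = profile$mf[keep][ord])
}

#' Fit the fork convergence point of a segment
#'
#' Locates the fcp as the breakpoint of a two-sided log-linear regression:
#' every unmasked bin centre strictly inside the segment arc (excluding
#' `origin_exclude` bins adjacent to each origin) is tried as a candidate,
#' the log2 marker frequency is regressed on arc position separately on the
#' two sides, and the candidate minimising the total sum of squared errors
#' is returned.  Ties are broken toward the smallest arc coordinate.
#'
#' @param profile An `mf_profile` (see [normalize_profiles()]).
#' @param segment One row of [replicon_segments()] (data.frame or list with
#'   `left_pos`, `right_pos`, `arc_length`, `mp`, origin names).
#' @param min_side Minimum unmasked bins required on each side of a
#'   candidate (default 5).
#' @param origin_exclude Number of bins adjacent to each origin excluded
#'   from the candidate grid (default 5), shielding the fit from
#'   origin-proximal initiation transients.
#' @return An object of class `"segment_fit"` with the fitted `fcp`
#'   (genome coordinate, bp), arm slopes/intercepts (log2 units, intercept
#'   at arc coordinate 0), `sse`, `mp`, signed `fcp_mp_bp` (positive
#'   clockwise) and `fcp_mp_pct` (percent of the segment arc); `sigma` and
#'   `s95` are `NA` until [fit_gaussian_width()] is applied.
#' @export
fit_breakpoint <- function(profile, segment, min_side = 5L, origin_exclude = 5L) {
  stopifnot(inherits(profile, "mf_profile"))
  seg <- as.list(segment)
  bins <- .segment_bins(profile, seg)
  n <- length(bins$s)
  if (seg$arc_length < 10 * profile$bin_size)
    stop("segment arc shorter than 10 bins")
  if (n < 2L * min_side)
    stop("too few unmasked bins in segment (", n, ")")
  excl <- origin_exclude * profile$bin_size
  idx <- which(bins$s > max(0, excl) &
               bins$s < seg$arc_length - excl &
               seq_len(n) >= min_side & seq_len(n) <= n - min_side + 1L)
  if (!length(idx)) stop("no admissible breakpoint candidates in segment")
  scan <- .two_piece_scan(bins$s, bins$log2mf, idx)
  L <- profile$replicon$length
  fcp_arc <- scan$break_x
  mp_arc <- seg$arc_length / 2
  d <- fcp_arc - mp_arc
  structure(list(
    replicon = profile$replicon$name,
    left_origin = seg$left_origin, right_origin = seg$right_origin,
    left_pos = seg$left_pos, right_pos = seg$right_pos,
    arc_length = seg$arc_length, bin_size = profile$bin_size,
    fcp = (seg$left_pos + fcp_arc) %% L, fcp_arc = fcp_arc,
    mp = seg$mp, mp_arc = mp_arc,
    fcp_mp_bp = d, fcp_mp_pct = 100 * abs(d) / seg$arc_length,
    left_slope = scan$left_slope, left_intercept = scan$left_intercept,
    right_slope = scan$right_slope, right_intercept = scan$right_intercept,
    sse = scan$sse, n_bins = n,
    sigma = NA_real_, s95 = NA_real_, sigma_flag = NA_character_),
    class = "segment_fit")
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("<segment_fit> %s [%s -> %s]: fcp %s, fcp-mp %+d bp (%.2f%%)",
              x$replicon, x$left_origin, x$right_origin,
              format(round(x$fcp), big.mark = ","), round(x$fcp_mp_bp),
              x$fcp_mp_pct))
  if (!is.na(x$sigma))
    cat(sprintf(", sigma %.0f bp, S95 %.0f bp [%s]", x$sigma, x$s95, x$sigma_flag))
  cat("\n")
  invisible(x)
}

#' The S95/sigma conversion constant
#'
#' S95 is the width of the region centred on the fcp containing 95% of
#' individual cells' fork convergence positions: `2 * 1.959964 * sigma`.
#' @export
S95_FACTOR <- 2 * 1.959964

#' Fit the Gaussian termination-zone width (S95)
#'
#' Holding the fcp fixed, finds the Gaussian spread `sigma` minimising the
#' sum of squared errors between the linear-scale marker frequencies and
#' the Gaussian-corrected model ([gaussian_corrected_mf()]), by bounded
#' 1-D minimisation over `sigma` in `[bin_size/10, arc_length/4]` (coarse
#' geometric grid plus golden-section refinement).  The two arm lines are
#' nuisance parameters of that objective: for each candidate `sigma` they
#' are refit by OLS in log2 space on the bins farther than `3*sigma` from
#' the fcp, so the rounded termination zone itself does not bias the arm
#' slopes the mixture is built from.  Reports `s95 = 2 * 1.959964 * sigma`
#' and updates the fit's line fields to the exclusion-refit values.
#'
#' @param profile The `mf_profile` the breakpoint was fitted on.
#' @param fit A `"segment_fit"` from [fit_breakpoint()].
#' @param refit_fcp If `TRUE`, the fcp is refit jointly with sigma over the
#'   candidate grid (off by default; the breakpoint is kept fixed).
#' @param min_core_bins Minimum unmasked bins required within one fifth of
#'   the arc around the fcp (default 10).
#' @return The fit with `sigma`, `s95` and `sigma_flag`
#'   (`"ok"`, `"lower_bound"` or `"upper_bound"`) filled in.
#' @export
fit_gaussian_width <- function(profile, fit, refit_fcp = FALSE,
                               min_core_bins = 10L) {
  stopifnot(inherits(fit, "segment_fit"), inherits(profile, "mf_profile"))
  seg <- fit
  bins <- .segment_bins(profile, seg)
  core <- abs(bins$s - fit$fcp_arc) <= fit$arc_length / 5
  if (sum(core) < min_core_bins)
    stop("too few unmasked bins near the fcp (", sum(core), ") to fit sigma")
  lo <- profile$bin_size / 10
  hi <- fit$arc_length / 4
  min_side <- 5L
  lines_for <- function(sigma, fcp_arc) {
    keep_l <- bins$s <= fcp_arc & (fcp_arc - bins$s) > 3 * sigma
    keep_r <- bins$s >= fcp_arc & (bins$s - fcp_arc) > 3 * sigma
    # never let the exclusion eat a whole arm
    if (sum(keep_l) < min_side) keep_l <- bins$s <= fcp_arc
    if (sum(keep_r) < min_side) keep_r <- bins$s >= fcp_arc
    ols <- function(x, y) {
      mx <- mean(x); my <- mean(y)
      vx <- sum((x - mx)^2)
      b <- if (vx > 0) sum((x - mx) * (y - my)) / vx else 0
      c(my - b * mx, b)
    }
    c(ols(bins$s[keep_l], bins$log2mf[keep_l]),
      ols(bins$s[keep_r], bins$log2mf[keep_r]))
  }
  sse_for <- function(sigma, fcp_arc) {
    ln <- lines_for(sigma, fcp_arc)
    pred <- gaussian_corrected_mf(bins$s, fcp_arc, sigma,
                                  ln[1L], ln[2L], ln[3L], ln[4L])
    sum((bins$mf - pred)^2)
  }
  best_sigma <- function(fcp_arc) {
    grid <- exp(seq(log(lo), log(hi), length.out = 40L))
    vals <- vapply(grid, sse_for, numeric(1L), fcp_arc = fcp_arc)
    k <- which.min(vals)
    bracket <- c(grid[max(k - 1L, 1L)], grid[min(k + 1L, length(grid))])
    opt <- stats::optimize(sse_for, bracket, fcp_arc = fcp_arc, tol = lo / 10)
    sigma <- opt$minimum
    if (vals[1L] <= opt$objective) sigma <- lo
    if (vals[length(vals)] <= opt$objective) sigma <- hi
    sigma
  }
  sigma <- best_sigma(fit$fcp_arc)
  if (isTRUE(refit_fcp)) {
    cand <- bins$s[bins$s > 0 & bins$s < fit$arc_length]
    for (round in 1:2) {
      vals <- vapply(cand, function(cc) sse_for(sigma, cc), numeric(1L))
      best <- cand[which.min(vals)]
      fit$fcp_arc <- best
      fit$fcp <- (fit$left_pos + best) %% profile$replicon$length
      sigma <- best_sigma(best)
    }
  }
  ln <- lines_for(sigma, fit$fcp_arc)
  fit$left_intercept <- ln[1L]; fit$left_slope <- ln[2L]
  fit$right_intercept <- ln[3L]; fit$right_slope <- ln[4L]
  fit$sigma <- sigma
  fit$s95 <- S95_FACTOR * sigma
  fit$sigma_flag <- if (sigma <= lo * 1.01) "lower_bound"
                    else if (sigma >= hi * 0.99) "upper_bound"
                    else "ok"
  fit
}

#' Localise a replication origin from a coverage peak
#'
#' Applies the two-sided regression machinery to an inverted-V: within a
#' window centred on the highest unmasked bin, every bin centre is tried as
#' the apex of an ascending + descending pair of log2 regression lines, and
#' the split minimising the total SSE is found.  By default the reported
#' apex is then refined to the intersection of the two arm regression
#' lines (refit on either side of the split, iterated once): the
#' grid-argmin split alone has a noise floor set by the local bin noise
#' around the kink, whereas the crossing of the two arm lines pools the
#' whole window and localises the origin several-fold more precisely.
#' Circular wrap is honoured.  Results are reported independently for each
#' window size (no averaging across windows).
#'
#' @param profile An `mf_profile`.
#' @param windows Window size(s) in bp (each >= 20 bins).
#' @param min_side Minimum bins per side of an apex candidate (default 5).
#' @param refine If `TRUE` (default) report the arm-line crossing; if
#'   `FALSE` report the raw grid-argmin bin centre.
#' @param slope_tol Minimum |slope| (log2/bp) for a genuine peak; below
#'   this on either side the profile is declared flat (default 1e-9).
#' @return `data.frame` with one row per window: `window`, `apex`
#'   (genome coordinate bp), `left_slope`, `right_slope`, `sse`.
#' @export
localize_origin <- function(profile, windows = c(4e5, 6e5), min_side = 5L,
                            refine = TRUE, slope_tol = 1e-9) {
  stopifnot(inherits(profile, "mf_profile"))
  L <- profile$replicon$length
  ctr <- bin_centers(profile)
  live <- !profile$mask & is.finite(profile$log2mf)
  if (!any(live)) stop("no unmasked bins")
  c0 <- ctr[live][which.max(profile$log2mf[live])]
  out <- lapply(windows, function(w) {
    if (w < 20 * profile$bin_size)
      stop("window must span at least 20 bins, got ", w, " bp")
    half <- w / 2
    d <- if (profile$replicon$circular) {
      dd <- (ctr - c0) %% L
      pmin(dd, L - dd)
    } else abs(ctr - c0)
    keep <- live & d <= half
    # arc coordinate increasing clockwise across the window
    s <- if (profile$replicon$circular) (ctr - (c0 - half)) %% L else ctr - (c0 - half)
    s <- s[keep]; y <- profile$log2mf[keep]
    ord <- order(s); s <- s[ord]; y <- y[ord]
    n <- length(s)
    if (n < 2L * min_side) stop("too few unmasked bins in window")
    idx <- seq.int(min_side, n - min_side + 1L)
    scan <- .two_piece_scan(s, y, idx)
    if (abs(scan$left_slope) < slope_tol || abs(scan$right_slope) < slope_tol ||
        scan$left_slope < 0 || scan$right_slope > 0)
      stop("no peak: profile is flat or not ascending/descending in window")
    apex_arc <- scan$break_x
    lsl <- scan$left_slope; rsl <- scan$right_slope; sse <- scan$sse
    if (isTRUE(refine)) {
      split <- scan$break_x
      for (iter in 1:2) {
        left <- s <= split; right <- s >= split
        if (sum(left) < min_side || sum(right) < min_side) break
        fl <- stats::coef(stats::lm.fit(cbind(1, s[left]), y[left]))
        fr <- stats::coef(stats::lm.fit(cbind(1, s[right]), y[right]))
        if (!(fl[2L] > 0 && fr[2L] < 0)) break
        xc <- (fr[1L] - fl[1L]) / (fl[2L] - fr[2L])
        if (!is.finite(xc)) break
        split <- min(max(xc, s[min_side]), s[n - min_side + 1L])
        apex_arc <- split; lsl <- fl[[2L]]; rsl <- fr[[2L]]
      }
    }
    apex <- if (profile$replicon$circular) ((c0 - half) + apex_arc) %% L
            else (c0 - half) + apex_arc
    data.frame(window = w, apex = apex,
               left_slope = lsl, right_slope = rsl, sse = sse)
  })
  do.call(rbind, out)
}

#' Slope asymmetry across a shared origin
#'
#' Compares the magnitudes of the log2 slopes of the two replication arms
#' leaving one origin shared by two adjacent segment fits.  A markedly
#' asymmetric pair (ratio outside `[1/threshold, threshold]`, strict) flags
#' a perturbed arm, e.g. head-on replication-transcription conflict at an
#' rrn operon.
#'
#' @param fit,neighbor Two `"segment_fit"`s sharing one origin.
#' @param threshold Flagging threshold (default 1.25).
#' @return List with `shared_origin`, `slope_fit`, `slope_neighbor`,
#'   `ratio` (|slope_fit| / |slope_neighbor|) and logical `flag`.
#' @export
slope_asymmetry <- function(fit, neighbor, threshold = 1.25) {
  stopifnot(inherits(fit, "segment_fit"), inherits(neighbor, "segment_fit"))
  if (fit$right_origin == neighbor$left_origin) {
    shared <- fit$right_origin
    a <- fit$right_slope; b <- neighbor$left_slope
  } else if (fit$left_origin == neighbor$right_origin) {
    shared <- fit$left_origin
    a <- fit$left_slope; b <- neighbor$right_slope
  } else {
    stop("fits do not share an origin")
  }
  if (a == 0 || b == 0) stop("zero slope on an arm leaving ", shared)
  ratio <- abs(a) / abs(b)
  list(shared_origin = shared, slope_fit = a, slope_neighbor = b,
       ratio = ratio,
       flag = ratio > threshold || ratio < 1 / threshold)
}

# log2 marker frequency at a genome position; if the containing bin is
# masked, the nearest unmasked bin within `max_hop` bins is used.
.log2mf_at <- function(profile, pos, max_hop = 5L) {
  n <- length(profile$mf)
  i0 <- floor((pos %% profile$replicon$length) / profile$bin_size) + 1L
  i0 <- min(max(i0, 1L), n)
  for (hop in 0:max_hop) {
    for (i in unique(c(i0 - hop, i0 + hop))) {
      j <- if (profile$replicon$circular) ((i - 1L) %% n) + 1L else i
      if (j >= 1L && j <= n && !profile$mask[j] && is.finite(profile$log2mf[j]))
        return(profile$log2mf[j])
    }
  }
  stop("no unmasked bin within ", max_hop, " bins of position ", round(pos))
}

#' Classify chr1/chr2 termination synchrony
#'
#' Compares the normalised log2 marker frequency at the chr2 fcp with that
#' at each chr1 terminal fcp.  A higher frequency at the chr2 fcp means
#' chr2 replication finishes earlier in the cell cycle ("chr2 ahead").
#'
#' @param profiles Named list of `mf_profile`s on a common normalisation
#'   (names = replicon names).
#' @param chr1_fits List of `"segment_fit"`s on the primary chromosome (or
#'   a single fit).
#' @param chr2_fit The `"segment_fit"` of the secondary chromosome.
#' @param tolerance_log2 Half-width of the "synchronous" band in log2 units
#'   (default 0.05, about a 3.5% copy-number difference).
#' @return `data.frame` with one row per chr1 fit: the fcp positions, the
#'   difference `delta_log2 = log2mf(fcp2) - log2mf(fcp1)` and the
#'   `classification` (`"chr2 ahead"`, `"chr2 behind"`, `"synchronous"`).
#' @export
termination_synchrony <- function(profiles, chr1_fits, chr2_fit,
                                  tolerance_log2 = 0.05) {
  if (inherits(chr1_fits, "segment_fit")) chr1_fits <- list(chr1_fits)
  stopifnot(inherits(chr2_fit, "segment_fit"))
  p2 <- profiles[[chr2_fit$replicon]]
  if (is.null(p2)) stop("no profile for replicon ", chr2_fit$replicon)
  mf2 <- .log2mf_at(p2, chr2_fit$fcp)
  ref <- vapply(profiles, function(p) p$normalization_reference, character(1L))
  if (length(unique(ref)) != 1L)
    stop("profiles are not on a common normalisation")
  out <- lapply(chr1_fits, function(f1) {
    p1 <- profiles[[f1$replicon]]
    if (is.null(p1)) stop("no profile for replicon ", f1$replicon)
    mf1 <- .log2mf_at(p1, f1$fcp)
    delta <- mf2 - mf1
    cls <- if (delta > tolerance_log2) "chr2 ahead"
           else if (delta < -tolerance_log2) "chr2 behind"
           else "synchronous"
    data.frame(chr1_replicon = f1$replicon,
               chr1_fcp = f1$fcp, chr2_fcp = chr2_fit$fcp,
               log2mf_chr1_fcp = mf1, log2mf_chr2_fcp = mf2,
               delta_log2 = delta, classification = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tabulate segment fits
#'
#' One row per fitted segment with the fcp (1-based for reporting), the
#' midpoint, the signed and percentage fcp-mp deviation, S95, slopes, and
#' shortest-arc distances from the fcp to the requested named loci.
#'
#' @param fits List of `"segment_fit"`s (or one).
#' @param genome A [genome_map()] supplying locus positions.
#' @param loci Character vector of locus names to report distances to;
#'   default: every locus whose name starts with `"dif"`.
#' @return `data.frame`.
#' @export
segment_report <- function(fits, genome, loci = NULL) {
  if (inherits(fits, "segment_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, inherits(genome, "genome_map"))
  loci <- loci %||% grep("^dif", genome$loci$name, value = TRUE)
  rows <- lapply(fits, function(f) {
    row <- data.frame(
      replicon = f$replicon, left_origin = f$left_origin,
      right_origin = f$right_origin,
      fcp = f$fcp + 1, mp = f$mp + 1,  # 1-based in reports
      fcp_mp_bp = f$fcp_mp_bp, fcp_mp_pct = f$fcp_mp_pct,
      sigma = f$sigma, s95 = f$s95,
      left_slope = f$left_slope, right_slope = f$right_slope,
      sse = f$sse, sse_per_bin = f$sse / f$n_bins,  # fit-quality veto handle
      stringsAsFactors = FALSE)
    for (lc in loci) {
      i <- match(lc, genome$loci$name)
      col <- paste0("dist_to_", lc)
      if (!is.na(i) && genome$loci$replicon[i] == f$replicon) {
        rep <- genome$replicons[[f$replicon]]
        row[[col]] <- circular_distance(rep, f$fcp %% rep$length,
                                        genome$loci$position[i], "shortest")
      } else {
        row[[col]] <- NA_real_
      }
    }
    row
  })
  do.call(rbind, rows)
}
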