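#' Replication parameters of an exponential culture
#'
#' In steady-state exponential growth the copy number of a locus replicated
#' `a` minutes after initiation is proportional to `2^(-a/tau)`
#' (Cooper-Helmstetter).  With a uniform fork speed `v` the log2 marker
#' frequency is therefore affine in position with slope magnitude
#' `1/(v*tau)` per bp on every origin-to-terminus arc.
#'
#' @param tau Doubling time in minutes (> 0).
#' @param v Fork speed in bp/minute (> 0).
#' @return An object of class `"replication_parameters"` with an extra
#'   field `slope = 1/(v*tau)` (log2 units per bp).
#' @export
replication_parameters <- function(tau, v) {
  stopifnot(is.finite(tau), tau > 0, is.finite(v), v > 0)
  structure(list(tau = tau, v = v, slope = 1 / (v * tau)),
            class = "replication_parameters")
}

#' @export
print.replication_parameters <- function(x, ...) {
  cat(sprintf("<replication_parameters> tau = %g min, v = %g bp/min, log2 slope = %.3g /bp\n",
              x$tau, x$v, x$slope))
  invisible(x)
}

#' Define a replication origin
#'
#' @param replicon Name of the replicon carrying the origin.
#' @param position Origin position in bp (0-based).
#' @param firing_offset Minutes after the reference initiation event at
#'   which this origin fires; 0 (default) means synchronous initiation.
#' @param name Optional origin name (e.g. `"oriC1"`, `"oriL3"`).
#' @return An object of class `"origin"`.
#' @export
origin <- function(replicon, position, firing_offset = 0, name = NULL) {
  stopifnot(is.character(replicon), length(replicon) == 1L)
  stopifnot(is.finite(position), position >= 0)
  stopifnot(is.finite(firing_offset), firing_offset >= 0)
  structure(list(replicon = replicon, position = position,
                 firing_offset = firing_offset,
                 name = name %||% sprintf("ori@%d", round(position))),
            class = "origin")
}

#' @export
print.origin <- function(x, ...) {
  cat(sprintf("<origin> %s on %s at %s bp, firing offset %g min\n",
              x$name, x$replicon, format(x$position, big.mark = ","),
              x$firing_offset))
  invisible(x)
}

.origins_on <- function(origins, replicon_name) {
  if (inherits(origins, "origin")) origins <- list(origins)
  Filter(function(o) o$replicon == replicon_name, origins)
}

#' Replication age of a position
#'
#' Minutes after the reference initiation event at which a position is
#' replicated: the minimum over all origins on the replicon and both fork
#' directions of `firing_offset + arc(origin -> x)/v`.  For equal fork
#' speeds this minimum correctly encodes where converging forks meet.
#'
#' @param x Position(s) in bp on the replicon (vectorised).
#' @param origins List of [origin()]s (at least one on the replicon).
#' @param params A [replication_parameters()].
#' @param replicon A [replicon()].
#' @return Replication age(s) in minutes.
#' @export
replication_age <- function(x, origins, params, replicon) {
  stopifnot(inherits(params, "replication_parameters"),
            inherits(replicon, "replicon"))
  ors <- .origins_on(origins, replicon$name)
  if (!length(ors)) stop("no origins on replicon ", replicon$name)
  L <- replicon$length
  age <- rep(Inf, length(x))
  for (o in ors) {
    cw <- (x - o$position) %% L
    ccw <- (o$position - x) %% L
    if (!replicon$circular) {
      cw <- ifelse(x >= o$position, x - o$position, Inf)
      ccw <- ifelse(x <= o$position, o$position - x, Inf)
    }
    age <- pmin(age, o$firing_offset + cw / params$v,
                o$firing_offset + ccw / params$v)
  }
  age
}

#' Inter-origin segments and their theoretical fork convergence points
#'
#' With `n` origins on a circular replicon there are exactly `n` segments,
#' one per adjacent origin pair in clockwise order (a single origin yields
#' one segment spanning the whole circle back to itself).  The theoretical
#' fcp of a segment is the position where the identity of the arriving fork
#' switches: for equal fork speeds it sits at arc
#' `(arc_length + v*(offset_right - offset_left))/2` clockwise of the left
#' origin — the segment midpoint when firing is synchronous, shifted by
#' `v*delta_offset/2` toward the later-firing origin otherwise.
#'
#' @param origins List of [origin()]s on the replicon.
#' @param params A [replication_parameters()].
#' @param replicon A [replicon()].
#' @return `data.frame` with one row per segment: `left_origin`,
#'   `right_origin` (names), `left_pos`, `right_pos`, `arc_length`, `fcp`
#'   (bp, mod length), `mp` (segment midpoint, bp mod length), and the ages
#'   `fcp_age` at which forks meet there.
#' @export
theoretical_fcps <- function(origins, params, replicon) {
  stopifnot(inherits(params, "replication_parameters"),
            inherits(replicon, "replicon"))
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
    # arrival-time equality: off_L + s/v = off_R + (arc - s)/v
    s <- (arc + params$v * (right$firing_offset - left$firing_offset)) / 2
    s <- min(max(s, 0), arc)  # a fork may be overrun before the other fires
    out[[i]] <- data.frame(
      left_origin = left$name, right_origin = right$name,
      left_pos = left$position, right_pos = right$position,
      arc_length = arc,
      fcp = (left$position + s) %% L,
      mp = (left$position + arc / 2) %% L,
      fcp_age = left$firing_offset + s / params$v,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Theoretical log2 marker frequency profile
#'
#' Evaluates the Cooper-Helmstetter expectation `log2mf(x) = C - age(x)/tau`
#' at bin centres for every replicon of a genome, with `C` chosen so the
#' profile minimum on the normalisation reference replicon is 0.
#'
#' @param genome A [genome_map()].
#' @param origins List of [origin()]s covering every replicon.
#' @param params A [replication_parameters()].
#' @param bin_size Bin width in bp.
#' @param reference Replicon anchoring the scale (default: first replicon).
#' @return Named list of `mf_profile` objects.
#' @export
theoretical_log2_profile <- function(genome, origins, params, bin_size,
                                     reference = NULL) {
  stopifnot(inherits(genome, "genome_map"))
  reference <- reference %||% names(genome$replicons)[1L]
  ages <- lapply(genome$replicons, function(rep) {
    n <- ceiling(rep$length / bin_size)
    replication_age((seq_len(n) - 0.5) * bin_size, origins, params, rep)
  })
  C <- max(ages[[reference]]) / params$tau
  lapply(genome$replicons, function(rep) {
    a <- ages[[rep$name]]
    l2 <- C - a / params$tau
    structure(list(replicon = rep, bin_size = bin_size,
                   mf = 2^l2, log2mf = l2,
                   mask = rep(FALSE, length(l2)),
                   normalization_reference = reference),
              class = "mf_profile")
  })
}

#' Gaussian-corrected marker frequency near a fork convergence point
#'
#' The fcp inferred from a population profile is an average: individual
#' cells' forks converge at positions spread around it.  Modelling that
#' spread as Gaussian with standard deviation `sigma` (bp), the expected
#' linear-scale marker frequency at arc position `s` is the mixture
#' \deqn{MF(s) = \Phi((fcp - s)/\sigma)\,2^{L(s)} + (1 - \Phi((fcp - s)/\sigma))\,2^{R(s)}}
#' where `L` and `R` are the left- and right-arm log2 regression lines and
#' the mixing weight is the probability that the convergence point lies
#' beyond `s`.  At `sigma = 0` this is exactly the piecewise model.
#'
#' @param s Arc position(s) in bp, clockwise from the left origin.
#' @param fcp Fork convergence point, arc coordinate (bp).
#' @param sigma Gaussian spread in bp (>= 0).
#' @param left_intercept,left_slope Left-arm log2 line (intercept at arc 0).
#' @param right_intercept,right_slope Right-arm log2 line.
#' @return Linear-scale marker frequency at `s`.
#' @export
gaussian_corrected_mf <- function(s, fcp, sigma,
                                  left_intercept, left_slope,
                                  right_intercept, right_slope) {
  if (sigma < 0) stop("sigma must be >= 0")
  Lv <- left_intercept + left_slope * s
  Rv <- right_intercept + right_slope * s
  if (sigma == 0) {
    w <- as.numeric(s < fcp) + 0.5 * (s == fcp)
  } else {
    w <- stats::pnorm((fcp - s) / sigma)
  }
  w * 2^Lv + (1 - w) * 2^Rv
}

#' crtS-coupled initiation of a secondary chromosome
#'
#' In *V. cholerae* the secondary chromosome initiates replication only
#' once the chr1 locus crtS has been replicated.  The oriC2 firing offset
#' is therefore the replication age of crtS under the chr1 origins, plus an
#' extra licensing delay.
#'
#' @param genome A [genome_map()] defining loci `crts_locus` and `ori2_locus`.
#' @param chr1_origins List of [origin()]s on the primary chromosome.
#' @param params A [replication_parameters()].
#' @param extra_delay Additional delay in minutes between crtS replication
#'   and oriC2 firing (>= 0).
#' @param crts_locus,ori2_locus Locus names (defaults `"crtS"`, `"oriC2"`).
#' @return An [origin()] for the secondary chromosome with the coupled
#'   firing offset.
#' @export
crts_coupled_offset <- function(genome, chr1_origins, params, extra_delay = 0,
                                crts_locus = "crtS", ori2_locus = "oriC2") {
  stopifnot(inherits(genome, "genome_map"), extra_delay >= 0)
  crts <- locus_position(genome, crts_locus)
  ori2 <- locus_position(genome, ori2_locus)
  chr1 <- genome$replicons[[crts$replicon]]
  age <- replication_age(crts$position, chr1_origins, params, chr1)
  origin(ori2$replicon, ori2$position,
         firing_offset = age + extra_delay, name = ori2_locus)
}

#' Extra delay that makes two chromosomes terminate together
#'
#' Solves for the crtS licensing delay under which the secondary chromosome
#' (initiating at the crtS replication age plus the delay) completes
#' replication at the same age as the primary one.  Returns 0 if
#' co-termination would require a negative delay.
#'
#' @inheritParams crts_coupled_offset
#' @param chr2 Name of the secondary replicon.
#' @return Delay in minutes.
#' @export
co_termination_delay <- function(genome, chr1_origins, params,
                                 chr2 = "chr2", crts_locus = "crtS") {
  crts <- locus_position(genome, crts_locus)
  chr1 <- genome$replicons[[crts$replicon]]
  crts_age <- replication_age(crts$position, chr1_origins, params, chr1)
  f1 <- theoretical_fcps(chr1_origins, params, chr1)
  chr1_end <- max(f1$fcp_age)
  chr2_time <- genome$replicons[[chr2]]$length / (2 * params$v)
  max(0, chr1_end - chr2_time - crts_age)
}
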