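#' Describe an rrn head-on perturbation
#'
#' A ribosomal RNA operon transcribed against the direction of an incoming
#' replication fork stalls or damages that fork, depressing marker
#' frequencies downstream of the locus (in the fork's travel direction).
#' Modelled as a multiplicative depression `1 - magnitude * ramp`, with a
#' linear ramp from full depression at the locus to none at `extent` bp
#' downstream, applied only to bins replicated by a head-on fork.
#'
#' @param replicon Replicon name.
#' @param position Locus position (bp, 0-based).
#' @param transcription_direction `"clockwise"` or `"counterclockwise"`.
#' @param magnitude Copy-number depression fraction in `[0, 1)`.
#' @param extent Length of the affected region in bp (> 0).
#' @return Object of class `"rrn_perturbation"`.
#' @export
rrn_perturbation <- function(replicon, position,
                             transcription_direction = c("clockwise", "counterclockwise"),
                             magnitude, extent) {
  transcription_direction <- match.arg(transcription_direction)
  stopifnot(magnitude >= 0, magnitude < 1, extent > 0)
  structure(list(replicon = replicon, position = position,
                 transcription_direction = transcription_direction,
                 magnitude = magnitude, extent = extent),
            class = "rrn_perturbation")
}

#' Assemble a forward-simulation recipe
#'
#' @param genome A [genome_map()].
#' @param origins List of [origin()]s covering every replicon (crtS-coupled
#'   offsets already resolved, e.g. via [crts_coupled_offset()]).
#' @param params A [replication_parameters()].
#' @param bin_size Bin width in bp.
#' @param mean_depth Mean reads per bin at the profile minimum.
#' @param sigma_map Gaussian fcp spread in bp: a single number applied to
#'   every segment, or a named list `replicon -> vector` (one value per
#'   clockwise segment of that replicon).  Default 0 (no spread).
#' @param perturbations List of [rrn_perturbation()]s (default none).
#' @param seed Integer seed for count sampling.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(genome, origins, params, bin_size = 1000,
                           mean_depth = 200, sigma_map = 0,
                           perturbations = list(), seed = 1L) {
  stopifnot(inherits(genome, "genome_map"),
            inherits(params, "replication_parameters"),
            mean_depth > 0)
  if (inherits(perturbations, "rrn_perturbation"))
    perturbations <- list(perturbations)
  structure(list(genome = genome, origins = origins, params = params,
                 bin_size = bin_size, mean_depth = mean_depth,
                 sigma_map = sigma_map, perturbations = perturbations,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.sigma_for <- function(sigma_map, replicon_name, n_segments) {
  if (is.numeric(sigma_map) && length(sigma_map) == 1L)
    return(rep(sigma_map, n_segments))
  s <- sigma_map[[replicon_name]]
  if (is.null(s)) return(rep(0, n_segments))
  if (length(s) == 1L) return(rep(s, n_segments))
  if (length(s) != n_segments)
    stop("sigma_map for ", replicon_name, " must have 1 or ", n_segments, " values")
  s
}

#' Expected (noise-free) marker frequency profile of a simulation recipe
#'
#' Evaluates, per bin, the Cooper-Helmstetter expectation with the Gaussian
#' fcp spread of each segment (mixture of the two arm exponentials, see
#' [gaussian_corrected_mf()]) and any head-on rrn perturbations.  Output is
#' on the linear scale, unnormalised (maximum near 1 at the earliest
#' origin).
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of `mf_profile` objects (unnormalised).
#' @export
expected_profile <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  params <- spec$params
  out <- lapply(spec$genome$replicons, function(rep) {
    n <- ceiling(rep$length / spec$bin_size)
    ctr <- (seq_len(n) - 0.5) * spec$bin_size
    segs <- theoretical_fcps(spec$origins, params, rep)
    sig <- .sigma_for(spec$sigma_map, rep$name, nrow(segs))
    mf <- rep(NA_real_, n)
    fork_cw <- rep(NA, n)  # direction of the fork replicating each bin
    L <- rep$length
    offs <- vapply(.origins_on(spec$origins, rep$name), `[[`, numeric(1L),
                   "firing_offset")
    names(offs) <- vapply(.origins_on(spec$origins, rep$name), `[[`,
                          character(1L), "name")
    for (k in seq_len(nrow(segs))) {
      sg <- segs[k, ]
      s <- (ctr - sg$left_pos) %% L
      inseg <- s < sg$arc_length
      s_in <- s[inseg]
      off_l <- offs[[sg$left_origin]]
      off_r <- offs[[sg$right_origin]]
      # left/right arm log2 lines in arc coordinates (Cooper-Helmstetter)
      Lint <- -off_l / params$tau; Lslo <- -1 / (params$v * params$tau)
      Rint <- -(off_r + sg$arc_length / params$v) / params$tau
      Rslo <- 1 / (params$v * params$tau)
      fcp_arc <- (sg$fcp - sg$left_pos) %% L
      mf[inseg] <- gaussian_corrected_mf(s_in, fcp_arc, sig[k],
                                         Lint, Lslo, Rint, Rslo)
      fork_cw[inseg] <- s_in < fcp_arc
    }
    for (p in spec$perturbations) {
      if (p$replicon != rep$name) next
      if (p$position < 0 || p$position >= L)
        stop("perturbation locus off-replicon at ", p$position)
      head_on_cw <- p$transcription_direction == "counterclockwise"
      # distance from locus to bin along the fork's travel direction
      d <- if (head_on_cw) (ctr - p$position) %% L else (p$position - ctr) %% L
      hit <- fork_cw == head_on_cw & d >= 0 & d <= p$extent
      ramp <- 1 - d / p$extent
      mf[hit] <- mf[hit] * (1 - p$magnitude * ramp[hit])
    }
    structure(list(replicon = rep, bin_size = spec$bin_size,
                   mf = mf, log2mf = log2(mf),
                   mask = rep(FALSE, n),
                   normalization_reference = NA_character_),
              class = "mf_profile")
  })
  out
}

#' Sample Poisson read counts from expected profiles
#'
#' Counts per bin are independent Poisson draws with mean
#' `mean_depth * MF(bin) / min(MF)`, the minimum taken over all unmasked
#' bins of all supplied profiles (so between-replicon copy-number ratios
#' are preserved).  Reproducible under `seed`.
#'
#' @param expected A single `mf_profile` or named list of them.
#' @param mean_depth Mean reads/bin at the profile minimum.
#' @param seed Integer seed.
#' @return Named list of [binned_coverage()].
#' @export
sample_counts <- function(expected, mean_depth, seed) {
  if (inherits(expected, "mf_profile")) expected <- list(expected)
  gmin <- min(vapply(expected, function(p) min(p$mf[!p$mask], na.rm = TRUE),
                     numeric(1L)))
  if (!is.finite(gmin) || gmin <= 0)
    stop("expected marker frequencies must be positive")
  set.seed(as.integer(seed))
  out <- lapply(expected, function(p) {
    lam <- mean_depth * p$mf / gmin
    lam[is.na(lam)] <- 0
    binned_coverage(p$replicon, p$bin_size, stats::rpois(length(lam), lam),
                    mask = p$mask)
  })
  names(out) <- vapply(expected, function(p) p$replicon$name, character(1L))
  out
}

#' Simulate a full binned-coverage dataset
#'
#' @param spec A [synthetic_spec()].
#' @return List with `expected` (noise-free profiles) and `coverages`
#'   (Poisson-sampled [binned_coverage()] per replicon).
#' @export
simulate_dataset <- function(spec) {
  exp_p <- expected_profile(spec)
  list(expected = exp_p,
       coverages = sample_counts(exp_p, spec$mean_depth, spec$seed))
}

# -- ready-made genome geometries (synthetic stand-ins; the true N16961
#    coordinates are configurable through parse_genome_config) -------------

#' Two-chromosome *V. cholerae*-like genome map (synthetic stand-in)
#'
#' chr1 of 2,961,149 bp and chr2 of 1,072,315 bp, with oriC1/oriC2 at
#' position 0, dif1/dif2 at the antipode, crtS 690 kb counter-clockwise of
#' oriC1 (left replichore), an rrn locus on the left replichore transcribed
#' counter-clockwise (co-oriented with WT replication), and ectopic origin
#' sites oriL3 (650 kb, left replichore) and oriR4 (1,190 kb, right
#' replichore).
#'
#' @param chr1_length,chr2_length Replicon lengths in bp.
#' @return A [genome_map()].
#' @export
vcholerae_like_genome <- function(chr1_length = 2961149, chr2_length = 1072315) {
  genome_map(
    list(replicon("chr1", chr1_length), replicon("chr2", chr2_length)),
    data.frame(
      name = c("oriC1", "dif1", "crtS", "oriL3", "oriR4", "rrn_left",
               "oriC2", "dif2"),
      replicon = c(rep("chr1", 6L), "chr2", "chr2"),
      position = c(0, round(chr1_length / 2), chr1_length - 690000,
                   chr1_length - 650000, 1190000, chr1_length - 620000,
                   0, round(chr2_length / 2)),
      stringsAsFactors = FALSE))
}

.fixture_spec <- function(genome, chr1_ori_names, params, bin_size,
                          mean_depth, sigma_map, perturbations,
                          extra_delay, seed) {
  ors1 <- lapply(chr1_ori_names, function(nm) {
    lp <- locus_position(genome, nm)
    origin(lp$replicon, lp$position, firing_offset = 0, name = nm)
  })
  ori2 <- crts_coupled_offset(genome, ors1, params, extra_delay = extra_delay)
  synthetic_spec(genome, c(ors1, list(ori2)), params,
                 bin_size = bin_size, mean_depth = mean_depth,
                 sigma_map = sigma_map, perturbations = perturbations,
                 seed = seed)
}

#' Wild-type-like two-chromosome fixture
#'
#' Single origin per chromosome, chr2 initiation coupled to crtS with the
#' licensing delay solved for co-termination of the two chromosomes.
#' Defaults emulate exponential growth in minimal medium: tau = 40 min,
#' v = 60 kb/min (log2 slope about 4.2e-7 per bp), 1 kb bins, 2300
#' reads/bin at the profile minimum (217x with 75 bp reads), and a tight
#' termination zone (sigma 1 kb on both chromosomes).
#'
#' @param seed Integer seed for count sampling.
#' @param tau,v Replication parameters (minutes, bp/minute).
#' @param bin_size,mean_depth Binning and depth of the simulated run.
#' @param sigma Gaussian fcp spread in bp (recycled to every segment).
#' @return List with `genome`, `params`, `spec`, `origins`, `expected`
#'   and `coverages`.
#' @export
make_wt_like_fixture <- function(seed = 1L, tau = 40, v = 60000,
                                 bin_size = 1000, mean_depth = 2300,
                                 sigma = 1000) {
  genome <- vcholerae_like_genome()
  params <- replication_parameters(tau, v)
  ors1 <- list(origin("chr1", 0, name = "oriC1"))
  delay <- co_termination_delay(genome, ors1, params)
  spec <- .fixture_spec(genome, "oriC1", params, bin_size, mean_depth,
                        sigma, list(), delay, seed)
  sim <- simulate_dataset(spec)
  c(list(genome = genome, params = params, spec = spec,
         origins = spec$origins), sim)
}

#' Ectopic-origin fixture (left or right replichore)
#'
#' Adds a second, synchronously firing copy of the chr1 origin at oriL3
#' (650 kb up the left replichore) or oriR4 (1,190 kb up the right
#' replichore).  The crtS licensing delay is kept at its wild-type value,
#' so chr2 termination becomes early ("chr2 ahead") with the left ectopic
#' origin (crtS 40 kb from oriL3) and late ("chr2 behind") with the right
#' one (crtS close to the last-replicated region of chr1).  Optionally a
#' head-on rrn perturbation on the left replichore.
#'
#' @param arm `"left"` (oriL3) or `"right"` (oriR4).
#' @param seed Integer seed.
#' @param sigma Gaussian fcp spread in bp for every segment (default
#'   20 kb, the broadened termination zones of ectopic strains).
#' @param rrn_magnitude Depression fraction of the head-on rrn
#'   perturbation (0 disables it).
#' @param rrn_extent Perturbed region length in bp.
#' @inheritParams make_wt_like_fixture
#' @return Same structure as [make_wt_like_fixture()].
#' @export
make_ectopic_fixture <- function(arm = c("left", "right"), seed = 1L,
                                 tau = 40, v = 60000, bin_size = 1000,
                                 mean_depth = 2300, sigma = 20000,
                                 rrn_magnitude = 0, rrn_extent = 200000) {
  arm <- match.arg(arm)
  genome <- vcholerae_like_genome()
  params <- replication_parameters(tau, v)
  ors_wt <- list(origin("chr1", 0, name = "oriC1"))
  delay <- co_termination_delay(genome, ors_wt, params)  # WT biology retained
  ect <- if (arm == "left") "oriL3" else "oriR4"
  perts <- list()
  if (rrn_magnitude > 0) {
    rrn <- locus_position(genome, "rrn_left")
    perts <- list(rrn_perturbation("chr1", rrn$position, "counterclockwise",
                                   rrn_magnitude, rrn_extent))
  }
  spec <- .fixture_spec(genome, c("oriC1", ect), params, bin_size,
                        mean_depth, sigma, perts, delay, seed)
  sim <- simulate_dataset(spec)
  c(list(genome = genome, params = params, spec = spec,
         origins = spec$origins), sim)
}

#' Write a simulated dataset as genome config + bedGraph files
#'
#' Emits exactly the files the fitting entry point consumes, so synthetic
#' and real data share one input path.
#'
#' @param fixture Output of [make_wt_like_fixture()],
#'   [make_ectopic_fixture()] or [simulate_dataset()] plus a `genome`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.yaml"))
  write_genome_config(fixture$genome, paths$genome)
  for (nm in names(fixture$coverages)) {
    p <- file.path(dir, paste0(nm, ".bedgraph"))
    write_coverage_bedgraph(fixture$coverages[[nm]], p)
    paths[[nm]] <- p
  }
  invisible(paths)
}
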