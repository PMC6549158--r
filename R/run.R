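#' @keywords internal
.stage_error <- function(stage, e) {
  msg <- conditionMessage(e)
  stop(structure(class = c("mfaterm_stage_error", "error", "condition"),
                 list(message = sprintf("[%s] %s", stage, msg),
                      call = NULL, stage = stage)))
}

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "mfaterm_stage_error")) stop(e)
    .stage_error(stage, e)
  })
}

#' Read and validate a run configuration
#'
#' A run configuration is YAML with fields: `genome` (path to a genome
#' config), `coverage` (map replicon name -> bedGraph path), `origins`
#' (list; each entry either `locus: <name>` referring to a genome-map
#' locus, or `replicon`/`position`, optionally `firing_offset`),
#' `reference` (normalisation reference replicon, default: first),
#' `secondary` (replicon for synchrony classification, optional), and fit
#' options `iqr_factor` (default 3), `synchrony_tolerance` (default 0.05),
#' `windows` (origin-localisation window sizes, default 400000/600000).
#'
#' @param path YAML run configuration path.
#' @return Validated list (`"run_config"`): `genome` (a [genome_map()]),
#'   `coverage_paths`, `origins` (list of [origin()]), options.
#' @export
read_run_config <- function(path) {
  .with_stage("config", {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$genome)) stop("run config needs a 'genome' path")
    gpath <- cfg$genome
    if (!file.exists(gpath))
      gpath <- file.path(dirname(path), cfg$genome)
    if (!file.exists(gpath)) stop("genome config not found: ", cfg$genome)
    genome <- parse_genome_config(gpath)
    if (is.null(cfg$coverage) || !length(cfg$coverage))
      stop("run config needs 'coverage' (replicon -> bedGraph path)")
    covp <- lapply(cfg$coverage, function(p) {
      if (!file.exists(p)) p <- file.path(dirname(path), p)
      if (!file.exists(p)) stop("coverage file not found: ", p)
      p
    })
    missing_cov <- setdiff(names(genome$replicons), names(covp))
    if (length(missing_cov))
      stop("no coverage declared for replicon(s): ",
           paste(missing_cov, collapse = ", "))
    if (is.null(cfg$origins) || !length(cfg$origins))
      stop("run config needs at least one origin")
    origins <- lapply(cfg$origins, function(o) {
      off <- o$firing_offset %||% 0
      if (!is.null(o$locus)) {
        lp <- locus_position(genome, o$locus)
        origin(lp$replicon, lp$position, firing_offset = off, name = o$locus)
      } else {
        if (is.null(o$replicon) || is.null(o$position))
          stop("each origin needs 'locus' or 'replicon'+'position'")
        origin(o$replicon, as.numeric(o$position), firing_offset = off,
               name = o$name %||% NULL)
      }
    })
    structure(list(
      genome = genome, coverage_paths = covp, origins = origins,
      reference = cfg$reference %||% names(genome$replicons)[1L],
      secondary = cfg$secondary,
      iqr_factor = cfg$iqr_factor %||% 3,
      synchrony_tolerance = cfg$synchrony_tolerance %||% 0.05,
      windows = unlist(cfg$windows %||% c(4e5, 6e5)),
      path = normalizePath(path)), class = "run_config")
  })
}

.load_profiles <- function(rc) {
  covs <- .with_stage("read", lapply(names(rc$coverage_paths), function(nm)
    read_bedgraph(rc$coverage_paths[[nm]], rc$genome$replicons[[nm]])))
  covs <- .with_stage("trim", lapply(covs, trim_outlier_bins,
                                     iqr_factor = rc$iqr_factor))
  .with_stage("normalize", normalize_profiles(covs, rc$reference))
}

# Predicted log2 model curve for one replicon, from its segment fits.
.model_curve <- function(profile, fits) {
  L <- profile$replicon$length
  ctr <- bin_centers(profile)
  pred <- rep(NA_real_, length(ctr))
  for (f in fits) {
    s <- (ctr - f$left_pos) %% L
    inseg <- s <= f$arc_length & is.na(pred)
    sig <- if (is.na(f$sigma)) 0 else f$sigma
    pred[inseg] <- log2(gaussian_corrected_mf(
      s[inseg], f$fcp_arc, sig,
      f$left_intercept, f$left_slope, f$right_intercept, f$right_slope))
  }
  out <- profile
  out$log2mf <- pred
  out$mf <- 2^pred
  out$mask <- is.na(pred)
  out
}

#' Run the full termination-fitting pipeline
#'
#' Executes trim, normalisation, per-segment breakpoint fit and Gaussian
#' width fit, then writes to the output directory: `segment_report.tsv`,
#' `synchrony.tsv` (when a secondary replicon is configured),
#' `<replicon>.log2mf.bedgraph` (trimmed, normalised data),
#' `<replicon>.model.bedgraph` (fitted curves), a `run.log` of every
#' parameter, and a snapshot of the run configuration.  Outputs are
#' deterministic: rerunning an identical configuration reproduces them
#' byte for byte.
#'
#' @param config Path to a run configuration, or a `"run_config"`.
#' @param outdir Output directory (created; default `mfaterm_run` next to
#'   the config).
#' @return Invisibly, a list with `fits`, `report`, `synchrony`,
#'   `profiles` and `outdir`.
#' @export
run_fit <- function(config, outdir = NULL) {
  rc <- if (inherits(config, "run_config")) config else read_run_config(config)
  outdir <- outdir %||% file.path(dirname(rc$path %||% "."), "mfaterm_run")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  profiles <- .load_profiles(rc)
  fits <- .with_stage("fit", {
    res <- list()
    for (nm in names(profiles)) {
      ors <- .origins_on(rc$origins, nm)
      if (!length(ors)) next
      segs <- replicon_segments(ors, rc$genome$replicons[[nm]])
      res[[nm]] <- lapply(seq_len(nrow(segs)), function(k) {
        f <- fit_breakpoint(profiles[[nm]], segs[k, ])
        fit_gaussian_width(profiles[[nm]], f)
      })
    }
    res
  })
  .with_stage("report", {
    report <- segment_report(unlist(fits, recursive = FALSE), rc$genome)
    utils::write.table(report, file.path(outdir, "segment_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    synchrony <- NULL
    if (!is.null(rc$secondary) && !is.null(fits[[rc$secondary]])) {
      chr1 <- setdiff(names(fits), rc$secondary)[1L]
      if (!is.na(chr1)) {
        synchrony <- termination_synchrony(
          profiles, fits[[chr1]], fits[[rc$secondary]][[1L]],
          tolerance_log2 = rc$synchrony_tolerance)
        utils::write.table(synchrony, file.path(outdir, "synchrony.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    for (nm in names(profiles)) {
      write_profile_bedgraph(profiles[[nm]],
                             file.path(outdir, paste0(nm, ".log2mf.bedgraph")))
      if (!is.null(fits[[nm]]))
        write_profile_bedgraph(.model_curve(profiles[[nm]], fits[[nm]]),
                               file.path(outdir, paste0(nm, ".model.bedgraph")))
    }
    if (!is.null(rc$path))
      file.copy(rc$path, file.path(outdir, "config_snapshot.yaml"),
                overwrite = TRUE)
    log_lines <- c(
      "mfaterm fit run",
      paste0("reference: ", rc$reference),
      paste0("secondary: ", rc$secondary %||% "(none)"),
      paste0("iqr_factor: ", rc$iqr_factor),
      paste0("synchrony_tolerance: ", rc$synchrony_tolerance),
      paste0("origins: ", paste(vapply(rc$origins, function(o)
        sprintf("%s@%s:%g+%gmin", o$name, o$replicon, o$position,
                o$firing_offset), character(1L)), collapse = "; ")),
      paste0("segments fitted: ", nrow(report)))
    writeLines(log_lines, file.path(outdir, "run.log"))
    invisible(list(fits = fits, report = report, synchrony = synchrony,
                   profiles = profiles, outdir = outdir))
  })
}

#' Write a ready-made simulated dataset plus its run configuration
#'
#' @param outdir Output directory.
#' @param fixture `"wt"`, `"left"` (oriL3 ectopic) or `"right"` (oriR4).
#' @param seed Integer seed for count sampling.
#' @param ... Passed to [make_wt_like_fixture()] / [make_ectopic_fixture()].
#' @return Invisibly, the fixture plus the written `config` path.
#' @export
run_simulate <- function(outdir, fixture = c("wt", "left", "right"),
                         seed = 1L, ...) {
  fixture <- match.arg(fixture)
  fx <- switch(fixture,
               wt = make_wt_like_fixture(seed = seed, ...),
               left = make_ectopic_fixture("left", seed = seed, ...),
               right = make_ectopic_fixture("right", seed = seed, ...))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_fixture(fx, outdir)
  ori_entries <- lapply(fx$spec$origins, function(o)
    list(replicon = o$replicon, position = o$position,
         firing_offset = o$firing_offset, name = o$name))
  cfg <- list(genome = "genome.yaml",
              coverage = as.list(stats::setNames(
                paste0(names(fx$coverages), ".bedgraph"),
                names(fx$coverages))),
              origins = ori_entries,
              reference = "chr1", secondary = "chr2")
  cfg_path <- file.path(outdir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(c(fx, list(config = cfg_path, paths = paths)))
}

#' Validate the method by localising origins from coverage peaks
#'
#' For each replicon carrying exactly one declared origin, localises the
#' coverage-peak apex at each configured window size and reports the
#' distance to the declared origin in bp and as a percentage of replicon
#' length.
#'
#' @param config Path to a run configuration, or a `"run_config"`.
#' @param outdir Optional output directory for `origin_validation.tsv`.
#' @return `data.frame` with columns `replicon`, `window`, `apex`,
#'   `declared`, `error_bp`, `error_pct`.
#' @export
run_validate <- function(config, outdir = NULL) {
  rc <- if (inherits(config, "run_config")) config else read_run_config(config)
  profiles <- .load_profiles(rc)
  out <- .with_stage("validate", {
    rows <- list()
    for (nm in names(profiles)) {
      ors <- .origins_on(rc$origins, nm)
      if (length(ors) != 1L) next
      rep <- rc$genome$replicons[[nm]]
      loc <- localize_origin(profiles[[nm]], windows = rc$windows)
      err <- circular_distance(rep, loc$apex %% rep$length,
                               rep(ors[[1L]]$position, nrow(loc)), "shortest")
      rows[[nm]] <- data.frame(replicon = nm, window = loc$window,
                               apex = loc$apex, declared = ors[[1L]]$position,
                               error_bp = err,
                               error_pct = 100 * err / rep$length,
                               stringsAsFactors = FALSE)
    }
    if (!length(rows)) stop("no replicon with a single declared origin")
    do.call(rbind, rows)
  })
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out, file.path(outdir, "origin_validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
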