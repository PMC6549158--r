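#' Binned coverage container
#'
#' Read counts per fixed-width bin on one replicon, with a per-bin mask.
#' Masked bins (`mask = TRUE`) are excluded from trimming statistics,
#' normalisation totals, minima and all downstream fits.
#'
#' @param replicon A [replicon()].
#' @param bin_size Bin width in bp.
#' @param counts Non-negative numeric vector, one value per bin; its length
#'   must equal `ceiling(length / bin_size)`.
#' @param mask Logical vector, `TRUE` = excluded; defaults to all `FALSE`.
#' @return An object of class `"binned_coverage"`.
#' @export
binned_coverage <- function(replicon, bin_size, counts, mask = NULL) {
  stopifnot(inherits(replicon, "replicon"))
  bin_size <- as.numeric(bin_size)
  stopifnot(is.finite(bin_size), bin_size > 0)
  n <- ceiling(replicon$length / bin_size)
  counts <- as.numeric(counts)
  if (length(counts) != n)
    stop(sprintf("expected %d bins (%s bp / %s bp bins), got %d counts",
                 n, format(replicon$length), format(bin_size), length(counts)))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  structure(list(replicon = replicon, bin_size = bin_size,
                 counts = counts, mask = mask),
            class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat(sprintf("<binned_coverage> %s: %d bins of %s bp, %d masked, median count %.1f\n",
              x$replicon$name, length(x$counts), format(x$bin_size),
              sum(x$mask), stats::median(x$counts[!x$mask])))
  invisible(x)
}

#' Bin centre coordinates
#'
#' @param x A `binned_coverage` or `mf_profile`.
#' @return Numeric vector of bin centres (0-based bp).
#' @export
bin_centers <- function(x) {
  (seq_along(x$counts %||% x$mf) - 0.5) * x$bin_size
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a bedGraph file into binned coverage
#'
#' Expects a standard 4-column bedGraph (chrom, start, end, value), 0-based
#' half-open, with uniform interval width; the interval width becomes the
#' bin size.  Intervals must all belong to `replicon`.
#'
#' @param path Path to a bedGraph file.
#' @param replicon A [replicon()] the coverage belongs to.
#' @return A [binned_coverage()] with all mask flags `FALSE`.
#' @export
read_bedgraph <- function(path, replicon) {
  stopifnot(inherits(replicon, "replicon"))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) stop("no records in bedGraph file: ", path)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(chroms), replicon$name)
  if (length(bad))
    stop("bedGraph contains unknown chromosome name(s): ", paste(bad, collapse = ", "))
  w <- GenomicRanges::width(gr)
  start0 <- GenomicRanges::start(gr) - 1L  # GRanges is 1-based
  bin_size <- w[1L]
  n <- ceiling(replicon$length / bin_size)
  # the final bin of a replicon whose length is not a bin multiple is short
  last_short <- replicon$length - (n - 1L) * bin_size
  full <- w == bin_size
  is_last <- start0 == (n - 1L) * bin_size & w == last_short
  if (!all(full | is_last))
    stop("bedGraph intervals are not a uniform ", bin_size, " bp grid")
  if (any(start0 %% bin_size != 0))
    stop("bedGraph intervals are not aligned to a ", bin_size, " bp grid")
  vals <- gr$score
  if (any(vals < 0)) stop("negative coverage values in ", path)
  counts <- numeric(n)
  counts[start0 / bin_size + 1L] <- vals
  binned_coverage(replicon, bin_size, counts)
}

#' Count read starts per bin from a sorted alignment file
#'
#' Counts the number of mapped-read start positions (leftmost aligned base)
#' falling in each bin, the start-count convention that makes bin counts
#' Poisson-like.  Unmapped reads are ignored.
#'
#' @param path Coordinate-sorted, indexed BAM file.
#' @param genome A [genome_map()] whose replicon names match the alignment
#'   header.
#' @param bin_size Bin width in bp.
#' @return Named list of [binned_coverage()], one per replicon with reads.
#' @export
depth_from_alignments <- function(path, genome, bin_size) {
  stopifnot(inherits(genome, "genome_map"))
  bf <- Rsamtools::BamFile(path)
  if (!file.exists(paste0(path, ".bai")) && !file.exists(sub("\\.bam$", ".bai", path)))
    stop("missing BAM index (.bai) for ", path)
  hdr <- Rsamtools::scanBamHeader(bf)$targets
  known <- names(genome$replicons)
  bad <- setdiff(names(hdr), known)
  if (length(bad))
    stop("alignment header names not in genome map: ", paste(bad, collapse = ", "))
  prm <- Rsamtools::ScanBamParam(
    what = c("rname", "pos"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  aln <- Rsamtools::scanBam(bf, param = prm)[[1L]]
  out <- list()
  for (nm in intersect(known, names(hdr))) {
    rep <- genome$replicons[[nm]]
    n <- ceiling(rep$length / bin_size)
    keep <- !is.na(aln$rname) & as.character(aln$rname) == nm
    start0 <- aln$pos[keep] - 1L  # BAM pos is 1-based
    idx <- pmin(floor(start0 / bin_size), n - 1L) + 1L
    counts <- tabulate(idx, nbins = n)
    out[[nm]] <- binned_coverage(rep, bin_size, counts)
  }
  out
}

#' Mask outlier bins
#'
#' Marks as excluded every bin whose count is zero or falls outside the
#' Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]`, with quartiles computed over the
#' currently unmasked bins of the replicon.  Counts are left unchanged;
#' only the mask is updated.  When the IQR is zero only zero-count bins are
#' masked.
#'
#' @param cov A [binned_coverage()] with at least 20 unmasked bins.
#' @param iqr_factor Positive fence multiplier `k` (default 3).
#' @return The coverage with an updated mask.
#' @export
trim_outlier_bins <- function(cov, iqr_factor = 3) {
  stopifnot(inherits(cov, "binned_coverage"), iqr_factor > 0)
  live <- !cov$mask
  if (sum(live) < 20L)
    stop("need at least 20 unmasked bins to estimate trimming fences, have ", sum(live))
  x <- cov$counts[live]
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - iqr_factor * iqr
  hi <- q[2L] + iqr_factor * iqr
  bad <- cov$counts == 0 | cov$counts < lo | cov$counts > hi
  mask <- cov$mask | bad
  if (all(mask)) stop("profile empty after trimming")
  cov$mask <- mask
  cov
}

#' Normalise coverages into marker frequency profiles
#'
#' All coverages are placed on one common scale: each count is divided by
#' the grand total of unmasked counts across every replicon, then all values
#' are divided by the minimum unmasked value on the reference replicon, so
#' that the lowest point of the reference profile equals 1 (log2 = 0).
#' Minima on the other replicons may differ from 0; the between-replicon
#' ratio (e.g. chr2/chr1 copy number) is preserved.
#'
#' @param covs List of [binned_coverage()] (or a single one).
#' @param reference Name of the replicon whose minimum anchors the scale.
#' @return Named list of `mf_profile` objects, one per input coverage, with
#'   fields `mf` (linear scale, `NA` on masked bins), `log2mf`, `mask`,
#'   `bin_size`, `replicon` and `normalization_reference`.
#' @export
normalize_profiles <- function(covs, reference) {
  if (inherits(covs, "binned_coverage")) covs <- list(covs)
  nms <- vapply(covs, function(cv) cv$replicon$name, character(1L))
  names(covs) <- nms
  if (!reference %in% nms)
    stop("reference replicon '", reference, "' is not among the coverages")
  ref <- covs[[reference]]
  if (all(ref$mask)) stop("reference replicon is fully masked")
  grand <- sum(vapply(covs, function(cv) sum(cv$counts[!cv$mask]), numeric(1L)))
  if (grand <= 0) stop("no unmasked reads to normalise on")
  ref_min <- min(ref$counts[!ref$mask] / grand)
  if (ref_min <= 0) stop("reference minimum is zero; trim zero bins first")
  lapply(covs, function(cv) {
    mf <- cv$counts / grand / ref_min
    mf[cv$mask] <- NA_real_
    structure(list(replicon = cv$replicon, bin_size = cv$bin_size,
                   mf = mf, log2mf = log2(mf), mask = cv$mask,
                   normalization_reference = reference),
              class = "mf_profile")
  })
}

#' @export
print.mf_profile <- function(x, ...) {
  rng <- range(x$log2mf, na.rm = TRUE)
  cat(sprintf("<mf_profile> %s: %d bins of %s bp (%d masked), log2 range [%.3f, %.3f], ref %s\n",
              x$replicon$name, length(x$mf), format(x$bin_size), sum(x$mask),
              rng[1L], rng[2L], x$normalization_reference))
  invisible(x)
}

#' Write a marker frequency profile as bedGraph
#'
#' Emits `log2mf` per unmasked bin (masked bins are omitted), suitable for
#' overlay with fitted model curves in a genome browser.
#'
#' @param profile An `mf_profile`.
#' @param path Output path.
#' @param what Either `"log2mf"` (default) or `"mf"`.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(profile, path, what = c("log2mf", "mf")) {
  stopifnot(inherits(profile, "mf_profile"))
  what <- match.arg(what)
  keep <- !profile$mask
  n <- length(profile$mf)
  starts0 <- (seq_len(n) - 1L) * profile$bin_size
  ends0 <- pmin(starts0 + profile$bin_size, profile$replicon$length)
  gr <- GenomicRanges::GRanges(
    seqnames = profile$replicon$name,
    ranges = IRanges::IRanges(start = starts0[keep] + 1L, end = ends0[keep]),
    score = profile[[what]][keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write binned coverage as bedGraph
#'
#' @param cov A [binned_coverage()]; all bins are written, masked or not.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(cov, path) {
  stopifnot(inherits(cov, "binned_coverage"))
  n <- length(cov$counts)
  starts0 <- (seq_len(n) - 1L) * cov$bin_size
  ends0 <- pmin(starts0 + cov$bin_size, cov$replicon$length)
  gr <- GenomicRanges::GRanges(
    seqnames = cov$replicon$name,
    ranges = IRanges::IRanges(start = starts0 + 1L, end = ends0),
    score = cov$counts)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
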