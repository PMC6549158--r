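#' Define a replicon
#'
#' A replicon is one replication unit: a chromosome (usually circular) with a
#' name and a length.  Coordinates on a replicon are 0-based, half-open
#' internally; human-readable reports convert to 1-based.
#'
#' @param name Replicon identifier (e.g. `"chr1"`).
#' @param length Length in bp (positive integer).
#' @param circular Logical; is the replicon circular?
#' @return An object of class `"replicon"`.
#' @examples
#' replicon("chr1", 2961149)
#' @export
replicon <- function(name, length, circular = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  length <- as.numeric(length)
  if (!is.finite(length) || length <= 0 || length != floor(length))
    stop("replicon length must be a positive integer, got ", length)
  structure(list(name = name, length = length, circular = isTRUE(circular)),
            class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Assemble a genome map
#'
#' A genome map holds one or more replicons plus named landmark loci
#' (origins, dif sites, crtS, rrn operons, ...), each placed on a replicon at
#' a 0-based position.
#'
#' @param replicons List of [replicon()] objects (unique names).
#' @param loci `data.frame` with columns `name`, `replicon`, `position`
#'   (0-based bp), or `NULL` for none.
#' @return An object of class `"genome_map"`.
#' @examples
#' gm <- genome_map(list(replicon("chr1", 1e6)),
#'                  data.frame(name = "oriC1", replicon = "chr1", position = 0))
#' @export
genome_map <- function(replicons, loci = NULL) {
  if (inherits(replicons, "replicon")) replicons <- list(replicons)
  stopifnot(is.list(replicons), length(replicons) >= 1L)
  ok <- vapply(replicons, inherits, logical(1L), what = "replicon")
  if (!all(ok)) stop("all elements of 'replicons' must be replicon objects")
  nms <- vapply(replicons, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("duplicate replicon names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(replicons) <- nms
  if (is.null(loci)) {
    loci <- data.frame(name = character(), replicon = character(),
                       position = numeric(), stringsAsFactors = FALSE)
  } else {
    loci <- as.data.frame(loci, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "replicon", "position") %in% names(loci)))
    loci <- loci[, c("name", "replicon", "position")]
    if (anyDuplicated(loci$name)) stop("duplicate locus names: ",
                                       paste(unique(loci$name[duplicated(loci$name)]), collapse = ", "))
    bad <- setdiff(loci$replicon, nms)
    if (length(bad)) stop("locus placed on unknown replicon: ", paste(bad, collapse = ", "))
    for (i in seq_len(nrow(loci))) {
      L <- replicons[[loci$replicon[i]]]$length
      p <- loci$position[i]
      if (!is.finite(p) || p != floor(p) || p < 0 || p >= L)
        stop(sprintf("locus '%s' position %s outside [0, %d) on %s",
                     loci$name[i], format(p), L, loci$replicon[i]))
    }
  }
  structure(list(replicons = replicons, loci = loci), class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %d replicon(s), %d locus/loci\n",
              length(x$replicons), nrow(x$loci)))
  for (r in x$replicons) print(r)
  if (nrow(x$loci)) print(x$loci, row.names = FALSE)
  invisible(x)
}

#' Look up a locus position
#'
#' @param genome A [genome_map()].
#' @param name Locus name.
#' @return List with `replicon` (name) and `position` (0-based bp).
#' @export
locus_position <- function(genome, name) {
  stopifnot(inherits(genome, "genome_map"))
  i <- match(name, genome$loci$name)
  if (is.na(i)) stop("locus not found in genome map: ", name)
  list(replicon = genome$loci$replicon[i], position = genome$loci$position[i])
}

#' Parse a genome configuration file
#'
#' The configuration is YAML with a `replicons` list (each entry: `name`,
#' `length`, optional `circular`, default `TRUE`) and an optional `loci`
#' list (each entry: `name`, `replicon`, `position` in bp, 0-based).
#'
#' @param path Path to a YAML genome configuration.
#' @return A validated [genome_map()].
#' @export
parse_genome_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$replicons) || !length(cfg$replicons))
    stop("genome config declares no replicons: ", path)
  reps <- lapply(cfg$replicons, function(r) {
    if (is.null(r$name) || is.null(r$length))
      stop("each replicon needs 'name' and 'length'")
    replicon(r$name, r$length, circular = if (is.null(r$circular)) TRUE else r$circular)
  })
  loci <- NULL
  if (!is.null(cfg$loci) && length(cfg$loci)) {
    loci <- do.call(rbind, lapply(cfg$loci, function(l) {
      if (is.null(l$name) || is.null(l$replicon) || is.null(l$position))
        stop("each locus needs 'name', 'replicon' and 'position'")
      data.frame(name = l$name, replicon = l$replicon,
                 position = as.numeric(l$position), stringsAsFactors = FALSE)
    }))
  }
  genome_map(reps, loci)
}

#' Write a genome configuration file
#'
#' Inverse of [parse_genome_config()].
#'
#' @param genome A [genome_map()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_genome_config <- function(genome, path) {
  stopifnot(inherits(genome, "genome_map"))
  cfg <- list(
    replicons = lapply(unname(genome$replicons), function(r)
      list(name = r$name, length = r$length, circular = r$circular)),
    loci = lapply(seq_len(nrow(genome$loci)), function(i)
      list(name = genome$loci$name[i], replicon = genome$loci$replicon[i],
           position = genome$loci$position[i]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Arc distance on a (possibly circular) replicon
#'
#' @param replicon A [replicon()].
#' @param a,b Positions in bp, each in `[0, length)`.
#' @param direction One of `"clockwise"` (increasing coordinate, wrapping),
#'   `"counterclockwise"`, or `"shortest"`.
#' @return Arc length in bp.
#' @export
circular_distance <- function(replicon, a, b,
                              direction = c("shortest", "clockwise", "counterclockwise")) {
  stopifnot(inherits(replicon, "replicon"))
  direction <- match.arg(direction)
  L <- replicon$length
  if (any(a < 0 | a >= L) || any(b < 0 | b >= L))
    stop("positions must lie in [0, replicon length)")
  cw <- (b - a) %% L
  if (!replicon$circular) {
    # on a linear replicon the only valid arc is the direct one
    if (direction == "clockwise" && any(b < a))
      stop("clockwise arc would cross the end of a linear replicon")
    if (direction == "counterclockwise" && any(b > a))
      stop("counterclockwise arc would cross the end of a linear replicon")
    return(abs(b - a))
  }
  switch(direction,
         clockwise = cw,
         counterclockwise = (a - b) %% L,
         shortest = pmin(cw, L - cw))
}
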