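## Ensemble diagnostics over internal coordinates: bond distances, angles,
## dihedrals; histograms and sampler-vs-sampler width comparisons.

#' Internal-coordinate specification
#'
#' @param kind "distance" (2 atoms), "angle" (3) or "dihedral" (4).
#' @param atoms integer atom indices (distinct, 1-based).
#' @param label optional label.
#' @return A validated list.
#' @export
InternalCoordinateSpec <- function(kind = c("distance", "angle", "dihedral"),
                                   atoms, label = NULL) {
  kind <- match.arg(kind)
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
  atoms <- as.integer(atoms)
  if (length(atoms) != need)
    stop(kind, " needs ", need, " atom indices")
  if (anyDuplicated(atoms)) stop("atom indices must be distinct")
  list(kind = kind, atoms = atoms,
       label = label %||% paste0(kind, "(", paste(atoms, collapse = "-"),
                                 ")"))
}

.coord_value <- function(x, spec) {
  a <- spec$atoms
  switch(spec$kind,
    distance = sqrt(sum((x[a[2], ] - x[a[1], ])^2)),
    angle = {
      u <- x[a[1], ] - x[a[2], ]
      v <- x[a[3], ] - x[a[2], ]
      cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    },
    dihedral = {
      b1 <- x[a[2], ] - x[a[1], ]
      b2 <- x[a[3], ] - x[a[2], ]
      b3 <- x[a[4], ] - x[a[3], ]
      n1 <- pracma::cross(b1, b2)
      n2 <- pracma::cross(b2, b3)
      if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) return(NA_real_)
      m1 <- pracma::cross(n1, b2 / sqrt(sum(b2^2)))
      ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
      if (ang <= -180) ang + 360 else ang   # IUPAC (-180, 180]
    })
}

#' Internal-coordinate series over an ensemble
#'
#' Distances in Angstrom; angles and dihedrals in degrees, dihedrals in
#' (-180, 180] with the IUPAC sign convention. Dihedrals undefined because
#' of collinear atoms are returned as NA (with a warning naming the
#' members).
#'
#' @param ensemble a [GeometryEnsemble-class] or [Trajectory-class].
#' @param spec an [InternalCoordinateSpec()].
#' @return Numeric vector, one value per member/frame.
#' @export
coordinateSeries <- function(ensemble, spec) {
  arr <- coordinateArray(ensemble)
  n <- dim(arr)[1]
  if (any(spec$atoms > n)) stop("atom indices out of range 1..", n)
  vals <- vapply(seq_len(dim(arr)[3]), function(k)
    .coord_value(arr[, , k, drop = TRUE], spec), numeric(1))
  if (anyNA(vals))
    warning("undefined ", spec$kind, " (collinear atoms) for member(s): ",
            paste(utils::head(which(is.na(vals)), 10), collapse = ", "))
  vals
}

## Freedman-Diaconis bin width on a pooled series
.fd_breaks <- function(pooled) {
  iqr <- stats::IQR(pooled)
  bw <- if (iqr > 0) 2 * iqr / length(pooled)^(1 / 3)
        else diff(range(pooled)) / 30
  if (bw <= 0) bw <- 1
  lo <- min(pooled) - bw / 2
  hi <- max(pooled) + bw
  seq(lo, hi, by = bw)
}

#' Histogram of an internal coordinate over an ensemble
#'
#' @param ensemble a [GeometryEnsemble-class] or [Trajectory-class].
#' @param spec an [InternalCoordinateSpec()].
#' @param breaks histogram breaks (default: Freedman-Diaconis).
#' @return A list: \code{breaks}, \code{counts}, \code{summary} (mean, std,
#'   min, max, n).
#' @export
coordinateHistogram <- function(ensemble, spec, breaks = NULL) {
  v <- coordinateSeries(ensemble, spec)
  v <- v[!is.na(v)]
  if (is.null(breaks)) breaks <- .fd_breaks(v)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts,
       summary = list(mean = mean(v), std = stats::sd(v), min = min(v),
                      max = max(v), n = length(v)))
}

#' Compare coordinate distributions from two samplers
#'
#' Histograms both ensembles on a common (pooled Freedman-Diaconis) binning
#' and reports the ratio of standard deviations std(a)/std(b) with a seeded
#' bootstrap confidence interval.
#'
#' @param ensembleA,ensembleB ensembles of the same molecule/topology.
#' @param spec an [InternalCoordinateSpec()].
#' @param breaks optional common breaks.
#' @param nBoot bootstrap resamples (default 1000).
#' @param level CI level (default 0.95).
#' @param seed bootstrap RNG seed.
#' @return A list: \code{histA}, \code{histB}, \code{stdRatio}, \code{ci}
#'   (length-2), \code{seriesA}, \code{seriesB}.
#' @export
compareSamplers <- function(ensembleA, ensembleB, spec, breaks = NULL,
                            nBoot = 1000, level = 0.95, seed = 1) {
  if (dim(coordinateArray(ensembleA))[1] !=
      dim(coordinateArray(ensembleB))[1])
    stop("ensembles have different atom counts")
  va <- stats::na.omit(coordinateSeries(ensembleA, spec))
  vb <- stats::na.omit(coordinateSeries(ensembleB, spec))
  if (is.null(breaks)) breaks <- .fd_breaks(c(va, vb))
  ha <- graphics::hist(va, breaks = breaks, plot = FALSE)
  hb <- graphics::hist(vb, breaks = breaks, plot = FALSE)
  ratio <- stats::sd(va) / stats::sd(vb)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(seed)
  boots <- vapply(seq_len(nBoot), function(i) {
    stats::sd(sample(va, replace = TRUE)) /
      stats::sd(sample(vb, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - level) / 2
  list(histA = list(breaks = ha$breaks, counts = ha$counts),
       histB = list(breaks = hb$breaks, counts = hb$counts),
       stdRatio = ratio,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       seriesA = as.numeric(va), seriesB = as.numeric(vb))
}

#' Export a paired histogram as CSV
#'
#' Columns bin_left, bin_right, count_a, count_b.
#'
#' @param comparison result of [compareSamplers()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeHistogramCSV <- function(comparison, path) {
  br <- comparison$histA$breaks
  df <- data.frame(bin_left = br[-length(br)], bin_right = br[-1],
                   count_a = comparison$histA$counts,
                   count_b = comparison$histB$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
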