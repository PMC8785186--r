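## Multi-frame XYZ reader/writer. Coordinates are Angstrom; the comment line
## carries the geometry label.

#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then one "symbol x y z" line
#' per atom, repeated per frame. Coordinates are taken as Angstrom. The
#' comment line becomes the geometry label.
#'
#' @param path file path.
#' @param masses optional masses in amu applied to every frame; defaults to
#'   standard atomic weights of the parsed symbols.
#' @return A list of [Geometry-class] objects.
#' @seealso [writeXYZ()]
#' @export
readXYZ <- function(path, masses = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  geoms <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("XYZ format error at line ", i, ": expected atom count, got '",
           lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("XYZ format error at line ", i, ": header says ", n,
           " atoms but file ends early")
    label <- trimws(lines[i + 1L])
    sym <- character(n)
    xyz <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4)
        stop("XYZ format error at line ", ln, ": expected 'symbol x y z'")
      sym[k] <- tok[1]
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(v))
        stop("XYZ format error at line ", ln, ": unparsable coordinates")
      xyz[k, ] <- v
    }
    m <- if (is.null(masses)) atomicMass(sym) else masses
    geoms[[length(geoms) + 1L]] <- Geometry(sym, xyz, m, label = label)
    i <- i + 2L + n
  }
  if (!length(geoms)) stop("no frames found in ", path)
  geoms
}

#' Write geometries to a multi-frame XYZ file
#'
#' Coordinates are printed with 10 decimal places (Angstrom), so a
#' write-read round trip preserves them far beyond 1e-6 A.
#'
#' @param geometries a [Geometry-class] or list of them (a
#'   [GeometryEnsemble-class] is accepted and expanded via [members()]).
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeXYZ <- function(geometries, path) {
  if (is(geometries, "Geometry")) geometries <- list(geometries)
  if (is(geometries, "GeometryEnsemble")) geometries <- members(geometries)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geometries) {
    n <- nAtoms(g)
    writeLines(as.character(n), con)
    writeLines(geometryLabel(g), con)
    xyz <- coordinates(g)
    writeLines(sprintf("%-3s %16.10f %16.10f %16.10f",
                       elementSymbols(g), xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
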