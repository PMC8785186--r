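## Frequency-data IO: the Molden frequency dialect ([FREQ], [FR-COORD],
## [FR-NORM-COORD]) and a JSON fixture format. [FR-COORD] is Bohr (Molden
## standard); the JSON fixture is Angstrom throughout and says so.

#' Read frequencies and normal-mode vectors
#'
#' Parses raw vibrational data: a reference geometry, frequencies in cm^-1
#' and Cartesian mode vectors (3 n_atoms components each). Two dialects are
#' supported: \code{"molden"} (sections \code{[FREQ]}, \code{[FR-COORD]} in
#' Bohr, \code{[FR-NORM-COORD]}) and \code{"json-fixture"} (a JSON object
#' with fields \code{symbols}, \code{coords_A}, optional \code{masses_amu},
#' \code{frequencies_cm1}, \code{modes}, all in package units).
#'
#' The mode vectors are returned raw (not mass-weighted, not normalized);
#' feed them to [normalModeAnalysis()] via a Hessian, or orthonormalize as
#' needed. No unit coercion happens silently: Molden coordinates are
#' converted Bohr -> Angstrom because the dialect fixes that unit.
#'
#' @param path file path.
#' @param dialect "molden" or "json-fixture".
#' @return A list with elements \code{geometry} ([Geometry-class]),
#'   \code{frequencies} (cm^-1) and \code{modes} (3n x n_modes matrix).
#' @export
readFrequencies <- function(path, dialect = c("molden", "json-fixture")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(dialect,
    "molden" = .read_molden_freq(path),
    "json-fixture" = .read_json_freq(path))
  n3 <- 3L * nAtoms(out$geometry)
  if (nrow(out$modes) != n3)
    stop("format error: mode vectors have ", nrow(out$modes),
         " components, expected 3 x n_atoms = ", n3)
  if (ncol(out$modes) != length(out$frequencies))
    stop("format error: ", ncol(out$modes), " mode vectors for ",
         length(out$frequencies), " frequencies")
  out
}

.read_molden_freq <- function(path) {
  lines <- readLines(path)
  tag <- grepl("^\\s*\\[", lines)
  sec_at <- which(tag)
  sec_name <- toupper(gsub("[\\[\\]\\s]", "", lines[sec_at], perl = TRUE))
  grab <- function(name) {
    hit <- which(sec_name == name)
    if (!length(hit)) stop("format error: missing Molden section [", name, "]")
    from <- sec_at[hit[1]] + 1L
    to <- if (hit[1] < length(sec_at)) sec_at[hit[1] + 1L] - 1L
          else length(lines)
    ln <- lines[from:to]
    ln[nzchar(trimws(ln))]
  }
  freqs <- as.numeric(grab("FREQ"))
  if (anyNA(freqs)) stop("format error: unparsable [FREQ] entries")
  coord_ln <- grab("FR-COORD")
  tok <- strsplit(trimws(coord_ln), "\\s+")
  sym <- vapply(tok, `[`, "", 1)
  xyz_bohr <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz_bohr)) stop("format error: unparsable [FR-COORD] entries")
  geom <- Geometry(sym, xyz_bohr * .const$bohr_A)
  mode_ln <- grab("FR-NORM-COORD")
  vib_at <- grep("vibration", mode_ln, ignore.case = TRUE)
  if (length(vib_at) != length(freqs))
    stop("format error: ", length(vib_at), " 'vibration' blocks for ",
         length(freqs), " frequencies")
  bounds <- c(vib_at, length(mode_ln) + 1L)
  modes <- vapply(seq_along(vib_at), function(i) {
    rows <- mode_ln[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    v <- as.numeric(unlist(strsplit(trimws(rows), "\\s+")))
    if (anyNA(v) || length(v) != 3L * nAtoms(geom))
      stop("format error: vibration ", i, " has ", length(v),
           " components, expected ", 3L * nAtoms(geom))
    v
  }, numeric(3L * nAtoms(geom)))
  list(geometry = geom, frequencies = freqs, modes = modes)
}

.read_json_freq <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("symbols", "coords_A", "frequencies_cm1", "modes")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("format error: JSON fixture missing field(s): ",
         paste(miss, collapse = ", "))
  coords <- matrix(as.numeric(unlist(x$coords_A)), ncol = 3, byrow = TRUE)
  masses <- if (!is.null(x$masses_amu)) as.numeric(x$masses_amu)
            else atomicMass(as.character(x$symbols))
  geom <- Geometry(as.character(x$symbols), coords, masses)
  modes <- x$modes
  if (is.list(modes)) modes <- do.call(cbind, lapply(modes, as.numeric))
  modes <- as.matrix(modes)
  ## fixture stores one mode per entry; accept either orientation
  nf <- length(x$frequencies_cm1)
  if (nrow(modes) == nf && ncol(modes) == 3L * nAtoms(geom))
    modes <- t(modes)
  list(geometry = geom, frequencies = as.numeric(x$frequencies_cm1),
       modes = modes)
}

#' Write a NormalModeSet in the Molden frequency dialect
#'
#' Emits \code{[Molden Format]}, \code{[FREQ]} (cm^-1), \code{[FR-COORD]}
#' (Bohr) and \code{[FR-NORM-COORD]} sections. Mode vectors are written
#' as-is (mass-weighted orthonormal columns); a comment records this, since
#' quantum-chemistry codes differ in their normalization conventions.
#'
#' @param modes a [NormalModeSet-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeMoldenFrequencies <- function(modes, path) {
  stopifnot(is(modes, "NormalModeSet"))
  geom <- modes@geometry
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[Molden Format]",
               "; mass-weighted orthonormal normal modes",
               "[FREQ]",
               sprintf("%12.4f", frequencies(modes)),
               "[FR-COORD]"), con)
  xyz_b <- coordinates(geom) / .const$bohr_A
  writeLines(sprintf("%-3s %16.10f %16.10f %16.10f",
                     elementSymbols(geom), xyz_b[, 1], xyz_b[, 2],
                     xyz_b[, 3]), con)
  writeLines("[FR-NORM-COORD]", con)
  L <- modeVectors(modes)
  for (i in seq_len(ncol(L))) {
    writeLines(sprintf("vibration %d", i), con)
    v <- matrix(L[, i], ncol = 3, byrow = TRUE)
    writeLines(sprintf(" %16.10f %16.10f %16.10f", v[, 1], v[, 2], v[, 3]),
               con)
  }
  invisible(path)
}
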