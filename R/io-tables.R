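## CSV/plain-text tables: transition tables (the sole engine contract
## replacing an external electronic-structure stage), spectra, GLE matrices
## and flux / quantum-yield tables. Every file states its units in the
## header or a comment line.

#' Read / write a vertical-transition table (CSV)
#'
#' The CSV contract is \code{geometry_id,state,delta_E_eV,osc_strength} with
#' a header. This is the interface through which an external
#' electronic-structure engine (or a bundled toy chromophore) supplies
#' vertical excitation energies and oscillator strengths per sampled
#' geometry.
#'
#' @param path file path.
#' @return \code{readTransitionTable}: a [TransitionTable-class].
#' @export
readTransitionTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("geometry_id", "state", "delta_E_eV", "osc_strength")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("transition table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$delta_E_eV) | df$delta_E_eV <= 0 |
               !is.finite(df$osc_strength) | df$osc_strength < 0)
  if (length(bad))
    stop("transition table validation failed at row(s): ",
         paste(utils::head(bad, 20), collapse = ", "),
         " (need delta_E_eV > 0 and osc_strength >= 0)")
  TransitionTable(df$geometry_id, df$state, df$delta_E_eV, df$osc_strength)
}

#' @param table a [TransitionTable-class].
#' @rdname readTransitionTable
#' @export
writeTransitionTable <- function(table, path) {
  stopifnot(is(table, "TransitionTable"))
  df <- records(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vertical transitions: energies in eV, f dimensionless",
               "geometry_id,state,delta_E_eV,osc_strength"), con)
  writeLines(sprintf("%s,%d,%.10g,%.10g", df$geometry_id, df$state,
                     df$delta_E_eV, df$osc_strength), con)
  invisible(path)
}

#' Write / read a spectrum as CSV
#'
#' Columns \code{energy_eV,wavelength_nm,sigma_cm2}; the wavelength column
#' is derived as \eqn{\lambda = hc/E} = 1239.841984.../E (eV nm). Values are
#' printed with 8 significant digits.
#'
#' @param spectrum a [Spectrum-class].
#' @param path file path.
#' @return Invisibly (write) the path; (read) a [Spectrum-class].
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  e <- energyGrid(spectrum)
  if (!length(e)) stop("empty spectrum")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# photoabsorption cross-section: eV, nm, cm^2 molecule^-1",
               "energy_eV,wavelength_nm,sigma_cm2"), con)
  writeLines(sprintf("%.8g,%.8g,%.8g", e, .const$hc_evnm / e,
                     crossSection(spectrum)), con)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("energy_eV", "sigma_cm2") %in% names(df)))
    stop("spectrum CSV must have columns energy_eV and sigma_cm2")
  o <- order(df$energy_eV)
  Spectrum(df$energy_eV[o], df$sigma_cm2[o])
}

#' Read GLE thermostat parameter matrices
#'
#' Reads whitespace-delimited square matrices A (drift) and C (stationary
#' covariance) in the GLE4MD layout: dimension (Ns+1) x (Ns+1) where the
#' first index is the physical (mass-scaled) momentum. Lines starting with
#' \code{#} are comments. Units are declared explicitly and converted to
#' internal units (fs^-1 for A, eV for C) on read. If \code{path_C} is
#' NULL, C defaults to kT x identity — classical canonical sampling — and
#' the returned object is flagged accordingly.
#'
#' @param path_A path to the drift matrix file.
#' @param path_C path to the covariance matrix file, or NULL.
#' @param temperature target temperature, K.
#' @param units_A "fs-1" or "ps-1".
#' @param units_C "eV" or "K" (C in K means C_ij = k_B * value).
#' @return A [GLEParameters-class] object.
#' @export
readGLEParameters <- function(path_A, path_C = NULL, temperature,
                              units_A = c("fs-1", "ps-1"),
                              units_C = c("eV", "K")) {
  units_A <- match.arg(units_A)
  units_C <- match.arg(units_C)
  A <- .read_matrix(path_A)
  if (nrow(A) != ncol(A)) stop("A matrix must be square")
  if (units_A == "ps-1") A <- A / 1000
  if (is.null(path_C)) {
    C <- diag(.const$kb_ev * temperature, nrow(A))
    classical <- TRUE
  } else {
    C <- .read_matrix(path_C)
    if (nrow(C) != ncol(C)) stop("C matrix must be square")
    if (!identical(dim(C), dim(A)))
      stop("dimension mismatch: A is ", nrow(A), "x", ncol(A), ", C is ",
           nrow(C), "x", ncol(C))
    if (units_C == "K") C <- C * .const$kb_ev
    classical <- FALSE
  }
  GLEParameters(A, C, temperature, classicalC = classical)
}

.read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  if (any(vapply(rows, anyNA, TRUE)))
    stop("unparsable matrix entries in ", path)
  nc <- unique(lengths(rows))
  if (length(nc) != 1) stop("ragged matrix rows in ", path)
  do.call(rbind, rows)
}

#' Construct GLEParameters from in-memory matrices
#'
#' @param A drift matrix, fs^-1.
#' @param C stationary covariance, eV.
#' @param temperature target temperature, K.
#' @param classicalC flag marking C = kT I defaults.
#' @return A [GLEParameters-class].
#' @export
GLEParameters <- function(A, C, temperature, classicalC = FALSE) {
  A <- as.matrix(A); C <- as.matrix(C)
  ## Class= must be named: a slot named "C" would otherwise partially
  ## match new()'s Class argument
  new(Class = "GLEParameters", A = A, C = (C + t(C)) / 2,
      ns = nrow(A) - 1L, temperature = as.numeric(temperature),
      classicalC = classicalC)
}

#' Write a matrix in the GLE plain-text layout
#'
#' @param m matrix.
#' @param path output path.
#' @param comment header comment (units!), written after "# ".
#' @return Invisibly, the path.
#' @export
writeGLEMatrix <- function(m, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(comment)) writeLines(paste("#", comment), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.16e", r),
                                           collapse = " ")), con)
  invisible(path)
}

#' Read an actinic-flux or quantum-yield table (CSV)
#'
#' Two columns: \code{wavelength_nm} and \code{value}. For flux tables the
#' value is photons cm^-2 s^-1 nm^-1; for quantum-yield tables it is the
#' dimensionless yield. Yields outside [0, 1] trigger a warning (multi-
#' fragment conventions allow > 1), negatives an error.
#'
#' @param path file path.
#' @param kind "flux" or "yield" (controls validation only).
#' @return data.frame(wavelength_nm, value), sorted by wavelength.
#' @export
readWavelengthTable <- function(path, kind = c("flux", "yield")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop(kind, " table must have columns wavelength_nm,value")
  df <- df[order(df$wavelength_nm), , drop = FALSE]
  if (any(diff(df$wavelength_nm) <= 0))
    stop("duplicate wavelengths in ", kind, " table")
  if (any(df$value < 0)) stop(kind, " values must be >= 0")
  if (kind == "yield" && any(df$value > 1))
    warning("quantum yields > 1 found; assuming multi-fragment convention")
  df
}
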