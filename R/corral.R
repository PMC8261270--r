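#' Define a corral (wavenumber binning) scheme
#'
#' A corral scheme partitions a wavenumber axis into consecutive half-open
#' bins ("corrals") of fixed width. The default — 5 cm\eqn{^{-1}} steps over
#' 0–4,000 cm\eqn{^{-1}} — yields the 800-element CIMVF descriptor. Corral
#' \code{k} (1-based, labelled \code{Fk}) covers
#' \eqn{[range\_low + (k-1)\,step,\; range\_low + k\,step)}, so \code{F1}
#' covers \eqn{[0, 5)} and \code{F601} covers \eqn{[3000, 3005)}.
#'
#' @param step corral width in cm^-1 (positive).
#' @param range_low,range_high representable wavenumber range in cm^-1;
#'   the width must be an integer multiple of \code{step}.
#' @return An object of class \code{"corral_scheme"}: a list with elements
#'   \code{step}, \code{range_low}, \code{range_high} and \code{n_corrals}.
#' @examples
#' sc <- corral_scheme()
#' sc$n_corrals        # 800
#' wavenumber_to_feature(1204.48, sc)  # 241
#' @export
corral_scheme <- function(step = 5, range_low = 0, range_high = 4000) {
  stopifnot(is.numeric(step), length(step) == 1L, is.finite(step),
            is.numeric(range_low), length(range_low) == 1L,
            is.numeric(range_high), length(range_high) == 1L)
  if (step <= 0) stop("'step' must be positive")
  if (range_high <= range_low) stop("'range_high' must exceed 'range_low'")
  n <- (range_high - range_low) / step
  if (abs(n - round(n)) > 1e-9)
    stop("corral range width must be an integer multiple of 'step'")
  structure(list(step = step, range_low = range_low, range_high = range_high,
                 n_corrals = as.integer(round(n))),
            class = "corral_scheme")
}

#' @export
print.corral_scheme <- function(x, ...) {
  cat(sprintf("Corral scheme: %d corrals of %g cm^-1 over [%g, %g) cm^-1\n",
              x$n_corrals, x$step, x$range_low, x$range_high))
  invisible(x)
}

#' Map a wavenumber to its corral (feature index)
#'
#' Returns the 1-based index \code{k} of the corral containing
#' \code{wavenumber}; the corral is the half-open interval
#' \eqn{[range\_low + (k-1)\,step,\; range\_low + k\,step)}. A wavenumber
#' exactly on a boundary belongs to the upper corral, and
#' \code{range_high} itself is out of range.
#'
#' @param wavenumber numeric vector of wavenumbers (cm^-1).
#' @param scheme a [corral_scheme()].
#' @return Integer vector of feature indices.
#' @seealso [feature_label()], [feature_range()]
#' @export
wavenumber_to_feature <- function(wavenumber, scheme = corral_scheme()) {
  stopifnot(inherits(scheme, "corral_scheme"), is.numeric(wavenumber))
  bad <- !is.finite(wavenumber) |
    wavenumber < scheme$range_low | wavenumber >= scheme$range_high
  if (any(bad))
    stop(sprintf("wavenumber out of range [%g, %g): %s", scheme$range_low,
                 scheme$range_high,
                 paste(utils::head(wavenumber[bad], 3), collapse = ", ")))
  as.integer(floor((wavenumber - scheme$range_low) / scheme$step)) + 1L
}

#' Feature labels and wavenumber ranges of corrals
#'
#' `feature_label()` renders 1-based corral indices as `"Fk"` labels;
#' `feature_range()` returns the half-open wavenumber interval a corral
#' covers.
#'
#' @param k integer vector of corral indices (1-based).
#' @param scheme a [corral_scheme()].
#' @return `feature_label()`: character vector. `feature_range()`: a
#'   two-column matrix with columns `low` and `high` (cm^-1), one row per
#'   index.
#' @examples
#' feature_range(601)  # 3000 3005
#' @export
feature_label <- function(k) {
  stopifnot(all(k >= 1), all(k == round(k)))
  paste0("F", as.integer(k))
}

#' @rdname feature_label
#' @export
feature_range <- function(k, scheme = corral_scheme()) {
  stopifnot(inherits(scheme, "corral_scheme"),
            all(k >= 1), all(k <= scheme$n_corrals), all(k == round(k)))
  low <- scheme$range_low + (k - 1) * scheme$step
  cbind(low = low, high = low + scheme$step)
}

#' Build the CIMVF descriptor of one spectrum
#'
#' Sums mode intensities within each corral of \code{scheme}, producing the
#' corralled intensity of molecular vibrational frequency (CIMVF) vector.
#' Modes outside \eqn{[range\_low, range\_high)} are excluded and counted in
#' a warning; the result does not depend on the order of the input modes.
#'
#' @param spectrum a [vib_spectrum()].
#' @param scheme a [corral_scheme()].
#' @return An object of class \code{"cimvf_descriptor"}: a named numeric
#'   vector of length \code{scheme$n_corrals} (names \code{F1}, ...,) with
#'   attributes \code{molecule_id} and \code{scheme}.
#' @examples
#' sp <- vib_spectrum(c(1204.48, 1202.0), c(2, 3), "dhc")
#' d <- build_cimvf(sp)
#' d[["F241"]]  # 5
#' @export
build_cimvf <- function(spectrum, scheme = corral_scheme()) {
  stopifnot(inherits(spectrum, "vib_spectrum"), inherits(scheme, "corral_scheme"))
  w <- spectrum$modes$wavenumber
  i <- spectrum$modes$intensity
  in_range <- w >= scheme$range_low & w < scheme$range_high
  n_dropped <- sum(!in_range)
  if (n_dropped > 0)
    warning(sprintf("%s: %d mode(s) outside [%g, %g) cm^-1 dropped",
                    spectrum$molecule_id, n_dropped, scheme$range_low,
                    scheme$range_high))
  values <- numeric(scheme$n_corrals)
  if (any(in_range)) {
    k <- wavenumber_to_feature(w[in_range], scheme)
    sums <- rowsum(i[in_range], k)
    values[as.integer(rownames(sums))] <- sums[, 1]
  }
  names(values) <- feature_label(seq_len(scheme$n_corrals))
  structure(values, molecule_id = spectrum$molecule_id, scheme = scheme,
            n_dropped = n_dropped, class = "cimvf_descriptor")
}

#' Descriptor matrix for a panel of spectra
#'
#' Applies [build_cimvf()] to a list of spectra and stacks the results into
#' an \code{n_molecules x n_corrals} matrix (rows named by molecule id,
#' columns \code{F1}...\code{Fn}).
#'
#' @param spectra list of [vib_spectrum()] objects.
#' @param scheme a [corral_scheme()].
#' @return Numeric matrix with attribute \code{scheme}.
#' @export
cimvf_matrix <- function(spectra, scheme = corral_scheme()) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  rows <- lapply(spectra, function(s) as.numeric(build_cimvf(s, scheme)))
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(spectra, function(s) s$molecule_id, character(1))
  colnames(m) <- feature_label(seq_len(scheme$n_corrals))
  attr(m, "scheme") <- scheme
  m
}

#' Read and write descriptor matrices
#'
#' The matrix is stored as CSV (rows = molecules, columns = F1...Fn) with a
#' JSON sidecar (\code{<path>.json}) recording the corral scheme, so a
#' matrix can be re-read without guessing the binning.
#'
#' @param m descriptor matrix as returned by [cimvf_matrix()].
#' @param path CSV file path; the sidecar is written to \code{<path>.json}.
#' @return `write_cimvf_matrix()` returns `path` invisibly;
#'   `read_cimvf_matrix()` returns the matrix with its `scheme` attribute
#'   restored.
#' @export
write_cimvf_matrix <- function(m, path) {
  scheme <- attr(m, "scheme")
  if (is.null(scheme)) stop("matrix has no 'scheme' attribute")
  df <- data.frame(molecule_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(scheme[c("step", "range_low", "range_high", "n_corrals")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cimvf_matrix
#' @export
read_cimvf_matrix <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("scheme sidecar not found: ", sidecar)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  scheme <- corral_scheme(sc$step, sc$range_low, sc$range_high)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  attr(m, "scheme") <- scheme
  m
}
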