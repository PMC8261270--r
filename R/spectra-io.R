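#' Construct a vibrational spectrum
#'
#' Holds one molecule's normal modes as (wavenumber, intensity) pairs.
#' Wavenumbers must be finite; intensities are treated as opaque nonnegative
#' weights (no unit is assumed). Negative wavenumbers — the common log-file
#' convention for imaginary frequencies, i.e. a non-minimum geometry — are
#' rejected by default; with \code{drop_imaginary = TRUE} they are dropped
#' with a warning instead.
#'
#' @param wavenumber numeric vector, cm^-1.
#' @param intensity numeric vector of the same length, nonnegative.
#' @param molecule_id non-empty identifier string.
#' @param source free-text provenance (e.g. the file the modes came from).
#' @param drop_imaginary drop negative-wavenumber modes with a warning
#'   instead of failing.
#' @return An object of class \code{"vib_spectrum"}: a list with
#'   \code{molecule_id}, \code{modes} (a data frame with columns
#'   \code{wavenumber}, \code{intensity}, input order preserved) and
#'   \code{source}.
#' @export
vib_spectrum <- function(wavenumber, intensity, molecule_id,
                         source = "", drop_imaginary = FALSE) {
  if (!is.character(molecule_id) || length(molecule_id) != 1L ||
      is.na(molecule_id) || !nzchar(molecule_id))
    stop("'molecule_id' must be a non-empty string")
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("'wavenumber' and 'intensity' must have the same length")
  if (anyNA(wavenumber) || anyNA(intensity) ||
      any(!is.finite(wavenumber)) || any(!is.finite(intensity)))
    stop(molecule_id, ": non-finite wavenumber or intensity")
  if (any(intensity < 0))
    stop(molecule_id, ": negative intensity")
  if (any(wavenumber < 0)) {
    if (drop_imaginary) {
      n_im <- sum(wavenumber < 0)
      warning(sprintf("%s: dropped %d imaginary (negative) frequencies",
                      molecule_id, n_im))
      keep <- wavenumber >= 0
      wavenumber <- wavenumber[keep]
      intensity <- intensity[keep]
    } else {
      stop(molecule_id, ": imaginary (negative) frequency present; ",
           "re-optimize the geometry or set drop_imaginary = TRUE")
    }
  }
  structure(list(molecule_id = molecule_id,
                 modes = data.frame(wavenumber = wavenumber,
                                    intensity = intensity),
                 source = source),
            class = "vib_spectrum")
}

#' @export
print.vib_spectrum <- function(x, ...) {
  cat(sprintf("Vibrational spectrum '%s': %d modes", x$molecule_id,
              nrow(x$modes)))
  if (nrow(x$modes) > 0)
    cat(sprintf(", %g-%g cm^-1", min(x$modes$wavenumber),
                max(x$modes$wavenumber)))
  cat("\n")
  invisible(x)
}

#' Read a two-column spectrum table
#'
#' The canonical exchange format for spectra: plain text, one mode per line,
#' wavenumber then intensity, separated by whitespace and/or commas. Lines
#' starting with \code{#} and blank lines are skipped; extra trailing fields
#' are ignored. Mode order is preserved as read.
#'
#' @param path file path.
#' @param molecule_id identifier for the molecule; defaults to the file name
#'   without extension.
#' @inheritParams vib_spectrum
#' @return A [vib_spectrum()].
#' @export
read_spectrum_table <- function(path,
                                molecule_id = sub("\\.[^.]*$", "", basename(path)),
                                drop_imaginary = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  w <- numeric(0)
  i <- numeric(0)
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[[ln]])
    if (!nzchar(txt) || startsWith(txt, "#")) next
    fields <- strsplit(txt, "[,[:space:]]+")[[1]]
    if (length(fields) < 2L)
      stop(sprintf("%s:%d: expected at least 2 fields, got %d",
                   path, ln, length(fields)))
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals))
      stop(sprintf("%s:%d: malformed numeric field in '%s'", path, ln, txt))
    w <- c(w, vals[1])
    i <- c(i, vals[2])
  }
  vib_spectrum(w, i, molecule_id, source = path,
               drop_imaginary = drop_imaginary)
}

#' Write a spectrum to the two-column table format
#'
#' Values are written with 17 significant digits so that a read/write round
#' trip reproduces every (wavenumber, intensity) pair bit-identically.
#'
#' @param spectrum a [vib_spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "vib_spectrum"))
  header <- sprintf("# molecule_id: %s", spectrum$molecule_id)
  body <- sprintf("%.17g %.17g", spectrum$modes$wavenumber,
                  spectrum$modes$intensity)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read normal modes from a GAMESS log file
#'
#' Extracts the per-mode vibrational frequencies and IR intensities from the
#' normal-modes section of a GAMESS output (the \code{FREQUENCY:} /
#' \code{IR INTENSITY:} line pairs). A trailing \code{I} after a frequency
#' (the imaginary-mode marker) is read as a negative wavenumber and handled
#' per \code{drop_imaginary}. Near-zero translational/rotational modes are
#' retained as parsed; filtering is the caller's decision.
#'
#' @inheritParams read_spectrum_table
#' @return A [vib_spectrum()].
#' @export
read_gamess_log <- function(path,
                            molecule_id = sub("\\.[^.]*$", "", basename(path)),
                            drop_imaginary = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  grab <- function(pattern) {
    out <- numeric(0)
    for (ln in grep(pattern, lines)) {
      tokens <- strsplit(trimws(sub(".*:", "", lines[[ln]])),
                         "[[:space:]]+")[[1]]
      tokens <- tokens[nzchar(tokens)]
      vals <- numeric(0)
      for (tk in tokens) {
        if (toupper(tk) == "I") {
          # imaginary-mode marker applies to the preceding frequency
          if (!length(vals))
            stop(sprintf("%s:%d: stray imaginary marker", path, ln))
          vals[length(vals)] <- -abs(vals[length(vals)])
        } else {
          v <- suppressWarnings(as.numeric(tk))
          if (is.na(v))
            stop(sprintf("%s:%d: malformed numeric field '%s'", path, ln, tk))
          vals <- c(vals, v)
        }
      }
      out <- c(out, vals)
    }
    out
  }
  freq <- grab("^[[:space:]]*FREQUENCY:")
  inten <- grab("^[[:space:]]*IR INTENSITY:")
  if (!length(freq))
    stop(path, ": no recognizable FREQUENCY block")
  if (length(freq) != length(inten))
    stop(sprintf("%s: %d frequencies but %d IR intensities", path,
                 length(freq), length(inten)))
  vib_spectrum(freq, inten, molecule_id, source = path,
               drop_imaginary = drop_imaginary)
}

#' Read a ligand-panel manifest
#'
#' A manifest binds spectra to class labels: a CSV with columns
#' \code{molecule_id}, \code{spectrum_path} and \code{label}
#' (\code{agonist} or \code{non-agonist}). Relative spectrum paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return A data frame with columns \code{molecule_id},
#'   \code{spectrum_path} (resolved) and \code{label} (factor).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "spectrum_path", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$molecule_id))
    stop("duplicate molecule_id in manifest")
  rel <- !grepl("^(/|[A-Za-z]:)", df$spectrum_path)
  df$spectrum_path[rel] <- file.path(dirname(path), df$spectrum_path[rel])
  df$label <- factor(df$label)
  df[, need]
}
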