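#' Shannon entropy of a binary class labelling
#'
#' \eqn{H(C) = -\sum_c p_c \log_2 p_c}, in bits. A balanced agonist /
#' non-agonist panel has \eqn{H(C) = 1} bit; a single-class labelling has 0.
#'
#' @param labels vector (factor, character or logical) of class labels.
#' @return Entropy in bits.
#' @export
class_entropy <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# entropy (bits) of binary splits given per-group class-1 counts k out of n;
# vectorized, 0*log(0) := 0
.bin_entropy <- function(k, n) {
  p <- ifelse(n > 0, k / n, 0)
  q <- 1 - p
  h <- numeric(length(p))
  pos <- p > 0
  h[pos] <- h[pos] - p[pos] * log2(p[pos])
  pos <- q > 0
  h[pos] <- h[pos] - q[pos] * log2(q[pos])
  h
}

# IG of presence/absence coding for every column of x at once
.ig_presence <- function(x, y1) {
  n <- length(y1)
  n1 <- sum(y1)
  H <- .bin_entropy(n1, n)
  pres <- x > 0
  np <- colSums(pres)                  # molecules with the feature present
  n1p <- colSums(pres & y1)            # ... of which class 1
  Hc <- (np / n) * .bin_entropy(n1p, np) +
    ((n - np) / n) * .bin_entropy(n1 - n1p, n - np)
  pmax(H - Hc, 0)
}

# best supervised binary split of one continuous feature: thresholds at
# midpoints between consecutive distinct sorted values, keep the max IG
.ig_best_split <- function(v, y1) {
  n <- length(v)
  o <- order(v)
  vs <- v[o]
  cum1 <- cumsum(y1[o])
  cut_at <- which(diff(vs) > 0)        # split after these positions
  if (!length(cut_at)) return(0)
  n1 <- cum1[n]
  H <- .bin_entropy(n1, n)
  nl <- cut_at
  n1l <- cum1[cut_at]
  Hc <- (nl / n) * .bin_entropy(n1l, nl) +
    ((n - nl) / n) * .bin_entropy(n1 - n1l, n - nl)
  max(pmax(H - Hc, 0))
}

.check_two_classes <- function(labels, n) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (length(labels) != n)
    stop("one label per molecule required")
  if (nlevels(labels) != 2L)
    stop("exactly two non-empty classes required, got ", nlevels(labels))
  labels
}

#' Information gain of descriptor features
#'
#' The information gain of a corral is the reduction in class entropy from
#' conditioning on the discretized feature,
#' \eqn{IG = H(C) - H(C \mid F)}, in bits. Two discretizers are available:
#' \describe{
#'   \item{\code{"presence"}}{the feature is binarized as intensity > 0
#'     (default).}
#'   \item{\code{"split"}}{supervised best binary split: all thresholds at
#'     midpoints of consecutive distinct observed values are evaluated and
#'     the maximum IG is kept.}
#' }
#' A degenerate discretization (all molecules on one side) yields 0 bits.
#'
#' @param x descriptor matrix (molecules x corrals), e.g. from
#'   [cimvf_matrix()]; a plain numeric vector is treated as one feature.
#' @param labels binary class labels, one per row of \code{x}.
#' @param discretizer \code{"presence"} or \code{"split"}.
#' @return Numeric vector of IG values in bits, one per column of \code{x},
#'   named by column. Always in \eqn{[0, H(C)]}.
#' @export
information_gain <- function(x, labels, discretizer = c("presence", "split")) {
  discretizer <- match.arg(discretizer)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  labels <- .check_two_classes(labels, nrow(x))
  y1 <- labels == levels(labels)[1]
  ig <- if (discretizer == "presence") {
    .ig_presence(x, y1)
  } else {
    apply(x, 2, .ig_best_split, y1 = y1)
  }
  names(ig) <- colnames(x)
  ig
}

#' Rank corrals by information gain
#'
#' Scores every corral with [information_gain()] and sorts by IG
#' descending, ties broken by ascending feature index. The subset with
#' strictly positive IG is the informative-feature selection.
#'
#' @inheritParams information_gain
#' @param scheme the [corral_scheme()] the columns of \code{x} follow; used
#'   to annotate wavenumber ranges.
#' @return A data frame (one row per corral, ranked) with columns
#'   \code{feature} (label), \code{index}, \code{range_low},
#'   \code{range_high} (cm^-1), \code{frequency} (molecules with nonzero
#'   intensity) and \code{ig_bits}.
#' @export
rank_features <- function(x, labels, discretizer = c("presence", "split"),
                          scheme = attr(x, "scheme")) {
  if (is.null(scheme)) scheme <- corral_scheme()
  ig <- information_gain(x, labels, discretizer)
  idx <- seq_len(ncol(x))
  rng <- feature_range(idx, scheme)
  out <- data.frame(feature = feature_label(idx), index = idx,
                    range_low = rng[, "low"], range_high = rng[, "high"],
                    frequency = presence_counts(x), ig_bits = as.numeric(ig))
  out <- out[order(-out$ig_bits, out$index), ]
  rownames(out) <- NULL
  out
}

#' Per-corral presence counts
#'
#' Number of molecules with nonzero intensity in each corral; the
#' "frequency" column of the informative-feature report.
#'
#' @param x descriptor matrix (molecules x corrals).
#' @return Integer vector, one count per column.
#' @export
presence_counts <- function(x) {
  colSums(x > 0)
}

#' Count corrals empty in every molecule of a class
#'
#' @param x descriptor matrix.
#' @param labels class labels, one per row.
#' @param class the class to count for; \code{NULL} counts corrals empty in
#'   the whole panel.
#' @return Integer: corrals with zero intensity in every selected molecule.
#' @export
zero_corral_count <- function(x, labels = NULL, class = NULL) {
  if (!is.null(class)) {
    if (is.null(labels)) stop("'labels' required when 'class' is given")
    keep <- labels == class
    if (!any(keep)) stop("class '", class, "' is empty")
    x <- x[keep, , drop = FALSE]
  }
  sum(colSums(x > 0) == 0)
}

#' Per-class mean intensity profile
#'
#' Column-wise arithmetic mean of the descriptors in one class — the
#' quantity plotted when comparing agonist and non-agonist vibrational
#' signatures along the wavenumber axis.
#'
#' @inheritParams zero_corral_count
#' @param class the class to average over.
#' @return Numeric vector of length \code{ncol(x)}, named by column.
#' @export
mean_intensity_profile <- function(x, labels, class) {
  keep <- labels == class
  if (!any(keep)) stop("class '", class, "' is empty")
  colMeans(x[keep, , drop = FALSE])
}
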