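#' Fit a CIMVF information-gain model
#'
#' The central estimator of the package: given a descriptor matrix for a
#' ligand panel and binary agonist / non-agonist labels, scores every corral
#' by information gain (bits), ranks them, and retains the training panel so
#' the fitted object can classify new molecules by nearest-neighbour search
#' over the informative (IG > 0) corrals.
#'
#' @param x descriptor matrix (molecules x corrals) from [cimvf_matrix()],
#'   rows named by molecule id.
#' @param labels binary class labels, one per row of \code{x}. The first
#'   factor level is the reference class for internal coding; IG is
#'   invariant to which class that is.
#' @param discretizer passed to [information_gain()].
#' @param scheme the [corral_scheme()]; defaults to the matrix's
#'   \code{scheme} attribute.
#' @return An object of class \code{"cimvf_fit"} with components
#'   \code{ranking} (the [rank_features()] data frame), \code{entropy}
#'   (H(C), bits), \code{selected} (indices with IG > 0), \code{x},
#'   \code{labels}, \code{discretizer}, \code{scheme} and \code{call}.
#' @seealso [predict.cimvf_fit()], [loocv_cimvf()]
#' @examples
#' sim <- simulate_spectra(n_per_class = 10, seed = 1)
#' m <- cimvf_matrix(sim$spectra)
#' fit <- cimvf_fit(m, sim$labels)
#' head(summary(fit)$informative)
#' @export
cimvf_fit <- function(x, labels, discretizer = c("presence", "split"),
                      scheme = attr(x, "scheme")) {
  discretizer <- match.arg(discretizer)
  if (is.null(scheme)) scheme <- corral_scheme()
  stopifnot(is.matrix(x), ncol(x) == scheme$n_corrals)
  labels <- .check_two_classes(labels, nrow(x))
  ranking <- rank_features(x, labels, discretizer, scheme)
  structure(list(ranking = ranking,
                 entropy = class_entropy(labels),
                 selected = sort(ranking$index[ranking$ig_bits > 0]),
                 x = x, labels = labels, discretizer = discretizer,
                 scheme = scheme, call = match.call()),
            class = "cimvf_fit")
}

#' @export
print.cimvf_fit <- function(x, ...) {
  n <- nrow(x$x)
  tab <- table(x$labels)
  cat(sprintf("CIMVF information-gain model (%s discretizer)\n", x$discretizer))
  cat(sprintf("  panel: %d molecules (%s)\n", n,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  cat(sprintf("  class entropy H(C) = %.4f bits\n", x$entropy))
  cat(sprintf("  informative corrals (IG > 0): %d of %d\n",
              length(x$selected), x$scheme$n_corrals))
  top <- utils::head(x$ranking[x$ranking$ig_bits > 0, ], 5)
  if (nrow(top)) {
    cat("  top corrals:\n")
    for (r in seq_len(nrow(top)))
      cat(sprintf("    %-5s %6g-%-6g cm^-1  IG = %.4f bits\n",
                  top$feature[r], top$range_low[r], top$range_high[r],
                  top$ig_bits[r]))
  }
  invisible(x)
}

#' Summarize a fitted CIMVF model
#'
#' The summary's \code{informative} table lists the corrals with IG > 0 in
#' rank order with their wavenumber ranges, presence frequencies and IG
#' scores — the informative-feature report for a panel.
#'
#' @param object a [cimvf_fit()] object.
#' @param ... unused.
#' @return An object of class \code{"summary.cimvf_fit"}.
#' @export
summary.cimvf_fit <- function(object, ...) {
  inf <- object$ranking[object$ranking$ig_bits > 0, , drop = FALSE]
  rownames(inf) <- NULL
  structure(list(n = nrow(object$x), class_counts = table(object$labels),
                 entropy = object$entropy, discretizer = object$discretizer,
                 informative = inf,
                 zero_corrals = vapply(levels(object$labels), function(cl)
                   zero_corral_count(object$x, object$labels, cl), integer(1))),
            class = "summary.cimvf_fit")
}

#' @export
print.summary.cimvf_fit <- function(x, ...) {
  cat(sprintf("CIMVF panel: %d molecules; H(C) = %.4f bits; discretizer: %s\n",
              x$n, x$entropy, x$discretizer))
  cat("empty corrals per class:",
      paste(sprintf("%s = %d", names(x$zero_corrals), x$zero_corrals),
            collapse = ", "), "\n")
  cat(sprintf("informative corrals (IG > 0): %d\n", nrow(x$informative)))
  if (nrow(x$informative)) {
    df <- x$informative
    df$wavenumber <- sprintf("%g-%g", df$range_low, df$range_high)
    print(df[, c("feature", "wavenumber", "frequency", "ig_bits")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.cimvf_fit <- function(object, ...) {
  ig <- object$ranking$ig_bits[order(object$ranking$index)]
  names(ig) <- feature_label(seq_along(ig))
  ig
}

# majority class of a label vector; ties go to the first factor level
.majority_class <- function(labels) {
  tab <- table(labels)
  levels(labels)[which.max(tab)]
}

# 1-NN on Euclidean distance over the given feature columns; distance ties
# broken by lower training-row index (which.min's convention)
.predict_1nn <- function(train_x, train_labels, new_x, features) {
  tr <- train_x[, features, drop = FALSE]
  nw <- new_x[, features, drop = FALSE]
  out <- character(nrow(nw))
  for (i in seq_len(nrow(nw))) {
    d2 <- rowSums(sweep(tr, 2, nw[i, ])^2)
    out[i] <- as.character(train_labels[which.min(d2)])
  }
  out
}

# naive presence-vote: each selected feature votes for the class whose
# training presence rate better matches the query's presence/absence of
# that feature; majority of votes wins, with ties (including no votes)
# falling back to the training majority class
.predict_vote <- function(train_x, train_labels, new_x, features) {
  lv <- levels(train_labels)
  pres <- train_x[, features, drop = FALSE] > 0
  rate1 <- colMeans(pres[train_labels == lv[1], , drop = FALSE])
  rate2 <- colMeans(pres[train_labels == lv[2], , drop = FALSE])
  fallback <- .majority_class(train_labels)
  out <- character(nrow(new_x))
  for (i in seq_len(nrow(new_x))) {
    on <- new_x[i, features] > 0
    p1 <- ifelse(on, rate1, 1 - rate1)
    p2 <- ifelse(on, rate2, 1 - rate2)
    v1 <- sum(p1 > p2)
    v2 <- sum(p2 > p1)
    out[i] <- if (v1 > v2) lv[1] else if (v2 > v1) lv[2] else fallback
  }
  out
}

#' Classify new molecules with a fitted CIMVF model
#'
#' Predicts agonist / non-agonist labels for new descriptors. The default
#' classifier is 1-nearest-neighbour on Euclidean distance over the
#' informative (IG > 0) corrals, with distance ties broken by lower
#' training-row index; \code{"vote"} is a naive presence-vote over the same
#' corrals (each corral votes for the class whose training presence rate
#' better matches the query's occupancy of it). If no corral scored IG > 0
#' the prediction falls back to the
#' training majority class (ties to the first factor level).
#'
#' @param object a [cimvf_fit()] object.
#' @param newdata descriptor matrix (or single descriptor vector) with the
#'   same corral scheme as the training panel.
#' @param classifier \code{"1nn"} or \code{"vote"}.
#' @param features \code{"ig_positive"} (default) restricts to corrals with
#'   IG > 0; \code{"all"} uses every corral.
#' @param ... unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.cimvf_fit <- function(object, newdata, classifier = c("1nn", "vote"),
                              features = c("ig_positive", "all"), ...) {
  classifier <- match.arg(classifier)
  features <- match.arg(features)
  if (is.vector(newdata) && is.numeric(newdata))
    newdata <- matrix(newdata, nrow = 1)
  stopifnot(ncol(newdata) == ncol(object$x))
  feat <- if (features == "all") seq_len(ncol(object$x)) else object$selected
  pred <- if (!length(feat)) {
    rep(.majority_class(object$labels), nrow(newdata))
  } else if (classifier == "1nn") {
    .predict_1nn(object$x, object$labels, newdata, feat)
  } else {
    .predict_vote(object$x, object$labels, newdata, feat)
  }
  factor(pred, levels = levels(object$labels))
}

#' Plot per-class mean CIMVF profiles
#'
#' Draws the mean corral intensity of each class against wavenumber, with
#' rug marks at the informative (IG > 0) corrals.
#'
#' @param x a [cimvf_fit()] object.
#' @param ... passed to [graphics::matplot()].
#' @return \code{x}, invisibly.
#' @export
plot.cimvf_fit <- function(x, ...) {
  lv <- levels(x$labels)
  mid <- x$scheme$range_low +
    (seq_len(x$scheme$n_corrals) - 0.5) * x$scheme$step
  prof <- sapply(lv, function(cl) mean_intensity_profile(x$x, x$labels, cl))
  graphics::matplot(mid, prof, type = "l", lty = 1, col = c(2, 4),
                    xlab = expression(paste("wavenumber (", cm^-1, ")")),
                    ylab = "mean corral intensity", ...)
  if (length(x$selected))
    graphics::rug(mid[x$selected], col = "grey40")
  graphics::legend("topright", legend = lv, col = c(2, 4), lty = 1, bty = "n")
  invisible(x)
}

#' Leave-one-out cross-validated classification of a ligand panel
#'
#' For each molecule in turn, the remaining n - 1 form the training fold:
#' informative corrals are re-scored within the fold (no information from
#' the held-out molecule enters feature selection), the fold's classifier
#' predicts the held-out label, and the per-fold predictions are pooled into
#' an overall accuracy and confusion table. Deterministic given the data and
#' the documented tie-break rules.
#'
#' @inheritParams cimvf_fit
#' @param classifier \code{"1nn"} (default) or \code{"vote"}; see
#'   [predict.cimvf_fit()].
#' @param selection \code{"fold"} recomputes the IG > 0 feature subset
#'   within each training fold (default); \code{"global"} selects once on
#'   the full panel (a laxer protocol that leaks the held-out molecule into
#'   selection, provided for comparison).
#' @param features \code{"ig_positive"} or \code{"all"} (no selection).
#' @return An object of class \code{"cimvf_loocv"}: list with
#'   \code{accuracy}, \code{confusion} (truth x predicted table),
#'   \code{predictions} (per-fold data frame with the number of selected
#'   features), and \code{n_fallback} (folds with an empty feature subset,
#'   predicted as the training-fold majority class).
#' @examples
#' sim <- simulate_spectra(n_per_class = 8, seed = 7)
#' cv <- loocv_cimvf(cimvf_matrix(sim$spectra), sim$labels)
#' cv$accuracy
#' @export
loocv_cimvf <- function(x, labels, classifier = c("1nn", "vote"),
                        discretizer = c("presence", "split"),
                        selection = c("fold", "global"),
                        features = c("ig_positive", "all"),
                        scheme = attr(x, "scheme")) {
  classifier <- match.arg(classifier)
  discretizer <- match.arg(discretizer)
  selection <- match.arg(selection)
  features <- match.arg(features)
  if (is.null(scheme)) scheme <- corral_scheme()
  labels <- .check_two_classes(labels, nrow(x))
  n <- nrow(x)
  all_feat <- seq_len(ncol(x))
  global_sel <- if (features == "all") all_feat else
    which(information_gain(x, labels, discretizer) > 0)
  pred <- character(n)
  n_feat <- integer(n)
  fold_features <- vector("list", n)
  n_fallback <- 0L
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_y <- droplevels(labels[-i])
    if (nlevels(tr_y) < 2) {
      # one-class training fold (1 molecule/class panels): majority fallback
      fold_features[[i]] <- integer(0)
      n_fallback <- n_fallback + 1L
      pred[i] <- .majority_class(tr_y)
      next
    }
    feat <- if (features == "all") all_feat
      else if (selection == "global") global_sel
      else which(information_gain(tr_x, tr_y, discretizer) > 0)
    fold_features[[i]] <- feat
    n_feat[i] <- length(feat)
    if (!length(feat)) {
      n_fallback <- n_fallback + 1L
      pred[i] <- .majority_class(tr_y)
    } else if (classifier == "1nn") {
      pred[i] <- .predict_1nn(tr_x, tr_y, x[i, , drop = FALSE], feat)
    } else {
      pred[i] <- .predict_vote(tr_x, tr_y, x[i, , drop = FALSE], feat)
    }
  }
  pred <- factor(pred, levels = levels(labels))
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  predictions <- data.frame(molecule_id = ids, truth = labels,
                            predicted = pred, n_features = n_feat)
  structure(list(accuracy = mean(pred == labels),
                 confusion = table(truth = labels, predicted = pred),
                 predictions = predictions,
                 fold_features = fold_features,
                 n_fallback = n_fallback,
                 classifier = classifier, discretizer = discretizer,
                 selection = selection),
            class = "cimvf_loocv")
}

#' @export
print.cimvf_loocv <- function(x, ...) {
  cat(sprintf("Leave-one-out CV (%s classifier, %s discretizer, %s selection)\n",
              x$classifier, x$discretizer, x$selection))
  cat(sprintf("  accuracy: %.4f (%d/%d)\n", x$accuracy,
              sum(diag(x$confusion)), sum(x$confusion)))
  if (x$n_fallback > 0)
    cat(sprintf("  folds with empty feature subset (majority fallback): %d\n",
                x$n_fallback))
  print(x$confusion)
  invisible(x)
}
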