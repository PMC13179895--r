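## Cross-validation of GBLUP predictive ability. Folds always partition
## lines (never individual plants), since the prediction target is the
## line's additive genetic value; plant-level input is first reduced to
## adjusted means, matching how predictive ability is defined (correlation
## of adjusted means with predicted GEBVs in the validation set).

cv_means <- function(data, grm, trait, line, experiment) {
  if (inherits(data, "adjusted_means")) {
    stats::setNames(data$value, data$line)
  } else if (is.numeric(data) && !is.null(names(data))) {
    data
  } else {
    am <- adjusted_means(data, trait, line = line, experiment = experiment)
    stats::setNames(am$value, am$line)
  }
}

cv_predict_folds <- function(y, Gfull, folds, refit = TRUE, varcomp = NULL,
                             ...) {
  ids <- names(y)
  pred <- stats::setNames(rep(NA_real_, length(y)), ids)
  failed <- 0L
  for (f in unique(folds)) {
    hold <- ids[folds == f]
    train <- setdiff(ids, hold)
    fit <- tryCatch(
      gblup(y[train], grm = Gfull,
            varcomp = if (refit) NULL else varcomp, ...),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    pred[hold] <- predict(fit, grm = Gfull, lines = hold)
  }
  list(pred = pred, failed = failed)
}

new_cv_result <- function(trait, scheme, k, repeats, seed, r, pred, obs,
                          folds, failed, h2 = NA_real_) {
  r <- r[!is.na(r)]
  structure(list(trait = trait, scheme = scheme, k = k, repeats = repeats,
                 seed = seed, r = r, r_mean = mean(r),
                 r_se = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_,
                 predictions = pred, observed = obs, folds = folds,
                 failed_folds = failed, h2 = h2,
                 accuracy = if (!is.na(h2)) prediction_accuracy(mean(r), h2) else NA_real_),
            class = "cv_result")
}

#' @method print cv_result
#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation%s%s\n", x$scheme,
              if (!is.null(x$trait)) paste0(" for '", x$trait, "'") else "",
              if (x$scheme == "kfold") sprintf(" (k = %d, %d repeat(s), seed %s)",
                                               x$k, x$repeats, x$seed) else ""))
  if (length(x$r) > 1) {
    cat(sprintf("  predictive ability r = %.3f +/- %.3f (mean +/- SE over repeats)\n",
                x$r_mean, x$r_se))
  } else {
    cat(sprintf("  predictive ability r = %.3f\n", x$r_mean))
  }
  if (!is.na(x$h2)) cat(sprintf("  prediction accuracy r/sqrt(h2) = %.3f (h2 = %.3f)\n",
                                x$accuracy, x$h2))
  if (x$failed_folds > 0) cat("  ", x$failed_folds, "fold fit(s) failed\n")
  invisible(x)
}

#' Leave-one-out cross-validation of GBLUP predictive ability
#'
#' Each line is left out in turn, the model is refitted on the remaining
#' lines (variance components re-estimated by default) and the held-out
#' line's additive genetic value is predicted; the predictive ability is the
#' single Pearson correlation between the adjusted means and the pooled
#' held-out predictions.
#'
#' @param data plant-level table, \code{adjusted_means} or named numeric
#'   vector of line means.
#' @param grm relationship matrix covering the phenotyped lines.
#' @param trait trait column (for plant-level input).
#' @param refit logical; re-estimate variance components per fold
#'   (default). \code{FALSE} uses \code{varcomp} for every fold (fast mode).
#' @param varcomp named \code{c(sa=, se=)} used when \code{refit = FALSE};
#'   defaults to a full-data means-mode fit.
#' @param h2 narrow-sense heritability from the complete-data model, used
#'   for the reported prediction accuracy; supply the value from a full
#'   plant-level \code{\link{gblup}} fit, or leave NA to skip the accuracy.
#' @param line,experiment column names for plant-level input.
#' @return a \code{cv_result}.
#' @export
loocv <- function(data, grm, trait = NULL, refit = TRUE, varcomp = NULL,
                  h2 = NA_real_, line = "line", experiment = "experiment") {
  y <- cv_means(data, grm, trait, line, experiment)
  y <- y[!is.na(y)]
  if (length(y) < 10) stop("need at least 10 lines for cross-validation")
  if (stats::sd(y) == 0) {
    stop("phenotype is constant: predictive ability undefined")
  }
  if (!refit && is.null(varcomp)) {
    full <- gblup(y, grm = grm)
    varcomp <- c(sa = full$varcomp[["sa"]], se = full$varcomp[["se"]])
  }
  folds <- stats::setNames(seq_along(y), names(y))
  res <- cv_predict_folds(y, grm, folds, refit = refit, varcomp = varcomp)
  ok <- !is.na(res$pred)
  r <- stats::cor(y[ok], res$pred[ok])
  new_cv_result(trait, "loocv", k = length(y), repeats = 1L, seed = NA,
                r = r, pred = res$pred, obs = y, folds = folds,
                failed = res$failed, h2 = h2)
}

#' Repeated k-fold cross-validation of GBLUP predictive ability
#'
#' Lines are randomly partitioned into k folds; each fold is predicted from
#' a model fitted on the others, and one predictive ability per repeat is
#' the correlation over the pooled held-out predictions of the k folds. The
#' summary is the mean and standard error over repeats. A fixed seed makes
#' fold assignments and results exactly reproducible. With \code{k = n} and
#' a single repeat the scheme reduces to leave-one-out exactly.
#'
#' @inheritParams loocv
#' @param k number of folds (default 5).
#' @param repeats number of random repetitions (default 100).
#' @param seed integer seed controlling all fold assignments.
#' @return a \code{cv_result}; \code{folds} holds the k-fold assignment
#'   matrix (lines x repeats) for audit.
#' @export
kfold_cv <- function(data, grm, trait = NULL, k = 5, repeats = 100,
                     seed = 1, refit = TRUE, varcomp = NULL, h2 = NA_real_,
                     line = "line", experiment = "experiment") {
  y <- cv_means(data, grm, trait, line, experiment)
  y <- y[!is.na(y)]
  n <- length(y)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  if (stats::sd(y) == 0) {
    stop("phenotype is constant: predictive ability undefined")
  }
  if (!refit && is.null(varcomp)) {
    full <- gblup(y, grm = grm)
    varcomp <- c(sa = full$varcomp[["sa"]], se = full$varcomp[["se"]])
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fold_mat <- matrix(NA_integer_, n, repeats, dimnames = list(names(y), NULL))
  r <- numeric(repeats)
  failed <- 0L
  last_pred <- NULL
  for (rep_i in seq_len(repeats)) {
    folds <- sample(rep_len(seq_len(k), n))
    fold_mat[, rep_i] <- folds
    res <- cv_predict_folds(y, grm, stats::setNames(folds, names(y)),
                            refit = refit, varcomp = varcomp)
    failed <- failed + res$failed
    ok <- !is.na(res$pred)
    r[rep_i] <- if (sum(ok) > 2) stats::cor(y[ok], res$pred[ok]) else NA_real_
    last_pred <- res$pred
  }
  new_cv_result(trait, "kfold", k = k, repeats = repeats, seed = seed,
                r = r, pred = last_pred, obs = y, folds = fold_mat,
                failed = failed, h2 = h2)
}

#' Prediction accuracy from predictive ability and heritability
#'
#' Accuracy = r / sqrt(h2): the predictive ability adjusted by the square
#' root of the narrow-sense heritability estimated from the complete-data
#' model. The sign of r is carried through, so negative predictive
#' abilities give negative accuracies.
#'
#' @param r predictive ability (Pearson correlation), in [-1, 1].
#' @param h2 narrow-sense heritability in (0, 1].
#' @return accuracy; NA with a warning when h2 is not positive.
#' @export
prediction_accuracy <- function(r, h2) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("r must lie in [-1, 1]")
  out <- r / sqrt(h2)
  bad <- !is.na(h2) & (h2 <= 0 | h2 > 1)
  if (any(bad)) {
    warning("h2 outside (0, 1]: accuracy undefined")
    out[bad] <- NA_real_
  }
  out
}
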