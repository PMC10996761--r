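## RBF-SVM outcome classifier on the four FR factors.
## Fixed hyperparameters: C = 1, gamma = 1/(number of factors) on
## z-scored features (kernel_scale = "auto" instead uses 1/dimension as
## e1071 would). Label convention: positive decision = seizure free;
## a decision value of exactly 0 is classified non-seizure-free so a
## growing virtual resection is never stopped by a boundary tie.

FEATURE_NAMES <- c("fr_rr", "spatial_frnet", "temporal_frnet_a", "temporal_frnet_b")

coerce_feature_matrix <- function(features) {
  if (inherits(features, "fr_features")) features <- list(features)
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, inherits, logical(1), "fr_features")))
    features <- do.call(rbind, lapply(features, as_feature_row))
  m <- as.matrix(as.data.frame(features))
  if (ncol(m) != 4L) stop("feature matrix must have the 4 FR factors as columns")
  colnames(m) <- FEATURE_NAMES
  storage.mode(m) <- "double"
  m
}

## impute flagged/missing components with the training-set feature mean
## (z-score 0): a neutral, deterministic contribution
impute_features <- function(m, center) {
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- center[j]
  m
}

fit_svm_core <- function(m, labels, opts) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("training labels are single-class")
  center <- colMeans(m, na.rm = TRUE)
  center[is.nan(center)] <- 0
  m <- impute_features(m, center)
  center <- colMeans(m)
  scale_ <- apply(m, 2, stats::sd)
  if (any(scale_ == 0))
    stop("constant feature: ", paste(FEATURE_NAMES[scale_ == 0], collapse = ", "))
  z <- scale(m, center = center, scale = scale_)
  gamma <- if (opts$kernel_scale == "fixed") 1 / ncol(m) else {
    ## median heuristic on the z-scored training rows
    med <- stats::median(stats::dist(z)^2)
    if (med > 0) 1 / med else 1 / ncol(m)
  }
  fit <- e1071::svm(x = z, y = factor(labels, levels = c(FALSE, TRUE)),
                    kernel = "radial", gamma = gamma, cost = 1, scale = FALSE)
  ## orientation of the libsvm decision value: positive = first label
  positive_is_szfree <- as.logical(fit$levels[fit$labels[1]])
  structure(list(
    center = center, scale = scale_, gamma = gamma, cost = 1,
    sv = fit$SV, coefs = as.numeric(fit$coefs), rho = fit$rho,
    positive_is_szfree = positive_is_szfree,
    n_train = nrow(m), labels = labels
  ), class = "fr_svm")
}

#' Train the FR outcome SVM
#'
#' Fits a radial-basis-function support vector machine labelling
#' post-operative seizure freedom from the four FR factors (FR RR,
#' spatial FRnet, temporal FRnet-A, temporal FRnet-B). Features are
#' z-scored on the training rows; the kernel coefficient is fixed at
#' gamma = 1/4 (one over the number of factors) and the penalty at
#' C = 1. Flagged (`NA`) feature components are imputed with the
#' training mean of that feature.
#'
#' @param features n x 4 matrix/data frame, or a list of
#'   [feature_vector()] results.
#' @param labels logical vector, `TRUE` = seizure free.
#' @param opts [fr_options()].
#' @return an object of class `fr_svm`.
#' @export
fr_svm <- function(features, labels, opts = fr_options()) {
  m <- coerce_feature_matrix(features)
  if (nrow(m) < 4) stop("need at least 4 training patients")
  if (nrow(m) != length(labels)) stop("features and labels disagree in length")
  fit_svm_core(m, labels, opts)
}

#' @export
print.fr_svm <- function(x, ...) {
  cat("FR outcome SVM (RBF kernel)\n")
  cat(sprintf("  gamma = %.4g, C = %g, %d support vectors, %d training patients (%d seizure free)\n",
              x$gamma, x$cost, nrow(x$sv), x$n_train, sum(x$labels)))
  invisible(x)
}

#' @export
summary.fr_svm <- function(object, ...) {
  print(object)
  cat("  feature normalization (mean / sd):\n")
  for (j in seq_along(FEATURE_NAMES))
    cat(sprintf("    %-18s %8.4f / %.4f\n", FEATURE_NAMES[j],
                object$center[j], object$scale[j]))
  invisible(object)
}

#' Decision values of the FR outcome SVM
#'
#' Signed decision-function values, oriented so positive means seizure
#' free. Computed directly from the stored support vectors, so a model
#' reloaded from JSON predicts identically.
#'
#' @param object an `fr_svm`.
#' @param features feature rows as in [fr_svm()].
#' @return numeric vector of decision values.
#' @export
decision_values <- function(object, features) {
  m <- coerce_feature_matrix(features)
  m <- impute_features(m, object$center)
  z <- scale(m, center = object$center, scale = object$scale)
  ## RBF kernel against the support vectors
  d2 <- outer(rowSums(z^2), rowSums(object$sv^2), "+") -
    2 * z %*% t(object$sv)
  k <- exp(-object$gamma * d2)
  d <- as.numeric(k %*% object$coefs - object$rho)
  if (object$positive_is_szfree) d else -d
}

#' @export
predict.fr_svm <- function(object, newdata, ...) {
  decision_values(object, newdata) > 0
}

#' Leave-one-out cross-validated accuracy
#'
#' n-fold leave-one-out: each fold refits the normalization and the SVM
#' on the remaining rows and classifies the held-out patient; accuracy
#' is one minus the misclassification fraction. Folds whose training
#' rows are single-label (or otherwise unfittable, e.g. a constant
#' feature) predict the majority training label, with ties broken by
#' the overall majority; a warning is logged.
#'
#' @param features n x 4 feature rows (n >= 3).
#' @param labels logical outcome labels.
#' @param opts [fr_options()].
#' @return accuracy in \[0, 1\].
#' @export
loocv_accuracy <- function(features, labels, opts = fr_options()) {
  m <- coerce_feature_matrix(features)
  labels <- as.logical(labels)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 patients for leave-one-out")
  overall_major <- mean(labels) >= 0.5
  pred <- logical(n)
  degenerate <- 0L
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_svm_core(m[-i, , drop = FALSE], labels[-i], opts),
                    error = function(e) NULL)
    if (is.null(fit)) {
      degenerate <- degenerate + 1L
      tr <- labels[-i]
      pred[i] <- if (mean(tr) > 0.5) TRUE else if (mean(tr) < 0.5) FALSE
        else overall_major
    } else {
      pred[i] <- predict(fit, m[i, , drop = FALSE])
    }
  }
  if (degenerate > 0)
    warning(degenerate, " fold(s) fell back to majority-label prediction")
  mean(pred == labels)
}

#' Serialize / reload an FR outcome SVM
#'
#' Writes the normalization statistics, hyperparameters and support
#' coefficients to a JSON sidecar; `read_fr_svm()` reconstructs a model
#' predicting identically to the original.
#'
#' @param object an `fr_svm`.
#' @param path JSON file path.
#' @return `write_fr_svm` invisibly returns `path`; `read_fr_svm`
#'   returns the reloaded `fr_svm`.
#' @export
write_fr_svm <- function(object, path) {
  payload <- list(center = object$center, scale = object$scale,
                  gamma = object$gamma, cost = object$cost,
                  sv = unclass(object$sv), coefs = object$coefs,
                  rho = object$rho,
                  positive_is_szfree = object$positive_is_szfree,
                  n_train = object$n_train, labels = object$labels)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fr_svm
#' @param path JSON file path.
#' @export
read_fr_svm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- matrix(as.numeric(as.matrix(p$sv)), nrow = length(p$coefs))
  structure(list(center = stats::setNames(as.numeric(p$center), FEATURE_NAMES),
                 scale = stats::setNames(as.numeric(p$scale), FEATURE_NAMES),
                 gamma = p$gamma, cost = p$cost, sv = sv,
                 coefs = as.numeric(p$coefs), rho = p$rho,
                 positive_is_szfree = p$positive_is_szfree,
                 n_train = p$n_train, labels = as.logical(p$labels)),
            class = "fr_svm")
}
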