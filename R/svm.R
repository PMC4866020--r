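# Soft-margin binary SVM with Gaussian (RBF) kernel. The dual quadratic
# program is solved exactly with quadprog; training sets in this domain
# are small (tens of compounds), so a dense QP solve is both simple and
# reproducible.

rbf_kernel <- function(a, b, sigma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

# median heuristic: sigma = median pairwise Euclidean distance
median_sigma <- function(x) {
  d <- stats::dist(x)
  s <- stats::median(d[d > 0])
  if (!is.finite(s) || s <= 0) 1 else s
}

#' SVM configuration
#'
#' @param cost Soft-margin box constraint C (default 1).
#' @param sigma Gaussian kernel bandwidth; `NULL` (default) uses the
#'   median heuristic on pairwise training distances.
#' @param standardize Center/scale features by training statistics
#'   before fitting (default `TRUE`).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(cost = 1, sigma = NULL, standardize = TRUE) {
  stopifnot(cost > 0, is.null(sigma) || sigma > 0)
  structure(list(cost = cost, sigma = sigma, standardize = standardize),
            class = "svm_config")
}

#' Train a Gaussian-kernel binary SVM
#'
#' Fits a soft-margin support vector machine by solving the dual
#' quadratic program. The first class encountered in `labels` is mapped
#' to +1; decision-value ties (exactly 0) resolve to that class.
#'
#' @param x Numeric feature matrix, one row per sample.
#' @param labels Vector with exactly two distinct values.
#' @param config An [svm_config()].
#' @return Object of class `rtca_svm`.
#' @export
train_svm <- function(x, labels, config = svm_config()) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("row/label mismatch", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) != 2) {
    stop("exactly two classes are required", call. = FALSE)
  }
  y <- ifelse(labels == classes[1], 1, -1)
  if (isTRUE(config$standardize)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    x <- scale(x, center = ctr, scale = scl)
  } else {
    ctr <- NULL; scl <- NULL
  }
  sigma <- if (is.null(config$sigma)) median_sigma(x) else config$sigma
  n <- nrow(x)
  K <- rbf_kernel(x, x, sigma)
  D <- (y %o% y) * K
  diag(D) <- diag(D) + 1e-8          # ridge for numerical definiteness
  C <- config$cost
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n),
                            Amat = Amat, bvec = bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-7
  coef <- alpha * y
  free <- alpha > 1e-7 & alpha < C - 1e-7
  if (!any(free)) free <- sv
  b <- mean((K[free, , drop = FALSE] %*% coef) - y[free])
  structure(list(x = x[sv, , drop = FALSE], coef = coef[sv], b = b,
                 sigma = sigma, classes = classes,
                 center = ctr, scale = scl, config = config),
            class = "rtca_svm")
}

svm_decision <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$x)) {
    stop("feature dimensionality differs from training", call. = FALSE)
  }
  if (!is.null(model$center)) {
    x <- scale(x, center = model$center, scale = model$scale)
  }
  as.numeric(rbf_kernel(x, model$x, model$sigma) %*% model$coef - model$b)
}

#' Predict class labels with a trained SVM
#'
#' @param object An `rtca_svm`.
#' @param newdata Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Character vector of predicted labels (empty for 0 rows).
#' @export
predict.rtca_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(character(0))
  f <- svm_decision(object, newdata)
  ifelse(f >= 0, object$classes[1], object$classes[2])
}

#' @export
print.rtca_svm <- function(x, ...) {
  cat(sprintf("<rtca_svm> %d support vectors, sigma=%.4g, C=%g (%s vs %s)\n",
              nrow(x$x), x$sigma, x$config$cost, x$classes[1], x$classes[2]))
  invisible(x)
}
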