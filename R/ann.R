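# Feedforward neural network with three hidden layers (24-12-6 by
# default), logistic-sigmoid hidden activations and a softmax readout,
# one output unit per cluster. Trained full-batch with Adam; a trained
# network is "accepted" once its training-set success rate reaches the
# acceptance threshold (85 % by default), with random restarts allowed.

#' ANN configuration
#'
#' @param hidden Hidden layer sizes (default `c(24, 12, 6)`).
#' @param accept_sr Training success rate at which the network is
#'   accepted and training stops (default 0.85). Pushing this higher on
#'   small imbalanced data invites over-fitting.
#' @param max_epochs Optimization epoch cap per restart (default 2000).
#' @param restarts Random re-initializations allowed when a run ends
#'   below `accept_sr` (default 5).
#' @param learning_rate Adam step size (default 0.01).
#' @param standardize Center/scale features by training statistics.
#' @param seed Optional integer seed for weight initialization.
#' @return A list of class `ann_config`.
#' @export
ann_config <- function(hidden = c(24L, 12L, 6L), accept_sr = 0.85,
                       max_epochs = 2000L, restarts = 5L,
                       learning_rate = 0.01, standardize = TRUE,
                       seed = NULL) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1),
            accept_sr > 0, accept_sr <= 1, max_epochs >= 0, restarts >= 1)
  structure(list(hidden = as.integer(hidden), accept_sr = accept_sr,
                 max_epochs = as.integer(max_epochs),
                 restarts = as.integer(restarts),
                 learning_rate = learning_rate,
                 standardize = standardize, seed = seed),
            class = "ann_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

ann_forward <- function(weights, x) {
  a <- x
  nl <- length(weights)
  acts <- vector("list", nl)
  for (l in seq_len(nl)) {
    z <- a %*% weights[[l]]$W + matrix(weights[[l]]$b, nrow(a),
                                       length(weights[[l]]$b), byrow = TRUE)
    a <- if (l < nl) sigmoid(z) else z
    acts[[l]] <- a
  }
  # softmax on the output layer
  zmax <- apply(a, 1, max)
  e <- exp(a - zmax)
  acts[[nl]] <- e / rowSums(e)
  acts
}

ann_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                 sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1]),
         b = numeric(sizes[l + 1]))
  })
}

ann_fit_once <- function(x, yind, sizes, cfg) {
  n <- nrow(x); K <- sizes[length(sizes)]
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yind)] <- 1
  w <- ann_init(sizes)
  nl <- length(w)
  mom <- lapply(w, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                    mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- cfg$learning_rate
  accepted <- FALSE; sr <- 0
  if (cfg$max_epochs >= 1) for (ep in seq_len(cfg$max_epochs)) {
    acts <- ann_forward(w, x)
    delta <- (acts[[nl]] - Y) / n              # softmax + cross-entropy
    grads <- vector("list", nl)
    for (l in nl:1) {
      a_prev <- if (l == 1) x else acts[[l - 1]]
      grads[[l]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
      if (l > 1) {
        delta <- (delta %*% t(w[[l]]$W)) * acts[[l - 1]] * (1 - acts[[l - 1]])
      }
    }
    for (l in seq_len(nl)) {
      m <- mom[[l]]
      m$mW <- b1 * m$mW + (1 - b1) * grads[[l]]$W
      m$vW <- b2 * m$vW + (1 - b2) * grads[[l]]$W^2
      m$mb <- b1 * m$mb + (1 - b1) * grads[[l]]$b
      m$vb <- b2 * m$vb + (1 - b2) * grads[[l]]$b^2
      mom[[l]] <- m
      corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
      w[[l]]$W <- w[[l]]$W - lr * (m$mW / corr1) / (sqrt(m$vW / corr2) + eps)
      w[[l]]$b <- w[[l]]$b - lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
    }
    if (ep %% 20 == 0 || ep == cfg$max_epochs) {
      pred <- max.col(ann_forward(w, x)[[nl]], ties.method = "first")
      sr <- mean(pred == yind)
      if (sr >= cfg$accept_sr) { accepted <- TRUE; break }
    }
  }
  pred <- max.col(ann_forward(w, x)[[nl]], ties.method = "first")
  list(weights = w, train_sr = mean(pred == yind), accepted = accepted)
}

#' Train a feedforward neural network classifier
#'
#' @param x Numeric feature matrix, one row per sample.
#' @param labels Class labels (two or more distinct values; one output
#'   unit per class, argmax readout).
#' @param config An [ann_config()].
#' @return Object of class `rtca_ann` with an `accepted` flag that is
#'   `TRUE` iff the training success rate reached `accept_sr`.
#' @export
train_ann <- function(x, labels, config = ann_config()) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("row/label mismatch", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) < 2) stop("at least two classes required", call. = FALSE)
  yind <- match(labels, classes)
  if (isTRUE(config$standardize)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    x <- scale(x, center = ctr, scale = scl)
  } else {
    ctr <- NULL; scl <- NULL
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  sizes <- c(ncol(x), config$hidden, length(classes))
  best <- NULL
  for (r in seq_len(config$restarts)) {
    fit <- ann_fit_once(x, yind, sizes, config)
    if (is.null(best) || fit$train_sr > best$train_sr) best <- fit
    if (best$accepted) break
  }
  structure(list(weights = best$weights, classes = classes,
                 accepted = best$accepted, train_sr = best$train_sr,
                 center = ctr, scale = scl, config = config),
            class = "rtca_ann")
}

#' Predict class labels with a trained ANN
#'
#' @param object An `rtca_ann`.
#' @param newdata Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.rtca_ann <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(character(0))
  if (ncol(newdata) != nrow(object$weights[[1]]$W)) {
    stop("feature dimensionality differs from training", call. = FALSE)
  }
  if (!is.null(object$center)) {
    newdata <- scale(newdata, center = object$center, scale = object$scale)
  }
  p <- ann_forward(object$weights, newdata)[[length(object$weights)]]
  object$classes[max.col(p, ties.method = "first")]
}

#' @export
print.rtca_ann <- function(x, ...) {
  cat(sprintf("<rtca_ann> %s; train SR %.3f (%s)\n",
              paste(c(nrow(x$weights[[1]]$W), x$config$hidden,
                      length(x$classes)), collapse = "-"),
              x$train_sr, if (x$accepted) "accepted" else "not accepted"))
  invisible(x)
}

# ---- portable model serialization --------------------------------------

#' Save a trained classifier to a portable JSON file
#'
#' The file embeds a format version, the model type, its configuration
#' and all numeric parameters, so models round-trip across sessions.
#'
#' @param model An `rtca_svm` or `rtca_ann`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
model_save <- function(model, path) {
  type <- class(model)[1]
  payload <- list(format = "rtcamoa-model", version = 1L, type = type,
                  model = unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Load a classifier saved by [model_save()]
#'
#' @param path Path to a model JSON file.
#' @return The restored model object.
#' @export
model_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format, "rtcamoa-model")) {
    stop("not an rtcamoa model file", call. = FALSE)
  }
  m <- payload$model
  if (payload$type == "rtca_svm") {
    m$x <- as.matrix(m$x)
    m$coef <- as.numeric(m$coef)
  } else if (payload$type == "rtca_ann") {
    m$weights <- lapply(m$weights, function(l)
      list(W = as.matrix(l$W), b = as.numeric(l$b)))
  }
  class(m) <- payload$type
  m
}
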