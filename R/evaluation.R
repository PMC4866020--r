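# Repeated stratified random-split evaluation. Unlike fixed-partition
# cross-validation, each of the (default 100) repetitions draws a fresh
# 70/30 split within every cluster, and the mean success rate over
# repetitions is the reported figure; with only a handful of compounds
# per cluster a fixed partition would bias the estimate.

#' Classification success rate
#'
#' Fraction of samples assigned their correct cluster.
#'
#' @param predicted,truth Equal-length non-empty label vectors.
#' @return SR in `[0, 1]`.
#' @export
success_rate <- function(predicted, truth) {
  if (length(predicted) == 0 || length(truth) == 0) {
    stop("empty inputs", call. = FALSE)
  }
  if (length(predicted) != length(truth)) {
    stop("length mismatch", call. = FALSE)
  }
  mean(as.character(predicted) == as.character(truth))
}

#' Mean classification error over tasks
#'
#' The error of one task is `1 - SR`; the average error E is the mean
#' over tasks.
#'
#' @param sr_values Non-empty numeric vector of success rates in `[0,1]`.
#' @return Average error E.
#' @export
average_error <- function(sr_values) {
  if (length(sr_values) == 0) stop("empty input", call. = FALSE)
  stopifnot(all(sr_values >= 0 & sr_values <= 1))
  mean(1 - sr_values)
}

#' Combine two classifiers by taking the better SR per task
#'
#' @param sr_a,sr_b Aligned per-task SR vectors of equal length.
#' @return Elementwise maximum.
#' @export
combine_best <- function(sr_a, sr_b) {
  if (length(sr_a) != length(sr_b)) stop("length mismatch", call. = FALSE)
  pmax(sr_a, sr_b)
}

round_half_up <- function(x) floor(x + 0.5)

#' Plan repeated stratified train/test splits
#'
#' For each repetition, `round(train_frac * size)` samples of every
#' cluster (round-half-up; e.g. 14 of 20 and 9 of 13 at 70 %) are drawn
#' without replacement for training; the rest form the test set. The
#' per-cluster counts are identical across repetitions, only the
#' membership varies. Fully reproducible from `seed`.
#'
#' @param labels Cluster label per sample (every cluster needs >= 2
#'   members so train and test are non-empty).
#' @param reps Number of repetitions (default 100).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return Object of class `split_plan`; element `splits` is a list of
#'   `list(train =, test =)` index vectors.
#' @export
split_plan <- function(labels, reps = 100L, train_frac = 0.7, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(reps >= 1, train_frac > 0, train_frac < 1)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("every cluster needs at least 2 members to stratify; merge or drop: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  n_train <- round_half_up(train_frac * as.numeric(tab))
  n_train <- pmin(pmax(n_train, 1), as.numeric(tab) - 1)
  names(n_train) <- names(tab)
  idx_by <- split(seq_along(labels), labels)
  rng <- local({ set.seed(seed); lapply(seq_len(reps), function(i)
    sample.int(.Machine$integer.max, 1)) })
  splits <- lapply(seq_len(reps), function(r) {
    set.seed(rng[[r]])
    tr <- unlist(lapply(names(idx_by), function(cl) {
      sample(idx_by[[cl]], n_train[[cl]])
    }), use.names = FALSE)
    list(train = sort(tr), test = setdiff(seq_along(labels), tr))
  })
  structure(list(splits = splits, reps = as.integer(reps),
                 train_frac = train_frac, n_train = n_train, seed = seed,
                 labels = labels),
            class = "split_plan")
}

resolve_classifier <- function(classifier, config) {
  if (is.list(classifier) && !is.null(classifier$train)) return(classifier)
  switch(as.character(classifier),
    svm = list(train = function(x, y)
                 train_svm(x, y, config = if (is.null(config)) svm_config()
                                          else config),
               predict = function(model, x) predict(model, x)),
    ann = list(train = function(x, y)
                 train_ann(x, y, config = if (is.null(config)) ann_config()
                                          else config),
               predict = function(model, x) predict(model, x)),
    stop("unknown classifier: ", classifier, call. = FALSE))
}

#' Repeated-split evaluation of a classifier
#'
#' Trains on each repetition's stratified training set and scores the
#' held-out samples; reports per-repetition SR and their mean.
#'
#' @param x Feature matrix, one row per sample.
#' @param labels Cluster label per sample.
#' @param classifier `"svm"`, `"ann"`, or a `list(train =, predict =)`
#'   pair (the train function receives `x`, `labels`; predict receives
#'   the fitted model and a feature matrix).
#' @param config Optional [svm_config()] / [ann_config()].
#' @param plan A [split_plan()] built on `labels` (or `NULL` to build
#'   one with `reps`, `seed`).
#' @param reps,seed Used only when `plan` is `NULL`.
#' @param task Optional task identifier stored in the result.
#' @return Object of class `evaluation_result` with `sr` (one value per
#'   repetition), `mean_sr`, `task`, `flags` (per-repetition notes, e.g.
#'   an ANN that never reached its acceptance SR).
#' @export
repeated_split_evaluation <- function(x, labels, classifier = "svm",
                                      config = NULL, plan = NULL,
                                      reps = 100L, seed = 1L,
                                      task = NA_character_) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("at least two clusters are required", call. = FALSE)
  }
  if (is.null(plan)) plan <- split_plan(labels, reps = reps, seed = seed)
  clf <- resolve_classifier(classifier, config)
  sr <- numeric(plan$reps)
  flags <- character(plan$reps)
  for (r in seq_len(plan$reps)) {
    sp <- plan$splits[[r]]
    model <- clf$train(x[sp$train, , drop = FALSE], labels[sp$train])
    pred <- clf$predict(model, x[sp$test, , drop = FALSE])
    sr[r] <- success_rate(pred, labels[sp$test])
    if (inherits(model, "rtca_ann") && !model$accepted) {
      flags[r] <- "ann_not_accepted"
    }
  }
  structure(list(sr = sr, mean_sr = mean(sr), task = task,
                 plan_seed = plan$seed, reps = plan$reps, flags = flags),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result>%s mean SR %.3f over %d repetitions (sd %.3f)\n",
              if (is.na(x$task)) "" else paste0(" ", x$task, ":"),
              x$mean_sr, x$reps, stats::sd(x$sr)))
  invisible(x)
}

#' Write evaluation results as delimited text
#'
#' Writes `task,rep,sr` rows plus a `<path>.summary` file with
#' `task,mean_sr,avg_error`.
#'
#' @param results A single `evaluation_result` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(results, path) {
  if (inherits(results, "evaluation_result")) results <- list(results)
  per_rep <- do.call(rbind, lapply(results, function(r)
    data.frame(task = r$task, rep = seq_along(r$sr), sr = r$sr)))
  utils::write.csv(per_rep, path, row.names = FALSE)
  summ <- do.call(rbind, lapply(results, function(r)
    data.frame(task = r$task, mean_sr = r$mean_sr,
               avg_error = 1 - r$mean_sr)))
  utils::write.csv(summ, paste0(path, ".summary"), row.names = FALSE)
  invisible(path)
}
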