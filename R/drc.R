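# Dose-response-curve statistics. The toxicity effect TE_t(k) is the
# percentage deviation of the k-th concentration curve from the
# negative control at time t -- either pointwise or through the area
# under the curve from 0 to t. The 11-element TE vector across
# concentrations at a fixed time is the DRC, an alternative (much
# smaller) classifier input whose per-time success-rate profile guides
# the choice of an informative time window.

curve_value_at <- function(curve, t) {
  i <- which(abs(curve$times - t) < 1e-8)
  if (length(i) != 1) stop("time ", t, " is not on the grid", call. = FALSE)
  curve$nci[i]
}

trapz_to <- function(curve, t) {
  i <- which(abs(curve$times - t) < 1e-8)
  if (length(i) != 1) stop("time ", t, " is not on the grid", call. = FALSE)
  idx <- seq_len(i)
  if (length(idx) < 2) stop("AUC needs t > start of grid", call. = FALSE)
  sum(diff(curve$times[idx]) *
        (utils::head(curve$nci[idx], -1) + utils::tail(curve$nci[idx], -1)) / 2)
}

#' Pointwise toxicity effect at one time and concentration rank
#'
#' `TE_t(k) = 100 * (TCRC_t(k) - NC_t) / NC_t`: 0 means no effect,
#' -100 means total kill relative to the negative control.
#'
#' @param set A [tcrc_set()].
#' @param t Hour on the grid.
#' @param k Concentration rank (1 = highest).
#' @return TE in percent.
#' @export
toxicity_effect_point <- function(set, t, k) {
  stopifnot(inherits(set, "tcrc_set"), k >= 1, k <= length(set$curves))
  nc <- curve_value_at(set$negative_control, t)
  if (nc == 0) stop("negative control is 0 at t=", t, call. = FALSE)
  100 * (curve_value_at(set$curves[[k]], t) - nc) / nc
}

#' AUC-based toxicity effect at one time and concentration rank
#'
#' As [toxicity_effect_point()] but comparing areas under the curves
#' from the start of the grid to `t` (composite trapezoid rule on the
#' hourly grid).
#'
#' @inheritParams toxicity_effect_point
#' @return TE in percent.
#' @export
toxicity_effect_auc <- function(set, t, k) {
  stopifnot(inherits(set, "tcrc_set"), k >= 1, k <= length(set$curves))
  auc_nc <- trapz_to(set$negative_control, t)
  if (auc_nc == 0) stop("negative-control AUC is 0 at t=", t, call. = FALSE)
  100 * (trapz_to(set$curves[[k]], t) - auc_nc) / auc_nc
}

#' Dose-response-curve profile at one time
#'
#' @param set A [tcrc_set()].
#' @param t Hour on the grid (for `variant = "auc"`, `t` must be past
#'   the first grid point).
#' @param variant `"point"` (default) or `"auc"`.
#' @return Object of class `drc_profile`: `te` (one TE percent per
#'   concentration rank, highest first), `time`, `variant`.
#' @export
drc_at_time <- function(set, t, variant = c("point", "auc")) {
  variant <- match.arg(variant)
  fun <- if (variant == "point") toxicity_effect_point else toxicity_effect_auc
  te <- vapply(seq_along(set$curves), function(k) fun(set, t, k), numeric(1))
  structure(list(te = te, time = t, variant = variant,
                 chemical_id = set$chemical_id),
            class = "drc_profile")
}

#' DRC feature matrix for a collection of TCRC sets
#'
#' @param sets List of [tcrc_set()] objects.
#' @param t Hour on the grid.
#' @param variant `"point"` or `"auc"`.
#' @return List with `x` (matrix, 11 columns), `labels`, `chemical_ids`.
#' @export
drc_features <- function(sets, t, variant = c("point", "auc")) {
  variant <- match.arg(variant)
  x <- do.call(rbind, lapply(sets, function(s) drc_at_time(s, t, variant)$te))
  rownames(x) <- vapply(sets, `[[`, character(1), "chemical_id")
  list(x = x,
       labels = vapply(sets, function(s) as.character(s$label), character(1)),
       chemical_ids = rownames(x))
}

#' Per-time success-rate profile of a DRC-input classifier
#'
#' For each requested hour, the 11-value DRC profiles are used as SVM
#' input and a repeated-split evaluation is run; linking the mean SRs
#' across hours shows when the clusters become distinguishable. DRC
#' features are used unstandardized (they are already relative
#' percentages).
#'
#' @param sets List of labeled [tcrc_set()] objects.
#' @param times Hours to evaluate (>= 1 values; hour 0 is excluded for
#'   the point variant since every curve is still at its normalization
#'   anchor there).
#' @param plan A [split_plan()] on the set labels (or `NULL` to build
#'   one from `reps`, `seed`).
#' @param config [svm_config()]; default disables standardization.
#' @param variant `"point"` or `"auc"`.
#' @param reps,seed Used when `plan` is `NULL`.
#' @return Data frame `time_h`, `mean_sr`.
#' @export
sr_time_profile <- function(sets, times, plan = NULL,
                            config = svm_config(standardize = FALSE),
                            variant = c("point", "auc"),
                            reps = 100L, seed = 1L) {
  variant <- match.arg(variant)
  if (length(times) < 1) stop("at least one time required", call. = FALSE)
  labels <- vapply(sets, function(s) as.character(s$label), character(1))
  if (is.null(plan)) plan <- split_plan(labels, reps = reps, seed = seed)
  mean_sr <- vapply(times, function(t) {
    ft <- drc_features(sets, t, variant)
    repeated_split_evaluation(ft$x, ft$labels, classifier = "svm",
                              config = config, plan = plan)$mean_sr
  }, numeric(1))
  data.frame(time_h = times, mean_sr = mean_sr)
}

#' Select the informative time window from an SR profile
#'
#' Returns the longest contiguous run of hours whose SR is at or above
#' the threshold, dropping the low-SR stretches from the input window.
#'
#' @param profile Data frame with `time_h` and `mean_sr` (as produced
#'   by [sr_time_profile()]).
#' @param threshold SR threshold; default is the profile mean.
#' @return Object of class `time_interval` (`start`, `end`, `threshold`),
#'   or `NULL` when no time meets the threshold (callers fall back to
#'   the full window).
#' @export
select_time_interval <- function(profile, threshold = NULL) {
  stopifnot(nrow(profile) >= 1)
  if (is.null(threshold)) threshold <- mean(profile$mean_sr)
  ok <- profile$mean_sr >= threshold
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  structure(list(start = profile$time_h[starts[best]],
                 end = profile$time_h[ends[best]],
                 threshold = threshold),
            class = "time_interval")
}

#' @export
print.time_interval <- function(x, ...) {
  cat(sprintf("<time_interval> %g-%g h (SR threshold %.3f)\n",
              x$start, x$end, x$threshold))
  invisible(x)
}

#' Restrict all curves of a TCRC set to a time interval
#'
#' Truncates every curve (and the negative control) to hours in
#' `[start, end]` inclusive; downstream featurization applies unchanged
#' to the shorter curves.
#'
#' @param set A [tcrc_set()].
#' @param interval A `time_interval` (or `list(start =, end =)`).
#' @return A new [tcrc_set()] on the restricted grid.
#' @export
restrict_tcrc <- function(set, interval) {
  stopifnot(inherits(set, "tcrc_set"))
  tt <- set$negative_control$times
  if (interval$start < min(tt) - 1e-8 || interval$end > max(tt) + 1e-8) {
    stop("interval outside the curve grid", call. = FALSE)
  }
  cut1 <- function(cv) {
    keep <- cv$times >= interval$start - 1e-8 & cv$times <= interval$end + 1e-8
    tcrc(cv$times[keep], cv$nci[keep], cv$concentration, cv$chemical_id)
  }
  tcrc_set(set$chemical_id, lapply(set$curves, cut1),
           cut1(set$negative_control), label = set$label,
           n_curves = length(set$curves))
}

#' Write DRC profiles as delimited text
#'
#' One row per (chemical, time): `chemical_id,time_h,variant,te_rank1..11`.
#'
#' @param sets List of [tcrc_set()] objects.
#' @param times Hours to export.
#' @param path Output path.
#' @param variant `"point"` or `"auc"`.
#' @return `path`, invisibly.
#' @export
write_drc <- function(sets, times, path, variant = c("point", "auc")) {
  variant <- match.arg(variant)
  rows <- list()
  for (t in times) {
    for (s in sets) {
      p <- drc_at_time(s, t, variant)
      rows[[length(rows) + 1]] <-
        c(list(chemical_id = s$chemical_id, time_h = t, variant = variant),
          as.list(stats::setNames(p$te,
                                  paste0("te_rank", seq_along(p$te)))))
    }
  }
  utils::write.csv(do.call(rbind.data.frame, rows), path, row.names = FALSE)
  invisible(path)
}
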