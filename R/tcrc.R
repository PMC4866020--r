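# ---- domain containers -------------------------------------------------

#' Construct a cell-index time series
#'
#' A `cell_index_series` holds raw cell-index (CI) values at (possibly
#' irregular) time points around chemical treatment. Time 0 is the point
#' right before treatment; CI at that point must be positive before
#' normalization is allowed.
#'
#' @param times Numeric vector of hours relative to treatment, strictly
#'   increasing, containing the value 0.
#' @param values Numeric CI values, one per time point.
#' @return An object of class `cell_index_series`.
#' @export
cell_index_series <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (!any(times == 0)) {
    stop("`times` must contain the treatment time point 0", call. = FALSE)
  }
  structure(list(times = times, values = values),
            class = "cell_index_series")
}

#' Construct a single time-concentration response curve (TCRC)
#'
#' @param times Hourly grid (h post-treatment), spacing exactly 1 h,
#'   starting at the treatment time.
#' @param nci Normalized cell-index values, one per grid point.
#' @param concentration Numeric concentration, or the string
#'   `"negative_control"`.
#' @param chemical_id Identifier of the tested chemical.
#' @return An object of class `tcrc`.
#' @export
tcrc <- function(times, nci, concentration, chemical_id = NA_character_) {
  stopifnot(is.numeric(times), is.numeric(nci))
  if (length(times) != length(nci)) {
    stop("`times` and `nci` must have equal length", call. = FALSE)
  }
  if (length(times) > 1 && max(abs(diff(times) - 1)) > 1e-8) {
    stop("TCRC grid spacing must be exactly 1 h", call. = FALSE)
  }
  structure(list(times = times, nci = nci, concentration = concentration,
                 chemical_id = chemical_id),
            class = "tcrc")
}

is_negative_control <- function(curve) {
  identical(curve$concentration, "negative_control")
}

#' Construct a TCRC set for one chemical
#'
#' Bundles the 11 concentration curves of one chemical (ordered from the
#' highest to the lowest concentration; serial dilution ratio about 3
#' between neighbours) together with the negative-control curve and an
#' optional MOA cluster label.
#'
#' @param chemical_id Identifier of the chemical.
#' @param curves List of 11 [tcrc()] objects, highest concentration first.
#' @param negative_control A [tcrc()] with concentration
#'   `"negative_control"`.
#' @param label Optional MOA cluster label (character) or `NA`.
#' @param n_curves Expected number of concentration curves (default 11).
#' @return An object of class `tcrc_set`.
#' @export
tcrc_set <- function(chemical_id, curves, negative_control, label = NA_character_,
                     n_curves = 11L) {
  if (length(curves) != n_curves) {
    stop(sprintf("expected %d concentration curves, got %d",
                 n_curves, length(curves)), call. = FALSE)
  }
  conc <- vapply(curves, function(cv) as.numeric(cv$concentration), numeric(1))
  if (any(diff(conc) >= 0)) {
    stop("curve concentrations must be strictly decreasing", call. = FALSE)
  }
  grids <- lapply(c(curves, list(negative_control)), `[[`, "times")
  g0 <- grids[[1]]
  same <- vapply(grids, function(g) {
    length(g) == length(g0) && max(abs(g - g0)) < 1e-8
  }, logical(1))
  if (!all(same)) stop("all curves must share one time grid", call. = FALSE)
  if (!is_negative_control(negative_control)) {
    stop("`negative_control` must have concentration \"negative_control\"",
         call. = FALSE)
  }
  structure(list(chemical_id = chemical_id, curves = curves,
                 negative_control = negative_control, label = label),
            class = "tcrc_set")
}

#' @export
print.tcrc_set <- function(x, ...) {
  conc <- vapply(x$curves, function(cv) as.numeric(cv$concentration), numeric(1))
  cat(sprintf("<tcrc_set> %s: %d curves + NC, %d h grid, conc %.3g..%.3g%s\n",
              x$chemical_id, length(x$curves),
              length(x$curves[[1]]$times) - 1L,
              max(conc), min(conc),
              if (is.na(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

# ---- preprocessing operations ------------------------------------------

#' Cell index from raw impedance measurements
#'
#' Converts one well's impedance readings at `K` measurement frequencies
#' into the dimensionless cell index
#' \deqn{CI = \max_k \left[ R_{cell}(f_k)/R_b(f_k) - 1 \right],}
#' the maximum relative impedance increase over the background (cell-free)
#' measurement. CI is 0 when cells are absent and is always \eqn{\ge -1}.
#'
#' @param r_cell Impedance with cells, one value per frequency (Ohm).
#' @param r_b Background impedance without cells (Ohm), same length,
#'   all strictly positive.
#' @return A single cell-index value.
#' @export
compute_cell_index <- function(r_cell, r_b) {
  if (length(r_cell) == 0 || length(r_b) == 0) {
    stop("empty frequency list", call. = FALSE)
  }
  if (length(r_cell) != length(r_b)) {
    stop("`r_cell` and `r_b` must have equal length", call. = FALSE)
  }
  if (any(r_b <= 0)) stop("background impedance must be > 0", call. = FALSE)
  max(r_cell / r_b - 1)
}

#' Normalize a cell-index series to the pre-treatment value
#'
#' Divides every CI value by the CI right before treatment (time 0), so
#' the normalized cell index (NCI) equals 1 at treatment time and seeding
#' variation between wells is removed.
#'
#' @param series A [cell_index_series()].
#' @return A list with `times` and `nci` (NCI at time 0 is exactly 1).
#' @export
normalize_ci <- function(series) {
  stopifnot(inherits(series, "cell_index_series"))
  i0 <- which(series$times == 0)
  ci0 <- series$values[i0]
  if (ci0 <= 0) {
    stop("CI at treatment time must be > 0 for normalization", call. = FALSE)
  }
  list(times = series$times, nci = series$values / ci0)
}

# Not-a-knot cubic spline: solves for second derivatives M_i with third-
# derivative continuity imposed at the second and second-to-last knots,
# then evaluates the piecewise cubic. Reproduces any single cubic exactly.
spline_notaknot <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i]     <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  # not-a-knot: M''' continuous across x[2] and x[n-1]
  A[1, 1] <- h[2];  A[1, 2] <- -(h[1] + h[2]);  A[1, 3] <- h[1]
  A[n, n - 2] <- h[n - 1]
  A[n, n - 1] <- -(h[n - 2] + h[n - 1])
  A[n, n]     <- h[n - 2]
  M <- solve(A, b)
  idx <- findInterval(xout, x, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx >= n] <- n - 1L
  hi <- h[idx]
  xa <- x[idx]
  t1 <- x[idx + 1] - xout
  t2 <- xout - xa
  M[idx] * t1^3 / (6 * hi) + M[idx + 1] * t2^3 / (6 * hi) +
    (y[idx] / hi - M[idx] * hi / 6) * t1 +
    (y[idx + 1] / hi - M[idx + 1] * hi / 6) * t2
}

#' Resample an irregular NCI series onto a uniform hourly grid
#'
#' RTCA instruments log at slightly irregular intervals; the wavelet
#' featurization requires a uniform grid. A not-a-knot cubic spline is
#' interpolated through the observations and evaluated at whole hours.
#' Interpolation only: the requested grid must lie inside the observed
#' time span.
#'
#' @param times Observed times (h), strictly increasing, at least 4 points.
#' @param values NCI values at `times`.
#' @param t_start,t_end First and last grid hour (defaults 0 and the
#'   largest whole hour inside the span).
#' @return A list with `times` (hourly grid) and `nci`.
#' @export
resample_uniform <- function(times, values, t_start = 0, t_end = NULL) {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(unique(times)) < 4) {
    stop("at least 4 distinct time points are required", call. = FALSE)
  }
  o <- order(times)
  times <- times[o]; values <- values[o]
  if (is.null(t_end)) t_end <- floor(max(times))
  grid <- seq(t_start, t_end, by = 1)
  if (grid[1] < min(times) - 1e-9 || grid[length(grid)] > max(times) + 1e-9) {
    stop("requested grid lies outside the observed time span", call. = FALSE)
  }
  nci <- spline_notaknot(times, values, grid)
  # pass through observed values exactly at coinciding nodes
  hit <- match(round(grid, 9), round(times, 9))
  nci[!is.na(hit)] <- values[hit[!is.na(hit)]]
  list(times = grid, nci = nci)
}

#' Full preprocessing of one well: normalize and resample
#'
#' @param series A [cell_index_series()] spanning at least `t_end` hours.
#' @param concentration Concentration or `"negative_control"`.
#' @param chemical_id Chemical identifier.
#' @param t_end Last grid hour (default 72, giving 73 samples).
#' @return A [tcrc()].
#' @export
preprocess_well <- function(series, concentration,
                            chemical_id = NA_character_, t_end = 72) {
  nrm <- normalize_ci(series)
  keep <- nrm$times >= 0
  rs <- resample_uniform(nrm$times[keep], nrm$nci[keep],
                         t_start = 0, t_end = t_end)
  tcrc(rs$times, rs$nci, concentration, chemical_id)
}
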