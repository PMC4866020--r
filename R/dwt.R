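# Multilevel discrete wavelet transform, order-2 Daubechies, half-point
# symmetric boundary extension. Conventions follow the classic MATLAB
# wavedec/waverec filter bank: each level maps a block of length L to
# approximation/detail blocks of length floor((L + lf - 1)/2) with
# lf = 4, which yields the coefficient-count arithmetic this package's
# featurization relies on (e.g. 876 -> 439, 221, 112, 57, 30, 30).

db2_filters <- function() {
  s3 <- sqrt(3)
  lo_r <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  list(lo_d = rev(lo_r),
       hi_d = c(-lo_r[1], lo_r[2], -lo_r[3], lo_r[4]),
       lo_r = lo_r,
       hi_r = rev(c(-lo_r[1], lo_r[2], -lo_r[3], lo_r[4])),
       lf = 4L)
}

# full linear convolution via the C fast path in stats::filter
conv_full <- function(x, f) {
  n <- length(x); m <- length(f)
  xp <- c(numeric(m - 1), x, numeric(m - 1))
  y <- stats::filter(xp, f, method = "convolution", sides = 1)
  as.numeric(y)[m:(n + 2 * m - 2)]
}

# half-point symmetric extension by e samples on each side; the infinite
# extension has period 2L with pattern x_1..x_L, x_L..x_1
sym_ext <- function(x, e) {
  L <- length(x)
  per <- c(x, rev(x))
  i <- (1 - e):(L + e)
  per[((i - 1) %% (2 * L)) + 1]
}

# one analysis step: symmetric extension, valid convolution, keep
# even-indexed samples
dwt_step <- function(x, flt) {
  L <- length(x); lf <- flt$lf
  ext <- sym_ext(x, lf - 1)
  va <- conv_full(ext, flt$lo_d)
  vd <- conv_full(ext, flt$hi_d)
  keep <- lf:(length(ext))           # valid part of the full convolution
  va <- va[keep]; vd <- vd[keep]
  idx <- seq(2, length(va), by = 2)  # even-phase downsampling
  list(a = va[idx], d = vd[idx])
}

# one synthesis step: zero-stuff at even positions, convolve with
# reconstruction filters, crop 3 leading samples, keep L
idwt_step <- function(a, d, L, flt) {
  la <- length(a)
  ua <- numeric(2 * la); ud <- numeric(2 * la)
  pos <- seq(2, 2 * la, by = 2)
  ua[pos] <- a; ud[pos] <- d
  y <- conv_full(ua, flt$lo_r) + conv_full(ud, flt$hi_r)
  y[4:(3 + L)]
}

#' Block lengths of a multilevel wavelet decomposition
#'
#' Applies the length recursion `L_next = floor((L + 3)/2)` of the
#' 4-tap filter bank, returning the per-block lengths in coarse-to-fine
#' order (CA_n, CD_n, ..., CD_1).
#'
#' @param length_in Input signal length.
#' @param level Decomposition level `n >= 1`.
#' @return Named integer vector `c(CA<n>, CD<n>, ..., CD1)`.
#' @export
dwt_block_lengths <- function(length_in, level) {
  stopifnot(length_in >= 1, level >= 1)
  lens <- integer(level)
  L <- as.integer(length_in)
  for (j in seq_len(level)) {
    L <- (L + 3L) %/% 2L
    lens[j] <- L
  }
  out <- c(lens[level], rev(lens))
  names(out) <- c(paste0("CA", level), paste0("CD", level:1))
  out
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a signal with the order-2 Daubechies filter pair and
#' half-point symmetric boundary extension. Level 1 splits the signal
#' into approximation (CA_1) and detail (CD_1) blocks; each further
#' level re-decomposes the previous approximation, leaving one
#' approximation block CA_n and detail blocks CD_n ... CD_1.
#'
#' @param signal Numeric vector (non-empty).
#' @param level Decomposition level `n >= 1`.
#' @return An object of class `wavelet_decomposition` with elements
#'   `approx` (CA_n), `details` (list CD_n, ..., CD_1 coarse-to-fine),
#'   `level`, `block_lengths`, and `length_in`.
#' @export
dwt_decompose <- function(signal, level = 5L) {
  if (length(signal) == 0) stop("empty signal", call. = FALSE)
  if (level < 1) stop("`level` must be >= 1", call. = FALSE)
  flt <- db2_filters()
  details <- vector("list", level)
  a <- as.numeric(signal)
  for (j in seq_len(level)) {
    st <- dwt_step(a, flt)
    a <- st$a
    details[[j]] <- st$d
  }
  details <- rev(details)              # CD_n first (coarse-to-fine)
  names(details) <- paste0("CD", level:1)
  bl <- c(length(a), vapply(details, length, integer(1)))
  names(bl) <- c(paste0("CA", level), names(details))
  structure(list(approx = a, details = details, level = level,
                 block_lengths = bl, length_in = length(signal)),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> level %d of %d samples; blocks: %s\n",
              x$level, x$length_in,
              paste(names(x$block_lengths), x$block_lengths,
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Inverse multilevel wavelet transform
#'
#' Reconstructs the original signal from all coefficient blocks; the
#' filter bank is perfectly reconstructing, so the result matches the
#' input of [dwt_decompose()] to machine precision.
#'
#' @param dec A `wavelet_decomposition`.
#' @return Numeric vector of length `dec$length_in`.
#' @export
dwt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  flt <- db2_filters()
  # lengths of the approximation at each level, finest to coarsest
  lens <- integer(dec$level + 1)
  lens[1] <- dec$length_in
  for (j in seq_len(dec$level)) lens[j + 1] <- (lens[j] + 3L) %/% 2L
  a <- dec$approx
  for (j in dec$level:1) {
    d <- dec$details[[paste0("CD", j)]]
    a <- idwt_step(a, d, lens[j], flt)
  }
  a
}

#' Flatten a decomposition coarse-to-fine
#'
#' @param dec A `wavelet_decomposition`.
#' @return Numeric vector `c(CA_n, CD_n, ..., CD_1)`.
#' @export
dwt_flatten <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  c(dec$approx, unlist(dec$details, use.names = FALSE))
}
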