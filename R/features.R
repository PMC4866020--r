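# Classifier input construction: concatenation of concentration curves,
# wavelet decomposition, and coarse-to-fine coefficient pruning W_n(m).

#' Concatenate the curves of a TCRC set into one input vector
#'
#' Builds the vector TCRC(n): the `n` highest-concentration curves in
#' rank order (rank 1 = highest concentration), optionally followed by
#' the negative-control curve. With the default 73-sample grid,
#' TCRC(11) has 803 points and TCRC(11)+NC has 876.
#'
#' @param set A [tcrc_set()].
#' @param n Number of highest-concentration curves to include (1..11).
#' @param include_nc Append the negative-control curve? Default `TRUE`.
#' @return An object of class `concatenated_input` with `values`,
#'   `segment_lengths`, `n_concentrations`, `include_nc`.
#' @export
concatenate_tcrc <- function(set, n = 11L, include_nc = TRUE) {
  stopifnot(inherits(set, "tcrc_set"))
  if (n < 1 || n > length(set$curves)) {
    stop(sprintf("`n` must be in 1..%d", length(set$curves)), call. = FALSE)
  }
  curves <- set$curves[seq_len(n)]
  if (include_nc) curves <- c(curves, list(set$negative_control))
  values <- unlist(lapply(curves, `[[`, "nci"), use.names = FALSE)
  structure(list(values = values,
                 segment_lengths = vapply(curves, function(cv)
                   length(cv$nci), integer(1)),
                 n_concentrations = as.integer(n),
                 include_nc = isTRUE(include_nc),
                 chemical_id = set$chemical_id,
                 label = set$label),
            class = "concatenated_input")
}

#' Prune a wavelet decomposition coarse-to-fine: the W_n(m) selection
#'
#' Keeps the `m` coarsest coefficient blocks of an n-level
#' decomposition: CA_n first, then CD_n, CD_{n-1}, ... Detail blocks at
#' fine levels mostly carry small fluctuations and noise, so pruning
#' from the fine end compresses the curve while retaining its shape.
#' `m = n + 1` keeps every coefficient; W_n(m) is always a prefix of
#' W_n(m+1).
#'
#' @param dec A `wavelet_decomposition` from [dwt_decompose()].
#' @param m Number of blocks to keep, `1 <= m <= level + 1`.
#' @return An object of class `feature_vector` with `values`,
#'   `provenance` (e.g. `"W5(4)"`), `level`, `kept_blocks`.
#' @export
select_coefficients <- function(dec, m) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  if (m < 1 || m > dec$level + 1) {
    stop(sprintf("`m` must be in 1..%d", dec$level + 1), call. = FALSE)
  }
  blocks <- c(list(dec$approx), unname(dec$details))[seq_len(m)]
  structure(list(values = unlist(blocks, use.names = FALSE),
                 provenance = sprintf("W%d(%d)", dec$level, m),
                 level = dec$level, kept_blocks = as.integer(m)),
            class = "feature_vector")
}

#' Input-size reduction achieved by a feature vector
#'
#' @param feature A `feature_vector` (or any object with `values`), or a
#'   plain numeric vector.
#' @param raw_length Length of the raw input it replaces.
#' @return Reduction as a whole percentage: `round(100 * (1 - len/raw))`.
#' @export
reduction_percent <- function(feature, raw_length) {
  if (raw_length <= 0) stop("`raw_length` must be > 0", call. = FALSE)
  len <- if (is.list(feature)) length(feature$values) else length(feature)
  round(100 * (1 - len / raw_length))
}

#' Featurize a collection of TCRC sets into a classifier input matrix
#'
#' Applies [concatenate_tcrc()] to every set and, unless `raw = TRUE`,
#' an n-level wavelet decomposition followed by the W_n(m) pruning.
#'
#' @param sets List of [tcrc_set()] objects.
#' @param n Number of highest-concentration curves (default 11).
#' @param include_nc Append the negative control (default `TRUE`).
#' @param level Decomposition level (default 5).
#' @param m Blocks kept, 1..level+1 (default `level + 1`, all blocks).
#' @param raw If `TRUE`, skip the wavelet step and use the concatenated
#'   curves directly.
#' @return List with `x` (numeric matrix, one row per chemical), `labels`
#'   (character), `chemical_ids`, `provenance`.
#' @export
featurize_sets <- function(sets, n = 11L, include_nc = TRUE,
                           level = 5L, m = level + 1L, raw = FALSE) {
  stopifnot(length(sets) >= 1)
  rows <- lapply(sets, function(s) {
    ci <- concatenate_tcrc(s, n = n, include_nc = include_nc)
    if (raw) return(ci$values)
    select_coefficients(dwt_decompose(ci$values, level = level), m = m)$values
  })
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(sets, `[[`, character(1), "chemical_id")
  list(x = x,
       labels = vapply(sets, function(s) as.character(s$label), character(1)),
       chemical_ids = rownames(x),
       provenance = if (raw) sprintf("raw TCRC(%d)%s", n,
                                     if (include_nc) "+NC" else "")
                    else sprintf("W%d(%d) of TCRC(%d)%s", level, m, n,
                                 if (include_nc) "+NC" else ""))
}

#' Write a feature table as delimited text
#'
#' One row per chemical: `chemical_id,label,provenance,v1..vk`.
#'
#' @param feats Result of [featurize_sets()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(feats, path) {
  df <- data.frame(chemical_id = feats$chemical_ids,
                   label = feats$labels,
                   provenance = feats$provenance,
                   feats$x, check.names = FALSE)
  colnames(df) <- c("chemical_id", "label", "provenance",
                    paste0("v", seq_len(ncol(feats$x))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
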