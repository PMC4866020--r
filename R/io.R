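# Delimited-text interfaces. Two formats are supported: the raw
# long-format instrument export (`well,time_h,value` plus a plate map
# `well,chemical_id,concentration,role,label`) and the resampled
# TCRC-set serialization (one row per chemical, curve and hour).

#' Read raw per-well recordings and a plate map into TCRC sets
#'
#' Each treated or negative-control well's series is normalized to its
#' value right before treatment (time 0) and resampled to the hourly
#' grid; wells are then grouped per chemical into [tcrc_set()] objects.
#' One well per (chemical, concentration) is expected.
#'
#' @param data_path CSV with header `well,time_h,value` (value = cell
#'   index; hours relative to treatment, must include 0).
#' @param platemap_path CSV with header
#'   `well,chemical_id,concentration,role[,label]`; `role` is
#'   `"treated"` or `"negative_control"`; concentrations in one
#'   declared unit, decimal notation.
#' @param t_end Last grid hour (default 72).
#' @return List of [tcrc_set()] objects.
#' @export
read_rtca <- function(data_path, platemap_path, t_end = 72) {
  dat <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  pm <- utils::read.csv(platemap_path, stringsAsFactors = FALSE)
  need <- c("well", "time_h", "value")
  if (!all(need %in% names(dat))) {
    stop("data file needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  needp <- c("well", "chemical_id", "concentration", "role")
  if (!all(needp %in% names(pm))) {
    stop("plate map needs columns ", paste(needp, collapse = ","),
         call. = FALSE)
  }
  if (!"label" %in% names(pm)) pm$label <- NA_character_
  well_curve <- function(well, concentration, chemical_id) {
    d <- dat[dat$well == well, ]
    if (nrow(d) == 0) stop("no data for well ", well, call. = FALSE)
    d <- d[order(d$time_h), ]
    ser <- cell_index_series(d$time_h, d$value)
    preprocess_well(ser, concentration, chemical_id, t_end = t_end)
  }
  sets <- list()
  for (chem in unique(pm$chemical_id)) {
    rows <- pm[pm$chemical_id == chem, ]
    tr <- rows[rows$role == "treated", ]
    ncw <- rows[rows$role == "negative_control", ]
    if (nrow(ncw) != 1) {
      stop("chemical ", chem, " needs exactly one negative-control well",
           call. = FALSE)
    }
    tr <- tr[order(-as.numeric(tr$concentration)), ]
    curves <- lapply(seq_len(nrow(tr)), function(i)
      well_curve(tr$well[i], as.numeric(tr$concentration[i]), chem))
    nc <- well_curve(ncw$well[1], "negative_control", chem)
    nc$concentration <- "negative_control"
    lab <- tr$label[1]
    sets[[length(sets) + 1]] <-
      tcrc_set(chem, curves, nc,
               label = if (is.null(lab) || is.na(lab)) NA_character_
                       else as.character(lab),
               n_curves = nrow(tr))
  }
  sets
}

#' Serialize TCRC sets as delimited text
#'
#' One row per (chemical, curve, hour):
#' `chemical_id,label,concentration,role,time_h,nci`.
#'
#' @param sets List of [tcrc_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tcrc_sets <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    one <- function(cv, role) {
      data.frame(chemical_id = s$chemical_id,
                 label = if (is.na(s$label)) "" else s$label,
                 concentration = if (role == "negative_control") ""
                                 else as.numeric(cv$concentration),
                 role = role, time_h = cv$times, nci = cv$nci)
    }
    do.call(rbind, c(lapply(s$curves, one, role = "treated"),
                     list(one(s$negative_control, "negative_control"))))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read TCRC sets written by [write_tcrc_sets()]
#'
#' @param path Input path.
#' @return List of [tcrc_set()] objects (exact round trip).
#' @export
read_tcrc_sets <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(concentration = "character"))
  sets <- list()
  for (chem in unique(d$chemical_id)) {
    dc <- d[d$chemical_id == chem, ]
    lab <- dc$label[1]
    tr <- dc[dc$role == "treated", ]
    concs <- unique(as.numeric(tr$concentration))
    concs <- sort(concs, decreasing = TRUE)
    curves <- lapply(concs, function(cc) {
      di <- tr[abs(as.numeric(tr$concentration) - cc) < 1e-12, ]
      di <- di[order(di$time_h), ]
      tcrc(di$time_h, di$nci, cc, chem)
    })
    dn <- dc[dc$role == "negative_control", ]
    dn <- dn[order(dn$time_h), ]
    nc <- tcrc(dn$time_h, dn$nci, "negative_control", chem)
    sets[[length(sets) + 1]] <-
      tcrc_set(chem, curves, nc,
               label = if (is.na(lab) || lab == "") NA_character_
                       else as.character(lab),
               n_curves = length(curves))
  }
  sets
}

#' Write a generated dataset in the raw instrument format
#'
#' Emits the `well,time_h,value` + plate-map pair consumed by
#' [read_rtca()], one synthetic well per curve.
#'
#' @param dataset Result of [generate_dataset()].
#' @param data_path,platemap_path Output paths.
#' @return `data_path`, invisibly.
#' @export
write_raw_dataset <- function(dataset, data_path, platemap_path) {
  dat <- list(); pm <- list()
  for (s in dataset$sets) {
    curves <- c(s$curves, list(s$negative_control))
    for (i in seq_along(curves)) {
      cv <- curves[[i]]
      nc <- is_negative_control(cv)
      well <- sprintf("%s_w%02d", s$chemical_id, i)
      dat[[length(dat) + 1]] <- data.frame(well = well, time_h = cv$times,
                                           value = cv$nci)
      pm[[length(pm) + 1]] <- data.frame(
        well = well, chemical_id = s$chemical_id,
        concentration = if (nc) "" else as.numeric(cv$concentration),
        role = if (nc) "negative_control" else "treated",
        label = if (is.na(s$label)) "" else s$label)
    }
  }
  utils::write.csv(do.call(rbind, dat), data_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, pm), platemap_path, row.names = FALSE)
  invisible(data_path)
}
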