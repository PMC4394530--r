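# Delimited-text and YAML interchange: cohort tables, evoked exports,
# ground-truth sidecars, head-model archives, provenance.

cohort_csv_columns <- c("subject_id", "sex", "age", "episode", "smoker",
                        "hypnotic", "drug", "dose_mg", "bdi_pre", "bdi_post")

#' Write / read a cohort clinical table as CSV
#'
#' The CSV carries the clinical columns (subject_id, sex, age,
#' episode, smoker, hypnotic, drug, dose_mg, bdi_pre, bdi_post); any
#' additional columns present (e.g. simulated LDAEP values) are
#' appended after them.
#'
#' @param tab cohort data frame (or a `cohort` object).
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly;
#'   `read_cohort_csv` the data frame.
#' @export
write_cohort_csv <- function(tab, path) {
  if (inherits(tab, "cohort")) tab <- tab$table
  miss <- setdiff(cohort_csv_columns, names(tab))
  if (length(miss)) stopf("cohort table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  ord <- c(cohort_csv_columns, setdiff(names(tab), cohort_csv_columns))
  utils::write.csv(tab[, ord], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_csv_columns, names(tab))
  if (length(miss)) stopf("cohort CSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tab
}

#' Export an evoked set as a long table
#'
#' One row per channel x time x intensity, with a JSON provenance
#' sidecar recording filter settings, reference, rejection counts.
#'
#' @param evoked an `evoked_set`.
#' @param path CSV path (`<path>.json` gets the provenance).
#' @param provenance named list merged into the sidecar.
#' @return Invisibly, `path`.
#' @export
write_evoked <- function(evoked, path, provenance = list()) {
  stopifnot(inherits(evoked, "evoked_set"))
  rows <- list()
  for (k in seq_along(evoked$intensities)) {
    d <- evoked$data[[k]]
    rows[[k]] <- data.frame(
      intensity_db = evoked$intensities[k],
      channel = rep(evoked$channels, times = ncol(d)),
      time_ms = rep(evoked$times, each = nrow(d)),
      amplitude_uv = as.vector(d)
    )
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  side <- c(provenance,
            list(intensities = evoked$intensities,
                 n_epochs_used = evoked$n_epochs_used,
                 rejection_rate = evoked$rejection_rate,
                 reference = evoked$reference,
                 srate = evoked$srate))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write per-subject ground truth as YAML
#'
#' @param gt a [ground_truth()] object or a named list of them.
#' @param path YAML path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth_yaml <- function(gt, path) {
  if (inherits(gt, "ground_truth")) gt <- list(subject = unclass(gt))
  yaml::write_yaml(lapply(gt, unclass), path)
  invisible(path)
}

#' Serialize / restore a head model
#'
#' The archive is a directory holding a YAML descriptor plus CSV
#' matrices (source positions, lead field, ROI indices), so it is
#' plain text throughout.
#'
#' @param model a [build_head_model()] object.
#' @param dir archive directory.
#' @return `write_head_model` returns `dir` invisibly;
#'   `read_head_model` the restored `head_model`.
#' @export
write_head_model <- function(model, dir) {
  stopifnot(inherits(model, "head_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(
    list(sensors = model$sensors, orientation = model$orientation,
         radii = model$radii, cond = model$cond,
         source_radius = model$source_radius,
         roi = lapply(model$roi, as.integer)),
    file.path(dir, "descriptor.yaml"))
  utils::write.csv(as.data.frame(model$source_pos),
                   file.path(dir, "source_pos.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$L),
                   file.path(dir, "leadfield.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$sensor_pos),
                   file.path(dir, "sensor_pos.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_head_model
#' @export
read_head_model <- function(dir) {
  desc <- yaml::read_yaml(file.path(dir, "descriptor.yaml"))
  sp <- as.matrix(utils::read.csv(file.path(dir, "source_pos.csv")))
  L <- as.matrix(utils::read.csv(file.path(dir, "leadfield.csv")))
  sens <- as.matrix(utils::read.csv(file.path(dir, "sensor_pos.csv")))
  dimnames(sp) <- dimnames(L) <- NULL
  rownames(sens) <- desc$sensors
  colnames(sens) <- NULL
  structure(
    list(sensors = desc$sensors, sensor_pos = sens, source_pos = sp,
         orientation = desc$orientation, L = L,
         roi = lapply(desc$roi, as.integer),
         radii = unlist(desc$radii), cond = unlist(desc$cond),
         source_radius = desc$source_radius),
    class = "head_model"
  )
}
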