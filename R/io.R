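# Readers and writers for the pipeline's plain-text interchange formats:
# long-format TSV for CHC and Ct tables, per-trial trajectory CSV with a
# targets sidecar, and JSON ground-truth records.

#' Read / write a CHC intensity table (long-format TSV)
#'
#' Columns: `sample_id genotype age_days replicate platform compound
#' intensity`.  An optional descriptor TSV (columns as in
#' [compound_descriptors()]) covers compound names outside the grammar.
#'
#' @param path TSV path.
#' @param descriptor_path Optional descriptor TSV path.
#' @param state Processing state of the stored table, default `"raw"`.
#' @return `read_chc_table()`: a [chc_table()]; `write_chc_table()`: the
#'   path, invisibly.
#' @export
read_chc_table <- function(path, descriptor_path = NULL, state = "raw") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  desc <- NULL
  if (!is.null(descriptor_path)) {
    extra <- readr::read_tsv(descriptor_path, show_col_types = FALSE)
    desc <- compound_descriptors(unique(df$compound), extra = extra)
  }
  chc_table(df, descriptors = desc, state = state)
}

#' @param table A [chc_table()].
#' @rdname read_chc_table
#' @export
write_chc_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Write / read a set of trial trajectories (CSV + targets sidecar)
#'
#' The trajectory file has columns
#' `trial_id,replicate,frame,time_s,x_mm,y_mm` (all trials concatenated);
#' the sidecar has `trial_id,target_label,treatment,x_mm,y_mm`.
#'
#' @param trials List of [trajectory()] objects.
#' @param path Trajectory CSV path.
#' @param targets_path Targets sidecar CSV path.
#' @return `write_trajectories()`: `path`, invisibly;
#'   `read_trajectories()`: a list of [trajectory()] objects.
#' @export
write_trajectories <- function(trials, path, targets_path) {
  frames <- dplyr::bind_rows(lapply(trials, function(tr) {
    tibble::tibble(trial_id = tr$trial_id, replicate = tr$replicate,
                   frame = seq_len(nrow(tr$frames)),
                   time_s = tr$frames$time_s,
                   x_mm = tr$frames$x_mm, y_mm = tr$frames$y_mm)
  }))
  targets <- dplyr::bind_rows(lapply(trials, function(tr) {
    tibble::tibble(trial_id = tr$trial_id,
                   target_label = tr$targets$label,
                   treatment = tr$targets$treatment,
                   x_mm = tr$targets$x_mm, y_mm = tr$targets$y_mm)
  }))
  readr::write_csv(frames, path)
  readr::write_csv(targets, targets_path)
  invisible(path)
}

#' @param arena Arena descriptor attached to each read trajectory.
#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, targets_path,
                              arena = list(center = c(0, 0),
                                           radius_mm = 27.5)) {
  frames <- readr::read_csv(path, show_col_types = FALSE)
  targets <- readr::read_csv(targets_path, show_col_types = FALSE)
  lapply(split(frames, frames$trial_id), function(fr) {
    tg <- targets[targets$trial_id == fr$trial_id[1], ]
    fps <- 1 / stats::median(diff(fr$time_s))
    trajectory(trial_id = fr$trial_id[1], replicate = fr$replicate[1],
               fps = fps,
               frames = fr[, c("time_s", "x_mm", "y_mm")],
               targets = tibble::tibble(label = tg$target_label,
                                        treatment = tg$treatment,
                                        x_mm = tg$x_mm, y_mm = tg$y_mm),
               arena = arena)
  })
}

#' Read / write a Ct table (CSV)
#'
#' Columns: `condition,bio_rep,tech_rep,gene,ct`.
#'
#' @param path CSV path.
#' @param reference Reference gene checked on read, default `"rp49"`.
#' @return `read_ct_table()`: a validated Ct tibble;
#'   `write_ct_table()`: the path, invisibly.
#' @export
read_ct_table <- function(path, reference = "rp49") {
  ct_table(readr::read_csv(path, show_col_types = FALSE), reference)
}

#' @param table A Ct tibble.
#' @rdname read_ct_table
#' @export
write_ct_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Write a ground-truth record as JSON
#'
#' @param truth Ground-truth list from a generator.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
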