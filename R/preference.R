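# Two-choice preference assay: dwell-time scoring of trajectories and
# courtship bout lists into per-trial preference percentages.

#' Construct a two-choice trial trajectory
#'
#' Frame-indexed positions of the single choosing male together with the
#' two stationary (decapitated) target flies and the arena geometry.  The
#' two targets must carry distinct treatments (`"manipulated"` vs
#' `"control"`) and be far enough apart that their scoring circles cannot
#' overlap.
#'
#' @param trial_id,replicate Labels identifying the trial and the
#'   experimental replicate it belongs to.
#' @param fps Recording frame rate (frames/s).
#' @param frames Data frame with columns `time_s`, `x_mm`, `y_mm`; times
#'   strictly increasing.
#' @param targets Data frame with columns `label`, `treatment`
#'   (`"manipulated"`/`"control"`), `x_mm`, `y_mm`; exactly two rows.
#' @param arena List with `center` (x, y in mm) and `radius_mm`.
#' @param circle_radius_mm Scoring-circle radius used to validate target
#'   separation, default 3.
#' @return A `trajectory` object.
#' @export
trajectory <- function(trial_id, replicate, fps, frames, targets,
                       arena = list(center = c(0, 0), radius_mm = 27.5),
                       circle_radius_mm = 3) {
  frames <- tibble::as_tibble(frames)
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("time_s", "x_mm", "y_mm") %in% names(frames)),
            all(c("label", "treatment", "x_mm", "y_mm") %in% names(targets)),
            nrow(targets) == 2L)
  if (!setequal(targets$treatment, c("manipulated", "control"))) {
    stop("targets must carry distinct treatments 'manipulated' and ",
         "'control'", call. = FALSE)
  }
  if (is.unsorted(frames$time_s, strictly = TRUE)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  sep <- sqrt(diff(targets$x_mm)^2 + diff(targets$y_mm)^2)
  if (sep <= 2 * circle_radius_mm) {
    stop("target separation (", round(sep, 2), " mm) must exceed twice the ",
         "scoring-circle radius", call. = FALSE)
  }
  structure(list(trial_id = trial_id, replicate = replicate, fps = fps,
                 frames = frames, targets = targets, arena = arena),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> trial", x$trial_id, "replicate", x$replicate, "|",
      nrow(x$frames), "frames @", x$fps, "fps\n")
  invisible(x)
}

#' Per-target dwell times of a trajectory
#'
#' A frame counts toward a target when the choosing fly's position lies
#' within `circle_radius_mm` of the target center, boundary inclusive
#' (distance exactly equal to the radius counts).  Dwell time is the frame
#' count divided by the frame rate.  Frames with missing coordinates are
#' dropped from both the numerator and the denominator and reported in
#' `frames_dropped`.
#'
#' @param traj A [trajectory()].
#' @param circle_radius_mm Scoring-circle radius in mm, default 3.
#' @return A list with `t_manipulated_s`, `t_control_s`, `t_outside_s`,
#'   `by_label` (named dwell times keyed by target label), `frames_used`,
#'   `frames_dropped`.  `t_manipulated + t_control + t_outside`
#'   equals `frames_used / fps` exactly.
#' @export
dwell_times <- function(traj, circle_radius_mm = 3) {
  stopifnot(inherits(traj, "trajectory"))
  sep <- sqrt(diff(traj$targets$x_mm)^2 + diff(traj$targets$y_mm)^2)
  if (sep <= 2 * circle_radius_mm) {
    stop("scoring circles overlap (separation ", round(sep, 2),
         " mm <= 2 x ", circle_radius_mm, " mm): trial unusable",
         call. = FALSE)
  }
  fr <- traj$frames
  ok <- stats::complete.cases(fr[, c("x_mm", "y_mm")])
  n_drop <- sum(!ok)
  if (n_drop > 0L) {
    message("trial ", traj$trial_id, ": dropping ", n_drop,
            " frame(s) with missing coordinates")
  }
  fr <- fr[ok, ]
  counts <- vapply(seq_len(2), function(i) {
    d2 <- (fr$x_mm - traj$targets$x_mm[i])^2 +
      (fr$y_mm - traj$targets$y_mm[i])^2
    sum(d2 <= circle_radius_mm^2)
  }, numeric(1))
  t_by_label <- stats::setNames(counts / traj$fps, traj$targets$label)
  t_by_treat <- stats::setNames(counts / traj$fps, traj$targets$treatment)
  list(t_manipulated_s = unname(t_by_treat["manipulated"]),
       t_control_s = unname(t_by_treat["control"]),
       t_outside_s = (nrow(fr) - sum(counts)) / traj$fps,
       by_label = t_by_label,
       frames_used = nrow(fr),
       frames_dropped = n_drop)
}

.trial_score_row <- function(trial_id, replicate, t_manip, t_ctrl,
                             kept, reason) {
  total <- t_manip + t_ctrl
  tibble::tibble(
    trial_id = trial_id, replicate = replicate,
    t_manipulated_s = t_manip, t_control_s = t_ctrl, t_total_s = total,
    preference_pct = if (total > 0) 100 * t_manip / total else NA_real_,
    kept = kept,
    exclusion_reason = reason)
}

#' Score a two-choice trial from its dwell times
#'
#' Preference is the percentage of target-directed time spent with the
#' manipulated fly: `100 * t_manip / (t_manip + t_ctrl)`.  Trials whose
#' total target time is less than `min_total_s` (default 50 s, i.e. 2.8%
#' of a 30-min observation) reflect a male that never engaged and are
#' excluded; a total of exactly `min_total_s` is kept.
#'
#' @param t_manip_s,t_ctrl_s Dwell times (s) for the manipulated and
#'   control targets.
#' @param min_total_s Minimum total target time to keep the trial.
#' @param trial_id,replicate Optional labels carried into the score row.
#' @return A one-row `TrialScore` tibble: `trial_id`, `replicate`,
#'   `t_manipulated_s`, `t_control_s`, `t_total_s`, `preference_pct`
#'   (`NA` when total is 0), `kept`, `exclusion_reason`.
#' @export
#' @examples
#' score_trial(300, 300)
#' score_trial(30, 19.9)  # total 49.9 s < 50 s: excluded
score_trial <- function(t_manip_s, t_ctrl_s, min_total_s = 50,
                        trial_id = NA_character_,
                        replicate = NA_character_) {
  stopifnot(t_manip_s >= 0, t_ctrl_s >= 0, min_total_s >= 0)
  total <- t_manip_s + t_ctrl_s
  if (total == 0) {
    return(.trial_score_row(trial_id, replicate, t_manip_s, t_ctrl_s,
                            kept = FALSE, reason = "zero_target_time"))
  }
  if (total < min_total_s) {
    return(.trial_score_row(trial_id, replicate, t_manip_s, t_ctrl_s,
                            kept = FALSE, reason = "below_min_total"))
  }
  .trial_score_row(trial_id, replicate, t_manip_s, t_ctrl_s,
                   kept = TRUE, reason = NA_character_)
}

#' Score a trajectory into a TrialScore
#'
#' Convenience wrapper: [dwell_times()] followed by [score_trial()].
#'
#' @inheritParams dwell_times
#' @inheritParams score_trial
#' @return A one-row `TrialScore` tibble.
#' @export
score_trajectory <- function(traj, circle_radius_mm = 3, min_total_s = 50) {
  dt <- dwell_times(traj, circle_radius_mm)
  score_trial(dt$t_manipulated_s, dt$t_control_s, min_total_s,
              trial_id = traj$trial_id, replicate = traj$replicate)
}

#' Score a live courtship assay from a bout list
#'
#' Human-scored courtship bouts (orientation, wing vibration, attempted
#' copulation) are filtered to bouts strictly longer than `min_bout_s`
#' (default 20 s; a bout of exactly 20 s is discarded), summed per target,
#' and converted to a preference percentage exactly as in [score_trial()].
#' The live assay has no minimum-total rule; a trial with no retained
#' bouts is excluded with preference undefined.
#'
#' @param bouts Data frame with columns `treatment`
#'   (`"manipulated"`/`"control"`), `start_s`, `end_s` (end > start), and
#'   optionally `trial_id`, `replicate`.
#' @param min_bout_s Minimum bout duration; only strictly longer bouts are
#'   counted as courtship.
#' @param trial_id,replicate Labels; taken from `bouts` if present there.
#' @return A one-row `TrialScore` tibble.
#' @export
score_courtship <- function(bouts, min_bout_s = 20,
                            trial_id = NA_character_,
                            replicate = NA_character_) {
  bouts <- tibble::as_tibble(bouts)
  stopifnot(all(c("treatment", "start_s", "end_s") %in% names(bouts)),
            all(bouts$treatment %in% c("manipulated", "control")))
  if (any(bouts$end_s <= bouts$start_s)) {
    stop("bouts must have end_s > start_s", call. = FALSE)
  }
  if ("trial_id" %in% names(bouts) && nrow(bouts)) trial_id <- bouts$trial_id[1]
  if ("replicate" %in% names(bouts) && nrow(bouts)) replicate <- bouts$replicate[1]
  dur <- bouts$end_s - bouts$start_s
  keep <- dur > min_bout_s
  t_manip <- sum(dur[keep & bouts$treatment == "manipulated"])
  t_ctrl <- sum(dur[keep & bouts$treatment == "control"])
  if (t_manip + t_ctrl == 0) {
    return(.trial_score_row(trial_id, replicate, 0, 0,
                            kept = FALSE, reason = "no_retained_bouts"))
  }
  .trial_score_row(trial_id, replicate, t_manip, t_ctrl,
                   kept = TRUE, reason = NA_character_)
}

#' Pool trial scores across experimental replicates
#'
#' Concatenates TrialScore tables from several replicates while preserving
#' replicate labels, so the stratified permutation scheme can still
#' randomize within replicates.  Trial ids must be disjoint.
#'
#' @param ... TrialScore tibbles (or a single list of them).
#' @return One combined TrialScore tibble.
#' @export
pool_replicates <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  out <- dplyr::bind_rows(parts)
  dup <- out$trial_id[duplicated(out$trial_id)]
  if (length(dup)) {
    stop("duplicate trial id(s) across replicates: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  out
}

#' Exclusion threshold as a percentage of the observation time
#'
#' Expresses the minimum-total-dwell rule as a percentage of the full
#' observation (e.g. 50 s of a 30-min video is 2.8% after rounding to one
#' decimal).
#'
#' @param min_total_s Exclusion threshold in seconds, default 50.
#' @param observation_s Observation length in seconds, default 1800 (30 min).
#' @param digits Decimals to round to, default 1.
#' @return The threshold as a percentage.
#' @export
#' @examples
#' exclusion_threshold_pct()  # 2.8
exclusion_threshold_pct <- function(min_total_s = 50, observation_s = 1800,
                                    digits = 1) {
  stopifnot(observation_s > 0, min_total_s >= 0)
  round(100 * min_total_s / observation_s, digits)
}
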