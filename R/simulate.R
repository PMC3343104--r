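# Seeded synthetic-data generators with known ground truth: CHC intensity
# tables, two-choice trajectories, and qPCR Ct tables.  Defaults mirror the
# study conditions the downstream analyses assume.

#' Configuration for the synthetic CHC table generator
#'
#' The generative model is log-normal intensity variation around
#' per-compound baselines, filtered through unknown compound-specific
#' detection efficiencies (which per-sample normalization must cancel),
#' with optional multiplicative genotype and age effects on the ln scale:
#' \deqn{\ln raw = \ln eff_j + \ln base_j + g \cdot (\beta_j + \gamma (c_j -
#'   \bar c)) + \delta \cdot age + N(0, \sigma)}
#' where g indicates a non-control genotype, \eqn{\beta_j} is the
#' per-compound genotype effect, \eqn{\gamma} the per-carbon chain-length
#' component (centered on the midpoint of `carbon_range`), \eqn{\delta}
#' the per-day age drift and \eqn{\sigma} the biological SD.
#'
#' @param n_compounds Number of compounds (default 26, a GC/MS panel).
#' @param carbon_range Integer range of carbon-chain lengths, default
#'   21:29.
#' @param genotypes Genotype labels; the first is the control.
#' @param ages_days Sampling ages, default c(6, 23, 37, 48).
#' @param replicates_per_cell Biological replicates per genotype x age
#'   cell, default 5.
#' @param baseline_abundances Positive baseline per compound; drawn
#'   log-normally from the seed when `NULL`.
#' @param detection_efficiency Positive per-compound multiplier, constant
#'   across samples (a nuisance unknown to the analysis); drawn
#'   log-normally when `NULL`.
#' @param genotype_effect_ln Additive ln-scale genotype effect per
#'   compound (recycled), default 0.
#' @param chain_slope_ln Per-carbon component of the genotype effect,
#'   default 0.
#' @param age_slope_ln Per-day ln-scale drift, default 0.
#' @param noise_sd_ln Biological SD on the ln scale, default 0.3.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `chc_sim_config` list.
#' @export
chc_sim_config <- function(n_compounds = 26, carbon_range = 21:29,
                           genotypes = c("control", "mutant"),
                           ages_days = c(6, 23, 37, 48),
                           replicates_per_cell = 5,
                           baseline_abundances = NULL,
                           detection_efficiency = NULL,
                           genotype_effect_ln = 0,
                           chain_slope_ln = 0,
                           age_slope_ln = 0,
                           noise_sd_ln = 0.3,
                           seed = 1L) {
  stopifnot(n_compounds >= 1, length(genotypes) >= 1,
            length(ages_days) >= 1, replicates_per_cell >= 1,
            noise_sd_ln >= 0)
  if (!is.null(baseline_abundances)) {
    stopifnot(length(baseline_abundances) == n_compounds,
              all(baseline_abundances > 0))
  }
  if (!is.null(detection_efficiency)) {
    stopifnot(length(detection_efficiency) == n_compounds,
              all(detection_efficiency > 0))
  }
  structure(list(n_compounds = n_compounds, carbon_range = carbon_range,
                 genotypes = genotypes, ages_days = ages_days,
                 replicates_per_cell = replicates_per_cell,
                 baseline_abundances = baseline_abundances,
                 detection_efficiency = detection_efficiency,
                 genotype_effect_ln = genotype_effect_ln,
                 chain_slope_ln = chain_slope_ln,
                 age_slope_ln = age_slope_ln,
                 noise_sd_ln = noise_sd_ln,
                 seed = as.integer(seed)),
            class = "chc_sim_config")
}

# Default compound panel: for each chain length an alkane, a monoene, a
# diene and a methyl-branched form, carbon-major, truncated to n.
.default_panel <- function(n, carbon_range) {
  names <- unlist(lapply(carbon_range, function(k) {
    c(paste0("nC", k), paste0("C", k, ":1"), paste0("C", k, ":2"),
      paste0("2-MeC", k - 1))
  }))
  if (n > length(names)) {
    stop("n_compounds too large for carbon_range (max ",
         length(names), ")", call. = FALSE)
  }
  names[seq_len(n)]
}

#' Generate a synthetic CHC intensity table with known ground truth
#'
#' @param cfg A [chc_sim_config()].
#' @return A list: `table` (a raw-state [chc_table()]) and `truth` (the
#'   realized baselines, efficiencies, per-compound total genotype effects
#'   and the config).
#' @export
generate_chc_table <- function(cfg) {
  stopifnot(inherits(cfg, "chc_sim_config"))
  if (cfg$n_compounds < 1 || length(cfg$genotypes) < 1 ||
      length(cfg$ages_days) < 1) {
    stop("empty design: need compounds, genotypes and ages", call. = FALSE)
  }
  panel <- .default_panel(cfg$n_compounds, cfg$carbon_range)
  desc <- compound_descriptors(panel)
  carbon <- desc$carbon_count
  c_mid <- mean(range(cfg$carbon_range))
  withr::with_seed(cfg$seed, {
    base <- cfg$baseline_abundances %||%
      exp(stats::rnorm(cfg$n_compounds, mean = log(1e5), sd = 1))
    eff <- cfg$detection_efficiency %||%
      exp(stats::rnorm(cfg$n_compounds, mean = 0, sd = 0.5))
    beta <- rep_len(cfg$genotype_effect_ln, cfg$n_compounds)
    effect <- beta + cfg$chain_slope_ln * (carbon - c_mid)
    design <- expand.grid(replicate = paste0("R",
                            seq_len(cfg$replicates_per_cell)),
                          age_days = cfg$ages_days,
                          genotype = cfg$genotypes,
                          stringsAsFactors = FALSE)
    design$sample_id <- sprintf("S%03d", seq_len(nrow(design)))
    rows <- design[rep(seq_len(nrow(design)), each = cfg$n_compounds), ]
    rows$compound <- rep(panel, times = nrow(design))
    mut <- as.numeric(rows$genotype != cfg$genotypes[1])
    j <- rep(seq_len(cfg$n_compounds), times = nrow(design))
    ln_raw <- log(eff[j]) + log(base[j]) +
      mut * effect[j] +
      cfg$age_slope_ln * rows$age_days +
      stats::rnorm(nrow(rows), sd = cfg$noise_sd_ln)
    rows$intensity <- exp(ln_raw)
    rows$platform <- "GCMS"
    tbl <- chc_table(rows, descriptors = desc, state = "raw")
    list(table = tbl,
         truth = list(config = cfg,
                      compounds = panel,
                      carbon_count = carbon,
                      baseline_abundances = base,
                      detection_efficiency = eff,
                      genotype_effect_total_ln = effect))
  })
}

#' Configuration for the two-choice trial generator
#'
#' Trajectories follow a discrete-time two-state (at-target / wandering)
#' process: the male alternates geometric-length wandering and visiting
#' bouts; each visit is allocated to the manipulated target with
#' probability `true_preference_pct / 100`, so only dwell times -- the
#' quantity the assay scores -- carry signal.  `dwell_fraction` sets the
#' long-run fraction of time spent in either scoring circle and
#' `mean_visit_s` the mean length of one visit.
#'
#' The default arena is a 55 mm circular dish with targets 18 mm apart and
#' 8.5 mm from the wall (both at 19 mm from the center, on a chord).
#'
#' @param true_preference_pct True preference for the manipulated target
#'   in \[0, 100\], default 50 (no preference).
#' @param n_trials Number of trials, default 40.
#' @param n_replicates Experimental replicates, trials assigned
#'   round-robin, default 2.
#' @param duration_s Recording length (s), default 1800 (30 min).
#' @param fps Frames per second, default 2.
#' @param arena_radius_mm Arena radius, default 27.5.
#' @param target_separation_mm Distance between targets, default 18.
#' @param wall_offset_mm Distance of each target from the wall, default
#'   8.5.
#' @param circle_radius_mm Scoring-circle radius, default 3.
#' @param dwell_fraction Expected fraction of time inside either circle,
#'   default 0.3.
#' @param mean_visit_s Mean visit length (s), default 5.
#' @param seed Integer seed.
#' @return A `trial_sim_config` list.
#' @export
trial_sim_config <- function(true_preference_pct = 50, n_trials = 40,
                             n_replicates = 2, duration_s = 1800, fps = 2,
                             arena_radius_mm = 27.5,
                             target_separation_mm = 18,
                             wall_offset_mm = 8.5,
                             circle_radius_mm = 3,
                             dwell_fraction = 0.3,
                             mean_visit_s = 5,
                             seed = 1L) {
  stopifnot(true_preference_pct >= 0, true_preference_pct <= 100,
            n_trials >= 1, n_replicates >= 1, duration_s > 0, fps > 0,
            dwell_fraction >= 0, dwell_fraction <= 1, mean_visit_s > 0)
  if (target_separation_mm <= 2 * circle_radius_mm) {
    stop("target separation must exceed twice the circle radius",
         call. = FALSE)
  }
  d_center <- arena_radius_mm - wall_offset_mm
  if (d_center + circle_radius_mm > arena_radius_mm) {
    stop("scoring circles overlap the arena boundary", call. = FALSE)
  }
  if (target_separation_mm > 2 * d_center) {
    stop("targets cannot be both ", target_separation_mm, " mm apart and ",
         wall_offset_mm, " mm from the wall in this arena", call. = FALSE)
  }
  structure(list(true_preference_pct = true_preference_pct,
                 n_trials = n_trials, n_replicates = n_replicates,
                 duration_s = duration_s, fps = fps,
                 arena_radius_mm = arena_radius_mm,
                 target_separation_mm = target_separation_mm,
                 wall_offset_mm = wall_offset_mm,
                 circle_radius_mm = circle_radius_mm,
                 dwell_fraction = dwell_fraction,
                 mean_visit_s = mean_visit_s,
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

# Bout sequence for one trial: alternating wander/visit runs of geometric
# length; each visit targets A (manipulated) with probability pref/100.
# Runs are drawn in batches for speed.  Returns a data.frame of runs
# (state, target, n = frames).
.sim_bouts <- function(n_frames, dwell_fraction, mean_visit_frames, pref) {
  if (dwell_fraction == 0) {
    return(data.frame(state = "wander", target = NA_character_,
                      n = n_frames))
  }
  p_exit <- 1 / mean_visit_frames
  if (dwell_fraction >= 1) {
    k <- ceiling(n_frames * p_exit) + 8L
    repeat {
      ns <- stats::rgeom(k, p_exit) + 1L
      if (sum(ns) >= n_frames) break
      k <- 2L * k
    }
    states <- rep(TRUE, length(ns))
  } else {
    p_enter <- min(dwell_fraction * p_exit / (1 - dwell_fraction), 1)
    visiting_first <- stats::runif(1) < dwell_fraction
    k <- ceiling(n_frames / (1 / p_enter + mean_visit_frames)) + 8L
    repeat {
      w <- stats::rgeom(k, p_enter) + 1L
      v <- stats::rgeom(k, p_exit) + 1L
      ns <- as.integer(rbind(w, v))          # w1 v1 w2 v2 ...
      states <- rep(c(FALSE, TRUE), k)       # FALSE = wander
      if (visiting_first) {
        ns <- c(stats::rgeom(1L, p_exit) + 1L, ns)
        states <- c(TRUE, states)
      }
      if (sum(ns) >= n_frames) break
      k <- 2L * k
    }
  }
  cum <- cumsum(ns)
  last <- which(cum >= n_frames)[1]
  ns <- ns[seq_len(last)]
  states <- states[seq_len(last)]
  ns[last] <- ns[last] - (cum[last] - n_frames)
  keep <- ns > 0L
  ns <- ns[keep]
  states <- states[keep]
  target <- rep(NA_character_, length(ns))
  target[states] <- ifelse(stats::runif(sum(states)) < pref / 100, "A", "B")
  data.frame(state = ifelse(states, "visit", "wander"),
             target = target, n = ns)
}

.target_positions <- function(cfg) {
  d_center <- cfg$arena_radius_mm - cfg$wall_offset_mm
  half <- cfg$target_separation_mm / 2
  x <- sqrt(d_center^2 - half^2)
  tibble::tibble(label = c("A", "B"),
                 x_mm = c(x, x),
                 y_mm = c(half, -half))
}

# Uniform points in the arena disc, rejected from both scoring circles.
.wander_points <- function(n, cfg, tpos) {
  out_x <- numeric(0); out_y <- numeric(0)
  r_arena <- cfg$arena_radius_mm
  while (length(out_x) < n) {
    m <- max(2L * (n - length(out_x)), 16L)
    r <- r_arena * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    x <- r * cos(th); y <- r * sin(th)
    ok <- rep(TRUE, m)
    for (i in 1:2) {
      ok <- ok & ((x - tpos$x_mm[i])^2 + (y - tpos$y_mm[i])^2 >
                    cfg$circle_radius_mm^2)
    }
    out_x <- c(out_x, x[ok]); out_y <- c(out_y, y[ok])
  }
  cbind(out_x[seq_len(n)], out_y[seq_len(n)])
}

#' Generate a synthetic set of two-choice trial trajectories
#'
#' Each trial is a full frame-indexed trajectory (`duration_s * fps`
#' frames): visiting frames are placed inside the chosen target's scoring
#' circle, wandering frames uniformly in the arena outside both circles.
#' The manipulated target's side of the arena is randomized per trial and
#' trials are assigned round-robin to replicates.
#'
#' @param cfg A [trial_sim_config()].
#' @return A list: `trials` (list of [trajectory()] objects) and `truth`
#'   (config plus per-trial replicate assignment).
#' @export
generate_trial_set <- function(cfg) {
  stopifnot(inherits(cfg, "trial_sim_config"))
  n_frames <- round(cfg$duration_s * cfg$fps)
  mean_visit_frames <- cfg$mean_visit_s * cfg$fps
  withr::with_seed(cfg$seed, {
    trials <- vector("list", cfg$n_trials)
    reps <- paste0("R", ((seq_len(cfg$n_trials) - 1) %% cfg$n_replicates) + 1)
    for (t in seq_len(cfg$n_trials)) {
      tpos <- .target_positions(cfg)
      if (stats::runif(1) < 0.5) tpos$y_mm <- -tpos$y_mm  # randomize side
      runs <- .sim_bouts(n_frames, cfg$dwell_fraction, mean_visit_frames,
                         cfg$true_preference_pct)
      state <- rep(runs$state, runs$n)
      target <- rep(runs$target, runs$n)
      x <- numeric(n_frames); y <- numeric(n_frames)
      wander_idx <- which(state == "wander")
      if (length(wander_idx)) {
        pts <- .wander_points(length(wander_idx), cfg, tpos)
        x[wander_idx] <- pts[, 1]; y[wander_idx] <- pts[, 2]
      }
      for (lab in c("A", "B")) {
        idx <- which(state == "visit" & target == lab)
        if (!length(idx)) next
        rr <- 0.8 * cfg$circle_radius_mm * sqrt(stats::runif(length(idx)))
        th <- stats::runif(length(idx), 0, 2 * pi)
        ctr <- tpos[tpos$label == lab, ]
        x[idx] <- ctr$x_mm + rr * cos(th)
        y[idx] <- ctr$y_mm + rr * sin(th)
      }
      targets <- tibble::tibble(label = tpos$label,
                                treatment = c("manipulated", "control"),
                                x_mm = tpos$x_mm, y_mm = tpos$y_mm)
      trials[[t]] <- trajectory(
        trial_id = sprintf("T%03d", t), replicate = reps[t], fps = cfg$fps,
        frames = tibble::tibble(time_s = (seq_len(n_frames) - 1) / cfg$fps,
                                x_mm = x, y_mm = y),
        targets = targets,
        arena = list(center = c(0, 0), radius_mm = cfg$arena_radius_mm),
        circle_radius_mm = cfg$circle_radius_mm)
    }
    list(trials = trials,
         truth = list(config = cfg, replicate = reps))
  })
}

#' Simulate two-choice trial scores at the bout level
#'
#' Runs the same two-state dwell process as [generate_trial_set()] but
#' records only the per-target frame counts, skipping per-frame positions.
#' The dwell-time marginals are identical; use this for large simulation
#' studies (null calibration, power) where the trajectory itself is not
#' needed.
#'
#' @param cfg A [trial_sim_config()].
#' @param min_total_s Kept rule passed to [score_trial()], default 50.
#' @return A TrialScore tibble with one row per trial.
#' @export
simulate_trial_scores <- function(cfg, min_total_s = 50) {
  stopifnot(inherits(cfg, "trial_sim_config"))
  n_frames <- round(cfg$duration_s * cfg$fps)
  mean_visit_frames <- cfg$mean_visit_s * cfg$fps
  withr::with_seed(cfg$seed, {
    reps <- paste0("R", ((seq_len(cfg$n_trials) - 1) %% cfg$n_replicates) + 1)
    rows <- lapply(seq_len(cfg$n_trials), function(t) {
      runs <- .sim_bouts(n_frames, cfg$dwell_fraction, mean_visit_frames,
                         cfg$true_preference_pct)
      tA <- sum(runs$n[runs$state == "visit" & runs$target == "A"],
                na.rm = TRUE) / cfg$fps
      tB <- sum(runs$n[runs$state == "visit" & runs$target == "B"],
                na.rm = TRUE) / cfg$fps
      score_trial(tA, tB, min_total_s,
                  trial_id = sprintf("T%03d", t), replicate = reps[t])
    })
    dplyr::bind_rows(rows)
  })
}

#' Configuration for the synthetic Ct table generator
#'
#' Ct values follow `Ct = baseline_ct - ln(expression) / ln 2 + noise`:
#' one extra ln-2 of expression costs one cycle.  The manipulated
#' condition expresses each gene at its `true_ln_fold_change`; the
#' reference gene is constitutive (fold change 0, enforced).  Noise is
#' applied independently to every technical reaction.
#'
#' @param genes Gene labels including the reference, default
#'   c("eloF", "rp49").
#' @param reference Reference gene label, default "rp49".
#' @param true_ln_fold_change Named ln fold changes for target genes;
#'   unnamed genes default to 0.  The reference must be 0.
#' @param n_biological_replicates Independent RNA extractions per
#'   condition, default 3.
#' @param n_technical_replicates RT-PCR reactions per extraction, default
#'   5.
#' @param ct_noise_sd Per-reaction Ct noise (cycles), default 0.15.
#' @param baseline_ct Named baseline Ct per gene; default 24 for targets,
#'   18 for the reference.
#' @param seed Integer seed.
#' @return A `ct_sim_config` list.
#' @export
ct_sim_config <- function(genes = c("eloF", "rp49"), reference = "rp49",
                          true_ln_fold_change = NULL,
                          n_biological_replicates = 3,
                          n_technical_replicates = 5,
                          ct_noise_sd = 0.15,
                          baseline_ct = NULL,
                          seed = 1L) {
  stopifnot(length(genes) >= 2, reference %in% genes,
            n_biological_replicates >= 1, n_technical_replicates >= 1,
            ct_noise_sd >= 0)
  lnfc <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(true_ln_fold_change)) {
    stopifnot(!is.null(names(true_ln_fold_change)),
              all(names(true_ln_fold_change) %in% genes))
    lnfc[names(true_ln_fold_change)] <- true_ln_fold_change
  }
  if (lnfc[[reference]] != 0) {
    stop("the reference gene must have true fold change 0", call. = FALSE)
  }
  if (is.null(baseline_ct)) {
    baseline_ct <- stats::setNames(rep(24, length(genes)), genes)
    baseline_ct[reference] <- 18
  }
  stopifnot(all(genes %in% names(baseline_ct)))
  structure(list(genes = genes, reference = reference,
                 true_ln_fold_change = lnfc,
                 n_biological_replicates = n_biological_replicates,
                 n_technical_replicates = n_technical_replicates,
                 ct_noise_sd = ct_noise_sd,
                 baseline_ct = baseline_ct,
                 seed = as.integer(seed)),
            class = "ct_sim_config")
}

#' Generate a synthetic Ct table with known ground truth
#'
#' @param cfg A [ct_sim_config()].
#' @return A list: `table` (a Ct tibble, see [ct_table()]) and `truth`
#'   (the config, with its true ln fold changes).
#' @export
generate_ct_table <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  withr::with_seed(cfg$seed, {
    grid <- expand.grid(
      tech_rep = paste0("T", seq_len(cfg$n_technical_replicates)),
      gene = cfg$genes,
      bio_rep = paste0("B", seq_len(cfg$n_biological_replicates)),
      condition = c("manipulated", "control"),
      stringsAsFactors = FALSE)
    ln_expr <- ifelse(grid$condition == "manipulated",
                      cfg$true_ln_fold_change[grid$gene], 0)
    grid$ct <- cfg$baseline_ct[grid$gene] - ln_expr / log(2) +
      stats::rnorm(nrow(grid), sd = cfg$ct_noise_sd)
    tbl <- ct_table(tibble::as_tibble(grid[, .ct_cols]),
                    reference = cfg$reference)
    list(table = tbl, truth = list(config = cfg))
  })
}
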