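test_that("identical configs and seeds give byte-identical CHC tables", {
  cfg <- chc_sim_config(n_compounds = 6, seed = 101)
  g1 <- generate_chc_table(cfg)
  g2 <- generate_chc_table(cfg)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  g3 <- generate_chc_table(chc_sim_config(n_compounds = 6, seed = 102))
  expect_false(identical(g1$table$intensity, g3$table$intensity))
})

test_that("noiseless single-cell CHC tables have equal replicate rows", {
  cfg <- chc_sim_config(n_compounds = 5, genotypes = "control",
                        ages_days = 6, replicates_per_cell = 4,
                        noise_sd_ln = 0, seed = 1)
  tab <- generate_chc_table(cfg)$table
  per_compound <- tapply(tab$intensity, tab$compound,
                         function(x) diff(range(x)))
  expect_true(all(per_compound == 0))
})

test_that("detection efficiencies are invisible after normalization", {
  cfg_flat <- chc_sim_config(n_compounds = 5, noise_sd_ln = 0,
                             detection_efficiency = rep(1, 5), seed = 31)
  cfg_skew <- chc_sim_config(n_compounds = 5, noise_sd_ln = 0,
                             detection_efficiency = c(5, 0.2, 1, 3, 0.5),
                             seed = 31)
  n_flat <- normalize_profile(generate_chc_table(cfg_flat)$table)
  n_skew <- normalize_profile(generate_chc_table(cfg_skew)$table)
  # same seed, same baselines: normalized profiles differ (efficiency is a
  # per-compound, not per-sample, factor) but per-sample scaling cancels --
  # multiplying all of a sample's raw intensities by c leaves profiles
  # unchanged, which is tested in test-chc-table; here: efficiencies do not
  # change *between-genotype contrasts* on the ln scale
  d_flat <- delta_profile(n_flat, "mutant", "control")
  d_skew <- delta_profile(n_skew, "mutant", "control")
  # with zero genotype effect both deltas are exactly zero
  expect_equal(d_flat$difference, rep(0, 5), tolerance = 1e-12)
  expect_equal(d_skew$difference, rep(0, 5), tolerance = 1e-12)
})

test_that("empty CHC designs are rejected at configuration", {
  expect_error(chc_sim_config(n_compounds = 0), "n_compounds")
  expect_error(chc_sim_config(genotypes = character(0)), "genotypes")
  expect_error(chc_sim_config(replicates_per_cell = 0), "replicates")
  expect_error(chc_sim_config(baseline_abundances = c(1, -1, 1),
                              n_compounds = 3), "baseline")
})

test_that("trial generation is seed-deterministic", {
  cfg <- trial_sim_config(n_trials = 3, duration_s = 60, seed = 41)
  t1 <- generate_trial_set(cfg)
  t2 <- generate_trial_set(cfg)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  s1 <- simulate_trial_scores(cfg)
  s2 <- simulate_trial_scores(cfg)
  expect_identical(s1, s2)
})

test_that("trajectory geometry honors the arena constraints", {
  cfg <- trial_sim_config(n_trials = 2, duration_s = 30, seed = 43)
  tr <- generate_trial_set(cfg)$trials[[1]]
  expect_identical(nrow(tr$frames), 60L)  # duration * fps
  sep <- sqrt(diff(tr$targets$x_mm)^2 + diff(tr$targets$y_mm)^2)
  expect_equal(sep, 18, tolerance = 1e-9)
  d_wall <- cfg$arena_radius_mm -
    sqrt(tr$targets$x_mm^2 + tr$targets$y_mm^2)
  expect_equal(d_wall, c(8.5, 8.5), tolerance = 1e-9)
  # all frames inside the arena
  r <- sqrt(tr$frames$x_mm^2 + tr$frames$y_mm^2)
  expect_true(all(r <= cfg$arena_radius_mm + 1e-9))
  expect_error(trial_sim_config(circle_radius_mm = 10), "overlap|separation")
  expect_error(trial_sim_config(target_separation_mm = 40), "apart")
})

test_that("complete bias sends every visit to the manipulated target", {
  cfg <- trial_sim_config(true_preference_pct = 100, n_trials = 6,
                          duration_s = 300, dwell_fraction = 0.4, seed = 47)
  scores <- dplyr::bind_rows(lapply(generate_trial_set(cfg)$trials,
                                    score_trajectory))
  kept <- scores[scores$kept, ]
  expect_gt(nrow(kept), 0)
  expect_true(all(kept$preference_pct == 100))
})

test_that("trajectory scoring and bout-level scoring agree in distribution", {
  cfg_a <- trial_sim_config(true_preference_pct = 65, n_trials = 30,
                            duration_s = 600, seed = 53)
  traj_scores <- dplyr::bind_rows(lapply(generate_trial_set(cfg_a)$trials,
                                         score_trajectory))
  bout_scores <- simulate_trial_scores(
    trial_sim_config(true_preference_pct = 65, n_trials = 30,
                     duration_s = 600, seed = 54))
  m1 <- mean(traj_scores$preference_pct[traj_scores$kept])
  m2 <- mean(bout_scores$preference_pct[bout_scores$kept])
  expect_lt(abs(m1 - m2), 10)  # same model, independent seeds
  expect_lt(abs(m1 - 65), 10)
})

test_that("trials are assigned round-robin to replicates", {
  sc <- simulate_trial_scores(trial_sim_config(n_trials = 7,
                                               n_replicates = 3,
                                               duration_s = 30, seed = 55))
  expect_identical(sc$replicate,
                   paste0("R", c(1, 2, 3, 1, 2, 3, 1)))
})

test_that("unbiased trials score near 50 on average", {
  sc <- simulate_trial_scores(trial_sim_config(true_preference_pct = 50,
                                               n_trials = 60, seed = 57))
  kept <- sc[sc$kept, ]
  se <- stats::sd(kept$preference_pct) / sqrt(nrow(kept))
  expect_lt(abs(mean(kept$preference_pct) - 50), 4 * se + 1)
})

test_that("Ct generation is seed-deterministic and validated", {
  cfg <- ct_sim_config(seed = 61)
  expect_identical(serialize(generate_ct_table(cfg), NULL),
                   serialize(generate_ct_table(cfg), NULL))
  expect_error(ct_sim_config(genes = c("eloF", "rp49"),
                             true_ln_fold_change = c(rp49 = 1)),
               "reference")
  expect_error(ct_sim_config(genes = "eloF", reference = "rp49"))
})

test_that("noiseless Ct tables give exactly zero ddCt downstream", {
  cfg <- ct_sim_config(ct_noise_sd = 0, seed = 63)
  tab <- generate_ct_table(cfg)$table
  fc <- delta_delta_ct(tab, "eloF")
  expect_equal(fc$delta_delta_ct, rep(0, 3))
  expect_equal(fc$ln_fold_change, rep(0, 3))
})

test_that("an injected ln fold change of ln 4 is recovered", {
  cfg <- ct_sim_config(true_ln_fold_change = c(eloF = log(4)), seed = 65)
  tab <- generate_ct_table(cfg)$table
  res <- qpcr_fold_changes(tab)
  expect_lt(abs(res$ln_fold_change - log(4)), 4 * res$se + 0.05)
  expect_lt(res$p_two_sided, 0.001)
})
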