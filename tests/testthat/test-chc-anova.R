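make_ln_table <- function(values_df) {
  # values_df: genotype, age_days, replicate, compound, intensity (ln scale)
  tbl <- values_df
  tbl$sample_id <- paste(tbl$genotype, tbl$age_days, tbl$replicate, sep = "_")
  tbl$platform <- "GCMS"
  chc_table(tbl[, c("sample_id", "genotype", "age_days", "replicate",
                    "platform", "compound", "intensity")],
            state = "ln_normalized")
}

test_that("balanced 2x2 ANOVA matches the textbook sums-of-squares oracle", {
  set.seed(42)
  grid <- expand.grid(genotype = c("control", "mutant"),
                      age_days = c(6, 23),
                      replicate = paste0("R", 1:4),
                      stringsAsFactors = FALSE)
  grid$compound <- "nC23"
  grid$intensity <- -3 + 0.5 * (grid$genotype == "mutant") +
    0.2 * (grid$age_days == 23) + rnorm(nrow(grid), sd = 0.3)
  res <- per_compound_anova(make_ln_table(grid), holm = FALSE)
  oracle <- oracle_two_way_anova(data.frame(y = grid$intensity,
                                            a = grid$genotype,
                                            b = grid$age_days))
  expect_equal(res$F_genotype, unname(oracle$F["a"]), tolerance = 1e-8)
  expect_equal(res$F_age, unname(oracle$F["b"]), tolerance = 1e-8)
  expect_equal(res$F_interaction, unname(oracle$F["ab"]), tolerance = 1e-8)
  expect_equal(res$p_genotype, oracle$p[1], tolerance = 1e-8)
  expect_equal(res$p_age, oracle$p[2], tolerance = 1e-8)
  expect_equal(res$p_interaction, oracle$p[3], tolerance = 1e-8)
})

test_that("equal genotype cell means give F_genotype = 0, p = 1", {
  grid <- expand.grid(genotype = c("control", "mutant"),
                      age_days = c(6, 23),
                      replicate = paste0("R", 1:3),
                      stringsAsFactors = FALSE)
  grid$compound <- "nC23"
  # residuals depend only on replicate: cell means equal across genotypes
  grid$intensity <- -3 + 0.4 * (grid$age_days == 23) +
    c(R1 = -0.1, R2 = 0, R3 = 0.1)[grid$replicate]
  res <- per_compound_anova(make_ln_table(grid), holm = FALSE)
  expect_equal(res$F_genotype, 0, tolerance = 1e-12)
  expect_equal(res$p_genotype, 1, tolerance = 1e-12)
})

test_that("a compound without replication is flagged and skipped", {
  grid <- expand.grid(genotype = c("control", "mutant"),
                      age_days = c(6, 23),
                      replicate = "R1", stringsAsFactors = FALSE)
  one_rep <- grid
  one_rep$compound <- "nC23"
  one_rep$intensity <- rnorm(nrow(one_rep))
  full <- expand.grid(genotype = c("control", "mutant"),
                      age_days = c(6, 23),
                      replicate = c("R1", "R2"), stringsAsFactors = FALSE)
  full$compound <- "nC25"
  full$intensity <- rnorm(nrow(full))
  # nC23 has one observation per cell -> zero residual df
  both <- rbind(one_rep, full)
  expect_message(res <- per_compound_anova(make_ln_table(both)), "nC23")
  expect_true(is.na(res$p_genotype[res$compound == "nC23"]))
  expect_false(res$holm_significant[res$compound == "nC23"])
  expect_false(is.na(res$p_genotype[res$compound == "nC25"]))
})

test_that("the explicit exclusion list removes flagged observations", {
  set.seed(7)
  grid <- expand.grid(genotype = c("control", "mutant"),
                      age_days = c(6, 23),
                      replicate = paste0("R", 1:4),
                      stringsAsFactors = FALSE)
  grid$compound <- "nC23"
  grid$intensity <- rnorm(nrow(grid))
  tbl <- make_ln_table(grid)
  excl <- tibble::tibble(compound = "nC23",
                         sample_id = tbl$sample_id[1])
  res_all <- per_compound_anova(tbl, holm = FALSE)
  res_excl <- per_compound_anova(tbl, holm = FALSE, exclude = excl)
  expect_false(isTRUE(all.equal(res_all$F_genotype, res_excl$F_genotype)))
})

test_that("Holm step-down matches hand enumeration and p.adjust", {
  # 0.001 passes 0.05/4; 0.02 fails 0.05/3 -> exactly one significant
  h <- holm_correction(c(0.001, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_identical(h$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(h$threshold, 0.05 / c(4, 3, 2, 1))

  expect_true(holm_correction(0.04, 0.05)$significant)
  expect_false(any(holm_correction(rep(1, 5), 0.05)$significant))
  expect_equal(nrow(holm_correction(numeric(0), 0.05)), 0L)

  # cross-check against stats::p.adjust on random vectors
  set.seed(1)
  for (i in 1:25) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(holm_correction(p, alpha)$significant,
                     unname(stats::p.adjust(p, "holm") <= alpha))
  }
})

test_that("Holm count sits between Bonferroni and unadjusted counts", {
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(4:40, 1))^2
    alpha <- 0.05
    holm_n <- sum(holm_correction(p, alpha)$significant)
    bonf_n <- sum(p <= alpha / length(p))
    raw_n <- sum(p <= alpha)
    expect_gte(holm_n, bonf_n)
    expect_lte(holm_n, raw_n)
    # every Holm-significant p is unadjusted-significant
    expect_true(all(p[holm_correction(p, alpha)$significant] <= alpha))
  }
})

test_that("chance expectation is n * alpha", {
  expect_equal(expected_chance_significant(26, 0.05), 1.3)
  expect_equal(expected_chance_significant(0, 0.05), 0)
  expect_equal(expected_chance_significant(12, 0.05), 0.6)
})
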