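make_norm_table <- function(df) {
  df$sample_id <- paste(df$genotype, df$age_days, df$replicate, sep = "_")
  df$platform <- "GCMS"
  chc_table(df[, c("sample_id", "genotype", "age_days", "replicate",
                   "platform", "compound", "intensity")],
            state = "normalized")
}

two_group_table <- function(ctrl_means, manip_means, compounds) {
  rows <- expand.grid(genotype = c("control", "mutant"), age_days = 6,
                      replicate = c("R1", "R2"), compound = compounds,
                      stringsAsFactors = FALSE)
  mm <- ifelse(rows$genotype == "control",
               ctrl_means[rows$compound], manip_means[rows$compound])
  rows$intensity <- mm
  make_norm_table(rows)
}

test_that("delta profile is zero when manipulation equals control", {
  cmp <- c("nC23", "nC25", "nC27")
  m <- stats::setNames(c(0.2, 0.3, 0.5), cmp)
  d <- delta_profile(two_group_table(m, m, cmp), "mutant", "control",
                     mode = "single_age")
  expect_equal(d$difference, rep(0, 3))
  expect_equal(d$percent_change, rep(0, 3))
})

test_that("difference and percent change follow their definitions", {
  cmp <- c("nC23", "nC25", "nC27")
  ctrl <- stats::setNames(c(0.2, 0.3, 0.5), cmp)
  manip <- stats::setNames(c(0.1, 0.4, 0.5), cmp)
  d <- delta_profile(two_group_table(ctrl, manip, cmp), "mutant", "control",
                     mode = "single_age")
  i <- match("nC23", d$compound)
  expect_equal(d$difference[i], -0.1)
  expect_equal(d$percent_change[i], -50)
})

test_that("zero control mean flags percent change undefined", {
  cmp <- c("nC23", "nC25")
  ctrl <- stats::setNames(c(0, 1), cmp)
  manip <- stats::setNames(c(0.5, 0.5), cmp)
  d <- delta_profile(two_group_table(ctrl, manip, cmp), "mutant", "control",
                     mode = "single_age")
  i <- match("nC23", d$compound)
  expect_false(d$percent_defined[i])
  expect_true(is.na(d$percent_change[i]))
  expect_equal(d$difference[i], 0.5)
})

test_that("main-effect mode weights ages equally and demands shared ages", {
  rows <- expand.grid(genotype = c("control", "mutant"),
                      age_days = c(6, 23), replicate = c("R1", "R2"),
                      compound = "nC23", stringsAsFactors = FALSE)
  # unbalanced replication within age 23 for the mutant
  rows$intensity <- 0.5
  rows$intensity[rows$genotype == "mutant" & rows$age_days == 6] <- 0.7
  rows$intensity[rows$genotype == "mutant" & rows$age_days == 23] <- 0.9
  tbl <- make_norm_table(rows)
  d <- delta_profile(tbl, "mutant", "control")
  # equal per-age weights: mean(0.7, 0.9) - 0.5
  expect_equal(d$difference, 0.3)

  missing_age <- make_norm_table(
    rows[!(rows$genotype == "mutant" & rows$age_days == 23), ])
  expect_error(delta_profile(missing_age, "mutant", "control"), "same ages")
})

test_that("chain-length regression recovers an exact linear fit", {
  cmp <- c("nC23", "nC25", "nC27", "nC29")
  d <- tibble::tibble(compound = cmp,
                      mean_control = 0.25, mean_manipulation = 0.25,
                      difference = 0,
                      percent_defined = TRUE,
                      percent_change = c(-10, 0, 10, 20))
  class(d) <- c("delta_profile", class(d))
  # exact collinear points: lm warns about a perfect fit, which is the point
  fit <- suppressWarnings(chain_length_regression(d, compound_descriptors(cmp)))
  expect_equal(fit$slope, 5, tolerance = 1e-10)
  expect_lt(fit$p, 1e-6)

  d$percent_change <- rep(0, 4)
  fit0 <- suppressWarnings(chain_length_regression(d, compound_descriptors(cmp)))
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_equal(fit0$intercept, 0, tolerance = 1e-12)

  d$percent_change <- c(10, 0, -10, -20)
  fitneg <- suppressWarnings(chain_length_regression(d, compound_descriptors(cmp)))
  expect_equal(fitneg$slope, -5, tolerance = 1e-10)
  expect_equal(fitneg$p, fit$p, tolerance = 1e-10)
})

test_that("chain-length regression rejects degenerate designs", {
  cmp <- c("nC23", "C23:1", "C23:2")
  d <- tibble::tibble(compound = cmp, mean_control = 0.3,
                      mean_manipulation = 0.3, difference = 0,
                      percent_defined = TRUE, percent_change = c(1, 2, 3))
  class(d) <- c("delta_profile", class(d))
  expect_error(chain_length_regression(d, compound_descriptors(cmp)),
               "degenerate")
})

test_that("delta correlation matches the product-moment oracle", {
  cmp <- paste0("nC", c(21, 23, 25, 27, 29))
  a <- c(-0.04, -0.01, 0.00, 0.02, 0.03)
  b <- c(-0.03, -0.02, 0.01, 0.01, 0.03)
  da <- tibble::tibble(compound = cmp, difference = a)
  db <- tibble::tibble(compound = cmp, difference = b)
  class(da) <- c("delta_profile", class(da))
  class(db) <- c("delta_profile", class(db))
  res <- delta_correlation(da, db)
  expect_equal(res$r, oracle_pearson(a, b), tolerance = 1e-12)

  expect_equal(suppressWarnings(delta_correlation(da, da))$r, 1,
               tolerance = 1e-12)
  dneg <- da; dneg$difference <- -a
  expect_equal(suppressWarnings(delta_correlation(da, dneg))$r, -1,
               tolerance = 1e-12)

  short <- da[1:2, ]
  expect_error(delta_correlation(short, db), "shared")
})
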