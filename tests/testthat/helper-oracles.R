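# Independent oracles used by the tests.  These re-derive expected values
# from first principles (textbook sums of squares, exhaustive enumeration,
# product-moment formulas) and never call the implementation under test.

# Balanced two-way ANOVA with interaction, computed from explicit sums of
# squares (equal cell sizes assumed).  df: columns y, a, b.
oracle_two_way_anova <- function(df) {
  a <- factor(df$a); b <- factor(df$b); y <- df$y
  I <- nlevels(a); J <- nlevels(b); n <- nrow(df) / (I * J)
  stopifnot(n == round(n), n >= 2)
  grand <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ss_a <- n * J * sum((ma - grand)^2)
  ss_b <- n * I * sum((mb - grand)^2)
  ss_cells <- n * sum((mab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((y - mab[cbind(a, b)])^2)
  df_a <- I - 1; df_b <- J - 1; df_ab <- df_a * df_b
  df_err <- I * J * (n - 1)
  ms_err <- ss_err / df_err
  f <- c(a = (ss_a / df_a) / ms_err,
         b = (ss_b / df_b) / ms_err,
         ab = (ss_ab / df_ab) / ms_err)
  p <- c(a = stats::pf(f["a"], df_a, df_err, lower.tail = FALSE),
         b = stats::pf(f["b"], df_b, df_err, lower.tail = FALSE),
         ab = stats::pf(f["ab"], df_ab, df_err, lower.tail = FALSE))
  list(F = f, p = unname(p))
}

# Exhaustive per-trial label-flip null: all 2^n flip patterns, raw tail
# proportions (no add-one smoothing).
oracle_flip_null <- function(prefs, stat_fun = mean) {
  n <- length(prefs)
  stopifnot(n <= 14)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  apply(patterns, 1, function(fl) {
    p <- prefs
    p[unlist(fl)] <- 100 - p[unlist(fl)]
    stat_fun(p)
  })
}

oracle_flip_p_upper <- function(prefs, stat_fun = mean) {
  null <- oracle_flip_null(prefs, stat_fun)
  mean(null >= stat_fun(prefs))
}

# Pearson r straight from the product-moment formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Small hand-built raw CHC table.
toy_chc_table <- function(intensities, compounds = names(intensities),
                          sample_id = "S1", genotype = "control",
                          age_days = 6, replicate = "R1") {
  chc_table(tibble::tibble(
    sample_id = sample_id, genotype = genotype, age_days = age_days,
    replicate = replicate, platform = "GCMS",
    compound = compounds, intensity = unname(intensities)))
}

# A straight-line trajectory visiting fixed points; targets on the x axis.
toy_trajectory <- function(xy, fps = 2, targets_x = c(-9, 9)) {
  n <- nrow(xy)
  trajectory(
    trial_id = "T1", replicate = "R1", fps = fps,
    frames = tibble::tibble(time_s = (seq_len(n) - 1) / fps,
                            x_mm = xy[, 1], y_mm = xy[, 2]),
    targets = tibble::tibble(label = c("A", "B"),
                             treatment = c("manipulated", "control"),
                             x_mm = targets_x, y_mm = c(0, 0)))
}
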