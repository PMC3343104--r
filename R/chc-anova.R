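# Per-compound two-factor ANOVA with Holm-Bonferroni multiplicity control.

#' Per-compound two-factor ANOVA (genotype x age)
#'
#' For each compound, fits `ln intensity ~ genotype * age` with both
#' factors categorical and reports F and p for the genotype main effect,
#' the age main effect and the interaction.  Sums of squares are Type II
#' (via [car::Anova()]); for balanced designs all conventions coincide.
#'
#' Compounds with zero residual degrees of freedom (no replication) are
#' flagged: their p-values are `NA` and they are excluded from the Holm
#' correction.
#'
#' @param table A `chc_table` in `"ln_normalized"` state (the scale on
#'   which residuals are approximately normal).  A `"normalized"` table is
#'   accepted with a warning.
#' @param alpha Family-wise error rate for the Holm step-down, default 0.05.
#' @param holm Apply the Holm-Bonferroni correction to the genotype
#'   p-values and fill `holm_significant`? Default `TRUE`.
#' @param exclude Optional data frame of `(compound, sample_id)` pairs to
#'   drop before fitting -- an explicit outlier-removal list, so that any
#'   "remove and reanalyse" step is visible in code rather than silent.
#' @return A tibble with one row per compound, in input compound order:
#'   `compound`, `F_genotype`, `p_genotype`, `F_age`, `p_age`,
#'   `F_interaction`, `p_interaction`, `holm_significant`.
#' @export
per_compound_anova <- function(table, alpha = 0.05, holm = TRUE,
                               exclude = NULL) {
  stopifnot(inherits(table, "chc_table"))
  if (chc_state(table) == "raw") {
    stop("per-compound ANOVA requires a normalized (preferably ",
         "ln-transformed) table", call. = FALSE)
  }
  if (chc_state(table) == "normalized") {
    warning("running ANOVA on the linear (not ln) scale")
  }
  df <- tibble::as_tibble(table)
  if (!is.null(exclude)) {
    stopifnot(all(c("compound", "sample_id") %in% names(exclude)))
    key <- paste(df$compound, df$sample_id)
    df <- df[!key %in% paste(exclude$compound, exclude$sample_id), ]
  }
  if (length(unique(df$genotype)) < 2L || length(unique(df$age_days)) < 2L) {
    stop("need at least two genotype levels and two age levels",
         call. = FALSE)
  }
  compounds <- unique(table$compound)
  one <- function(cmp) {
    d <- df[df$compound == cmp, ]
    d$genotype <- factor(d$genotype)
    d$age_f <- factor(d$age_days)
    n_cells <- nrow(unique(d[, c("genotype", "age_f")]))
    res <- tibble::tibble(compound = cmp,
                          F_genotype = NA_real_, p_genotype = NA_real_,
                          F_age = NA_real_, p_age = NA_real_,
                          F_interaction = NA_real_, p_interaction = NA_real_)
    if (nrow(d) - n_cells <= 0L) {
      message("compound ", cmp, ": zero residual df, ANOVA skipped")
      return(res)
    }
    fit <- stats::lm(intensity ~ genotype * age_f, data = d)
    aov2 <- car::Anova(fit, type = 2)
    pick <- function(term, col) aov2[term, col]
    res$F_genotype <- pick("genotype", "F value")
    res$p_genotype <- pick("genotype", "Pr(>F)")
    res$F_age <- pick("age_f", "F value")
    res$p_age <- pick("age_f", "Pr(>F)")
    res$F_interaction <- pick("genotype:age_f", "F value")
    res$p_interaction <- pick("genotype:age_f", "Pr(>F)")
    res
  }
  out <- dplyr::bind_rows(lapply(compounds, one))
  out$holm_significant <- if (holm) {
    holm_correction(out$p_genotype, alpha)$significant
  } else {
    NA
  }
  out
}

#' Holm-Bonferroni step-down correction
#'
#' Orders the m non-missing p-values ascending and compares the k-th
#' smallest against `alpha / (m - k + 1)`, stopping at the first failure;
#' everything from the first failure on is non-significant.  Controls the
#' family-wise error rate at `alpha` while being uniformly more powerful
#' than the plain Bonferroni correction.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]; `NA`s are carried
#'   through as non-significant and do not count toward m.
#' @param alpha Family-wise error rate in (0, 1).
#' @return A tibble in input order: `p`, `rank` (ascending rank among
#'   non-missing p-values), `threshold` (the per-rank Holm threshold
#'   `alpha / (m - rank + 1)`) and `significant`.
#' @export
#' @examples
#' holm_correction(c(0.001, 0.02, 0.03, 0.04), alpha = 0.05)
holm_correction <- function(p_values, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (length(p_values) == 0L) {
    return(tibble::tibble(p = numeric(), rank = integer(),
                          threshold = numeric(), significant = logical()))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  ok <- !is.na(p_values)
  m <- sum(ok)
  rank_ok <- rank(p_values[ok], ties.method = "first")
  thr_ok <- alpha / (m - rank_ok + 1)
  ord <- order(rank_ok)
  pass_sorted <- cumprod(p_values[ok][ord] <= thr_ok[ord]) == 1
  sig_ok <- logical(m)
  sig_ok[ord] <- pass_sorted
  out <- tibble::tibble(p = p_values,
                        rank = NA_integer_,
                        threshold = NA_real_,
                        significant = FALSE)
  out$rank[ok] <- rank_ok
  out$threshold[ok] <- thr_ok
  out$significant[ok] <- sig_ok
  out
}

#' Expected number of significant tests under the null
#'
#' With `n_tests` independent true-null hypotheses each tested at level
#' `alpha`, the expected number of (false) rejections is `n_tests * alpha`
#' -- e.g. 1.3 for a 26-compound GC/MS panel at alpha = 0.05.  Used to set
#' the observed count of per-compound differences against its chance
#' expectation.
#'
#' @param n_tests Number of tests (>= 0).
#' @param alpha Per-test significance level.
#' @return `n_tests * alpha`.
#' @export
#' @examples
#' expected_chance_significant(26, 0.05)
expected_chance_significant <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 0, alpha >= 0, alpha <= 1)
  n_tests * alpha
}
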