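# Delta profiles: per-compound effect of a genetic manipulation vs its
# control, and regressions of those effects on chain length or on the
# effects of another manipulation.

#' Per-compound effect of a manipulation relative to its control
#'
#' For every compound, computes the difference of mean normalized intensity
#' (manipulation - control) and the corresponding percent change
#' (100 x difference / control mean).  In `"main_effect_across_ages"` mode
#' the group mean is the unweighted average of per-age group means --
#' matching an ANOVA main effect under equal cell weighting -- and both
#' groups must have been measured at the same ages.  In `"single_age"` mode
#' plain group means are used (the typical design for manipulations
#' measured at one age).
#'
#' @param table A `chc_table` in `"normalized"` state.
#' @param manipulation,control Genotype labels to compare.
#' @param mode `"main_effect_across_ages"` or `"single_age"`.
#' @return A `delta_profile` tibble with one row per compound:
#'   `compound`, `mean_control`, `mean_manipulation`, `difference`,
#'   `percent_change` and `percent_defined` (FALSE where the control mean
#'   is zero, in which case `percent_change` is `NA`).
#' @export
delta_profile <- function(table, manipulation, control,
                          mode = c("main_effect_across_ages", "single_age")) {
  stopifnot(inherits(table, "chc_table"))
  if (chc_state(table) != "normalized") {
    stop("delta_profile() works on normalized intensities; got state '",
         chc_state(table), "'", call. = FALSE)
  }
  mode <- match.arg(mode)
  df <- tibble::as_tibble(table)
  df <- df[df$genotype %in% c(manipulation, control), ]
  for (g in c(manipulation, control)) {
    if (!any(df$genotype == g)) stop("genotype '", g, "' not in table",
                                     call. = FALSE)
  }
  if (mode == "main_effect_across_ages") {
    ages_m <- sort(unique(df$age_days[df$genotype == manipulation]))
    ages_c <- sort(unique(df$age_days[df$genotype == control]))
    if (!identical(ages_m, ages_c)) {
      stop("main_effect_across_ages requires both genotypes measured at ",
           "the same ages", call. = FALSE)
    }
    means <- df |>
      dplyr::group_by(.data$genotype, .data$age_days, .data$compound) |>
      dplyr::summarise(m = mean(.data$intensity), .groups = "drop") |>
      dplyr::group_by(.data$genotype, .data$compound) |>
      dplyr::summarise(m = mean(.data$m), .groups = "drop")
  } else {
    means <- df |>
      dplyr::group_by(.data$genotype, .data$compound) |>
      dplyr::summarise(m = mean(.data$intensity), .groups = "drop")
  }
  wide <- tidyr::pivot_wider(means, names_from = "genotype",
                             values_from = "m")
  out <- tibble::tibble(
    compound = wide$compound,
    mean_control = wide[[control]],
    mean_manipulation = wide[[manipulation]],
    difference = wide[[manipulation]] - wide[[control]]
  )
  out$percent_defined <- out$mean_control != 0
  out$percent_change <- ifelse(out$percent_defined,
                               100 * out$difference / out$mean_control,
                               NA_real_)
  # preserve the table's compound order
  out <- out[match(intersect(unique(table$compound), out$compound),
                   out$compound), ]
  class(out) <- c("delta_profile", class(out))
  attr(out, "manipulation") <- manipulation
  attr(out, "control") <- control
  attr(out, "mode") <- mode
  out
}

#' Regression of per-compound percent change on carbon-chain length
#'
#' Tests whether a manipulation shifts the profile toward longer- or
#' shorter-chained compounds: ordinary least squares of percent change of
#' normalized intensity on carbon count, with the two-sided p-value for a
#' nonzero slope.
#'
#' @param delta A `delta_profile` (see [delta_profile()]).
#' @param descriptors Compound-descriptor tibble supplying `carbon_count`
#'   per compound ([compound_descriptors()]).
#' @return A list with `slope` (percent change per carbon), `intercept`,
#'   `p` (two-sided, slope), `r_squared` and `n` compounds used.
#' @export
chain_length_regression <- function(delta, descriptors) {
  stopifnot(inherits(delta, "delta_profile"))
  d <- dplyr::inner_join(tibble::as_tibble(delta),
                         descriptors[, c("name", "carbon_count")],
                         by = c(compound = "name"))
  d <- d[d$percent_defined & !is.na(d$carbon_count), ]
  if (nrow(d) < 3L) {
    stop("need >= 3 compounds with defined percent change and carbon count",
         call. = FALSE)
  }
  if (length(unique(d$carbon_count)) < 2L) {
    stop("all carbon counts identical: degenerate design", call. = FALSE)
  }
  fit <- stats::lm(percent_change ~ carbon_count, data = d)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = unname(sm$coefficients["carbon_count", "Pr(>|t|)"]),
       r_squared = sm$r.squared,
       n = nrow(d))
}

#' Correlation between the delta profiles of two manipulations
#'
#' Quantifies whether two manipulations move the CHC profile in the same
#' direction: Pearson correlation and least-squares regression of B's
#' per-compound differences on A's, over compounds shared by both
#' profiles.
#'
#' @param delta_a,delta_b `delta_profile` objects.
#' @return A list with `r` (Pearson), `slope`, `intercept`, `p` (two-sided,
#'   slope) and `n` shared compounds.
#' @export
delta_correlation <- function(delta_a, delta_b) {
  stopifnot(inherits(delta_a, "delta_profile"),
            inherits(delta_b, "delta_profile"))
  shared <- intersect(delta_a$compound, delta_b$compound)
  if (length(shared) < 3L) {
    stop("need >= 3 shared compounds", call. = FALSE)
  }
  a <- delta_a$difference[match(shared, delta_a$compound)]
  b <- delta_b$difference[match(shared, delta_b$compound)]
  fit <- stats::lm(b ~ a)
  sm <- summary(fit)
  list(r = stats::cor(a, b),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = unname(sm$coefficients["a", "Pr(>|t|)"]),
       n = length(shared))
}
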