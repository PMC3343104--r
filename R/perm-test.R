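# Tests of two-choice preference against the 50% null: one-sample Wilcoxon
# signed-rank, and a replicate-stratified permutation procedure.

#' Wilcoxon signed-rank test of preference against the no-preference null
#'
#' One-sample signed-rank test of the kept trials' preference percentages
#' against `null_value` (50% = no preference).  Differences of exactly zero
#' are dropped before ranking, as usual for the signed-rank statistic.  The
#' exact null distribution is used for n <= 25 when there are no ties among
#' the absolute differences; otherwise the normal approximation with
#' continuity correction.
#'
#' @param preferences Numeric vector of preference percentages (kept
#'   trials); `NA`s are dropped.
#' @param null_value Null preference, default 50.
#' @return A list: `W` (signed-rank statistic), `p_two_sided`, `n_used`
#'   (after zero-dropping), `n_zero_dropped`, `method` (`"exact"` or
#'   `"normal_approx"`), `degenerate` (TRUE when every difference is zero,
#'   in which case p = 1).
#' @export
#' @examples
#' wilcoxon_vs_null(c(60, 70, 55, 65, 80, 75))  # exact p = 2/2^6
wilcoxon_vs_null <- function(preferences, null_value = 50) {
  x <- preferences[!is.na(preferences)]
  if (length(x) < 1L) stop("need >= 1 kept trial", call. = FALSE)
  d <- x - null_value
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(list(W = 0, p_two_sided = 1, n_used = 0L,
                n_zero_dropped = n_zero, method = "degenerate",
                degenerate = TRUE))
  }
  ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- length(d) <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(W = unname(wt$statistic),
       p_two_sided = wt$p.value,
       n_used = length(d),
       n_zero_dropped = n_zero,
       method = if (use_exact) "exact" else "normal_approx",
       degenerate = FALSE)
}

.perm_statistic <- function(statistic) {
  switch(statistic, mean = mean, median = stats::median,
         stop("unknown statistic '", statistic, "'", call. = FALSE))
}

#' Replicate-stratified permutation test of pooled preference
#'
#' Trials from several experimental replicates are pooled and the group
#' attractiveness statistic (mean preference over kept trials by default)
#' is tested against the no-preference null by randomizing treatment
#' labels and rebuilding the statistic.  Because each randomization only
#' relabels flies within a trial -- and every trial belongs to one
#' replicate -- the randomization is automatically confined within
#' replicates, respecting the stratified design.
#'
#' Two schemes are available:
#' \describe{
#'   \item{`"trial_flip"` (default)}{each trial's two treatment labels are
#'     independently swapped with probability 1/2, mapping its preference
#'     p to 100 - p.  This preserves the paired two-choice structure.}
#'   \item{`"pooled_within_replicate"`}{within each replicate the dwell
#'     times of all target flies are pooled, relabeled at random
#'     (half manipulated, half control) and re-paired into trials, whose
#'     preferences are then recomputed; the kept rule (`min_total_s`) is
#'     re-applied.  A looser reading of label randomization "among flies
#'     within a replicate" that breaks the pairing.}
#' }
#'
#' All `n_randomizations` statistic values are pooled into one null
#' distribution.  Tail probabilities use the add-one rule
#' `(1 + #extreme) / (n + 1)` with ties to the observed value counted as
#' extreme, which guarantees a valid p in (0, 1]; the two-sided p is
#' `min(1, 2 * min(tails))`.
#'
#' @param trials A TrialScore tibble (see [score_trial()],
#'   [pool_replicates()]); only rows with `kept == TRUE` enter the
#'   statistic.
#' @param n_randomizations Number of randomizations, default 30000.
#' @param statistic `"mean"` (default) or `"median"` preference over kept
#'   trials.
#' @param scheme `"trial_flip"` or `"pooled_within_replicate"`.
#' @param sided `"two_sided"` (default), `"greater"` (preference above
#'   50) or `"less"`.
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @param min_total_s Kept rule re-applied under the pooled scheme.
#' @param keep_null Retain the full null sample (for audit) instead of a
#'   summary? Default `FALSE`.
#' @return A `permutation_result` list: `observed_statistic`,
#'   `n_randomizations`, `p_one_sided`, `p_two_sided`, `sidedness`,
#'   `scheme`, `statistic`, `seed`, `n_trials`, `degenerate`, and
#'   `null_sample` (full vector if `keep_null`, else a five-number
#'   summary).
#' @export
stratified_permutation_test <- function(trials, n_randomizations = 30000,
                                        statistic = c("mean", "median"),
                                        scheme = c("trial_flip",
                                                   "pooled_within_replicate"),
                                        sided = c("two_sided", "greater",
                                                  "less"),
                                        seed = 1L, min_total_s = 50,
                                        keep_null = FALSE) {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  sided <- match.arg(sided)
  if (n_randomizations < 1) stop("n_randomizations must be >= 1",
                                 call. = FALSE)
  kept <- trials[trials$kept, , drop = FALSE]
  if (nrow(kept) < 1L) stop("need >= 1 kept trial", call. = FALSE)
  if (any(is.na(kept$replicate))) {
    stop("replicate labels must be present for the stratified scheme",
         call. = FALSE)
  }
  stat_fun <- .perm_statistic(statistic)
  prefs <- kept$preference_pct
  observed <- stat_fun(prefs)
  degenerate <- all(prefs == 50)

  null_stats <- withr::with_seed(seed, {
    if (scheme == "trial_flip") {
      n <- nrow(kept)
      flips <- matrix(stats::runif(n_randomizations * n) < 0.5,
                      nrow = n_randomizations)
      pm <- matrix(prefs, nrow = n_randomizations, ncol = n, byrow = TRUE)
      pm[flips] <- 100 - pm[flips]
      if (statistic == "mean") rowMeans(pm)
      else apply(pm, 1, stats::median)
    } else {
      reps <- split(seq_len(nrow(kept)), kept$replicate)
      vapply(seq_len(n_randomizations), function(i) {
        pref_list <- lapply(reps, function(idx) {
          times <- c(kept$t_manipulated_s[idx], kept$t_control_s[idx])
          lab <- sample(rep(c("m", "c"), each = length(idx)))
          ord <- sample(seq_along(times))
          tm <- times[ord][lab == "m"]
          tc <- times[ord][lab == "c"]
          tot <- tm + tc
          ok <- tot >= min_total_s & tot > 0
          100 * tm[ok] / tot[ok]
        })
        v <- unlist(pref_list, use.names = FALSE)
        if (length(v) == 0L) return(NA_real_)
        stat_fun(v)
      }, numeric(1))
    }
  })
  null_stats <- null_stats[!is.na(null_stats)]
  n_eff <- length(null_stats)
  p_upper <- (1 + sum(null_stats >= observed)) / (n_eff + 1)
  p_lower <- (1 + sum(null_stats <= observed)) / (n_eff + 1)
  p_two <- min(1, 2 * min(p_upper, p_lower))
  p_one <- switch(sided,
                  greater = p_upper,
                  less = p_lower,
                  two_sided = min(p_upper, p_lower))
  if (degenerate) p_two <- 1
  structure(list(observed_statistic = observed,
                 n_randomizations = n_eff,
                 p_one_sided = p_one,
                 p_two_sided = p_two,
                 sidedness = sided,
                 scheme = scheme,
                 statistic = statistic,
                 seed = seed,
                 n_trials = nrow(kept),
                 degenerate = degenerate,
                 null_sample = if (keep_null) null_stats
                               else summary(null_stats)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$statistic, " preference = ",
      round(x$observed_statistic, 2), " over ", x$n_trials, " trials\n",
      "  ", x$n_randomizations, " randomizations (", x$scheme, "), ",
      x$sidedness, ": p_one = ", signif(x$p_one_sided, 4),
      ", p_two = ", signif(x$p_two_sided, 4), "\n", sep = "")
  if (x$degenerate) cat("  (degenerate: all preferences at 50)\n")
  invisible(x)
}
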