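# Correlation-matrix PCA of CHC profiles followed by per-component ANCOVA
# (genotype as factor, age as continuous covariate).

#' PCA on compound correlations followed by per-component ANCOVA
#'
#' Distills profile-wide changes into a few uncorrelated components and
#' asks how genotype and aging move samples along each.  Compounds are
#' standardized to zero mean and unit variance (so the decomposition is of
#' the compound correlation matrix, giving every compound equal weight
#' regardless of its abundance); zero-variance compounds are dropped with a
#' message.  For each retained component an ANCOVA
#' `score ~ genotype * age` is fitted with age continuous; the interaction
#' term is reported separately so that "aging acts in parallel in both
#' genotypes" can be asserted as a non-significant interaction.
#'
#' Type II sums of squares ([car::Anova()]) give the genotype and age
#' p-values; the genotype effect estimate is the genotype coefficient of
#' the additive model (the age-adjusted between-genotype shift), reported
#' for two-level genotype factors.
#'
#' @param table A `chc_table` in `"normalized"` or `"ln_normalized"` state
#'   (default analyses use the ln scale).
#' @param n_components Number of leading components to retain for the
#'   ANCOVA stage.
#' @return A `pca_ancova` list: `scores` (tibble: sample metadata plus
#'   `PC1..`), `variance_fraction` (all components; sums to 1),
#'   `loadings`, `ancova` (tibble: one row per retained component with
#'   `genotype_estimate`, `p_genotype`, `age_slope`, `p_age`,
#'   `p_interaction`), `dropped_compounds`.
#' @export
pca_ancova <- function(table, n_components = 2) {
  stopifnot(inherits(table, "chc_table"))
  if (chc_state(table) == "raw") {
    stop("pca_ancova() requires a normalized or ln-normalized table",
         call. = FALSE)
  }
  df <- tibble::as_tibble(table)
  wide <- tidyr::pivot_wider(
    df[, c("sample_id", "genotype", "age_days", "compound", "intensity")],
    names_from = "compound", values_from = "intensity")
  meta <- wide[, c("sample_id", "genotype", "age_days")]
  mat <- as.matrix(wide[, setdiff(names(wide), names(meta))])
  rownames(mat) <- wide$sample_id
  if (anyNA(mat)) stop("samples x compounds matrix has missing cells",
                       call. = FALSE)
  vars <- apply(mat, 2, stats::var)
  dropped <- colnames(mat)[vars == 0]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " zero-variance compound(s) before standardization: ",
            paste(dropped, collapse = ", "))
    mat <- mat[, vars > 0, drop = FALSE]
  }
  gcounts <- table(meta$genotype)
  if (any(gcounts < 2L)) stop("need >= 2 samples per genotype", call. = FALSE)
  if (nrow(mat) <= n_components) {
    stop("need more samples than retained components", call. = FALSE)
  }
  pca <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  frac <- pca$sdev^2 / sum(pca$sdev^2)
  k <- min(n_components, ncol(pca$x))
  scores <- dplyr::bind_cols(meta,
                             tibble::as_tibble(pca$x[, seq_len(k),
                                                     drop = FALSE]))
  two_level <- length(gcounts) == 2L
  anc <- lapply(seq_len(k), function(i) {
    d <- data.frame(score = pca$x[, i],
                    genotype = factor(meta$genotype),
                    age = meta$age_days)
    full <- stats::lm(score ~ genotype * age, data = d)
    aov2 <- car::Anova(full, type = 2)
    add <- stats::lm(score ~ genotype + age, data = d)
    est <- if (two_level) unname(stats::coef(add)[2]) else NA_real_
    tibble::tibble(component = paste0("PC", i),
                   variance_fraction = frac[i],
                   genotype_estimate = est,
                   p_genotype = aov2["genotype", "Pr(>F)"],
                   age_slope = unname(stats::coef(add)["age"]),
                   p_age = aov2["age", "Pr(>F)"],
                   p_interaction = aov2["genotype:age", "Pr(>F)"])
  })
  structure(list(scores = scores,
                 variance_fraction = frac,
                 loadings = pca$rotation,
                 ancova = dplyr::bind_rows(anc),
                 dropped_compounds = dropped),
            class = "pca_ancova")
}

#' @export
print.pca_ancova <- function(x, ...) {
  cat("<pca_ancova> ", nrow(x$scores), " samples, ",
      length(x$variance_fraction), " components (",
      paste0(round(100 * x$variance_fraction[seq_len(min(3,
        length(x$variance_fraction)))], 1), "%", collapse = ", "),
      " ...)\n", sep = "")
  print(x$ancova)
  invisible(x)
}
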