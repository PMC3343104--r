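# Relative expression by the delta-delta-Ct method, normalized to a
# reference gene, with replicate-based z-tests on the ln scale.

.ct_cols <- c("condition", "bio_rep", "tech_rep", "gene", "ct")

#' Validate a Ct table
#'
#' @param table Data frame with columns `condition`
#'   (`"manipulated"`/`"control"`), `bio_rep`, `tech_rep`, `gene`, `ct`.
#' @param reference Reference (endogenous control) gene label, e.g.
#'   `"rp49"`; must be present for every (condition, biological replicate).
#' @return The table as a tibble, invisibly validated.
#' @export
ct_table <- function(table, reference = "rp49") {
  table <- tibble::as_tibble(table)[, .ct_cols]
  attr(table, "out.attrs") <- NULL  # expand.grid residue
  stopifnot(all(.ct_cols %in% names(table)),
            all(table$condition %in% c("manipulated", "control")),
            all(is.finite(table$ct)), all(table$ct > 0))
  cells <- unique(table[, c("condition", "bio_rep")])
  ref <- unique(table[table$gene == reference, c("condition", "bio_rep")])
  if (nrow(dplyr::anti_join(cells, ref, by = c("condition", "bio_rep")))) {
    stop("reference gene '", reference, "' missing for some ",
         "(condition, biological replicate) cells", call. = FALSE)
  }
  table
}

#' Per-replicate ln fold changes by the delta-delta-Ct method
#'
#' Technical replicates are averaged to one Ct per (condition, biological
#' replicate, gene).  Then per cell `dCt = Ct_gene - Ct_reference`,
#' `ddCt = dCt_manipulated - dCt_control` per pairing, fold change
#' `= 2^-ddCt`, and `ln fold change = -ddCt * ln 2`.  Because every Ct
#' enters as a within-sample difference, adding a constant to all Cts
#' leaves the result unchanged.
#'
#' Pairing of manipulated vs control biological replicates: when the two
#' conditions share the same replicate labels, replicates are paired by
#' label (`pairing = "by_label"`); otherwise, or on request, each
#' manipulated replicate is compared against the mean control dCt
#' (`pairing = "vs_control_mean"`).
#'
#' @param table A Ct table (see [ct_table()]).
#' @param gene Target gene label (must differ from `reference`).
#' @param reference Reference gene label, default `"rp49"`.
#' @param pairing `"auto"` (default: by label when labels match),
#'   `"by_label"` or `"vs_control_mean"`.
#' @return A tibble with one row per pairing: `gene`, `bio_rep`,
#'   `delta_delta_ct`, `fold_change`, `ln_fold_change`, plus the pairing
#'   mode in the `pairing` attribute.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   condition = rep(c("manipulated", "control"), each = 4),
#'   bio_rep = rep(c("B1", "B1"), each = 2, times = 2),
#'   tech_rep = rep(c("T1", "T2"), times = 4),
#'   gene = rep(c("eloF", "rp49"), each = 2, times = 2),
#'   ct = c(22, 22, 27, 27, 24, 24, 27, 27))
#' delta_delta_ct(tbl, "eloF")  # ddCt = -2, fold change 4
delta_delta_ct <- function(table, gene, reference = "rp49",
                           pairing = c("auto", "by_label",
                                       "vs_control_mean")) {
  pairing <- match.arg(pairing)
  if (identical(gene, reference)) {
    stop("target gene must differ from the reference gene", call. = FALSE)
  }
  table <- ct_table(table, reference)
  if (!any(table$gene == gene)) {
    stop("gene '", gene, "' not in table", call. = FALSE)
  }
  avg <- table[table$gene %in% c(gene, reference), ] |>
    dplyr::group_by(.data$condition, .data$bio_rep, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  wide <- tidyr::pivot_wider(avg, names_from = "gene", values_from = "ct")
  if (anyNA(wide[[gene]])) {
    drop <- wide$bio_rep[is.na(wide[[gene]])]
    message("dropping replicate(s) without target Ct: ",
            paste(drop, collapse = ", "))
    wide <- wide[!is.na(wide[[gene]]), ]
  }
  wide$dct <- wide[[gene]] - wide[[reference]]
  man <- wide[wide$condition == "manipulated", ]
  ctl <- wide[wide$condition == "control", ]
  if (nrow(man) == 0L || nrow(ctl) == 0L) {
    stop("need both conditions for gene '", gene, "'", call. = FALSE)
  }
  labels_match <- setequal(man$bio_rep, ctl$bio_rep)
  if (pairing == "auto") {
    pairing <- if (labels_match) "by_label" else "vs_control_mean"
  }
  if (pairing == "by_label") {
    if (!labels_match) {
      stop("by_label pairing requires matching replicate labels in both ",
           "conditions", call. = FALSE)
    }
    ddct <- man$dct - ctl$dct[match(man$bio_rep, ctl$bio_rep)]
  } else {
    ddct <- man$dct - mean(ctl$dct)
  }
  out <- tibble::tibble(gene = gene,
                        bio_rep = man$bio_rep,
                        delta_delta_ct = ddct,
                        fold_change = 2^(-ddct),
                        ln_fold_change = -ddct * log(2))
  attr(out, "pairing") <- pairing
  out
}

#' z-test of ln fold changes across biological replicates
#'
#' Tests the null of no expression change: `z = mean / (sd / sqrt(n))`
#' over the per-replicate ln fold changes, with the two-sided p-value from
#' the standard normal.  The standard error reported is the
#' between-biological-replicate SE of the mean.  A Student-t variant is
#' available behind `use_t = TRUE` but the standard normal is the default.
#'
#' @param ln_fold_changes Numeric vector, one ln fold change per
#'   biological replicate (>= 2 values).
#' @param gene Optional gene label carried into the result.
#' @param use_t Use a t reference distribution (df = n - 1) instead of the
#'   standard normal? Default `FALSE`.
#' @return A `FoldChangeResult` tibble row: `gene`, `ln_fold_change`
#'   (mean), `se`, `z`, `p_two_sided`, `n_biological_replicates`,
#'   `degenerate` (zero variance).
#' @export
#' @examples
#' z_test_fold_change(c(0.5, 0.6, 0.7))
z_test_fold_change <- function(ln_fold_changes, gene = NA_character_,
                               use_t = FALSE) {
  x <- ln_fold_changes[!is.na(ln_fold_changes)]
  n <- length(x)
  if (n < 2L) stop("need >= 2 biological replicates", call. = FALSE)
  m <- mean(x)
  se <- stats::sd(x) / sqrt(n)
  degenerate <- se == 0
  if (degenerate) {
    z <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    z <- m / se
    p <- if (use_t) 2 * stats::pt(-abs(z), df = n - 1)
         else 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(gene = gene, ln_fold_change = m, se = se, z = z,
                 p_two_sided = p, n_biological_replicates = n,
                 degenerate = degenerate)
}

#' Fold-change analysis for a panel of genes
#'
#' Runs [delta_delta_ct()] and [z_test_fold_change()] for each target gene
#' against the reference.
#'
#' @inheritParams delta_delta_ct
#' @param genes Target gene labels; default: every gene in the table
#'   except the reference.
#' @param use_t Passed to [z_test_fold_change()].
#' @return A tibble of FoldChangeResult rows, one per gene.
#' @export
qpcr_fold_changes <- function(table, genes = NULL, reference = "rp49",
                              pairing = "auto", use_t = FALSE) {
  table <- ct_table(table, reference)
  if (is.null(genes)) genes <- setdiff(unique(table$gene), reference)
  dplyr::bind_rows(lapply(genes, function(g) {
    fc <- delta_delta_ct(table, g, reference, pairing)
    z_test_fold_change(fc$ln_fold_change, gene = g, use_t = use_t)
  }))
}
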