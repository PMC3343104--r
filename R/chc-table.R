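# ChcSampleTable: long-format samples x compounds intensity table with a
# state tag (raw -> normalized -> ln_normalized) and compound descriptors.

.chc_cols <- c("sample_id", "genotype", "age_days", "replicate", "platform",
               "compound", "intensity")

#' Construct a CHC sample table
#'
#' A long-format table of per-sample, per-compound intensities with sample
#' metadata (genotype, age, replicate, platform).  The table carries a
#' processing state: `"raw"` (instrument peak intensities), `"normalized"`
#' (relative quantitation, see [normalize_profile()]) or `"ln_normalized"`
#' (natural-log scale, see [ln_transform()]), plus the compound-descriptor
#' table used to decide which compounds are identified hydrocarbons.
#'
#' @param data A data frame with columns `sample_id`, `genotype`,
#'   `age_days`, `replicate`, `platform` (`"GCMS"` or `"LDIMS"`),
#'   `compound`, `intensity`.
#' @param descriptors Optional compound-descriptor tibble
#'   ([compound_descriptors()]); parsed from the compound names if omitted.
#' @param state Processing state; new tables are `"raw"`.
#' @return A `chc_table` (a tibble subclass).
#' @export
chc_table <- function(data, descriptors = NULL, state = "raw") {
  stopifnot(all(.chc_cols %in% names(data)))
  state <- match.arg(state, c("raw", "normalized", "ln_normalized"))
  data <- tibble::as_tibble(data)[, .chc_cols]
  attr(data, "out.attrs") <- NULL  # expand.grid residue
  stopifnot(all(data$platform %in% c("GCMS", "LDIMS")))
  if (state != "ln_normalized" && any(data$intensity < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed in ", state, " state",
         call. = FALSE)
  }
  if (is.null(descriptors)) {
    descriptors <- compound_descriptors(unique(data$compound))
  }
  missing <- setdiff(unique(data$compound), descriptors$name)
  if (length(missing)) {
    stop("no descriptor for compound(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(data,
            class = c("chc_table", class(tibble::tibble())),
            chc_state = state,
            descriptors = descriptors)
}

#' @export
print.chc_table <- function(x, ...) {
  cat("<chc_table> state:", chc_state(x),
      "|", length(unique(x$sample_id)), "samples x",
      length(unique(x$compound)), "compounds\n")
  NextMethod()
}

#' Processing state of a CHC table
#' @param table A `chc_table`.
#' @return `"raw"`, `"normalized"` or `"ln_normalized"`.
#' @export
chc_state <- function(table) attr(table, "chc_state", exact = TRUE)

#' Compound descriptors attached to a CHC table
#' @param table A `chc_table`.
#' @return The descriptor tibble.
#' @export
chc_descriptors <- function(table) attr(table, "descriptors", exact = TRUE)

.rewrap_chc <- function(data, template, state) {
  structure(tibble::as_tibble(data),
            class = class(template),
            chc_state = state,
            descriptors = chc_descriptors(template),
            ln_epsilon = attr(template, "ln_epsilon", exact = TRUE),
            excluded_samples = attr(template, "excluded_samples", exact = TRUE))
}

#' Relative quantitation of a raw CHC table
#'
#' Compound-dependent detection efficiencies make absolute levels
#' unrecoverable on both GC/MS and LDI-MS, so each identified-hydrocarbon
#' intensity is divided by the per-sample sum of the peak intensities of
#' all identified hydrocarbons.  Compounds not flagged as identified
#' hydrocarbons are excluded from the denominator and dropped from the
#' normalized table.  Because the divisor is per-sample, any per-sample
#' multiplicative factor (detection efficiency, amount loaded, laser
#' position) cancels exactly.
#'
#' Samples whose identified intensities are all zero cannot be normalized;
#' they are excluded and recorded in the `excluded_samples` attribute.
#'
#' @param table A `chc_table` in `"raw"` state (a `"normalized"` table is
#'   accepted too; the operation is idempotent).
#' @return A `chc_table` in `"normalized"` state; per sample the identified
#'   intensities sum to 1.
#' @export
normalize_profile <- function(table) {
  stopifnot(inherits(table, "chc_table"))
  if (chc_state(table) == "ln_normalized") {
    stop("normalize_profile() expects a table in 'raw' (or 'normalized') ",
         "state, not 'ln_normalized'", call. = FALSE)
  }
  desc <- chc_descriptors(table)
  identified <- desc$name[desc$is_identified_hydrocarbon]
  kept <- table[table$compound %in% identified, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no identified hydrocarbons present; nothing to normalize",
         call. = FALSE)
  }
  sums <- tapply(kept$intensity, kept$sample_id, sum, na.rm = TRUE)
  bad <- names(sums)[sums <= 0]
  if (length(bad)) {
    message("excluding ", length(bad),
            " sample(s) with all-zero identified intensities: ",
            paste(bad, collapse = ", "))
    kept <- kept[!kept$sample_id %in% bad, , drop = FALSE]
  }
  kept$intensity <- kept$intensity / as.numeric(sums[kept$sample_id])
  out <- .rewrap_chc(kept, table, "normalized")
  attr(out, "excluded_samples") <- bad
  out
}

#' Natural-log transform of a normalized CHC table
#'
#' Profile statistics are run on the natural-log scale, where model
#' residuals of the per-compound ANOVA are approximately normal.  Zeros
#' (chromatographic non-detections) would map to -Inf, so when the table
#' contains any zero intensity a pseudo-count epsilon equal to half the
#' smallest positive normalized intensity is added to every value before
#' taking logs; when no zeros are present epsilon is 0 and the transform is
#' a plain `log()`.  The epsilon used is recorded in the `ln_epsilon`
#' attribute.
#'
#' @param table A `chc_table` in `"normalized"` state.
#' @return A `chc_table` in `"ln_normalized"` state.
#' @export
ln_transform <- function(table) {
  stopifnot(inherits(table, "chc_table"))
  if (chc_state(table) != "normalized") {
    stop("ln_transform() expects a table in 'normalized' state, got '",
         chc_state(table), "'", call. = FALSE)
  }
  x <- table$intensity
  eps <- if (any(x == 0)) min(x[x > 0]) / 2 else 0
  out <- table
  out$intensity <- log(x + eps)
  out <- .rewrap_chc(out, table, "ln_normalized")
  attr(out, "ln_epsilon") <- eps
  out
}
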