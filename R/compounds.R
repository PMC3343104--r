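# Compound descriptors and the CHC naming grammar.

# Positional-monoene and diene shorthand: chain length implied by the stem.
.monoene_aliases <- c(T = 23L, Pe = 25L, H = 27L)
.diene_aliases <- c(PD = 25L, HD = 27L, ND = 29L)

#' Parse a cuticular-hydrocarbon compound name
#'
#' Supported grammar, mirroring common shorthand for fly cuticular
#' hydrocarbons:
#' \itemize{
#'   \item `nC23` -- linear alkane, 23 carbons.
#'   \item `7-T`, `7-Pe`, `7-H` -- positional monoenes; the stem encodes the
#'     chain length (T = tricosene C23, Pe = pentacosene C25,
#'     H = heptacosene C27).
#'   \item `7,11-HD`, `7,11-ND`, `5,9-PD` -- dienes (PD = C25, HD = C27,
#'     ND = C29).
#'   \item `2-MeC26` -- methyl-branched alkane; the carbon count includes the
#'     methyl carbon (2-MeC26 has 27 carbons).
#'   \item `C24:0`, `C25:1`, `C26:2` -- chain length : number of double bonds.
#'   \item `C27H54O2`, `C23H46` -- molecular formulas; oxygen marks the
#'     compound as oxygenated, otherwise the class follows from the degree of
#'     unsaturation.
#' }
#' Names outside this grammar require an explicit descriptor row (see
#' [compound_descriptors()]).
#'
#' @param name A single compound name.
#' @return A one-row tibble with columns `name`, `compound_class`
#'   (`alkane`, `monoene`, `diene`, `methyl-branched`, `oxygenated`,
#'   `other`), `carbon_count`, `n_double_bonds`,
#'   `is_identified_hydrocarbon` and `style` (the grammar family matched,
#'   used by [format_compound_name()] to round-trip).
#' @seealso [format_compound_name()], [compound_descriptors()]
#' @export
#' @examples
#' parse_compound_name("7,11-HD")
#' parse_compound_name("2-MeC26")
parse_compound_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  row <- function(class, carbons, dbl, style, identified = TRUE) {
    tibble::tibble(
      name = name, compound_class = class,
      carbon_count = as.integer(carbons), n_double_bonds = as.integer(dbl),
      is_identified_hydrocarbon = identified, style = style
    )
  }
  if (grepl("^nC[0-9]+$", name)) {
    return(row("alkane", sub("^nC", "", name), 0L, "n-alkane"))
  }
  m <- regmatches(name, regexec("^([0-9]+)-(T|Pe|H)$", name))[[1]]
  if (length(m)) {
    return(row("monoene", .monoene_aliases[[m[3]]], 1L, "monoene-alias"))
  }
  m <- regmatches(name, regexec("^([0-9]+),([0-9]+)-(PD|HD|ND)$", name))[[1]]
  if (length(m)) {
    return(row("diene", .diene_aliases[[m[4]]], 2L, "diene-alias"))
  }
  m <- regmatches(name, regexec("^2-MeC([0-9]+)$", name))[[1]]
  if (length(m)) {
    return(row("methyl-branched", as.integer(m[2]) + 1L, 0L, "methyl"))
  }
  m <- regmatches(name, regexec("^C([0-9]+):([0-9]+)$", name))[[1]]
  if (length(m)) {
    dbl <- as.integer(m[3])
    class <- c("alkane", "monoene", "diene")[dbl + 1L]
    if (is.na(class)) class <- "other"
    return(row(class, m[2], dbl, "carbon-colon"))
  }
  m <- regmatches(name, regexec("^C([0-9]+)H([0-9]+)(O([0-9]*))?$", name))[[1]]
  if (length(m)) {
    nc <- as.integer(m[2]); nh <- as.integer(m[3])
    dbl <- max(0L, (2L * nc + 2L - nh) %/% 2L)
    if (nzchar(m[4])) {
      return(row("oxygenated", nc, dbl, "formula"))
    }
    class <- if (dbl == 0L) "alkane" else if (dbl == 1L) "monoene"
             else if (dbl == 2L) "diene" else "other"
    return(row(class, nc, dbl, "formula"))
  }
  stop("compound name '", name, "' is outside the supported grammar; ",
       "supply an explicit descriptor row", call. = FALSE)
}

#' Format a compound descriptor back into its name
#'
#' Inverse of [parse_compound_name()] for the supported grammar: for any
#' name the parser accepts, formatting the parsed descriptor reproduces the
#' name exactly.
#'
#' @param descriptor A one-row descriptor tibble as returned by
#'   [parse_compound_name()].
#' @return The compound name as a string.
#' @export
format_compound_name <- function(descriptor) {
  stopifnot(nrow(descriptor) == 1L)
  d <- descriptor
  switch(d$style,
    "n-alkane" = paste0("nC", d$carbon_count),
    "monoene-alias" = ,
    "diene-alias" = ,
    "formula" = ,
    "methyl" = ,
    "carbon-colon" = d$name,
    stop("unknown compound style '", d$style, "'", call. = FALSE)
  )
}

#' Build a compound-descriptor table
#'
#' Parses every name through the CHC grammar; names the grammar does not
#' cover must be given in `extra`, a tibble with the same columns as the
#' parser output (minus `style`).  The oxygenated ester-like compounds that
#' co-elute with the hydrocarbon profile are counted as identified (and so
#' enter the normalization denominator) by default; set
#' `oxygenated_identified = FALSE` to exclude them.
#'
#' @param names Character vector of compound names.
#' @param extra Optional tibble of descriptor rows for names outside the
#'   grammar (columns `name`, `compound_class`, `carbon_count`,
#'   `n_double_bonds`, `is_identified_hydrocarbon`).
#' @param oxygenated_identified Should oxygenated compounds count as
#'   identified hydrocarbons for normalization purposes? Default `TRUE`.
#' @return A tibble with one row per compound.
#' @export
#' @examples
#' compound_descriptors(c("nC23", "7-T", "7,11-HD", "2-MeC26", "C27H54O2"))
compound_descriptors <- function(names, extra = NULL,
                                 oxygenated_identified = TRUE) {
  stopifnot(!anyDuplicated(names))
  extra_names <- if (is.null(extra)) character() else extra$name
  rows <- lapply(names, function(nm) {
    if (nm %in% extra_names) {
      r <- extra[extra$name == nm, , drop = FALSE]
      if (!"style" %in% names(r)) r$style <- "explicit"
      return(r[, c("name", "compound_class", "carbon_count", "n_double_bonds",
                   "is_identified_hydrocarbon", "style")])
    }
    parse_compound_name(nm)
  })
  out <- dplyr::bind_rows(rows)
  if (!oxygenated_identified) {
    out$is_identified_hydrocarbon[out$compound_class == "oxygenated"] <- FALSE
  }
  stopifnot(all(out$carbon_count >= 1L | is.na(out$carbon_count)))
  out
}
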