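# Plants x markers genotype container shared by linkage and fine mapping.

#' Genotype matrix of an F2 family
#'
#' A data frame of plants by markers using the field's F2 codes:
#' `A` = P1 homozygote, `H` = heterozygote, `B` = P2 homozygote,
#' `C` = dominant class ("not A", used for dominantly scored columns such as
#' the trait) and `U` = missing. Each column uses a single coding scheme,
#' either `"codominant"` (A/H/B) or `"dominant"` (A/C).
#'
#' @param df data frame with an `id` column followed by marker/trait columns
#'   of genotype codes.
#' @param positions named numeric vector of 1-based physical positions for
#'   marker columns (the trait column needs no position).
#' @param codings named character vector (`"codominant"` or `"dominant"`) per
#'   non-id column; defaults to codominant for positioned columns.
#' @return the data frame with class `genotype_matrix` and attributes
#'   `positions` and `codings`.
#' @export
genotype_matrix <- function(df, positions, codings = NULL) {
  if (!"id" %in% names(df)) stopf("genotype matrix needs an 'id' column")
  if (anyDuplicated(df$id)) stopf("duplicate plant ids")
  cols <- setdiff(names(df), "id")
  codings <- codings %||%
    stats::setNames(rep("codominant", length(cols)), cols)
  if (!all(names(positions) %in% cols))
    stopf("positions refer to unknown columns")
  bad <- setdiff(names(codings), cols)
  if (length(bad)) stopf("codings refer to unknown columns: %s",
                         paste(bad, collapse = ", "))
  for (cl in cols) {
    coding <- codings[[cl]] %||% "codominant"
    ok <- switch(coding,
                 codominant = c("A", "H", "B", "U"),
                 dominant = c("A", "C", "U"),
                 stopf("unknown coding '%s' for column '%s'", coding, cl))
    vals <- df[[cl]]
    if (!all(vals %in% ok | is.na(vals)))
      stopf("column '%s' (%s) contains codes outside {%s}",
            cl, coding, paste(ok, collapse = ","))
  }
  structure(df, positions = positions, codings = codings,
            class = c("genotype_matrix", "data.frame"))
}

marker_names <- function(gm) names(attr(gm, "positions"))

marker_positions <- function(gm) attr(gm, "positions")

marker_coding <- function(gm, marker) {
  codings <- attr(gm, "codings")
  codings[[marker]] %||% "codominant"
}

# subset plants, preserving class/attributes
gm_subset <- function(gm, rows) {
  out <- gm[rows, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, positions = attr(gm, "positions"),
            codings = attr(gm, "codings"),
            class = class(gm))
}
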