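# Recombinant screening and substitution mapping: narrowing a candidate
# interval by intersecting genotype-phenotype compatibility constraints
# across recombinant plants.

#' Screen recombinants between two flanking markers
#'
#' Returns the plants whose genotype class differs between the two flanking
#' (codominant) markers — the definition of a recombinant in the interval.
#' Plants missing a genotype at either flank are skipped with a log entry.
#'
#' @param gm a [genotype_matrix()] (e.g. an F2:3 screen).
#' @param flank_left,flank_right names of the flanking marker columns.
#' @return the recombinant subset of `gm`, with attribute `screen_counts`
#'   (total, missing_skipped, recombinant).
#' @export
screen_recombinants <- function(gm, flank_left, flank_right) {
  for (fk in c(flank_left, flank_right)) {
    if (!fk %in% names(gm)) stopf("flanking marker '%s' not found", fk)
    if (marker_coding(gm, fk) != "codominant")
      stopf("flanking marker '%s' must be codominantly scored", fk)
  }
  gl <- gm[[flank_left]]; gr <- gm[[flank_right]]
  missing <- gl %in% "U" | gr %in% "U" | is.na(gl) | is.na(gr)
  rec <- !missing & gl != gr
  counts <- c(total = nrow(gm), missing_skipped = sum(missing),
              recombinant = sum(rec))
  log_msg("screen_recombinants",
          sprintf("total=%d missing_skipped=%d recombinant=%d",
                  counts[1], counts[2], counts[3]))
  out <- gm_subset(gm, rec)
  attr(out, "screen_counts") <- counts
  out
}

# Compatibility of a candidate locus position (at each marker) with one
# recombinant's genotype + phenotype, under complete penetrance:
#  * recessive plant: the locus cannot sit where the plant carries a dominant
#    allele (het or dominant-parent homozygote); only recessive-parent
#    homozygous markers are compatible.
#  * dominant plant: the locus cannot sit where the plant is homozygous for
#    the recessive-parent allele; het regions are uninformative (dominance
#    masks them), so only recessive-hom markers exclude.
#  * missing genotypes are uninformative (compatible).
compat_row <- function(codes, recessive, recessive_hom) {
  unknown <- codes %in% "U" | is.na(codes)
  if (recessive) (codes == recessive_hom) | unknown
  else (codes != recessive_hom) | unknown
}

#' Refine a candidate interval from recombinant genotypes and phenotypes
#'
#' Substitution mapping: each recombinant excludes the candidate-locus
#' positions incompatible with its own phenotype (see the rules in the
#' source); the refined interval is the maximal run of markers compatible
#' with all recombinants, with breakpoints placed at the midpoint between the
#' last compatible and first incompatible marker (the true crossover position
#' being unobserved). With zero recombinants the interval is returned
#' unchanged. Conflicting recombinants (no marker compatible with all plants)
#' raise an error naming the plants — the signature of a phenotyping or
#' genotyping error, or of non-single-gene inheritance.
#'
#' @param rec a recombinant [genotype_matrix()] (see
#'   [screen_recombinants()]); its trait column must code phenotypes as
#'   A (recessive) / C (dominant).
#' @param current the current `genomic_interval` being narrowed.
#' @param markers marker columns to use (default: all positioned markers
#'   inside `current`, ordered by position).
#' @param dominant_class which homozygote class carries the dominant allele:
#'   `"B"` (P2 dominant, default) or `"A"`.
#' @param trait trait column name.
#' @return a one-row `genomic_interval`, with attributes `compatible_markers`
#'   and `n_recombinants`.
#' @export
refine_interval <- function(rec, current, markers = NULL,
                            dominant_class = c("B", "A"), trait = "trait") {
  dominant_class <- match.arg(dominant_class)
  recessive_hom <- if (dominant_class == "B") "A" else "B"
  stopifnot(inherits(current, "genomic_interval"), nrow(current) == 1L)
  pos <- marker_positions(rec)
  markers <- markers %||%
    names(sort(pos[pos >= current$start & pos <= current$end]))
  if (length(markers) < 1L) stopf("no markers inside the current interval")
  pos <- pos[markers]
  if (any(diff(pos) <= 0)) stopf("marker positions must be strictly increasing")
  if (nrow(rec) == 0L) {
    out <- current
    attr(out, "compatible_markers") <- markers
    attr(out, "n_recombinants") <- 0L
    return(out)
  }
  if (!trait %in% names(rec)) stopf("trait column '%s' not found", trait)
  phen <- rec[[trait]]
  if (any(!phen %in% c("A", "C")))
    stopf("trait column must use codes A (recessive) / C (dominant)")
  comp <- vapply(seq_len(nrow(rec)), function(i) {
    compat_row(unlist(rec[i, markers], use.names = FALSE),
               recessive = phen[i] == "A", recessive_hom = recessive_hom)
  }, logical(length(markers)))
  comp <- matrix(comp, nrow = length(markers))
  all_ok <- rowSums(!comp) == 0L
  if (!any(all_ok)) {
    per_plant <- colSums(comp) == 0L
    detail <- if (any(per_plant))
      sprintf("plant(s) excluding every marker: %s",
              paste(rec$id[per_plant], collapse = ", "))
    else sprintf("mutually conflicting plants: %s",
                 paste(rec$id, collapse = ", "))
    stopf("no sub-interval is compatible with all recombinants (%s)", detail)
  }
  runs <- rle(all_ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok_runs <- which(runs$values)
  if (length(ok_runs) > 1L)
    warnf("compatible markers are non-contiguous; keeping the longest run")
  pick <- ok_runs[which.max(runs$lengths[ok_runs])]
  i0 <- starts[pick]; i1 <- ends[pick]
  new_start <- if (i0 == 1L) current$start
               else max(current$start, ceiling((pos[i0 - 1L] + pos[i0]) / 2))
  new_end <- if (i1 == length(markers)) current$end
             else min(current$end, floor((pos[i1] + pos[i1 + 1L]) / 2))
  out <- genomic_interval(current$chrom, new_start, new_end,
                          confidence_level = current$confidence_level)
  attr(out, "compatible_markers") <- markers[i0:i1]
  attr(out, "n_recombinants") <- nrow(rec)
  out
}
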