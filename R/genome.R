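# Genome and locus descriptions used by the population simulator.

#' Single-chromosome genome model
#'
#' Describes the simulated chromosome: its length, a constant recombination
#' rate, the positions of segregating SNPs and the parental alleles at each
#' SNP. Every simulated SNP is fixed-different between the parents: parent P1
#' carries the reference base, parent P2 the alternative base.
#'
#' @param chrom chromosome name.
#' @param length_bp chromosome length in bp.
#' @param cm_per_mb constant recombination rate in cM/Mb (>= 0; 0 gives a
#'   chromosome with zero map length, i.e. no crossovers).
#' @param snp_positions strictly increasing integer vector of 1-based SNP
#'   positions within `[1, length_bp]`.
#' @param ref,alt nucleotide vectors (recycled) giving the P1 and P2 alleles.
#' @return an object of class `genome_model`.
#' @seealso [desk_genome()] for the default desk-scale genome.
#' @export
genome_model <- function(chrom = "chr3", length_bp = 25e6, cm_per_mb = 3,
                         snp_positions, ref = "A", alt = "T") {
  if (!is_count(length_bp)) stopf("'length_bp' must be a positive integer")
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1L || cm_per_mb < 0)
    stopf("'cm_per_mb' must be a single non-negative number")
  pos <- as.numeric(snp_positions)
  if (length(pos) < 1L) stopf("at least one SNP position is required")
  if (any(pos != floor(pos)) || any(pos < 1) || any(pos > length_bp))
    stopf("SNP positions must be integers in [1, length_bp]")
  if (any(diff(pos) <= 0)) stopf("SNP positions must be strictly increasing")
  m <- length(pos)
  ref <- rep_len(toupper(as.character(ref)), m)
  alt <- rep_len(toupper(as.character(alt)), m)
  if (any(ref == alt)) stopf("ref and alt alleles must differ at every SNP")
  structure(list(chrom = as.character(chrom)[1], length_bp = as.numeric(length_bp),
                 cm_per_mb = cm_per_mb, snp_positions = pos,
                 ref = ref, alt = alt),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %s, %.3f Mb, %d SNPs, %.2f cM/Mb (map %.1f cM)\n",
              x$chrom, x$length_bp / 1e6, length(x$snp_positions), x$cm_per_mb,
              x$length_bp / 1e6 * x$cm_per_mb))
  invisible(x)
}

#' Default desk-scale genome
#'
#' One 25-Mb chromosome carrying `n_snps` segregating SNPs with the causal
#' position guaranteed to be among them. This mirrors the geometry of a
#' mid-sized pseudochromosome scaled to desk size; the recombination rate is a
#' free parameter, not an estimate of any real map.
#'
#' @param n_snps number of SNPs (default 5000).
#' @param length_bp chromosome length (default 25 Mb).
#' @param cm_per_mb recombination rate (default 3 cM/Mb).
#' @param causal_pos position forced into the SNP set (default 14.75 Mb).
#' @param chrom chromosome name.
#' @param seed RNG seed for positions and alleles.
#' @return a `genome_model`.
#' @export
desk_genome <- function(n_snps = 5000, length_bp = 25e6, cm_per_mb = 3,
                        causal_pos = 14.75e6, chrom = "chr3", seed = NULL) {
  with_seed(seed, {
    pos <- sort(sample.int(length_bp, n_snps * 1.05 + 10))
    pos <- unique(c(pos, causal_pos))
    # thin back to n_snps keeping the causal position
    keep <- sort(sample(setdiff(seq_along(pos), match(causal_pos, pos)),
                        n_snps - 1L))
    pos <- sort(c(pos[keep], causal_pos))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snps, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    genome_model(chrom = chrom, length_bp = length_bp, cm_per_mb = cm_per_mb,
                 snp_positions = pos, ref = ref, alt = unname(alt))
  })
}

#' Causal locus of a single-gene dominant trait
#'
#' @param position_bp 1-based position of the causal SNP; must be one of the
#'   genome's SNP positions when used with the simulator.
#' @param dominant_parent which parent carries the dominant allele
#'   (`"P1"` or `"P2"`).
#' @param phenotypes named character vector with elements `dominant` and
#'   `recessive` giving the phenotype labels.
#' @return an object of class `causal_locus`.
#' @export
causal_locus <- function(position_bp = 14.75e6, dominant_parent = "P2",
                         phenotypes = c(dominant = "black", recessive = "yellow")) {
  dominant_parent <- match.arg(dominant_parent, c("P1", "P2"))
  if (!is_count(position_bp)) stopf("'position_bp' must be a positive integer")
  if (!all(c("dominant", "recessive") %in% names(phenotypes)))
    stopf("'phenotypes' needs named elements 'dominant' and 'recessive'")
  structure(list(position_bp = as.numeric(position_bp),
                 dominant_parent = dominant_parent,
                 phenotypes = phenotypes[c("dominant", "recessive")]),
            class = "causal_locus")
}
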