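# Shared fixtures, built in code at test time.

# tiny genome: m evenly spaced SNPs on a short chromosome
tiny_genome <- function(m = 5, length_bp = 1e6, cm_per_mb = 3,
                        causal = NULL) {
  pos <- round(seq(length_bp / (m + 1), length_bp, length.out = m))
  if (!is.null(causal)) pos <- sort(unique(c(pos, causal)))
  genome_model(chrom = "chrT", length_bp = length_bp, cm_per_mb = cm_per_mb,
               snp_positions = pos, ref = "A", alt = "T")
}

tiny_locus <- function(position_bp) {
  causal_locus(position_bp, dominant_parent = "P2",
               phenotypes = c(dominant = "black", recessive = "yellow"))
}

# hand-built pooled variant table
toy_pooled <- function(chrom = "chr3",
                       pos = c(100L, 200L, 300L),
                       ref_low = c(6L, 0L, 30L), alt_low = c(6L, 10L, 30L),
                       ref_high = c(6L, 0L, 30L), alt_high = c(6L, 10L, 30L),
                       chrom_length = 1000) {
  pooled_variants(data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                             ref_low = ref_low, alt_low = alt_low,
                             ref_high = ref_high, alt_high = alt_high,
                             stringsAsFactors = FALSE),
                  chrom_length = chrom_length)
}

# independent two-locus coupling-phase F2 probability table used as an
# oracle: brute-force enumeration over the 16 ordered gamete pairs.
oracle_f2_table <- function(r) {
  gam <- expand.grid(a = 0:1, b = 0:1)  # alleles at locus 1 and 2
  gam$p <- ifelse(gam$a == gam$b, (1 - r) / 2, r / 2)
  P <- matrix(0, 3, 3, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
  for (i in seq_len(4)) for (j in seq_len(4)) {
    g1 <- gam$a[i] + gam$a[j]
    g2 <- gam$b[i] + gam$b[j]
    P[g1 + 1, g2 + 1] <- P[g1 + 1, g2 + 1] + gam$p[i] * gam$p[j]
  }
  P
}

# oracle multinomial log-likelihood for a 3x3 (or collapsed) count table
oracle_loglik <- function(counts, r, dominant2 = FALSE) {
  P <- oracle_f2_table(r)
  if (dominant2) P <- cbind(A = P[, 1], C = P[, 2] + P[, 3])
  use <- counts > 0
  if (any(P[use] <= 0)) return(-Inf)
  sum(counts[use] * log(P[use]))
}

# genotype matrix built from explicit code vectors
toy_gm <- function(markers, positions, trait = NULL, codings = NULL) {
  n <- length(markers[[1]])
  df <- data.frame(id = sprintf("P%03d", seq_len(n)), markers,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(trait)) df$trait <- trait
  cods <- codings %||% stats::setNames(
    c(rep("codominant", length(markers)), if (!is.null(trait)) "dominant"),
    c(names(markers), if (!is.null(trait)) "trait"))
  genotype_matrix(df, positions = positions, codings = cods)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
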