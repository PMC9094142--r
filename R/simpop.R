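# Population simulator: gametes, F2 and F2:3 populations, sequencing pools.
#
# The crossover model is Poisson count + uniform placement (no interference),
# the model under which Haldane's mapping function is exact. Phase is always
# known: populations derive from inbred parents, so every plant stores its two
# haplotypes explicitly (0 = P1 allele, 1 = P2 allele).

new_population <- function(id, hapA, hapB, phenotype, generation, genome, locus,
                           parent = NA_character_) {
  structure(list(id = id, hapA = hapA, hapB = hapB,
                 genotype = hapA + hapB, phenotype = phenotype,
                 generation = generation, genome = genome, locus = locus,
                 parent = parent),
            class = "bsa_population")
}

#' @export
print.bsa_population <- function(x, ...) {
  tab <- table(x$phenotype)
  cat(sprintf("%s population: %d plants x %d SNPs; phenotypes: %s\n",
              x$generation, length(x$id), ncol(x$genotype),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
length.bsa_population <- function(x) length(x$id)

causal_index <- function(genome, locus) {
  ci <- match(locus$position_bp, genome$snp_positions)
  if (is.na(ci))
    stopf("causal position %d is not among the genome's SNP positions",
          locus$position_bp)
  ci
}

# Vectorised gamete engine. hap1/hap2 are the parent's two phased haplotypes
# (0/1 per SNP). Returns an n x m integer matrix with attribute "crossovers".
sim_gametes <- function(hap1, hap2, genome, n) {
  pos <- genome$snp_positions
  m <- length(pos)
  morgans <- genome$length_bp / 1e6 * genome$cm_per_mb / 100
  k <- stats::rpois(n, morgans)
  start <- sample.int(2L, n, replace = TRUE) - 1L   # which haplotype leads
  out <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    if (k[i] == 0L) {
      out[i, ] <- if (start[i] == 0L) hap1 else hap2
    } else {
      breaks <- sort(stats::runif(k[i], 1, genome$length_bp))
      sel <- (start[i] + findInterval(pos, breaks)) %% 2L
      out[i, ] <- ifelse(sel == 0L, hap1, hap2)
    }
  }
  attr(out, "crossovers") <- k
  out
}

#' Simulate one gamete from a phased parent
#'
#' Crossover count is Poisson with mean equal to the chromosome's map length
#' in Morgans (`length_bp/1e6 * cm_per_mb / 100`); crossover positions are
#' uniform on the chromosome (no interference). The returned haplotype
#' alternates parental origin at each crossover.
#'
#' @param parent a list with phased haplotypes `hap1` and `hap2` (0/1 vectors
#'   over the genome's SNPs). A plain `genotype` vector is accepted only if it
#'   contains no heterozygous site (phase would otherwise be unknown).
#' @param genome a [genome_model()].
#' @param seed optional RNG seed.
#' @return integer vector of per-SNP alleles in \{0, 1\}, with attribute
#'   `crossovers` giving the crossover count.
#' @export
simulate_gamete <- function(parent, genome, seed = NULL) {
  if (is.null(parent$hap1) || is.null(parent$hap2)) {
    g <- parent$genotype %||% parent
    if (any(g == 1L))
      stopf(paste("parent has heterozygous sites but no phased haplotypes;",
                  "phase is only known for plants built from inbred parents",
                  "(F1/F2 context)"))
    parent <- list(hap1 = as.integer(g / 2L), hap2 = as.integer(g / 2L))
  }
  with_seed(seed, {
    g <- sim_gametes(parent$hap1, parent$hap2, genome, 1L)
    structure(as.integer(g[1L, ]), crossovers = attr(g, "crossovers"))
  })
}

assign_phenotype <- function(dosage_p2, locus) {
  dom_dosage <- if (locus$dominant_parent == "P2") dosage_p2 else 2L - dosage_p2
  ifelse(dom_dosage >= 1L, locus$phenotypes[["dominant"]],
         locus$phenotypes[["recessive"]])
}

#' Simulate an F2 population
#'
#' Each F2 plant is the union of two independent F1 gametes (the F1 is
#' heterozygous at every SNP, phase P1-haplotype/P2-haplotype). Phenotypes are
#' assigned from the causal-locus dosage with complete penetrance, so the
#' dominant:recessive ratio converges to 3:1.
#'
#' @param n number of plants.
#' @param genome a [genome_model()].
#' @param locus a [causal_locus()]; its position must be one of the genome's
#'   SNPs.
#' @param seed optional RNG seed.
#' @return a `bsa_population` with fields `id`, `hapA`, `hapB`, `genotype`
#'   (P2-allele dosage matrix, plants x SNPs) and `phenotype`.
#' @export
make_f2 <- function(n, genome, locus, seed = NULL) {
  if (!is_count(n)) stopf("'n' must be a positive integer")
  ci <- causal_index(genome, locus)
  m <- length(genome$snp_positions)
  f1_h1 <- rep(0L, m); f1_h2 <- rep(1L, m)
  with_seed(seed, {
    hapA <- sim_gametes(f1_h1, f1_h2, genome, n)
    hapB <- sim_gametes(f1_h1, f1_h2, genome, n)
    phen <- assign_phenotype(hapA[, ci] + hapB[, ci], locus)
    new_population(sprintf("F2_%05d", seq_len(n)), hapA, hapB, phen,
                   "F2", genome, locus)
  })
}

#' Self selected F2 plants into an F2:3 recombinant screen
#'
#' Emulates a large F2:3 screen: F2 parents that are heterozygous at both
#' flanking markers are selfed; offspring genotypes and phenotypes are
#' assigned as in [make_f2()]. Parents not heterozygous at both flanks are
#' excluded with a warning.
#'
#' @param pop an F2 `bsa_population`.
#' @param flanks numeric length-2 vector of flanking marker positions (must be
#'   SNP positions of the population's genome).
#' @param n_offspring_total total number of F2:3 seedlings to simulate,
#'   distributed uniformly at random over the eligible parents.
#' @param parents optional indices/ids of candidate F2 parents (default: all).
#' @param seed optional RNG seed.
#' @return a `bsa_population` of generation `"F2:3"`; field `parent` records
#'   each offspring's F2 parent id.
#' @export
make_f23_screen <- function(pop, flanks, n_offspring_total, parents = NULL,
                            seed = NULL) {
  stopifnot(inherits(pop, "bsa_population"))
  if (!is_count(n_offspring_total)) stopf("'n_offspring_total' must be >= 1")
  fi <- match(flanks, pop$genome$snp_positions)
  if (anyNA(fi)) stopf("flanking positions must be SNP positions of the genome")
  idx <- if (is.null(parents)) seq_along(pop$id)
         else if (is.character(parents)) match(parents, pop$id)
         else as.integer(parents)
  if (anyNA(idx)) stopf("unknown parent id(s)")
  het <- pop$genotype[idx, fi[1]] == 1L & pop$genotype[idx, fi[2]] == 1L
  if (any(!het)) {
    warnf("excluding %d parent(s) not heterozygous at both flanking markers: %s",
          sum(!het), paste(utils::head(pop$id[idx[!het]], 5), collapse = ", "))
    idx <- idx[het]
  }
  if (length(idx) == 0L) stopf("no eligible heterozygous F2 parents remain")
  ci <- causal_index(pop$genome, pop$locus)
  with_seed(seed, {
    par_of <- idx[sample.int(length(idx), n_offspring_total, replace = TRUE)]
    m <- length(pop$genome$snp_positions)
    hapA <- matrix(0L, n_offspring_total, m)
    hapB <- matrix(0L, n_offspring_total, m)
    for (p in unique(par_of)) {
      rows <- which(par_of == p)
      hapA[rows, ] <- sim_gametes(pop$hapA[p, ], pop$hapB[p, ], pop$genome,
                                  length(rows))
      hapB[rows, ] <- sim_gametes(pop$hapA[p, ], pop$hapB[p, ], pop$genome,
                                  length(rows))
    }
    phen <- assign_phenotype(hapA[, ci] + hapB[, ci], pop$locus)
    new_population(sprintf("F23_%05d", seq_len(n_offspring_total)),
                   hapA, hapB, phen, "F2:3", pop$genome, pop$locus,
                   parent = pop$id[par_of])
  })
}

#' Specification of one phenotype-selected sequencing pool
#'
#' @param n_plants number of plants pooled.
#' @param mean_depth mean sequencing depth per site (reads/site).
#' @param phenotype phenotype label selecting the plants.
#' @return a `pool_spec` object.
#' @export
pool_spec <- function(n_plants = 30, mean_depth = 60, phenotype) {
  if (!is_count(n_plants)) stopf("'n_plants' must be a positive integer")
  if (!is.numeric(mean_depth) || mean_depth <= 0)
    stopf("'mean_depth' must be positive")
  structure(list(n_plants = as.integer(n_plants), mean_depth = mean_depth,
                 phenotype = as.character(phenotype)), class = "pool_spec")
}

sample_pool_counts <- function(pop, spec) {
  sel <- which(pop$phenotype == spec$phenotype)
  if (length(sel) < spec$n_plants)
    stopf("pool '%s' needs %d plants but only %d have that phenotype (short by %d)",
          spec$phenotype, spec$n_plants, length(sel),
          spec$n_plants - length(sel))
  take <- sel[sample.int(length(sel), spec$n_plants)]
  p_alt <- colSums(pop$genotype[take, , drop = FALSE]) / (2 * spec$n_plants)
  depth <- stats::rpois(length(p_alt), spec$mean_depth)  # floor 0: depth-0 sites kept
  alt <- stats::rbinom(length(p_alt), depth, p_alt)
  list(ref = depth - alt, alt = alt)
}

#' Build the two phenotype-selected pools and their pooled variant table
#'
#' For each SNP the pool allele frequency is `p = sum(dosage)/(2 n)`, site
#' depth is Poisson(`mean_depth`) (depth-0 sites are emitted so downstream
#' filters are exercised) and the alt read count is Binomial(depth, p). The
#' `low` pool is the recessive-phenotype bulk and the `high` pool the
#' dominant-phenotype bulk; `alt` is the P2 allele.
#'
#' @param pop an F2 `bsa_population`.
#' @param low,high [pool_spec()]s for the recessive and dominant bulks;
#'   defaults use 30 plants at 60x, selecting the locus's phenotype labels.
#' @param seed optional RNG seed.
#' @return a `pooled_variants` data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `ref_low`, `alt_low`, `ref_high`, `alt_high`.
#' @export
make_pools <- function(pop, low = NULL, high = NULL, seed = NULL) {
  stopifnot(inherits(pop, "bsa_population"))
  low <- low %||% pool_spec(30, 60, pop$locus$phenotypes[["recessive"]])
  high <- high %||% pool_spec(30, 60, pop$locus$phenotypes[["dominant"]])
  with_seed(seed, {
    cl <- sample_pool_counts(pop, low)
    ch <- sample_pool_counts(pop, high)
    pooled_variants(
      data.frame(chrom = pop$genome$chrom, pos = pop$genome$snp_positions,
                 ref = pop$genome$ref, alt = pop$genome$alt,
                 ref_low = cl$ref, alt_low = cl$alt,
                 ref_high = ch$ref, alt_high = ch$alt,
                 stringsAsFactors = FALSE),
      chrom_length = pop$genome$length_bp,
      pools = list(low = low, high = high))
  })
}

#' Construct a pooled variant table
#'
#' Validates and classes a data frame of biallelic SNPs with per-pool
#' ref/alt read depths for exactly two pools (`low` = recessive bulk,
#' `high` = dominant bulk).
#'
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ref_low`, `alt_low`, `ref_high`, `alt_high`.
#' @param chrom_length optional chromosome length (bp) carried as an
#'   attribute for windowing.
#' @param pools optional list of pool metadata.
#' @return the validated data frame with class `pooled_variants`.
#' @export
pooled_variants <- function(df, chrom_length = NULL, pools = NULL) {
  need <- c("chrom", "pos", "ref", "alt",
            "ref_low", "alt_low", "ref_high", "alt_high")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  depths <- as.matrix(df[, c("ref_low", "alt_low", "ref_high", "alt_high")])
  if (any(depths < 0)) stopf("read depths must be non-negative")
  if (any(df$pos < 1)) stopf("positions must be >= 1")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, chrom_length = chrom_length, pools = pools,
            class = c("pooled_variants", "data.frame"))
}

#' Extract an F2 marker-genotype matrix from a simulated population
#'
#' Converts P2-allele dosages at selected SNP positions into the A/H/B marker
#' codes used for linkage and fine mapping (A = P1 homozygote, H =
#' heterozygote, B = P2 homozygote), and the phenotype into the dominant-trait
#' codes A/C (A = recessive phenotype, C = dominant class).
#'
#' @param pop a `bsa_population`.
#' @param marker_positions SNP positions to use as markers.
#' @param marker_names optional marker names (default `M01`, `M02`, ...).
#' @param trait name of the trait column (default `"trait"`).
#' @return a `genotype_matrix` (see [genotype_matrix()]).
#' @export
as_genotype_matrix <- function(pop, marker_positions, marker_names = NULL,
                               trait = "trait") {
  stopifnot(inherits(pop, "bsa_population"))
  mi <- match(marker_positions, pop$genome$snp_positions)
  if (anyNA(mi)) stopf("marker positions must be SNP positions of the genome")
  marker_names <- marker_names %||% sprintf("M%02d", seq_along(mi))
  codes <- matrix(c("A", "H", "B")[pop$genotype[, mi, drop = FALSE] + 1L],
                  nrow = length(pop$id),
                  dimnames = list(NULL, marker_names))
  df <- data.frame(id = pop$id, codes,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df[[trait]] <- ifelse(pop$phenotype == pop$locus$phenotypes[["recessive"]],
                        "A", "C")
  positions <- stats::setNames(as.numeric(marker_positions), marker_names)
  codings <- stats::setNames(c(rep("codominant", length(mi)), "dominant"),
                             c(marker_names, trait))
  genotype_matrix(df, positions = positions, codings = codings)
}
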