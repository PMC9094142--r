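# Umbrella pipeline: simulate -> segregate -> bsa -> linkage -> finemap ->
# candidate gene. Every stage writes its table with a provenance header and
# logs parameters, seeds and record counts; a failure halts with a
# stage-named error.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full mapping pipeline on simulated data
#'
#' Executes the stage order of a mapping-by-sequencing study at desk scale:
#' population and pool simulation, segregation test, delta-SNP-index profile
#' with null CIs and candidate-region calling, marker-trait linkage map,
#' F2:3 recombinant screening with interval refinement, and candidate-gene
#' variant annotation. All outputs are written under `out_dir`; reruns with
#' identical configuration and seed produce byte-identical files.
#'
#' @param config a configuration list (see [default_config()]) or a path to a
#'   DCF config file.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config's seed when non-NULL.
#' @return (invisibly) a list with the main stage results and output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  out <- function(f) file.path(out_dir, f)

  # -- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    genome <- desk_genome(n_snps = cfg$n_snps, length_bp = cfg$length_bp,
                          cm_per_mb = cfg$cm_per_mb,
                          causal_pos = cfg$causal_pos, chrom = cfg$chrom,
                          seed = derive_seed(cfg$seed, 1))
    locus <- causal_locus(cfg$causal_pos, cfg$dominant_parent,
                          c(dominant = cfg$phenotype_dominant,
                            recessive = cfg$phenotype_recessive))
    pop <- make_f2(cfg$n_f2, genome, locus, seed = derive_seed(cfg$seed, 2))
    pools <- make_pools(pop,
                        low = pool_spec(cfg$pool_n, cfg$pool_depth,
                                        cfg$phenotype_recessive),
                        high = pool_spec(cfg$pool_n, cfg$pool_depth,
                                         cfg$phenotype_dominant),
                        seed = derive_seed(cfg$seed, 3))
    log_msg("simulate", sprintf("n_f2=%d n_snps=%d seed=%d",
                                length(pop), length(genome$snp_positions),
                                cfg$seed))
    paths$pools_tsv <- write_pooled_tsv(pools, out("pooled_variants.tsv"),
                                         cfg, cfg$seed)
    paths$pools_vcf <- write_pooled_vcf(pools, out("pooled_variants.vcf"),
                                         cfg, cfg$seed)
    list(genome = genome, locus = locus, pop = pop, pools = pools)
  })

  # -- segregate --------------------------------------------------------
  seg <- stage("segregate", {
    counts <- c(sum(sim$pop$phenotype == cfg$phenotype_dominant),
                sum(sim$pop$phenotype == cfg$phenotype_recessive))
    res <- chi_square_gof(counts, c(3, 1))
    write_tsv_with_header(as.data.frame(res), out("segregation.tsv"),
                          provenance_header(cfg, cfg$seed))
    res
  })

  # -- bsa --------------------------------------------------------------
  bsa <- stage("bsa", {
    prof <- bsa_profile(sim$pools, pool_sizes = c(cfg$pool_n, cfg$pool_n),
                        window_bp = cfg$window_bp, step_bp = cfg$step_bp,
                        min_depth = cfg$min_depth, low_cut = cfg$low_cut,
                        high_cut = cfg$high_cut, rule = cfg$filter_rule,
                        n_reps = cfg$n_reps, call_level = cfg$call_level,
                        seed = derive_seed(cfg$seed, 4))
    hdr <- provenance_header(cfg, cfg$seed)
    note <- "#delta=index_low-index_high (recessive minus dominant bulk; alt=P2 allele)"
    paths$snps <- write_tsv_with_header(prof$snps, out("snp_index.tsv"),
                                         c(hdr, note))
    paths$windows <- write_tsv_with_header(prof$windows, out("windows.tsv"),
                                            c(hdr, note))
    paths$regions_bed <- write_bed(prof$regions, out("candidate_regions.bed"))
    rpt <- sprintf("%s:%.0f-%.0f (%.1f Mb, sign %+d, level %.2f)",
                   prof$regions$chrom, prof$regions$start, prof$regions$end,
                   prof$regions$length_bp / 1e6, prof$regions$sign,
                   prof$regions$confidence_level)
    writeLines(c(hdr, "#candidate regions", rpt), out("candidate_regions.txt"))
    prof
  })

  # -- linkage ----------------------------------------------------------
  lnk <- stage("linkage", {
    if (nrow(bsa$regions) == 0) stopf("no candidate region to place markers in")
    reg <- bsa$regions[which.max(abs(bsa$regions$peak_delta)), ]
    pos <- sim$genome$snp_positions
    cand <- pos[pos >= reg$start & pos <= reg$end]
    mk <- unique(c(cand[round(seq(1, length(cand),
                                  length.out = cfg$n_markers))],
                   cfg$causal_pos))
    gm <- as_genotype_matrix(sim$pop, sort(mk),
                             sprintf("SC_%02d", seq_along(mk)))
    paths$genotypes <- write_genotype_tsv(gm, out("genotypes_f2.tsv"),
                                           cfg, cfg$seed)
    map <- trait_map(gm)
    paths$map <- write_tsv_with_header(map, out("trait_map.tsv"),
                                        provenance_header(cfg, cfg$seed))
    list(gm = gm, map = map)
  })

  # -- finemap ----------------------------------------------------------
  fm <- stage("finemap", {
    map <- lnk$map
    coseg <- map$marker[map$cosegregating]
    if (length(coseg) == 0)
      coseg <- map$marker[which.min(map$r_hat)]
    pos <- stats::setNames(map$pos_bp, map$marker)
    ci <- range(pos[coseg])
    left <- map$marker[max(which(map$pos_bp < ci[1]), 1)]
    right <- map$marker[min(which(map$pos_bp > ci[2]), nrow(map))]
    flanks <- c(pos[[left]], pos[[right]])
    current <- genomic_interval(cfg$chrom, flanks[1], flanks[2])
    f23 <- make_f23_screen(sim$pop, flanks, cfg$n_f23,
                           parents = which(sim$pop$genotype[
                             , match(flanks[1], sim$genome$snp_positions)] == 1L &
                             sim$pop$genotype[
                             , match(flanks[2], sim$genome$snp_positions)] == 1L),
                           seed = derive_seed(cfg$seed, 5))
    inner <- sim$genome$snp_positions[
      sim$genome$snp_positions >= flanks[1] &
        sim$genome$snp_positions <= flanks[2]]
    inner <- unique(sort(c(
      inner[round(seq(1, length(inner),
                      length.out = min(cfg$n_finemap_markers, length(inner))))],
      cfg$causal_pos)))
    gm23 <- as_genotype_matrix(f23, inner, sprintf("FM_%02d", seq_along(inner)))
    rec <- screen_recombinants(gm23, "FM_01",
                               sprintf("FM_%02d", length(inner)))
    refined <- refine_interval(rec, current)
    paths$finemap_bed <- write_bed(refined, out("finemap_interval.bed"))
    writeLines(c(provenance_header(cfg, cfg$seed),
                 sprintf("#recombinants=%d", nrow(rec)),
                 sprintf("%s:%.0f-%.0f (%.1f kb)", refined$chrom, refined$start,
                         refined$end, refined$length_bp / 1e3)),
               out("finemap_interval.txt"))
    list(interval = refined, recombinants = rec)
  })

  # -- candidate gene ---------------------------------------------------
  cand <- stage("candgene", {
    fixture <- synthetic_ppo_gene()
    eff <- do.call(rbind, lapply(seq_len(nrow(fixture$variants)), function(i) {
      v <- fixture$variants[i, ]
      annotate_variant(fixture$model, v$cds_pos, v$ref_base, v$alt_base,
                       v$name)
    }))
    paths$effects <- write_tsv_with_header(eff, out("variant_effects.tsv"),
                                            provenance_header(cfg, cfg$seed))
    paths$cds <- write_cds_fasta(fixture$model, out("candidate_cds.fasta"))
    list(gene = fixture$model, effects = eff)
  })

  log_msg("pipeline", sprintf("complete; outputs in %s", out_dir))
  invisible(list(config = cfg, simulate = sim, segregation = seg, bsa = bsa,
                 linkage = lnk, finemap = fm, candgene = cand, paths = paths))
}
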