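Package: bsamap
Title: Bulked Segregant Analysis, Linkage and Fine Mapping of Single-Locus Traits
Version: 1.0.0
Authors@R:
    person("bsamap", "Developers", email = "bsamap@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mapping a single dominant
    Mendelian locus in a biparental cross. Simulates F2 and F2:3 populations
    with a Poisson (no-interference) crossover model, phenotype-selected
    sequencing bulks and depth-sampled pooled allele counts; computes per-SNP
    and sliding-window SNP-index and delta-SNP-index profiles with
    simulation-based null confidence intervals and calls candidate regions;
    estimates two-point recombination fractions and LOD scores in F2 designs
    with Haldane map distances; refines candidate intervals by recombinant
    (substitution) mapping; and annotates candidate-gene coding variants,
    haplotype-phenotype concordance and relative expression (2^-ddCt).
    Includes chi-square segregation tests, minimal VCF/BED/TSV interchange and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
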