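# CDS translation, variant-effect annotation, haplotype concordance, ddCt.

test_that("translation handles hand-checkable cases and strand symmetry", {
  expect_equal(translate_cds("ATGTTTTAA"), "MF")
  expect_warning(translate_cds("TTTTAA"), "ATG")
  expect_warning(translate_cds("ATGTAATTT"), "internal stop")
  expect_error(translate_cds("ATGTNTTAA"), "position 5")
  expect_error(translate_cds("ATGTT"), "divisible")
  # reverse-strand gene model gives the same protein as its forward twin
  seq_fwd <- "ATGGCTAAGTAA"
  gseq <- paste0("NNN", seq_fwd, "NNN")  # padding never touched by exons
  gseq <- gsub("N", "G", gseq)
  fwd <- gene_model("g+", strand = "+",
                    exons = data.frame(start = 4, end = 15), genome_seq = gseq)
  rseq <- paste0("GGG", bsamap:::revcomp(seq_fwd), "GGG")
  rev <- gene_model("g-", strand = "-",
                    exons = data.frame(start = 4, end = 15), genome_seq = rseq)
  expect_equal(splice_and_translate(fwd), splice_and_translate(rev))
  expect_equal(splice_and_translate(fwd), "MAK")
})

test_that("translation matches Biostrings on random codons", {
  set.seed(2024)
  codons <- names(bsamap:::STANDARD_CODE)
  picks <- sample(codons, 1000, replace = TRUE)
  # avoid premature stops by translating codon-by-codon prefixed with ATG
  for (chunk in split(picks, ceiling(seq_along(picks) / 50))) {
    body <- chunk[bsamap:::STANDARD_CODE[chunk] != "*"]
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    mine <- suppressWarnings(translate_cds(cds))
    oracle <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(paste0(mine, "*"), oracle)
  }
})

test_that("the synthetic PPO fixture matches its printed structural facts", {
  fx <- synthetic_ppo_gene()
  expect_equal(unname(fx$model$widths), c(482, 862))
  expect_equal(nchar(fx$model$cds_seq), 1344)
  expect_equal(nchar(fx$model$cds_seq) / 3, 448)  # codons incl. stop
  prot <- splice_and_translate(fx$model)
  expect_equal(nchar(prot), 447)
  # effect classes of the four variants
  eff <- do.call(rbind, lapply(seq_len(4), function(i) {
    v <- fx$variants[i, ]
    annotate_variant(fx$model, v$cds_pos, v$ref_base, v$alt_base, v$name)
  }))
  expect_equal(eff$synonymous, c(FALSE, TRUE, FALSE, FALSE))
  # 670: codon 224 position 1, Leu -> Phe
  expect_equal(eff$codon_index[1], 224)
  expect_equal(eff$codon_pos[1], 1)
  expect_equal(eff$ref_aa[1], "L")
  expect_equal(eff$alt_aa[1], "F")
  # 822: third position of codon 274 (822 = 3 * 274)
  expect_equal(eff$codon_index[2], 274)
  expect_equal(eff$codon_pos[2], 3)
})

test_that("annotate_variant validates coordinates and reference bases", {
  fx <- synthetic_ppo_gene()
  expect_error(annotate_variant(fx$model, 0, "A", "T"), "outside")
  expect_error(annotate_variant(fx$model, 670, "G", "T"),
               "expected C, given G")
  # four-fold degenerate third-position change is synonymous
  m <- gene_model("t", exons = data.frame(start = 1, end = 9),
                  cds_seq = "ATGGGGTAA")
  ann <- annotate_variant(m, 6, "G", "T")
  expect_true(ann$synonymous)
  expect_equal(ann$alt_codon, "GGT")
})

test_that("synonymous flags agree with full-CDS retranslation on random variants", {
  fx <- synthetic_ppo_gene()
  cds <- fx$model$cds_seq
  set.seed(31)
  n_ok <- 0
  for (k in seq_len(1000)) {
    p <- sample.int(nchar(cds) - 3, 1)  # spare the stop codon
    ref <- substr(cds, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ann <- annotate_variant(fx$model, p, ref, alt)
    mutated <- cds
    substr(mutated, p, p) <- alt
    oracle_syn <- identical(suppressWarnings(translate_cds(mutated)),
                            suppressWarnings(translate_cds(cds)))
    # a non-synonymous single change can also truncate (stop gain); the flag
    # must match the full retranslation diff exactly
    expect_identical(ann$synonymous, oracle_syn)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 1000)
})

test_that("CDS/genomic converters round-trip across the intron", {
  fx <- synthetic_ppo_gene()
  pos <- c(1, 482, 483, 670, 1344)
  gpos <- cds_to_genomic(fx$model, pos)
  # exon2 starts 1570 bp after exon1 ends
  expect_equal(gpos[3] - gpos[2], 1571)
  expect_equal(genomic_to_cds(fx$model, gpos), pos)
  expect_error(genomic_to_cds(fx$model, fx$model$exons$end[1] + 1),
               "not exonic")
})

test_that("haplotype classification reproduces the two-haplotype pattern", {
  hapY <- c("C", "G", "C", "G")
  hapB <- c("T", "T", "T", "A")
  het <- paste(hapY, hapB, sep = "/")
  calls <- data.frame(
    id = sprintf("S%02d", 1:89),
    rbind(matrix(hapY, 52, 4, byrow = TRUE),
          matrix(hapB, 13, 4, byrow = TRUE),
          matrix(het, 24, 4, byrow = TRUE)),
    stringsAsFactors = FALSE)
  names(calls)[2:5] <- paste0("v", c(670, 822, 887, 931))
  phen <- c(rep("yellow", 52), rep("black", 13), rep("black", 24))
  cls <- classify_haplotypes(calls, phen, dominant_label = "black")
  expect_equal(cls$concordance, 1.0)
  expect_equal(sort(cls$groups$haplotype), c("C-G-C-G", "T-T-T-A"))
  expect_equal(cls$groups$phenotype[cls$groups$haplotype == "C-G-C-G"],
               "yellow")
  het_rows <- cls$assignments$zygosity == "heterozygous"
  expect_equal(sum(het_rows), 24)
  # het pair is phased against the two known haplotypes (incl. the G/A site
  # where alphabetic sorting would scramble phase)
  expect_true(all(cls$assignments$hap1[het_rows] == "C-G-C-G"))
  expect_true(all(cls$assignments$hap2[het_rows] == "T-T-T-A"))
  # label permutation destroys concordance
  phen_shuf <- with_seed(5, sample(phen))
  cls2 <- classify_haplotypes(calls, phen_shuf, dominant_label = "black")
  expect_lt(cls2$concordance, 1.0)
  # duplicate ids are an error
  calls2 <- calls; calls2$id[2] <- calls2$id[1]
  expect_error(classify_haplotypes(calls2, phen, "black"), "duplicate")
})

test_that("relative expression implements 2^-ddCt", {
  expect_equal(relative_expression(20, 20, 20, 20), 1)   # ddCt = 0
  expect_equal(relative_expression(19, 20, 20, 20), 2)   # ddCt = -1
  expect_equal(relative_expression(25, 20, 24, 20), 0.5) # ddCt = 1
  expect_equal(relative_expression(c(20, 19), c(20, 20), 20, 20), c(1, 2))
  expect_error(relative_expression(NA, 20, 20, 20), "finite")
})
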