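# Candidate-gene layer: CDS splicing and translation, variant-effect
# annotation, haplotype grouping with phenotype concordance, and the
# 2^-ddCt relative-expression helper.

# Standard genetic code, written out so translation does not depend on any
# other package (tests check it against an independent implementation).
STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

check_acgt <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0)
    stopf("non-ACGT character '%s' in %s at position %d",
          substr(seq, bad, bad), what, bad)
  invisible(seq)
}

#' Gene model with exon structure and spliced CDS
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with 1-based inclusive `start`/`end` columns, in
#'   genomic order.
#' @param cds_seq spliced CDS sequence (5'->3' on the coding strand); if
#'   omitted, it is extracted from `genome_seq`.
#' @param genome_seq chromosome sequence (character) to splice from.
#' @return an object of class `gene_model`; the CDS length must equal the
#'   summed exon lengths and be divisible by 3.
#' @export
gene_model <- function(gene_id, chrom = "chr3", strand = c("+", "-"), exons,
                       cds_seq = NULL, genome_seq = NULL) {
  strand <- match.arg(strand)
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (any(exons$end < exons$start)) stopf("exon end < start")
  if (is.unsorted(exons$start, strictly = TRUE))
    stopf("exons must be given in increasing genomic order")
  widths <- exons$end - exons$start + 1
  if (is.null(cds_seq)) {
    if (is.null(genome_seq)) stopf("provide either 'cds_seq' or 'genome_seq'")
    parts <- substring(genome_seq, exons$start, exons$end)
    cds_seq <- paste(parts, collapse = "")
    if (strand == "-") cds_seq <- revcomp(cds_seq)
  }
  cds_seq <- toupper(cds_seq)
  check_acgt(cds_seq, "CDS")
  if (nchar(cds_seq) != sum(widths))
    stopf("CDS length (%d) does not match summed exon lengths (%d)",
          nchar(cds_seq), sum(widths))
  if (nchar(cds_seq) %% 3 != 0)
    stopf("CDS length %d is not divisible by 3", nchar(cds_seq))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, widths = widths, cds_seq = cds_seq),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d exon(s) of %s bp, CDS %d bp (%d codons)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              paste(x$widths, collapse = "+"), nchar(x$cds_seq),
              nchar(x$cds_seq) / 3))
  invisible(x)
}

#' Translate a CDS with the standard genetic code
#'
#' Translation stops at the first stop codon; an internal (non-terminal) stop
#' triggers a warning, as does a CDS not starting with ATG.
#'
#' @param cds_seq nucleotide string, length divisible by 3.
#' @return the protein sequence (stop codon not included).
#' @export
translate_cds <- function(cds_seq) {
  cds_seq <- toupper(cds_seq)
  check_acgt(cds_seq, "CDS")
  if (nchar(cds_seq) %% 3 != 0) stopf("CDS length is not divisible by 3")
  n <- nchar(cds_seq) / 3
  codons <- substring(cds_seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  if (codons[1] != "ATG") warnf("CDS does not start with ATG")
  aa <- unname(STANDARD_CODE[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    if (stop_at[1] < n)
      warnf("internal stop codon at codon %d; translation truncated", stop_at[1])
    aa <- aa[seq_len(stop_at[1] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Splice and translate a gene model
#'
#' @param model a [gene_model()].
#' @return protein sequence from [translate_cds()].
#' @export
splice_and_translate <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  translate_cds(model$cds_seq)
}

#' Convert spliced-CDS coordinates to genomic coordinates (and back)
#'
#' @param model a [gene_model()].
#' @param cds_pos 1-based position within the spliced CDS.
#' @return genomic 1-based position.
#' @export
cds_to_genomic <- function(model, cds_pos) {
  L <- nchar(model$cds_seq)
  if (any(cds_pos < 1 | cds_pos > L)) stopf("cds_pos outside [1, %d]", L)
  # walk exons in transcription order
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  w <- ex$end - ex$start + 1
  offs <- c(0, cumsum(w))
  vapply(cds_pos, function(p) {
    i <- max(which(offs < p))
    within <- p - offs[i]
    if (model$strand == "+") ex$start[i] + within - 1
    else ex$end[i] - within + 1
  }, numeric(1))
}

#' @rdname cds_to_genomic
#' @param genomic_pos 1-based genomic position within an exon.
#' @export
genomic_to_cds <- function(model, genomic_pos) {
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  w <- ex$end - ex$start + 1
  offs <- c(0, cumsum(w))
  vapply(genomic_pos, function(g) {
    i <- which(g >= ex$start & g <= ex$end)
    if (length(i) != 1L) stopf("position %d is not exonic", g)
    within <- if (model$strand == "+") g - ex$start[i] + 1 else ex$end[i] - g + 1
    offs[i] + within
  }, numeric(1))
}

#' Annotate the coding effect of a CDS variant
#'
#' Locates the affected codon (`codon_index = ceiling(cds_pos/3)`,
#' `codon_pos = ((cds_pos-1) mod 3) + 1`), substitutes the alternative base
#' and re-translates that codon.
#'
#' @param model a [gene_model()].
#' @param cds_pos 1-based position within the spliced CDS.
#' @param ref_base,alt_base reference and alternative bases; `ref_base` must
#'   match the model's CDS at `cds_pos`.
#' @param name optional variant name.
#' @return one-row data frame: `name`, `cds_pos`, `ref_base`, `alt_base`,
#'   `codon_index`, `codon_pos`, `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `synonymous`.
#' @export
annotate_variant <- function(model, cds_pos, ref_base, alt_base, name = NULL) {
  stopifnot(inherits(model, "gene_model"))
  L <- nchar(model$cds_seq)
  if (cds_pos < 1 || cds_pos > L) stopf("cds_pos %d outside [1, %d]", cds_pos, L)
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  have <- substr(model$cds_seq, cds_pos, cds_pos)
  if (have != ref_base)
    stopf("reference mismatch at CDS position %d: expected %s, given %s",
          cds_pos, have, ref_base)
  codon_index <- ceiling(cds_pos / 3)
  codon_pos <- ((cds_pos - 1) %% 3) + 1
  ref_codon <- substr(model$cds_seq, 3 * codon_index - 2, 3 * codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_base
  ref_aa <- unname(STANDARD_CODE[ref_codon])
  alt_aa <- unname(STANDARD_CODE[alt_codon])
  data.frame(name = name %||% sprintf("%s:%d", model$gene_id, cds_pos),
             cds_pos = cds_pos, ref_base = ref_base, alt_base = alt_base,
             codon_index = codon_index, codon_pos = codon_pos,
             ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa,
             synonymous = ref_aa == alt_aa, stringsAsFactors = FALSE)
}

#' Group samples by haplotype and measure phenotype concordance
#'
#' Samples scored at a set of coding variants are grouped by haplotype
#' string. Homozygous samples define the known haplotypes; heterozygous
#' samples (any `X/Y` call) are phased against the known haplotypes and
#' stored as an unordered pair. Each haplotype's phenotype is the majority
#' phenotype of its homozygous carriers; a sample's predicted phenotype is
#' its haplotype's phenotype if homozygous, and the dominant label if its two
#' haplotypes disagree (complete dominance). Concordance is the fraction of
#' classifiable samples whose observed phenotype matches the prediction.
#'
#' @param calls data frame with an `id` column and one column per variant;
#'   entries are single bases (`"C"`) or unordered het calls (`"C/T"`).
#'   Duplicate ids are an error; samples with missing calls are excluded with
#'   a log entry.
#' @param phenotype character vector of phenotype labels, parallel to
#'   `calls` rows.
#' @param dominant_label which phenotype label is dominant.
#' @return list with `assignments` (per sample: haplotypes, zygosity,
#'   predicted and observed phenotype, concordant flag), `groups` (per
#'   haplotype: size among homozygotes, assigned phenotype) and `concordance`
#'   in [0, 1].
#' @export
classify_haplotypes <- function(calls, phenotype, dominant_label) {
  if (!"id" %in% names(calls)) stopf("'calls' needs an 'id' column")
  if (anyDuplicated(calls$id))
    stopf("conflicting duplicate sample ids: %s",
          paste(unique(calls$id[duplicated(calls$id)]), collapse = ", "))
  if (length(phenotype) != nrow(calls))
    stopf("'phenotype' length must match rows of 'calls'")
  vcols <- setdiff(names(calls), "id")
  if (length(vcols) == 0L) stopf("no variant columns")
  cm <- as.matrix(calls[, vcols, drop = FALSE])
  missing <- apply(cm, 1, function(x) any(is.na(x) | x == "" | x == "."))
  if (any(missing)) {
    log_msg("classify_haplotypes",
            sprintf("excluding %d sample(s) with missing calls", sum(missing)))
    cm <- cm[!missing, , drop = FALSE]
    ids <- calls$id[!missing]; phen <- phenotype[!missing]
  } else {
    ids <- calls$id; phen <- phenotype
  }
  het_row <- apply(cm, 1, function(x) any(grepl("/", x, fixed = TRUE)))
  hap_str <- function(x) paste(x, collapse = "-")
  known <- unique(apply(cm[!het_row, , drop = FALSE], 1, hap_str))
  n <- length(ids)
  h1 <- h2 <- character(n)
  for (i in seq_len(n)) {
    if (!het_row[i]) {
      h1[i] <- h2[i] <- hap_str(cm[i, ])
    } else {
      alleles <- strsplit(cm[i, ], "/", fixed = TRUE)
      fits <- function(a, b) all(mapply(function(al, x, y) setequal(al, unique(c(x, y))),
                                        alleles, strsplit(a, "-")[[1]],
                                        strsplit(b, "-")[[1]]))
      pair <- NULL
      if (length(known) >= 2) {
        combos <- utils::combn(known, 2, simplify = FALSE)
        hit <- Filter(function(pr) fits(pr[1], pr[2]), combos)
        if (length(hit) == 1L) pair <- sort(hit[[1]])
      }
      if (is.null(pair)) {
        # unphaseable against known haplotypes: keep the genotype string
        g <- vapply(alleles, function(a) paste(sort(a), collapse = "/"), "")
        h1[i] <- h2[i] <- hap_str(g)
      } else {
        h1[i] <- pair[1]; h2[i] <- pair[2]
      }
    }
  }
  hom_tab <- table(haplotype = h1[!het_row], phenotype = phen[!het_row])
  groups <- data.frame(haplotype = rownames(hom_tab),
                       n_homozygous = as.integer(rowSums(hom_tab)),
                       phenotype = colnames(hom_tab)[max.col(hom_tab, "first")],
                       stringsAsFactors = FALSE)
  hap_phen <- stats::setNames(groups$phenotype, groups$haplotype)
  predicted <- vapply(seq_len(n), function(i) {
    p1 <- hap_phen[h1[i]]; p2 <- hap_phen[h2[i]]
    if (is.na(p1) || is.na(p2)) return(NA_character_)
    if (p1 == p2) unname(p1) else dominant_label
  }, "")
  concordant <- predicted == phen
  assignments <- data.frame(id = ids, hap1 = h1, hap2 = h2,
                            zygosity = ifelse(h1 == h2, "homozygous",
                                              "heterozygous"),
                            predicted = predicted, phenotype = phen,
                            concordant = concordant, stringsAsFactors = FALSE)
  list(assignments = assignments, groups = groups,
       concordance = mean(concordant, na.rm = TRUE))
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddCt = (ct_target_sample - ct_ref_sample) - (ct_target_calib -
#' ct_ref_calib)`; the fold change is `2^-ddCt`.
#'
#' @param ct_target_sample,ct_ref_sample Ct of the target and reference gene
#'   in the sample of interest.
#' @param ct_target_calib,ct_ref_calib Ct of target and reference gene in the
#'   calibrator sample.
#' @return fold change(s), vectorised over inputs.
#' @export
relative_expression <- function(ct_target_sample, ct_ref_sample,
                                ct_target_calib, ct_ref_calib) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_calib, ct_ref_calib)
  if (any(!is.finite(cts))) stopf("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) - (ct_target_calib - ct_ref_calib)
  2^(-ddct)
}

#' Synthetic polyphenol-oxidase candidate gene fixture
#'
#' A synthetic two-exon PPO-like gene (exons of 482 and 862 bp separated by a
#' 1,570-bp intron; spliced CDS of 1,344 bp = 448 codons) constructed so that
#' four coding SNPs at spliced-CDS positions 670, 822, 887 and 931 reproduce
#' the canonical effect pattern of the bitter-gourd seed-coat PPO candidate:
#' 670 C>T is non-synonymous (Leu>Phe), 822 G>T is synonymous, and 887 C>T
#' and 931 G>A are non-synonymous. All other codons are synthetic filler —
#' the true gene sequence is not reproduced.
#'
#' @param seed RNG seed for the filler codons (default 101).
#' @return list with elements `model` (a [gene_model()]) and `variants`
#'   (data frame `name`, `cds_pos`, `ref_base`, `alt_base`).
#' @export
synthetic_ppo_gene <- function(seed = 101) {
  n_codons <- 448L  # 1344 / 3, includes the terminal stop
  codons <- with_seed(seed, {
    pool <- names(STANDARD_CODE)[STANDARD_CODE != "*"]
    sample(pool, n_codons, replace = TRUE)
  })
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  codons[224] <- "CTT"  # 670-672: C670T -> TTT, Leu->Phe
  codons[274] <- "GCG"  # 820-822: G822T -> GCT, Ala->Ala (synonymous)
  codons[296] <- "TCA"  # 886-888: C887T -> TTA, Ser->Leu
  codons[311] <- "GAA"  # 931-933: G931A -> AAA, Glu->Lys
  cds <- paste(codons, collapse = "")
  # genomic placement inside the fine-mapped region: exon1 482 bp,
  # intron 1570 bp, exon2 862 bp
  e1s <- 14765101
  exons <- data.frame(start = c(e1s, e1s + 482 + 1570),
                      end = c(e1s + 481, e1s + 482 + 1570 + 861))
  model <- gene_model("MCPPO_SYN", chrom = "chr3", strand = "+",
                      exons = exons, cds_seq = cds)
  variants <- data.frame(
    name = paste0("SNP_PPO:", c(670, 822, 887, 931)),
    cds_pos = c(670, 822, 887, 931),
    ref_base = c("C", "G", "C", "G"),
    alt_base = c("T", "T", "T", "A"),
    stringsAsFactors = FALSE)
  list(model = model, variants = variants)
}
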