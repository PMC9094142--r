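---
title: "Mapping a dominant seed-coat locus: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant seed-coat locus: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

bsamap implements the forward-genetics chain used to clone single-gene
qualitative traits in crop plants — exemplified by seed-coat colour, where a
black coat is typically dominant over yellow and, in several cucurbits, maps
to a polyphenol-oxidase (PPO) gene. This vignette is the package's own
account of the underlying models, the tunable parameters and the design
decisions that were genuinely open. It states no empirical result that the
test suite does not itself compute.

## 1. The genetic model

All analyses assume a biparental cross between two inbred lines (P1, P2),
an F1, and an F2 (optionally an F2:3 generation selfed from chosen F2
plants). The trait is controlled by one locus with complete dominance: any
plant carrying at least one dominant allele shows the dominant phenotype.
Under this model

* the F2 segregates 3:1 (dominant:recessive) — tested by
  `chi_square_gof()`;
* plants of the recessive phenotype are homozygous for the
  recessive-parent allele at the locus; dominant-phenotype plants are 1/3
  homozygous and 2/3 heterozygous;
* consequently, in phenotype-selected sequencing bulks the expected
  alternative-allele (P2) frequency at the causal locus is 0 in the
  recessive bulk and 2/3 in the dominant bulk, so the expected
  |ΔSNP-index| is 2/3 — the quantity the power tests check.

## 2. The synthetic-data generator (what it emulates, what it does not)

`desk_genome()`, `make_f2()`, `make_f23_screen()` and `make_pools()` state
the world the analysis assumes:

| parameter | default | why |
|---|---|---|
| chromosome length | 25 Mb | geometry of a mid-size pseudochromosome, desk-scaled |
| SNPs | 5,000 | desk-scale stand-in for millions of genome-wide SNPs |
| recombination rate | 3 cM/Mb | a typical plant euchromatic rate; the real map rate of the source chromosome is unpublished, so this is a free parameter, not an estimate |
| causal position | 14.75 Mb | mid-arm placement mirroring the mapped locus |
| bulks | 30 + 30 plants | the classical QTL-seq bulk size |
| depth | Poisson(60) per site | ~60× resequencing; depth-0 sites are emitted so the filter stage is honestly exercised |
| F2 size (power runs) | 240 | see below |
| F2:3 screen | 2,975 seedlings | the fine-mapping screen size of the motivating design |

Crossovers are Poisson-counted with mean equal to the map length in Morgans
and placed uniformly — the no-interference model under which Haldane's
mapping function is exact, keeping the simulator and the linkage module
mutually consistent. All SNPs are fixed-different between parents
(`P1 = ref`, `P2 = alt`), as in crosses between well-separated lines;
polymorphism thinning is left to configuration. Pool counts are
`p = Σdosage/(2n)`, `depth ~ Poisson`, `alt ~ Binomial(depth, p)`.

**F2 size for the power simulations.** A 120-plant F2 yields on average
exactly 30 recessive plants, so requiring a 30-plant recessive bulk would
fail in about half of all seeded runs on feasibility alone. The generator's
power default is `n_f2 = 240`, which makes a 30-plant recessive bulk
available with near certainty while leaving the bulk size and depth at their
stated values. This is a feasibility choice about the simulated world, fixed
once, not a tuning knob.

The generator does **not** model read-level artifacts: sequencing error,
alignment bias, structural variants, segregation distortion, or incomplete
penetrance. A green test therefore establishes that the statistics behave
correctly under the stated sampling model — not that they are robust to
artifacts the model excludes.

## 3. BSA-seq statistics

Per-pool SNP-index is `alt/(ref+alt)`; `delta = index_low − index_high`
(recessive bulk minus dominant bulk, alt = P2 allele, so the causal peak is
negative; the sign convention is written into every output header). Windows
of 1,000 kb advance in 100-kb steps starting at position 1; terminal windows
truncate at the chromosome end; window statistics are unweighted means over
passing SNPs (an alternative — recomputing an index from summed window
depths — is deliberately not the default, as the mean-of-SNPs reading is the
common QTL-seq practice).

**Filter semantics.** The canonical filter excludes SNPs with per-pool depth
below 7 and SNPs with index < 0.3 or > 0.7. Whether the index rule applies
per pool or only when both pools violate it is ambiguous in common usage.
bsamap defaults to the *both-pools* reading: a SNP uninformative in both
bulks carries no signal, while at the causal locus one pool is near 0/1 and
the other near 1/3 — the per-pool ("either") reading would delete exactly
the strongest signal. The either-pool variant remains available
(`rule = "either"`).

**The "bootstrap" CI.** The confidence envelope is a null-model simulation
conditioned on observed depths (Mendelian genotype resampling in each bulk,
then binomial read sampling), not a resampling of observed SNPs: the
question the interval answers is "how far can Δ wander from 0 under no
linkage at this depth?", and only a null simulation provides that envelope.
Quantiles are empirical with linear interpolation; the table is cached per
distinct depth pair, and — being a pure function of pool sizes and the depth
pair — may be precomputed and shared across simulations
(`bsa_profile(ci_table = ...)`). Window-level bounds are the arithmetic mean
of member-SNP bounds: depth-aware and conservative for window means, which
average many SNPs. Windows escaping the envelope are merged (overlapping or
adjacent, same sign) into candidate intervals reported 1-based inclusive;
BED export converts to 0-based half-open.

On a single desk-scale chromosome every SNP is partially linked to the
locus, so the called region is typically a large fraction of the
chromosome; at genome scale, unlinked chromosomes supply the sea of null
windows that keeps called regions narrow. The acceptance surface is
therefore *containment* of the true locus, not the width of the call.

## 4. Linkage

`estimate_rf()` maximises the multinomial likelihood of the 9-class (or
collapsed, for dominant A/C coding) joint F2 genotype table built from
coupling-phase gamete frequencies ((1−r)/2, r/2) over r ∈ [0, 0.5]
(`optimize()`, with the boundary r = 0 checked explicitly so perfect
co-segregation returns exactly 0). Coupling phase is assumed throughout —
both mapping designs derive from inbred parents. Repulsion-phase data drive
r̂ to 0.5 and are reported as unlinked rather than silently refit.
`r̂ = 0.5` maps to infinite Haldane distance and is reported as an
`Inf`/"unlinked" sentinel, never a numeric cap. Missing codes are dropped
pairwise, never imputed. Marker order is taken from physical positions on
the assembled chromosome; regression-based map ordering (as in JoinMap) is
out of scope, so two-point Haldane distances are expected to agree with
published multipoint maps only approximately.

## 5. Fine mapping

`screen_recombinants()` keeps plants whose genotype class differs between
the flanking markers. `refine_interval()` applies substitution-mapping
logic: a recessive plant excludes every marker where it carries a dominant
allele (H or dominant-parent homozygote); a dominant plant excludes only
markers homozygous for the recessive-parent allele — its heterozygous
regions are uninformative under dominance, and using them would import
dominance-masking errors. The refined interval is the maximal marker run
compatible with all recombinants.

**Breakpoints.** True crossover positions are unobserved, so bounds are
placed at inter-marker midpoints (ceiling on the left, floor on the right —
a deterministic tie-break). When the causal position is itself among the
markers (as in the simulated screens), the compatible run contains it and
midpoint bounds can never cut it out, which is why the soundness property
(100% containment) is attainable and asserted exactly. Non-contiguous
compatibility — impossible under complete penetrance — yields the longest
run with a warning; an empty compatible set raises an error naming the
conflicting plants, the signature of a phenotyping error or non-single-gene
inheritance.

## 6. Candidate-gene layer

Variant coordinates are spliced-CDS positions, with converters to and from
genomic coordinates for GFF3 input (the positions of the motivating PPO
variants exceed exon 1's length yet are coding, so they can only be spliced
coordinates). Translation uses a written-out standard genetic code; the
test suite checks it against an independent implementation
(`Biostrings::translate`), and `annotate_variant`'s synonymous flag is
checked against full-CDS retranslation — the dual-route design keeps the
implementation and its oracle separate.

The packaged `synthetic_ppo_gene()` fixture is **synthetic by design**: it
reproduces only the printed structural facts of the motivating candidate
(two exons of 482 + 862 bp, a 1,570-bp intron, variants at spliced
positions 670/822/887/931 with the Leu→Phe, synonymous, and two further
non-synonymous effects); every other codon is seeded filler, because the
true gene sequence is not published in text form.

`classify_haplotypes()` phases heterozygous samples against the haplotypes
observed in homozygotes (naïve per-site allele sorting would scramble phase
at sites whose alleles sort differently), assigns each haplotype the
majority phenotype of its homozygous carriers, and predicts heterozygotes
as dominant when their two haplotypes disagree. Concordance 1.0 means
perfect genotype–phenotype association. `relative_expression()` implements
2^−ΔΔCt.

## 7. Numerical and engineering choices

* Quantiles: type-7 (linear interpolation) everywhere.
* r̂ optimisation: bounded 1-D `optimize()` at tolerance 1e−8 with explicit
  boundary checks; the test suite cross-checks against a 1e−4 grid search.
* Window means: cumulative-sum implementation, O(n + windows), verified
  against a naïve re-enumeration oracle.
* Seeds: every stochastic function takes an explicit seed, evaluated under
  a restore-on-exit RNG guard (`with_seed()`); pipeline stages derive
  per-stage seeds from one base seed (`derive_seed()`); identical seeds
  yield byte-identical output files (timestamps are deliberately excluded
  from provenance headers).
* Readers error with line numbers on malformed fields and count skipped
  multiallelic records; they never coerce silently.
* Config: DCF (`key: value`) via `read.dcf` — base R's native key-value
  format — with strict unknown-key rejection.

## 8. Known limitations

Single chromosome per simulation; no interference, sequencing error or
segregation distortion; fine-mapping assumes complete penetrance and
directly observed phenotypes (no progeny-test deconvolution of
heterozygotes); InDel-index profiles and probabilistic breakpoint posteriors
are out of scope. The 2,000-replicate null CIs used in the bundled
simulations (down from the 10,000 default) trade a little quantile precision
for speed; the full-replicate default remains available.
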