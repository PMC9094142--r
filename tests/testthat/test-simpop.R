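# Population simulator: crossover model, F2/F2:3 construction, pool sampling.

test_that("zero map length gives unrecombined parental gametes", {
  g <- tiny_genome(m = 50, cm_per_mb = 0)
  f1 <- list(hap1 = rep(0L, 50), hap2 = rep(1L, 50))
  for (s in 1:5) {
    gam <- simulate_gamete(f1, g, seed = s)
    expect_true(all(gam == gam[1]))  # one parental haplotype, no switch
  }
})

test_that("unphased heterozygous parent input is refused", {
  g <- tiny_genome(m = 4)
  expect_error(simulate_gamete(list(genotype = c(0L, 1L, 2L, 0L)), g),
               "phase")
  # homozygous genotype-only input is fine
  expect_silent(gam <- simulate_gamete(list(genotype = c(0L, 2L, 2L, 0L)), g,
                                       seed = 1))
  expect_identical(as.integer(gam), c(0L, 1L, 1L, 0L))
})

test_that("crossover counts are Poisson with the map-length mean", {
  # 25 Mb at 3 cM/Mb = 0.75 Morgans
  g <- genome_model(length_bp = 25e6, cm_per_mb = 3, snp_positions = c(1, 25e6))
  f1 <- list(hap1 = c(0L, 0L), hap2 = c(1L, 1L))
  n <- 10000
  k <- with_seed(42, {
    gam <- bsamap:::sim_gametes(f1$hap1, f1$hap2, g, n)
    attr(gam, "crossovers")
  })
  se <- sqrt(0.75 / n)
  expect_lt(abs(mean(k) - 0.75), 3 * se)
})

test_that("recombinant gamete fraction matches Haldane's formula", {
  # two SNPs 10 cM apart: r = (1 - exp(-0.2))/2
  g <- genome_model(length_bp = 4e6, cm_per_mb = 5,
                    snp_positions = c(1e6, 3e6))
  f1 <- list(hap1 = c(0L, 0L), hap2 = c(1L, 1L))
  n <- 20000
  gam <- with_seed(7, bsamap:::sim_gametes(f1$hap1, f1$hap2, g, n))
  rec_frac <- mean(gam[, 1] != gam[, 2])
  r_expect <- (1 - exp(-0.2)) / 2
  se <- sqrt(r_expect * (1 - r_expect) / n)
  expect_lt(abs(rec_frac - r_expect), 3 * se)
})

test_that("F2 populations segregate 3:1 with 1/3 homozygous dominants", {
  g <- tiny_genome(m = 3, causal = 5e5)
  loc <- tiny_locus(5e5)
  pop <- make_f2(10000, g, loc, seed = 11)
  ci <- match(5e5, g$snp_positions)
  dom_frac <- mean(pop$phenotype == "black")
  expect_lt(abs(dom_frac - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  # conditional on the dominant phenotype: 1/3 hom, 2/3 het at the locus
  dos <- pop$genotype[pop$phenotype == "black", ci]
  expect_true(all(dos >= 1))
  hom_frac <- mean(dos == 2L)
  expect_lt(abs(hom_frac - 1 / 3), 3 * sqrt(2 / 9 / length(dos)))
  # recessive plants are homozygous P1
  expect_true(all(pop$genotype[pop$phenotype == "yellow", ci] == 0L))
})

test_that("seeding makes populations and pools reproducible", {
  g <- tiny_genome(m = 20, causal = 5e5)
  loc <- tiny_locus(5e5)
  p1 <- make_f2(147, g, loc, seed = 5)
  p2 <- make_f2(147, g, loc, seed = 5)
  expect_identical(p1$genotype, p2$genotype)
  expect_identical(p1$phenotype, p2$phenotype)
  q1 <- make_pools(p1, seed = 9)
  q2 <- make_pools(p2, seed = 9)
  expect_identical(as.data.frame(q1), as.data.frame(q2))
  p3 <- make_f2(147, g, loc, seed = 6)
  expect_false(identical(p1$genotype, p3$genotype))
})

test_that("unlinked-SNP genotype frequencies calibrate to 1:2:1", {
  g <- tiny_genome(m = 2, length_bp = 4e6, cm_per_mb = 3, causal = 2e6)
  loc <- tiny_locus(2e6)
  pop <- make_f2(6000, g, loc, seed = 21)
  for (j in which(g$snp_positions != 2e6)) {
    tab <- tabulate(pop$genotype[, j] + 1L, 3)
    p <- tab / 6000
    for (k in 1:3) {
      exp_p <- c(0.25, 0.5, 0.25)[k]
      expect_lt(abs(p[k] - exp_p), 3 * sqrt(exp_p * (1 - exp_p) / 6000))
    }
  }
})

test_that("pool construction follows the frequency/depth model", {
  g <- tiny_genome(m = 2, causal = 5e5)
  loc <- tiny_locus(5e5)
  pop <- make_f2(400, g, loc, seed = 31)
  pools <- make_pools(pop, seed = 32)
  ci <- match(5e5, g$snp_positions)
  # allele conservation at every simulated site
  expect_true(all(pools$ref_low + pools$alt_low >= 0))
  si <- compute_snp_index(pools)
  # recessive pool fixed for the P1 (ref) allele at the causal locus
  expect_equal(si$index_low[ci], 0)
  # dominant pool near 2/3 for the P2 allele
  expect_lt(abs(si$index_high[ci] - 2 / 3), 0.2)
  # shortfall is a named error
  expect_error(make_pools(pop, low = pool_spec(10000, 60, "yellow")),
               "short by")
})

test_that("expected delta converges to -2/3 at the causal locus, 0 elsewhere", {
  g <- tiny_genome(m = 2, length_bp = 4e6, causal = 2e6)
  loc <- tiny_locus(2e6)
  deltas <- vapply(1:40, function(s) {
    pop <- make_f2(240, g, loc, seed = 100 + s)
    pv <- make_pools(pop, low = pool_spec(30, 200, "yellow"),
                     high = pool_spec(30, 200, "black"), seed = 200 + s)
    si <- compute_snp_index(pv)
    si$delta[match(2e6, g$snp_positions)]
  }, numeric(1))
  expect_lt(abs(mean(deltas) + 2 / 3), 0.05)
})

test_that("F2:3 selfing follows the two-locus enumeration oracle", {
  # one chromosome, two markers ~10 cM apart; F2 parent het at both
  g <- genome_model(length_bp = 4e6, cm_per_mb = 5,
                    snp_positions = c(1e6, 3e6), ref = "A", alt = "T")
  loc <- causal_locus(1e6, "P2")
  f1_pop <- bsamap:::new_population("F1_1", matrix(0L, 1, 2), matrix(1L, 1, 2),
                                    "black", "F2", g, loc)
  n <- 20000
  off <- make_f23_screen(f1_pop, flanks = c(1e6, 3e6), n_offspring_total = n,
                         seed = 77)
  obs <- table(factor(off$genotype[, 1], 0:2), factor(off$genotype[, 2], 0:2))
  r <- (1 - exp(-0.2)) / 2
  expected <- oracle_f2_table(r) * n
  # chi-square GOF against the enumerated selfing table
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 8))
})

test_that("F2:3 screen excludes non-heterozygous parents and r=0 gives no recombinants", {
  g <- tiny_genome(m = 3, causal = 5e5)
  loc <- tiny_locus(5e5)
  pop <- make_f2(50, g, loc, seed = 3)
  fl <- g$snp_positions[c(1, length(g$snp_positions))]
  het <- pop$genotype[, 1] == 1L & pop$genotype[, ncol(pop$genotype)] == 1L
  if (any(!het)) {
    expect_warning(make_f23_screen(pop, fl, 100, seed = 4), "excluding")
  }
  # r = 0 between flanks: zero-recombination chromosome
  g0 <- tiny_genome(m = 4, cm_per_mb = 0, causal = 5e5)
  loc0 <- tiny_locus(5e5)
  hetpop <- bsamap:::new_population("F1_1", matrix(0L, 1, 5), matrix(1L, 1, 5),
                                    "black", "F2", g0, loc0)
  off <- make_f23_screen(hetpop, g0$snp_positions[c(1, 5)], 2000, seed = 5)
  expect_true(all(off$genotype[, 1] == off$genotype[, 5]))
})

test_that("recombinant count in a tight screen matches 2*N*r expectation", {
  # flanks 42.7 kb apart at 3 cM/Mb: r ~ 0.000128 * 10 = 0.00128
  g <- genome_model(length_bp = 2e5, cm_per_mb = 3,
                    snp_positions = c(80000, 122682), ref = "A", alt = "T")
  loc <- causal_locus(80000, "P2")
  par <- bsamap:::new_population("F2_het", matrix(0L, 1, 2), matrix(1L, 1, 2),
                                 "black", "F2", g, loc)
  n <- 2975
  r <- haldane_r(42.682 * 3 / 1000)  # kb * cM/Mb / 1000 -> cM
  reps <- 20
  counts <- vapply(seq_len(reps), function(s) {
    off <- make_f23_screen(par, c(80000, 122682), n, seed = 400 + s)
    sum(off$genotype[, 1] != off$genotype[, 2])
  }, numeric(1))
  expected <- 2 * n * r
  se <- sqrt(expected / reps)  # Poisson-ish noise on the mean
  expect_lt(abs(mean(counts) - expected), 4 * se)
  expect_lt(expected, 12)  # "a few plants" at this marker spacing
})
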