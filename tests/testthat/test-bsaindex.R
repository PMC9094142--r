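# SNP-index, filtering, windows, null CIs and region calling.

test_that("per-SNP indices follow alt/(ref+alt) with NA at zero depth", {
  pv <- toy_pooled(pos = c(100L, 200L, 300L, 400L),
                   ref_low = c(6L, 0L, 30L, 0L), alt_low = c(6L, 10L, 30L, 0L),
                   ref_high = c(6L, 0L, 30L, 5L), alt_high = c(6L, 10L, 30L, 5L))
  si <- compute_snp_index(pv)
  expect_equal(si$index_low, c(0.5, 1.0, 0.5, NA))
  expect_equal(si$delta[1:3], c(0, 0, 0))
  expect_true(is.na(si$delta[4]))
  expect_false(si$pass_filter[4])
  expect_error(
    compute_snp_index(toy_pooled(ref_low = c(-1L, 0L, 3L))), "non-negative")
})

test_that("index and delta respect their bounds on random pools", {
  for (s in 1:5) {
    dat <- with_seed(s, {
      d <- rpois(200, 30)
      a <- rbinom(200, d, runif(200))
      d2 <- rpois(200, 30)
      a2 <- rbinom(200, d2, runif(200))
      toy_pooled(pos = seq_len(200) * 10L, ref_low = d - a, alt_low = a,
                 ref_high = d2 - a2, alt_high = a2, chrom_length = 3000)
    })
    si <- compute_snp_index(dat)
    ok <- si$pass_filter
    expect_true(all(si$index_low[ok] >= 0 & si$index_low[ok] <= 1))
    expect_true(all(si$index_high[ok] >= 0 & si$index_high[ok] <= 1))
    expect_true(all(abs(si$delta[ok]) <= 1))
  }
})

test_that("the depth and both-pool index filters apply as stated", {
  pv <- toy_pooled(pos = c(100L, 200L, 300L, 400L),
                   # 1: depth 6 in low pool -> depth rule ("less than 7")
                   ref_low = c(3L, 10L, 1L, 10L), alt_low = c(3L, 30L, 9L, 10L),
                   # 2: indices (0.75, 0.75) -> both above 0.7 -> excluded
                   # 3: indices (0.9, 0.33) -> only one pool above -> retained
                   # 4: (0.5, 0.5) retained
                   ref_high = c(20L, 10L, 20L, 15L), alt_high = c(20L, 30L, 10L, 15L))
  si <- compute_snp_index(pv)
  flt <- filter_snps(si)
  expect_equal(flt$pos, c(300L, 400L))
  counts <- attr(flt, "filter_counts")
  expect_equal(unname(counts["removed_depth"]), 1L)
  expect_equal(unname(counts["removed_index"]), 1L)
  # low-index variant of the rule: both pools below 0.3 -> excluded
  pv2 <- toy_pooled(pos = c(100L, 200L),
                    ref_low = c(18L, 10L), alt_low = c(2L, 10L),
                    ref_high = c(16L, 10L), alt_high = c(4L, 10L))
  expect_equal(filter_snps(compute_snp_index(pv2))$pos, 200L)
  # either-pool reading excludes the one-sided SNP too
  flt_e <- filter_snps(si, rule = "either")
  expect_equal(flt_e$pos, 400L)
})

test_that("window tiling matches the stated arithmetic on a 2-Mb chromosome", {
  pv <- toy_pooled(pos = c(1L, 1999999L), ref_low = c(5L, 5L),
                   alt_low = c(5L, 5L), ref_high = c(5L, 5L),
                   alt_high = c(5L, 5L), chrom_length = 2e6)
  si <- compute_snp_index(pv)
  w <- sliding_windows(si, window_bp = 1e6, step_bp = 1e5)
  expect_equal(nrow(w), 20L)
  expect_equal(w$start, seq(1, 1900001, by = 1e5))
  expect_equal(w$end[1], 1e6)
  expect_equal(w$end[20], 2e6)  # terminal truncation
  expect_error(sliding_windows(si, step_bp = 0), "positive")
})

test_that("window means equal brute-force recomputation on a toy SNP set", {
  set.seed(404)
  n <- 50
  pos <- sort(sample.int(2e6, n))
  d <- rpois(n, 40) + 7L
  a <- rbinom(n, d, 0.5)
  d2 <- rpois(n, 40) + 7L
  a2 <- rbinom(n, d2, 0.5)
  pv <- toy_pooled(pos = pos, ref_low = d - a, alt_low = a,
                   ref_high = d2 - a2, alt_high = a2, chrom_length = 2e6)
  si <- compute_snp_index(pv)
  w <- sliding_windows(si, window_bp = 1e6, step_bp = 1e5)
  # naive O(n * windows) oracle
  for (i in seq_len(nrow(w))) {
    inw <- si$pos >= w$start[i] & si$pos <= w$end[i]
    expect_equal(w$n_snps[i], sum(inw))
    if (any(inw)) {
      expect_equal(w$mean_delta[i], mean(si$delta[inw]))
      expect_equal(w$mean_index_low[i], mean(si$index_low[inw]))
    } else {
      expect_true(is.na(w$mean_delta[i]))
    }
  }
  # constant-delta property: every non-empty window mean equals the constant
  si2 <- si; si2$delta <- 0.25
  w2 <- sliding_windows(si2, window_bp = 1e6, step_bp = 1e5)
  expect_true(all(w2$mean_delta[w2$n_snps > 0] == 0.25))
})

test_that("null CI tables are seeded, nested, and narrow with depth", {
  dp <- rbind(c(60, 60), c(1e6, 1e6), c(0, 60))
  ci1 <- bootstrap_null_ci(c(30, 30), dp, n_reps = 2000, seed = 5)
  ci2 <- bootstrap_null_ci(c(30, 30), dp, n_reps = 2000, seed = 5)
  expect_identical(ci1, ci2)  # seeding contract
  ci3 <- bootstrap_null_ci(c(30, 30), dp, n_reps = 2000, seed = 6)
  expect_false(identical(ci1$ci95_hi, ci3$ci95_hi))
  # nesting: 99% interval encloses 95% at every depth pair
  ok <- !is.na(ci1$ci95_lo)
  expect_true(all(ci1$ci99_lo[ok] <= ci1$ci95_lo[ok]))
  expect_true(all(ci1$ci99_hi[ok] >= ci1$ci95_hi[ok]))
  # infinite-depth limit strictly narrower than depth 60
  w60 <- diff(unlist(ci1[ci1$depth_low == 60, c("ci95_lo", "ci95_hi")]))
  winf <- diff(unlist(ci1[ci1$depth_low == 1e6, c("ci95_lo", "ci95_hi")]))
  expect_lt(winf, w60)
  # genotype-sampling-only half-width bound: sd of delta at infinite depth
  # is sqrt(2 * 1/(8*30)); the 95% half-width is near 1.96 * that sd
  sd_geno <- sqrt(2 / (8 * 30))
  expect_lt(abs(winf / 2 - 1.96 * sd_geno), 0.02)
  # zero-depth pair has undefined CI
  expect_true(is.na(ci1$ci95_lo[ci1$depth_low == 0]))
  expect_error(bootstrap_null_ci(c(30, 30), dp, n_reps = 50), ">= 100")
})

test_that("null deltas fall outside their own 95% CI about 5% of the time", {
  # self-consistency at moderate scale (the acceptance suite runs the full
  # 10,000-SNP version)
  n_snps <- 2000
  set.seed(314)
  dl <- rpois(n_snps, 60); dh <- rpois(n_snps, 60)
  p_l <- rbinom(n_snps, 60, 0.5) / 60
  p_h <- rbinom(n_snps, 60, 0.5) / 60
  delta <- rbinom(n_snps, dl, p_l) / dl - rbinom(n_snps, dh, p_h) / dh
  ci <- bootstrap_null_ci(c(30, 30), cbind(dl, dh), n_reps = 4000, seed = 271)
  idx <- match(paste(dl, dh), paste(ci$depth_low, ci$depth_high))
  out <- delta < ci$ci95_lo[idx] | delta > ci$ci95_hi[idx]
  rate <- mean(out, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / n_snps))
})

test_that("region calling merges adjacent significant windows by sign", {
  w <- structure(
    data.frame(chrom = "chr3",
               start = seq(1, 2000001, by = 1e6),
               end = seq(1, 2000001, by = 1e6) + 1e6 - 1,
               n_snps = 5L,
               mean_index_low = 0.5, mean_index_high = 0.5,
               mean_delta = c(0.5, 0.5, -0.5),
               ci95_lo = -0.3, ci95_hi = 0.3,
               stringsAsFactors = FALSE),
    window_bp = 1e6, step_bp = 1e6, chrom_length = 3e6,
    class = c("window_stats", "data.frame"))
  iv <- call_candidate_regions(w, level = 0.95)
  expect_equal(nrow(iv), 2L)        # +peak run and -peak window
  expect_equal(iv$start, c(1, 2000001))
  expect_equal(iv$end, c(2000000, 3000000))
  expect_equal(iv$sign, c(1L, -1L))
  expect_equal(iv$length_bp, c(2e6, 1e6))
  # single significant window: interval 1..1,000,000
  w1 <- w[1, , drop = FALSE]
  class(w1) <- class(w); attr(w1, "window_bp") <- 1e6
  iv1 <- call_candidate_regions(w1, 0.95)
  expect_equal(c(iv1$start, iv1$end, iv1$length_bp), c(1, 1e6, 1e6))
  # nothing significant -> empty interval set, not an error
  w0 <- w; w0$mean_delta <- 0
  expect_equal(nrow(call_candidate_regions(w0, 0.95)), 0L)
})

test_that("interval arithmetic is 1-based inclusive", {
  iv <- genomic_interval("chr3", 11600001, 19355601)
  expect_equal(iv$length_bp, 7755601)
  expect_equal(round(iv$length_bp / 1e6, 1), 7.8)
  iv2 <- genomic_interval("chr3", 14755455, 14798136)
  expect_equal(round(iv2$length_bp / 1e3, 1), 42.7)
  expect_equal(genomic_interval("c", 5, 5)$length_bp, 1)
  expect_error(genomic_interval("c", 10, 5), ">=")
})

test_that("end-to-end profile flags the causal region (single seeded run)", {
  g <- desk_genome(n_snps = 1200, seed = 1)
  pop <- make_f2(240, g, causal_locus(), seed = 2)
  pv <- make_pools(pop, seed = 3)
  prof <- bsa_profile(pv, n_reps = 500, seed = 4)
  expect_gt(nrow(prof$regions), 0)
  hit <- prof$regions$start <= 14.75e6 & prof$regions$end >= 14.75e6
  expect_true(any(hit))
  # causal-window delta magnitude near 2/3
  w <- prof$windows
  iw <- which(w$start <= 14.75e6 & w$end >= 14.75e6)
  expect_lt(abs(mean(abs(w$mean_delta[iw])) - 2 / 3), 0.1)
})
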