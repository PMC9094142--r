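# BSA-seq statistics: SNP-index, filtering, sliding windows, null-simulation
# confidence intervals and candidate-region calling.
#
# Conventions: the SNP-index of a pool is alt/(ref+alt) with alt = the P2
# (dominant-parent by default) allele; delta = index_low - index_high, i.e.
# recessive bulk minus dominant bulk. Near a dominant causal locus the
# recessive bulk is fixed for the P1 allele (index_low -> 0) while the
# dominant bulk has P2-allele frequency 2/3 (index_high -> 2/3), so delta
# approaches -2/3; its magnitude is the quantity of interest. Coordinates are
# 1-based inclusive throughout; BED export converts to 0-based half-open.

#' Per-SNP pool indices and delta
#'
#' Computes each pool's SNP-index `alt/(ref+alt)` and their difference
#' `delta = index_low - index_high`. Pools with zero depth yield an undefined
#' (NA) index and `pass_filter = FALSE`.
#'
#' @param pv a [pooled_variants()] table.
#' @return a `snp_index` data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth_low`, `depth_high`, `index_low`, `index_high`, `delta`,
#'   `pass_filter`.
#' @export
compute_snp_index <- function(pv) {
  stopifnot(inherits(pv, "pooled_variants"))
  dl <- pv$ref_low + pv$alt_low
  dh <- pv$ref_high + pv$alt_high
  il <- ifelse(dl > 0, pv$alt_low / dl, NA_real_)
  ih <- ifelse(dh > 0, pv$alt_high / dh, NA_real_)
  out <- data.frame(chrom = pv$chrom, pos = pv$pos, ref = pv$ref, alt = pv$alt,
                    depth_low = dl, depth_high = dh,
                    index_low = il, index_high = ih,
                    delta = il - ih,
                    pass_filter = dl > 0 & dh > 0,
                    stringsAsFactors = FALSE)
  structure(out, chrom_length = attr(pv, "chrom_length"),
            pools = attr(pv, "pools"),
            class = c("snp_index", "data.frame"))
}

#' Filter SNPs on depth and index informativeness
#'
#' A SNP is excluded if either pool's depth is below `min_depth`, or if its
#' index is below `low_cut` in both pools, or above `high_cut` in both pools
#' (`rule = "both"`, the default: a SNP uninformative in both bulks carries no
#' mapping signal, while a causal-region SNP has one pool near fixation and is
#' kept). `rule = "either"` applies the index cuts per pool instead. Counts of
#' records removed per rule are logged and attached as attribute
#' `filter_counts`.
#'
#' @param si a `snp_index` table from [compute_snp_index()].
#' @param min_depth minimum per-pool depth (default 7: depths below 7 are
#'   excluded).
#' @param low_cut,high_cut index cutoffs (defaults 0.3 and 0.7).
#' @param rule `"both"` (default) or `"either"`; see Details.
#' @return the passing subset of `si`.
#' @export
filter_snps <- function(si, min_depth = 7, low_cut = 0.3, high_cut = 0.7,
                        rule = c("both", "either")) {
  stopifnot(inherits(si, "snp_index"))
  rule <- match.arg(rule)
  il <- si$index_low; ih <- si$index_high
  depth_fail <- si$depth_low < min_depth | si$depth_high < min_depth
  na_fail <- is.na(il) | is.na(ih)
  idx_fail <- if (rule == "both") {
    (il < low_cut & ih < low_cut) | (il > high_cut & ih > high_cut)
  } else {
    (il < low_cut | ih < low_cut) | (il > high_cut | ih > high_cut)
  }
  idx_fail[is.na(idx_fail)] <- FALSE
  fail <- depth_fail | na_fail | idx_fail
  counts <- c(input = nrow(si),
              removed_depth = sum(depth_fail | na_fail),
              removed_index = sum(idx_fail & !(depth_fail | na_fail)),
              passed = sum(!fail))
  log_msg("filter_snps",
          sprintf("input=%d removed_depth=%d removed_index=%d passed=%d rule=%s",
                  counts[1], counts[2], counts[3], counts[4], rule))
  out <- si[!fail, , drop = FALSE]
  out$pass_filter <- TRUE
  rownames(out) <- NULL
  structure(out, chrom_length = attr(si, "chrom_length"),
            pools = attr(si, "pools"), filter_counts = counts,
            class = class(si))
}

window_starts <- function(chrom_length, step_bp) {
  seq.int(1L, chrom_length, by = step_bp)
}

# windowed means of several columns via cumulative sums: O(n + n_windows)
window_means <- function(pos, values, starts, ends) {
  n <- length(pos)
  i0 <- findInterval(starts - 1L, pos) + 1L   # first SNP index in window
  i1 <- findInterval(ends, pos)               # last SNP index in window
  nsnp <- pmax(i1 - i0 + 1L, 0L)
  means <- lapply(values, function(v) {
    cs <- c(0, cumsum(v))
    out <- ifelse(nsnp > 0, (cs[i1 + 1L] - cs[i0]) / nsnp, NA_real_)
    out
  })
  c(list(n_snps = nsnp), means)
}

#' Sliding-window statistics
#'
#' Tiles each chromosome with windows of `window_bp` starting at 1, 1 + step,
#' ... (terminal windows truncated at the chromosome end) and computes the
#' unweighted mean SNP-index of each pool and the mean delta over the passing
#' SNPs in each window. Windows containing no SNP are emitted with
#' `n_snps = 0` and undefined means. Confidence bounds are left unset; see
#' [add_window_ci()].
#'
#' @param si a (filtered) `snp_index` table, sorted by position.
#' @param window_bp window size in bp (default 1,000 kb).
#' @param step_bp step length in bp (default 100 kb); must be positive.
#' @param chrom_length chromosome length; defaults to the table's
#'   `chrom_length` attribute or the maximum SNP position.
#' @return a `window_stats` data frame with columns `chrom`, `start`, `end`,
#'   `n_snps`, `mean_index_low`, `mean_index_high`, `mean_delta`.
#' @export
sliding_windows <- function(si, window_bp = 1e6, step_bp = 1e5,
                            chrom_length = NULL) {
  stopifnot(inherits(si, "snp_index"))
  if (!is.numeric(step_bp) || step_bp <= 0) stopf("'step_bp' must be positive")
  if (!is.numeric(window_bp) || window_bp <= 0)
    stopf("'window_bp' must be positive")
  chrom_length <- chrom_length %||% attr(si, "chrom_length") %||% max(si$pos)
  pieces <- lapply(split(seq_len(nrow(si)), si$chrom), function(rows) {
    sub <- si[rows, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    starts <- window_starts(chrom_length, step_bp)
    ends <- pmin(starts + window_bp - 1, chrom_length)
    wm <- window_means(sub$pos,
                       list(mean_index_low = sub$index_low,
                            mean_index_high = sub$index_high,
                            mean_delta = sub$delta),
                       starts, ends)
    data.frame(chrom = sub$chrom[1], start = starts, end = ends,
               n_snps = wm$n_snps,
               mean_index_low = wm$mean_index_low,
               mean_index_high = wm$mean_index_high,
               mean_delta = wm$mean_delta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, window_bp = window_bp, step_bp = step_bp,
            chrom_length = chrom_length,
            class = c("window_stats", "data.frame"))
}

ci_colnames <- function(levels) {
  lv <- sprintf("ci%02d", round(levels * 100))
  as.vector(rbind(paste0(lv, "_lo"), paste0(lv, "_hi")))
}

#' Null-simulation confidence intervals for delta, per depth pair
#'
#' The "bootstrap" CI of QTL-seq practice: for each replicate and pool, `n`
#' F2 genotypes are drawn from the Mendelian (1/4, 1/2, 1/4) distribution
#' (equivalently, the pooled allele count is Binomial(2n, 1/2)), the pool
#' allele frequency `p` is formed, an alt read count Binomial(depth, p) is
#' drawn, and `delta = index_low - index_high` is computed. Empirical
#' linear-interpolation quantiles of the null delta are stored per distinct
#' (depth_low, depth_high) pair. This is a null envelope around delta = 0
#' conditioned on the observed depths, not a resampling of observed SNPs.
#'
#' @param pool_sizes length-2 integer vector `(n_low, n_high)` of plants per
#'   pool.
#' @param depth_pairs two-column matrix/data frame of observed per-SNP depths
#'   (low, high); only distinct pairs are simulated (cached).
#' @param n_reps number of null replicates (default 10,000; minimum 100).
#' @param levels confidence levels (default 0.95 and 0.99).
#' @param seed optional RNG seed.
#' @param chunk_size maximum simulated values per block (memory control).
#' @return a `ci_table` data frame: `depth_low`, `depth_high`, then
#'   `ci95_lo`, `ci95_hi`, `ci99_lo`, `ci99_hi` (names follow `levels`).
#'   Pairs with a zero depth get NA bounds (CI undefined).
#' @export
bootstrap_null_ci <- function(pool_sizes = c(30, 30), depth_pairs,
                              n_reps = 10000, levels = c(0.95, 0.99),
                              seed = NULL, chunk_size = 5e6) {
  if (length(pool_sizes) != 2L || any(pool_sizes < 1))
    stopf("'pool_sizes' must be two integers >= 1")
  if (n_reps < 100) stopf("'n_reps' must be >= 100")
  dp <- unique(as.data.frame(depth_pairs)[, 1:2])
  names(dp) <- c("depth_low", "depth_high")
  dp <- dp[order(dp$depth_low, dp$depth_high), , drop = FALSE]
  rownames(dp) <- NULL
  probs <- as.vector(vapply(levels,
                            function(l) c((1 - l) / 2, 1 - (1 - l) / 2),
                            numeric(2)))
  qn <- ci_colnames(levels)
  npair <- nrow(dp)
  qmat <- matrix(NA_real_, npair, length(probs), dimnames = list(NULL, qn))
  with_seed(seed, {
    p_low <- stats::rbinom(n_reps, 2L * pool_sizes[1], 0.5) / (2 * pool_sizes[1])
    p_high <- stats::rbinom(n_reps, 2L * pool_sizes[2], 0.5) / (2 * pool_sizes[2])
    ok <- which(dp$depth_low > 0 & dp$depth_high > 0)
    block <- max(1L, floor(chunk_size / n_reps))
    for (b in split(ok, ceiling(seq_along(ok) / block))) {
      k <- length(b)
      size_l <- rep(dp$depth_low[b], each = n_reps)
      size_h <- rep(dp$depth_high[b], each = n_reps)
      d <- stats::rbinom(k * n_reps, size_l, rep.int(p_low, k)) / size_l -
           stats::rbinom(k * n_reps, size_h, rep.int(p_high, k)) / size_h
      dim(d) <- c(n_reps, k)
      qmat[b, ] <- t(apply(d, 2L, stats::quantile, probs = probs,
                           names = FALSE, type = 7))
    }
  })
  out <- cbind(dp, as.data.frame(qmat))
  structure(out, pool_sizes = pool_sizes, n_reps = n_reps, levels = levels,
            class = c("ci_table", "data.frame"))
}

#' Attach per-SNP null CI bounds from a CI table
#'
#' @param si a `snp_index` table.
#' @param ci a `ci_table` from [bootstrap_null_ci()] covering the SNPs' depth
#'   pairs.
#' @return `si` with the CI bound columns appended.
#' @export
attach_snp_ci <- function(si, ci) {
  stopifnot(inherits(si, "snp_index"), inherits(ci, "ci_table"))
  key <- paste(si$depth_low, si$depth_high)
  idx <- match(key, paste(ci$depth_low, ci$depth_high))
  if (anyNA(idx))
    stopf("%d depth pair(s) missing from the CI table; recompute it from these SNPs",
          sum(is.na(idx)))
  qn <- setdiff(names(ci), c("depth_low", "depth_high"))
  for (cl in qn) si[[cl]] <- ci[[cl]][idx]
  structure(si, chrom_length = attr(si, "chrom_length"),
            pools = attr(si, "pools"), levels = attr(ci, "levels"),
            class = class(si))
}

#' Window-level confidence bounds
#'
#' The window CI is the arithmetic mean of the member SNPs' per-depth null CI
#' bounds — conservative and depth-aware. (An alternative, quantiles of
#' simulated window means, can be built by windowing simulated deltas; the
#' mean-of-bounds default follows standard QTL-seq practice.)
#'
#' @param windows a `window_stats` table from [sliding_windows()].
#' @param si the `snp_index` table (with CI columns from [attach_snp_ci()])
#'   that produced the windows.
#' @return `windows` with mean CI bound columns appended.
#' @export
add_window_ci <- function(windows, si) {
  stopifnot(inherits(windows, "window_stats"), inherits(si, "snp_index"))
  qn <- grep("^ci[0-9]+_(lo|hi)$", names(si), value = TRUE)
  if (length(qn) == 0) stopf("no CI columns on 'si'; call attach_snp_ci() first")
  for (ch in unique(windows$chrom)) {
    wi <- windows$chrom == ch
    sub <- si[si$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    wm <- window_means(sub$pos, as.list(sub[qn]),
                       windows$start[wi], windows$end[wi])
    for (cl in qn) windows[[cl]][wi] <- wm[[cl]]
  }
  windows
}

#' One-based inclusive genomic interval(s)
#'
#' @param chrom chromosome name(s).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param confidence_level optional confidence level annotation.
#' @param sign optional sign of the peak (+1/-1).
#' @return a `genomic_interval` data frame with `length_bp = end - start + 1`.
#' @export
genomic_interval <- function(chrom, start, end, confidence_level = NA_real_,
                             sign = NA_integer_) {
  if (any(end < start)) stopf("interval end must be >= start")
  n <- length(chrom)
  out <- data.frame(chrom = chrom, start = as.numeric(start),
                    end = as.numeric(end),
                    length_bp = as.numeric(end) - as.numeric(start) + 1,
                    sign = rep_len(sign, n),
                    confidence_level = rep_len(confidence_level, n),
                    stringsAsFactors = FALSE)
  structure(out, class = c("genomic_interval", "data.frame"))
}

#' Call candidate regions from significant windows
#'
#' A window is significant when its mean delta lies outside its null CI at the
#' requested level. Overlapping or adjacent significant windows of the same
#' sign are merged; each merged run is reported as one interval spanning the
#' first window start to the last window end. Positive and negative peaks are
#' both reported with their sign. No significant window yields an empty list.
#'
#' @param windows a `window_stats` table with CI columns
#'   (see [add_window_ci()]).
#' @param level confidence level to call at (default 0.95); the matching
#'   `ciXX_lo/hi` columns must be present.
#' @return a `genomic_interval` data frame (possibly 0 rows) with `sign`,
#'   `n_windows` and `peak_delta` columns.
#' @export
call_candidate_regions <- function(windows, level = 0.95) {
  stopifnot(inherits(windows, "window_stats"))
  lo <- sprintf("ci%02d_lo", round(level * 100))
  hi <- sprintf("ci%02d_hi", round(level * 100))
  if (!all(c(lo, hi) %in% names(windows)))
    stopf("windows lack %s/%s columns; run add_window_ci() at that level", lo, hi)
  w <- windows[!is.na(windows$mean_delta) & !is.na(windows[[lo]]), , drop = FALSE]
  sig <- w$mean_delta < w[[lo]] | w$mean_delta > w[[hi]]
  w <- w[sig, , drop = FALSE]
  empty <- genomic_interval(character(), numeric(), numeric())
  empty$n_windows <- integer(); empty$peak_delta <- numeric()
  if (nrow(w) == 0) return(empty)
  w$sign <- ifelse(w$mean_delta > 0, 1L, -1L)
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  res <- list()
  cur <- NULL
  flush <- function(cur) genomic_interval(cur$chrom, cur$start, cur$end,
                                          confidence_level = level,
                                          sign = cur$sign)
  for (i in seq_len(nrow(w))) {
    row <- w[i, ]
    if (!is.null(cur) && row$chrom == cur$chrom && row$sign == cur$sign &&
        row$start <= cur$end + 1) {
      cur$end <- max(cur$end, row$end)
      cur$n_windows <- cur$n_windows + 1L
      if (abs(row$mean_delta) > abs(cur$peak_delta)) cur$peak_delta <- row$mean_delta
    } else {
      if (!is.null(cur)) res[[length(res) + 1L]] <- cur
      cur <- list(chrom = row$chrom, start = row$start, end = row$end,
                  sign = row$sign, n_windows = 1L, peak_delta = row$mean_delta)
    }
  }
  res[[length(res) + 1L]] <- cur
  out <- do.call(rbind, lapply(res, function(cur) {
    iv <- flush(cur)
    iv$n_windows <- cur$n_windows
    iv$peak_delta <- cur$peak_delta
    iv
  }))
  rownames(out) <- NULL
  out
}

#' End-to-end BSA-seq profile from a pooled variant table
#'
#' Convenience wrapper: index computation, filtering, sliding windows, null
#' CI simulation on the observed depth pairs, window CIs and candidate-region
#' calls.
#'
#' @param pv a [pooled_variants()] table.
#' @param pool_sizes plants per pool `(n_low, n_high)`.
#' @param window_bp,step_bp window geometry (defaults 1 Mb / 100 kb).
#' @param min_depth,low_cut,high_cut,rule filter settings; see
#'   [filter_snps()].
#' @param n_reps null replicates (default 10,000).
#' @param levels confidence levels.
#' @param call_level level at which regions are called.
#' @param seed RNG seed for the null simulation.
#' @param ci_table optional precomputed [bootstrap_null_ci()] table covering
#'   the observed depth pairs (e.g. shared across simulations).
#' @return list with elements `snps` (filtered, CI-annotated), `windows`,
#'   `regions` and `filter_counts`.
#' @export
bsa_profile <- function(pv, pool_sizes = c(30, 30), window_bp = 1e6,
                        step_bp = 1e5, min_depth = 7, low_cut = 0.3,
                        high_cut = 0.7, rule = "both", n_reps = 10000,
                        levels = c(0.95, 0.99), call_level = 0.95,
                        seed = NULL, ci_table = NULL) {
  si <- compute_snp_index(pv)
  flt <- filter_snps(si, min_depth = min_depth, low_cut = low_cut,
                     high_cut = high_cut, rule = rule)
  ci <- ci_table %||% bootstrap_null_ci(pool_sizes,
                                        flt[, c("depth_low", "depth_high")],
                                        n_reps = n_reps, levels = levels,
                                        seed = seed)
  flt <- attach_snp_ci(flt, ci)
  win <- sliding_windows(flt, window_bp = window_bp, step_bp = step_bp)
  win <- add_window_ci(win, flt)
  regions <- call_candidate_regions(win, level = call_level)
  list(snps = flt, windows = win, regions = regions,
       filter_counts = attr(flt, "filter_counts"))
}
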