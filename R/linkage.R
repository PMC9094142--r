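# Two-point F2 linkage: recombination-fraction ML estimation, LOD scores,
# Haldane distances, marker grouping and the marker-to-trait map.
#
# Coupling phase is assumed (both parents inbred); the joint F2 genotype
# distribution at two loci follows from coupling-phase gamete frequencies
# (1-r)/2 (parental) and r/2 (recombinant). Dominant scoring collapses the
# het and P2-homozygote classes into class "C".

# 3x3 joint F2 genotype probabilities; rows/cols are P2-allele dosage 0/1/2
# (codes A/H/B) at locus 1/2.
f2_joint_probs <- function(r) {
  gam <- matrix(c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2), 2, 2)
  P <- matrix(0, 3, 3, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
  for (a1 in 0:1) for (a2 in 0:1) for (b1 in 0:1) for (b2 in 0:1)
    P[a1 + b1 + 1L, a2 + b2 + 1L] <- P[a1 + b1 + 1L, a2 + b2 + 1L] +
      gam[a1 + 1L, a2 + 1L] * gam[b1 + 1L, b2 + 1L]
  P
}

collapse_probs <- function(P, coding1, coding2) {
  if (coding1 == "dominant")
    P <- rbind(A = P["A", ], C = P["H", ] + P["B", ])
  if (coding2 == "dominant")
    P <- cbind(A = P[, "A"], C = P[, "H"] + P[, "B"])
  P
}

coding_levels <- function(coding) {
  switch(coding, codominant = c("A", "H", "B"), dominant = c("A", "C"),
         stopf("unknown coding '%s'", coding))
}

#' Estimate the recombination fraction between two F2 columns
#'
#' Builds the joint F2 genotype class table from coupling-phase gamete
#' frequencies, collapses classes according to each column's coding
#' (codominant A/H/B or dominant A/C), and maximises the multinomial
#' log-likelihood over r in [0, 0.5] by bounded 1-D optimisation.
#' `LOD = log10 L(r_hat) / L(0.5)`. Missing codes (`U`/NA) are dropped
#' pairwise, never imputed. If all jointly scored plants fall in one class
#' the estimate is undefined and flagged.
#'
#' @param g1,g2 genotype code vectors of equal length.
#' @param coding1,coding2 `"codominant"` or `"dominant"`.
#' @return a `two_point` object: `r_hat` in [0, 0.5], `lod`, `cm` (Haldane
#'   distance; `Inf` = unlinked sentinel at r_hat = 0.5), `n`, `counts`,
#'   `degenerate`.
#' @export
estimate_rf <- function(g1, g2, coding1 = "codominant", coding2 = "codominant") {
  if (length(g1) != length(g2)) stopf("genotype columns differ in length")
  keep <- !(g1 %in% "U" | g2 %in% "U" | is.na(g1) | is.na(g2))
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  lev1 <- coding_levels(coding1); lev2 <- coding_levels(coding2)
  if (!all(g1 %in% lev1)) stopf("column 1 has codes outside its coding")
  if (!all(g2 %in% lev2)) stopf("column 2 has codes outside its coding")
  counts <- table(factor(g1, lev1), factor(g2, lev2))
  res <- list(r_hat = NA_real_, lod = NA_real_, cm = NA_real_, n = n,
              counts = counts, coding = c(coding1, coding2),
              degenerate = FALSE)
  class(res) <- "two_point"
  if (n == 0 || sum(counts > 0) <= 1L) {
    res$degenerate <- TRUE
    return(res)
  }
  if (n < 20) warnf("only %d jointly scored plants; estimates will be noisy", n)
  cnt <- as.vector(counts)
  ll <- function(r) {
    p <- as.vector(collapse_probs(f2_joint_probs(r), coding1, coding2))
    use <- cnt > 0
    if (any(p[use] <= 0)) return(-Inf)
    sum(cnt[use] * log(p[use]))
  }
  opt <- stats::optimize(ll, c(0, 0.5), maximum = TRUE, tol = 1e-8)
  cand <- c(0, opt$maximum, 0.5)
  llv <- vapply(cand, ll, numeric(1))
  r_hat <- cand[which.max(llv)]
  ll_half <- llv[3L]
  res$r_hat <- r_hat
  res$lod <- max(0, (max(llv) - ll_half) / log(10))
  res$cm <- if (r_hat >= 0.5) Inf else haldane_cm(r_hat)
  res
}

#' @export
print.two_point <- function(x, ...) {
  if (x$degenerate) {
    cat("two-point estimate: degenerate (all plants in one class)\n")
  } else {
    cat(sprintf("two-point estimate: r = %.4f, LOD = %.2f, %s (n = %d)\n",
                x$r_hat, x$lod,
                if (is.finite(x$cm)) sprintf("%.2f cM", x$cm) else "unlinked",
                x$n))
  }
  invisible(x)
}

#' Haldane map distance from a recombination fraction
#'
#' `cM = -50 ln(1 - 2r)`, exact under the no-interference (Poisson) crossover
#' model. `r = 0.5` has infinite map distance and returns `Inf` with a
#' warning (the "unlinked" sentinel); `r < 0` or `r > 0.5` is an error.
#'
#' @param r recombination fraction(s) in [0, 0.5].
#' @return map distance(s) in centimorgans.
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r > 0.5)) stopf("recombination fraction must be in [0, 0.5]")
  if (any(r == 0.5)) warnf("r = 0.5 has infinite Haldane distance (unlinked)")
  ifelse(r == 0.5, Inf, -50 * log(1 - 2 * r))
}

#' Inverse Haldane function
#'
#' @param cm map distance(s) in centimorgans (>= 0).
#' @return recombination fraction(s) `r = (1 - exp(-cm/50))/2`.
#' @export
haldane_r <- function(cm) {
  if (any(cm < 0)) stopf("map distance must be non-negative")
  (1 - exp(-cm / 50)) / 2
}

#' All pairwise two-point estimates among markers
#'
#' @param gm a [genotype_matrix()].
#' @param markers marker names (default: all positioned markers).
#' @return data frame `marker1`, `marker2`, `r_hat`, `lod`, `cm`.
#' @export
pairwise_rf <- function(gm, markers = NULL) {
  markers <- markers %||% marker_names(gm)
  pairs <- utils::combn(markers, 2)
  out <- apply(pairs, 2, function(pr) {
    tp <- estimate_rf(gm[[pr[1]]], gm[[pr[2]]],
                      marker_coding(gm, pr[1]), marker_coding(gm, pr[2]))
    data.frame(marker1 = pr[1], marker2 = pr[2], r_hat = tp$r_hat,
               lod = tp$lod, cm = tp$cm, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group markers by single-linkage clustering
#'
#' Two markers are linked when `LOD >= lod_min` and `r_hat < r_max`; a marker
#' joins a group if linked to any member (transitive closure).
#'
#' @param results data frame with columns `marker1`, `marker2`, `r_hat`,
#'   `lod` (e.g. from [pairwise_rf()]).
#' @param lod_min LOD threshold (default 3.0).
#' @param r_max recombination-fraction threshold (default 0.4).
#' @return list of character vectors (linkage groups, singletons included),
#'   ordered by group size then first marker.
#' @export
group_markers <- function(results, lod_min = 3, r_max = 0.4) {
  markers <- sort(unique(c(results$marker1, results$marker2)))
  parent <- stats::setNames(seq_along(markers), markers)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  linked <- !is.na(results$r_hat) & results$lod >= lod_min & results$r_hat < r_max
  for (k in which(linked)) {
    i <- find(match(results$marker1[k], markers))
    j <- find(match(results$marker2[k], markers))
    if (i != j) parent[j] <- i
  }
  roots <- vapply(seq_along(markers), find, integer(1))
  groups <- split(markers, roots)
  groups <- groups[order(-lengths(groups),
                         vapply(groups, function(g) g[1], ""))]
  unname(lapply(groups, unname))
}

#' Marker-to-trait two-point map
#'
#' Applies [estimate_rf()] between every marker column and the trait column
#' and reports Haldane distances sorted by physical position. Markers with
#' `r_hat = 0` are flagged as co-segregating. All-missing marker columns are
#' excluded with a log entry.
#'
#' @param gm a [genotype_matrix()] whose trait column is coded A/C.
#' @param trait trait column name (default `"trait"`).
#' @return data frame `marker`, `pos_bp`, `r_hat`, `lod`, `cm`,
#'   `cosegregating`, ordered by position.
#' @export
trait_map <- function(gm, trait = "trait") {
  if (!trait %in% names(gm)) stopf("trait column '%s' not found", trait)
  pos <- marker_positions(gm)
  rows <- lapply(names(pos), function(mk) {
    col <- gm[[mk]]
    if (all(col %in% "U" | is.na(col))) {
      log_msg("trait_map", sprintf("marker %s has no scored plants; excluded", mk))
      return(NULL)
    }
    tp <- estimate_rf(col, gm[[trait]], marker_coding(gm, mk),
                      marker_coding(gm, trait))
    data.frame(marker = mk, pos_bp = pos[[mk]], r_hat = tp$r_hat,
               lod = tp$lod, cm = tp$cm,
               cosegregating = !tp$degenerate && tp$r_hat == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pos_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
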