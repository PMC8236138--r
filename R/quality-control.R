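# Column-standardize a frequency-normalized PFM: each column mapped to
# (x - mean) / sd over its 4 entries, or 0 when the column is uniform
# (zero variance -> correlation contribution 0, documented behaviour).
standardize_columns <- function(pfm) {
  p <- sweep(unclass(pfm), 2L, colSums(unclass(pfm)), "/")
  z <- scale(p)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z[is.na(z)] <- 0
  z
}

# Swap rows to the complementary bases (A<->T, C<->G).
complement_rows <- function(m) m[c(4L, 3L, 2L, 1L), , drop = FALSE]

# Best ungapped alignment statistic given a La x Lb matrix of per-column
# Pearson correlations: max over offsets with >= min_overlap columns of the
# summed correlation along the aligned diagonal divided by max(La, Lb) —
# the mean per-column correlation with unaligned overhang columns counting
# 0, so a short chance overlap cannot outscore a long faithful one.
# Returns stat and offset (b's first column relative to a's, 0-based).
best_diagonal_mean <- function(C, min_overlap = 4L) {
  La <- nrow(C); Lb <- ncol(C)
  best <- -Inf; best_o <- NA_integer_
  for (o in (min_overlap - Lb):(La - min_overlap)) {
    i <- max(1L, 1L + o):min(La, Lb + o)
    v <- sum(C[cbind(i, i - o)]) / max(La, Lb)
    if (v > best) { best <- v; best_o <- o }
  }
  list(stat = best, offset = best_o)
}

#' Motif similarity p-value by column permutation
#'
#' The similarity statistic is the maximum, over all ungapped offsets with
#' at least 4 overlapping columns and both orientations (the second motif
#' reverse-complemented), of the mean per-column Pearson correlation between
#' frequency-normalized columns, taken over `max(La, Lb)` positions so that
#' overhang columns outside the overlap contribute 0 — a short chance
#' overlap cannot outscore a long faithful alignment. Identical motifs
#' score exactly 1. The null distribution is obtained by shuffling the
#' second motif's column order `n_null` times (seeded);
#' `p = (1 + #\{null > observed\} + k) / (n_null + 1)` with `k` drawn
#' uniformly over the block of exact ties, the randomized rank that keeps
#' the permutation p exactly uniform under the null. This plays the role
#' of a Tomtom comparison between the optimized and canonical motifs in
#' the robust-collection filter: same decision semantics (p < 0.05),
#' explicit permutation null.
#'
#' @param pfm_a,pfm_b `pfm` objects, both of length >= 4.
#' @param n_null Number of column-shuffled null motifs (default 1000).
#' @param seed Integer seed for the permutation null.
#' @return List: `p`, `statistic`, `best_offset` (0-based position of
#'   `pfm_b`'s first column relative to `pfm_a`'s), `best_orientation`
#'   (`"+"` or `"-"`).
#' @export
motif_similarity_p <- function(pfm_a, pfm_b, n_null = 1000L, seed = 1L) {
  La <- motif_length(pfm_a); Lb <- motif_length(pfm_b)
  if (La < 4L || Lb < 4L) stop("motifs must have length >= 4")
  Za <- standardize_columns(pfm_a)
  Zb <- standardize_columns(pfm_b)
  # correlation of every a column with every b column / complemented b column
  Cf <- crossprod(Za, Zb) / 3
  Cr <- crossprod(Za, complement_rows(Zb)) / 3
  score_perm <- function(perm) {
    f <- best_diagonal_mean(Cf[, perm, drop = FALSE])
    r <- best_diagonal_mean(Cr[, perm, drop = FALSE][, Lb:1, drop = FALSE])
    if (f$stat >= r$stat) c(f$stat, f$offset, 1) else c(r$stat, r$offset, -1)
  }
  obs <- score_perm(seq_len(Lb))
  p <- with_seed(seed, {
    null <- vapply(seq_len(n_null),
                   function(i) score_perm(sample.int(Lb))[1], numeric(1))
    # ties are common (permutations fixing the best-aligned columns leave
    # the statistic unchanged), so the tied block is broken at random —
    # the randomized rank makes the permutation p exactly uniform under
    # the null instead of lumpy-conservative
    gt <- sum(null > obs[1] + 1e-12)
    eq <- sum(abs(null - obs[1]) <= 1e-12)
    (1 + gt + (sample.int(eq + 1L, 1L) - 1L)) / (n_null + 1)
  })
  list(p = p, statistic = obs[1], best_offset = as.integer(obs[2]),
       best_orientation = if (obs[3] > 0) "+" else "-")
}

#' Summit centrality p-value (CentriMo-style binomial scan)
#'
#' Tests whether hit distances to the peak summit are concentrated near 0.
#' For each candidate central half-width `w` in `5, 10, ...,
#' peak_halfwidth_for_test`, the number of hits within `w` is compared to a
#' Binomial(n, w / halfwidth) null by the exact upper-tail sum; the smallest
#' window p-value is Bonferroni-corrected by the number of windows tested
#' and capped at 1. Hits beyond the test half-width are clipped out (their
#' count is messaged). The multi-window scan with Bonferroni correction
#' keeps the test conservative under uniform (noise) hit placement.
#'
#' @param hits Site data.frame with a `dist_to_summit` column, or a numeric
#'   vector of distances.
#' @param peak_halfwidth_for_test Test half-width in bp (default 250). The
#'   uniform null assumes distances can reach this value, so pass the
#'   maximum achievable distance when peaks are narrower.
#' @return The corrected p-value in (0, 1].
#' @export
centrality_p <- function(hits, peak_halfwidth_for_test = 250) {
  d <- if (is.data.frame(hits)) hits$dist_to_summit else hits
  stopifnot(length(d) > 0L, peak_halfwidth_for_test >= 5)
  clipped <- sum(d > peak_halfwidth_for_test)
  if (clipped > 0L)
    message(clipped, " hit(s) beyond the test half-width clipped out")
  d <- d[d <= peak_halfwidth_for_test]
  if (!length(d)) stop("no hit within the test half-width")
  n <- length(d)
  ws <- seq(5, peak_halfwidth_for_test, by = 5)
  pw <- vapply(ws, function(w) {
    x <- sum(d <= w)
    pbinom(x - 1L, n, w / peak_halfwidth_for_test, lower.tail = FALSE)
  }, numeric(1))
  max(min(1, min(pw) * length(ws)), .Machine$double.xmin)
}

#' Robust-collection quality control
#'
#' Applies the two dataset-level filters: (1) similarity between the
#' optimized and canonical motifs ([motif_similarity_p()]) and (2) summit
#' centrality of the per-peak best hits ([centrality_p()]), each at
#' significance `alpha` (strict inequality). A dataset is robust when both
#' pass. Centrality is evaluated on the best-hit landscape over all peaks —
#' including peaks without a predicted direct site — which is what makes the
#' test informative: zone-filtered calls are concentrated near the summit by
#' construction.
#'
#' @param run List with `optimized_pfm`, `canonical_pfm`, `called_sites`,
#'   and (preferably) `landscape_hits`; when `landscape_hits` is absent the
#'   called sites are used for centrality.
#' @param alpha Significance level (default 0.05).
#' @param peak_halfwidth_for_test Half-width passed to [centrality_p()];
#'   default 250 bp, or the maximum observed distance (rounded up to 5 bp)
#'   when smaller, so narrow peaks do not fake central enrichment.
#' @param n_null,seed Passed to [motif_similarity_p()].
#' @return A list of class `dataset_qc`: `similarity_p`, `centrality_p`,
#'   `similarity_pass`, `centrality_pass`, `robust`.
#' @export
apply_qc <- function(run, alpha = 0.05, peak_halfwidth_for_test = NULL,
                     n_null = 1000L, seed = 1L) {
  stopifnot(!is.null(run$optimized_pfm), !is.null(run$canonical_pfm))
  hits <- run$landscape_hits %||% run$called_sites
  if (is.null(hits) || nrow(hits) == 0L)
    stop("no hits available for the centrality test")
  if (is.null(peak_halfwidth_for_test)) {
    peak_halfwidth_for_test <-
      min(250, max(5, 5 * ceiling(max(hits$dist_to_summit) / 5)))
  }
  sim <- motif_similarity_p(run$optimized_pfm, run$canonical_pfm,
                            n_null = n_null, seed = seed)
  cen <- centrality_p(hits, peak_halfwidth_for_test)
  structure(list(similarity_p = sim$p,
                 centrality_p = cen,
                 similarity_pass = sim$p < alpha,
                 centrality_pass = cen < alpha,
                 robust = sim$p < alpha && cen < alpha),
            class = "dataset_qc")
}

#' @export
print.dataset_qc <- function(x, ...) {
  cat(sprintf(
    "QC: similarity p = %.4g (%s), centrality p = %.4g (%s) -> %s\n",
    x$similarity_p, if (x$similarity_pass) "pass" else "fail",
    x$centrality_p, if (x$centrality_pass) "pass" else "fail",
    if (x$robust) "ROBUST" else "permissive only"))
  invisible(x)
}
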