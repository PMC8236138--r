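#' Per-peak best-hit landscape
#'
#' Scans every peak (both strands, no score floor) and returns exactly one
#' site per scannable peak: the best-scoring window anywhere in the peak.
#' The distance to the summit is measured from the site midpoint (floor) to
#' the summit position. Peaks narrower than the motif, or whose every window
#' contains N, are skipped.
#'
#' @param peaks Peak data.frame (see [read_peaks()]).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param pwm A `pwm` object.
#' @return Site data.frame: `chrom`, `start`, `end` (absolute, 0-based
#'   half-open), `strand`, `score`, `norm_score`, `peak_id`,
#'   `dist_to_summit`.
#' @export
collect_landscape <- function(peaks, genome, pwm) {
  L <- ncol(pwm$weights)
  ok <- peaks$end - peaks$start >= L
  if (!any(ok)) stop("no peak is wide enough to scan (motif length ", L, ")")
  idx <- which(ok)
  seqs <- vapply(idx, function(i)
    get_sequence(genome, peaks$chrom[i], peaks$start[i], peaks$end[i]),
    character(1))
  hits <- scan_best_hits(seqs, pwm)
  found <- !is.na(hits$score)
  idx <- idx[found]; hits <- hits[found, , drop = FALSE]
  if (!length(idx)) stop("no scannable window in any peak")
  abs_start <- peaks$start[idx] + hits$start
  mid <- abs_start + L %/% 2L
  summit <- peaks$start[idx] + peaks$summit_offset[idx]
  data.frame(chrom = peaks$chrom[idx], start = abs_start,
             end = abs_start + L, strand = hits$strand,
             score = hits$score, norm_score = hits$norm_score,
             peak_id = peaks$peak_id[idx],
             dist_to_summit = abs(mid - summit))
}

#' Maximum-entropy (Kapur) threshold of a 1-D distribution
#'
#' Builds an equal-width histogram of `values` over `[min, max]` and selects
#' the bin boundary maximizing the sum of the Shannon entropies of the
#' renormalized histogram below and above the boundary (Kapur's
#' maximum-entropy criterion — the parameter-free rule used to delimit the
#' enrichment zone). The criterion is flat across runs of empty bins, so
#' among tied boundaries the middle one is returned: between two separated
#' modes the threshold lands mid-gap rather than hugging a mode's edge.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param n_bins Number of histogram bins (default 100).
#' @param orientation `"keep_high"` or `"keep_low"` — which side of the
#'   threshold is retained downstream. Recorded on the result; the boundary
#'   itself does not depend on it.
#' @return The threshold (a bin boundary), with attributes `orientation`
#'   and `objective` (the entropy sum at the chosen boundary).
#' @export
max_entropy_threshold <- function(values, n_bins = 100L,
                                  orientation = c("keep_high", "keep_low")) {
  orientation <- match.arg(orientation)
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("need at least 2 distinct values to threshold")
  lo <- min(values); hi <- max(values)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(values, breaks,
                                            rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  p <- counts / sum(counts)
  ent <- function(q) {
    s <- sum(q)
    if (s <= 0) return(0)
    q <- q[q > 0] / s
    -sum(q * log(q))
  }
  obj <- vapply(seq_len(n_bins - 1L), function(k)
    ent(p[seq_len(k)]) + ent(p[(k + 1L):n_bins]), numeric(1))
  tied <- which(obj >= max(obj) - 1e-12)
  k_star <- tied[(length(tied) + 1L) %/% 2L]
  structure(breaks[k_star + 1L], orientation = orientation,
            objective = obj[k_star])
}

#' Learn the dataset-specific enrichment zone
#'
#' Applies [max_entropy_threshold()] independently to the two marginals of
#' the best-hit landscape: normalized PWM scores (high side kept) and
#' distances to the peak summit (low side kept). The zone is the rectangle
#' `{norm_score >= s*} x {dist <= d*}`. With fewer than `min_hits` hits the
#' zone is deemed undefined and an explicit no-zone result is returned —
#' never a silent empty set.
#'
#' @param hits Landscape from [collect_landscape()].
#' @param n_bins Histogram bins for both marginals (default 100).
#' @param min_hits Minimum hits needed to define a zone (default 50).
#' @return An object of class `enrichment_zone`: `defined`,
#'   `score_threshold`, `distance_threshold`, `n_points_used`,
#'   `histogram_bins`.
#' @export
define_enrichment_zone <- function(hits, n_bins = 100L, min_hits = 50L) {
  if (nrow(hits) < min_hits) {
    return(structure(list(defined = FALSE, score_threshold = NA_real_,
                          distance_threshold = NA_real_,
                          n_points_used = nrow(hits),
                          histogram_bins = as.integer(n_bins)),
                     class = "enrichment_zone"))
  }
  s_star <- max_entropy_threshold(hits$norm_score, n_bins, "keep_high")
  d_star <- max_entropy_threshold(hits$dist_to_summit, n_bins, "keep_low")
  structure(list(defined = TRUE,
                 score_threshold = as.numeric(s_star),
                 distance_threshold = as.numeric(d_star),
                 n_points_used = nrow(hits),
                 histogram_bins = as.integer(n_bins)),
            class = "enrichment_zone")
}

#' @export
print.enrichment_zone <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("Enrichment zone: undefined (%d hits < minimum)\n",
                x$n_points_used))
  } else {
    cat(sprintf(
      "Enrichment zone: norm_score >= %.4f & dist_to_summit <= %.1f bp (%d hits, %d bins)\n",
      x$score_threshold, x$distance_threshold, x$n_points_used,
      x$histogram_bins))
  }
  invisible(x)
}

#' Zone membership of sites
#'
#' @param sites Site data.frame with `norm_score` and `dist_to_summit`.
#' @param zone An `enrichment_zone`.
#' @return Logical vector, one entry per site.
#' @export
in_zone <- function(sites, zone) {
  if (!zone$defined) stop("enrichment zone is undefined for this dataset")
  sites$norm_score >= zone$score_threshold &
    sites$dist_to_summit <= zone$distance_threshold
}

#' Call TFBSs: best hit per peak inside the enrichment zone
#'
#' Rescans every peak with the (optimized) PWM, takes the best hit per peak,
#' and emits it if and only if it falls inside the zone — at most one site
#' per peak. Output is sorted by (chrom, start).
#'
#' @param peaks Peak data.frame.
#' @param pwm The `pwm` used for the final rescan (normally the optimized
#'   one).
#' @param zone A defined `enrichment_zone`.
#' @param genome A named [Biostrings::DNAStringSet].
#' @return Site data.frame as in [collect_landscape()], zone-filtered and
#'   sorted.
#' @export
call_tfbs <- function(peaks, pwm, zone, genome) {
  if (!zone$defined) stop("enrichment zone is undefined for this dataset")
  hits <- collect_landscape(peaks, genome, pwm)
  out <- hits[in_zone(hits, zone), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
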