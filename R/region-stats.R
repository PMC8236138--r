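#' Fraction of the genome covered by an interval set
#'
#' Overlapping intervals are merged before summing, so the result is
#' invariant to input order and duplication.
#'
#' @param intervals Interval data.frame (`chrom`, `start`, `end`).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return Covered fraction in `[0, 1]`.
#' @export
genome_coverage <- function(intervals, chrom_lengths) {
  if (nrow(intervals) == 0L) return(0)
  if (!all(intervals$chrom %in% names(chrom_lengths)))
    stop("interval on a chromosome absent from chrom_lengths")
  if (any(intervals$start < 0L |
            intervals$end > chrom_lengths[intervals$chrom]))
    stop("interval out of chromosome bounds")
  m <- merge_intervals(intervals)
  sum(m$end - m$start) / sum(chrom_lengths)
}

#' Chromosome-preserving random re-placement of intervals
#'
#' Each interval is re-placed uniformly at random on its own chromosome with
#' its length preserved (the `bedtools shuffle -chrom` behaviour), so
#' per-chromosome counts and the length multiset are invariant.
#' Deterministic given `seed`.
#'
#' @param intervals Interval data.frame.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param seed Integer seed.
#' @return Shuffled interval data.frame (same row order and extra columns).
#' @export
shuffle_intervals <- function(intervals, chrom_lengths, seed = NULL) {
  if (nrow(intervals) == 0L) return(intervals)
  len <- intervals$end - intervals$start
  room <- chrom_lengths[intervals$chrom] - len
  if (any(room < 0))
    stop("interval longer than its chromosome")
  out <- intervals
  with_seed(seed, {
    out$start <- as.integer(floor(runif(nrow(intervals)) * (room + 1)))
  })
  out$end <- out$start + len
  out
}

interval_midpoints <- function(x) (x$start + x$end) %/% 2L

#' Relative-distance distribution between two interval sets
#'
#' For every midpoint of `setA`, the two flanking `setB` midpoints on the
#' same chromosome are found and the relative distance
#' `min(d_prev, d_next) / (d_prev + d_next)` in `[0, 0.5]` is recorded
#' (the `bedtools reldist` statistic). A midpoints outside B's span are
#' dropped. Spatially unrelated sets give a uniform distribution; co-located
#' sets pile up near 0.
#'
#' @param setA,setB Interval data.frames; `setB` needs >= 2 intervals on
#'   each chromosome considered.
#' @param n_bins Histogram bins over `[0, 0.5]` (default 50).
#' @return List: `values` (the relative distances) and `histogram`
#'   (data.frame `bin_lo`, `bin_hi`, `count`, `fraction`).
#' @export
relative_distance_distribution <- function(setA, setB, n_bins = 50L) {
  vals <- unlist(lapply(intersect(unique(setA$chrom), unique(setB$chrom)),
                        function(ch) {
    b <- sort(interval_midpoints(setB[setB$chrom == ch, , drop = FALSE]))
    if (length(b) < 2L) return(numeric(0))
    a <- interval_midpoints(setA[setA$chrom == ch, , drop = FALSE])
    a <- a[a >= b[1] & a <= b[length(b)]]
    if (!length(a)) return(numeric(0))
    i <- findInterval(a, b)
    at_top <- i == length(b) # exactly on the last midpoint
    rd <- numeric(length(a))
    rd[at_top] <- 0
    if (any(!at_top)) {
      dp <- a[!at_top] - b[i[!at_top]]
      dn <- b[i[!at_top] + 1L] - a[!at_top]
      rd[!at_top] <- pmin(dp, dn) / (dp + dn)
    }
    rd
  }), use.names = FALSE)
  if (!length(vals)) stop("no computable A/B midpoint pair")
  breaks <- seq(0, 0.5, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  list(values = vals,
       histogram = data.frame(bin_lo = breaks[-length(breaks)],
                              bin_hi = breaks[-1], count = counts,
                              fraction = counts / length(vals)))
}

#' Expression specificity of a region across cell types
#'
#' `1 - H(p) / log2(N)` where `p` is the expression vector normalized to sum
#' 1 and `H` its Shannon entropy (`0 * log 0 = 0`): 0 for ubiquitous
#' (uniform) activity, 1 for exclusive (one-hot) activity.
#'
#' @param values Non-negative expression values over `N >= 2` cell types or
#'   tissues, with a positive sum.
#' @return Specificity in `[0, 1]`.
#' @export
specificity <- function(values) {
  stopifnot(length(values) >= 2L, all(values >= 0))
  s <- sum(values)
  if (s <= 0) stop("all-zero expression profile is not scorable")
  p <- values / s
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  1 - h / log2(length(values))
}

#' Number of distinct TFs bound per region
#'
#' @param regions Interval data.frame.
#' @param sites_by_tf Named list (TF -> site data.frame).
#' @return Integer vector, one count per region row.
#' @export
tfs_per_region <- function(regions, sites_by_tf) {
  if (nrow(regions) == 0L) return(integer(0))
  hits <- vapply(sites_by_tf, function(s) overlaps_any(regions, s),
                 logical(nrow(regions)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(regions))
  as.integer(rowSums(hits))
}

#' Pairwise co-localization correlation between site sets
#'
#' Each set is expanded by `expand_bp` on both sides (clipped at 0 and, when
#' `chrom_lengths` is given, at the chromosome end) and self-merged. The
#' intersection-fraction matrix `F[i, j]` — the fraction of set i's merged
#' regions overlapping set j — is then summarized as the Pearson correlation
#' matrix between the rows of `F`.
#'
#' @param site_sets Named list (>= 2) of interval data.frames.
#' @param expand_bp Expansion in bp per side (default 50).
#' @param chrom_lengths Optional named vector to clip expanded intervals.
#' @return List: `correlation` (symmetric, unit diagonal) and `fractions`
#'   (the F matrix).
#' @export
pairwise_colocalization <- function(site_sets, expand_bp = 50L,
                                    chrom_lengths = NULL) {
  stopifnot(length(site_sets) >= 2L, !is.null(names(site_sets)))
  expanded <- lapply(site_sets, function(s) {
    s$start <- pmax(0L, s$start - expand_bp)
    s$end <- s$end + expand_bp
    if (!is.null(chrom_lengths))
      s$end <- pmin(s$end, chrom_lengths[s$chrom])
    merge_intervals(s)
  })
  n <- length(expanded)
  F <- matrix(0, n, n, dimnames = list(names(site_sets), names(site_sets)))
  for (i in seq_len(n)) for (j in seq_len(n))
    F[i, j] <- mean(overlaps_any(expanded[[i]], expanded[[j]]))
  R <- suppressWarnings(cor(t(F)))
  R[is.na(R)] <- 0 # constant rows carry no co-localization signal
  diag(R) <- 1
  list(correlation = R, fractions = F)
}
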