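# Internal interval helpers. All public coordinates are 0-based half-open
# (BED); GRanges is 1-based closed, so conversion is start+1 / end.

as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

granges_to_df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Merge overlapping intervals
#'
#' Collapses a 0-based half-open interval set to its union (adjacent
#' book-ended intervals are merged, matching `bedtools merge`).
#'
#' @param intervals Data.frame with `chrom`, `start`, `end`.
#' @return Sorted data.frame of disjoint intervals.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  out <- granges_to_df0(GenomicRanges::reduce(as_granges0(intervals)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Logical: does each interval of a overlap any interval of b?
overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  # disjoint chromosome sets are a legitimate no-overlap case, not a
  # seqlevel mismatch worth warning about
  suppressWarnings(IRanges::overlapsAny(as_granges0(a), as_granges0(b)))
}
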