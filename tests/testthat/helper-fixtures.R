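# Shared fixtures: built in code at test time, sized for speed.

# A small deterministic sharp PFM. Irregular counts keep every column's
# weights distinct, so no two windows can tie in floating point; the
# consensus ACGGTACA is not its own reverse complement.
tiny_pfm <- function() {
  counts <- matrix(c(
    # A   C   G   T  (one column per row here; matrix is 4 x 8)
    85,  3,  7,  5,
     2, 88,  6,  4,
     6,  3, 86,  5,
     4,  6, 83,  7,
     3,  5,  8, 84,
    87,  4,  6,  3,
     5, 89,  2,  4,
    82,  7,  6,  5), nrow = 4)
  new_pfm(counts, motif_id = "TEST0001", tf_name = "TestTF")
}

consensus_of <- function(pfm) {
  paste(c("A", "C", "G", "T")[apply(unclass(pfm), 2, which.max)],
        collapse = "")
}

# Small genome + planted peaks, cached per session to keep the suite fast.
small_fixture <- local({
  cache <- list()
  function(seed = 1L, n_bound = 60L, n_decoy = 60L) {
    key <- paste(seed, n_bound, n_decoy)
    if (is.null(cache[[key]])) {
      genome <- make_genome(c(chr1 = 120000L, chr2 = 120000L), seed = seed)
      pfm <- make_pfm(length = 14L, consensus_prob = c(0.85, 0.97),
                      seed = seed + 101L)
      pl <- plant_peaks(genome, pfm, n_bound, n_decoy, peak_width = 400L,
                        summit_jitter_sd = 10, seed = seed + 202L)
      cache[[key]] <<- list(genome = pl$genome, pfm = pfm,
                            peaks = pl$peaks, truth = pl$truth)
    }
    cache[[key]]
  }
})

# Brute-force best-hit oracle: enumerate every window on both strands in R.
brute_best_hit <- function(seq, pwm) {
  L <- ncol(pwm$weights)
  n <- nchar(seq)
  if (n < L) return(NULL)
  best <- NULL
  for (s in 0:(n - L)) {
    win <- substr(seq, s + 1, s + L)
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else revcomp(win)
      letters <- strsplit(w, "")[[1]]
      if (any(!letters %in% c("A", "C", "G", "T"))) next
      sc <- sum(vapply(seq_len(L), function(j)
        pwm$weights[letters[j], j], numeric(1)))
      if (is.null(best) || sc > best$score)
        best <- list(score = sc, start = s, strand = strand)
    }
  }
  best
}

# Fraction of called sites matching a planted truth row within tol bp.
recovery_stats <- function(called, truth, tol = 3) {
  tr <- truth[truth$planted, ]
  if (nrow(called) == 0L) return(c(precision = NA, recall = 0))
  ok <- vapply(seq_len(nrow(called)), function(i)
    any(tr$plant_chrom == called$chrom[i] &
          abs(tr$plant_start - called$start[i]) <= tol), logical(1))
  c(precision = mean(ok), recall = sum(ok) / nrow(tr))
}
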