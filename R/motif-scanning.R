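DNA_ALPHA <- c("A", "C", "G", "T")

# Integer-encode a DNA string: A=1, C=2, G=3, T=4, N=0. Case-insensitive.
encode_dna <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], DNA_ALPHA)
  v[is.na(v)] <- 0L
  as.integer(v)
}

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over A/C/G/T/N (case-insensitive).
#' @return Upper-case reverse complement.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Weights are `log2(((counts + pseudocount * bg) / (colsum + pseudocount))
#' / bg)`, the standard log-odds construction with a background-distributed
#' pseudocount. `max_score`/`min_score` are the column-wise extrema sums used
#' to normalize window scores into `[0, 1]`.
#'
#' @param pfm A `pfm` object (see [new_pfm()]).
#' @param pseudocount Positive pseudocount, distributed by background.
#'   Default 0.8, common JASPAR practice.
#' @param background Background probabilities for A, C, G, T; must be
#'   positive and sum to 1. Default uniform.
#' @return An object of class `pwm`: a list with `weights` (4 x L),
#'   `background`, `pseudocount`, `min_score`, `max_score`, `motif_id`,
#'   `tf_name`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8,
                       background = rep(0.25, 4)) {
  stopifnot(pseudocount > 0, length(background) == 4L,
            all(background > 0), abs(sum(background) - 1) < 1e-9)
  counts <- unclass(pfm)
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("PFM has a zero-sum column")
  p <- sweep(counts + pseudocount * background, 2L, cs + pseudocount, "/")
  w <- log2(p / background)
  rownames(w) <- DNA_ALPHA
  new_pwm(w, background, pseudocount,
          motif_id = attr(pfm, "motif_id") %||% "motif",
          tf_name = attr(pfm, "tf_name") %||% "TF")
}

new_pwm <- function(weights, background = rep(0.25, 4), pseudocount = NA_real_,
                    motif_id = "motif", tf_name = "TF") {
  structure(list(weights = weights,
                 background = background,
                 pseudocount = pseudocount,
                 min_score = sum(apply(weights, 2L, min)),
                 max_score = sum(apply(weights, 2L, max)),
                 motif_id = motif_id, tf_name = tf_name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), %d columns, score range [%.3f, %.3f]\n",
              x$motif_id, x$tf_name, ncol(x$weights),
              x$min_score, x$max_score))
  invisible(x)
}

#' Motif length of a PFM or PWM
#' @param x A `pfm` or `pwm`.
#' @return Number of motif columns.
#' @export
motif_length <- function(x) {
  if (is(x, "pwm")) ncol(x$weights) else ncol(unclass(x))
}

pwm_norm_score <- function(pwm, score) {
  (score - pwm$min_score) / (pwm$max_score - pwm$min_score)
}

empty_sites <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), norm_score = numeric(),
             peak_id = character(), dist_to_summit = integer())
}

#' Best PWM hit in a sequence
#'
#' Scores every window of width L on both strands (the minus strand scores
#' the window's reverse complement) and returns the single best hit with
#' normalized score `(score - min_score) / (max_score - min_score)` at or
#' above `min_norm_score`. Ties break to the leftmost start, then the plus
#' strand. Windows containing N are skipped, so assembly gaps can never
#' produce inflated scores.
#'
#' @param seq DNA string.
#' @param pwm A `pwm` object.
#' @param min_norm_score Score floor in `[0, 1]`; hits below it return NULL.
#' @return One-row data.frame with `start` (0-based, within `seq`), `end`,
#'   `strand`, `score`, `norm_score`, or NULL when no qualifying window
#'   exists.
#' @export
scan_best_hit <- function(seq, pwm, min_norm_score = 0) {
  L <- ncol(pwm$weights)
  if (nchar(seq) < L) return(NULL)
  m <- .best_window_scan(list(encode_dna(seq)), pwm$weights)
  if (is.na(m[1, 1])) return(NULL)
  ns <- pwm_norm_score(pwm, m[1, 1])
  if (ns < min_norm_score) return(NULL)
  data.frame(start = as.integer(m[1, 2]), end = as.integer(m[1, 2]) + L,
             strand = if (m[1, 3] > 0) "+" else "-",
             score = m[1, 1], norm_score = ns)
}

# Batch best-hit scan over a character vector of sequences; NA rows where no
# window is scannable. Returns a data.frame (start/end relative to each seq).
scan_best_hits <- function(seqs, pwm) {
  L <- ncol(pwm$weights)
  m <- .best_window_scan(lapply(seqs, encode_dna), pwm$weights)
  data.frame(start = as.integer(m[, 2]), end = as.integer(m[, 2]) + L,
             strand = ifelse(is.na(m[, 3]), NA_character_,
                             ifelse(m[, 3] > 0, "+", "-")),
             score = m[, 1], norm_score = pwm_norm_score(pwm, m[, 1]))
}

gc_fraction <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  sum(v %in% c("G", "C")) / length(v)
}

gc_bin <- function(gc_percent, bin_width = 5) {
  round(gc_percent / bin_width) * bin_width
}

#' Sample %GC-matched genomic background sequences
#'
#' For each positive sequence, draws genomic windows of `length` bp whose
#' %GC falls in the same `bin_width`-wide GC bin (bins centred on multiples
#' of `bin_width`, the BiasAway convention) as that positive. Windows
#' containing N are rejected and resampled. Deterministic given `seed`.
#'
#' When a positive's GC bin is unreachable in the genome (an extreme-GC
#' positive on a balanced genome) the sampler falls back, after
#' `max_retries` draws, to the sampled window closest in %GC to the target
#' bin and reports how many positives were relaxed; with `strict = TRUE`
#' the unreachable bin is an error instead.
#'
#' @param positive_seqs Character vector of positive sequences.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param length Background window length in bp (default 100).
#' @param n_per_positive Backgrounds drawn per positive.
#' @param bin_width GC bin width in percentage points (default 5).
#' @param seed Integer seed.
#' @param max_retries Sampling attempts per required window before falling
#'   back (or failing, when strict).
#' @param strict Error on an unreachable GC bin instead of relaxing.
#' @return Character vector of `length(positive_seqs) * n_per_positive`
#'   background sequences.
#' @export
gc_matched_background <- function(positive_seqs, genome, length = 100L,
                                  n_per_positive = 1L, bin_width = 5,
                                  seed = NULL, max_retries = 2000L,
                                  strict = FALSE) {
  stopifnot(length(positive_seqs) > 0L)
  lens <- chrom_lengths(genome)
  if (any(lens < length)) lens <- lens[lens >= length]
  if (!length(lens)) stop("no chromosome long enough for background windows")
  bins <- gc_bin(100 * vapply(positive_seqs, gc_fraction, numeric(1)),
                 bin_width)
  relaxed <- 0L
  out <- with_seed(seed, {
    unlist(lapply(rep(bins, each = n_per_positive), function(target_bin) {
      nearest <- NULL
      nearest_gap <- Inf
      for (try in seq_len(max_retries)) {
        chrom <- sample(names(lens), 1L, prob = lens)
        start <- sample.int(lens[[chrom]] - length + 1L, 1L) - 1L
        s <- get_sequence(genome, chrom, start, start + length)
        if (grepl("N", s, fixed = TRUE)) next
        gc <- 100 * gc_fraction(s)
        if (gc_bin(gc, bin_width) == target_bin) return(s)
        if (abs(gc - target_bin) < nearest_gap) {
          nearest_gap <- abs(gc - target_bin)
          nearest <- s
        }
      }
      if (strict || is.null(nearest))
        stop(sprintf("no genomic window found for GC bin %g%% after %d tries",
                     target_bin, max_retries))
      relaxed <<- relaxed + 1L
      nearest
    }), use.names = FALSE)
  })
  if (relaxed > 0L)
    message(relaxed, " background window(s) relaxed to the nearest ",
            "achievable %GC")
  out
}

#' Area under the ROC curve from two score sets
#'
#' Computed as the Mann-Whitney statistic: `P(pos > neg) + 0.5 P(pos = neg)`
#' over all positive/negative pairs, via midranks.
#'
#' @param pos_scores,neg_scores Non-empty numeric vectors.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(pos_scores, neg_scores) {
  stopifnot(length(pos_scores) > 0L, length(neg_scores) > 0L)
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
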