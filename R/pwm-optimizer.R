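#' Configuration for dataset-specific PWM optimization
#'
#' @param positive_halfwidth Half-width in bp of the positive window around
#'   each peak summit (default 50, giving 101 bp positives).
#' @param negative_length Length in bp of GC-matched background sequences
#'   (default 100).
#' @param epochs Perceptron epochs (default 50).
#' @param learning_rate Size of the averaged pairwise update (default 0.3,
#'   matching the scale of log-odds weights).
#' @param early_stop_patience Epochs without an AUROC improvement before
#'   stopping early (default 10).
#' @param seed Integer seed driving background sampling and pair sampling.
#' @return A list of class `optimization_config`.
#' @export
optimization_config <- function(positive_halfwidth = 50L,
                                negative_length = 100L,
                                epochs = 50L,
                                learning_rate = 0.3,
                                early_stop_patience = 10L,
                                seed = 1L) {
  stopifnot(epochs >= 0L, learning_rate > 0, positive_halfwidth > 0L,
            negative_length > 0L)
  structure(list(positive_halfwidth = as.integer(positive_halfwidth),
                 negative_length = as.integer(negative_length),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = seed),
            class = "optimization_config")
}

#' Build positive and GC-matched negative training sets
#'
#' Positives are the sequences summit +/- `positive_halfwidth` bp (101 bp at
#' the default); one GC-matched genomic background of `negative_length` bp
#' is sampled per positive. Peaks whose extended window leaves the
#' chromosome are dropped (their count is messaged).
#'
#' @param peaks Peak data.frame (see [read_peaks()]).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param config An [optimization_config()].
#' @param seed Seed for background sampling; defaults to `config$seed`.
#' @return List with `positives` and `negatives` character vectors.
#' @export
build_training_sets <- function(peaks, genome, config = optimization_config(),
                                seed = config$seed) {
  hw <- config$positive_halfwidth
  lens <- chrom_lengths(genome)
  summit <- peaks$start + peaks$summit_offset
  lo <- summit - hw
  hi <- summit + hw + 1L
  keep <- peaks$chrom %in% names(lens) & lo >= 0L &
    hi <= lens[peaks$chrom]
  if (sum(!keep) > 0L)
    message(sum(!keep), " peak(s) dropped: summit window out of bounds")
  if (!any(keep)) stop("no peaks retained for training")
  positives <- unname(vapply(which(keep), function(i) {
    get_sequence(genome, peaks$chrom[i], lo[i], hi[i])
  }, character(1)))
  negatives <- gc_matched_background(positives, genome,
                                     length = config$negative_length,
                                     seed = seed)
  list(positives = positives, negatives = negatives)
}

# Best-window score and PWM-frame letter encoding for each sequence.
# For minus-strand bests the letters are the reverse complement of the
# window, i.e. the letters the PWM columns actually scored.
best_windows_encoded <- function(enc, pwm) {
  L <- ncol(pwm$weights)
  m <- .best_window_scan(enc, pwm$weights)
  letters <- lapply(seq_along(enc), function(i) {
    if (is.na(m[i, 1])) return(NULL)
    s <- as.integer(m[i, 2])
    win <- enc[[i]][(s + 1L):(s + L)]
    if (m[i, 3] < 0) win <- rev(5L - win)
    win
  })
  list(score = m[, 1], norm = pwm_norm_score(pwm, m[, 1]), letters = letters)
}

#' Optimize a PWM against peak and background sequences
#'
#' A pairwise ranking perceptron that maximizes the AUROC separating
#' positive (peak) from negative (background) sequences. Each epoch:
#' every sequence is scored by its best-window normalized score; misranked
#' positive/negative pairs (a negative's best window scoring at least as
#' high as a positive's) are sampled, capped at
#' `10 * min(n_pos, n_neg)` pairs per epoch; the weight matrix receives
#' `learning_rate` times the average, over the sampled pairs, of
#' `one-hot(positive best window) - one-hot(negative best window)`,
#' column-aligned to the best windows (averaging keeps the step at the
#' learning-rate scale however many pairs are misranked); the
#' AUROC is then recomputed and the best-so-far weight matrix kept. With
#' `epochs = 0`, or when no epoch improves the AUROC, the input PWM is
#' returned unchanged. Motif length never changes.
#'
#' @param pfm The starting `pfm` (canonical motif).
#' @param positives,negatives Character vectors of training sequences.
#' @param config An [optimization_config()].
#' @return A list of class `optimization_result` with `initial_pwm`,
#'   `optimized_pwm`, `auroc_initial`, `auroc_final`, `auroc_per_epoch`.
#' @export
optimize_pwm <- function(pfm, positives, negatives,
                         config = optimization_config()) {
  stopifnot(length(positives) > 0L, length(negatives) > 0L)
  pwm0 <- pfm_to_pwm(pfm)
  enc_pos <- lapply(positives, encode_dna)
  enc_neg <- lapply(negatives, encode_dna)
  np <- length(enc_pos); nn <- length(enc_neg)
  pair_cap <- 10L * min(np, nn)

  eval_auroc <- function(pwm) {
    bp <- best_windows_encoded(enc_pos, pwm)
    bn <- best_windows_encoded(enc_neg, pwm)
    list(a = auroc(bp$norm[!is.na(bp$norm)], bn$norm[!is.na(bn$norm)]),
         bp = bp, bn = bn)
  }

  state <- eval_auroc(pwm0)
  auroc_initial <- state$a
  best_w <- pwm0$weights
  best_a <- auroc_initial
  per_epoch <- numeric(0)

  if (config$epochs > 0L) {
    w <- pwm0$weights
    lr <- config$learning_rate
    L <- ncol(w)
    since_improve <- 0L
    with_seed(config$seed, {
      for (epoch in seq_len(config$epochs)) {
        bp <- state$bp; bn <- state$bn
        # misranked pairs on normalized best-window scores
        ok_p <- which(!is.na(bp$norm)); ok_n <- which(!is.na(bn$norm))
        mis <- which(outer(bp$norm[ok_p], bn$norm[ok_n], "<="),
                     arr.ind = TRUE)
        if (nrow(mis) > 0L) {
          if (nrow(mis) > pair_cap)
            mis <- mis[sample.int(nrow(mis), pair_cap), , drop = FALSE]
          # averaged ranking-perceptron step: learning_rate times the mean,
          # over sampled pairs, of (one-hot positive window - one-hot
          # negative window); averaging keeps the step size at the
          # learning-rate scale regardless of how many pairs are misranked
          wp <- do.call(rbind, bp$letters[ok_p[mis[, 1]]])
          wn <- do.call(rbind, bn$letters[ok_n[mis[, 2]]])
          delta <- vapply(seq_len(L), function(j)
            tabulate(wp[, j], 4L) - tabulate(wn[, j], 4L), numeric(4))
          w <- w + lr * delta / nrow(mis)
        }
        cand <- new_pwm(w, pwm0$background, pwm0$pseudocount,
                        motif_id = pwm0$motif_id, tf_name = pwm0$tf_name)
        state <- eval_auroc(cand)
        per_epoch <- c(per_epoch, state$a)
        if (state$a > best_a) {
          best_a <- state$a
          best_w <- w
          since_improve <- 0L
        } else {
          since_improve <- since_improve + 1L
          if (since_improve >= config$early_stop_patience) break
        }
      }
    })
  }

  optimized <- new_pwm(best_w, pwm0$background, pwm0$pseudocount,
                       motif_id = paste0(pwm0$motif_id, "_opt"),
                       tf_name = pwm0$tf_name)
  structure(list(initial_pwm = pwm0, optimized_pwm = optimized,
                 auroc_initial = auroc_initial, auroc_final = best_a,
                 auroc_per_epoch = per_epoch),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("PWM optimization: AUROC %.4f -> %.4f over %d epoch(s)\n",
              x$auroc_initial, x$auroc_final, length(x$auroc_per_epoch)))
  invisible(x)
}

#' Express an optimized PWM as a frequency-scale PFM
#'
#' Inverts the log-odds transform column-wise (`bg * 2^w`, renormalized) and
#' scales to counts of 100, so an optimized matrix can be compared with the
#' canonical PFM by [motif_similarity_p()] or written with
#' [write_jaspar_pfm()].
#'
#' @param pwm A `pwm` object.
#' @return A `pfm` object on counts scale 100.
#' @export
pwm_to_pfm <- function(pwm) {
  p <- pwm$background * 2^pwm$weights
  p <- sweep(p, 2L, colSums(p), "/")
  new_pfm(100 * p, motif_id = pwm$motif_id, tf_name = pwm$tf_name)
}
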