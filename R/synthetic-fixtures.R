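#' Generate a random genome
#'
#' I.i.d. letters with `P(G) + P(C) = gc`, split evenly within the GC and AT
#' pairs. Deterministic given `seed`.
#'
#' @param chrom_lengths Named vector of chromosome lengths (each >= 1 kb).
#' @param gc Genome GC content in (0, 1), default 0.5.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
make_genome <- function(chrom_lengths, gc = 0.5, seed = 1L) {
  stopifnot(gc > 0, gc < 1, all(chrom_lengths >= 1000L))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(n)
      paste(sample(names(prob), n, replace = TRUE, prob = prob),
            collapse = ""), character(1))
    Biostrings::DNAStringSet(setNames(seqs, names(chrom_lengths)))
  })
}

#' Generate a random information-rich motif
#'
#' Each column gets a uniformly chosen consensus base carrying probability
#' `consensus_prob` (drawn per column from the given range), the remainder
#' split evenly. The defaults (14 columns at 0.85-0.97 consensus, ~1.5-1.9
#' bits per column) emulate the long, information-rich profiles — CTCF-class
#' motifs — that dominate high-confidence direct-binding collections.
#' Counts are on scale 100.
#'
#' @param length Motif length in columns (default 14).
#' @param consensus_prob Two-element range for the per-column consensus
#'   probability (default `c(0.85, 0.97)`).
#' @param seed Integer seed.
#' @param motif_id,tf_name Identifiers for the resulting `pfm`.
#' @return A `pfm` object.
#' @export
make_pfm <- function(length = 14L, consensus_prob = c(0.85, 0.97),
                     seed = 1L, motif_id = "SYN0001", tf_name = "SynTF") {
  stopifnot(length >= 4L)
  with_seed(seed, {
    counts <- vapply(seq_len(length), function(j) {
      p0 <- runif(1, consensus_prob[1], consensus_prob[2])
      cons <- sample.int(4L, 1L)
      col <- rep((1 - p0) / 3, 4)
      col[cons] <- p0
      100 * col
    }, numeric(4))
    new_pfm(counts, motif_id = motif_id, tf_name = tf_name)
  })
}

sample_motif_instance <- function(pfm, consensus_only = FALSE) {
  counts <- unclass(pfm)
  paste(vapply(seq_len(ncol(counts)), function(j) {
    if (consensus_only) DNA_ALPHA[which.max(counts[, j])]
    else sample(DNA_ALPHA, 1L, prob = counts[, j] / sum(counts[, j]))
  }, character(1)), collapse = "")
}

#' Plant motif-bearing and decoy peaks in a genome
#'
#' Lays out `n_bound + n_decoy` non-overlapping peaks of `peak_width` bp
#' with centred summits. Each bound peak receives one motif instance sampled
#' from the PFM's column distributions (or the consensus, with
#' `consensus_only = TRUE`), written into the genome so that the site
#' midpoint sits at `summit + round(Normal(0, summit_jitter_sd))` on a
#' random strand; decoy peaks are left untouched. The truth table records
#' the exact planted coordinates.
#'
#' @param genome A named [Biostrings::DNAStringSet]; returned modified.
#' @param pfm The motif to plant.
#' @param n_bound,n_decoy Numbers of motif-bearing and decoy peaks.
#' @param peak_width Peak width in bp (default 400).
#' @param summit_jitter_sd SD in bp of the planted-site offset from the
#'   summit (default 10).
#' @param seed Integer seed.
#' @param consensus_only Plant the consensus sequence instead of sampling.
#' @return List: `peaks` (peak data.frame), `truth` (data.frame `peak_id`,
#'   `planted`, `plant_chrom`, `plant_start`, `plant_end`, `plant_strand`,
#'   `summit_jitter_used`), `genome` (modified).
#' @export
plant_peaks <- function(genome, pfm, n_bound, n_decoy,
                        peak_width = 400L, summit_jitter_sd = 10,
                        seed = 1L, consensus_only = FALSE) {
  lens <- chrom_lengths(genome)
  L <- motif_length(pfm)
  gap <- 25L
  pitch <- peak_width + gap
  slots <- do.call(rbind, lapply(names(lens), function(ch) {
    n_slot <- (lens[[ch]] - gap) %/% pitch
    if (n_slot < 1L) return(NULL)
    data.frame(chrom = ch, start = gap + pitch * (seq_len(n_slot) - 1L))
  }))
  n_total <- n_bound + n_decoy
  if (is.null(slots) || nrow(slots) < n_total)
    stop("genome too small to place ", n_total, " non-overlapping peaks")
  chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  with_seed(seed, {
    chosen <- slots[sample.int(nrow(slots), n_total), , drop = FALSE]
    summit_offset <- peak_width %/% 2L
    peaks <- data.frame(chrom = chosen$chrom, start = chosen$start,
                        end = chosen$start + peak_width,
                        peak_id = sprintf("peak_%04d", seq_len(n_total)),
                        score = 100, summit_offset = summit_offset)
    planted <- c(rep(TRUE, n_bound), rep(FALSE, n_decoy))
    truth <- data.frame(peak_id = peaks$peak_id, planted = planted,
                        plant_chrom = NA_character_,
                        plant_start = NA_integer_, plant_end = NA_integer_,
                        plant_strand = NA_character_,
                        summit_jitter_used = NA_integer_)
    for (i in which(planted)) {
      jitter <- as.integer(round(rnorm(1, 0, summit_jitter_sd)))
      summit_abs <- peaks$start[i] + summit_offset
      site_start <- summit_abs + jitter - L %/% 2L
      site_start <- min(max(site_start, peaks$start[i]), peaks$end[i] - L)
      inst <- sample_motif_instance(pfm, consensus_only)
      strand <- sample(c("+", "-"), 1L)
      written <- if (strand == "+") inst else revcomp(inst)
      chars[[peaks$chrom[i]]][(site_start + 1L):(site_start + L)] <-
        strsplit(written, "")[[1]]
      truth$plant_chrom[i] <- peaks$chrom[i]
      truth$plant_start[i] <- site_start
      truth$plant_end[i] <- site_start + L
      truth$plant_strand[i] <- strand
      truth$summit_jitter_used[i] <- jitter
    }
    # shuffle row order so bound/decoy are interleaved as in real data
    o <- sample.int(n_total)
    peaks <- peaks[o, , drop = FALSE]; truth <- truth[o, , drop = FALSE]
    rownames(peaks) <- rownames(truth) <- NULL
    list(peaks = peaks, truth = truth,
         genome = Biostrings::DNAStringSet(
           setNames(vapply(chars, paste, character(1), collapse = ""),
                    names(genome))))
  })
}

#' The standard planted-peak test bed
#'
#' One call builds the whole fixture: a 2 x 300 kb genome at 50% GC, a 14-bp
#' information-rich motif, and 200 motif-planted plus 200 decoy peaks of
#' 400 bp with summit jitter SD 10 bp — the conditions under which the
#' pipeline's recovery is assessed.
#'
#' @param seed Integer seed driving every stage.
#' @param n_bound,n_decoy Peak counts (defaults 200/200).
#' @param peak_width,summit_jitter_sd Peak geometry (defaults 400 bp /
#'   10 bp).
#' @return List: `genome`, `pfm`, `peaks`, `truth`.
#' @export
standard_fixture <- function(seed = 1L, n_bound = 200L, n_decoy = 200L,
                             peak_width = 400L, summit_jitter_sd = 10) {
  genome <- make_genome(c(chr1 = 300000L, chr2 = 300000L), gc = 0.5,
                        seed = seed)
  pfm <- make_pfm(seed = seed + 101L)
  planted <- plant_peaks(genome, pfm, n_bound, n_decoy,
                         peak_width = peak_width,
                         summit_jitter_sd = summit_jitter_sd,
                         seed = seed + 202L)
  list(genome = planted$genome, pfm = pfm, peaks = planted$peaks,
       truth = planted$truth)
}

#' Generate a synthetic enhancer-expression matrix
#'
#' `n_specific` one-hot rows (exclusive activity) followed by
#' uniform-plus-noise rows (ubiquitous activity). Deterministic per seed.
#'
#' @param n_regions,n_celltypes Matrix dimensions.
#' @param n_specific Number of one-hot rows (<= `n_regions`).
#' @param noise Relative noise on the uniform rows (default 0.01).
#' @param seed Integer seed.
#' @return Numeric matrix `n_regions x n_celltypes` with region/cell-type
#'   dimnames.
#' @export
make_expression_matrix <- function(n_regions, n_celltypes, n_specific,
                                   noise = 0.01, seed = 1L) {
  stopifnot(n_specific <= n_regions, n_celltypes >= 2L)
  with_seed(seed, {
    m <- matrix(0, n_regions, n_celltypes,
                dimnames = list(sprintf("region_%04d", seq_len(n_regions)),
                                sprintf("celltype_%02d",
                                        seq_len(n_celltypes))))
    for (i in seq_len(n_specific))
      m[i, sample.int(n_celltypes, 1L)] <- 1
    if (n_specific < n_regions) {
      rest <- (n_specific + 1L):n_regions
      m[rest, ] <- 1 + noise * matrix(runif(length(rest) * n_celltypes),
                                      length(rest))
    }
    m
  })
}
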