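#' Unique bound loci across datasets
#'
#' Deduplicates sites to unique (chrom, start, end, TF) tuples — the
#' unit in which TFBS counts are reported: the same locus bound by the same
#' TF in several datasets counts once, but the same locus bound by two TFs
#' counts twice.
#'
#' @param sites Data.frame with `chrom`, `start`, `end` and optionally
#'   `tf_name` (a single anonymous TF is assumed when absent).
#' @return Sorted data.frame of unique loci (`chrom`, `start`, `end`,
#'   `tf_name`).
#' @export
unique_loci <- function(sites) {
  if (nrow(sites) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), tf_name = character()))
  tf <- if ("tf_name" %in% names(sites)) sites$tf_name else "TF"
  d <- unique(data.frame(chrom = sites$chrom, start = sites$start,
                         end = sites$end, tf_name = tf))
  d <- d[order(d$chrom, d$start, d$end, d$tf_name), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Call cis-regulatory modules by quantile-gap chaining
#'
#' Groups sorted unique loci into cis-regulatory modules (CRMs): the gaps
#' between consecutive locus starts on each chromosome are pooled
#' genome-wide, the `gap_quantile` quantile of that distribution becomes the
#' chaining threshold `g*`, single-linkage chaining merges consecutive loci
#' with gap <= `g*`, and chains of at least `min_order` loci become CRMs
#' spanning min start to max end. The learned threshold is returned as the
#' `gap_threshold` attribute; passing it back via `gap_threshold` reproduces
#' the same CRMs on any subset of their member loci (re-estimating the
#' quantile on members only would shrink it).
#'
#' @param loci Sorted unique loci (see [unique_loci()]).
#' @param min_order Minimum loci per CRM (default 3).
#' @param gap_quantile Quantile of the pooled gap distribution used as the
#'   chaining threshold (default 0.25).
#' @param gap_threshold Optional explicit threshold in bp, overriding the
#'   quantile estimate.
#' @return Data.frame of CRMs: `chrom`, `start`, `end`, `n_sites`,
#'   `n_distinct_tfs`, `site_ids` (comma-separated row indices into `loci`),
#'   with attribute `gap_threshold`.
#' @export
call_crms <- function(loci, min_order = 3L, gap_quantile = 0.25,
                      gap_threshold = NULL) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      n_distinct_tfs = integer(), site_ids = character())
  if (nrow(loci) < 2L) return(structure(empty, gap_threshold = NA_real_))
  o <- order(loci$chrom, loci$start, loci$end)
  if (!identical(o, seq_len(nrow(loci)))) stop("loci must be sorted")
  by_chrom <- split(seq_len(nrow(loci)), loci$chrom)
  gaps <- unlist(lapply(by_chrom, function(ix) {
    if (length(ix) < 2L) numeric(0) else diff(loci$start[ix])
  }), use.names = FALSE)
  if (is.null(gap_threshold)) {
    if (!length(gaps)) return(structure(empty, gap_threshold = NA_real_))
    gap_threshold <- as.numeric(quantile(gaps, gap_quantile))
  }
  crms <- do.call(rbind, lapply(by_chrom, function(ix) {
    if (!length(ix)) return(NULL)
    g <- diff(loci$start[ix])
    chain <- cumsum(c(0L, as.integer(g > gap_threshold)))
    do.call(rbind, lapply(split(ix, chain), function(members) {
      if (length(members) < min_order) return(NULL)
      data.frame(chrom = loci$chrom[members[1]],
                 start = min(loci$start[members]),
                 end = max(loci$end[members]),
                 n_sites = length(members),
                 n_distinct_tfs = length(unique(loci$tf_name[members])),
                 site_ids = paste(members, collapse = ","))
    }))
  }))
  if (is.null(crms)) crms <- empty
  crms <- crms[order(crms$chrom, crms$start), , drop = FALSE]
  rownames(crms) <- NULL
  structure(crms, gap_threshold = gap_threshold)
}

#' Pairwise motif similarity matrix
#'
#' Computes `-log10` of the permutation similarity p-value
#' ([motif_similarity_p()]) for every motif pair, symmetrized by taking the
#' conservative `max(p_ij, p_ji)` before the transform. This is the
#' similarity matrix whose rows are subsequently compared by correlation
#' distance in [cluster_motifs()].
#'
#' @param pfms List of `pfm` objects (>= 2).
#' @param n_null,seed Passed to [motif_similarity_p()]; one derived seed per
#'   pair keeps entries reproducible.
#' @return Symmetric numeric matrix of `-log10(p)` values, zero off-diagonal
#'   floor, motif ids as dimnames.
#' @export
motif_similarity_matrix <- function(pfms, n_null = 200L, seed = 1L) {
  n <- length(pfms)
  stopifnot(n >= 2L)
  ids <- vapply(pfms, function(p) attr(p, "motif_id"), character(1))
  P <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pij <- motif_similarity_p(pfms[[i]], pfms[[j]], n_null = n_null,
                                seed = seed + 1000L * i + j)$p
      pji <- motif_similarity_p(pfms[[j]], pfms[[i]], n_null = n_null,
                                seed = seed + 1000L * j + i)$p
      P[i, j] <- P[j, i] <- max(pij, pji)
    }
  }
  diag(P) <- 1 / (n_null + 1) # self-similarity: the smallest attainable p
  -log10(P)
}

#' Cluster motifs into archetypes
#'
#' Agglomerative complete-linkage clustering on the correlation distance
#' (`1 - Pearson`) between rows of the motif similarity matrix; flat
#' archetypes are obtained by cutting the dendrogram at `cut_height`. The
#' result is a partition: every motif belongs to exactly one archetype.
#'
#' @param similarity_matrix Output of [motif_similarity_matrix()].
#' @param cut_height Dendrogram cut height on the correlation-distance scale
#'   (default 0.7).
#' @return List of archetypes, each a list with `archetype_id`,
#'   `member_motif_ids`, `linkage_height` (the height at which the cluster
#'   is complete).
#' @export
cluster_motifs <- function(similarity_matrix, cut_height = 0.7) {
  ids <- rownames(similarity_matrix)
  d <- as.dist(1 - cor(t(similarity_matrix)))
  d[is.na(d)] <- 1 # zero-variance rows carry no signal: maximal distance
  hc <- hclust(d, method = "complete")
  if (!is.finite(cut_height)) cut_height <- max(hc$height)
  membership <- cutree(hc, h = cut_height)
  lapply(sort(unique(membership)), function(k) {
    members <- ids[membership == k]
    hgt <- if (length(members) == 1L) 0 else {
      sub <- as.matrix(d)[members, members]
      max(sub)
    }
    list(archetype_id = sprintf("archetype_%02d", k),
         member_motif_ids = members,
         linkage_height = hgt)
  })
}

# Align pfm_b onto pfm_a: best offset/orientation by the same statistic as
# motif_similarity_p. Returns b's frequency matrix in the chosen
# orientation plus the offset of its first column relative to a's.
align_to <- function(pfm_a, pfm_b) {
  Za <- standardize_columns(pfm_a)
  Zb <- standardize_columns(pfm_b)
  Lb <- ncol(Zb)
  f <- best_diagonal_mean(crossprod(Za, Zb) / 3)
  r <- best_diagonal_mean(crossprod(Za, complement_rows(Zb))[, Lb:1,
                                                            drop = FALSE] / 3)
  freq <- sweep(unclass(pfm_b), 2L, colSums(unclass(pfm_b)), "/")
  if (f$stat >= r$stat) {
    list(freq = freq, offset = f$offset)
  } else {
    list(freq = complement_rows(freq)[, Lb:1, drop = FALSE], offset = r$offset)
  }
}

#' Consensus motif of an archetype
#'
#' Aligns every member to the first (offset and orientation maximizing the
#' pairwise similarity statistic), averages frequency-normalized columns
#' position-wise over the union span — padding unaligned overhangs with the
#' uniform background — and rescales to counts of 100.
#'
#' @param member_pfms Non-empty list of `pfm` objects.
#' @param archetype_id Identifier for the resulting motif.
#' @return A `pfm` on counts scale 100.
#' @export
consensus_motif <- function(member_pfms, archetype_id = "archetype") {
  stopifnot(length(member_pfms) >= 1L)
  anchor <- member_pfms[[1]]
  aligned <- c(list(list(freq = sweep(unclass(anchor), 2L,
                                      colSums(unclass(anchor)), "/"),
                         offset = 0L)),
               lapply(member_pfms[-1], function(b) align_to(anchor, b)))
  starts <- vapply(aligned, function(a) a$offset, numeric(1))
  ends <- starts + vapply(aligned, function(a) ncol(a$freq), numeric(1)) - 1
  span <- min(starts):max(ends)
  acc <- matrix(0, 4L, length(span))
  for (a in aligned) {
    cols <- (a$offset - min(starts) + 1L):(a$offset - min(starts) +
                                             ncol(a$freq))
    pad <- matrix(0.25, 4L, length(span))
    pad[, cols] <- a$freq
    acc <- acc + pad
  }
  acc <- acc / length(aligned)
  new_pfm(100 * acc, motif_id = archetype_id, tf_name = archetype_id)
}

#' Collapse same-archetype sites into archetypal loci
#'
#' Within each archetype, overlapping site intervals (half-open overlap)
#' from the archetype's member motifs are merged into a single archetypal
#' locus; sites from different archetypes are never merged.
#'
#' @param sites_by_motif Named list (motif id -> site data.frame with
#'   `chrom`, `start`, `end`).
#' @param archetypes Output of [cluster_motifs()].
#' @return Data.frame of archetypal loci: `chrom`, `start`, `end`,
#'   `archetype_id`, sorted within archetype.
#' @export
collapse_to_archetypal_sites <- function(sites_by_motif, archetypes) {
  out <- lapply(archetypes, function(a) {
    members <- intersect(a$member_motif_ids, names(sites_by_motif))
    if (!length(members)) return(NULL)
    sites <- do.call(rbind, lapply(sites_by_motif[members], function(s)
      s[, c("chrom", "start", "end")]))
    if (nrow(sites) == 0L) return(NULL)
    merged <- merge_intervals(sites)
    merged$archetype_id <- a$archetype_id
    merged
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), archetype_id = character())
  rownames(out) <- NULL
  out
}
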