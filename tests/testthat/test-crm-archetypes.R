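test_that("unique loci deduplicate per TF, not across TFs", {
  sites <- data.frame(chrom = "chr1", start = c(100, 100, 100, 100),
                      end = c(110, 110, 110, 110),
                      tf_name = c("CTCF", "CTCF", "CTCF", "MAX"))
  u <- unique_loci(sites)
  expect_equal(nrow(u), 2L)
  expect_setequal(u$tf_name, c("CTCF", "MAX"))
  expect_equal(nrow(unique_loci(sites[0, ])), 0L)
})

test_that("quantile-gap chaining isolates a dense cluster of loci", {
  # 5 loci 10 bp apart, then 5 isolated loci with ~100 kb gaps: the 0.25
  # gap quantile lands on the small-gap population, so only the dense
  # cluster chains and singletons fall below min_order
  loci <- data.frame(chrom = "chr1",
                     start = c(0, 10, 20, 30, 40,
                               100000, 200000, 300000, 400000, 500000),
                     end = c(5, 15, 25, 35, 45,
                             100005, 200005, 300005, 400005, 500005),
                     tf_name = rep(c("A", "B"), 5))
  crms <- call_crms(loci)
  expect_equal(nrow(crms), 1L)
  expect_equal(crms$n_sites, 5L)
  expect_equal(crms$start, 0)
  expect_equal(crms$end, 45)
  expect_equal(crms$n_distinct_tfs, 2L)
  expect_equal(attr(crms, "gap_threshold"), 10)
})

test_that("min_order 1 places every locus in some CRM", {
  loci <- data.frame(chrom = "chr1", start = c(0, 50, 5000, 9000),
                     end = c(10, 60, 5010, 9010), tf_name = "X")
  crms <- call_crms(loci, min_order = 1L)
  expect_equal(sum(crms$n_sites), nrow(loci))
})

test_that("CRMs never overlap and re-calling at the learned threshold is idempotent", {
  set.seed(61)
  starts <- sort(sample(1:500000, 300))
  loci <- data.frame(chrom = "chr1", start = starts, end = starts + 10,
                     tf_name = sample(c("A", "B", "C"), 300, TRUE))
  crms <- call_crms(loci)
  if (nrow(crms) > 1L)
    expect_true(all(crms$start[-1] >= head(crms$end, -1)))
  # members of the called CRMs, re-chained at the recorded threshold
  member_idx <- sort(as.integer(unlist(strsplit(crms$site_ids, ","))))
  members <- loci[member_idx, ]
  rownames(members) <- NULL
  again <- call_crms(members, gap_threshold = attr(crms, "gap_threshold"))
  expect_equal(again$start, crms$start)
  expect_equal(again$end, crms$end)
  expect_equal(again$n_sites, crms$n_sites)
})

test_that("the similarity matrix is symmetric with duplicate pairs maximal", {
  pfms <- list(make_pfm(seed = 1, motif_id = "M1"),
               make_pfm(seed = 1, motif_id = "M2"), # duplicate of M1
               make_pfm(seed = 3, motif_id = "M3"),
               make_pfm(seed = 4, motif_id = "M4"))
  S <- motif_similarity_matrix(pfms, n_null = 100, seed = 9)
  expect_equal(S, t(S), tolerance = 1e-12)
  off_diag <- S["M1", c("M2", "M3", "M4")]
  expect_equal(names(which.max(off_diag)), "M2")
})

test_that("motif clustering is a partition with sane cut-height limits", {
  pfms <- list(make_pfm(seed = 1, motif_id = "M1"),
               make_pfm(seed = 1, motif_id = "M2"),
               make_pfm(seed = 3, motif_id = "M3"),
               make_pfm(seed = 4, motif_id = "M4"),
               make_pfm(seed = 5, motif_id = "M5"))
  S <- motif_similarity_matrix(pfms, n_null = 100, seed = 9)
  arch <- cluster_motifs(S, cut_height = 0.7)
  members <- unlist(lapply(arch, `[[`, "member_motif_ids"))
  expect_setequal(members, rownames(S))
  expect_equal(length(members), nrow(S)) # each motif exactly once
  # identical motifs always co-cluster
  in_same <- vapply(arch, function(a)
    all(c("M1", "M2") %in% a$member_motif_ids) ||
      !any(c("M1", "M2") %in% a$member_motif_ids), logical(1))
  expect_true(all(in_same))
  expect_length(cluster_motifs(S, cut_height = Inf), 1L)
})

test_that("consensus building preserves single members and resolves orientation", {
  pfm <- tiny_pfm()
  freq <- sweep(unclass(pfm), 2, colSums(unclass(pfm)), "/")
  single <- consensus_motif(list(pfm))
  expect_equal(unclass(single) / 100, freq, tolerance = 1e-9,
               ignore_attr = TRUE)
  twin <- consensus_motif(list(pfm, pfm))
  expect_equal(unclass(twin) / 100, freq, tolerance = 1e-9,
               ignore_attr = TRUE)
  m <- unclass(pfm)
  rc <- new_pfm(m[4:1, rev(seq_len(ncol(m)))], "rc")
  resolved <- consensus_motif(list(pfm, rc))
  expect_equal(unclass(resolved) / 100, freq, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("archetypal collapsing merges within but never across archetypes", {
  arch <- list(list(archetype_id = "archetype_01",
                    member_motif_ids = c("M1", "M2")),
               list(archetype_id = "archetype_02",
                    member_motif_ids = "M3"))
  sites <- list(
    M1 = data.frame(chrom = "chr1", start = 100L, end = 110L),
    M2 = data.frame(chrom = "chr1", start = c(105L, 500L),
                    end = c(115L, 510L)),
    M3 = data.frame(chrom = "chr1", start = 100L, end = 110L))
  out <- collapse_to_archetypal_sites(sites, arch)
  a1 <- out[out$archetype_id == "archetype_01", ]
  expect_equal(nrow(a1), 2L)
  expect_true(any(a1$start == 100 & a1$end == 115)) # [100,110)+[105,115)
  # the same coordinates under another archetype stay separate
  expect_equal(nrow(out[out$archetype_id == "archetype_02", ]), 1L)
  expect_lte(nrow(out), sum(vapply(sites, nrow, integer(1))))
  # within an archetype, collapsed loci are pairwise non-overlapping
  expect_true(all(a1$start[-1] >= head(a1$end, -1)))
})
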