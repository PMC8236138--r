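#' Build a region-set database for TFBS enrichment
#'
#' @param sets Named list of interval data.frames (`chrom`, `start`, `end`),
#'   each sorted by (chrom, start).
#' @param metadata Optional data.frame with one row per set: `set_id`,
#'   `tf_name`, `cell_or_tissue`, `treatment`, `dataset_id`. Defaults to
#'   blanks.
#' @return A list of class `region_set_db`.
#' @export
region_set_db <- function(sets, metadata = NULL) {
  stopifnot(length(sets) > 0L, !is.null(names(sets)),
            !anyDuplicated(names(sets)))
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (nrow(s) && !identical(order(s$chrom, s$start), seq_len(nrow(s))))
      stop("set '", nm, "' is not sorted by (chrom, start)")
  }
  if (is.null(metadata)) {
    metadata <- data.frame(set_id = names(sets), tf_name = "",
                           cell_or_tissue = "", treatment = "",
                           dataset_id = names(sets))
  }
  stopifnot(setequal(metadata$set_id, names(sets)))
  structure(list(sets = sets, metadata = metadata), class = "region_set_db")
}

dedup_intervals <- function(x) {
  d <- unique(x[, c("chrom", "start", "end")])
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  d
}

interval_key <- function(x) paste(x$chrom, x$start, x$end, sep = ":")

#' Fisher-exact TFBS-set enrichment against an explicit universe
#'
#' For each database set S, a 2x2 table is built at the region level:
#' `a` = query regions overlapping >= 1 interval of S, `b` = remaining query
#' regions, `c` = non-query universe regions overlapping S, `d` = the rest.
#' A one-sided (greater) Fisher exact test gives p; Benjamini-Hochberg
#' adjustment across all sets gives q; rows are ranked by ascending p, then
#' descending odds ratio. Query regions overlapping no universe region are
#' dropped (their count is messaged); the universe is deduplicated and
#' query regions are removed from it by exact coordinates.
#'
#' @param query,universe Interval data.frames (`chrom`, `start`, `end`).
#' @param db A [region_set_db()].
#' @return Data.frame: `set_id`, `tf_name`, `cell_or_tissue`, `a`, `b`,
#'   `c`, `d`, `odds_ratio` (sample odds ratio `ad/bc`), `p`, `q`, `rank`.
#' @export
enrich_with_universe <- function(query, universe, db) {
  stopifnot(is(db, "region_set_db"))
  if (nrow(query) == 0L || nrow(universe) == 0L)
    stop("empty query or universe")
  universe <- dedup_intervals(universe)
  query <- dedup_intervals(query)
  keep <- overlaps_any(query, universe)
  if (any(!keep))
    message(sum(!keep), " query region(s) outside the universe dropped")
  query <- query[keep, , drop = FALSE]
  if (nrow(query) == 0L) stop("no query region overlaps the universe")
  rest <- universe[!interval_key(universe) %in% interval_key(query), ,
                   drop = FALSE]
  nq <- nrow(query); nr <- nrow(rest)
  res <- do.call(rbind, lapply(names(db$sets), function(nm) {
    a <- sum(overlaps_any(query, db$sets[[nm]]))
    cc <- sum(overlaps_any(rest, db$sets[[nm]]))
    b <- nq - a
    d <- nr - cc
    p <- fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(set_id = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = (a * d) / (b * cc), p = p)
  }))
  meta <- db$metadata[match(res$set_id, db$metadata$set_id), ]
  res$tf_name <- meta$tf_name
  res$cell_or_tissue <- meta$cell_or_tissue
  res$q <- p.adjust(res$p, "BH")
  o <- order(res$p, -res$odds_ratio)
  res <- res[o, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("set_id", "tf_name", "cell_or_tissue", "a", "b", "c", "d",
          "odds_ratio", "p", "q", "rank")]
}

#' Differential TFBS-set enrichment between two region sets
#'
#' The universe is the deduplicated union of both queries and enrichment of
#' `query1` is tested within it — set enrichments of `query1` relative to
#' `query2`. Swapping the two arguments turns enrichment into depletion on
#' the same table margins.
#'
#' @param query1,query2 Interval data.frames.
#' @param db A [region_set_db()].
#' @return As [enrich_with_universe()].
#' @export
enrich_differential <- function(query1, query2, db) {
  stopifnot(nrow(query1) > 0L, nrow(query2) > 0L)
  universe <- dedup_intervals(rbind(query1[, c("chrom", "start", "end")],
                                    query2[, c("chrom", "start", "end")]))
  enrich_with_universe(query1, universe, db)
}

#' TFBS-set enrichment against the whole-database universe
#'
#' The universe is the union of every interval in the database, deduplicated
#' and merged where overlapping — enrichment relative to all stored TFBSs.
#'
#' @param query Interval data.frame.
#' @param db A [region_set_db()].
#' @return As [enrich_with_universe()].
#' @export
enrich_default_universe <- function(query, db) {
  stopifnot(is(db, "region_set_db"), length(db$sets) > 0L)
  universe <- merge_intervals(do.call(rbind, lapply(db$sets, function(s)
    s[, c("chrom", "start", "end")])))
  enrich_with_universe(query, universe, db)
}

#' Filter enrichment results by cell/tissue keywords
#'
#' Keeps sets whose `cell_or_tissue` metadata contains any keyword
#' (case-insensitive substring). Ranks are recomputed within the subset;
#' q-values are NOT recomputed — the filter is presentational.
#'
#' @param results Output of one of the `enrich_*` functions.
#' @param db The [region_set_db()] the results came from.
#' @param keywords Character vector; empty means no filtering.
#' @return Filtered results with recomputed `rank`.
#' @export
filter_results_by_metadata <- function(results, db, keywords = character()) {
  if (length(keywords) == 0L) return(results)
  cells <- db$metadata$cell_or_tissue[match(results$set_id,
                                            db$metadata$set_id)]
  keep <- Reduce(`|`, lapply(keywords, function(k)
    grepl(k, cells, ignore.case = TRUE, fixed = FALSE)))
  out <- results[keep, , drop = FALSE]
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
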