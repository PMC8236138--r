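#' Configuration for a full per-dataset run
#'
#' A single global seed is expanded into fixed per-stage seeds (offsets
#' +11 for training-set sampling, +23 for perceptron pair sampling, +37 for
#' the similarity permutation null), so each stage is individually
#' reproducible from the manifest.
#'
#' @param seed Global integer seed.
#' @param epochs,learning_rate,early_stop_patience Perceptron settings (see
#'   [optimization_config()]).
#' @param n_bins Histogram bins for the enrichment zone.
#' @param min_hits Minimum landscape hits to define a zone.
#' @param alpha QC significance level.
#' @param qc_n_null Permutation-null size for the similarity test.
#' @param dataset_id Identifier carried into outputs and the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, epochs = 50L, learning_rate = 0.3,
                       early_stop_patience = 10L, n_bins = 100L,
                       min_hits = 50L, alpha = 0.05, qc_n_null = 1000L,
                       dataset_id = "dataset") {
  structure(list(seed = as.integer(seed), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 n_bins = as.integer(n_bins),
                 min_hits = as.integer(min_hits), alpha = alpha,
                 qc_n_null = as.integer(qc_n_null),
                 dataset_id = dataset_id),
            class = "run_config")
}

#' Run the full direct-binding pipeline on one ChIP-seq dataset
#'
#' Executes the two-pass procedure: (1) build summit-centred positives and
#' GC-matched negatives, optimize the PWM by the ranking perceptron;
#' (2) collect the per-peak best-hit landscape with the optimized PWM,
#' learn the enrichment zone from it by maximum-entropy thresholding, and
#' keep the best in-zone hit per peak from the optimized-PWM rescan; then
#' apply the two QC filters. Zone-passing calls form the permissive site set; when
#' both QC filters pass the same calls are also emitted as the robust set —
#' so the robust loci are always a subset of the permissive ones. Datasets
#' whose landscape is too small for a zone yield an empty permissive set
#' and a manifest flag, never a silent empty result.
#'
#' @param peaks Peak data.frame (see [read_peaks()]).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param pfm The canonical `pfm` for the ChIP'ed TF.
#' @param config A [run_config()].
#' @return A list of class `dataset_run`: `permissive_sites`,
#'   `robust_sites` (NULL unless QC passes), `zone`, `qc` (NULL when no
#'   zone), `optimization`, `landscape`, `manifest`.
#' @export
run_dataset <- function(peaks, genome, pfm, config = run_config()) {
  opt_cfg <- optimization_config(epochs = config$epochs,
                                 learning_rate = config$learning_rate,
                                 early_stop_patience =
                                   config$early_stop_patience,
                                 seed = config$seed + 23L)
  train <- build_training_sets(peaks, genome, opt_cfg,
                               seed = config$seed + 11L)
  opt <- optimize_pwm(pfm, train$positives, train$negatives, opt_cfg)

  landscape <- collect_landscape(peaks, genome, opt$optimized_pwm)
  zone <- define_enrichment_zone(landscape, n_bins = config$n_bins,
                                 min_hits = config$min_hits)

  manifest <- list(dataset_id = config$dataset_id,
                   tool = "chipzone",
                   version = as.character(utils::packageVersion("chipzone")),
                   seed = config$seed,
                   config = unclass(config),
                   motif_id = attr(pfm, "motif_id"),
                   n_peaks = nrow(peaks),
                   n_landscape_hits = nrow(landscape),
                   auroc_initial = opt$auroc_initial,
                   auroc_final = opt$auroc_final,
                   zone_defined = zone$defined)

  if (!zone$defined) {
    manifest$n_sites_called <- 0L
    manifest$robust <- FALSE
    return(structure(list(permissive_sites = empty_sites(),
                          robust_sites = NULL, zone = zone, qc = NULL,
                          optimization = opt, landscape = landscape,
                          manifest = manifest),
                     class = "dataset_run"))
  }

  called <- call_tfbs(peaks, opt$optimized_pwm, zone, genome)
  qc <- apply_qc(list(optimized_pfm = pwm_to_pfm(opt$optimized_pwm),
                      canonical_pfm = pfm,
                      called_sites = called,
                      landscape_hits = landscape),
                 alpha = config$alpha, n_null = config$qc_n_null,
                 seed = config$seed + 37L)

  manifest$score_threshold <- zone$score_threshold
  manifest$distance_threshold <- zone$distance_threshold
  manifest$n_sites_called <- nrow(called)
  manifest$similarity_p <- qc$similarity_p
  manifest$centrality_p <- qc$centrality_p
  manifest$robust <- qc$robust

  structure(list(permissive_sites = called,
                 robust_sites = if (qc$robust) called else NULL,
                 zone = zone, qc = qc, optimization = opt,
                 landscape = landscape, manifest = manifest),
            class = "dataset_run")
}

#' @export
print.dataset_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Dataset %s: %d peaks -> %d sites (%s)\n", m$dataset_id,
              m$n_peaks, m$n_sites_called,
              if (isTRUE(m$robust)) "robust" else if (m$zone_defined)
                "permissive" else "no zone"))
  invisible(x)
}

#' Write the outputs of a dataset run to a directory
#'
#' Emits `permissive.bed` (always, possibly empty), `robust.bed` (only for
#' robust datasets), `qc.tsv` and `manifest.json`. File content hashes of
#' the inputs, when the caller worked from files, can be attached via
#' `input_paths` (hashed with [tools::md5sum()]).
#'
#' @param run A `dataset_run`.
#' @param out_dir Output directory (created if needed).
#' @param tf_name TF name for the BED name column.
#' @param input_paths Optional character vector of input file paths.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir, tf_name = "TF", input_paths = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- run$manifest
  if (!is.null(input_paths))
    m$input_md5 <- as.list(tools::md5sum(input_paths))
  write_sites_bed(run$permissive_sites, file.path(out_dir, "permissive.bed"),
                  tf_name = tf_name, dataset_id = m$dataset_id)
  if (!is.null(run$robust_sites))
    write_sites_bed(run$robust_sites, file.path(out_dir, "robust.bed"),
                    tf_name = tf_name, dataset_id = m$dataset_id)
  if (!is.null(run$qc)) {
    qc_df <- data.frame(dataset_id = m$dataset_id,
                        similarity_p = run$qc$similarity_p,
                        centrality_p = run$qc$centrality_p,
                        robust = run$qc$robust)
    write.table(qc_df, file.path(out_dir, "qc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
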