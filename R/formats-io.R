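#' Read a genome from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] and trims record names to the first
#' whitespace-delimited word (the chromosome identifier), matching the
#' convention of samtools/bedtools.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to a FASTA file
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Extract a genomic subsequence
#'
#' Coordinates are 0-based half-open, so the returned string has length
#' `end - start`. Output is upper-cased; the alphabet is restricted to
#' A, C, G, T, N.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return A character scalar of length `end - start`.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len))
  s <- toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                               start + 1L, end)))
  if (grepl("[^ACGTN]", s))
    stop("sequence contains letters outside A/C/G/T/N on ", chrom)
  s
}

#' Read ChIP-seq peaks from a narrowPeak or BED file
#'
#' Peaks are returned 0-based half-open with a summit offset relative to the
#' peak start (MACS convention). Three dialects are supported:
#'
#' * `"narrowPeak"` — BED6+4; the summit offset is column 10.
#' * `"bed_with_summit_col"` — BED with the summit offset as an extra final
#'   column.
#' * `"bed_midpoint"` — plain BED3+; the summit is the interval midpoint,
#'   `floor((end - start) / 2)`. The least-biased fallback when the peak
#'   caller did not report summits.
#'
#' Duplicate peak ids are made unique by suffixing `.2`, `.3`, ...; missing
#' names become `peak_<line>`.
#'
#' @param path Path to the peak file.
#' @param dialect One of `"narrowPeak"`, `"bed_with_summit_col"`,
#'   `"bed_midpoint"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `score`, `summit_offset`.
#' @export
read_peaks <- function(path,
                       dialect = c("narrowPeak", "bed_with_summit_col",
                                   "bed_midpoint")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_id = character(),
                      score = numeric(), summit_offset = integer()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  need <- switch(dialect, narrowPeak = 10L, bed_with_summit_col = 4L,
                 bed_midpoint = 3L)
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected >= %d fields, got %d",
                 bad[1], path, need, nf[bad[1]]))
  getf <- function(i) vapply(fields, `[`, character(1), i)
  chrom <- getf(1L)
  start <- suppressWarnings(as.integer(getf(2L)))
  end <- suppressWarnings(as.integer(getf(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop(sprintf("malformed line %d: start >= end (%d >= %d)",
                 bad[1], start[bad[1]], end[bad[1]]))
  peak_id <- if (all(nf >= 4L) && dialect != "bed_midpoint") getf(4L)
             else if (all(nf >= 4L)) getf(4L)
             else paste0("peak_", seq_along(lines))
  if (anyNA(peak_id) || any(peak_id == "."))
    peak_id[is.na(peak_id) | peak_id == "."] <-
      paste0("peak_", which(is.na(peak_id) | peak_id == "."))
  score <- if (all(nf >= 5L)) suppressWarnings(as.numeric(getf(5L)))
           else rep(NA_real_, length(lines))
  summit_offset <- switch(dialect,
    narrowPeak = suppressWarnings(as.integer(getf(10L))),
    bed_with_summit_col = suppressWarnings(as.integer(getf(nf[1]))),
    bed_midpoint = as.integer((end - start) %/% 2L))
  bad <- which(is.na(summit_offset) | summit_offset < 0L |
                 summit_offset >= end - start)
  if (length(bad))
    stop(sprintf("summit offset out of range for peak '%s' (line %d)",
                 peak_id[bad[1]], bad[1]))
  # auto-suffix duplicated ids
  if (anyDuplicated(peak_id)) {
    peak_id <- stats::ave(peak_id, peak_id, FUN = function(x) {
      if (length(x) == 1L) x else c(x[1], paste0(x[-1], ".", seq_along(x[-1]) + 1L))
    })
  }
  data.frame(chrom = chrom, start = start, end = end, peak_id = peak_id,
             score = score, summit_offset = summit_offset)
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_peaks()] under the `"narrowPeak"` dialect: columns 5-9
#' other than the score are written as placeholders, the summit offset goes
#' to column 10.
#'
#' @param peaks A peak data.frame (see [read_peaks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_narrowpeak <- function(peaks, path) {
  stopifnot(is.data.frame(peaks))
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    score, ".", -1, -1, -1, peaks$summit_offset)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a position frequency matrix
#'
#' @param counts 4 x L numeric matrix of non-negative base counts, rows in
#'   A, C, G, T order (rownames are set accordingly).
#' @param motif_id Motif identifier (e.g. a JASPAR accession).
#' @param tf_name TF name.
#' @return An object of class `pfm`.
#' @export
new_pfm <- function(counts, motif_id = "motif", tf_name = motif_id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("a PFM needs 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L) stop("motif length must be >= 4")
  if (any(counts < 0)) stop("negative counts in PFM")
  if (any(colSums(counts) <= 0)) stop("PFM has a zero-sum column")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(counts, motif_id = motif_id, tf_name = tf_name,
            class = c("pfm", "matrix", "array"))
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM %s (%s), %d columns\n", attr(x, "motif_id"),
              attr(x, "tf_name"), ncol(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text format: a `>ID NAME` header followed by four
#' bracketed rows, e.g. `A [ 10 5 0 ]`. Rows may appear in any order (they
#' are labelled); the result is always in A, C, G, T order.
#'
#' @param path Path to a JASPAR PFM file (one or more records).
#' @return A list of `pfm` objects.
#' @export
read_jaspar_pfm <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) stop("no JASPAR records (no '>' header) in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    header <- sub("^>", "", lines[starts[k]])
    parts <- strsplit(header, "[ \t]+")[[1]]
    motif_id <- parts[1]
    tf_name <- if (length(parts) >= 2L) parts[2] else motif_id
    body <- lines[(starts[k] + 1L):ends[k]]
    body <- body[grepl("^[ACGTacgt]", body)]
    if (length(body) != 4L)
      stop(sprintf("record %s: expected 4 base rows, found %d",
                   motif_id, length(body)))
    base <- toupper(substr(body, 1, 1))
    if (!setequal(base, c("A", "C", "G", "T")))
      stop("record ", motif_id, ": base rows must be A, C, G, T")
    vals <- lapply(body, function(l) {
      nums <- gsub("[][]", " ", sub("^[ACGTacgt]", "", l))
      as.numeric(strsplit(trimws(nums), "[ \t]+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1L)
      stop("record ", motif_id, ": unequal row lengths")
    counts <- do.call(rbind, vals[order(match(base, c("A", "C", "G", "T")))])
    new_pfm(counts, motif_id = motif_id, tf_name = tf_name)
  })
}

#' Write position frequency matrices in JASPAR format
#'
#' @param pfms A `pfm` or list of `pfm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  if (is(pfms, "pfm")) pfms <- list(pfms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", attr(p, "motif_id"), attr(p, "tf_name")), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(sprintf("%.10g", unclass(p)[b, ]),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write called sites as BED6
#'
#' Writes one line per site: chrom, start, end (0-based half-open),
#' `name = "<TF>_<dataset_id>"`, the PWM log-odds score rounded to 3
#' decimals, and strand. Input must already be sorted by (chrom, start);
#' sorting is the caller's explicit step.
#'
#' @param sites Site data.frame (see [scan_best_hit()]).
#' @param path Output path.
#' @param tf_name,dataset_id Components of the BED name column.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, tf_name = "TF",
                            dataset_id = "dataset") {
  if (nrow(sites) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  o <- order(sites$chrom, sites$start)
  if (!identical(o, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, start) before writing")
  out <- data.frame(sites$chrom, sites$start, sites$end,
                    paste0(tf_name, "_", dataset_id),
                    sprintf("%.3f", sites$score), sites$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 site file written by [write_sites_bed()]
#'
#' @param path Path to a BED6 file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_sites_bed <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  d <- read.table(path, sep = "\t", header = FALSE,
                  colClasses = c("character", "integer", "integer",
                                 "character", "numeric", "character"))
  names(d) <- c("chrom", "start", "end", "name", "score", "strand")
  d
}
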