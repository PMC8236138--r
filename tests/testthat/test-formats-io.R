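test_that("narrowPeak fields map to peak coordinates and summit offsets", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t300\tp1\t0\t.\t5.0\t4.0\t3.0\t50",
               "chr2\t0\t200\tp2\t10\t.\t1\t1\t1\t199"), f)
  p <- read_peaks(f, "narrowPeak")
  expect_equal(p$chrom, c("chr1", "chr2"))
  expect_equal(p$start, c(100L, 0L))
  expect_equal(p$end, c(300L, 200L))
  expect_equal(p$summit_offset, c(50L, 199L))
  expect_equal(p$peak_id, c("p1", "p2"))
})

test_that("bed_midpoint dialect places the summit at the floored midpoint", {
  f <- withr::local_tempfile()
  writeLines("chr1\t100\t301", f)
  p <- read_peaks(f, "bed_midpoint")
  expect_equal(p$summit_offset, 100L)
})

test_that("malformed peak lines are rejected with a line number", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t300\tp1\t0\t.\t1\t1\t1\t50",
               "chr1\t300\t100\tp2\t0\t.\t1\t1\t1\t50"), f)
  expect_error(read_peaks(f, "narrowPeak"), "line 2")
  writeLines("chr1\t100\t300\tpX\t0\t.\t1\t1\t1\t250", f)
  expect_error(read_peaks(f, "narrowPeak"), "pX")
})

test_that("duplicated peak ids are auto-suffixed to uniqueness", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t300\tdup\t0\t.\t1\t1\t1\t50",
               "chr1\t500\t700\tdup\t0\t.\t1\t1\t1\t50"), f)
  p <- read_peaks(f, "narrowPeak")
  expect_false(anyDuplicated(p$peak_id) > 0)
})

test_that("peaks survive a narrowPeak write/read round trip", {
  fx <- small_fixture()
  f <- withr::local_tempfile()
  write_peaks_narrowpeak(fx$peaks, f)
  back <- read_peaks(f, "narrowPeak")
  expect_equal(back[, c("chrom", "start", "end", "peak_id",
                        "summit_offset")],
               fx$peaks[, c("chrom", "start", "end", "peak_id",
                            "summit_offset")])
})

test_that("JASPAR PFMs parse with labelled rows in any order", {
  f <- withr::local_tempfile()
  writeLines(c(">MA0001.1 TFA",
               "C [ 0 10 ]",
               "A [ 10 0 ]",
               "T [ 0 0 ]",
               "G [ 0 0 ]"), f)
  expect_error(read_jaspar_pfm(f), "length") # L = 2 < 4 is invalid
  writeLines(c(">MA0001.1 TFA",
               "C [ 0 10 0 1 ]",
               "A [ 10 0 0 1 ]",
               "T [ 0 0 10 1 ]",
               "G [ 0 0 0 7 ]"), f)
  pfms <- read_jaspar_pfm(f)
  expect_length(pfms, 1L)
  expect_equal(unclass(pfms[[1]])["A", ], c(10, 0, 0, 1))
  expect_equal(unclass(pfms[[1]])["C", ], c(0, 10, 0, 1))
  expect_equal(colSums(unclass(pfms[[1]])), c(10, 10, 10, 10))
})

test_that("JASPAR files with missing rows or ragged rows are rejected", {
  f <- withr::local_tempfile()
  writeLines(c(">M1 X", "A [ 1 1 1 1 ]", "C [ 1 1 1 1 ]",
               "G [ 1 1 1 1 ]"), f)
  expect_error(read_jaspar_pfm(f), "4 base rows")
  writeLines(c(">M1 X", "A [ 1 1 1 1 ]", "C [ 1 1 1 ]",
               "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]"), f)
  expect_error(read_jaspar_pfm(f), "unequal")
})

test_that("multi-record JASPAR files round-trip through write/read", {
  pfms <- list(tiny_pfm(), make_pfm(seed = 7, motif_id = "SYN0002"))
  f <- withr::local_tempfile()
  write_jaspar_pfm(pfms, f)
  back <- read_jaspar_pfm(f)
  expect_length(back, 2L)
  for (k in 1:2) {
    expect_equal(unclass(back[[k]]), unclass(pfms[[k]]),
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(attr(back[[k]], "motif_id"), attr(pfms[[k]], "motif_id"))
  }
})

test_that("site BED output is BED6 with strand and rounded score", {
  sites <- data.frame(chrom = "chr1", start = 100L, end = 114L,
                      strand = "-", score = 12.3456, norm_score = 0.9,
                      peak_id = "p1", dist_to_summit = 3L)
  f <- withr::local_tempfile()
  write_sites_bed(sites, f, tf_name = "CTCF", dataset_id = "ds1")
  lines <- readLines(f)
  expect_equal(strsplit(lines, "\t")[[1]],
               c("chr1", "100", "114", "CTCF_ds1", "12.346", "-"))
})

test_that("site BED round trip reproduces coordinates exactly", {
  fx <- small_fixture()
  run_sites <- collect_landscape(fx$peaks, fx$genome,
                                 pfm_to_pwm(fx$pfm))
  run_sites <- run_sites[order(run_sites$chrom, run_sites$start), ]
  f <- withr::local_tempfile()
  write_sites_bed(run_sites, f)
  back <- read_sites_bed(f)
  expect_equal(back$start, run_sites$start)
  expect_equal(back$end, run_sites$end)
  expect_equal(back$strand, run_sites$strand)
  expect_equal(back$end - back$start,
               rep(motif_length(fx$pfm), nrow(back)))
})

test_that("unsorted sites are refused and empty site lists give empty files", {
  sites <- data.frame(chrom = c("chr1", "chr1"), start = c(200L, 100L),
                      end = c(214L, 114L), strand = "+", score = 1,
                      norm_score = 0.5, peak_id = c("a", "b"),
                      dist_to_summit = 0L)
  f <- withr::local_tempfile()
  expect_error(write_sites_bed(sites, f), "sorted")
  write_sites_bed(sites[0, ], f)
  expect_equal(file.size(f), 0)
  expect_equal(nrow(read_sites_bed(f)), 0L)
})

test_that("genome access is half-open, upper-cased and bounds-checked", {
  g <- Biostrings::DNAStringSet(c(chr1 = "acgtACGTNN"))
  expect_equal(get_sequence(g, "chr1", 0, 4), "ACGT")
  expect_equal(nchar(get_sequence(g, "chr1", 2, 9)), 7L)
  expect_equal(get_sequence(g, "chr1", 8, 10), "NN")
  expect_error(get_sequence(g, "chr1", 5, 11), "out of bounds")
  expect_error(get_sequence(g, "chr2", 0, 4), "unknown")
  f <- withr::local_tempfile()
  write_genome_fasta(g, f)
  expect_equal(as.character(read_genome_fasta(f)[["chr1"]]), "ACGTACGTNN")
})
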