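# Independent Kapur oracle: histogram via hist(), entropies by explicit
# loops, exhaustive search over every interior bin boundary.
oracle_kapur <- function(values, n_bins = 100L) {
  h <- hist(values, breaks = seq(min(values), max(values),
                                 length.out = n_bins + 1L), plot = FALSE)
  p <- h$counts / sum(h$counts)
  shannon <- function(q) {
    q <- q[q > 0]
    if (!length(q)) return(0)
    q <- q / sum(q)
    -sum(q * log(q))
  }
  obj <- rep(NA_real_, n_bins - 1L)
  for (k in 1:(n_bins - 1L))
    obj[k] <- shannon(p[1:k]) + shannon(p[(k + 1):n_bins])
  ties <- which(obj >= max(obj) - 1e-12)
  h$breaks[ties[(length(ties) + 1L) %/% 2L] + 1L]
}

test_that("the landscape has exactly one best hit per scannable peak", {
  fx <- small_fixture()
  pwm <- pfm_to_pwm(fx$pfm)
  hits <- collect_landscape(fx$peaks, fx$genome, pwm)
  expect_equal(nrow(hits), nrow(fx$peaks))
  expect_false(anyDuplicated(hits$peak_id) > 0)
  expect_true(all(hits$norm_score >= 0 & hits$norm_score <= 1))
  expect_true(all(hits$dist_to_summit >= 0))
  # sites lie inside their peaks
  m <- match(hits$peak_id, fx$peaks$peak_id)
  expect_true(all(hits$start >= fx$peaks$start[m] &
                    hits$end <= fx$peaks$end[m]))
})

test_that("per-peak landscape hits equal brute-force enumeration", {
  fx <- small_fixture()
  pwm <- pfm_to_pwm(fx$pfm)
  set.seed(31)
  idx <- sample(nrow(fx$peaks), 20)
  peaks <- fx$peaks[idx, ]
  hits <- collect_landscape(peaks, fx$genome, pwm)
  for (i in seq_len(nrow(peaks))) {
    seq <- get_sequence(fx$genome, peaks$chrom[i], peaks$start[i],
                        peaks$end[i])
    want <- brute_best_hit(seq, pwm)
    got <- hits[hits$peak_id == peaks$peak_id[i], ]
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$start - peaks$start[i], want$start)
  }
})

test_that("a consensus site at the summit yields near-zero distance", {
  g <- make_genome(c(chr1 = 5000L), seed = 2)
  pfm <- tiny_pfm()
  pl <- plant_peaks(g, pfm, 1, 0, peak_width = 400L, summit_jitter_sd = 0,
                    seed = 3, consensus_only = TRUE)
  hits <- collect_landscape(pl$peaks, pl$genome, pfm_to_pwm(pfm))
  expect_lte(hits$dist_to_summit, 1L) # L even: midpoint sits within 1 bp
})

test_that("maximum-entropy thresholds match the exhaustive oracle", {
  set.seed(17)
  for (i in 1:50) {
    values <- c(rnorm(sample(50:400, 1), 0.25, 0.05 * runif(1, 0.5, 2)),
                runif(sample(50:400, 1)))
    expect_equal(as.numeric(max_entropy_threshold(values)),
                 oracle_kapur(values), tolerance = 1e-12)
  }
})

test_that("the threshold separates two well-separated point masses", {
  set.seed(23)
  values <- c(rnorm(1000, 0.2, 0.01), rnorm(1000, 0.9, 0.01))
  t <- max_entropy_threshold(values)
  expect_gt(t, 0.25)
  expect_lt(t, 0.85)
})

test_that("equal-width binning makes the threshold scale-equivariant", {
  set.seed(29)
  values <- c(rnorm(300, 10, 1), rnorm(300, 40, 4))
  t1 <- as.numeric(max_entropy_threshold(values))
  t2 <- as.numeric(max_entropy_threshold(values * 7))
  expect_equal(t2, 7 * t1, tolerance = 1e-9)
  expect_error(max_entropy_threshold(rep(1, 10)), "distinct")
})

test_that("too few hits give an explicit no-zone result", {
  fx <- small_fixture()
  hits <- collect_landscape(fx$peaks[1:10, ], fx$genome,
                            pfm_to_pwm(fx$pfm))
  zone <- define_enrichment_zone(hits)
  expect_false(zone$defined)
  expect_true(is.na(zone$score_threshold))
  expect_error(call_tfbs(fx$peaks, pfm_to_pwm(fx$pfm), zone, fx$genome),
               "undefined")
})

test_that("zone membership is monotone in score and distance", {
  fx <- small_fixture()
  hits <- collect_landscape(fx$peaks, fx$genome, pfm_to_pwm(fx$pfm))
  zone <- define_enrichment_zone(hits)
  expect_true(zone$defined)
  inside <- hits[in_zone(hits, zone), ]
  # raising score / lowering distance never leaves the zone
  boosted <- inside
  boosted$norm_score <- pmin(1, boosted$norm_score + 0.01)
  boosted$dist_to_summit <- pmax(0, boosted$dist_to_summit - 5)
  expect_true(all(in_zone(boosted, zone)))
})

test_that("zone detection keeps planted hits and rejects diffuse noise", {
  # 80% of hits concentrated at the summit with high scores, 20% uniform
  set.seed(41)
  for (rep in 1:5) {
    n <- 500
    planted <- data.frame(norm_score = rnorm(0.8 * n, 0.95, 0.01),
                          dist_to_summit = abs(rnorm(0.8 * n, 0, 2)))
    noise <- data.frame(norm_score = runif(0.2 * n, 0, 1),
                        dist_to_summit = runif(0.2 * n, 0, 200))
    hits <- rbind(planted, noise)
    zone <- define_enrichment_zone(hits)
    expect_gte(mean(in_zone(planted, zone)), 0.9)
    expect_lte(mean(in_zone(noise, zone)), 0.2)
  }
})

test_that("called sites are unique per peak and hit planted coordinates", {
  g <- make_genome(c(chr1 = 100000L, chr2 = 100000L), seed = 5)
  pfm <- make_pfm(seed = 6)
  pl <- plant_peaks(g, pfm, 80, 20, summit_jitter_sd = 0, seed = 7,
                    consensus_only = TRUE)
  pwm <- pfm_to_pwm(pfm)
  hits <- collect_landscape(pl$peaks, pl$genome, pwm)
  zone <- define_enrichment_zone(hits)
  called <- call_tfbs(pl$peaks, pwm, zone, pl$genome)
  expect_lte(nrow(called), nrow(pl$peaks))
  expect_false(anyDuplicated(called$peak_id) > 0)
  expect_identical(order(called$chrom, called$start),
                   seq_len(nrow(called)))
  # every called planted peak sits on its planted coordinates +/- 1 bp
  tr <- pl$truth[pl$truth$planted, ]
  m <- match(called$peak_id, tr$peak_id)
  hit_planted <- !is.na(m)
  expect_gt(mean(hit_planted), 0.8)
  expect_true(all(abs(called$start[hit_planted] -
                        tr$plant_start[m[hit_planted]]) <= 1))
})
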