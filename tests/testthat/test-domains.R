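test_that("insulation score is zero on a uniform matrix and symmetric", {
  m <- cm_from(matrix(5, 50, 50), resolution = 5e4, state = "balanced")
  ins <- insulation_score(m, window_bins = 5)
  eligible <- 6:45
  expect_equal(ins[eligible], rep(0, length(eligible)))
  expect_true(all(is.na(ins[c(1:5, 46:50)])))

  # transpose invariance (symmetry of the window)
  set.seed(6)
  v <- matrix(rpois(2500, 10) + 1, 50, 50)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  m2 <- cm_from(v, resolution = 5e4, state = "balanced")
  m2t <- cm_from(t(v), resolution = 5e4, state = "balanced")
  expect_equal(insulation_score(m2, 5), insulation_score(m2t, 5))
  expect_error(insulation_score(cm_from(matrix(1, 8, 8)), 5), "shorter")
})

test_that("two touching TADs give a unique insulation minimum at the join", {
  # brute-force oracle: recompute every window mean with explicit loops
  n <- 60
  labels <- rep(1:2, each = 30)
  v <- block_matrix(labels, within = 3, between = 1, decay = 0.5)
  m <- cm_from(v, resolution = 5e4, state = "balanced")
  w <- 5
  ins <- insulation_score(m, w)
  oracle <- rep(NA_real_, n)
  for (b in (w + 1):(n - w)) {
    s <- 0
    for (i in (b - w):(b - 1)) for (j in (b + 1):(b + w)) s <- s + v[i, j]
    oracle[b] <- s / w^2
  }
  oracle <- log2(oracle / mean(oracle, na.rm = TRUE))
  expect_equal(ins, oracle)
  expect_equal(which.min(ins), 30)
})

test_that("moving-average smoothing shrinks at edges and spreads spikes", {
  expect_equal(smooth_insulation(rep(2, 10), 7), rep(2, 10))

  x <- rep(0, 21); x[11] <- 7
  sm <- smooth_insulation(x, 7)
  expect_equal(sm[8:14], rep(1, 7))
  expect_equal(sm[15], 0)

  ramp <- 1:20
  smr <- smooth_insulation(ramp, 7)
  expect_equal(smr[4:17], as.numeric(4:17))
  # edges shrink symmetrically: first value is its own window
  expect_equal(smr[1], 1)
  expect_equal(smr[2], 2)
})

test_that("border calling applies the cutoff and leftmost-plateau rule", {
  x <- rep(0, 20); x[10] <- -0.10
  expect_equal(call_tad_borders(x, cutoff = -0.086), 10L)
  x2 <- rep(0, 20); x2[10] <- -0.05
  expect_equal(call_tad_borders(x2, cutoff = -0.086), integer())
  # plateau minimum: leftmost bin wins
  x3 <- rep(0, 20); x3[10:11] <- -0.2
  expect_equal(call_tad_borders(x3, cutoff = -0.086), 10L)
  # boundary value exactly at the cutoff is not a border (strict)
  x4 <- rep(0, 20); x4[10] <- -0.086
  expect_equal(call_tad_borders(x4, cutoff = -0.086), integer())
})

test_that("TADs tile between borders and respect mask gaps", {
  bins <- bin_table("chrX", 20 * 5e4, 5e4)
  tads <- tads_from_borders(c(7L, 13L), bins)
  expect_equal(nrow(tads), 3)
  expect_equal(tads$first_bin, c(1, 8, 14))
  expect_equal(tads$last_bin, c(7, 13, 20))

  expect_equal(nrow(tads_from_borders(integer(), bins)), 1)

  # a masked gap breaks TADs; short fragments are discarded
  bins$masked[9:10] <- TRUE
  tads2 <- tads_from_borders(c(4L), bins, min_bins = 3)
  expect_equal(tads2$first_bin, c(1, 5, 11))
  expect_equal(tads2$last_bin, c(4, 8, 20))
  # border adjacent to the gap: the gap edge delimits the TAD
  tads3 <- tads_from_borders(c(8L), bins, min_bins = 3)
  expect_equal(tads3$first_bin, c(1, 11))
  expect_equal(tads3$last_bin, c(8, 20))
})

test_that("domain score matches closed forms and scaling invariance", {
  # a TAD contacting nothing outside scores 1
  v <- matrix(0, 20, 20)
  v[1:5, 1:5] <- 2
  v[6:20, 6:20] <- 1
  m <- cm_from(v, resolution = 5e4, state = "balanced")
  tads <- data.frame(chrom = "chrX", start = 0, end = 5 * 5e4,
                     first_bin = 1, last_bin = 5)
  expect_equal(domain_score(m, tads), 1)

  # uniform matrix: k-bin TAD on an n-bin chromosome scores k/n exactly
  u <- cm_from(matrix(1, 100, 100), resolution = 5e4, state = "balanced")
  tads2 <- data.frame(chrom = "chrX", start = 0, end = 5e5,
                      first_bin = 1, last_bin = 10)
  expect_equal(domain_score(u, tads2), 10 / 100)

  # invariant to global scaling, in [0,1], increasing in enrichment
  set.seed(16)
  ds_at <- function(enrich) {
    labels <- rep(1:4, each = 10)
    v <- block_matrix(labels, within = enrich, between = 1, decay = 1)
    counts <- matrix(rpois(1600, v * 400), 40, 40)
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
    m <- cm_from(counts, resolution = 5e4)
    tads <- data.frame(chrom = "chrX", start = 0, end = 10 * 5e4,
                       first_bin = 11, last_bin = 20)
    domain_score(m, tads)
  }
  d1 <- ds_at(1.5); d2 <- ds_at(2.5); d3 <- ds_at(4)
  expect_true(all(c(d1, d2, d3) >= 0 & c(d1, d2, d3) <= 1))
  expect_true(d1 < d2 && d2 < d3)

  ms <- cm_from(v * 7.5, resolution = 5e4, state = "balanced")
  expect_equal(domain_score(ms, tads), domain_score(m, tads))
})

test_that("relative domain score places the midpoint on the start-end axis", {
  expect_equal(relative_domain_score(0.2, 0.2, 0.6), 0)
  expect_equal(relative_domain_score(0.2, 0.6, 0.6), 1)
  expect_equal(relative_domain_score(0.2, 0.4, 0.6), 0.5)
  expect_true(is.na(relative_domain_score(0.3, 0.31, 0.305)))
  expect_error(relative_domain_score(c(.1, .2), .3, c(.4, .5, .6)), "length")
})

test_that("early/late classification matches the exhaustive 1-D oracle", {
  scores <- c(0.05, 0.06, 0.70, 0.72)
  cls <- classify_tads_early_late(scores, seed = 1)
  expect_identical(cls$class, c("late", "late", "early", "early"))
  expect_equal(cls$fraction_early, 0.5)
  expect_equal(cls$fraction_above_0.2, 0.5)

  # oracle: best 2-partition of sorted values by within-SS over all splits
  best_split <- function(x) {
    xs <- sort(x)
    ss <- sapply(1:(length(xs) - 1), function(i) {
      a <- xs[1:i]; b <- xs[-(1:i)]
      sum((a - mean(a))^2) + sum((b - mean(b))^2)
    })
    xs[which.min(ss)]  # largest value of the lower cluster
  }
  set.seed(17)
  for (rep in 1:5) {
    x <- c(runif(10, 0, 0.3), runif(10, 0.6, 1))
    cls2 <- classify_tads_early_late(x, seed = rep)
    thr <- best_split(x)
    expect_identical(cls2$class == "early", x > thr)
  }

  expect_error(classify_tads_early_late(rep(0.5, 10)), "identical")
  # permutation invariance of labels
  x <- c(0.1, 0.9, 0.15, 0.8, 0.05, 0.85)
  p <- c(3, 1, 5, 2, 6, 4)
  c1 <- classify_tads_early_late(x, seed = 2)$class
  c2 <- classify_tads_early_late(x[p], seed = 2)$class
  expect_identical(c1[p], c2)
})

test_that("relative per-TAD metrics rescale and filter by end-state count", {
  vals <- rbind(c(10, 10, 10),     # flat -> excluded
                c(0, 5, 20),      # rel(D5) = 0.25
                c(0, 7, 14))      # 14 end peaks < 15 -> excluded
  rel <- relative_metric_per_tad(vals, start = 1, end = 3, min_count = 15)
  expect_true(all(is.na(rel[1, ])))
  expect_equal(rel[2, ], c(0, 0.25, 1))
  expect_true(all(is.na(rel[3, ])))

  # expression variant: no count filter, only flatness
  expr <- rbind(c(2, 3, 4), c(5, 5, 5))
  rele <- relative_metric_per_tad(expr, 1, 3, min_count = 0)
  expect_equal(rele[1, ], c(0, 0.5, 1))
  expect_true(all(is.na(rele[2, ])))
})

test_that("planted borders are recovered and insulation IQR tracks depth", {
  cfg <- sim_config(seed = 23, chrom_length = 40e6, resolution = 5e4,
                    depth = 1.2e7, masked_fraction = 0)
  set.seed(23)
  n <- 800
  tid <- xistruct:::make_tad_ids(n, c(30, 60))
  sim <- simulate_hic_matrix(cfg, tad_id = tid, attenuation = 1, damping = 1)
  b <- ice_balance(filter_bins(sim$matrix))
  sm <- smooth_insulation(insulation_score(b, 10), 7)
  borders <- call_tad_borders(sm, -0.086)
  planted <- attr(tid, "borders")
  expect_true(all(vapply(planted,
                         function(x) min(abs(borders - x)) <= 1, logical(1))))
  expect_true(all(vapply(borders,
                         function(x) min(abs(planted - x)) <= 1, logical(1))))

  # insulation range widens as TADs strengthen (attenuation series)
  iqr_at <- function(att, seed) {
    set.seed(seed)
    s <- simulate_hic_matrix(cfg, tad_id = tid, attenuation = att,
                             damping = 1)
    bb <- ice_balance(filter_bins(s$matrix))
    IQR(smooth_insulation(insulation_score(bb, 10), 7), na.rm = TRUE)
  }
  iqrs <- mapply(iqr_at, c(0, 0.5, 1), 101:103)
  expect_true(all(diff(iqrs) > 0))
})
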