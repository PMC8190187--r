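test_that("correlation matrix rescale maps percentiles onto [-1, 1]", {
  set.seed(12)
  labels <- rep(rep(1:2, each = 5), 8)
  v <- block_matrix(labels, within = 3, between = 0.8, decay = 1)
  counts <- matrix(rpois(length(v), v * 200), nrow(v), ncol(v))
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  m <- cm_from(counts, resolution = 5e4)
  cm <- build_correlation_matrix(m)
  cc <- cm$corr
  expect_equal(diag(cc), rep(0, nrow(cc)))
  expect_true(all(cc >= -1 & cc <= 1))
  # two-block planted matrix: within-block correlation near +1 after rescale
  same <- outer(labels, labels, "==")
  off <- upper.tri(cc)
  expect_gt(mean(cc[same & off]), 0.5)
  expect_lt(mean(cc[!same & off]), 0)
  # ~5% of off-diagonal entries saturate at each end by construction
  expect_equal(mean(cc[off] <= -1 + 1e-12), 0.05, tolerance = 0.02)
  expect_equal(mean(cc[off] >= 1 - 1e-12), 0.05, tolerance = 0.02)
})

test_that("k-means on weighted eigenvectors recovers planted blocks", {
  cfg <- sim_config(seed = 8, chrom_length = 18e6, resolution = 5e4,
                    depth = 2e7)
  sim <- simulate_cluster_matrix(cfg, k = 6, n_archetypes = 3)
  cm <- build_correlation_matrix(sim$matrix)
  cl <- cluster_spatial(cm, k = 6, n_eig = 6, restarts = 10, seed = 8)
  tab <- table(cl, sim$cluster)
  # perfect recovery up to label permutation
  expect_equal(sum(apply(tab, 1, max)), length(sim$cluster))

  # determinism given seed
  cl2 <- cluster_spatial(cm, k = 6, n_eig = 6, restarts = 10, seed = 8)
  expect_identical(cl, cl2)

  # k = 2 on a clean two-block matrix: exact recovery
  labels <- rep(rep(1:2, each = 6), 6)
  v <- block_matrix(labels, within = 2, between = 0.4)
  diag(v) <- 0
  cl3 <- cluster_spatial(v, k = 2, n_eig = 2, restarts = 5, seed = 1)
  expect_equal(sum(apply(table(cl3, labels), 1, max)), length(labels))

  # permuting bin order then unpermuting labels changes nothing
  set.seed(99)
  p <- sample(length(labels))
  cl4 <- cluster_spatial(v[p, p], k = 2, n_eig = 2, restarts = 5, seed = 1)
  unperm <- integer(length(labels)); unperm[p] <- cl4
  expect_equal(sum(apply(table(unperm, labels), 1, max)), length(labels))
})

test_that("label alignment equals the exhaustive-permutation oracle", {
  # identical clusterings map to identity
  x <- rep(1:4, each = 10)
  al <- align_cluster_labels(x, x)
  expect_identical(as.integer(al), x)
  expect_identical(attr(al, "mapping"), 1:4)

  # a known permutation is recovered exactly
  pmap <- c(3L, 1L, 4L, 2L)
  al2 <- align_cluster_labels(x, pmap[x])
  expect_identical(as.integer(al2), pmap[x])

  # with label noise, agreement matches brute force over all k! mappings
  set.seed(7)
  for (k in c(3, 5, 6)) {
    ref <- sample(k, 120, replace = TRUE)
    noisy <- ref
    flip <- sample(120, 12)
    noisy[flip] <- sample(k, 12, replace = TRUE)
    scr <- sample(k)  # scramble labels on top of the noise
    lab <- scr[noisy]
    al3 <- align_cluster_labels(lab, ref)
    oracle <- align_oracle(lab, ref, k)
    expect_equal(sum(al3 == ref), oracle$agreement)
    # alignment never decreases agreement relative to the input labelling
    expect_gte(sum(al3 == ref), sum(lab == ref))
  }
})

test_that("cluster interaction matrix averages O/E by label pair", {
  n <- 40
  u <- cm_from(matrix(2, n, n), state = "observed_over_expected")
  clustering <- rep(1:4, each = 10)
  cim <- cluster_interaction_matrix(u, clustering)
  expect_equal(cim, matrix(2, 4, 4))

  labels <- rep(rep(1:4, each = 5), 2)
  v <- block_matrix(labels, within = 3, between = 0.5)
  mb <- cm_from(v, state = "observed_over_expected")
  cimb <- cluster_interaction_matrix(mb, labels)
  expect_equal(cimb, t(cimb))
  expect_gt(min(diag(cimb)), max(cimb[upper.tri(cimb)]))
  expect_error(cluster_interaction_matrix(u, rep(c(1, 3), each = 20)),
               "empty cluster")
})

test_that("consolidation groups archetypes and orders them by PC1", {
  cfg <- sim_config(seed = 5, chrom_length = 36e6, resolution = 5e4,
                    depth = 4e7)
  sim <- simulate_cluster_matrix(cfg)
  cm <- build_correlation_matrix(sim$matrix)
  cl <- cluster_spatial(cm, 12, 12, 10, seed = 5)
  al <- align_cluster_labels(cl, sim$cluster)
  oe <- observed_over_expected(sim$matrix)$matrix
  cim <- cluster_interaction_matrix(oe, al)
  cons <- consolidate_subcompartments(al, cim, sim$pc1_proxy)
  # clusters sharing an archetype share a subcompartment, exactly
  expect_equal(length(unique(cons$cluster_to_sub)), 5)
  tab <- table(cons$cluster_to_sub, sim$archetype)
  expect_equal(sum(apply(tab, 1, max)), 12)
  # the group with the highest mean PC1 is A1, the lowest B2
  by_sub <- tapply(sim$pc1_proxy, cons$subcompartment, mean)
  expect_equal(names(which.max(by_sub)), "A1")
  expect_equal(names(which.min(by_sub)), "B2")
  ord <- by_sub[c("A1", "A2", "AB", "B1", "B2")]
  expect_true(all(diff(ord) < 0))
  expect_error(consolidate_subcompartments(rep(1:4, 10), matrix(1, 4, 4),
                                           rnorm(40)), "at least 5")
})

test_that("PC1 ties in consolidation break by the smaller lowest cluster id", {
  # two groups with identical mean PC1: 4 clusters, 2 interaction archetypes
  clustering <- rep(1:4, each = 10)
  cim <- diag(4) + 1
  cim[1, 2] <- cim[2, 1] <- 2  # clusters 1+2 alike
  cim[3, 4] <- cim[4, 3] <- 2  # clusters 3+4 alike
  pc1 <- rep(0, 40)            # all means tie
  # k = 5 impossible with 4 clusters; use the internal order helper through
  # a 5-cluster variant
  cim5 <- diag(5) + 1
  cim5[1, 2] <- cim5[2, 1] <- 2
  clustering5 <- rep(1:5, each = 8)
  cons <- consolidate_subcompartments(clustering5, cim5, rep(0, 40))
  # every group ties at mean PC1 zero: names assigned in order of the
  # lowest member cluster id
  grp_of <- cons$cluster_to_sub
  first_ids <- tapply(seq_len(5), grp_of, min)
  expect_identical(names(sort(first_ids)),
                   c("A1", "A2", "AB", "B1", "B2")[seq_along(first_ids)])
})

test_that("inter-mega-domain strong-interaction fractions follow planting", {
  n <- 60
  set.seed(14)
  v <- matrix(runif(n * n, 0.5, 1.5), n, n)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  clustering <- rep(1:3, each = 20)
  # boost cluster 2's cross-boundary long-range contacts tenfold
  left <- 1:30; right <- 31:60
  boost <- clustering == 2
  v[boost, right] <- v[boost, right] * ifelse(outer(rep(TRUE, sum(boost)),
                                                    right > 30), 10, 1)
  v[right, boost] <- t(v[boost, right])
  m <- cm_from(v, resolution = 1e5, state = "balanced")
  frac <- inter_megadomain_fraction(m, clustering, split_point = 30e5,
                                    min_dist = 5e5)
  expect_true(which.max(frac) == 2)
  expect_true(all(frac >= 0 & frac <= 1, na.rm = TRUE))

  # all qualifying values equal: every pair ties at the threshold -> 1.0
  ve <- matrix(1, n, n)
  me <- cm_from(ve, resolution = 1e5, state = "balanced")
  frace <- inter_megadomain_fraction(me, clustering, split_point = 30e5,
                                     min_dist = 5e5)
  expect_equal(unname(frace), rep(1, 3))

  # a cluster with no qualifying pairs is missing, not zero
  clustering2 <- c(rep(1, 30), rep(2, 29), 3)
  frac2 <- inter_megadomain_fraction(m, clustering2, split_point = 30e5,
                                     min_dist = 28e5)
  expect_true(is.na(frac2[3]) || frac2[3] >= 0)  # bin 60 may not qualify

  # without ties the pair-weighted mean fraction equals top_frac
  frac_all <- inter_megadomain_fraction(m, rep(1, n), split_point = 30e5,
                                        min_dist = 5e5, top_frac = 0.2)
  expect_equal(unname(frac_all[1]), 0.2, tolerance = 0.01)
})

test_that("track aggregation weights overlaps and tests cluster contrasts", {
  bins <- bin_table("chrX", 10e5, 1e5)
  clustering <- rep(1:2, each = 5)

  # constant track: all groups equal, p = 1
  track <- data.frame(chrom = "chrX", start = 0, end = 10e5, value = 2)
  ann <- annotate_clusters_with_track(clustering, bins, track)
  expect_equal(unname(ann$means), c(2, 2))
  expect_equal(ann$pvalues[1, 2], 1)

  # track equal to cluster id separates groups perfectly
  track2 <- data.frame(chrom = "chrX", start = c(0, 5e5), end = c(5e5, 10e5),
                       value = c(1, 2))
  ann2 <- annotate_clusters_with_track(clustering, bins, track2)
  expect_equal(unname(ann2$means), c(1, 2))
  expect_lt(ann2$pvalues[1, 2], 0.01)

  # an interval covering half a bin contributes with half the weight
  track3 <- data.frame(chrom = "chrX", start = c(0, 5e4), end = c(5e4, 1e5),
                       value = c(4, 0))
  ann3 <- annotate_clusters_with_track(clustering, bins, track3)
  expect_equal(ann3$bin_values[1], (4 * 5e4 + 0 * 5e4) / 1e5)

  trackw <- data.frame(chrom = "chr1", start = 0, end = 1e5, value = 1)
  expect_error(annotate_clusters_with_track(clustering, bins, trackw),
               "different chromosome")
})
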