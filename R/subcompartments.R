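#' Clipped correlation matrix for spatial clustering
#'
#' Prepares the bin-bin similarity matrix that spatial clustering runs on:
#' observed-over-expected normalization, ICE row-sum balancing, clipping of
#' outlier entries above the 90th percentile, Pearson correlation, zeroed
#' diagonal, then a linear rescale that maps the 5th/95th percentiles of the
#' correlation values onto -1/+1 (clipping outside).
#'
#' @param matrix raw `ContactMatrix` with mask flags.
#' @param clip_q percentile for entry clipping before correlation.
#' @param rescale_q two-sided percentile pair for the final rescale.
#' @return list: `corr` (n x n matrix, NA rows/cols at masked bins) and
#'   `keep` (indices of unmasked bins).
#' @export
build_correlation_matrix <- function(matrix, clip_q = 0.9,
                                     rescale_q = c(0.05, 0.95)) {
  oe <- observed_over_expected(matrix)$matrix
  # empty distance classes (single far pairs with zero counts) carry no
  # signal; treat them as zero contact before balancing
  und <- is.na(oe$values) & !oe$bins$masked[row(oe$values)] &
    !oe$bins$masked[col(oe$values)]
  oe$values[und] <- 0
  bal <- ice_balance(oe)
  keep <- which(!bal$bins$masked)
  m <- bal$values[keep, keep, drop = FALSE]
  m[is.na(m)] <- 0
  hi <- stats::quantile(m, clip_q, type = 7)
  m[m > hi] <- hi
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate constant rows in balanced matrix")
  cc <- stats::cor(m)
  diag(cc) <- 0
  q <- stats::quantile(cc, rescale_q, type = 7)
  cc <- (cc - q[1]) / (q[2] - q[1]) * 2 - 1
  cc[cc < -1] <- -1
  cc[cc > 1] <- 1
  diag(cc) <- 0
  n <- nrow(matrix$bins)
  out <- matrix(NA_real_, n, n)
  out[keep, keep] <- cc
  list(corr = out, keep = keep)
}

kmeanspp_centers <- function(x, k) {
  # k-means++ seeding: first center uniform, then proportional to squared
  # distance to the nearest chosen center
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - x[rep(centers[1], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1)) {
    p <- d2 / sum(d2)
    centers[j + 1] <- sample.int(n, 1, prob = p)
    nd2 <- rowSums((x - x[rep(centers[j + 1], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd2)
  }
  x[centers, , drop = FALSE]
}

#' Spatial clustering on weighted eigenvectors
#'
#' Eigendecomposes the clipped correlation matrix, builds a feature matrix
#' from the `n_eig` leading eigenvectors (by algebraic eigenvalue,
#' descending) each scaled by its signed eigenvalue, and runs k-means with
#' k-means++ initialization, keeping the best of `restarts` runs by total
#' within-cluster sum of squares.
#'
#' @param corr output of [build_correlation_matrix()] (or a bare symmetric
#'   matrix, taken to be fully unmasked).
#' @param k number of clusters (default 12).
#' @param n_eig number of leading eigenvectors (default 12).
#' @param restarts k-means restarts (default 10).
#' @param seed RNG seed for reproducible clustering.
#' @return integer vector of cluster ids (1..k) per bin, NA at masked bins.
#' @export
cluster_spatial <- function(corr, k = 12, n_eig = 12, restarts = 10,
                            seed = 1L) {
  if (is.matrix(corr)) corr <- list(corr = corr, keep = seq_len(nrow(corr)))
  keep <- corr$keep
  if (k > length(keep)) stop("k exceeds the number of unmasked bins")
  cc <- corr$corr[keep, keep, drop = FALSE]
  ev <- eigen(cc, symmetric = TRUE)
  use <- seq_len(min(n_eig, ncol(ev$vectors)))
  if (sum(ev$values > 0) < n_eig)
    warning("fewer than ", n_eig, " positive eigenvalues; using signed values")
  feats <- ev$vectors[, use, drop = FALSE] %*% diag(ev$values[use], length(use))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    cen <- kmeanspp_centers(feats, k)
    fit <- suppressWarnings(
      stats::kmeans(feats, centers = cen, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  out <- rep(NA_integer_, nrow(corr$corr))
  out[keep] <- best$cluster
  out
}

#' Align cluster labels to a reference clustering
#'
#' Finds the bijective relabelling of `labels` that maximizes the total
#' number of bins agreeing with `reference_labels` (optimal assignment on
#' the k x k contingency table, solved as a maximum-weight bipartite
#' matching).
#'
#' @param labels integer cluster ids (1..k, NA allowed).
#' @param reference_labels reference ids over the same bins, same k.
#' @return relabelled integer vector; attribute `mapping` gives, for each
#'   input label, the reference label it was mapped to.
#' @export
align_cluster_labels <- function(labels, reference_labels) {
  if (length(labels) != length(reference_labels))
    stop("clusterings cover different bin sets")
  ok <- !is.na(labels) & !is.na(reference_labels)
  k <- max(labels, reference_labels, na.rm = TRUE)
  tab <- matrix(0, k, k)
  t0 <- table(factor(labels[ok], levels = 1:k),
              factor(reference_labels[ok], levels = 1:k))
  tab[] <- as.numeric(t0)
  g <- igraph::graph_from_biadjacency_matrix(tab + 1e-9, weighted = TRUE)
  m <- igraph::max_bipartite_match(g)
  mapping <- m$matching[seq_len(k)] - k  # row node i matched to col node
  out <- mapping[labels]
  attributes(out) <- NULL
  out <- as.integer(out)
  attr(out, "mapping") <- as.integer(mapping)
  out
}

#' Mean O/E interaction between clusters
#'
#' Entry (c1, c2) is the mean O/E value over all unmasked bin pairs with
#' those cluster labels, excluding the matrix diagonal.
#'
#' @param matrix O/E `ContactMatrix`.
#' @param clustering integer cluster ids per bin (NA at masked bins).
#' @return k x k symmetric matrix of mean interactions.
#' @export
cluster_interaction_matrix <- function(matrix, clustering) {
  k <- max(clustering, na.rm = TRUE)
  if (any(tabulate(clustering, k) == 0)) stop("empty cluster")
  v <- matrix$values
  ij <- which(!is.na(v) & row(v) != col(v), arr.ind = TRUE)
  ci <- clustering[ij[, 1]]; cj <- clustering[ij[, 2]]
  ok <- !is.na(ci) & !is.na(cj)
  key <- (ci[ok] - 1) * k + cj[ok]
  s <- rowsum(v[ij[ok, , drop = FALSE]], key)
  n <- rowsum(rep(1, sum(ok)), key)
  out <- matrix(NA_real_, k, k)
  at <- as.integer(rownames(s))
  out[cbind((at - 1) %/% k + 1, (at - 1) %% k + 1)] <- s[, 1] / n[, 1]
  (out + t(out)) / 2
}

#' Consolidate spatial clusters into five subcompartments
#'
#' Groups the k cluster interaction profiles into 5 subcompartments by
#' average-linkage hierarchical clustering (Euclidean distance on the rows
#' of the cluster-interaction matrix, with the self-interaction diagonal
#' left out: grouping reflects how clusters interact with the rest of the
#' chromosome, not their internal cohesion), orders the groups by
#' descending mean calibrated PC1 of their member bins, and names them A1,
#' A2, AB, B1, B2 in that order. Ties in mean PC1 are broken by the smaller
#' lowest cluster id.
#'
#' @param clustering integer cluster ids per bin.
#' @param cluster_interactions k x k matrix from
#'   [cluster_interaction_matrix()].
#' @param pc1 per-bin calibrated PC1 (reference sample).
#' @return list: `subcompartment` (per-bin factor-like character vector),
#'   `cluster_to_sub` (named character vector mapping cluster id ->
#'   subcompartment).
#' @export
consolidate_subcompartments <- function(clustering, cluster_interactions, pc1) {
  k <- nrow(cluster_interactions)
  if (k < 5) stop("need at least 5 clusters to form 5 subcompartments")
  ci <- cluster_interactions
  diag(ci) <- NA  # mutual interactions only; dist() rescales over shared coords
  hc <- stats::hclust(stats::dist(ci), method = "average")
  grp <- stats::cutree(hc, k = 5)
  mean_pc1 <- vapply(1:5, function(g) {
    mean(pc1[clustering %in% which(grp == g)], na.rm = TRUE)
  }, numeric(1))
  lowest_id <- vapply(1:5, function(g) min(which(grp == g)), numeric(1))
  ord <- order(-mean_pc1, lowest_id)
  names5 <- c("A1", "A2", "AB", "B1", "B2")
  grp_name <- character(5)
  grp_name[ord] <- names5
  cluster_to_sub <- grp_name[grp]
  names(cluster_to_sub) <- as.character(seq_len(k))
  sub <- cluster_to_sub[clustering]
  attributes(sub) <- NULL
  list(subcompartment = sub, cluster_to_sub = cluster_to_sub)
}

#' Fraction of strong long-range inter-mega-domain interactions per cluster
#'
#' Restricts to bin pairs separated by more than `min_dist` bp that lie on
#' opposite sides of the mega-domain boundary, marks the top `top_frac` of
#' those pairs by contact value as strong (threshold at the (1 - top_frac)
#' quantile; ties at the threshold are included), and reports per cluster
#' the fraction of strong pairs among all qualifying pairs touching it.
#'
#' @param matrix balanced `ContactMatrix`.
#' @param clustering integer cluster ids per bin.
#' @param split_point mega-domain boundary (bp).
#' @param min_dist minimal genomic separation (bp, default 8.2 Mb).
#' @param top_frac fraction defining "strong" (default 0.2).
#' @return numeric vector of per-cluster fractions (NA for clusters without
#'   qualifying pairs).
#' @export
inter_megadomain_fraction <- function(matrix, clustering, split_point,
                                      min_dist = 8.2e6, top_frac = 0.2) {
  bins <- matrix$bins
  mid <- (bins$start + bins$end) / 2
  side <- bins$start < split_point
  v <- matrix$values
  ij <- which(upper.tri(v) & !is.na(v), arr.ind = TRUE)
  dist_bp <- abs(mid[ij[, 1]] - mid[ij[, 2]])
  qual <- dist_bp > min_dist & (side[ij[, 1]] != side[ij[, 2]])
  if (!any(qual)) stop("no qualifying long-range inter-mega-domain pairs")
  ij <- ij[qual, , drop = FALSE]
  val <- v[ij]
  thr <- stats::quantile(val, 1 - top_frac, type = 7)
  strong <- val >= thr
  k <- max(clustering, na.rm = TRUE)
  frac <- rep(NA_real_, k)
  for (c in seq_len(k)) {
    touch <- clustering[ij[, 1]] %in% c | clustering[ij[, 2]] %in% c
    if (any(touch)) frac[c] <- sum(strong[touch]) / sum(touch)
  }
  frac
}

#' Aggregate a genomic signal track by cluster
#'
#' Computes a length-weighted mean track value per bin from bedGraph-style
#' intervals, groups bins by cluster (or subcompartment) label, and runs
#' two-sided unpaired Wilcoxon rank-sum tests between all label pairs.
#'
#' @param clustering per-bin labels (integer or character; NA skipped).
#' @param bins bin table at the clustering's resolution.
#' @param track data.frame with columns chrom, start, end, value.
#' @return list: `bin_values` (per-bin weighted means), `by_cluster` (named
#'   list of value vectors), `means` (named numeric), `pvalues` (symmetric
#'   matrix of rank-sum p-values).
#' @export
annotate_clusters_with_track <- function(clustering, bins, track) {
  if (!all(track$chrom %in% unique(bins$chrom)))
    stop("track is on a different chromosome than the bin table")
  bv <- weighted_bin_means(bins, track)
  labs <- sort(unique(clustering[!is.na(clustering)]))
  by_cluster <- lapply(labs, function(l) bv[which(clustering == l)])
  names(by_cluster) <- as.character(labs)
  means <- vapply(by_cluster, mean, numeric(1), na.rm = TRUE)
  p <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i < j) {
      xi <- by_cluster[[i]][is.finite(by_cluster[[i]])]
      xj <- by_cluster[[j]][is.finite(by_cluster[[j]])]
      pv <- if (!length(xi) || !length(xj)) NA_real_
        else if (length(unique(c(xi, xj))) < 2) 1
        else suppressWarnings(stats::wilcox.test(xi, xj)$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  }
  diag(p) <- 1
  list(bin_values = bv, by_cluster = by_cluster, means = means, pvalues = p)
}

weighted_bin_means <- function(bins, track) {
  n <- nrow(bins)
  num <- numeric(n); den <- numeric(n)
  for (r in seq_len(nrow(track))) {
    ts <- track$start[r]; te <- track$end[r]
    hit <- which(bins$end > ts & bins$start < te)
    if (!length(hit)) next
    ov <- pmin(bins$end[hit], te) - pmax(bins$start[hit], ts)
    num[hit] <- num[hit] + ov * track$value[r]
    den[hit] <- den[hit] + ov
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
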