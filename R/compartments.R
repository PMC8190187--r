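#' A/B compartment eigenvector on a mega-domain-split matrix
#'
#' Computes the compartment signal (PC1) of a contact matrix, optionally
#' splitting the chromosome at a mega-domain boundary and treating each arm
#' independently. For each sub-matrix the pipeline is: observed-over-expected
#' normalization, Pearson correlation matrix over unmasked bins, leading
#' eigenvector of the correlation matrix. Each arm's eigenvector is oriented
#' so it correlates positively with GC content (the A compartment is GC-rich
#' and positive by convention); the arms are then concatenated, reinserting
#' NA at masked bins.
#'
#' Run with `split_point = NULL` on a mega-domain matrix, PC1 tracks the two
#' mega-domains rather than compartments; supplying the boundary coordinate
#' recovers the finer checkerboard on each arm.
#'
#' @param matrix raw or balanced `ContactMatrix` (O/E is computed internally;
#'   an O/E matrix is used as is).
#' @param split_point mega-domain boundary in bp, or NULL for whole-matrix PC1.
#' @param gc per-bin GC-content (or any A-orienting covariate); NULL skips
#'   orientation.
#' @return data.frame: bin table columns plus `raw_pc1` (NA at masked bins)
#'   and `arm` ("left"/"right"; all "left" when unsplit).
#' @export
split_pca_compartments <- function(matrix, split_point = NULL, gc = NULL) {
  bins <- matrix$bins
  n <- nrow(bins)
  arm <- if (is.null(split_point)) rep("left", n) else
    ifelse(bins$start < split_point, "left", "right")
  pc1 <- rep(NA_real_, n)
  for (a in unique(arm)) {
    sel <- which(arm == a)
    sub <- subset_matrix(matrix, sel)
    pc1[sel] <- arm_pc1(sub, if (is.null(gc)) NULL else gc[sel])
  }
  out <- bins
  out$raw_pc1 <- pc1
  out$arm <- arm
  out
}

subset_matrix <- function(matrix, sel) {
  out <- matrix
  out$values <- matrix$values[sel, sel, drop = FALSE]
  out$bins <- matrix$bins[sel, , drop = FALSE]
  out$bins$index <- seq_along(sel) - 1L
  out
}

arm_pc1 <- function(sub, gc) {
  keep <- which(!sub$bins$masked)
  if (length(keep) < 10) stop("sub-matrix has fewer than 10 unmasked bins")
  oe <- if (sub$state == "observed_over_expected") sub else
    observed_over_expected(sub)$matrix
  m <- oe$values[keep, keep, drop = FALSE]
  m[is.na(m)] <- 1  # neutral O/E for empty distance classes
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) stop("zero-variance matrix: no compartment signal")
  flat <- sds == 0
  cc <- matrix(0, length(keep), length(keep))
  cc[!flat, !flat] <- stats::cor(m[, !flat, drop = FALSE])
  ev <- eigen(cc, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (!is.null(gc)) {
    orient <- stats::cor(v, gc[keep])
    if (!is.na(orient) && orient < 0) v <- -v
  }
  pc1 <- rep(NA_real_, nrow(sub$bins))
  pc1[keep] <- v
  pc1
}

#' Calibrate PC1 with a two-component Gaussian mixture
#'
#' Centres the compartment eigenvector at the density intersection of a
#' two-component unequal-variance Gaussian mixture and rescales to [-1, +1].
#' The extreme 5% of values (2.5% per tail) are removed before fitting only;
#' every finite bin receives a calibrated value. Steps: fit the mixture,
#' locate the intersection x* of the two weighted component densities
#' between the means by bisection, subtract x*, then divide positive values
#' by the maximum positive value and negative values by |minimum|. Bins with
#' positive calibrated values are labelled "A", negative "B".
#'
#' @param raw_pc1 numeric vector (NA allowed at masked bins), >= 20 finite
#'   values.
#' @param trim total trimmed fraction before fitting (default 0.05).
#' @param seed unused (the mixture fit is deterministic); kept for interface
#'   stability.
#' @return data.frame with columns raw_pc1, calibrated, label
#'   ("A"/"B"/NA) and attribute `intersection` (x*).
#' @importFrom mclust Mclust mclustBIC
#' @export
calibrate_pc1_gmm <- function(raw_pc1, trim = 0.05, seed = NULL) {
  fin <- which(is.finite(raw_pc1))
  if (length(fin) < 20) stop("need at least 20 finite PC1 values")
  x <- raw_pc1[fin]
  if (length(unique(x)) < 2) stop("fewer than 2 distinct PC1 values")
  q <- stats::quantile(x, c(trim / 2, 1 - trim / 2), type = 7)
  xfit <- x[x >= q[1] & x <= q[2]]
  fit <- Mclust(xfit, G = 2, modelNames = "V", verbose = FALSE)
  xstar <- if (is.null(fit) ||
               abs(diff(fit$parameters$mean)) < .Machine$double.eps^0.5) {
    warning("mixture components indistinguishable; centring at trimmed median")
    stats::median(xfit)
  } else {
    gmm_intersection(fit$parameters$pro, fit$parameters$mean,
                     sqrt(fit$parameters$variance$sigmasq))
  }
  centred <- raw_pc1 - xstar
  pos <- centred > 0 & is.finite(centred)
  neg <- centred < 0 & is.finite(centred)
  calibrated <- centred
  if (any(pos)) calibrated[pos] <- centred[pos] / max(centred[pos])
  if (any(neg)) calibrated[neg] <- centred[neg] / abs(min(centred[neg]))
  label <- ifelse(!is.finite(calibrated), NA_character_,
                  ifelse(calibrated > 0, "A", "B"))
  out <- data.frame(raw_pc1 = raw_pc1, calibrated = calibrated, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "intersection") <- xstar
  out
}

#' Intersection of two weighted Gaussian densities
#'
#' Root of w1*phi1(x) - w2*phi2(x) between the two component means, found by
#' bisection (uniroot). Exported so the calibration can be checked against a
#' grid-scan oracle.
#'
#' @param w,mu,sigma length-2 vectors of weights, means, standard deviations.
#' @return the intersection point between the means.
#' @export
gmm_intersection <- function(w, mu, sigma) {
  o <- order(mu)
  w <- w[o]; mu <- mu[o]; sigma <- sigma[o]
  f <- function(x) w[1] * stats::dnorm(x, mu[1], sigma[1]) -
    w[2] * stats::dnorm(x, mu[2], sigma[2])
  lo <- mu[1]; hi <- mu[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    # dominant component covers both means; fall back to a grid scan
    g <- seq(lo, hi, length.out = 1e4)
    return(g[which.min(abs(f(g)))])
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Count compartment segments
#'
#' Merges runs of consecutive same-label unmasked bins into segments, drops
#' segments shorter than `min_segment` (neighbours across a dropped segment
#' are not re-merged), and reports per-label counts. Masked bins break runs.
#'
#' @param track data.frame from [calibrate_pc1_gmm()] cbound to a bin table
#'   (needs chrom, start, end, label).
#' @param min_segment minimal segment length in bp (default 300 kb).
#' @return list: `n_A`, `n_B`, and `segments` (BED-like data.frame with
#'   chrom, start, end, label).
#' @export
count_compartments <- function(track, min_segment = 3e5) {
  lab <- track$label
  lab[is.na(lab)] <- "."
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(chrom = track$chrom[starts],
                    start = track$start[starts],
                    end = track$end[ends],
                    label = r$values,
                    stringsAsFactors = FALSE)
  seg <- seg[seg$label %in% c("A", "B") & (seg$end - seg$start) >= min_segment, ]
  rownames(seg) <- NULL
  list(n_A = sum(seg$label == "A"), n_B = sum(seg$label == "B"),
       segments = seg)
}

#' Saddle aggregation of O/E contacts by PC1 rank
#'
#' Bins are ranked by PC1 and split into `n_cat` equal-count categories
#' (ties broken by bin index); the grid entry (c1, c2) is the mean log2 O/E
#' over all unmasked bin pairs in that category pair (diagonal pairs
#' excluded). The grid is symmetrized. Categories are ordered by ascending
#' PC1, so the B-most bins come first.
#'
#' @param matrix O/E `ContactMatrix`.
#' @param raw_pc1 per-bin PC1 on the same bins.
#' @param n_cat number of rank categories (default 50).
#' @return n_cat x n_cat matrix of mean log2 O/E; NA where a category pair
#'   has no finite pair.
#' @export
saddle_aggregate <- function(matrix, raw_pc1, n_cat = 50) {
  stopifnot(matrix$state == "observed_over_expected")
  keep <- which(!matrix$bins$masked & is.finite(raw_pc1))
  ord <- keep[order(raw_pc1[keep], keep)]
  cat_of <- integer(nrow(matrix$bins))
  cat_of[ord] <- ceiling(seq_along(ord) / (length(ord) / n_cat))
  cat_of[ord] <- pmin(cat_of[ord], n_cat)
  v <- log2(matrix$values)
  grid <- matrix(NA_real_, n_cat, n_cat)
  cnt <- matrix(0, n_cat, n_cat)
  ij <- which(is.finite(v) & row(v) != col(v), arr.ind = TRUE)
  ci <- cat_of[ij[, 1]]; cj <- cat_of[ij[, 2]]
  ok <- ci > 0 & cj > 0
  s <- rowsum(v[ij[ok, , drop = FALSE]], group = (ci[ok] - 1) * n_cat + cj[ok])
  k <- rowsum(rep(1, sum(ok)), group = (ci[ok] - 1) * n_cat + cj[ok])
  at <- as.integer(rownames(s))
  grid[cbind((at - 1) %/% n_cat + 1, (at - 1) %% n_cat + 1)] <- s[, 1] / k[, 1]
  (grid + t(grid)) / 2
}

#' Compartmentalization strength
#'
#' Classifies bins by PC1 percentile (top `frac` = A, bottom `frac` = B) and
#' summarizes each interaction type by the median log2 O/E over its bin
#' pairs. Overall strength is (AA + BB)/2 - AB in log2 units.
#'
#' @param matrix O/E `ContactMatrix`.
#' @param raw_pc1 per-bin PC1.
#' @param frac percentile fraction defining each extreme class (default 0.2).
#' @return list: strength_AA, strength_BB, strength_AB, overall.
#' @export
compartment_strength <- function(matrix, raw_pc1, frac = 0.2) {
  stopifnot(matrix$state == "observed_over_expected")
  keep <- which(!matrix$bins$masked & is.finite(raw_pc1))
  qs <- stats::quantile(raw_pc1[keep], c(frac, 1 - frac), type = 7)
  b_bins <- keep[raw_pc1[keep] <= qs[1]]
  a_bins <- keep[raw_pc1[keep] >= qs[2]]
  if (length(a_bins) < 5 || length(b_bins) < 5)
    stop("fewer than 5 bins in a compartment class")
  v <- matrix$values
  diag(v) <- NA_real_  # self-pairs are not compartment signal
  med <- function(rows, cols) {
    x <- log2(v[rows, cols])
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    stats::median(x)
  }
  aa <- med(a_bins, a_bins)
  bb <- med(b_bins, b_bins)
  ab <- med(a_bins, b_bins)
  list(strength_AA = aa, strength_BB = bb, strength_AB = ab,
       overall = (aa + bb) / 2 - ab)
}
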