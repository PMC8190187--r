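#' Insulation score
#'
#' For each bin b where the full window fits inside the chromosome, the
#' mean contact value over the `window_bins` x `window_bins` square spanning
#' (b-window .. b-1) x (b+1 .. b+window) is computed; the raw score is
#' log2(S(b) / mean of S over eligible bins). Bins whose window contains no
#' finite value (fully masked stretch) are NA.
#'
#' @param matrix balanced `ContactMatrix` (typically 50-kb resolution).
#' @param window_bins half-window in bins (default 10, i.e. 500 kb at 50 kb).
#' @return numeric per-bin raw insulation score (NA where undefined).
#' @export
insulation_score <- function(matrix, window_bins = 10) {
  v <- matrix$values
  n <- nrow(v)
  if (n < 2 * window_bins + 1)
    stop("chromosome shorter than 2*window+1 bins")
  s <- rep(NA_real_, n)
  for (b in (window_bins + 1):(n - window_bins)) {
    block <- v[(b - window_bins):(b - 1), (b + 1):(b + window_bins),
               drop = FALSE]
    if (any(is.finite(block))) s[b] <- mean(block, na.rm = TRUE)
  }
  mu <- mean(s, na.rm = TRUE)
  out <- log2(s / mu)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Moving-average smoothing of an insulation track
#'
#' Centred moving average of span `span`; the window shrinks symmetrically
#' at chromosome edges and NA values are ignored.
#'
#' @param track numeric raw insulation scores.
#' @param span window span in bins (odd, default 7).
#' @return smoothed numeric vector (NA where the raw value was NA).
#' @export
smooth_insulation <- function(track, span = 7) {
  h <- span %/% 2
  n <- length(track)
  out <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    if (is.na(track[b])) next
    r <- min(h, b - 1, n - b)  # shrink symmetrically at edges
    w <- track[(b - r):(b + r)]
    out[b] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Call TAD borders from a smoothed insulation track
#'
#' Borders are local minima of the smoothed insulation score that fall
#' below `cutoff`. A minimum is a bin (or leftmost bin of an equal-valued
#' plateau) whose nearest finite non-equal neighbours on both sides are
#' strictly greater.
#'
#' @param smoothed smoothed insulation scores.
#' @param cutoff score threshold (default -0.086).
#' @return integer vector of border bin positions (1-based), possibly empty.
#' @export
call_tad_borders <- function(smoothed, cutoff = -0.086) {
  fin <- which(is.finite(smoothed))
  if (length(fin) < 3) return(integer())
  x <- smoothed[fin]
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  borders <- integer()
  for (i in seq_along(r$values)) {
    if (i == 1 || i == length(r$values)) next  # runs at track ends
    if (r$values[i] < r$values[i - 1] && r$values[i] < r$values[i + 1] &&
        r$values[i] < cutoff)
      borders <- c(borders, fin[starts[i]])  # leftmost bin of a plateau
  }
  borders
}

#' TAD intervals from borders
#'
#' Splits each contiguous unmasked region at its border bins: a border bin
#' closes the TAD to its left and the next TAD starts one bin later. Mask
#' gaps break TADs. TADs shorter than `min_bins` bins are discarded.
#'
#' @param borders integer border bin positions (1-based).
#' @param bins bin table (mask flags respected).
#' @param min_bins minimal TAD size in bins (default 3).
#' @return data.frame with columns chrom, start, end, first_bin, last_bin
#'   (1-based inclusive bin range).
#' @export
tads_from_borders <- function(borders, bins, min_bins = 3) {
  n <- nrow(bins)
  open <- !bins$masked
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tads <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    lo <- starts[i]; hi <- ends[i]
    cuts <- sort(borders[borders >= lo & borders < hi])
    seg_start <- c(lo, cuts + 1)
    seg_end <- c(cuts, hi)
    for (s in seq_along(seg_start)) {
      if (seg_end[s] - seg_start[s] + 1 < min_bins) next
      tads[[length(tads) + 1]] <- data.frame(
        chrom = bins$chrom[seg_start[s]],
        start = bins$start[seg_start[s]],
        end = bins$end[seg_end[s]],
        first_bin = seg_start[s], last_bin = seg_end[s],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(tads))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      first_bin = integer(), last_bin = integer()))
  out <- do.call(rbind, tads)
  rownames(out) <- NULL
  out
}

#' Per-TAD domain score
#'
#' Fraction of a TAD's cis contacts that are internal: the sum of the
#' contact submatrix among the TAD's bins divided by the total contacts of
#' the TAD's bins with the whole chromosome. In [0, 1]; NA for a TAD with
#' no contacts.
#'
#' @param matrix balanced `ContactMatrix`.
#' @param tads data.frame from [tads_from_borders()].
#' @return numeric per-TAD score.
#' @export
domain_score <- function(matrix, tads) {
  v <- matrix$values
  vapply(seq_len(nrow(tads)), function(t) {
    sel <- tads$first_bin[t]:tads$last_bin[t]
    tot <- sum(v[sel, , drop = FALSE], na.rm = TRUE)
    if (tot == 0) return(NA_real_)
    sum(v[sel, sel], na.rm = TRUE) / tot
  }, numeric(1))
}

#' Relative domain score across a time course
#'
#' Places the mid-timepoint domain score on the start-to-end axis:
#' (mid - start) / (end - start). TADs whose start and end scores differ by
#' less than `eps` are reported NA.
#'
#' @param ds_start,ds_mid,ds_end aligned per-TAD domain-score vectors.
#' @param eps minimal |end - start| for a defined ratio (default 0.01).
#' @return numeric per-TAD relative score.
#' @export
relative_domain_score <- function(ds_start, ds_mid, ds_end, eps = 0.01) {
  if (length(ds_start) != length(ds_mid) || length(ds_mid) != length(ds_end))
    stop("domain-score vectors differ in length")
  denom <- ds_end - ds_start
  out <- (ds_mid - ds_start) / denom
  out[abs(denom) < eps] <- NA_real_
  out
}

#' Classify TADs as early or late by relative domain score
#'
#' One-dimensional k-means (k = 2) on the finite relative scores; the
#' cluster with the larger centre is "early". The fraction of TADs with
#' relative score > 0.2 is reported alongside as a threshold cross-check.
#'
#' @param relative_scores numeric per-TAD relative scores (>= 4 finite).
#' @param seed RNG seed for k-means.
#' @return list: `class` (character "early"/"late"/NA per TAD),
#'   `fraction_early` (k-means based), `fraction_above_0.2`.
#' @export
classify_tads_early_late <- function(relative_scores, seed = 1L) {
  fin <- which(is.finite(relative_scores))
  if (length(fin) < 4) stop("need at least 4 TADs with finite relative scores")
  x <- relative_scores[fin]
  if (length(unique(x)) < 2) stop("all relative scores identical")
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2, nstart = 10)
  early_cl <- which.max(km$centers)
  cls <- rep(NA_character_, length(relative_scores))
  cls[fin] <- ifelse(km$cluster == early_cl, "early", "late")
  list(class = cls,
       fraction_early = mean(km$cluster == early_cl),
       fraction_above_0.2 = mean(x > 0.2))
}

#' Relative per-TAD trajectory of an omics metric
#'
#' Rescales a per-TAD metric (peak counts or mean expression) measured at
#' several timepoints onto the start-to-end axis: rel(t) =
#' (x_t - x_start)/(x_end - x_start), so the start sample maps to 0 and the
#' end sample to 1. TADs with an end-state count below `min_count` (set
#' `min_count = 0` for expression) or a flat start-to-end difference are
#' dropped (NA rows).
#'
#' @param values TAD x timepoint numeric matrix.
#' @param start,end column indices (or names) of the start and end samples.
#' @param min_count minimal end-state value for inclusion (default 15, the
#'   peak-count filter).
#' @param eps minimal |x_end - x_start| (default 1e-8).
#' @return matrix of the same shape with relative values (excluded TADs NA).
#' @export
relative_metric_per_tad <- function(values, start, end, min_count = 15,
                                    eps = 1e-8) {
  values <- as.matrix(values)
  xs <- values[, start]
  xe <- values[, end]
  denom <- xe - xs
  keep <- xe >= min_count & abs(denom) > eps & is.finite(denom)
  out <- (values - xs) / denom
  out[!keep, ] <- NA_real_
  out
}
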