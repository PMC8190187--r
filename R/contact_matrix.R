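#' Bin table for a single chromosome
#'
#' Builds the per-bin annotation table underlying a contact matrix. Bins are
#' contiguous, non-overlapping, sorted and of equal width (the resolution),
#' except possibly the last bin which may be truncated at the chromosome end.
#' Coordinates are 0-based, half-open.
#'
#' @param chrom chromosome name (single string).
#' @param chrom_length chromosome length in bp.
#' @param resolution bin width in bp.
#' @param mappability per-bin mappable fraction in [0,1]; recycled if scalar.
#' @param n_re_sites per-bin restriction-site counts; recycled if scalar.
#' @param masked logical per-bin mask; recycled if scalar.
#' @return data.frame with columns chrom, start, end, index (0-based),
#'   mappability, n_re_sites, masked.
#' @export
bin_table <- function(chrom, chrom_length, resolution,
                      mappability = 1, n_re_sites = 1L, masked = FALSE) {
  stopifnot(chrom_length > 0, resolution > 0)
  starts <- seq(0L, chrom_length - 1L, by = resolution)
  ends <- pmin(starts + resolution, chrom_length)
  n <- length(starts)
  df <- data.frame(
    chrom = chrom,
    start = as.numeric(starts),
    end = as.numeric(ends),
    index = seq_len(n) - 1L,
    mappability = rep_len(mappability, n),
    n_re_sites = as.integer(rep_len(n_re_sites, n)),
    masked = rep_len(as.logical(masked), n),
    stringsAsFactors = FALSE
  )
  stopifnot(all(df$mappability >= 0 & df$mappability <= 1),
            all(df$n_re_sites >= 0))
  df
}

#' Construct a contact matrix
#'
#' A symmetric, non-negative intra-chromosomal contact matrix tied to a bin
#' table. `state` records what the values mean: raw counts, ICE-balanced
#' values, or observed-over-expected ratios. Masked bins carry NA rows and
#' columns after filtering.
#'
#' @param values symmetric numeric matrix (n_bins x n_bins).
#' @param bins bin table from [bin_table()].
#' @param state one of "raw", "balanced", "observed_over_expected".
#' @param allele free-form allele label, e.g. "mus" or "cas".
#' @return object of class `ContactMatrix`.
#' @export
contact_matrix <- function(values, bins,
                           state = c("raw", "balanced", "observed_over_expected"),
                           allele = "NA") {
  state <- match.arg(state)
  values <- as.matrix(values)
  n <- nrow(bins)
  if (nrow(values) != n || ncol(values) != n)
    stop("values must be ", n, " x ", n, " to match the bin table")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("contact matrix must be symmetric")
  if (any(values < 0, na.rm = TRUE)) stop("negative contact values")
  structure(
    list(values = values, bins = bins, state = state, allele = allele,
         resolution = resolution_of(bins)),
    class = "ContactMatrix"
  )
}

resolution_of <- function(bins) {
  w <- bins$end - bins$start
  if (nrow(bins) > 1) w[1] else w
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins @ %d bp (%s), allele=%s, state=%s, %d masked\n",
              nrow(x$bins), as.integer(x$resolution), x$bins$chrom[1],
              x$allele, x$state, sum(x$bins$masked)))
  invisible(x)
}

#' Read a contact matrix from a triplet file
#'
#' Reads a whitespace/tab-separated triplet file `bin1 bin2 count` (0-based
#' bin indices, upper or lower triangle or both; duplicate (i,j)/(j,i)
#' records are summed once) together with a BED-style bin table and returns
#' a raw symmetric `ContactMatrix`. A header line starting with `bin1` is
#' skipped. Gzip files are handled transparently by R's connections.
#'
#' @param path triplet file path.
#' @param bins_path bin table path: BED3+ with columns chrom, start, end and
#'   optionally mappability, n_re_sites (tab-separated, no header or a
#'   header starting with "chrom").
#' @param allele allele label to attach.
#' @return raw `ContactMatrix`.
#' @export
read_contacts <- function(path, bins_path, allele = "NA") {
  bins <- read_bin_table(bins_path)
  n <- nrow(bins)
  first <- tryCatch(readLines(path, n = 1), error = function(e) character())
  skip <- length(first) && grepl("^bin", first[1])
  empty <- length(first) == 0 || (skip && length(readLines(path, n = 2)) < 2)
  if (empty) {
    trip <- data.frame(bin1 = numeric(), bin2 = numeric(), count = numeric())
  } else {
    trip <- utils::read.table(path, header = FALSE, skip = as.integer(skip),
                              col.names = c("bin1", "bin2", "count"),
                              colClasses = "numeric",
                              comment.char = "#", blank.lines.skip = TRUE)
  }
  values <- triplets_to_matrix(trip$bin1, trip$bin2, trip$count, n)
  contact_matrix(values, bins, state = "raw", allele = allele)
}

read_bin_table <- function(bins_path) {
  first <- readLines(bins_path, n = 1)
  has_header <- grepl("^chrom", first)
  bed <- utils::read.table(bins_path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!has_header) {
    names(bed)[1:3] <- c("chrom", "start", "end")
    if (ncol(bed) >= 4) names(bed)[4] <- "mappability"
    if (ncol(bed) >= 5) names(bed)[5] <- "n_re_sites"
  }
  if (is.null(bed$mappability)) bed$mappability <- 1
  if (is.null(bed$n_re_sites)) bed$n_re_sites <- 1L
  bed$index <- seq_len(nrow(bed)) - 1L
  if (is.null(bed$masked)) bed$masked <- FALSE
  bed[c("chrom", "start", "end", "index", "mappability", "n_re_sites", "masked")]
}

triplets_to_matrix <- function(i, j, count, n) {
  if (length(i) && (any(i < 0 | i >= n) || any(j < 0 | j >= n)))
    stop("bin index out of range [0, ", n - 1, "]")
  if (any(count < 0)) stop("negative counts in triplet file")
  m <- matrix(0, n, n)
  if (length(i)) {
    # fold every record into the upper triangle, then mirror once
    lo <- pmin(i, j); hi <- pmax(i, j)
    idx <- lo * n + hi  # unique key per unordered pair
    agg <- rowsum(count, group = idx)
    at <- as.numeric(rownames(agg))
    lo2 <- at %/% n; hi2 <- at %% n
    m[cbind(lo2 + 1, hi2 + 1)] <- agg[, 1]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  m
}

#' Write a contact matrix to a triplet file
#'
#' Writes the upper triangle (including diagonal) of the matrix as
#' `bin1\tbin2\tvalue` with a header line. NA entries (masked bins) are
#' skipped; zeros are omitted, so a round trip through [read_contacts()]
#' reproduces the unmasked entries exactly.
#'
#' @param matrix a `ContactMatrix`.
#' @param path output path.
#' @export
write_contacts <- function(matrix, path) {
  v <- matrix$values
  n <- nrow(v)
  ut <- which(upper.tri(v, diag = TRUE) & !is.na(v) & v != 0, arr.ind = TRUE)
  df <- data.frame(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                   count = v[ut])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("bin1\tbin2\tcount", con)
  if (nrow(df))
    utils::write.table(df[order(df$bin1, df$bin2), ], con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Low-count threshold from the first density maximum
#'
#' Computes a heuristic low-count threshold for per-bin total counts: the
#' x-position of the kernel-density local maximum with the smallest x
#' (Gaussian kernel, Silverman's bandwidth, 512-point grid spanning the data
#' range). Bins whose row sum falls strictly below the returned value are
#' regarded as low-count. For an effectively constant vector the constant is
#' returned.
#'
#' @param row_sums numeric vector of per-bin total counts (>= 10 positive
#'   values required).
#' @return the count threshold (scalar).
#' @export
first_max_threshold <- function(row_sums) {
  x <- row_sums[is.finite(row_sums)]
  if (all(x == 0)) stop("all-zero row sums: cannot estimate a count threshold")
  if (sum(x > 0) < 10) stop("need at least 10 positive row sums")
  if (diff(range(x)) < .Machine$double.eps^0.5) return(x[1])
  d <- stats::density(x, bw = "nrd0", kernel = "gaussian", n = 512,
                      from = min(x), to = max(x))
  y <- d$y
  is_max <- c(FALSE, y[2:511] > y[1:510] & y[2:511] > y[3:512], FALSE)
  if (!any(is_max)) return(d$x[which.max(y)])
  d$x[which(is_max)[1]]
}

#' Flag unusable bins
#'
#' Masks bins with low mappability, no restriction-enzyme sites, or a total
#' count strictly below the first-density-maximum threshold, and blanks the
#' corresponding matrix rows/columns to NA.
#'
#' @param matrix raw `ContactMatrix` whose bin table carries mappability and
#'   n_re_sites.
#' @param mappability_min mappability cutoff (bins strictly below are masked).
#' @return the `ContactMatrix` with updated mask and NA rows/columns.
#' @export
filter_bins <- function(matrix, mappability_min = 0.5) {
  bins <- matrix$bins
  rs <- rowSums(matrix$values, na.rm = TRUE)
  thr <- first_max_threshold(rs)
  bins$masked <- bins$mappability < mappability_min |
    bins$n_re_sites == 0 |
    rs < thr
  apply_mask(matrix, bins)
}

apply_mask <- function(matrix, bins) {
  v <- matrix$values
  v[bins$masked, ] <- NA_real_
  v[, bins$masked] <- NA_real_
  out <- matrix
  out$values <- v
  out$bins <- bins
  out
}

#' ICE matrix balancing
#'
#' Iterative correction: repeatedly divides the matrix by the outer product
#' of its (normalized) unmasked row sums until all unmasked row sums agree
#' within `tol` (relative). Unmasked rows that are all zero are auto-masked
#' with a warning. Total unmasked signal is preserved.
#'
#' @param matrix raw (or other) `ContactMatrix` with mask flags set.
#' @param tol relative row-sum tolerance.
#' @param max_iter maximum iterations.
#' @return `ContactMatrix` with state "balanced".
#' @export
ice_balance <- function(matrix, tol = 1e-5, max_iter = 200) {
  bins <- matrix$bins
  keep <- !bins$masked
  rs0 <- rowSums(matrix$values[keep, keep, drop = FALSE], na.rm = TRUE)
  dead <- which(keep)[rs0 == 0]
  if (length(dead)) {
    warning(length(dead), " unmasked bin(s) with zero contacts auto-masked")
    bins$masked[dead] <- TRUE
    matrix <- apply_mask(matrix, bins)
    keep <- !bins$masked
  }
  w <- matrix$values[keep, keep, drop = FALSE]
  total <- sum(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    s <- s / mean(s)
    if (max(abs(s - 1)) < tol) { converged <- TRUE; break }
    w <- w / outer(s, s)
  }
  if (!converged) stop("ICE did not converge in ", max_iter, " iterations")
  w <- w * (total / sum(w))
  out <- matrix
  out$values[keep, keep] <- w
  out$bins <- bins
  out$state <- "balanced"
  apply_mask(out, bins)
}

#' Observed-over-expected normalization and distance-decay profile
#'
#' Divides each entry by the mean value at its genomic distance (in bins),
#' computed over unmasked pairs only. Distance classes whose mean is zero
#' (or that contain no unmasked pair) yield NA entries.
#'
#' @param matrix raw or balanced `ContactMatrix`.
#' @return list with elements `matrix` (state "observed_over_expected") and
#'   `decay` (numeric vector, decay[d+1] = mean value at distance d bins).
#' @export
observed_over_expected <- function(matrix) {
  v <- matrix$values
  n <- nrow(v)
  d <- abs(row(v) - col(v))
  ok <- !is.na(v)
  sums <- rowsum(v[ok], d[ok])
  cnts <- rowsum(rep(1, sum(ok)), d[ok])
  decay <- rep(NA_real_, n)
  decay[as.integer(rownames(sums)) + 1] <- sums[, 1] / cnts[, 1]
  expected <- matrix(decay[d + 1], n, n)
  oe <- v / expected
  oe[!is.finite(oe)] <- NA_real_
  out <- matrix
  out$values <- oe
  out$state <- "observed_over_expected"
  list(matrix = out, decay = decay)
}

#' Mix two contact matrices in silico
#'
#' Entrywise convex combination emulating a mixed cell population:
#' `(1 - ratio) * m_a + ratio * m_b` after depth matching (each input scaled
#' to the same total unmasked signal), so `ratio` is a cell fraction rather
#' than a read fraction.
#'
#' @param m_a,m_b `ContactMatrix` objects on the same bin table and state.
#' @param ratio mixing fraction of `m_b` in [0,1].
#' @return mixed `ContactMatrix` (same state).
#' @export
mix_matrices <- function(m_a, m_b, ratio) {
  stopifnot(ratio >= 0, ratio <= 1)
  if (!identical(dim(m_a$values), dim(m_b$values)) ||
      !isTRUE(all.equal(m_a$bins[c("start", "end")], m_b$bins[c("start", "end")])))
    stop("bin tables differ between matrices")
  if (!identical(m_a$state, m_b$state)) stop("matrix states differ")
  ta <- sum(m_a$values, na.rm = TRUE)
  tb <- sum(m_b$values, na.rm = TRUE)
  target <- (ta + tb) / 2
  out <- m_a
  out$values <- (1 - ratio) * (m_a$values * target / ta) +
    ratio * (m_b$values * target / tb)
  out$allele <- paste0(m_a$allele, "+", m_b$allele, "@", ratio)
  out
}

#' Write a per-bin scalar track as bedGraph
#'
#' @param bins bin table.
#' @param values numeric per-bin values; NA rows are dropped.
#' @param path output path.
#' @export
write_bedgraph <- function(bins, values, path) {
  keep <- !is.na(values)
  utils::write.table(
    data.frame(bins$chrom[keep], as.integer(bins$start[keep]),
               as.integer(bins$end[keep]), values[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
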