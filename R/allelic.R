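#' Assign a read to a parental genome
#'
#' Decision rule over a pair of alignments of the same read against the two
#' parental genomes: unmapped if both mapping qualities are 0; otherwise the
#' genome with the strictly greater alignment score wins; equal scores are
#' ambiguous.
#'
#' @param mapq1,mapq2 mapping qualities in genome 1 / genome 2.
#' @param as1,as2 alignment scores in genome 1 / genome 2.
#' @return character vector over {"genome1","genome2","ambiguous","unmapped"}
#'   (vectorized).
#' @export
assign_allele <- function(mapq1, mapq2, as1, as2) {
  out <- ifelse(mapq1 == 0 & mapq2 == 0, "unmapped",
         ifelse(as1 > as2, "genome1",
         ifelse(as2 > as1, "genome2", "ambiguous")))
  out
}

#' Allelic expression ratio
#'
#' mus / (mus + cas); NA when both counts are zero.
#'
#' @param mus,cas non-negative allele-resolved counts (vectorized).
#' @return numeric ratio in [0, 1] or NA.
#' @export
allelic_ratio <- function(mus, cas) {
  if (any(mus < 0, na.rm = TRUE) || any(cas < 0, na.rm = TRUE))
    stop("negative allelic counts")
  tot <- mus + cas
  ifelse(tot > 0, mus / tot, NA_real_)
}

#' Filter the allelic gene table for informative, expressed genes
#'
#' Two-stage funnel: (1) keep genes with sufficient sequence polymorphisms
#' (`snp_informative`); (2) among those, keep genes whose cas expression in
#' the reference column is at or above its 25th percentile (genes strictly
#' below the percentile are removed; ties are kept).
#'
#' @param table data.frame with columns `snp_informative` (logical) and the
#'   cas-count column named by `cas_col`.
#' @param cas_col name of the cas expression column used for the percentile
#'   filter.
#' @param pct percentile (default 0.25), computed with the type-7
#'   (linear-interpolation) quantile.
#' @return list: `table` (filtered), `funnel` (named counts: input,
#'   snp_informative, expressed).
#' @export
filter_expressed_genes <- function(table, cas_col = "cas_count", pct = 0.25) {
  if (!nrow(table)) stop("empty gene table")
  n0 <- nrow(table)
  s1 <- table[table$snp_informative, , drop = FALSE]
  thr <- stats::quantile(s1[[cas_col]], pct, type = 7)
  s2 <- s1[s1[[cas_col]] >= thr, , drop = FALSE]
  rownames(s2) <- NULL
  list(table = s2,
       funnel = c(input = n0, snp_informative = nrow(s1),
                  expressed = nrow(s2)))
}

#' Absolute allele-specific expression
#'
#' Splits bulk counts by the allelic ratio: mus = bulk * ratio,
#' cas = bulk * (1 - ratio). Corrects for SNP-density bias in the raw
#' allele-resolved counts.
#'
#' @param bulk non-negative bulk counts.
#' @param ratio allelic ratio in [0, 1].
#' @return data.frame with columns mus_abs, cas_abs.
#' @export
absolute_allelic_expression <- function(bulk, ratio) {
  stopifnot(all(bulk >= 0, na.rm = TRUE),
            all(ratio >= 0 & ratio <= 1, na.rm = TRUE))
  data.frame(mus_abs = bulk * ratio, cas_abs = bulk * (1 - ratio))
}

#' Escapee, reactivation and biallelic calls from allelic ratios
#'
#' A gene escapes X-inactivation if its ratio in the reference (inactive
#' state) sample exceeds `escapee_cutoff`; it counts as reactivated at a
#' sample once its ratio there exceeds the same cutoff. Genes are
#' biallelic at the endpoint if both endpoint ratios lie strictly inside
#' the `biallelic` interval; reactivation analyses are restricted to these
#' genes. All thresholds are strict.
#'
#' @param ratios gene x sample matrix (or data.frame) of allelic ratios.
#' @param reference column of the inactive-state sample.
#' @param endpoints columns of the two endpoint samples.
#' @param escapee_cutoff ratio cutoff (default 0.14).
#' @param biallelic open interval for biallelic expression (default
#'   c(0.4, 0.6)).
#' @return list: `escapee` (logical per gene), `reactivated` (gene x sample
#'   logical matrix), `biallelic_endpoint` (logical per gene),
#'   `reactivation_timepoint` (first sample index, by column order of
#'   `ratios`, at which a biallelic non-escapee gene exceeds the cutoff; NA
#'   if never or ineligible).
#' @export
classify_allelic_status <- function(ratios, reference, endpoints,
                                    escapee_cutoff = 0.14,
                                    biallelic = c(0.4, 0.6)) {
  ratios <- as.matrix(ratios)
  miss <- c(reference, endpoints)
  if (is.character(miss) && !all(miss %in% colnames(ratios)))
    stop("missing designated reference/endpoint samples")
  escapee <- ratios[, reference] > escapee_cutoff
  reactivated <- ratios > escapee_cutoff
  bi <- ratios[, endpoints[1]] > biallelic[1] &
    ratios[, endpoints[1]] < biallelic[2] &
    ratios[, endpoints[2]] > biallelic[1] &
    ratios[, endpoints[2]] < biallelic[2]
  eligible <- bi & !escapee
  first_on <- apply(reactivated, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  first_on[!eligible | is.na(eligible)] <- NA_integer_
  list(escapee = escapee, reactivated = reactivated,
       biallelic_endpoint = bi, reactivation_timepoint = first_on)
}

#' Fraction of reactivated genes per cluster over time
#'
#' For each cluster and timepoint, the fraction of eligible genes (biallelic
#' at the endpoints, not escapees) whose allelic ratio exceeds the
#' reactivation cutoff.
#'
#' @param reactivated gene x sample logical matrix
#'   (from [classify_allelic_status()]).
#' @param eligible logical per gene.
#' @param clustering cluster label per gene.
#' @return cluster x sample matrix of fractions (NA for clusters with no
#'   eligible gene).
#' @export
fraction_reactivated_per_cluster <- function(reactivated, eligible,
                                             clustering) {
  labs <- sort(unique(clustering[!is.na(clustering)]))
  out <- matrix(NA_real_, length(labs), ncol(reactivated),
                dimnames = list(as.character(labs), colnames(reactivated)))
  for (i in seq_along(labs)) {
    sel <- which(clustering == labs[i] & eligible)
    if (length(sel))
      out[i, ] <- colMeans(reactivated[sel, , drop = FALSE])
  }
  out
}

#' Distance to the nearest escapee
#'
#' For every gene, the minimal TSS-to-TSS distance to an escapee gene other
#' than itself (escapees get the distance to the nearest other escapee).
#'
#' @param tss numeric TSS coordinates (bp).
#' @param escapee logical per gene.
#' @return numeric distances in bp (NA if no other escapee exists).
#' @export
distance_to_nearest_escapee <- function(tss, escapee) {
  if (!any(escapee, na.rm = TRUE)) stop("no escapees")
  esc_idx <- which(escapee)
  vapply(seq_along(tss), function(g) {
    others <- setdiff(esc_idx, g)
    if (!length(others)) return(NA_real_)
    min(abs(tss[g] - tss[others]))
  }, numeric(1))
}

#' Relative differential peak trajectory per cluster
#'
#' Differential peaks of a sample are its peaks with no overlap (>= 1 bp)
#' with any baseline peak. Per cluster, the value of a sample is its count
#' of differential peaks divided by the end sample's count of differential
#' peaks in that cluster, so the baseline maps to 0 and the end sample to 1.
#' Peaks are assigned to clusters by midpoint.
#'
#' @param peak_sets named list of BED-like data.frames (chrom, start, end),
#'   one per sample.
#' @param baseline_sample,end_sample names in `peak_sets`.
#' @param cluster_intervals data.frame chrom, start, end, cluster.
#' @return cluster x sample matrix of relative values (NA where the end
#'   sample has no differential peak in a cluster).
#' @export
relative_differential_peaks <- function(peak_sets, baseline_sample,
                                        end_sample, cluster_intervals) {
  base <- peak_sets[[baseline_sample]]
  diff_counts <- lapply(peak_sets, function(p) {
    d <- p[!overlaps_any(p, base), , drop = FALSE]
    count_peaks_per_cluster(d, cluster_intervals)
  })
  labs <- sort(unique(cluster_intervals$cluster))
  m <- do.call(cbind, diff_counts)
  dimnames(m) <- list(as.character(labs), names(peak_sets))
  endc <- m[, end_sample]
  out <- sweep(m, 1, endc, "/")
  out[endc == 0, ] <- NA_real_
  out
}

overlaps_any <- function(query, subject) {
  if (!nrow(query)) return(logical())
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] & subject$end > query$start[i])
  }, logical(1))
}

count_peaks_per_cluster <- function(peaks, cluster_intervals) {
  labs <- sort(unique(cluster_intervals$cluster))
  out <- stats::setNames(numeric(length(labs)), as.character(labs))
  if (!nrow(peaks)) return(out)
  mid <- (peaks$start + peaks$end) / 2
  for (i in seq_len(nrow(peaks))) {
    hit <- which(cluster_intervals$chrom == peaks$chrom[i] &
                   cluster_intervals$start <= mid[i] &
                   cluster_intervals$end > mid[i])
    if (length(hit))
      out[as.character(cluster_intervals$cluster[hit[1]])] <-
        out[as.character(cluster_intervals$cluster[hit[1]])] + 1
  }
  out
}

#' Promoter accessibility around the TSS
#'
#' Sums signal x overlap-length of a bedGraph track over the window
#' [TSS - half_window, TSS + half_window) per gene.
#'
#' @param track data.frame chrom, start, end, value.
#' @param tss numeric TSS coordinates.
#' @param chrom chromosome of the genes (single string or per-gene vector).
#' @param half_window half window in bp (default 2000).
#' @return numeric per-gene summed signal.
#' @export
promoter_accessibility <- function(track, tss, chrom, half_window = 2000) {
  chrom <- rep_len(chrom, length(tss))
  vapply(seq_along(tss), function(g) {
    ws <- tss[g] - half_window; we <- tss[g] + half_window
    if (ws < 0) stop("TSS window extends off the chromosome")
    hit <- track$chrom == chrom[g] & track$start < we & track$end > ws
    if (!any(hit)) return(0)
    ov <- pmin(track$end[hit], we) - pmax(track$start[hit], ws)
    sum(ov * track$value[hit])
  }, numeric(1))
}

#' ATAC peak density per cluster
#'
#' Counts peaks per cluster (midpoint assignment) and divides by the cluster
#' territory in megabases.
#'
#' @param peaks BED-like data.frame chrom, start, end.
#' @param cluster_intervals data.frame chrom, start, end, cluster.
#' @return named numeric vector of peaks per Mb.
#' @export
peak_density_per_cluster <- function(peaks, cluster_intervals) {
  counts <- count_peaks_per_cluster(peaks, cluster_intervals)
  labs <- names(counts)
  bp <- vapply(labs, function(l) {
    sel <- cluster_intervals$cluster == l
    sum(cluster_intervals$end[sel] - cluster_intervals$start[sel])
  }, numeric(1))
  if (any(bp == 0)) stop("cluster with empty territory")
  counts / (bp / 1e6)
}
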