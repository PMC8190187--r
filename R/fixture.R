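#' Build the bundled worked fixture
#'
#' Generates a small deterministic allelic dataset (genes, clusters, peaks,
#' signal) and writes it, together with a manifest of expected outputs for
#' every allelic-pipeline stage, to `out_dir`. The manifest values are
#' computed here by independent brute-force loops, not by the pipeline
#' functions, so the committed fixture doubles as an oracle. Regeneration
#' with the same seed is byte-identical.
#'
#' @param seed RNG seed (the bundled copy uses 42).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
make_worked_fixture <- function(seed = 42L, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed, chrom_length = 10e6, n_genes = 60,
                    gene_depth = 100, escapee_fraction = 0.15,
                    noninformative_fraction = 0.2)
  ns <- length(cfg$timepoints)
  clusters <- data.frame(chrom = cfg$chrom,
                         start = seq(0, 8e6, by = 2e6),
                         end = seq(2e6, 10e6, by = 2e6),
                         cluster = 1:5)
  genes <- generate_allelic_counts(cfg, cluster_intervals = clusters)
  sched <- matrix(rep(c(0, 0.25, 0.5, 1, 1), each = 5), nrow = 5,
                  dimnames = list(as.character(1:5), cfg$timepoints))
  peaks <- generate_peak_sets(cfg, clusters, n_baseline = 5, n_new = 12,
                              schedule = sched)

  tab <- genes$table
  utils::write.table(tab, file.path(out_dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(clusters, file.path(out_dir, "clusters.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (s in cfg$timepoints)
    utils::write.table(peaks$peak_sets[[s]],
                       file.path(out_dir, paste0("peaks_", s, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  utils::write.table(peaks$signal, file.path(out_dir, "signal.bedGraph"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  # ---- brute-force manifest (plain loops, no pipeline functions) ----
  gene_ids <- unique(tab$gene)
  ref <- cfg$timepoints[1]
  endpoints <- cfg$timepoints[c(ns - 1, ns)]
  get <- function(g, s, col) tab[tab$gene == g & tab$sample == s, col]
  ratio <- matrix(NA_real_, length(gene_ids), ns,
                  dimnames = list(gene_ids, cfg$timepoints))
  for (g in gene_ids) for (s in cfg$timepoints) {
    m <- get(g, s, "mus_count"); c <- get(g, s, "cas_count")
    if (m + c > 0) ratio[g, s] <- m / (m + c)
  }

  # funnel: informative genes, then cas expression in the reference sample
  # at or above its 25th percentile among informative genes
  informative <- vapply(gene_ids,
                        function(g) get(g, ref, "snp_informative"),
                        logical(1))
  cas_ref <- vapply(gene_ids, function(g) get(g, ref, "cas_count"),
                    numeric(1))
  cs <- sort(cas_ref[informative])
  h <- (length(cs) - 1) * 0.25  # type-7 quantile by hand
  thr <- cs[floor(h) + 1] + (h - floor(h)) * (cs[floor(h) + 2] - cs[floor(h) + 1])
  expressed <- informative & cas_ref >= thr
  funnel <- c(input = length(gene_ids), snp_informative = sum(informative),
              expressed = sum(expressed))

  escapee <- ratio[, ref] > 0.14
  biallelic <- ratio[, endpoints[1]] > 0.4 & ratio[, endpoints[1]] < 0.6 &
    ratio[, endpoints[2]] > 0.4 & ratio[, endpoints[2]] < 0.6
  eligible <- biallelic & !escapee
  react_tp <- rep(NA_integer_, length(gene_ids))
  names(react_tp) <- gene_ids
  for (g in gene_ids) {
    if (!isTRUE(eligible[g])) next
    for (s in seq_len(ns)) {
      if (!is.na(ratio[g, s]) && ratio[g, s] > 0.14) {
        react_tp[g] <- s
        break
      }
    }
  }

  gene_cluster <- genes$truth$cluster[gene_ids]
  frac_react <- matrix(NA_real_, 5, ns,
                       dimnames = list(as.character(1:5), cfg$timepoints))
  for (cl in 1:5) {
    sel <- gene_ids[which(gene_cluster == cl & eligible)]
    if (!length(sel)) next
    for (s in seq_len(ns))
      frac_react[cl, s] <- mean(ratio[sel, s] > 0.14)
  }

  # relative differential peaks, end sample = first endpoint (iPSC)
  base_p <- peaks$peak_sets[[ref]]
  diff_count <- matrix(0, 5, ns,
                       dimnames = list(as.character(1:5), cfg$timepoints))
  for (s in cfg$timepoints) {
    p <- peaks$peak_sets[[s]]
    for (i in seq_len(nrow(p))) {
      ov <- FALSE
      for (j in seq_len(nrow(base_p)))
        if (p$start[i] < base_p$end[j] && p$end[i] > base_p$start[j]) {
          ov <- TRUE
          break
        }
      if (ov) next
      mid <- (p$start[i] + p$end[i]) / 2
      for (cl in 1:5)
        if (clusters$start[cl] <= mid && clusters$end[cl] > mid)
          diff_count[cl, s] <- diff_count[cl, s] + 1
    }
  }
  rel_peaks <- diff_count / diff_count[, endpoints[1]]
  rel_peaks[diff_count[, endpoints[1]] == 0, ] <- NA_real_

  # promoter accessibility: signal x overlap over TSS +/- 2 kb
  tss <- vapply(gene_ids, function(g) get(g, ref, "tss"), numeric(1))
  acc <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  sig <- peaks$signal
  for (g in seq_along(gene_ids)) {
    ws <- tss[g] - 2000; we <- tss[g] + 2000
    for (r in seq_len(nrow(sig))) {
      ov <- min(sig$end[r], we) - max(sig$start[r], ws)
      if (ov > 0) acc[g] <- acc[g] + ov * sig$value[r]
    }
  }

  # peak density of the reference sample, peaks per Mb by midpoint
  dens <- stats::setNames(numeric(5), as.character(1:5))
  p <- peaks$peak_sets[[ref]]
  for (i in seq_len(nrow(p))) {
    mid <- (p$start[i] + p$end[i]) / 2
    for (cl in 1:5)
      if (clusters$start[cl] <= mid && clusters$end[cl] > mid)
        dens[cl] <- dens[cl] + 1
  }
  dens <- dens / 2  # each cluster spans 2 Mb

  manifest <- list(
    seed = seed,
    samples = cfg$timepoints,
    reference = ref,
    endpoints = endpoints,
    funnel = as.list(funnel),
    escapees = gene_ids[which(escapee)],
    biallelic_endpoint = gene_ids[which(biallelic)],
    reactivation_timepoint = as.list(react_tp[!is.na(react_tp)]),
    fraction_reactivated = mat_to_list(frac_react),
    relative_differential_peaks = mat_to_list(rel_peaks),
    promoter_accessibility = as.list(acc),
    peak_density = as.list(dens)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

mat_to_list <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  names(out) <- rownames(m)
  out
}

#' Load the bundled worked fixture
#'
#' @param dir fixture directory; defaults to the copy shipped in the
#'   package.
#' @return list: `genes` (long table), `clusters`, `peak_sets`, `signal`,
#'   `manifest`.
#' @export
load_worked_fixture <- function(dir = system.file("extdata", "fixture",
                                                  package = "xistruct")) {
  genes <- utils::read.table(file.path(dir, "genes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  clusters <- utils::read.table(file.path(dir, "clusters.bed"), sep = "\t",
                                col.names = c("chrom", "start", "end",
                                              "cluster"),
                                stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  samples <- manifest$samples
  peak_sets <- lapply(samples, function(s)
    utils::read.table(file.path(dir, paste0("peaks_", s, ".bed")), sep = "\t",
                      col.names = c("chrom", "start", "end"),
                      stringsAsFactors = FALSE))
  names(peak_sets) <- samples
  signal <- utils::read.table(file.path(dir, "signal.bedGraph"), sep = "\t",
                              col.names = c("chrom", "start", "end", "value"),
                              stringsAsFactors = FALSE)
  list(genes = genes, clusters = clusters, peak_sets = peak_sets,
       signal = signal, manifest = manifest)
}
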