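#' Simulation configuration
#'
#' Bundles the knobs of the synthetic chromosome generators. Defaults
#' emulate the study conditions: a 170-Mb X chromosome, two mega-domains
#' split at 75.6 Mb, compartment checkerboard of contrast 0.3 at 100-kb
#' bins, TADs of 2x intra-domain enrichment at 50-kb bins, power-law
#' distance decay with exponent 1, Poisson count noise at 5e6 contacts,
#' 5% masked bins, 100 genes with 10% escapees, and staged reactivation
#' over the pseudo-time course.
#'
#' @param seed master RNG seed.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length (bp).
#' @param resolution bin size (bp).
#' @param split_point mega-domain boundary (bp).
#' @param megadomain_damping multiplicative factor for cross-boundary pairs
#'   (1 = no mega-domains).
#' @param contrast compartment checkerboard contrast in [0,1).
#' @param mean_seg_bins mean compartment segment length in bins.
#' @param min_seg_bins minimal compartment segment length in bins.
#' @param tad_enrichment intra-TAD enrichment factor minus one is scaled by
#'   the per-timepoint attenuation (2 = contacts doubled inside TADs).
#' @param tad_size_bins two-element range of TAD sizes in bins.
#' @param attenuation per-pseudo-timepoint TAD attenuation in [0,1]
#'   (0 = no TADs, 1 = full enrichment).
#' @param alpha distance-decay exponent.
#' @param depth expected total contacts per matrix.
#' @param masked_fraction fraction of bins masked.
#' @param n_genes number of genes.
#' @param escapee_fraction fraction of genes escaping silencing.
#' @param noninformative_fraction fraction of genes without usable SNPs.
#' @param gene_depth mean allelic read depth per gene.
#' @param dispersion negative-binomial dispersion for RNA counts.
#' @param timepoints sample names of the pseudo-time course; the first is
#'   the inactive reference, the last two are the reactivated endpoints.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom = "chrX",
                       chrom_length = 170e6,
                       resolution = 1e5,
                       split_point = 75.6e6,
                       megadomain_damping = 0.4,
                       contrast = 0.3,
                       mean_seg_bins = 12,
                       min_seg_bins = 4,
                       tad_enrichment = 2,
                       tad_size_bins = c(15, 35),
                       attenuation = c(0, 0.5, 1),
                       alpha = 1,
                       depth = 5e6,
                       masked_fraction = 0.05,
                       n_genes = 100,
                       escapee_fraction = 0.1,
                       noninformative_fraction = 0.2,
                       gene_depth = 100,
                       dispersion = 0.1,
                       timepoints = c("NPC", "D2", "D5", "iPSC", "ESC")) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Alternating compartment segment labels
#'
#' Draws alternating A/B segments with geometric-like lengths (minimum
#' enforced) covering `n_bins` bins.
#'
#' @param n_bins number of bins.
#' @param mean_seg_bins,min_seg_bins segment length distribution.
#' @return character vector of "A"/"B" labels; attribute `n_segments`.
#' @keywords internal
make_compartment_labels <- function(n_bins, mean_seg_bins = 12,
                                    min_seg_bins = 4) {
  labels <- character(0)
  cur <- "A"
  while (length(labels) < n_bins) {
    len <- min_seg_bins + stats::rgeom(1, 1 / (mean_seg_bins - min_seg_bins))
    labels <- c(labels, rep(cur, len))
    cur <- if (cur == "A") "B" else "A"
  }
  labels <- labels[seq_len(n_bins)]
  attr(labels, "n_segments") <- length(rle(labels)$lengths)
  labels
}

make_tad_ids <- function(n_bins, size_range) {
  ids <- integer(0)
  tad <- 0L
  borders <- integer(0)
  while (length(ids) < n_bins) {
    tad <- tad + 1L
    len <- sample(size_range[1]:size_range[2], 1)
    if (length(ids)) borders <- c(borders, length(ids))
    ids <- c(ids, rep(tad, len))
  }
  ids <- ids[seq_len(n_bins)]
  # a truncated trailing TAD shorter than the minimum merges into its
  # neighbour so every planted border separates two real TADs
  last_len <- sum(ids == ids[n_bins])
  if (last_len < size_range[1] && length(borders)) {
    ids[ids == ids[n_bins]] <- ids[n_bins] - 1L
    borders <- borders[-length(borders)]
  }
  attr(ids, "borders") <- borders  # last bin of each TAD but the final one
  ids
}

expected_hic <- function(n_bins, compartment, tad_id, split_bin, contrast,
                         enrichment, damping, alpha) {
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  e <- (pmax(d, 1))^(-alpha)
  if (!is.null(compartment) && contrast > 0) {
    same <- outer(compartment, compartment, "==")
    e <- e * ifelse(same, 1 + contrast, 1 - contrast)
  }
  if (!is.null(tad_id) && enrichment > 0) {
    same_tad <- outer(tad_id, tad_id, "==")
    e <- e * (1 + enrichment * same_tad)
  }
  if (!is.null(split_bin) && damping < 1) {
    left <- seq_len(n_bins) <= split_bin
    cross <- outer(left, left, "!=")
    e <- e * ifelse(cross, damping, 1)
  }
  e
}

#' Simulate one allele-resolved Hi-C contact matrix
#'
#' Builds the expected matrix depth * d^(-alpha) * C * T * M — checkerboard
#' compartments (C), intra-TAD enrichment (T), inter-mega-domain damping
#' (M) — draws Poisson counts, and zeroes/flags masked bins. Mappability
#' and restriction-site annotations are drawn so that masked bins fail the
#' filters they emulate.
#'
#' @param config `sim_config`.
#' @param compartment per-bin "A"/"B" labels or NULL.
#' @param tad_id per-bin TAD ids or NULL.
#' @param attenuation TAD attenuation in [0,1] for this matrix.
#' @param damping overrides the config mega-domain damping (use 1 for an
#'   active-X-like matrix without mega-domains).
#' @param allele allele label.
#' @param masked logical per-bin mask, or NULL to draw from
#'   `masked_fraction`.
#' @return list: `matrix` (raw `ContactMatrix`), `gc` (per-bin GC-like
#'   orientation track).
#' @export
simulate_hic_matrix <- function(config, compartment = NULL, tad_id = NULL,
                                attenuation = 1,
                                damping = config$megadomain_damping,
                                allele = "mus", masked = NULL) {
  n_bins <- ceiling(config$chrom_length / config$resolution)
  split_bin <- if (damping < 1)
    floor(config$split_point / config$resolution) else NULL
  e <- expected_hic(n_bins, compartment, tad_id, split_bin,
                    config$contrast * (!is.null(compartment)),
                    (config$tad_enrichment - 1) * attenuation *
                      (!is.null(tad_id)),
                    damping, config$alpha)
  e <- e * (config$depth / sum(e))
  counts <- matrix(0, n_bins, n_bins)
  ut <- upper.tri(e, diag = TRUE)
  counts[ut] <- stats::rpois(sum(ut), e[ut])
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  if (is.null(masked))
    masked <- stats::runif(n_bins) < config$masked_fraction
  mapp <- stats::runif(n_bins, 0.7, 1)
  res_sites <- stats::rpois(n_bins, 8) + 1L
  # masked bins fail one of the real filters
  fail_mode <- sample(2, sum(masked), replace = TRUE)
  mapp[masked][fail_mode == 1] <- stats::runif(sum(fail_mode == 1), 0, 0.45)
  res_sites[masked][fail_mode == 2] <- 0L
  bins <- bin_table(config$chrom, config$chrom_length, config$resolution,
                    mappability = mapp, n_re_sites = res_sites,
                    masked = masked)
  counts[masked, ] <- 0
  counts[, masked] <- 0
  cm <- contact_matrix(counts, bins, state = "raw", allele = allele)
  cm <- apply_mask(cm, bins)
  comp_a <- if (is.null(compartment)) rep(0, n_bins) else
    as.numeric(compartment == "A")
  gc_track <- 0.40 + 0.04 * comp_a + stats::rnorm(n_bins, 0, 0.002)
  list(matrix = cm, gc = gc_track)
}

#' Generate allele-pair contact maps across pseudo-time
#'
#' Produces, per pseudo-timepoint of the attenuation schedule, a mus-like
#' matrix (mega-domains, compartments, TADs attenuated per schedule) and a
#' cas-like matrix (no mega-domains, full TADs), sharing one bin mask, plus
#' the planted ground truth.
#'
#' @param config `sim_config`.
#' @return list: `maps` (list per timepoint of list(mus, cas)), `truth`
#'   (compartment labels, tad borders/ids, gc, masked, n_segments).
#' @export
generate_contact_maps <- function(config) {
  set.seed(config$seed)
  n_bins <- ceiling(config$chrom_length / config$resolution)
  compartment <- make_compartment_labels(n_bins, config$mean_seg_bins,
                                         config$min_seg_bins)
  tad_id <- make_tad_ids(n_bins, config$tad_size_bins)
  masked <- stats::runif(n_bins) < config$masked_fraction
  maps <- vector("list", length(config$attenuation))
  gc <- NULL
  for (t in seq_along(config$attenuation)) {
    mus <- simulate_hic_matrix(config, compartment, tad_id,
                               attenuation = config$attenuation[t],
                               allele = "mus", masked = masked)
    cas <- simulate_hic_matrix(config, compartment, tad_id,
                               attenuation = 1, damping = 1,
                               allele = "cas", masked = masked)
    if (is.null(gc)) gc <- mus$gc
    maps[[t]] <- list(mus = mus$matrix, cas = cas$matrix)
  }
  list(maps = maps,
       truth = list(compartment = compartment,
                    n_segments = attr(compartment, "n_segments"),
                    tad_id = as.integer(tad_id),
                    tad_borders = attr(tad_id, "borders"),
                    gc = gc, masked = masked))
}

#' Simulate a matrix with planted spatial clusters
#'
#' Plants `k` spatial clusters drawn from `n_archetypes` interaction
#' archetypes. Bins are assigned to clusters in short contiguous segments
#' (default 6 bins, i.e. 300 kb at 50-kb resolution, matching the scale of
#' real subcompartment domains) laid out in balanced random order. The
#' contact rate of a bin pair is power-law decay modulated by an
#' archetype-level affinity gradient (like attracts like), a strong
#' same-cluster self-affinity that makes each cluster individually
#' identifiable, and a small symmetric per-cluster-pair jitter; counts are
#' Poisson.
#'
#' @param config `sim_config` (seed, depth, alpha, resolution, chrom_length
#'   used).
#' @param k number of planted clusters.
#' @param n_archetypes number of interaction archetypes (subcompartments).
#' @param affinity archetype-level affinity contrast.
#' @param self_affinity extra same-cluster contrast making each cluster
#'   identifiable.
#' @param jitter half-width of the uniform per-cluster-pair affinity jitter.
#' @param seg_bins bins per contiguous cluster segment.
#' @return list: `matrix` (raw `ContactMatrix`), `cluster` (planted ids),
#'   `archetype` (length-k map cluster -> archetype), `pc1_proxy` (per-bin
#'   score making archetype order recoverable).
#' @export
simulate_cluster_matrix <- function(config, k = 12, n_archetypes = 5,
                                    affinity = 0.1, self_affinity = 5,
                                    jitter = 0.01, seg_bins = 6) {
  set.seed(config$seed)
  n_bins <- ceiling(config$chrom_length / config$resolution)
  n_seg <- floor(n_bins / seg_bins)
  seg_cluster <- sample(rep(seq_len(k), length.out = n_seg))
  cluster <- rep(seg_cluster, each = seg_bins)[seq_len(n_bins)]
  cluster[is.na(cluster)] <- seg_cluster[n_seg]  # remainder joins last segment
  archetype <- rep(seq_len(n_archetypes), length.out = k)
  # archetype affinity: like attracts like, graded by archetype distance
  arch_aff <- 1 + affinity *
    (1 - abs(outer(seq_len(n_archetypes), seq_len(n_archetypes), "-")) /
       (n_archetypes - 1) * 2)
  arch_aff <- pmax(arch_aff, 0.1)
  caff <- arch_aff[archetype, archetype] + diag(self_affinity, k)
  jit <- matrix(stats::runif(k * k, -jitter, jitter), k, k)
  caff <- pmax(caff + (jit + t(jit)) / 2, 0.05)
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  e <- (pmax(d, 1))^(-config$alpha) * caff[cbind(
    rep(cluster, n_bins), rep(cluster, each = n_bins))]
  dim(e) <- c(n_bins, n_bins)
  e <- e * (config$depth / sum(e))
  counts <- matrix(0, n_bins, n_bins)
  ut <- upper.tri(e, diag = TRUE)
  counts[ut] <- stats::rpois(sum(ut), e[ut])
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  bins <- bin_table(config$chrom, config$chrom_length, config$resolution)
  cm <- contact_matrix(counts, bins, state = "raw", allele = "mus")
  # archetype 1 is the most A-like: proxy PC1 descends with archetype index
  pc1_proxy <- (n_archetypes - archetype[cluster]) / (n_archetypes - 1) * 2 - 1
  list(matrix = cm, cluster = cluster, archetype = archetype,
       pc1_proxy = pc1_proxy)
}

#' Generate allele-resolved gene counts across pseudo-time
#'
#' Plants an escapee set (allelic ratio 0.3 at all times), silenced genes
#' (ratio 0.02 before their reactivation timepoint, 0.5 after), staged
#' reactivation timepoints, and a non-informative SNP fraction. cas counts
#' are negative binomial around a lognormal per-gene depth; mus counts
#' follow the planted ratio.
#'
#' @param config `sim_config`.
#' @param cluster_intervals optional data.frame (chrom, start, end, cluster)
#'   to place genes into clusters; NULL assigns cluster NA.
#' @return list: `table` (long data.frame gene x sample with counts and
#'   ratio), `truth` (escapee ids, reactivation timepoint per gene,
#'   noninformative ids), `samples`.
#' @export
generate_allelic_counts <- function(config, cluster_intervals = NULL) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  samples <- config$timepoints
  ns <- length(samples)
  tss <- sort(round(stats::runif(n, 1e5, config$chrom_length - 1e5)))
  gene <- sprintf("gene%03d", seq_len(n))
  escapee <- stats::runif(n) < config$escapee_fraction
  noninf <- stats::runif(n) < config$noninformative_fraction
  # silenced genes reactivate between the second sample and the first endpoint
  react_tp <- sample(2:(ns - 1), n, replace = TRUE)
  react_tp[escapee] <- NA_integer_
  mu <- stats::rlnorm(n, log(config$gene_depth), 0.4)
  size <- 1 / config$dispersion
  ratio_planted <- matrix(0.02, n, ns)
  for (g in seq_len(n)) {
    if (escapee[g]) ratio_planted[g, ] <- 0.3
    else ratio_planted[g, seq(react_tp[g], ns)] <- 0.5
  }
  rows <- list()
  for (s in seq_len(ns)) {
    # shared Gamma expression factor: counts are marginally negative
    # binomial, but the allelic ratio carries only sampling noise, as
    # biological expression variability hits both alleles together
    lambda <- stats::rgamma(n, shape = size, rate = size)
    cas <- stats::rpois(n, mu * lambda * (1 - ratio_planted[, s]))
    mus <- stats::rpois(n, mu * lambda * ratio_planted[, s])
    bulk <- stats::rpois(n, 2 * mu * lambda)
    rows[[s]] <- data.frame(gene = gene, chrom = config$chrom, tss = tss,
                            sample = samples[s], mus_count = mus,
                            cas_count = cas, bulk_count = bulk,
                            snp_informative = !noninf,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$ratio <- allelic_ratio(tab$mus_count, tab$cas_count)
  cluster <- rep(NA_integer_, n)
  if (!is.null(cluster_intervals)) {
    for (g in seq_len(n)) {
      hit <- which(cluster_intervals$start <= tss[g] &
                     cluster_intervals$end > tss[g])
      if (length(hit)) cluster[g] <- cluster_intervals$cluster[hit[1]]
    }
  }
  list(table = tab,
       truth = list(escapee = gene[escapee],
                    reactivation_timepoint = stats::setNames(react_tp, gene),
                    noninformative = gene[noninf],
                    cluster = stats::setNames(cluster, gene)),
       samples = samples)
}

#' Generate per-timepoint peak sets and a signal track
#'
#' A baseline peak set plus monotonically accruing new peaks per cluster:
#' at timepoint t each cluster has gained `schedule[cluster, t]` of its
#' final new peaks (schedule entries in [0,1], non-decreasing per row). The
#' bedGraph signal track covers each peak with a constant height.
#'
#' @param config `sim_config`.
#' @param cluster_intervals data.frame chrom, start, end, cluster.
#' @param n_baseline baseline peaks per cluster.
#' @param n_new final new peaks per cluster.
#' @param schedule cluster x timepoint matrix of accrual fractions; NULL
#'   uses a linear ramp 0 -> 1.
#' @return list: `peak_sets` (named list of BED data.frames), `signal`
#'   (bedGraph data.frame of the final timepoint), `truth` (schedule, new
#'   peak counts per cluster per timepoint).
#' @export
generate_peak_sets <- function(config, cluster_intervals, n_baseline = 5,
                               n_new = 12, schedule = NULL) {
  set.seed(config$seed + 2L)
  samples <- config$timepoints
  ns <- length(samples)
  labs <- sort(unique(cluster_intervals$cluster))
  if (is.null(schedule)) {
    schedule <- matrix(rep(seq(0, 1, length.out = ns), each = length(labs)),
                       nrow = length(labs),
                       dimnames = list(as.character(labs), samples))
  }
  width <- 400
  draw_peaks <- function(cl, m) {
    sel <- cluster_intervals[cluster_intervals$cluster == cl, , drop = FALSE]
    # lay peaks on a grid so baseline and new peaks never overlap
    slots <- unlist(lapply(seq_len(nrow(sel)), function(r) {
      seq(sel$start[r], sel$end[r] - width, by = 4 * width)
    }))
    starts <- sort(sample(slots, m))
    data.frame(chrom = sel$chrom[1], start = starts, end = starts + width,
               stringsAsFactors = FALSE)
  }
  base_peaks <- list(); new_peaks <- list()
  for (cl in labs) {
    all_p <- draw_peaks(cl, n_baseline + n_new)
    pick <- sample(nrow(all_p), n_baseline)
    base_peaks[[as.character(cl)]] <- all_p[pick, , drop = FALSE]
    np <- all_p[-pick, , drop = FALSE]
    new_peaks[[as.character(cl)]] <- np[sample(nrow(np)), , drop = FALSE]
  }
  peak_sets <- list()
  new_counts <- matrix(0L, length(labs), ns,
                       dimnames = list(as.character(labs), samples))
  for (s in seq_len(ns)) {
    rows <- list()
    for (cl in as.character(labs)) {
      m <- round(schedule[cl, s] * n_new)
      new_counts[cl, s] <- m
      rows[[cl]] <- rbind(base_peaks[[cl]],
                          if (m > 0) new_peaks[[cl]][seq_len(m), ])
    }
    p <- do.call(rbind, rows)
    peak_sets[[samples[s]]] <- p[order(p$start), , drop = FALSE]
  }
  final <- peak_sets[[samples[ns]]]
  signal <- data.frame(chrom = final$chrom, start = final$start,
                       end = final$end,
                       value = round(stats::runif(nrow(final), 0.5, 2), 3),
                       stringsAsFactors = FALSE)
  list(peak_sets = peak_sets, signal = signal,
       truth = list(schedule = schedule, new_counts = new_counts))
}
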