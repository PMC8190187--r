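#!/usr/bin/env Rscript
# Generates the synthetic study: an X-like chromosome carrying two
# mega-domains (boundary 75.6 Mb scaled into a 40-Mb desk-scale chromosome),
# A/B compartments, TADs that strengthen over a three-step pseudo-time
# course on the inactive allele, allelic gene counts with planted escapees
# and staged reactivation, and peak sets that accrue over time.
# Writes triplet matrices, tracks and tables under results/sim/.

suppressPackageStartupMessages(library(xistruct))

seed <- 20260921 %% 1000L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed, chrom_length = 40e6, resolution = 1e5,
                  split_point = 17.8e6,  # boundary at the same relative spot
                  depth = 3e6, attenuation = c(0, 0.5, 1))
maps <- generate_contact_maps(cfg)

for (t in seq_along(cfg$attenuation)) {
  for (al in c("mus", "cas")) {
    write_contacts(maps$maps[[t]][[al]],
                   file.path(out, sprintf("hic_t%d_%s.tsv", t, al)))
  }
}
bt <- maps$maps[[1]]$mus$bins
utils::write.table(bt[c("chrom", "start", "end", "mappability",
                        "n_re_sites")],
                   file.path(out, "bins.bed"), sep = "\t", quote = FALSE,
                   row.names = FALSE, col.names = FALSE)
write_bedgraph(bt, maps$truth$gc, file.path(out, "gc.bedGraph"))
utils::write.table(
  data.frame(compartment = maps$truth$compartment,
             tad_id = maps$truth$tad_id, masked = maps$truth$masked),
  file.path(out, "truth_bins.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

clusters <- data.frame(chrom = cfg$chrom,
                       start = seq(0, 32e6, by = 8e6),
                       end = seq(8e6, 40e6, by = 8e6), cluster = 1:5)
genes <- generate_allelic_counts(cfg, cluster_intervals = clusters)
utils::write.table(genes$table, file.path(out, "genes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
peaks <- generate_peak_sets(cfg, clusters)
for (s in names(peaks$peak_sets))
  utils::write.table(peaks$peak_sets[[s]],
                     file.path(out, paste0("peaks_", s, ".bed")),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
utils::write.table(clusters, file.path(out, "clusters.bed"), sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)

cat(sprintf(
  "simulated %d bins x %d pseudo-timepoints x 2 alleles; %d planted\n",
  nrow(bt), length(cfg$attenuation), attr(maps$truth$compartment,
                                          "n_segments")),
  sprintf("compartment segments, %d TAD borders, %d genes (%d escapees)\n",
          length(maps$truth$tad_borders), cfg$n_genes,
          length(genes$truth$escapee)))
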