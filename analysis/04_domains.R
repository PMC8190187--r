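#!/usr/bin/env Rscript
# TAD dynamics on the simulated pseudo-time course: insulation scores,
# border calling at the -0.086 cutoff, domain scores per timepoint,
# relative domain scores, early/late TAD classification, and the
# in-silico mixing control showing that a single cell-mixture ratio
# predicts a uniform relative domain score. Writes results/domains/.

suppressPackageStartupMessages(library(xistruct))

out <- "results/domains"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 13, chrom_length = 50e6, resolution = 5e4,
                  depth = 2e7, masked_fraction = 0.03)
set.seed(13)
n <- 1000
tid <- xistruct:::make_tad_ids(n, c(30, 60))
masked <- runif(n) < cfg$masked_fraction

mats <- lapply(seq_along(cfg$attenuation), function(t) {
  set.seed(13 + t)
  simulate_hic_matrix(cfg, tad_id = tid,
                      attenuation = cfg$attenuation[t],
                      damping = if (t < 3) cfg$megadomain_damping else 1,
                      masked = masked)$matrix
})
bal <- lapply(mats, ice_balance)

# TADs called on the final (active-like) state, reused across timepoints
sm_end <- smooth_insulation(insulation_score(bal[[3]], 10), 7)
borders <- call_tad_borders(sm_end, -0.086)
tads <- tads_from_borders(borders, bal[[3]]$bins)
utils::write.table(tads[c("chrom", "start", "end")],
                   file.path(out, "tads.bed"), sep = "\t", quote = FALSE,
                   row.names = FALSE, col.names = FALSE)
for (t in 1:3) {
  ins <- insulation_score(bal[[t]], 10)
  write_bedgraph(bal[[t]]$bins, smooth_insulation(ins, 7),
                 file.path(out, sprintf("insulation_t%d.bedGraph", t)))
}

ds <- vapply(bal, domain_score, numeric(nrow(tads)), tads = tads)
rel <- relative_domain_score(ds[, 1], ds[, 2], ds[, 3])
cls <- classify_tads_early_late(rel, seed = 13)
utils::write.table(
  data.frame(tads[c("chrom", "start", "end")],
             ds_start = round(ds[, 1], 4), ds_mid = round(ds[, 2], 4),
             ds_end = round(ds[, 3], 4), relative = round(rel, 4),
             dynamics = cls$class),
  file.path(out, "domain_scores.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

iqr <- vapply(bal, function(b)
  IQR(smooth_insulation(insulation_score(b, 10), 7), na.rm = TRUE),
  numeric(1))
planted <- attr(tid, "borders")
recall <- mean(vapply(planted, function(x) min(abs(borders - x)) <= 1,
                      logical(1)))
cat(sprintf(
  "%d/%d planted borders recovered within 1 bin (%d called); insulation
  IQR grows %.3f -> %.3f -> %.3f across the time course; mean domain score
  %.3f -> %.3f -> %.3f; %.0f%% of TADs classify as early\n",
  round(recall * length(planted)), length(planted), length(borders),
  iqr[1], iqr[2], iqr[3], mean(ds[, 1], na.rm = TRUE),
  mean(ds[, 2], na.rm = TRUE), mean(ds[, 3], na.rm = TRUE),
  100 * cls$fraction_early))

# mixing control: relative scores of NPC/ESC mixtures sit at the ratio
mix_rows <- lapply(c(0, 0.25, 0.5, 0.75, 1), function(r) {
  dsr <- domain_score(mix_matrices(bal[[1]], bal[[3]], r), tads)
  relr <- relative_domain_score(ds[, 1], dsr, ds[, 3])
  data.frame(ratio = r, mean_rel = round(mean(relr, na.rm = TRUE), 4),
             sd_rel = round(sd(relr, na.rm = TRUE), 4))
})
mix_tab <- do.call(rbind, mix_rows)
utils::write.table(mix_tab, file.path(out, "mixing_linearity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("in-silico mixing: mean relative domain score per mixing ratio =\n")
print(mix_tab, row.names = FALSE)
cat("a heterogeneous NPC/ESC population would put every TAD at the same\n",
    "relative score; spread across TADs in real data argues against it\n")
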