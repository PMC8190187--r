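# Shared helpers: small deterministic matrices and files built in code.

# symmetric ContactMatrix from an explicit matrix, unmasked by default
cm_from <- function(values, resolution = 1e5, chrom = "chrX",
                    state = "raw", masked = NULL) {
  n <- nrow(values)
  bins <- bin_table(chrom, n * resolution, resolution)
  if (!is.null(masked)) bins$masked <- masked
  m <- contact_matrix(values, bins, state = state)
  if (!is.null(masked)) m <- xistruct:::apply_mask(m, bins)
  m
}

# block-structured expected matrix with optional decay, Poisson-free
block_matrix <- function(labels, within = 2, between = 0.5, decay = NULL) {
  n <- length(labels)
  same <- outer(labels, labels, "==")
  v <- ifelse(same, within, between)
  if (!is.null(decay)) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    v <- v * (pmax(d, 1))^(-decay)
  }
  v
}

# brute-force exhaustive best label permutation (oracle for alignment)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

align_oracle <- function(labels, reference, k) {
  best <- -1; best_map <- NULL
  for (p in perms(seq_len(k))) {
    agree <- sum(p[labels] == reference, na.rm = TRUE)
    if (agree > best) { best <- agree; best_map <- p }
  }
  list(agreement = best, mapping = best_map)
}

write_triplets <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

write_bins <- function(n, resolution = 1e5, path,
                       mappability = 1, n_re_sites = 5L) {
  bt <- bin_table("chrX", n * resolution, resolution,
                  mappability = mappability, n_re_sites = n_re_sites)
  utils::write.table(bt[c("chrom", "start", "end", "mappability",
                          "n_re_sites")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}
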