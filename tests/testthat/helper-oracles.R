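# Independent oracles and tiny builders shared across test files.

# Closed-form LOD from one-predictor least squares at a fully typed marker.
lod_closed_form <- function(y, g) {
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  (length(y) / 2) * log10(rss0 / rss1)
}

# Brute-force per-SNP window assignment (oracle for window_counts).
window_counts_brute <- function(catalog, chrom, start, end, w) {
  n_win <- ceiling((end - start) / w)
  tot <- integer(n_win); disc <- integer(n_win)
  for (i in seq_len(nrow(catalog))) {
    p <- catalog$pos[i]
    if (catalog$chrom[i] != chrom || p < start || p >= end) next
    for (k in seq_len(n_win)) {
      lo <- start + (k - 1) * w; hi <- min(lo + w, end)
      if (p >= lo && p < hi) {
        tot[k] <- tot[k] + 1L
        if (catalog$allele_a[i] != catalog$allele_b[i])
          disc[k] <- disc[k] + 1L
        break
      }
    }
  }
  list(n_total = tot, n_discordant = disc)
}

# Brute-force per-cell dot-plot statistics (oracle for dotplot_stats).
dotplot_brute <- function(counts, norm, clusters, gene, cluster) {
  frac <- 0; m <- 0; n <- 0
  for (i in seq_len(nrow(counts))) {
    if (clusters[i] != cluster) next
    n <- n + 1
    if (counts[i, gene] > 0) frac <- frac + 1
    m <- m + norm[i, gene]
  }
  if (n == 0) list(fraction = 0, mean = 0)
  else list(fraction = frac / n, mean = m / n)
}

# Small dense map for fast scans: nm markers every 2 Mbp, 0.5 cM/Mbp.
tiny_map <- function(nm = 6, start = 10e6, by = 2e6) {
  bp <- start + (seq_len(nm) - 1) * by
  genetic_map("1", sprintf("m%02d", seq_len(nm)), bp, bp / 1e6 * 0.5)
}

# Two-group expression set from explicit per-group matrices.
tiny_expr <- function(m1, m2, genes = paste0("g", seq_len(nrow(m1)))) {
  m <- cbind(m1, m2)
  rownames(m) <- genes
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  expression_set(m, rep(c("A", "B"), c(ncol(m1), ncol(m2))))
}
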