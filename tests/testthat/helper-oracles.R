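# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately share no code with the implementation paths
# they check.

# Per-base majority-overlap oracle: category of one TE against gene bodies
# and strand-aware flanks, on a small genome laid out as logical vectors.
oracle_te_category <- function(te, genes, flank_bp, chrom_len) {
  cover <- function(rows) {
    v <- logical(chrom_len)
    for (i in seq_len(nrow(rows))) {
      s <- max(rows$start[i], 0); e <- min(rows$end[i], chrom_len)
      if (s < e) v[(s + 1):e] <- TRUE
    }
    v
  }
  g <- genes[genes$chrom == te$chrom, , drop = FALSE]
  if (nrow(g) == 0) return("intergenic")
  plus <- g$strand == "+"
  up <- data.frame(start = ifelse(plus, g$start - flank_bp, g$end),
                   end = ifelse(plus, g$start, g$end + flank_bp))
  dn <- data.frame(start = ifelse(plus, g$end, g$start - flank_bp),
                   end = ifelse(plus, g$end + flank_bp, g$start))
  feats <- list(genic = cover(g), upstream = cover(up),
                downstream = cover(dn))
  te_bases <- (te$start + 1):te$end
  te_len <- te$end - te$start
  for (cat in c("genic", "upstream", "downstream")) {
    if (2 * sum(feats[[cat]][te_bases]) > te_len) return(cat)
  }
  "intergenic"
}

# Naive O(n*m) midpoint counter over an interval set.
oracle_count <- function(midpoints, intervals) {
  total <- 0L
  for (i in seq_len(nrow(intervals))) {
    total <- total + sum(midpoints >= intervals$start[i] &
                           midpoints < intervals$end[i])
  }
  total
}

# Exact two-sided signed-rank p by literal enumeration of all 2^n sign
# assignments (n <= ~12).
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_plus <- signs %*% r
  min(1, 2 * mean(w_plus <= w_obs + 1e-9))
}

# Random gene set on one chromosome: non-overlapping, stranded.
random_genes <- function(n, chrom_len, gene_len = 50) {
  slots <- sort(sample.int(chrom_len - gene_len, n))
  keep <- c(TRUE, diff(slots) > gene_len)
  slots <- slots[keep]
  data.frame(gene_id = sprintf("g%d", seq_along(slots)), chrom = "chr1",
             start = slots, end = slots + gene_len,
             strand = sample(c("+", "-"), length(slots), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Random TE set (may be nested/overlapping) on one chromosome.
random_tes <- function(n, chrom_len, max_len = 120) {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(te_id = sprintf("te%d", seq_len(n)), chrom = "chr1",
             start = start, end = start + len,
             te_class = "II",
             superfamily = sample(te_superfamilies(), n, replace = TRUE),
             category = "unassigned", stringsAsFactors = FALSE)
}

# A fast low-depth synth config for integration tests.
small_synth_config <- function(seed = 1, te_per_superfamily = 6, ...) {
  synth_config(seed = seed, n_chrom = 2, chrom_len = 2e5, n_genes = 24,
               te_per_superfamily = te_per_superfamily,
               base_intensity = 0.05, igg_intensity = 0.05, ...)
}
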