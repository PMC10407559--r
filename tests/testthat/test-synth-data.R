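test_that("config validation rejects out-of-range planted parameters", {
  expect_error(synth_config(te_depletion = 0), "te_depletion")
  expect_error(synth_config(te_depletion = 1.2), "te_depletion")
  expect_error(synth_config(flank_enrichment = 0.5), ">= 1")
  expect_error(synth_config(boosted_superfamilies = "LINEX"), "unknown")
  expect_error(synth_config(n_genes = 5000), "infeasible")
  expect_error(synth_config(te_category_fractions =
                              c(genic = 1, upstream = 1, downstream = 0,
                                intergenic = 0)), "sum to 1")
})

test_that("annotation simulation is deterministic and well-formed", {
  cfg <- small_synth_config(seed = 3)
  a1 <- simulate_annotations(cfg)
  a2 <- simulate_annotations(cfg)
  expect_identical(a1, a2)
  g <- a1$genes
  # genes non-overlapping with both flanks inside bounds
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    gc <- gc[order(gc$start), ]
    expect_true(all(gc$start - cfg$flank_bp >= 0))
    expect_true(all(gc$end + cfg$flank_bp <= a1$chrom_lens[[ch]]))
    if (nrow(gc) > 1)
      expect_true(all(gc$start[-1] - cfg$flank_bp >=
                        gc$end[-nrow(gc)] + cfg$flank_bp))
  }
  expect_equal(nrow(a1$tes), sum(cfg$te_per_superfamily))
})

test_that("the majority-overlap rule recovers every planted TE category", {
  cfg <- small_synth_config(seed = 4)
  ann <- simulate_annotations(cfg)
  got <- assign_te_categories(ann$tes, ann$genes, cfg$flank_bp,
                              ann$chrom_lens)$category
  want <- ifelse(ann$tes$target_category == "genic", "genic",
                 ann$tes$target_category)
  expect_equal(got, want)
})

test_that("a TE-free configuration dissects into pure non-TE regions", {
  cfg <- small_synth_config(seed = 5)
  cfg$te_per_superfamily[] <- 0
  ann <- simulate_annotations(cfg)
  expect_equal(nrow(ann$tes), 0)
  dis <- dissect_genes(ann$genes, ann$tes, cfg$flank_bp, ann$chrom_lens)
  expect_true(all(dis$segments$segment_class == "nonte"))
  expect_true(all(dis$regions$n_te == 0))
})

test_that("segment midpoint counts follow the planted Poisson intensity", {
  cfg <- small_synth_config(seed = 6)
  ann <- simulate_annotations(cfg)
  frags <- simulate_midpoints(cfg, ann, "diploid", "igg")
  # flat IgG: expected igg_intensity * chrom_len midpoints per chromosome
  mid <- fragment_midpoint(frags$start, frags$end)
  for (ch in names(ann$chrom_lens)) {
    n <- sum(frags$chrom == ch)
    expected <- cfg$igg_intensity * ann$chrom_lens[[ch]]
    expect_lt(abs(n - expected), 4 * sqrt(expected))
  }
  # fragments are 150 bp spans centred on their midpoints
  expect_true(all(frags$end - frags$start == 150))
})

test_that("fragment simulation is deterministic per (condition, track)", {
  cfg <- small_synth_config(seed = 7)
  ann <- simulate_annotations(cfg)
  f1 <- simulate_midpoints(cfg, ann, "tetraploid", "chip")
  f2 <- simulate_midpoints(cfg, ann, "tetraploid", "chip")
  expect_identical(f1, f2)
  f3 <- simulate_midpoints(cfg, ann, "diploid", "chip")
  expect_false(identical(f1, f3))
})

test_that("the tetraploid boost is planted only on boosted carrier regions", {
  cfg <- small_synth_config(seed = 8)
  ann <- simulate_annotations(cfg)
  dis <- dissect_genes(ann$genes, ann$tes, cfg$flank_bp, ann$chrom_lens)
  map_d <- ploidyTE:::.intensity_map(cfg, ann, "diploid", dis)
  map_t <- ploidyTE:::.intensity_map(cfg, ann, "tetraploid", dis)
  expect_equal(map_d[, c("chrom", "start", "end")],
               map_t[, c("chrom", "start", "end")])
  ratio <- map_t$intensity / map_d$intensity
  expect_true(all(ratio %in% c(1, cfg$tetraploid_boost)))
  boosted <- which(ratio > 1)
  # boosted pieces are exactly the nonte segments of regions carrying a
  # boosted superfamily
  reg <- dis$regions
  carrier <- reg[vapply(strsplit(reg$superfamilies, ","),
                        function(s) any(s %in% cfg$boosted_superfamilies),
                        logical(1)), ]
  seg <- dis$segments
  seg_key <- paste(seg$gene_id, seg$region_kind)
  boosted_seg <- seg[seg$segment_class == "nonte" &
                       seg_key %in% paste(carrier$gene_id,
                                          carrier$region_kind), ]
  expect_setequal(paste(map_d$chrom[boosted], map_d$start[boosted]),
                  paste(boosted_seg$chrom, boosted_seg$start))
  # planted intensity ratio for those pieces equals beta by construction
  expect_equal(unique(ratio[boosted]), cfg$tetraploid_boost)
})

test_that("a null configuration plants no contrast at all", {
  cfg <- small_synth_config(seed = 9, te_depletion = 1,
                            flank_enrichment = 1, tetraploid_boost = 1)
  ann <- simulate_annotations(cfg)
  dis <- dissect_genes(ann$genes, ann$tes, cfg$flank_bp, ann$chrom_lens)
  map_d <- ploidyTE:::.intensity_map(cfg, ann, "diploid", dis)
  map_t <- ploidyTE:::.intensity_map(cfg, ann, "tetraploid", dis)
  expect_equal(unique(map_d$intensity), cfg$base_intensity)
  expect_equal(unique(map_t$intensity), cfg$base_intensity)
})

test_that("expression counts couple to the genic IgG ratio with the planted slope", {
  cfg <- small_synth_config(seed = 10)
  ig <- data.frame(gene_id = sprintf("g%02d", 1:40),
                   diploid = runif(40, 0.8, 1.6),
                   tetraploid = runif(40, 0.8, 2.4))
  expr <- simulate_counts(cfg, ig)
  expect_identical(simulate_counts(cfg, ig)$counts, expr$counts)
  expect_equal(dim(expr$counts), c(40L, 2L * cfg$n_replicates))
  expect_equal(expr$truth$true_log2fc,
               cfg$coupling_slope * (ig$tetraploid - ig$diploid))
  # zero slope: identical means across conditions
  cfg0 <- small_synth_config(seed = 10, coupling_slope = 0)
  expr0 <- simulate_counts(cfg0, ig)
  expect_true(all(expr0$truth$true_log2fc == 0))
  expect_true(all(expr0$truth$true_label == "ns"))
})

test_that("generated annotation files round-trip through the parsers", {
  cfg <- small_synth_config(seed = 11)
  ann <- simulate_annotations(cfg)
  gff <- tempfile(fileext = ".gff3")
  bed <- tempfile(fileext = ".bed")
  write_gene_annotation(ann$genes, gff)
  write_te_annotation(ann$tes, bed)
  expect_no_warning(genes2 <- read_gene_annotation(gff))
  expect_no_warning(tes2 <- read_te_annotation(bed, "bed"))
  expect_equal(genes2, ann$genes[order(ann$genes$chrom, ann$genes$start), ],
               ignore_attr = TRUE)
  expect_equal(tes2[, c("chrom", "start", "end", "superfamily")],
               ann$tes[, c("chrom", "start", "end", "superfamily")])
})
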