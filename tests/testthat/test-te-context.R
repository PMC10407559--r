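gene_df <- function(start, end, strand = "+", id = "g1", chrom = "chr1") {
  data.frame(gene_id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

te_df <- function(start, end, superfamily = "LINE", chrom = "chr1") {
  n <- length(start)
  superfamily <- rep(superfamily, length.out = n)
  data.frame(te_id = sprintf("te%d", seq_len(n)),
             chrom = rep(chrom, length.out = n),
             start = start, end = end, te_class = te_class_of(superfamily),
             superfamily = superfamily,
             category = rep("unassigned", n), stringsAsFactors = FALSE)
}

test_that("flanks are strand-aware and clipped at chromosome bounds", {
  g <- gene_df(1000, 2000, "+")
  expect_equal(flank_region(g, 2000, "upstream", 5000),
               list(chrom = "chr1", start = 0L, end = 1000L))  # clipped left
  expect_equal(flank_region(g, 2000, "downstream", 5000),
               list(chrom = "chr1", start = 2000L, end = 4000L))
  gm <- gene_df(1000, 2000, "-")
  expect_equal(flank_region(gm, 2000, "upstream", 5000),
               list(chrom = "chr1", start = 2000L, end = 4000L))
  expect_equal(flank_region(gm, 2000, "downstream", 5000),
               list(chrom = "chr1", start = 0L, end = 1000L))
  # upstream of a + gene starting at 0 vanishes entirely
  expect_null(flank_region(gene_df(0, 500, "+"), 2000, "upstream", 5000))
  # clipping at the right end
  expect_equal(flank_region(gene_df(1000, 2000, "+"), 2000, "downstream",
                            3000)$end, 3000L)
})

test_that("majority-overlap categories respect the strictly-more-than-half rule", {
  chrom_lens <- c(chr1 = 100000L)
  g <- gene_df(140, 500)
  # overlap 60 of 100 -> genic
  expect_equal(assign_te_categories(te_df(100, 200), g, 20,
                                    chrom_lens)$category, "genic")
  # overlap exactly 50 of 100 -> NOT genic, nothing else -> intergenic
  g2 <- gene_df(150, 500)
  expect_equal(assign_te_categories(te_df(100, 200), g2, 20,
                                    chrom_lens)$category, "intergenic")
  # TE overlapping nothing
  expect_equal(assign_te_categories(te_df(5000, 5100), g, 20,
                                    chrom_lens)$category, "intergenic")
  # TE on a chromosome absent from the gene set -> intergenic with warning
  expect_warning(
    res <- assign_te_categories(te_df(100, 200, chrom = "chr9"), g, 20,
                                chrom_lens = c(chrom_lens, chr9 = 1000L)),
    "chr9")
  expect_equal(res$category, "intergenic")
})

test_that("category priority is body > upstream > downstream", {
  # two genes arranged so one TE is >50% in g1's downstream flank AND >50%
  # in g2's upstream flank region: upstream wins
  genes <- rbind(gene_df(1000, 2000, "+", "g1"),
                 gene_df(4100, 5000, "+", "g2"))
  te <- te_df(2500, 3500)  # inside g1 downstream [2000,4000) & g2 upstream [2100,4100)
  got <- assign_te_categories(te, genes, 2000, c(chr1 = 10000L))$category
  expect_equal(got, "upstream")
})

test_that("dissection tiles regions exactly, merging and clipping TEs", {
  region <- list(chrom = "chr1", start = 0, end = 1000)
  d <- dissect_region(region, te_df(200, 300))
  expect_equal(d$te_segments, data.frame(start = 200L, end = 300L))
  expect_equal(d$nonte_segments,
               data.frame(start = c(0L, 300L), end = c(200L, 1000L)))
  # overlapping TEs merge
  d2 <- dissect_region(region, te_df(c(200, 350), c(400, 500)))
  expect_equal(d2$te_segments, data.frame(start = 200L, end = 500L))
  # TE extending beyond the region is clipped
  d3 <- dissect_region(region, te_df(900, 1200))
  expect_equal(d3$te_segments, data.frame(start = 900L, end = 1000L))
  expect_equal(d3$nonte_segments, data.frame(start = 0L, end = 900L))
  # no TEs: the whole region is one non-TE segment
  d4 <- dissect_region(region, te_df(integer(), integer()))
  expect_equal(d4$nonte_segments, data.frame(start = 0L, end = 1000L))
  expect_equal(nrow(d4$te_segments), 0)
})

test_that("dissection tiling invariant holds on random TE sets", {
  set.seed(42)
  for (i in 1:1000) {
    rs <- sample.int(500, 1) - 1L
    re <- rs + sample.int(800, 1)
    tes <- random_tes(sample.int(12, 1), chrom_len = 1500)
    d <- dissect_region(list(chrom = "chr1", start = rs, end = re), tes)
    te_len <- sum(d$te_segments$end - d$te_segments$start)
    nonte_len <- sum(d$nonte_segments$end - d$nonte_segments$start)
    expect_equal(te_len + nonte_len, re - rs)
    all_seg <- rbind(d$te_segments, d$nonte_segments)
    all_seg <- all_seg[order(all_seg$start), ]
    # disjoint, within region, and tiling without gaps
    expect_true(all(all_seg$start >= rs & all_seg$end <= re))
    if (nrow(all_seg) > 1)
      expect_equal(all_seg$start[-1], all_seg$end[-nrow(all_seg)])
  }
})

test_that("category assignment agrees with the per-base brute-force oracle", {
  set.seed(7)
  chrom_len <- 3000L
  for (i in 1:500) {
    genes <- random_genes(sample.int(6, 1), chrom_len)
    te_len <- sample.int(150, 1)
    te_start <- sample.int(chrom_len - te_len, 1)
    te <- te_df(te_start, te_start + te_len)
    flank <- sample(c(20L, 60L, 150L), 1)
    got <- assign_te_categories(te, genes, flank,
                                c(chr1 = chrom_len))$category
    want <- oracle_te_category(list(chrom = "chr1", start = te_start,
                                    end = te_start + te_len),
                               genes, flank, chrom_len)
    expect_equal(got, want)
  }
})

test_that("category assignment is invariant under splitting a gene body", {
  genes1 <- gene_df(1000, 3000)
  genes2 <- rbind(gene_df(1000, 1700, id = "g1a"),
                  gene_df(1700, 3000, id = "g1b"))
  # TE straddling the split point: each half < 50%, union > 50%
  te <- te_df(1500, 1900)
  cl <- c(chr1 = 10000L)
  expect_equal(assign_te_categories(te, genes1, 200, cl)$category, "genic")
  expect_equal(assign_te_categories(te, genes2, 200, cl)$category, "genic")
})

test_that("per-gene dissections share a TE that spans two genes' regions", {
  genes <- rbind(gene_df(1000, 2000, "+", "g1"),
                 gene_df(2500, 3500, "+", "g2"))
  te <- te_df(1900, 2600)  # ends in g1 body, starts in g2 body
  dis <- dissect_genes(genes, te, flank_bp = 100, c(chr1 = 10000L))
  seg <- dis$segments
  te_rows <- seg[seg$segment_class == "te" & seg$region_kind == "body", ]
  expect_setequal(te_rows$gene_id, c("g1", "g2"))
  expect_equal(te_rows$end[te_rows$gene_id == "g1"], 2000L)
  expect_equal(te_rows$start[te_rows$gene_id == "g2"], 2500L)
})

test_that("carrier lookup is scoped to the requested region kind", {
  genes <- gene_df(2000, 3000)
  te_up <- te_df(500, 900, "LINE")  # in the upstream flank only
  dis <- dissect_genes(genes, te_up, flank_bp = 2000, c(chr1 = 10000L))
  expect_equal(genes_carrying_superfamily(dis, "LINE", "upstream"), "g1")
  expect_equal(genes_carrying_superfamily(dis, "LINE", "body"), character())
  expect_equal(genes_carrying_superfamily(dis, "CACTA", "upstream"),
               character())
  expect_error(genes_carrying_superfamily(dis, "NotAFamily"), "unknown")
})
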