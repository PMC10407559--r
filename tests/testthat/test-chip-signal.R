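frag_df <- function(start, end, chrom = "chr1", mapq = 60L) {
  n <- length(start)
  data.frame(chrom = rep(chrom, length.out = n), start = start, end = end,
             mapq = rep(mapq, length.out = n), stringsAsFactors = FALSE)
}

iv <- function(start, end, chrom = "chr1") {
  n <- length(start)
  data.frame(chrom = rep(chrom, length.out = n), start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("fragment midpoints floor the centre of the template", {
  expect_equal(fragment_midpoint(100, 250), 175L)
  expect_equal(fragment_midpoint(100, 251), 175L)  # odd length floors
  expect_equal(fragment_midpoint(0, 2), 1L)
  expect_error(fragment_midpoint(100, 100), "empty")
})

test_that("the midpoint index sorts positions and tracks library size", {
  fr <- frag_df(c(500, 100, 300), c(650, 250, 450),
                chrom = c("chr1", "chr1", "chr2"))
  idx <- build_midpoint_index(fr)
  expect_equal(idx$library_size, 3)
  expect_equal(idx$positions$chr1, c(175, 575))
  expect_equal(idx$positions$chr2, 375)
  # empty input: valid index with library_size 0; density then errors
  idx0 <- build_midpoint_index(fr[0, ])
  expect_equal(idx0$library_size, 0L)
  expect_error(interval_signal(idx0, idx, iv(0, 100)), "library")
})

test_that("counting uses half-open boundaries over disjoint intervals", {
  idx <- build_midpoint_index(frag_df(c(100, 150), c(250, 250)))  # 175, 200
  expect_equal(count_midpoints(idx, iv(175, 200)), 1L)  # 175 in, 200 out
  expect_equal(count_midpoints(idx, iv(176, 201)), 1L)  # 200 in, 175 out
  expect_equal(count_midpoints(idx, iv(integer(), integer())), 0L)
  expect_error(count_midpoints(idx, iv(c(0, 100), c(150, 300))), "overlap")
  # bookended intervals are fine and partition their union
  expect_equal(count_midpoints(idx, iv(c(0, 180), c(180, 300))), 2L)
})

test_that("counting matches a naive scan on random configurations", {
  set.seed(11)
  for (i in 1:200) {
    mids <- sort(sample.int(1000, sample.int(60, 1), replace = TRUE)) - 1L
    idx <- list(positions = list(chr1 = mids), library_size = length(mids))
    class(idx) <- "midpoint_index"
    # random disjoint intervals from sorted breakpoints
    bp <- sort(sample.int(1001, 2 * sample.int(5, 1), replace = FALSE)) - 1L
    ivs <- iv(bp[c(TRUE, FALSE)], bp[c(FALSE, TRUE)])
    expect_equal(count_midpoints(idx, ivs), oracle_count(mids, ivs))
  }
})

test_that("counts are conserved over a chromosome partition", {
  set.seed(3)
  fr <- frag_df(sample.int(9000, 500, replace = TRUE),
                integer(500))
  fr$end <- fr$start + 150L
  idx <- build_midpoint_index(fr)
  cuts <- c(0L, sort(sample.int(9999, 7)), 10000L)
  parts <- iv(cuts[-length(cuts)], cuts[-1])
  expect_equal(count_midpoints(idx, parts), length(idx$positions$chr1))
})

test_that("density is normalized per bp and per million fragments", {
  # 10 midpoints in 1000 bp with a library of 1e6 -> density 0.01
  pos <- seq(50, 950, by = 100)
  fr <- frag_df(pos - 25, pos + 25)
  idx <- build_midpoint_index(fr)
  idx$library_size <- 1e6
  sig0 <- interval_signal(idx, idx, iv(0, 1000))
  expect_equal(sig0$count, 10L)
  expect_equal(sig0$density, 0.01)
})

test_that("identical ChIP and IgG tracks give igg_ratio exactly 1", {
  set.seed(5)
  fr <- frag_df(sample.int(5000, 300, replace = TRUE), integer(300))
  fr$end <- fr$start + 150L
  idx <- build_midpoint_index(fr)
  for (ivs in list(iv(0, 1000), iv(c(10, 2000), c(1500, 3000)))) {
    expect_identical(interval_signal(idx, idx, ivs)$igg_ratio, 1)
  }
})

test_that("igg_ratio is the pseudocounted ratio of densities", {
  chip <- build_midpoint_index(frag_df(c(100, 200), c(300, 400)))
  igg <- build_midpoint_index(frag_df(100, 300))
  s <- interval_signal(chip, igg, iv(0, 1000), pseudocount = 0)
  # densities: 2/1000/(2/1e6) = 1000 ; 1/1000/(1/1e6) = 1000 -> ratio 1
  expect_equal(s$igg_ratio, 1)
  s2 <- interval_signal(chip, igg, iv(150, 250), pseudocount = 0)
  # chip: 1 midpoint (200) of 2, igg: 1 of 1 -> densities 5000 vs 10000
  expect_equal(s2$igg_ratio, 0.5)
  expect_error(interval_signal(chip, igg, iv(integer(), integer())),
               "length")
})

test_that("density is invariant under duplicating every fragment", {
  set.seed(9)
  fr <- frag_df(sample.int(5000, 200, replace = TRUE), integer(200))
  fr$end <- fr$start + 150L
  idx1 <- build_midpoint_index(fr)
  idx2 <- build_midpoint_index(rbind(fr, fr))
  ivs <- iv(c(0, 2500), c(2000, 4000))
  s1 <- interval_signal(idx1, idx1, ivs)
  s2 <- interval_signal(idx2, idx2, ivs)
  expect_equal(s2$count, 2L * s1$count)
  expect_equal(s2$density, s1$density)
})

test_that("50% thinning moves density by less than 3 binomial SEs", {
  set.seed(13)
  fr <- frag_df(sample.int(50000, 20000, replace = TRUE), integer(20000))
  fr$end <- fr$start + 150L
  idx_full <- build_midpoint_index(fr)
  keep <- runif(nrow(fr)) < 0.5
  idx_thin <- build_midpoint_index(fr[keep, ])
  ivs <- iv(10000, 20000)
  d_full <- interval_signal(idx_full, idx_full, ivs)$density
  d_thin <- interval_signal(idx_thin, idx_thin, ivs)$density
  k <- count_midpoints(idx_full, ivs)
  se <- d_full / sqrt(k)  # relative binomial SE at p = 0.5
  expect_lt(abs(d_thin - d_full), 3 * se)
})

test_that("signal tables aggregate per gene, region kind and segment class", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(1000L, 6000L), end = c(2000L, 7000L),
                      strand = "+", stringsAsFactors = FALSE)
  tes <- data.frame(te_id = "te1", chrom = "chr1", start = 1200L,
                    end = 1500L, te_class = "I", superfamily = "LINE",
                    category = "unassigned", stringsAsFactors = FALSE)
  dis <- dissect_genes(genes, tes, flank_bp = 500, c(chr1 = 10000L))
  pos <- c(1100, 1300, 1400, 1700, 6500)
  fr <- frag_df(pos - 75, pos + 75)
  idx <- build_midpoint_index(fr)
  tab <- signal_table(dis, idx, idx)
  # TE-free g2 body has only a nonte row
  g2 <- tab[tab$gene_id == "g2" & tab$region_kind == "body", ]
  expect_equal(g2$segment_class, "nonte")
  # g1 body: te row counts midpoints 1300,1400 on 300 bp; nonte 1100,1700
  g1te <- tab[tab$gene_id == "g1" & tab$region_kind == "body" &
                tab$segment_class == "te", ]
  expect_equal(g1te$count_chip, 2L)
  expect_equal(g1te$length_bp, 300L)
  g1non <- tab[tab$gene_id == "g1" & tab$region_kind == "body" &
                 tab$segment_class == "nonte", ]
  expect_equal(g1non$count_chip, 2L)
  expect_equal(g1non$length_bp, 700L)
  # identical chip/igg tracks: every row has ratio 1
  expect_true(all(tab$igg_ratio == 1))
})

test_that("planted depletion shows up as nonte > te mean body signal", {
  cfg <- small_synth_config(seed = 2)
  sim <- simulate_dataset(cfg)
  idx_chip <- build_midpoint_index(sim$fragments$diploid_chip)
  idx_igg <- build_midpoint_index(sim$fragments$diploid_igg)
  tab <- signal_table(sim$dissection, idx_chip, idx_igg)
  body <- tab[tab$region_kind == "body", ]
  m_te <- mean(body$igg_ratio[body$segment_class == "te"])
  m_non <- mean(body$igg_ratio[body$segment_class == "nonte"])
  # planted intensities: delta * lambda on TE bodies vs >= phi * lambda
  # on non-TE segments of carrier genes; expect a clear separation
  expect_gt(m_non, m_te)
  expect_gt(m_non / m_te, 1.5)
})
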