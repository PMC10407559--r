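# Synthetic study generator: toy genome, gene/TE annotations, ChIP and IgG
# fragments with planted piecewise-constant intensity, and NB expression
# counts negatively coupled to the planted genic H3K27me3 level.

#' Configuration for the synthetic study
#'
#' Defaults define the study conditions the analysis is calibrated against:
#' 500 non-overlapping genes on five 1 Mb chromosomes, 75 TEs per superfamily
#' placed 30/15/15/15 into gene bodies / upstream flanks / downstream flanks /
#' intergenic space (at most one TE per gene region, so superfamily strata do
#' not mix), base ChIP intensity `lambda = 0.02` midpoints/bp, TE-body
#' depletion `delta = 0.3`, flank enrichment `phi = 1.4` on non-TE segments
#' of TE-carrying regions, tetraploid boost `beta = 1.5` applied on top of
#' `phi` only for the [boosted_superfamilies()], a flat IgG track, and
#' negative-binomial counts whose mean is coupled to the genic IgG ratio with
#' slope -0.8 (log2 units per unit of IgG ratio).
#'
#' @param seed Integer seed; every downstream simulation derives its RNG
#'   state from it.
#' @param n_chrom,chrom_len Number and length (bp) of chromosomes.
#' @param n_genes Total genes, placed uniformly without overlap and with
#'   both flanks inside chromosome bounds.
#' @param gene_len_bp Gene length range `c(min, max)` (or a single fixed
#'   length).
#' @param flank_bp Flank width (default 2000).
#' @param te_per_superfamily TEs per superfamily (single count applied to
#'   all 12, or a full named vector).
#' @param te_len_bp TE length range `c(min, max)`.
#' @param te_category_fractions Named fractions (genic, upstream,
#'   downstream, intergenic) of each superfamily's TEs.
#' @param base_intensity Expected ChIP midpoints per bp (`lambda`).
#' @param te_depletion Multiplier `delta` in (0, 1] on TE bodies.
#' @param flank_enrichment Multiplier `phi >= 1` on non-TE segments of
#'   TE-carrying gene regions.
#' @param tetraploid_boost Multiplier `beta >= 1` applied on top of `phi`
#'   in the tetraploid condition, only for regions carrying a boosted
#'   superfamily.
#' @param boosted_superfamilies Superfamilies receiving the boost.
#' @param igg_intensity Flat IgG midpoint intensity per bp.
#' @param expr_base_mean,expr_dispersion Negative-binomial mean and
#'   dispersion of the expression counts.
#' @param coupling_slope log2 expression change per unit of genic IgG-ratio
#'   difference from the cohort mean (negative couples high H3K27me3 to low
#'   expression).
#' @param n_replicates Expression replicates per condition.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_chrom = 5, chrom_len = 1e6,
                         n_genes = 500, gene_len_bp = c(1500, 2500),
                         flank_bp = 2000,
                         te_per_superfamily = 75,
                         te_len_bp = c(200, 1000),
                         te_category_fractions = c(genic = 0.4,
                                                   upstream = 0.2,
                                                   downstream = 0.2,
                                                   intergenic = 0.2),
                         base_intensity = 0.02,
                         te_depletion = 0.3,
                         flank_enrichment = 1.4,
                         tetraploid_boost = 1.5,
                         boosted_superfamilies = c("LINE", "CACTA",
                                                   "PIF/Harbinger",
                                                   "Tc1/Mariner",
                                                   "DNA/Unclassed"),
                         igg_intensity = 0.02,
                         expr_base_mean = 200,
                         expr_dispersion = 0.05,
                         coupling_slope = -0.8,
                         n_replicates = 2) {
  if (length(te_per_superfamily) == 1)
    te_per_superfamily <- setNames(rep(te_per_superfamily, 12),
                                   te_superfamilies())
  if (!setequal(names(te_per_superfamily), te_superfamilies()))
    .err("te_per_superfamily must name the 12 canonical superfamilies",
         "ploidyTE_config_error")
  if (length(gene_len_bp) == 1) gene_len_bp <- rep(gene_len_bp, 2)
  if (length(te_len_bp) == 1) te_len_bp <- rep(te_len_bp, 2)
  stopifnot(gene_len_bp[1] <= gene_len_bp[2], te_len_bp[1] <= te_len_bp[2])
  if (!(te_depletion > 0 && te_depletion <= 1))
    .err("te_depletion must lie in (0, 1]", "ploidyTE_config_error")
  if (flank_enrichment < 1 || tetraploid_boost < 1)
    .err("flank_enrichment and tetraploid_boost must be >= 1",
         "ploidyTE_config_error")
  if (base_intensity <= 0 || igg_intensity <= 0)
    .err("intensities must be > 0", "ploidyTE_config_error")
  .check_superfamily(boosted_superfamilies)
  frac <- te_category_fractions
  if (!setequal(names(frac),
                c("genic", "upstream", "downstream", "intergenic")) ||
      any(frac < 0) || abs(sum(frac) - 1) > 1e-8)
    .err("te_category_fractions must be non-negative, named genic/upstream/downstream/intergenic and sum to 1",
         "ploidyTE_config_error")
  if (te_len_bp[2] > gene_len_bp[1] || te_len_bp[2] > flank_bp)
    .err("TE length range must fit inside the smallest gene body and flank",
         "ploidyTE_config_error")
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              chrom_len = as.integer(chrom_len), n_genes = n_genes,
              gene_len_bp = as.integer(gene_len_bp),
              flank_bp = as.integer(flank_bp),
              te_per_superfamily = te_per_superfamily[te_superfamilies()],
              te_len_bp = as.integer(te_len_bp),
              te_category_fractions = frac[c("genic", "upstream",
                                             "downstream", "intergenic")],
              base_intensity = base_intensity, te_depletion = te_depletion,
              flank_enrichment = flank_enrichment,
              tetraploid_boost = tetraploid_boost,
              boosted_superfamilies = boosted_superfamilies,
              igg_intensity = igg_intensity,
              expr_base_mean = expr_base_mean,
              expr_dispersion = expr_dispersion,
              coupling_slope = coupling_slope,
              n_replicates = as.integer(n_replicates))
  # placement feasibility: footprints (gene + both flanks) must fit loosely
  if (n_genes * (gene_len_bp[2] + 2 * flank_bp) > 0.7 * n_chrom * chrom_len)
    .err("infeasible packing: genes + flanks exceed 70% of the genome",
         "ploidyTE_config_error")
  structure(cfg, class = "synth_config")
}

# deterministic sub-seeds: one RNG stream per simulation stage
.stage_seed <- function(config, offset) {
  as.integer((as.numeric(config$seed) * 7 + offset) %% 2147483647)
}

#' Simulate gene and TE annotations
#'
#' Genes are placed uniformly and non-overlapping, with both 2 kb flanks
#' inside chromosome bounds and disjoint from all other genes' footprints
#' (body plus flanks), so every (gene, region kind) region is a disjoint
#' interval. Each superfamily's TEs are split across target categories per
#' `te_category_fractions` and placed fully inside their target feature —
#' at most one TE per (gene, region kind) — or inside intergenic gaps, so
#' the majority-overlap rule recovers the intended category for every TE.
#' Deterministic given `config$seed`.
#'
#' @param config A `synth_config`.
#' @return List with `genes`, `tes` (with `target_category` truth column;
#'   `category` left `"unassigned"`), and `chrom_lens`.
#' @export
simulate_annotations <- function(config) {
  set.seed(.stage_seed(config, 0))
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  chrom_lens <- setNames(rep(config$chrom_len, config$n_chrom), chroms)
  flank <- config$flank_bp

  # allocate genes to chromosomes (near-even split)
  n_per <- diff(floor(seq(0, config$n_genes, length.out =
                            config$n_chrom + 1)))
  gene_rows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    n <- n_per[ci]
    if (n == 0) next
    glen <- config$gene_len_bp[1] +
      floor(runif(n) * (config$gene_len_bp[2] - config$gene_len_bp[1] + 1))
    fp <- glen + 2L * flank  # footprint lengths
    slack <- config$chrom_len - sum(fp)
    if (slack < 0)
      .err("infeasible packing on a chromosome", "ploidyTE_config_error")
    gaps <- floor(sort(runif(n)) * slack)
    fp_start <- gaps + cumsum(c(0L, fp[-n]))
    start <- as.integer(fp_start + flank)
    gene_rows[[ci]] <- data.frame(
      gene_id = sprintf("g%04d", gid + seq_len(n)),
      chrom = chroms[ci], start = start, end = as.integer(start + glen),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    gid <- gid + n
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL

  # per-superfamily category counts (remainder goes to intergenic)
  sfs <- te_superfamilies()
  frac <- config$te_category_fractions
  counts <- lapply(config$te_per_superfamily, function(n) {
    k <- floor(n * frac[c("genic", "upstream", "downstream")])
    c(k, intergenic = n - sum(k))
  })
  tot_cat <- Reduce(`+`, counts)
  if (any(tot_cat[c("genic", "upstream", "downstream")] > nrow(genes)))
    .err("more genic/flank TEs requested than genes available",
         "ploidyTE_config_error")

  up <- flank_regions(genes, flank, "upstream", chrom_lens)
  dn <- flank_regions(genes, flank, "downstream", chrom_lens)
  feature_of <- list(
    genic = genes[, c("gene_id", "chrom", "start", "end")],
    upstream = up, downstream = dn)

  te_rows <- list()
  # distinct host regions per category across superfamilies
  hosts <- lapply(c(genic = "genic", upstream = "upstream",
                    downstream = "downstream"), function(cat) {
    sample(seq_len(nrow(feature_of[[cat]])), tot_cat[[cat]])
  })
  ptr <- c(genic = 0L, upstream = 0L, downstream = 0L)
  # intergenic gaps = complement of gene footprints
  gaps <- do.call(rbind, lapply(chroms, function(ch) {
    g <- genes[genes$chrom == ch, ]
    cmp <- .complement_spans(g$start - flank, g$end + flank,
                             0L, chrom_lens[[ch]])
    if (nrow(cmp)) cbind(chrom = ch, cmp) else NULL
  }))
  for (sf in sfs) {
    for (cat in c("genic", "upstream", "downstream", "intergenic")) {
      n <- counts[[sf]][[cat]]
      if (n == 0) next
      tlen <- config$te_len_bp[1] +
        floor(runif(n) * (config$te_len_bp[2] - config$te_len_bp[1] + 1))
      if (cat == "intergenic") {
        fit <- gaps[gaps$end - gaps$start >= config$te_len_bp[2], ]
        pick <- sample(seq_len(nrow(fit)), n, replace = TRUE,
                       prob = fit$end - fit$start - config$te_len_bp[2] + 1)
        off <- pmin(floor(runif(n) * (fit$end[pick] - fit$start[pick] -
                                        tlen + 1)),
                    fit$end[pick] - fit$start[pick] - tlen)
        ch <- fit$chrom[pick]; ts <- fit$start[pick] + off
      } else {
        sel <- hosts[[cat]][ptr[[cat]] + seq_len(n)]
        ptr[[cat]] <- ptr[[cat]] + n
        f <- feature_of[[cat]][sel, ]
        off <- pmin(floor(runif(n) * (f$end - f$start - tlen + 1)),
                    f$end - f$start - tlen)
        ch <- f$chrom; ts <- f$start + off
      }
      te_rows[[length(te_rows) + 1L]] <- data.frame(
        chrom = ch, start = as.integer(ts), end = as.integer(ts + tlen),
        superfamily = sf, target_category = cat, stringsAsFactors = FALSE)
    }
  }
  tes <- do.call(rbind, te_rows)
  if (is.null(tes))
    tes <- data.frame(chrom = character(), start = integer(),
                      end = integer(), superfamily = character(),
                      target_category = character(),
                      stringsAsFactors = FALSE)
  tes <- tes[order(tes$chrom, tes$start, tes$end), ]
  tes <- data.frame(te_id = sprintf("te%05d", seq_len(nrow(tes))),
                    chrom = tes$chrom, start = tes$start, end = tes$end,
                    te_class = te_class_of(tes$superfamily),
                    superfamily = tes$superfamily,
                    category = rep("unassigned", nrow(tes)),
                    target_category = tes$target_category,
                    stringsAsFactors = FALSE)
  rownames(tes) <- NULL
  list(genes = genes, tes = tes, chrom_lens = chrom_lens)
}

# Piecewise-constant ChIP intensity map (per-bp expected midpoints):
# TE bodies: lambda * delta; non-TE segments of TE-carrying gene regions:
# lambda * phi (* beta for boosted regions in the tetraploid); everything
# else: lambda. Returns data.frame(chrom, start, end, intensity).
.intensity_map <- function(config, annotations, condition,
                           dissection = NULL) {
  lam <- config$base_intensity
  if (is.null(dissection))
    dissection <- dissect_genes(annotations$genes, annotations$tes,
                                config$flank_bp, annotations$chrom_lens)
  seg <- dissection$segments
  reg <- dissection$regions
  key <- paste(reg$gene_id, reg$region_kind)
  seg_key <- paste(seg$gene_id, seg$region_kind)
  carrier <- reg$n_te > 0
  boosted <- carrier & vapply(strsplit(reg$superfamilies, ",", fixed = TRUE),
                              function(s) any(s %in%
                                                config$boosted_superfamilies),
                              logical(1))
  mult <- ifelse(seg$segment_class == "te", config$te_depletion,
                 ifelse(carrier[match(seg_key, key)],
                        config$flank_enrichment, 1))
  if (condition == "tetraploid") {
    idx <- seg$segment_class == "nonte" & boosted[match(seg_key, key)]
    mult[idx] <- mult[idx] * config$tetraploid_boost
  }
  pieces <- data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                       intensity = lam * mult, stringsAsFactors = FALSE)
  # intergenic TEs (outside every gene region) at lambda * delta
  reg_by_chrom <- split(reg, reg$chrom)
  bg <- list()
  for (ch in names(annotations$chrom_lens)) {
    r <- reg_by_chrom[[ch]]
    outside <- .complement_spans(
      if (is.null(r)) integer() else r$start,
      if (is.null(r)) integer() else r$end,
      0L, annotations$chrom_lens[[ch]])
    t <- annotations$tes[annotations$tes$chrom == ch, ]
    # clip TEs to the outside-gaps, then mark as depleted
    te_out <- if (nrow(t)) {
      .ir_df(IRanges::intersect(.ir(t$start, t$end),
                                .ir(outside$start, outside$end)))
    } else data.frame(start = integer(), end = integer())
    if (nrow(te_out))
      pieces <- rbind(pieces, data.frame(chrom = ch, start = te_out$start,
                                         end = te_out$end,
                                         intensity = lam *
                                           config$te_depletion))
    rest <- .complement_spans(te_out$start, te_out$end, 0L,
                              annotations$chrom_lens[[ch]])
    # background = rest minus the gene regions
    if (!is.null(r) && nrow(r)) {
      rest <- .ir_df(IRanges::setdiff(.ir(rest$start, rest$end),
                                      .ir(r$start, r$end)))
    }
    if (nrow(rest))
      bg[[ch]] <- data.frame(chrom = ch, start = rest$start, end = rest$end,
                             intensity = lam)
  }
  out <- rbind(pieces, do.call(rbind, bg))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Simulate ChIP or IgG fragments for one condition
#'
#' Midpoint counts per intensity segment are Poisson with mean
#' `intensity * length`; positions are uniform within the segment. Fragments
#' are reconstructed as fixed-length 150 bp spans centred on the midpoints
#' (MNase mononucleosome scale), MAPQ 60. The IgG track is flat at
#' `igg_intensity`. Deterministic given `config$seed`, `condition` and
#' `track`.
#'
#' @param config A `synth_config`.
#' @param annotations Result of [simulate_annotations()].
#' @param condition `"diploid"` or `"tetraploid"`.
#' @param track `"chip"` or `"igg"`.
#' @param dissection Optional precomputed `region_dissection` (avoids
#'   recomputing it for each of the four tracks).
#' @return Fragment data.frame (`chrom`, `start`, `end`, `mapq`).
#' @export
simulate_midpoints <- function(config, annotations,
                               condition = c("diploid", "tetraploid"),
                               track = c("chip", "igg"),
                               dissection = NULL) {
  condition <- match.arg(condition)
  track <- match.arg(track)
  offset <- match(paste(condition, track),
                  c("diploid chip", "diploid igg",
                    "tetraploid chip", "tetraploid igg"))
  set.seed(.stage_seed(config, offset))
  if (track == "igg") {
    map <- data.frame(chrom = names(annotations$chrom_lens), start = 0L,
                      end = unname(annotations$chrom_lens),
                      intensity = config$igg_intensity,
                      stringsAsFactors = FALSE)
  } else {
    map <- .intensity_map(config, annotations, condition, dissection)
  }
  len <- map$end - map$start
  n <- rpois(nrow(map), map$intensity * len)
  tot <- sum(n)
  seg <- rep.int(seq_len(nrow(map)), n)
  pos <- map$start[seg] + floor(runif(tot) * len[seg])
  # keep the 150 bp span inside the chromosome without moving the midpoint
  lim <- unname(annotations$chrom_lens[map$chrom[seg]])
  pos <- pmin(pmax(pos, 75), lim - 75)
  out <- data.frame(chrom = map$chrom[seg],
                    start = as.integer(pos - 75L),
                    end = as.integer(pos + 75L),
                    mapq = 60L, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Simulate an expression count matrix coupled to genic H3K27me3
#'
#' Per gene and condition the negative-binomial mean is
#' `mu = expr_base_mean * 2^(coupling_slope * (igg_ratio - cohort_mean))`,
#' where `cohort_mean` is the grand mean of the genic IgG ratios over both
#' conditions, so a between-condition chromatin difference translates into
#' `coupling_slope * delta_igg_ratio` log2 units of expression change.
#' Counts are `rnbinom(mu, size = 1/expr_dispersion)`, `n_replicates`
#' columns per condition. Genes whose planted |log2 fold change| exceeds
#' `lfc_min` are recorded as true DE.
#'
#' @param config A `synth_config`.
#' @param igg_ratios Data.frame with columns `gene_id`, `diploid`,
#'   `tetraploid`: the genic (gene-body) IgG ratios per condition.
#' @param lfc_min Threshold defining the recorded true labels (default 1).
#' @return List with `counts` (genes x replicate-columns matrix), `coldata`
#'   (condition/replicate per column), `truth` (per gene: `true_log2fc`,
#'   `true_label`).
#' @export
simulate_counts <- function(config, igg_ratios, lfc_min = 1) {
  set.seed(.stage_seed(config, 5))
  stopifnot(all(c("gene_id", "diploid", "tetraploid") %in%
                  names(igg_ratios)))
  centre <- mean(c(igg_ratios$diploid, igg_ratios$tetraploid))
  mu <- cbind(
    diploid = config$expr_base_mean *
      2^(config$coupling_slope * (igg_ratios$diploid - centre)),
    tetraploid = config$expr_base_mean *
      2^(config$coupling_slope * (igg_ratios$tetraploid - centre)))
  nrep <- config$n_replicates
  coldata <- data.frame(
    condition = rep(c("diploid", "tetraploid"), each = nrep),
    replicate = rep(seq_len(nrep), 2), stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow = nrow(igg_ratios), ncol = nrow(coldata),
                   dimnames = list(igg_ratios$gene_id,
                                   paste0(coldata$condition, "_rep",
                                          coldata$replicate)))
  for (j in seq_len(nrow(coldata))) {
    counts[, j] <- rnbinom(nrow(mu), mu = mu[, coldata$condition[j]],
                           size = 1 / config$expr_dispersion)
  }
  true_lfc <- log2(mu[, "tetraploid"] / mu[, "diploid"])
  truth <- data.frame(gene_id = igg_ratios$gene_id,
                      true_log2fc = true_lfc,
                      true_label = ifelse(abs(true_lfc) <= lfc_min, "ns",
                                          ifelse(true_lfc > 0, "up", "down")),
                      stringsAsFactors = FALSE)
  list(counts = counts, coldata = coldata, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_annotations()] and [simulate_midpoints()] for the four
#' (condition, track) combinations; the expression counts are generated by
#' the pipeline once genic IgG ratios are available (see
#' [run_simulated_pipeline()]).
#'
#' @param config A `synth_config`.
#' @return List with `annotations`, `dissection`, and `fragments` (named
#'   list `diploid_chip`, `diploid_igg`, `tetraploid_chip`,
#'   `tetraploid_igg`).
#' @export
simulate_dataset <- function(config) {
  ann <- simulate_annotations(config)
  dis <- dissect_genes(ann$genes, ann$tes, config$flank_bp, ann$chrom_lens)
  combos <- expand.grid(condition = c("diploid", "tetraploid"),
                        track = c("chip", "igg"), stringsAsFactors = FALSE)
  frags <- Map(function(cond, trk)
    simulate_midpoints(config, ann, cond, trk, dissection = dis),
    combos$condition, combos$track)
  names(frags) <- paste(combos$condition, combos$track, sep = "_")
  list(annotations = ann, dissection = dis, fragments = frags)
}
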