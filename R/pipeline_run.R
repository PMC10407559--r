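# End-to-end orchestration: from files (run_ploidy_pipeline) or from the
# synthetic generator (run_simulated_pipeline).

# genic (whole gene body) igg_ratio per gene for one condition
.body_igg_ratios <- function(genes, chip_index, igg_index,
                             pseudocount = 1e-3) {
  body <- genes[, c("chrom", "start", "end")]
  n_chip <- .counts_per_interval(chip_index, body)
  n_igg <- .counts_per_interval(igg_index, body)
  len <- body$end - body$start
  d_chip <- n_chip / len / (chip_index$library_size / 1e6)
  d_igg <- n_igg / len / (igg_index$library_size / 1e6)
  setNames((d_chip + pseudocount) / (d_igg + pseudocount), genes$gene_id)
}

#' Run the full analysis on a synthetic study
#'
#' Generates annotations and fragments from `config`, dissects gene regions,
#' quantifies both conditions, runs the stratified ploidy comparisons and the
#' within-condition TE-vs-non-TE contrasts, simulates expression counts
#' coupled to the realized genic IgG ratios, and links chromatin to
#' expression. Fully deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param pseudocount IgG-ratio pseudocount (default 1e-3).
#' @return List with `annotations`, `dissection`, `indices`, `signal`
#'   (per condition), `comparisons`, `contrasts` (per condition),
#'   `counts`, `tpm` (per-condition replicate-averaged named vectors),
#'   `links`, `config`.
#' @export
run_simulated_pipeline <- function(config, pseudocount = 1e-3) {
  sim <- simulate_dataset(config)
  idx <- lapply(sim$fragments, build_midpoint_index)
  sig <- list(
    diploid = signal_table(sim$dissection, idx$diploid_chip,
                           idx$diploid_igg, pseudocount),
    tetraploid = signal_table(sim$dissection, idx$tetraploid_chip,
                              idx$tetraploid_igg, pseudocount))
  comparisons <- run_comparisons(sim$dissection, sig$diploid,
                                 sig$tetraploid)
  contrasts <- list(
    diploid = te_vs_nonte_contrast(sig$diploid, sim$dissection, "diploid"),
    tetraploid = te_vs_nonte_contrast(sig$tetraploid, sim$dissection,
                                      "tetraploid"))
  genes <- sim$annotations$genes
  igg_ratios <- data.frame(
    gene_id = genes$gene_id,
    diploid = unname(.body_igg_ratios(genes, idx$diploid_chip,
                                      idx$diploid_igg, pseudocount)),
    tetraploid = unname(.body_igg_ratios(genes, idx$tetraploid_chip,
                                         idx$tetraploid_igg, pseudocount)),
    stringsAsFactors = FALSE)
  expr <- simulate_counts(config, igg_ratios)
  lengths_bp <- setNames(genes$end - genes$start, genes$gene_id)
  tpm_mat <- apply(expr$counts, 2, tpm, lengths_bp = lengths_bp)
  tpm_by_cond <- lapply(c(diploid = "diploid", tetraploid = "tetraploid"),
                        function(cond) {
    cols <- expr$coldata$condition == cond
    setNames(rowMeans(tpm_mat[, cols, drop = FALSE]), genes$gene_id)
  })
  links <- link_expression(comparisons, tpm_by_cond$diploid,
                           tpm_by_cond$tetraploid, sim$dissection)
  list(annotations = sim$annotations, dissection = sim$dissection,
       indices = idx, signal = sig, comparisons = comparisons,
       contrasts = contrasts, counts = expr, tpm = tpm_by_cond,
       links = links, config = config)
}

#' Run the full analysis from annotation and alignment files
#'
#' File-based counterpart of [run_simulated_pipeline()], driven by a
#' validated [run_config][validate_config()]: reads annotations and
#' fragments, dissects, quantifies, compares, optionally links expression
#' (when a `counts` table is configured), and writes the report to
#' `out_dir`.
#'
#' @param config A `run_config` from [read_run_config()] /
#'   [validate_config()].
#' @return Invisible list with `dissection`, `signal`, `comparisons`,
#'   `contrasts`, `links`, `files` (report paths).
#' @export
run_ploidy_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  genes <- read_gene_annotation(config$genes)
  tes <- read_te_annotation(config$tes, format = config$te_format)
  dis <- dissect_genes(genes, tes, config$flank_bp, config$chrom_lens)
  idx <- list(
    diploid_chip = build_midpoint_index(
      read_fragments(config$diploid$chip, config$mapq_min)),
    diploid_igg = build_midpoint_index(
      read_fragments(config$diploid$igg, config$mapq_min)),
    tetraploid_chip = build_midpoint_index(
      read_fragments(config$tetraploid$chip, config$mapq_min)),
    tetraploid_igg = build_midpoint_index(
      read_fragments(config$tetraploid$igg, config$mapq_min)))
  sig <- list(
    diploid = signal_table(dis, idx$diploid_chip, idx$diploid_igg,
                           config$pseudocount),
    tetraploid = signal_table(dis, idx$tetraploid_chip, idx$tetraploid_igg,
                              config$pseudocount))
  comparisons <- run_comparisons(dis, sig$diploid, sig$tetraploid,
                                 tissue = config$tissue,
                                 min_pairs = config$min_pairs,
                                 pairing = config$pairing)
  contrasts <- rbind(
    te_vs_nonte_contrast(sig$diploid, dis, "diploid", config$min_pairs),
    te_vs_nonte_contrast(sig$tetraploid, dis, "tetraploid",
                         config$min_pairs))
  links <- data.frame()
  if (!is.null(config$counts)) {
    tab <- read.delim(config$counts, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (!all(c("gene_id", "length_bp") %in% names(tab)))
      .err("counts table needs gene_id and length_bp columns",
           "ploidyTE_parse_error")
    tpm_of <- function(cond) {
      cols <- grep(paste0("^", cond, "_rep"), names(tab), value = TRUE)
      if (length(cols) == 0)
        .err(sprintf("counts table has no %s_rep* columns", cond),
             "ploidyTE_parse_error")
      m <- vapply(cols, function(cn) tpm(tab[[cn]], tab$length_bp),
                  numeric(nrow(tab)))
      setNames(rowMeans(m), tab$gene_id)
    }
    links <- link_expression(comparisons, tpm_of("diploid"),
                             tpm_of("tetraploid"), dis, config$min_pairs)
  }
  files <- write_report(comparisons,
                        if (nrow(links)) links else
                          data.frame(superfamily = character(),
                                     n_genes = integer(),
                                     h3k27me3_direction = character(),
                                     h3k27me3_q = numeric(),
                                     expression_direction = character(),
                                     expression_p = numeric(),
                                     concordant_negative = logical()),
                        config$out_dir, contrasts = contrasts)
  invisible(list(dissection = dis, signal = sig, comparisons = comparisons,
                 contrasts = contrasts, links = links, files = files))
}
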