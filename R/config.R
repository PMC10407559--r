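# Run-configuration validation (YAML front end for the pipeline).

.config_defaults <- list(flank_bp = 2000, mapq_min = 50, pseudocount = 1e-3,
                         fdr_max = 0.01, lfc_min = 1, pairing = "paired",
                         tissue = "root", te_format = "bed", seed = 1,
                         min_pairs = 5)

.config_known <- c(names(.config_defaults),
                   "genes", "tes", "chrom_lens", "diploid", "tetraploid",
                   "counts", "de_stats", "out_dir")

#' Validate a raw run configuration
#'
#' Injects defaults (flank 2000 bp, MAPQ 50, pseudocount 1e-3, FDR 0.01,
#' log2FC 1, paired testing), rejects unknown keys (typo guard), checks
#' threshold ranges and verifies that every referenced input path exists.
#'
#' @param raw A named list, typically parsed from YAML. Required keys:
#'   `genes`, `tes`, `diploid` and `tetraploid` (each a list with `chip` and
#'   `igg` paths), `out_dir`. Optional: `chrom_lens` (named list of
#'   chromosome lengths), `counts` (TSV with `gene_id`, `length_bp` and
#'   `<condition>_rep<k>` columns), `de_stats`, `te_format`, thresholds.
#' @return The validated configuration (class `run_config`).
#' @export
validate_config <- function(raw) {
  if (!is.list(raw)) .err("configuration must be a mapping",
                          "ploidyTE_config_error")
  unknown <- setdiff(names(raw), .config_known)
  if (length(unknown))
    .err(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), "ploidyTE_config_error")
  cfg <- utils::modifyList(.config_defaults, raw)
  for (key in c("genes", "tes", "out_dir"))
    if (is.null(cfg[[key]]))
      .err(sprintf("missing required configuration key: %s", key),
           "ploidyTE_config_error")
  for (cond in c("diploid", "tetraploid")) {
    if (is.null(cfg[[cond]]) || is.null(cfg[[cond]]$chip) ||
        is.null(cfg[[cond]]$igg))
      .err(sprintf("missing required configuration key: %s (needs chip and igg paths)",
                   cond), "ploidyTE_config_error")
  }
  if (cfg$mapq_min < 0) .err("mapq_min must be >= 0", "ploidyTE_config_error")
  if (cfg$pseudocount <= 0)
    .err("pseudocount must be > 0", "ploidyTE_config_error")
  if (cfg$fdr_max <= 0 || cfg$fdr_max >= 1)
    .err("fdr_max must lie in (0, 1)", "ploidyTE_config_error")
  if (cfg$lfc_min < 0) .err("lfc_min must be >= 0", "ploidyTE_config_error")
  if (cfg$flank_bp <= 0) .err("flank_bp must be > 0", "ploidyTE_config_error")
  if (!cfg$pairing %in% c("paired", "unpaired"))
    .err("pairing must be 'paired' or 'unpaired'", "ploidyTE_config_error")
  if (!cfg$te_format %in% c("bed", "gff3"))
    .err("te_format must be 'bed' or 'gff3'", "ploidyTE_config_error")
  paths <- c(cfg$genes, cfg$tes, cfg$diploid$chip, cfg$diploid$igg,
             cfg$tetraploid$chip, cfg$tetraploid$igg, cfg$counts,
             cfg$de_stats)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    .err(sprintf("input path(s) do not exist: %s",
                 paste(missing, collapse = ", ")), "ploidyTE_config_error")
  if (!is.null(cfg$chrom_lens))
    cfg$chrom_lens <- unlist(cfg$chrom_lens)
  structure(cfg, class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' @param path Path to a YAML file; see [validate_config()] for the schema.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    .err(sprintf("configuration file '%s' does not exist", path),
         "ploidyTE_config_error")
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) .err(sprintf(
                    "failed to parse YAML '%s': %s", path,
                    conditionMessage(e)), "ploidyTE_config_error"))
  validate_config(raw)
}
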