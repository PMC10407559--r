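# Stratified paired comparisons between ploidies and the expression linkage.

.kinds <- c("body", "upstream", "downstream")

# named igg_ratio vectors per (kind, class) from a signal table
.signal_lookup <- function(sig, kind, cls) {
  s <- sig[sig$region_kind == kind & sig$segment_class == cls, ]
  setNames(s$igg_ratio, s$gene_id)
}

#' Paired diploid-vs-tetraploid comparisons stratified by superfamily
#'
#' For every region kind (body / upstream / downstream) x segment class
#' (te / nonte) x stratum (each of the 12 superfamilies plus `"all"`), runs a
#' paired Wilcoxon signed-rank test on per-gene `igg_ratio` values matched by
#' gene ID between the two conditions. A superfamily stratum is restricted to
#' genes carrying that superfamily in the same region kind, so flank strata
#' stay region-local. BH adjustment is applied across all testable records of
#' the run. Strata with fewer than `min_pairs` matched genes are emitted with
#' `p_value = NA` and counted in a warning.
#'
#' @param dissection A `region_dissection` (defines carrier strata).
#' @param signal_diploid,signal_tetraploid Signal tables
#'   ([signal_table()]) for the two conditions, sharing a gene-ID space.
#' @param tissue Tissue label passed through to the records (default
#'   `"root"`).
#' @param min_pairs Minimum matched genes to test a stratum (default 5).
#' @param pairing `"paired"` (Wilcoxon signed-rank, the default) or
#'   `"unpaired"` (Mann-Whitney rank-sum fallback via
#'   [stats::wilcox.test()]).
#' @return Data.frame of class `comparison_table`: one row per stratum with
#'   `tissue`, `region_kind`, `segment_class`, `superfamily`, `n_pairs`,
#'   `median_diploid`, `median_tetraploid`, `W`, `p_value`, `q_value`,
#'   `direction` (`"tetraploid_greater"`, `"diploid_greater"`, `"none"`).
#' @export
run_comparisons <- function(dissection, signal_diploid, signal_tetraploid,
                            tissue = "root", min_pairs = 5,
                            pairing = c("paired", "unpaired")) {
  pairing <- match.arg(pairing)
  strata <- c("all", te_superfamilies())
  rows <- list()
  n_small <- 0L
  for (kind in .kinds) {
    carriers <- lapply(setNames(te_superfamilies(), te_superfamilies()),
                       genes_carrying_superfamily,
                       dissection = dissection, region_kind = kind)
    for (cls in c("te", "nonte")) {
      vd <- .signal_lookup(signal_diploid, kind, cls)
      vt <- .signal_lookup(signal_tetraploid, kind, cls)
      common <- intersect(names(vd), names(vt))
      for (sf in strata) {
        g <- if (sf == "all") common else intersect(common, carriers[[sf]])
        n <- length(g)
        if (n < min_pairs) {
          n_small <- n_small + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            tissue = tissue, region_kind = kind, segment_class = cls,
            superfamily = sf, n_pairs = n,
            median_diploid = if (n) median(vd[g]) else NA_real_,
            median_tetraploid = if (n) median(vt[g]) else NA_real_,
            W = NA_real_, p_value = NA_real_, direction = "none",
            stringsAsFactors = FALSE)
          next
        }
        if (pairing == "paired") {
          res <- wilcoxon_signed_rank(vt[g], vd[g])
          W <- res$W; p <- res$p_value; dir <- res$direction
        } else {
          wt <- suppressWarnings(stats::wilcox.test(vt[g], vd[g]))
          W <- unname(wt$statistic); p <- wt$p.value
          md <- median(vt[g]) - median(vd[g])
          dir <- if (md > 0) "a_greater" else if (md < 0) "b_greater" else "none"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          tissue = tissue, region_kind = kind, segment_class = cls,
          superfamily = sf, n_pairs = n,
          median_diploid = median(vd[g]),
          median_tetraploid = median(vt[g]),
          W = W, p_value = p,
          direction = switch(dir, a_greater = "tetraploid_greater",
                             b_greater = "diploid_greater", "none"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_small > 0)
    warning(sprintf("%d stratum/strata with fewer than %d matched genes emitted with p = NA",
                    n_small, min_pairs))
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_adjust(out$p_value[ok])
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Paired TE vs non-TE contrast within genes
#'
#' Within one condition's signal table, pairs each gene's TE-segment
#' `igg_ratio` with its non-TE-segment `igg_ratio` in the same region kind
#' (genes lacking either class in that region are excluded) and tests the
#' difference per region kind and superfamily stratum (plus `"all"`) with the
#' paired Wilcoxon signed-rank test. Direction `"nonte_greater"` indicates TE
#' bodies depleted of signal relative to their flanking chromatin. BH across
#' all testable records.
#'
#' @param signal One condition's [signal_table()].
#' @param dissection The matching `region_dissection`.
#' @param condition Condition label passed through (default `"diploid"`).
#' @param min_pairs Minimum pairs to test (default 5).
#' @return Data.frame: `condition`, `region_kind`, `superfamily`, `n_pairs`,
#'   `median_te`, `median_nonte`, `W`, `p_value`, `q_value`, `direction`
#'   (`"nonte_greater"`, `"te_greater"`, `"none"`).
#' @export
te_vs_nonte_contrast <- function(signal, dissection, condition = "diploid",
                                 min_pairs = 5) {
  rows <- list()
  n_small <- 0L
  for (kind in .kinds) {
    vte <- .signal_lookup(signal, kind, "te")
    vnon <- .signal_lookup(signal, kind, "nonte")
    common <- intersect(names(vte), names(vnon))
    carriers <- lapply(setNames(te_superfamilies(), te_superfamilies()),
                       genes_carrying_superfamily,
                       dissection = dissection, region_kind = kind)
    for (sf in c("all", te_superfamilies())) {
      g <- if (sf == "all") common else intersect(common, carriers[[sf]])
      n <- length(g)
      if (n < min_pairs) {
        n_small <- n_small + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          condition = condition, region_kind = kind, superfamily = sf,
          n_pairs = n, median_te = if (n) median(vte[g]) else NA_real_,
          median_nonte = if (n) median(vnon[g]) else NA_real_,
          W = NA_real_, p_value = NA_real_, direction = "none",
          stringsAsFactors = FALSE)
        next
      }
      res <- wilcoxon_signed_rank(vnon[g], vte[g])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condition, region_kind = kind, superfamily = sf,
        n_pairs = n, median_te = median(vte[g]),
        median_nonte = median(vnon[g]), W = res$W, p_value = res$p_value,
        direction = switch(res$direction, a_greater = "nonte_greater",
                           b_greater = "te_greater", "none"),
        stringsAsFactors = FALSE)
    }
  }
  if (n_small > 0)
    warning(sprintf("%d stratum/strata with fewer than %d paired genes emitted with p = NA",
                    n_small, min_pairs))
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_adjust(out$p_value[ok])
  out
}

#' Link chromatin differences to expression of TE-cognate genes
#'
#' For each superfamily, takes the genic non-TE chromatin comparison from
#' [run_comparisons()] and runs a paired Wilcoxon test on per-gene expression
#' (TPM, tetraploid vs diploid) restricted to the genes carrying that
#' superfamily in their body. `concordant_negative` is `TRUE` when the two
#' directions oppose each other (H3K27me3 higher and expression lower, or
#' vice versa) — the negative association expected of a repressive mark.
#' Superfamilies with an empty carrier set are skipped with a warning.
#'
#' @param comparisons A `comparison_table` from [run_comparisons()].
#' @param tpm_diploid,tpm_tetraploid Named per-gene TPM vectors (replicates
#'   already averaged).
#' @param dissection The `region_dissection` defining carrier sets.
#' @param min_pairs Minimum carrier genes to test expression (default 5).
#' @return Data.frame: `superfamily`, `n_genes`, `h3k27me3_direction`,
#'   `h3k27me3_q`, `expression_direction`, `expression_p`,
#'   `concordant_negative`.
#' @export
link_expression <- function(comparisons, tpm_diploid, tpm_tetraploid,
                            dissection, min_pairs = 5) {
  rows <- list()
  for (sf in te_superfamilies()) {
    g <- genes_carrying_superfamily(dissection, sf, "body")
    g <- intersect(g, intersect(names(tpm_diploid), names(tpm_tetraploid)))
    if (length(g) == 0) {
      warning(sprintf("superfamily %s skipped: empty carrier gene set", sf))
      next
    }
    chrom_rec <- comparisons[comparisons$region_kind == "body" &
                               comparisons$segment_class == "nonte" &
                               comparisons$superfamily == sf, ]
    h3_dir <- if (nrow(chrom_rec)) chrom_rec$direction[1] else "none"
    h3_q <- if (nrow(chrom_rec)) chrom_rec$q_value[1] else NA_real_
    if (length(g) >= min_pairs) {
      res <- wilcoxon_signed_rank(tpm_tetraploid[g], tpm_diploid[g])
      e_dir <- switch(res$direction, a_greater = "tetraploid_greater",
                      b_greater = "diploid_greater", "none")
      e_p <- res$p_value
    } else {
      e_dir <- "none"; e_p <- NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      superfamily = sf, n_genes = length(g),
      h3k27me3_direction = h3_dir, h3k27me3_q = h3_q,
      expression_direction = e_dir, expression_p = e_p,
      concordant_negative =
        (h3_dir == "tetraploid_greater" & e_dir == "diploid_greater") |
        (h3_dir == "diploid_greater" & e_dir == "tetraploid_greater"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(superfamily = character(), n_genes = integer(),
                      h3k27me3_direction = character(),
                      h3k27me3_q = numeric(),
                      expression_direction = character(),
                      expression_p = numeric(),
                      concordant_negative = logical())
  rownames(out) <- NULL
  out
}

#' Write the comparison report
#'
#' Writes `comparisons.tsv`, `expression_links.tsv`, optionally
#' `te_vs_nonte.tsv`, and a plain-text `summary.txt` naming the superfamilies
#' whose genic non-TE chromatin is significantly higher in the tetraploid.
#' Output is deterministic: rerunning on identical inputs reproduces the
#' files byte for byte.
#'
#' @param comparisons A `comparison_table`.
#' @param links Expression-link table from [link_expression()] (may have
#'   zero rows; the file then holds only the header).
#' @param out_dir Output directory (created if missing).
#' @param contrasts Optional TE-vs-non-TE table ([te_vs_nonte_contrast()]).
#' @param alpha Significance threshold used in the summary (default 0.05 on
#'   q-values).
#' @return Invisible character vector of the files written.
#' @export
write_report <- function(comparisons, links, out_dir, contrasts = NULL,
                         alpha = 0.05) {
  if (nrow(comparisons) == 0)
    .err("empty comparison table", "ploidyTE_value_error")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    .err(sprintf("cannot write to directory '%s'", out_dir),
         "ploidyTE_value_error")
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(tsv(as.data.frame(comparisons), "comparisons.tsv"),
             tsv(links, "expression_links.tsv"))
  if (!is.null(contrasts)) files <- c(files, tsv(contrasts, "te_vs_nonte.tsv"))
  sig <- comparisons[!is.na(comparisons$q_value) &
                       comparisons$q_value < alpha &
                       comparisons$region_kind == "body" &
                       comparisons$segment_class == "nonte" &
                       comparisons$superfamily != "all" &
                       comparisons$direction == "tetraploid_greater", ]
  summary_path <- file.path(out_dir, "summary.txt")
  lines <- c(
    sprintf("comparison records: %d (%d testable)", nrow(comparisons),
            sum(!is.na(comparisons$p_value))),
    sprintf("genic non-TE chromatin higher in tetraploid (q < %g): %s",
            alpha,
            if (nrow(sig)) paste(sort(sig$superfamily), collapse = ", ")
            else "none"),
    sprintf("expression links: %d superfamilies, %d concordant negative",
            nrow(links), sum(links$concordant_negative)))
  writeLines(lines, summary_path)
  invisible(c(files, summary_path))
}
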