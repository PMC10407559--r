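#' Strand-aware flanking regions of genes
#'
#' For a `+` gene, upstream is `[start - flank_bp, start)` and downstream is
#' `[end, end + flank_bp)`; mirrored for `-` genes. Flanks are clipped to
#' `[0, chrom_len)`; genes whose flank is emptied by clipping are omitted
#' from the result.
#'
#' @param genes Gene data.frame ([read_gene_annotation()]).
#' @param flank_bp Flank width in bp (default 2000, the 2 kb window used
#'   throughout the analysis).
#' @param which `"upstream"` or `"downstream"`.
#' @param chrom_lens Named vector of chromosome lengths (bp). `NULL` disables
#'   right-end clipping.
#' @return Data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
flank_regions <- function(genes, flank_bp = 2000,
                          which = c("upstream", "downstream"),
                          chrom_lens = NULL) {
  which <- match.arg(which)
  if (flank_bp <= 0) .err("flank_bp must be > 0", "ploidyTE_value_error")
  if (nrow(genes) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer()))
  plus <- genes$strand == "+"
  left <- (which == "upstream") == plus  # flank sits left of the body?
  start <- ifelse(left, genes$start - flank_bp, genes$end)
  end <- ifelse(left, genes$start, genes$end + flank_bp)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lens)) {
    len <- chrom_lens[genes$chrom]
    if (anyNA(len))
      .err(sprintf("chrom_lens lacks chromosome(s): %s",
                   paste(unique(genes$chrom[is.na(len)]), collapse = ", ")),
           "ploidyTE_value_error")
    if (any(len < genes$end))
      .err("chrom_lens smaller than a gene end", "ploidyTE_value_error")
    end <- pmin(end, unname(len))
  }
  keep <- start < end
  out <- data.frame(gene_id = genes$gene_id[keep], chrom = genes$chrom[keep],
                    start = as.integer(start[keep]),
                    end = as.integer(end[keep]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flank of a single gene
#'
#' Scalar convenience wrapper around [flank_regions()]. Returns `NULL` when
#' clipping empties the flank (for example the upstream flank of a `+` gene
#' starting at position 0).
#'
#' @param gene One-row gene data.frame.
#' @inheritParams flank_regions
#' @param chrom_len Chromosome length in bp (scalar), or `NULL`.
#' @return A list with `chrom`, `start`, `end`, or `NULL`.
#' @export
flank_region <- function(gene, flank_bp = 2000,
                         which = c("upstream", "downstream"),
                         chrom_len = NULL) {
  stopifnot(nrow(gene) == 1)
  cl <- if (is.null(chrom_len)) NULL else setNames(chrom_len, gene$chrom)
  res <- flank_regions(gene, flank_bp, which, cl)
  if (nrow(res) == 0) return(NULL)
  list(chrom = res$chrom, start = res$start, end = res$end)
}

#' Assign each TE to a genomic context by the majority-overlap rule
#'
#' A TE is assigned to the first category, in priority order
#' body > upstream > downstream, whose feature union covers strictly more
#' than half of the TE length; TEs clearing the bar for no category are
#' intergenic. Overlapping features within a category are unioned before the
#' overlap is computed, so no base is double-counted. TEs on chromosomes
#' absent from the gene annotation are intergenic (with a warning).
#'
#' @param tes TE data.frame ([read_te_annotation()]).
#' @param genes Gene data.frame.
#' @param flank_bp Flank width in bp (default 2000).
#' @param chrom_lens Optional named chromosome lengths for flank clipping.
#' @return `tes` with the `category` column filled with one of
#'   `"genic"`, `"upstream"`, `"downstream"`, `"intergenic"`.
#' @export
assign_te_categories <- function(tes, genes, flank_bp = 2000,
                                 chrom_lens = NULL) {
  .check_intervals(tes, "TE")
  .check_intervals(genes, "gene")
  feats <- list(
    genic      = genes[, c("chrom", "start", "end")],
    upstream   = flank_regions(genes, flank_bp, "upstream", chrom_lens),
    downstream = flank_regions(genes, flank_bp, "downstream", chrom_lens))
  category <- rep("intergenic", nrow(tes))
  orphan <- setdiff(unique(tes$chrom), unique(genes$chrom))
  if (length(orphan))
    warning(sprintf("TE(s) on chromosome(s) without genes treated as intergenic: %s",
                    paste(orphan, collapse = ", ")))
  for (ch in intersect(unique(tes$chrom), unique(genes$chrom))) {
    ti <- which(tes$chrom == ch)
    te_len <- tes$end[ti] - tes$start[ti]
    assigned <- rep(FALSE, length(ti))
    for (cat in c("genic", "upstream", "downstream")) {
      f <- feats[[cat]]
      f <- f[f$chrom == ch, , drop = FALSE]
      if (nrow(f) == 0) next
      red <- .merge_spans(f$start, f$end)
      ov <- .overlap_widths(tes$start[ti], tes$end[ti], red$start, red$end)
      hit <- !assigned & ov * 2 > te_len  # strictly more than half
      category[ti[hit]] <- cat
      assigned <- assigned | hit
    }
  }
  tes$category <- category
  tes
}

# Total overlap width of each query [qs,qe) with a set of DISJOINT sorted
# subject spans [ss,se). Vectorized over queries.
.overlap_widths <- function(qs, qe, ss, se) {
  if (length(ss) == 0) return(rep(0L, length(qs)))
  q <- .ir(qs, qe)
  s <- .ir(ss, se)
  hits <- IRanges::findOverlaps(q, s)
  if (length(hits) == 0) return(rep(0L, length(qs)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  w <- pmin(qe[qh], se[sh]) - pmax(qs[qh], ss[sh])
  out <- rep(0L, length(qs))
  agg <- tapply(w, qh, sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Partition one region into TE and non-TE segments
#'
#' TE spans are clipped to the region, merged where overlapping or bookended,
#' and complemented within the region. The two segment sets are disjoint,
#' sorted, and tile the region exactly. The TE annotation may contain nested
#' or mutually overlapping records and records extending beyond the region.
#'
#' @param region A list or one-row data.frame with `chrom`, `start`, `end`.
#' @param tes TE data.frame (any chromosomes; only overlapping records
#'   contribute).
#' @return A list with `te_segments` and `nonte_segments` (data.frames with
#'   `start`, `end`) and `superfamilies` (labels of TEs contributing >= 1 bp
#'   after clipping, sorted).
#' @export
dissect_region <- function(region, tes) {
  rs <- as.integer(region$start); re <- as.integer(region$end)
  if (!(rs >= 0 && rs < re))
    .err("region must satisfy 0 <= start < end", "ploidyTE_value_error")
  sel <- tes$chrom == region$chrom & tes$end > rs & tes$start < re
  hit <- tes[sel, , drop = FALSE]
  cs <- pmax(hit$start, rs); ce <- pmin(hit$end, re)
  te_seg <- .merge_spans(cs, ce)
  nonte_seg <- .complement_spans(te_seg$start, te_seg$end, rs, re)
  list(te_segments = te_seg, nonte_segments = nonte_seg,
       superfamilies = sort(unique(hit$superfamily)))
}

#' Dissect gene bodies and flanks into TE and non-TE segments
#'
#' Builds the body, upstream and downstream region of every gene and
#' partitions each into TE and non-TE segments with [dissect_region()]. A TE
#' intersecting two genes' regions contributes its clipped span to both
#' dissections (dissection is per-gene; the [assign_te_categories()] context
#' is per-TE).
#'
#' @param genes Gene data.frame.
#' @param tes TE data.frame.
#' @param flank_bp Flank width in bp (default 2000).
#' @param chrom_lens Optional named chromosome lengths.
#' @return An object of class `region_dissection`: list with
#'   \describe{
#'     \item{regions}{one row per (gene, region_kind): `gene_id`,
#'       `region_kind`, `chrom`, `start`, `end`, `length_bp`, `te_bp`,
#'       `n_te`, `superfamilies` (comma-separated, `""` if TE-free).}
#'     \item{segments}{one row per segment: `gene_id`, `region_kind`,
#'       `chrom`, `start`, `end`, `segment_class` (`"te"`/`"nonte"`).}
#'   }
#' @export
dissect_genes <- function(genes, tes, flank_bp = 2000, chrom_lens = NULL) {
  .check_intervals(genes, "gene")
  .check_intervals(tes, "TE")
  regions <- rbind(
    cbind(region_kind = "body",
          genes[, c("gene_id", "chrom", "start", "end")]),
    cbind(region_kind = "upstream",
          flank_regions(genes, flank_bp, "upstream", chrom_lens)[
            , c("gene_id", "chrom", "start", "end")]),
    cbind(region_kind = "downstream",
          flank_regions(genes, flank_bp, "downstream", chrom_lens)[
            , c("gene_id", "chrom", "start", "end")]))
  regions <- regions[, c("gene_id", "region_kind", "chrom", "start", "end")]
  rownames(regions) <- NULL

  # pre-split TEs per chromosome to keep the per-region work small
  tes_by_chrom <- split(tes, tes$chrom)
  seg_list <- vector("list", nrow(regions))
  te_bp <- integer(nrow(regions))
  n_te <- integer(nrow(regions))
  sfs <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    d <- dissect_region(r, tes_by_chrom[[r$chrom]] %||%
                          tes[0, , drop = FALSE])
    te_bp[i] <- sum(d$te_segments$end - d$te_segments$start)
    n_te[i] <- nrow(d$te_segments)
    sfs[i] <- paste(d$superfamilies, collapse = ",")
    seg <- rbind(
      if (nrow(d$te_segments)) cbind(d$te_segments, segment_class = "te"),
      if (nrow(d$nonte_segments)) cbind(d$nonte_segments,
                                        segment_class = "nonte"))
    if (!is.null(seg) && nrow(seg))
      seg_list[[i]] <- data.frame(gene_id = r$gene_id,
                                  region_kind = r$region_kind,
                                  chrom = r$chrom, seg,
                                  stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_list)
  segments <- segments[order(segments$chrom, segments$gene_id,
                             segments$region_kind, segments$start), ]
  rownames(segments) <- NULL
  regions$length_bp <- regions$end - regions$start
  regions$te_bp <- te_bp
  regions$n_te <- n_te
  regions$superfamilies <- sfs
  structure(list(regions = regions, segments = segments,
                 flank_bp = flank_bp),
            class = "region_dissection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.region_dissection <- function(x, ...) {
  cat(sprintf("region_dissection: %d genes, %d regions, %d segments (flank %d bp)\n",
              length(unique(x$regions$gene_id)), nrow(x$regions),
              nrow(x$segments), x$flank_bp))
  invisible(x)
}

#' Genes carrying a TE of a given superfamily in a region kind
#'
#' @param dissection A `region_dissection` from [dissect_genes()].
#' @param superfamily One canonical superfamily label.
#' @param region_kind Region kind the carrier status refers to (default
#'   `"body"`: TE-cognate genes in the strict sense).
#' @return Character vector of gene IDs.
#' @export
genes_carrying_superfamily <- function(dissection, superfamily,
                                       region_kind = c("body", "upstream",
                                                       "downstream")) {
  region_kind <- match.arg(region_kind)
  .check_superfamily(superfamily)
  stopifnot(length(superfamily) == 1)
  reg <- dissection$regions
  reg <- reg[reg$region_kind == region_kind & nzchar(reg$superfamilies), ]
  if (nrow(reg) == 0) return(character())
  hit <- vapply(strsplit(reg$superfamilies, ",", fixed = TRUE),
                function(s) superfamily %in% s, logical(1))
  sort(unique(reg$gene_id[hit]))
}

#' Write a dissection to TSV
#'
#' One row per segment: `gene_id`, `region_kind`, `chrom`, `start`, `end`,
#' `segment_class`, `superfamilies` (of the parent region).
#'
#' @param dissection A `region_dissection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dissection <- function(dissection, path) {
  seg <- dissection$segments
  key <- paste(dissection$regions$gene_id, dissection$regions$region_kind)
  seg$superfamilies <- dissection$regions$superfamilies[
    match(paste(seg$gene_id, seg$region_kind), key)]
  write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
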