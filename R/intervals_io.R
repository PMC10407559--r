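#' Read a gene annotation from GFF3
#'
#' Retains records of feature type `gene`, converts the 1-based inclusive
#' GFF3 coordinates to the package-internal 0-based half-open convention and
#' sorts by (chromosome, start). Genes must be stranded (`+` or `-`) and carry
#' a unique `ID` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_gene_annotation <- function(path) {
  gff <- tryCatch(rtracklayer::readGFF(path),
                  error = function(e) .err(sprintf(
                    "failed to parse GFF3 '%s': %s", path, conditionMessage(e)),
                    "ploidyTE_parse_error"))
  gff <- as.data.frame(gff)
  gff <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(gff) == 0)
    .err(sprintf("no 'gene' records in '%s'", path), "ploidyTE_parse_error")
  if (!"ID" %in% names(gff) || anyNA(gff$ID))
    .err("gene record without an ID attribute", "ploidyTE_parse_error")
  bad <- which(gff$start > gff$end)
  if (length(bad))
    .err(sprintf("gene record with start > end (ID=%s, %s:%d-%d)",
                 gff$ID[bad[1]], gff$seqid[bad[1]],
                 gff$start[bad[1]], gff$end[bad[1]]),
         "ploidyTE_parse_error")
  dup <- unique(gff$ID[duplicated(gff$ID)])
  if (length(dup))
    .err(sprintf("duplicate gene ID(s): %s", paste(dup, collapse = ", ")),
         "ploidyTE_parse_error")
  strand <- as.character(gff$strand)
  if (any(!strand %in% c("+", "-")))
    .err(sprintf("unstranded gene record(s), e.g. ID=%s",
                 gff$ID[which(!strand %in% c("+", "-"))[1]]),
         "ploidyTE_parse_error")
  out <- data.frame(gene_id = as.character(gff$ID),
                    chrom   = as.character(gff$seqid),
                    start   = as.integer(gff$start) - 1L,
                    end     = as.integer(gff$end),
                    strand  = strand,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  .check_intervals(out, "gene")
  out
}

#' Write a gene table back to GFF3
#'
#' Inverse of [read_gene_annotation()]: internal 0-based half-open
#' coordinates are converted back to 1-based inclusive GFF3 records of type
#' `gene` with an `ID` attribute.
#'
#' @param genes Gene data.frame as returned by [read_gene_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  .check_intervals(genes, "gene")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges   = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand   = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a TE annotation from BED4 or GFF3
#'
#' Each record must carry a superfamily label: the BED name field, or a GFF3
#' attribute (`attr_key`, default `"superfamily"`). Labels are first passed
#' through `superfamily_map` (named character vector, raw -> canonical), then
#' matched against the 12 canonical labels of [te_superfamilies()]. Labels
#' still unknown are mapped to `LTR/Unclassed` (if `unknown_class = "I"`) or
#' `DNA/Unclassed` (`unknown_class = "II"`) with a warning.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` (BED4, 0-based half-open on disk) or `"gff3"`.
#' @param superfamily_map Optional named character vector mapping raw labels
#'   to canonical superfamily labels.
#' @param unknown_class Class used to bucket unknown labels, `"II"` (default)
#'   or `"I"`.
#' @param attr_key GFF3 attribute holding the superfamily label.
#' @return A data.frame with columns `te_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `te_class`, `superfamily` and `category`
#'   (initialized to `"unassigned"`; see [assign_te_categories()]).
#' @export
read_te_annotation <- function(path, format = c("bed", "gff3"),
                               superfamily_map = NULL,
                               unknown_class = c("II", "I"),
                               attr_key = "superfamily") {
  format <- match.arg(format)
  unknown_class <- match.arg(unknown_class)
  if (format == "bed") {
    raw <- tryCatch(
      read.delim(path, header = FALSE, stringsAsFactors = FALSE),
      error = function(e) .err(sprintf("failed to read BED '%s': %s",
                                       path, conditionMessage(e)),
                               "ploidyTE_parse_error"))
    if (ncol(raw) < 4)
      .err("BED TE annotation needs 4 columns (chrom, start, end, name)",
           "ploidyTE_parse_error")
    df <- data.frame(chrom = as.character(raw[[1]]),
                     start = as.integer(raw[[2]]),
                     end   = as.integer(raw[[3]]),
                     label = as.character(raw[[4]]),
                     stringsAsFactors = FALSE)
    if (any(df$start >= df$end))
      .err(sprintf("BED record with start >= end at line %d",
                   which(df$start >= df$end)[1]),
           "ploidyTE_parse_error")
  } else {
    gff <- tryCatch(as.data.frame(rtracklayer::readGFF(path)),
                    error = function(e) .err(sprintf(
                      "failed to parse GFF3 '%s': %s", path,
                      conditionMessage(e)), "ploidyTE_parse_error"))
    if (!attr_key %in% names(gff))
      .err(sprintf("TE GFF3 lacks the '%s' attribute", attr_key),
           "ploidyTE_parse_error")
    df <- data.frame(chrom = as.character(gff$seqid),
                     start = as.integer(gff$start) - 1L,
                     end   = as.integer(gff$end),
                     label = as.character(gff[[attr_key]]),
                     stringsAsFactors = FALSE)
  }
  if (any(is.na(df$label) | !nzchar(df$label)))
    .err("TE record with missing superfamily label", "ploidyTE_parse_error")
  lab <- df$label
  if (!is.null(superfamily_map)) {
    hit <- lab %in% names(superfamily_map)
    lab[hit] <- unname(superfamily_map[lab[hit]])
  }
  unknown <- !(lab %in% te_superfamilies())
  if (any(unknown)) {
    bucket <- if (unknown_class == "I") "LTR/Unclassed" else "DNA/Unclassed"
    warning(sprintf("%d TE record(s) with unknown superfamily label(s) (%s) mapped to %s",
                    sum(unknown),
                    paste(unique(lab[unknown]), collapse = ", "), bucket))
    lab[unknown] <- bucket
  }
  out <- data.frame(te_id = sprintf("te%05d", seq_len(nrow(df))),
                    chrom = df$chrom, start = df$start, end = df$end,
                    te_class = te_class_of(lab), superfamily = lab,
                    category = "unassigned", stringsAsFactors = FALSE)
  .check_intervals(out, "TE")
  out
}

#' Write a TE table to BED4
#'
#' @param tes TE data.frame as returned by [read_te_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_te_annotation <- function(tes, path) {
  .check_intervals(tes, "TE")
  write.table(tes[, c("chrom", "start", "end", "superfamily")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read paired-end fragments from a BAM file or a fragment table
#'
#' From a BAM file, one fragment is emitted per properly paired, primary,
#' mapped read pair, taken as the template span of the leftmost mate
#' (positive TLEN). Secondary, supplementary, unmapped and improperly paired
#' records are excluded. "Uniquely mapped" is operationalized as the MAPQ
#' filter alone: fragments are retained when MAPQ is strictly greater than
#' `mapq_min`. Pairs that survive the flag/MAPQ filters but have a
#' non-positive template length are skipped and counted in a warning.
#' Duplicate fragments are not removed.
#'
#' A tab-delimited fragment table (any non-`.bam` path) must have a header
#' with columns `chrom`, `start`, `end`, `mapq` (0-based half-open).
#'
#' @param path BAM file (`.bam`) or TSV fragment table.
#' @param mapq_min MAPQ threshold; fragments with `mapq <= mapq_min` are
#'   dropped (strict inequality, default 50).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `mapq`.
#' @export
read_fragments <- function(path, mapq_min = 50) {
  if (!file.exists(path))
    .err(sprintf("fragment source '%s' does not exist", path),
         "ploidyTE_parse_error")
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    flags <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                    isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(
      flag = flags, what = c("rname", "pos", "isize", "mapq"))
    res <- tryCatch(Rsamtools::scanBam(path, param = param)[[1]],
                    error = function(e) .err(sprintf(
                      "failed to read BAM '%s': %s", path,
                      conditionMessage(e)), "ploidyTE_parse_error"))
    keep_q <- !is.na(res$mapq) & res$mapq > mapq_min
    left <- keep_q & !is.na(res$isize) & res$isize > 0
    # leftmost mates failing TLEN sanity: proper primary pairs we must skip
    n_bad_tlen <- sum(keep_q & !is.na(res$isize) & res$isize == 0) / 2
    if (n_bad_tlen > 0)
      warning(sprintf("%d retained pair(s) skipped for non-positive template length",
                      n_bad_tlen))
    out <- data.frame(chrom = as.character(res$rname[left]),
                      start = res$pos[left] - 1L,
                      end   = res$pos[left] - 1L + res$isize[left],
                      mapq  = res$mapq[left], stringsAsFactors = FALSE)
  } else {
    tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                    error = function(e) .err(sprintf(
                      "failed to read fragment table '%s': %s", path,
                      conditionMessage(e)), "ploidyTE_parse_error"))
    need <- c("chrom", "start", "end", "mapq")
    if (!all(need %in% names(tab)))
      .err("fragment table needs columns chrom, start, end, mapq",
           "ploidyTE_parse_error")
    out <- tab[tab$mapq > mapq_min,
               c("chrom", "start", "end", "mapq"), drop = FALSE]
    rownames(out) <- NULL
  }
  .check_intervals(out, "fragment")
  out
}

#' Write a fragment table as TSV
#'
#' @param fragments Fragment data.frame (`chrom`, `start`, `end`, `mapq`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  write.table(fragments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
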