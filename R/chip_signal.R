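#' Fragment midpoint
#'
#' The midpoint of a paired-end template `[start, end)` is
#' `floor((start + end) / 2)`, the package's point estimate of nucleosome
#' position. Vectorized.
#'
#' @param start,end 0-based half-open fragment coordinates.
#' @return Integer vector of midpoint positions.
#' @export
#' @examples
#' fragment_midpoint(100, 250)  # 175
fragment_midpoint <- function(start, end) {
  if (any(start >= end))
    .err("empty fragment (start >= end)", "ploidyTE_value_error")
  (as.integer(start) + as.integer(end)) %/% 2L
}

#' Build a midpoint index from fragments
#'
#' Stores per-chromosome sorted midpoint positions plus the library size
#' (total retained fragment count), the unit for per-million depth
#' normalization.
#'
#' @param fragments Fragment data.frame (`chrom`, `start`, `end`), e.g. from
#'   [read_fragments()].
#' @return An object of class `midpoint_index`: list with `positions` (named
#'   list of sorted integer vectors) and `library_size`.
#' @export
build_midpoint_index <- function(fragments) {
  if (nrow(fragments) == 0)
    return(structure(list(positions = list(), library_size = 0L),
                     class = "midpoint_index"))
  .check_intervals(fragments, "fragment")
  mid <- fragment_midpoint(fragments$start, fragments$end)
  pos <- lapply(split(mid, fragments$chrom), sort)
  structure(list(positions = pos,
                 library_size = nrow(fragments)),
            class = "midpoint_index")
}

#' @export
print.midpoint_index <- function(x, ...) {
  cat(sprintf("midpoint_index: %d fragments on %d chromosome(s)\n",
              x$library_size, length(x$positions)))
  invisible(x)
}

# midpoints in [start, end) per interval; vectorized via binary search
.counts_per_interval <- function(index, intervals) {
  n <- nrow(intervals)
  out <- integer(n)
  for (ch in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == ch)
    x <- index$positions[[ch]]
    if (is.null(x) || length(x) == 0) next
    out[idx] <- findInterval(intervals$end[idx] - 0.5, x) -
      findInterval(intervals$start[idx] - 0.5, x)
  }
  out
}

#' Count midpoints falling in a set of disjoint intervals
#'
#' Half-open semantics: a midpoint at position `p` is counted for an interval
#' `[start, end)` iff `start <= p < end`. The intervals must be pairwise
#' disjoint (bookended is fine); overlapping intervals would double-count and
#' raise an error.
#'
#' @param index A `midpoint_index`.
#' @param intervals Data.frame with `chrom`, `start`, `end`.
#' @return Total midpoint count (integer scalar).
#' @export
count_midpoints <- function(index, intervals) {
  if (nrow(intervals) == 0) return(0L)
  .check_intervals(intervals, "interval")
  if (.has_overlap(intervals))
    .err("intervals overlap; counts would be double-counted",
         "ploidyTE_value_error")
  sum(.counts_per_interval(index, intervals))
}

#' Normalized, IgG-corrected signal over an interval set
#'
#' Density is `count / length_bp / (library_size / 1e6)`: midpoints per bp
#' per million retained fragments, making the value comparable across
#' interval lengths and sequencing depths. The IgG correction is a ratio of
#' densities with a symmetric pseudocount:
#' `igg_ratio = (density_chip + eps) / (density_igg + eps)`.
#'
#' @param chip_index,igg_index `midpoint_index` objects for the ChIP and the
#'   IgG control library; both must have non-zero library size.
#' @param intervals Disjoint interval set (data.frame `chrom`,`start`,`end`)
#'   with positive total length.
#' @param pseudocount Symmetric pseudocount `eps` in density units
#'   (per bp per million; default 1e-3).
#' @return List with `count`, `length_bp`, `density`, `density_igg`,
#'   `igg_ratio`.
#' @export
interval_signal <- function(chip_index, igg_index, intervals,
                            pseudocount = 1e-3) {
  if (chip_index$library_size == 0 || igg_index$library_size == 0)
    .err("zero library size", "ploidyTE_value_error")
  len <- sum(intervals$end - intervals$start)
  if (length(len) == 0 || len <= 0)
    .err("zero total interval length", "ploidyTE_value_error")
  n_chip <- count_midpoints(chip_index, intervals)
  n_igg <- count_midpoints(igg_index, intervals)
  d_chip <- n_chip / len / (chip_index$library_size / 1e6)
  d_igg <- n_igg / len / (igg_index$library_size / 1e6)
  list(count = n_chip, length_bp = len,
       density = d_chip, density_igg = d_igg,
       igg_ratio = (d_chip + pseudocount) / (d_igg + pseudocount))
}

#' Per-gene signal table over a dissection
#'
#' One row per (gene, region kind, segment class): counts are summed across
#' the gene's segments of that class and divided by the summed length
#' (length-weighted aggregation, robust to tiny segments), then depth- and
#' IgG-normalized as in [interval_signal()]. Classes with zero total length
#' in a region have no row. A TE shared by two genes' regions contributes its
#' clipped span to both genes' rows.
#'
#' @param dissection A `region_dissection` from [dissect_genes()].
#' @param chip_index,igg_index `midpoint_index` objects.
#' @param pseudocount Pseudocount for the IgG ratio (default 1e-3).
#' @return Data.frame with columns `gene_id`, `region_kind`, `segment_class`,
#'   `n_segments`, `length_bp`, `count_chip`, `count_igg`, `density_chip`,
#'   `density_igg`, `igg_ratio`.
#' @export
signal_table <- function(dissection, chip_index, igg_index,
                         pseudocount = 1e-3) {
  if (chip_index$library_size == 0 || igg_index$library_size == 0)
    .err("zero library size", "ploidyTE_value_error")
  seg <- dissection$segments
  seg$count_chip <- .counts_per_interval(chip_index, seg)
  seg$count_igg <- .counts_per_interval(igg_index, seg)
  seg$len <- seg$end - seg$start
  key <- paste(seg$gene_id, seg$region_kind, seg$segment_class, sep = "\r")
  agg <- rowsum(cbind(len = seg$len, count_chip = seg$count_chip,
                      count_igg = seg$count_igg, n = 1L), key, reorder = FALSE)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- data.frame(gene_id = parts[, 1], region_kind = parts[, 2],
                    segment_class = parts[, 3],
                    n_segments = as.integer(agg[, "n"]),
                    length_bp = as.integer(agg[, "len"]),
                    count_chip = as.integer(agg[, "count_chip"]),
                    count_igg = as.integer(agg[, "count_igg"]),
                    stringsAsFactors = FALSE)
  out$density_chip <- out$count_chip / out$length_bp /
    (chip_index$library_size / 1e6)
  out$density_igg <- out$count_igg / out$length_bp /
    (igg_index$library_size / 1e6)
  out$igg_ratio <- (out$density_chip + pseudocount) /
    (out$density_igg + pseudocount)
  out <- out[order(out$gene_id, out$region_kind, out$segment_class), ]
  rownames(out) <- NULL
  out
}
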