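# Internal interval helpers. All coordinates are 0-based half-open; IRanges
# (1-based inclusive) is used only transiently for merge/complement algebra.

# data.frame(start, end) [0-based half-open] -> IRanges
.ir <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# IRanges -> data.frame(start, end) [0-based half-open]
.ir_df <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Validate an interval data.frame with columns chrom/start/end.
.check_intervals <- function(df, what = "interval",
                             cols = c("chrom", "start", "end")) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    .err(sprintf("%s table lacks column(s): %s", what,
                 paste(missing_cols, collapse = ", ")),
         "ploidyTE_value_error")
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
    .err(sprintf("%s with empty chromosome name", what), "ploidyTE_value_error")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    .err(sprintf("%s with start >= end or negative start (e.g. %s:[%s,%s))",
                 what, df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]),
         "ploidyTE_value_error")
  invisible(df)
}

# Merge overlapping or bookended intervals on ONE chromosome.
# Input/output: data.frame(start, end), output sorted.
.merge_spans <- function(start, end) {
  if (length(start) == 0) return(data.frame(start = integer(), end = integer()))
  .ir_df(IRanges::reduce(.ir(start, end)))
}

# Complement of (merged) spans within [region_start, region_end).
.complement_spans <- function(start, end, region_start, region_end) {
  region <- .ir(region_start, region_end)
  if (length(start) == 0) return(.ir_df(region))
  .ir_df(IRanges::setdiff(region, .ir(start, end)))
}

# TRUE if intervals (single chromosome assumed handled by caller) contain an
# overlapping pair; bookended intervals are fine.
.has_overlap <- function(df) {
  if (nrow(df) < 2) return(FALSE)
  any(vapply(split(df, df$chrom), function(d) {
    o <- order(d$start, d$end)
    any(d$start[o][-1] < d$end[o][-nrow(d)])
  }, logical(1)))
}
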