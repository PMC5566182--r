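# Internal coordinate convention: 0-based half-open [start, stop), like BED.
# Printed-style TSV reports and qPCR/signal tables use 1-based inclusive
# coordinates; conversion happens only at the I/O boundary.

#' Default genome assembly label
#'
#' All intervals carry an assembly label so that designs on different builds
#' cannot be compared silently. The default matches UCSC hg19.
#' @export
DEFAULT_ASSEMBLY <- "GRCh37/hg19"

#' Construct a table of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start,stop integer vectors, 0-based half-open.
#' @param assembly assembly label stored as an attribute.
#' @param ... further columns, recycled by `data.frame()`.
#' @return a `data.frame` with at least `chrom`, `start`, `stop` and an
#'   `assembly` attribute.
#' @export
genomic_intervals <- function(chrom, start, stop, ...,
                              assembly = DEFAULT_ASSEMBLY) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   stop = as.numeric(stop),
                   ..., stringsAsFactors = FALSE)
  attr(df, "assembly") <- assembly
  validate_intervals(df)
}

#' Validate an interval table
#'
#' Checks the invariants every interval table must satisfy: non-empty
#' chromosome names and `start < stop` (zero-width intervals are rejected).
#'
#' @param df data.frame with `chrom`, `start`, `stop`.
#' @param context label used in error messages.
#' @return `df`, invisibly usable, unchanged.
#' @export
validate_intervals <- function(df, context = "interval table") {
  req <- c("chrom", "start", "stop")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(context, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(df)
  if (any(is.na(df$chrom) | !nzchar(df$chrom))) {
    stop(context, ": empty chromosome name")
  }
  bad <- which(!(df$start < df$stop))
  if (length(bad)) {
    stop(sprintf("%s: start must be < stop (row %s)", context,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  df
}

#' @noRd
interval_assembly <- function(df) {
  a <- attr(df, "assembly")
  if (is.null(a)) DEFAULT_ASSEMBLY else a
}

# Convert an internal interval table to GRanges (1-based inclusive).
#' @noRd
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$stop))
}

#' @noRd
interval_width <- function(df) df$stop - df$start

# Overlap width of one interval against a table of intervals on any chrom.
#' @noRd
overlap_widths <- function(chrom, start, stop, db) {
  same <- db$chrom == chrom
  w <- numeric(nrow(db))
  w[same] <- pmax(0, pmin(stop, db$stop[same]) - pmax(start, db$start[same]))
  w
}

# Round half away from zero, the convention used for printed percentages
# and sizes (base round() is half-to-even).
#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Printed size in kb from 1-based inclusive coordinates.
#' @noRd
size_kb_1based <- function(start1, stop1) {
  round_half_up((stop1 - start1 + 1) / 1000)
}

#' @noRd
sort_by_position <- function(df) {
  df[order(df$chrom, df$start, df$stop), , drop = FALSE]
}
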