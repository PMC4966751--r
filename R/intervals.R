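#' Genomic interval records
#'
#' All coordinates in mirtrio are 0-based half-open (BED convention);
#' 1-based formats (GFF3) are converted at parse time. `genomic_interval()`
#' builds a single validated interval; sets of intervals are plain data frames
#' with columns `seq_name`, `start`, `end`, `strand` (and any extra columns).
#'
#' @param seq_name Chromosome / contig name.
#' @param start 0-based start.
#' @param end End (exclusive); must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row data frame of class `genomic_interval`.
#' @examples
#' genomic_interval("chr1", 100, 180)
#' @export
genomic_interval <- function(seq_name, start, end, strand = "+") {
  stopifnot(length(seq_name) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  out <- data.frame(seq_name = as.character(seq_name), start = start,
                    end = end, strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", class(out))
  out
}

# Convert an interval data frame (0-based half-open) to GRanges (1-based).
as_granges <- function(df) {
  stopifnot(all(c("seq_name", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$seq_name,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

interval_width <- function(df) df$end - df$start
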