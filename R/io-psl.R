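#' Read BLAT hits from a PSL file
#'
#' Parses BLAT's tabular PSL output (with or without the 5-line `psLayout`
#' header) into one record per hit. Target coordinates in PSL are already
#' 0-based half-open on the forward strand and are kept that way. Identity is
#' defined as `matches / (matches + misMatches + qBaseInsert)`; note this is a
#' documented, fixed definition and differs slightly from the BLAT web
#' server's percent identity. Matched length is the number of aligned query
#' bases (`matches + misMatches + repMatches + nCount`).
#'
#' @param path Path to a PSL file.
#' @return A data frame with one row per hit: `query_id`, `seq_name`,
#'   `start`, `end`, `strand`, `matched_length`, `identity`, `query_length`,
#'   `block_count`, `block_sizes`, `t_starts`.
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  # Skip header: keep lines whose first field is an integer.
  keep <- grepl("^[0-9]+\t", lines)
  lines <- lines[keep]
  empty <- data.frame(
    query_id = character(), seq_name = character(), start = integer(),
    end = integer(), strand = character(), matched_length = integer(),
    identity = numeric(), query_length = integer(), block_count = integer(),
    block_sizes = character(), t_starts = character(),
    stringsAsFactors = FALSE
  )
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 21L)
  if (length(bad))
    stop("malformed PSL line ", which(keep)[bad[1]], ": expected 21 fields, found ",
         nf[bad[1]])
  f <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i) suppressWarnings(as.integer(f(i)))
  matches <- num(1); mism <- num(2); rep_m <- num(3); n_count <- num(4)
  q_gap_bases <- num(6)
  if (anyNA(matches) || anyNA(mism) || anyNA(q_gap_bases))
    stop("malformed PSL line ", which(keep)[which(is.na(matches + mism + q_gap_bases))[1]],
         ": non-numeric count field")
  strand <- substr(f(9), 1L, 1L)
  out <- data.frame(
    query_id = f(10),
    seq_name = f(14),
    start = num(16),
    end = num(17),
    strand = strand,
    matched_length = matches + mism + rep_m + n_count,
    identity = matches / (matches + mism + q_gap_bases),
    query_length = num(11),
    block_count = num(18),
    block_sizes = f(19),
    t_starts = f(21),
    stringsAsFactors = FALSE
  )
  if (any(out$matched_length > out$query_length))
    stop("malformed PSL line ", which(out$matched_length > out$query_length)[1],
         ": matched length exceeds query length")
  out
}
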