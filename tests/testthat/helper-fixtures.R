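# Shared fixture builders; everything is generated in code at test time.

# One PSL line (21 tab-separated fields). Coordinates 0-based half-open.
psl_line <- function(matches, mism = 0L, qname = "hsa-mir-x", qsize = matches + mism,
                     tname = "chr1", tstart = 1000L, strand = "+",
                     q_gap_bases = 0L, rep_matches = 0L, n_count = 0L,
                     block_sizes = NULL, t_starts = NULL) {
  span <- matches + mism + rep_matches + n_count
  tend <- tstart + span + 0L
  if (is.null(block_sizes)) {
    block_sizes <- paste0(span, ",")
    t_starts <- paste0(tstart, ",")
    block_count <- 1L
  } else {
    block_count <- length(strsplit(block_sizes, ",")[[1]])
    bs <- as.integer(strsplit(block_sizes, ",")[[1]])
    ts <- as.integer(strsplit(t_starts, ",")[[1]])
    tstart <- min(ts)
    tend <- max(ts + bs)
  }
  paste(matches, mism, rep_matches, n_count, 0L, q_gap_bases, 0L, 0L, strand,
        qname, qsize, 0L, matches + mism, tname, 50000000L, tstart, tend,
        block_count, block_sizes, "0,", t_starts, sep = "\t")
}

psl_header <- c(
  "psLayout version 3", "",
  "match\tmis- \trep. \tN's\tQ gap\tQ gap\tT gap\tT gap\tstrand\tQ        \tQ   \tQ    \tQ  \tT        \tT   \tT    \tT  \tblock\tblockSizes \tqStarts\t tStarts",
  "     \tmatch\tmatch\t   \tcount\tbases\tcount\tbases\t      \tname     \tsize\tstart\tend\tname     \tsize\tstart\tend\tcount",
  "---------------------------------------------------------------------------------------------------------------------------------------------------------------"
)

write_psl <- function(lines, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".psl", .local_envir = parent.frame())
  writeLines(c(if (header) psl_header, lines), path)
  path
}

write_mifam <- function(stanzas) {
  path <- withr::local_tempfile(fileext = ".dat", .local_envir = parent.frame())
  lines <- unlist(lapply(seq_along(stanzas), function(i) {
    members <- stanzas[[i]]
    c(sprintf("AC   MIPF%07d", i),
      sprintf("ID   fam-%d", i),
      sprintf("MI   MI%07d  %s", seq_along(members), members),
      "//")
  }))
  writeLines(lines, path)
  path
}

# Independent brute-force classifier for one alignment column; the oracle
# used against orient_and_count.
classify_column <- function(h, c_, o) {
  bases <- c("A", "C", "G", "T")
  if (!(h %in% bases) || !(c_ %in% bases) || !(o %in% bases)) return("excluded")
  if (h == c_ && h == o) return("invariant")
  if (h == c_ && h != o) return("orang_or_ancestral")
  if (o == c_) return("human")
  if (o == h) return("chimp")
  "multiallelic"
}

# Random gapped triplet alignment for property tests.
random_triplet <- function(width, p_gap = 0.05, p_n = 0.02) {
  draw <- function() {
    x <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    x[runif(width) < p_gap] <- "-"
    x[runif(width) < p_n] <- "N"
    x
  }
  triplet_alignment(paste(draw(), collapse = ""),
                    paste(draw(), collapse = ""),
                    paste(draw(), collapse = ""))
}

# Minimal simulation config for fast tests.
small_config <- function(n_ps = 20L, n_cf = 12L, seed = 7L, ...) {
  simulation_config(
    n_mirnas = c("primate-specific" = n_ps, "ConFam" = n_cf),
    seed = seed, ...
  )
}
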