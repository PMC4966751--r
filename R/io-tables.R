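#' Read per-sequence minimum free energies
#'
#' Two-column TSV: sequence id and folding minimum free energy in kcal/mol
#' (typically negative; more negative = more stable hairpin).
#'
#' @param path Path to the TSV (no header, or header `id<TAB>mfe`).
#' @return Data frame with columns `id`, `mfe`.
#' @export
read_mfe_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(df[[2]])) {          # header present
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  }
  names(df)[1:2] <- c("id", "mfe")
  if (!all(is.finite(df$mfe))) stop("non-finite MFE value in ", path)
  df[, c("id", "mfe")]
}

#' Read liftOver output intervals (BED6)
#'
#' @param path Path to a BED file (0-based half-open, as produced by liftOver).
#' @return Interval data frame: `seq_name`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    seq_name = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Read miRNA precursor/mature annotation from a miRBase-style GFF3
#'
#' Precursors are `miRNA_primary_transcript` records and matures are `miRNA`
#' records (linked to their precursor by the `Derives_from` attribute).
#' Coordinates are converted to 0-based half-open. Seed coordinates are
#' derived from each mature record as positions 2-8 of the mature sequence,
#' strand-aware.
#'
#' @param path Path to the GFF3 file.
#' @return List with interval data frames `precursors` (`mirna_id` column),
#'   `matures` (`mature_id`, `mirna_id`) and `seeds` (same keys; 7-bp spans).
#' @export
read_mirna_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  as_df <- function(g, id_col) {
    ids <- if (!is.null(g$Name)) as.character(g$Name) else as.character(g$ID)
    data.frame(
      seq_name = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      id = ids, stringsAsFactors = FALSE
    )
  }
  pre <- as_df(gr[gr$type == "miRNA_primary_transcript"])
  names(pre)[names(pre) == "id"] <- "mirna_id"
  mat_gr <- gr[gr$type == "miRNA"]
  mat <- as_df(mat_gr)
  names(mat)[names(mat) == "id"] <- "mature_id"
  mat$mirna_id <- if (length(mat_gr) && !is.null(mat_gr$Derives_from)) {
    acc2name <- setNames(
      as.character(gr$Name[gr$type == "miRNA_primary_transcript"]),
      as.character(gr$ID[gr$type == "miRNA_primary_transcript"])
    )
    unname(acc2name[as.character(mat_gr$Derives_from)])
  } else rep(NA_character_, nrow(mat))
  seeds <- mat
  if (nrow(seeds)) {
    plus <- seeds$strand != "-"
    s <- ifelse(plus, seeds$start + 1L, seeds$end - 8L)
    seeds$start <- as.integer(s)
    seeds$end <- as.integer(s + 7L)
  }
  list(precursors = pre, matures = mat, seeds = seeds)
}

#' Read a target-prediction table
#'
#' TSV with header columns `mirna_id`, `gene_id`, `conserved` (0/1 or
#' TRUE/FALSE), `context_score` (total context score, more negative =
#' stronger site).
#'
#' @param path Path to the TSV.
#' @return Data frame with those four columns; duplicate (miRNA, gene) pairs
#'   are collapsed keeping the best (lowest) context score.
#' @export
read_targets_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("mirna_id", "gene_id", "conserved", "context_score") %in% names(df)))
  df$conserved <- as.logical(df$conserved)
  ord <- order(df$mirna_id, df$gene_id, df$context_score)
  df <- df[ord, ]
  df[!duplicated(df[, c("mirna_id", "gene_id")]), , drop = FALSE]
}

#' Read a gene-to-GO-term map
#'
#' @param path TSV with header columns `gene_id`, `go_id`.
#' @return Data frame with unique (`gene_id`, `go_id`) rows.
#' @export
read_go_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "go_id") %in% names(df)))
  unique(df[, c("gene_id", "go_id")])
}
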