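# Sequence access for a genome represented as a named list
# (species -> named character vector of chromosome sequences, or
# DNAStringSet). Coordinates 0-based half-open; clipped at contig edges.
get_genome_seq <- function(genomes, species, seq_name, start, end) {
  g <- genomes[[species]]
  if (is.null(g)) stop("no genome for species ", species)
  chrom <- if (methods::is(g, "DNAStringSet")) as.character(g[[seq_name]])
           else g[[seq_name]]
  if (is.null(chrom)) stop("no sequence ", seq_name, " for species ", species)
  n <- nchar(chrom)
  s <- max(0L, start); e <- min(n, end)
  if (s >= e) return("")
  substr(chrom, s + 1L, e)
}

rev_comp <- function(x)
  paste(rev_comp_chars(strsplit(toupper(x), "", fixed = TRUE)[[1]]), collapse = "")

# Project a query onto a reference by global pairwise alignment: returns a
# character vector of length nchar(ref) giving the query base aligned to
# each reference position ('-' where the query has none); insertions
# relative to the reference are dropped.
project_onto_reference <- function(ref, qry) {
  nr <- nchar(ref)
  if (!nchar(qry)) return(rep("-", nr))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(qry), subject = Biostrings::DNAString(ref),
    type = "global-local", gapOpening = 4, gapExtension = 1
  )
  sub_chars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  pat_chars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  out <- rep("-", nr)
  ref_pos <- Biostrings::start(Biostrings::subject(pa)) - 1L
  keep <- sub_chars != "-"
  out[ref_pos + seq_len(sum(keep))] <- pat_chars[keep]
  out
}

#' Re-align three unaligned sequences onto the human reference
#'
#' Built-in re-aligner used for fixtures and the pipeline when no external
#' aligner output is supplied: the chimpanzee and orang-utan sequences are
#' each globally aligned to the human sequence and projected onto human
#' positions (insertions relative to human are dropped, consistent with the
#' human-anchored trimming applied downstream).
#'
#' @param human,chimp,orang Unaligned sequence strings.
#' @param id Optional locus id.
#' @return A [triplet_alignment] of width `nchar(human)`.
#' @export
align_triplet_to_human <- function(human, chimp, orang, id = NULL) {
  human <- toupper(human)
  triplet_alignment(
    human,
    paste(project_onto_reference(human, toupper(chimp)), collapse = ""),
    paste(project_onto_reference(human, toupper(orang)), collapse = ""),
    id = id
  )
}

#' Extract and align the 40-bp flanking regions of a locus
#'
#' Extracts `extract_width` bp upstream and downstream of the resolved
#' interval in each species (strand-aware: minus-strand loci are
#' reverse-complemented so flanks are read in transcript orientation),
#' aligns each species' flanks to the human flanks, and keeps the
#' `keep_width` bp immediately adjacent to the precursor on each side. The
#' locus is rejected when a species' resolved strand disagrees with the
#' precursor alignment (`strand` reason) or when a species covers less than
#' `min_coverage` of the targeted `2 * keep_width` bp (`flank_coverage`).
#'
#' @param intervals Named list (`human`, `chimp`, `orang`) of one-row
#'   interval data frames (`seq_name`, `start`, `end`, `strand`).
#' @param genomes Named list of genome sequence sets (see
#'   [simulate_triplets]).
#' @param keep_width Flank width kept per side (default 40).
#' @param extract_width Raw extraction width per side (default 100).
#' @param min_coverage Minimum aligned fraction of the kept flanks
#'   (default 0.5).
#' @param precursor_strand Strand of the precursor alignment per species
#'   (named vector); defaults to the interval strands.
#' @param id Optional locus id.
#' @return A [triplet_alignment] of width `2 * keep_width` (left flank then
#'   right flank), or a `curation_rejection`.
#' @export
extract_flank_alignment <- function(intervals, genomes, keep_width = 40L,
                                    extract_width = 100L, min_coverage = 0.5,
                                    precursor_strand = NULL, id = NULL) {
  stopifnot(all(TRIO_SPECIES %in% names(intervals)))
  if (!is.null(precursor_strand)) {
    for (sp in names(precursor_strand)) {
      if (intervals[[sp]]$strand != precursor_strand[[sp]])
        return(structure(list(id = id, reason = "strand",
                              detail = paste0(sp, " flank strand discordant ",
                                              "with precursor alignment")),
                         class = "curation_rejection"))
    }
  }
  flank <- function(sp) {
    iv <- intervals[[sp]]
    up <- get_genome_seq(genomes, sp, iv$seq_name, iv$start - extract_width, iv$start)
    dn <- get_genome_seq(genomes, sp, iv$seq_name, iv$end, iv$end + extract_width)
    if (iv$strand == "-") list(up = rev_comp(dn), dn = rev_comp(up))
    else list(up = up, dn = dn)
  }
  fh <- flank("human")
  # kept human flanks: the keep_width bases immediately adjacent to the locus
  up_h <- substr(fh$up, max(1L, nchar(fh$up) - keep_width + 1L), nchar(fh$up))
  dn_h <- substr(fh$dn, 1L, keep_width)
  rows <- list(human = paste0(up_h, dn_h))
  for (sp in c("chimp", "orang")) {
    fs <- flank(sp)
    up_p <- project_onto_reference(fh$up, fs$up)
    dn_p <- project_onto_reference(fh$dn, fs$dn)
    up_keep <- tail(up_p, nchar(up_h))
    dn_keep <- head(dn_p, nchar(dn_h))
    rows[[sp]] <- paste(c(up_keep, dn_keep), collapse = "")
  }
  target <- 2L * keep_width
  for (sp in c("chimp", "orang")) {
    covered <- sum(strsplit(rows[[sp]], "")[[1]] != "-")
    if (covered < min_coverage * target)
      return(structure(list(id = id, reason = "flank_coverage",
                            detail = sprintf("%s flank aligns over %d of %d bp",
                                             sp, covered, target)),
                       class = "curation_rejection"))
  }
  if (nchar(rows$human) < min_coverage * target)
    return(structure(list(id = id, reason = "flank_coverage",
                          detail = "human flank truncated at contig edge"),
                     class = "curation_rejection"))
  triplet_alignment(rows$human, rows$chimp, rows$orang, id = id)
}
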