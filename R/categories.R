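#' Cluster assignment for miRNA precursors
#'
#' A cluster is a run of two or more miRNAs on the same chromosome and
#' strand, each at less than `max_gap` bp from the next (single-linkage
#' chaining on the end-to-start gap between adjacent precursors). miRNAs not
#' in any such run are non-clustered. Assignment is invariant to input
#' order.
#'
#' @param mirnas Interval data frame with columns `mirna_id`, `seq_name`,
#'   `start`, `end`, `strand`.
#' @param max_gap Gap threshold in bp (default 10 kb).
#' @return Data frame `mirna_id`, `clustered` (`"clustered"`/
#'   `"non-clustered"`), `cluster_id` (NA for singletons), in input order.
#' @export
assign_clusters <- function(mirnas, max_gap = 10000L) {
  stopifnot(all(c("mirna_id", "seq_name", "start", "end", "strand") %in% names(mirnas)))
  n <- nrow(mirnas)
  ord <- order(mirnas$seq_name, mirnas$strand, mirnas$start, mirnas$end)
  s <- mirnas[ord, ]
  cluster <- integer(n)
  cid <- 0L
  if (n) {
    cid <- 1L
    cluster[1L] <- 1L
    if (n > 1L) for (i in 2:n) {
      same <- s$seq_name[i] == s$seq_name[i - 1L] & s$strand[i] == s$strand[i - 1L]
      gap <- s$start[i] - s$end[i - 1L]
      if (!same || gap >= max_gap) cid <- cid + 1L
      cluster[i] <- cid
    }
  }
  sizes <- table(cluster)
  clustered <- as.integer(sizes[as.character(cluster)]) >= 2L
  out <- data.frame(
    mirna_id = s$mirna_id,
    clustered = ifelse(clustered, "clustered", "non-clustered"),
    cluster_id = ifelse(clustered, paste0("cluster_", cluster), NA_character_),
    stringsAsFactors = FALSE
  )
  out[match(mirnas$mirna_id, out$mirna_id), , drop = FALSE]
}

#' Copy-number and conservation classification from a family map
#'
#' A miRNA is multiple-copy iff it belongs to a family with two or more
#' members. Conservation class: `primate-specific` when every species in the
#' family is a primate, or when the miRNA is an orphan human entry absent
#' from the family file; `ConFam` when the family has at least one
#' non-primate member. The `no-primate` class cannot apply to human query
#' miRNAs; if a queried id sits in a family without any primate member it is
#' flagged with a warning.
#'
#' @param ids Character vector of human miRNA ids.
#' @param families A `family_map` from [read_family_file].
#' @return Data frame `mirna_id`, `copies` (`"multiple"`/`"single"`),
#'   `conservation` (`"primate-specific"`/`"ConFam"`), `family_id`.
#' @export
assign_copies_and_conservation <- function(ids, families) {
  mem <- families$members
  fam_of <- setNames(mem$family_id, mem$mirna_id)
  fam_size <- lengths(families$families)
  fam_all_primate <- vapply(families$families, function(ms)
    all(mem$primate[match(ms, mem$mirna_id)]), logical(1))
  fam_any_primate <- vapply(families$families, function(ms)
    any(mem$primate[match(ms, mem$mirna_id)]), logical(1))
  fid <- unname(fam_of[ids])
  orphan <- is.na(fid)
  copies <- ifelse(!orphan & fam_size[fid] >= 2L, "multiple", "single")
  conservation <- ifelse(orphan | fam_all_primate[fid], "primate-specific", "ConFam")
  no_primate <- !orphan & !fam_any_primate[fid]
  if (any(no_primate))
    warning("query miRNA in a family with no primate member: ",
            paste(ids[no_primate], collapse = ", "))
  data.frame(mirna_id = ids, copies = copies, conservation = conservation,
             family_id = ifelse(orphan, NA_character_, fid),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genomic context of a miRNA relative to protein-coding genes
#'
#' `genic:exon` when at least one nucleotide overlaps an annotated exon
#' (exon wins over UTR and intron); else `genic:UTR` / `genic:intron` by
#' overlap with those parts; `intergenic` when the nearest protein-coding
#' gene is more than `intergenic_distance` bp away; miRNAs within that
#' distance but overlapping no gene part are `unassigned` (the
#' genic/intergenic dichotomy leaves them undefined and they are excluded
#' from context contrasts).
#'
#' @param mirnas Interval data frame with `mirna_id`.
#' @param genes List of interval data frames: `genes` (whole gene spans) and
#'   `parts` (with a `part` column in `exon`/`intron`/`UTR`).
#' @param intergenic_distance Distance threshold in bp (default 50 kb).
#' @return Data frame `mirna_id`, `context`.
#' @export
assign_context <- function(mirnas, genes, intergenic_distance = 50000L) {
  gr_mir <- as_granges(mirnas)
  GenomicRanges::strand(gr_mir) <- "*"
  part_hit <- function(part) {
    p <- genes$parts[genes$parts$part == part, , drop = FALSE]
    if (!nrow(p)) return(rep(FALSE, nrow(mirnas)))
    gp <- as_granges(p)
    GenomicRanges::strand(gp) <- "*"
    IRanges::overlapsAny(gr_mir, gp)
  }
  in_exon <- part_hit("exon")
  in_utr <- part_hit("UTR")
  in_intron <- part_hit("intron")
  gg <- as_granges(genes$genes)
  GenomicRanges::strand(gg) <- "*"
  d <- GenomicRanges::distanceToNearest(gr_mir, gg)
  dist <- rep(Inf, nrow(mirnas))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  context <- ifelse(in_exon, "genic:exon",
             ifelse(in_utr, "genic:UTR",
             ifelse(in_intron, "genic:intron",
             ifelse(dist > intergenic_distance, "intergenic", "unassigned"))))
  data.frame(mirna_id = mirnas$mirna_id, context = context,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate two category axes and test independence
#'
#' Fisher's exact test (two-sided) on the 2x2 cross-tabulation of two label
#' axes, e.g. copy number against clustering.
#'
#' @param labels Data frame of category labels.
#' @param axis_a,axis_b Column names in `labels`.
#' @return List with `table` and `p`. A degenerate margin gives `p = 1`
#'   with a warning.
#' @export
category_contingency <- function(labels, axis_a, axis_b) {
  tab <- table(labels[[axis_a]], labels[[axis_b]])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("degenerate margin in ", axis_a, " x ", axis_b, "; p set to 1")
    return(list(table = tab, p = 1))
  }
  list(table = tab, p = fisher.test(tab)$p.value)
}

#' Concatenate alignments of one category
#'
#' Column-wise concatenation of member alignments, recording per-locus
#' boundaries so that category bootstraps can resample at the miRNA level.
#' Any counting statistic on the concatenated alignment equals the sum over
#' members.
#'
#' @param alignments List of [triplet_alignment] objects.
#' @return A [triplet_alignment] with attribute `boundaries` (data frame
#'   `id`, `start`, `end`, 1-based column spans). An empty input yields a
#'   zero-width alignment flagged with attribute `empty = TRUE`.
#' @export
concatenate_by_category <- function(alignments) {
  if (!length(alignments)) {
    out <- triplet_alignment("", "", "", id = "empty")
    attr(out, "boundaries") <- data.frame(id = character(), start = integer(),
                                          end = integer())
    attr(out, "empty") <- TRUE
    return(out)
  }
  widths <- vapply(alignments, `[[`, numeric(1), "width")
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  seqs <- vapply(TRIO_SPECIES, function(sp)
    paste(vapply(alignments, function(a) a$seqs[[sp]], character(1)),
          collapse = ""), character(1))
  out <- triplet_alignment(seqs[["human"]], seqs[["chimp"]], seqs[["orang"]])
  attr(out, "boundaries") <- data.frame(
    id = vapply(seq_along(alignments), function(i)
      alignments[[i]]$id %||% as.character(i), character(1)),
    start = as.integer(starts), end = as.integer(ends),
    stringsAsFactors = FALSE
  )
  out
}
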