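#' Pick the best BLAT hit for one query
#'
#' Hits shorter than `min_coverage` of the query length are dropped (they are
#' classified with non-matching miRNAs); survivors are ordered by matched
#' length (descending), then identity (descending), with a deterministic
#' (`seq_name`, `start`) tie-break so the result is invariant to input
#' order. Exact ties on both length and identity are flagged `ambiguous`.
#'
#' @param hits Data frame of hits from [read_psl], all for one query.
#' @param min_coverage Minimum matched length as a fraction of the query
#'   length (default 0.8).
#' @return The selected hit (one-row data frame with an `ambiguous` column),
#'   or `NULL` when no hit survives.
#' @export
select_best_blat_hit <- function(hits, min_coverage = 0.8) {
  if (is.null(hits) || !nrow(hits)) return(NULL)
  if (length(unique(hits$query_id)) > 1L)
    stop("hits mix query ids: ", paste(unique(hits$query_id), collapse = ", "))
  keep <- hits[hits$matched_length >= min_coverage * hits$query_length, , drop = FALSE]
  if (!nrow(keep)) return(NULL)
  ord <- order(-keep$matched_length, -keep$identity, keep$seq_name, keep$start)
  keep <- keep[ord, , drop = FALSE]
  best <- keep[1L, , drop = FALSE]
  best$ambiguous <- nrow(keep) > 1L &&
    keep$matched_length[2L] == best$matched_length &&
    keep$identity[2L] == best$identity
  rownames(best) <- NULL
  best
}

#' Reconcile BLAT and liftOver evidence for one species
#'
#' When both sources exist, overlap by at least one bp and agree in strand,
#' the call interval spans the leftmost start to the rightmost end of the
#' intersecting set and the evidence class is `blat+liftover`. With only a
#' liftOver interval the class is `liftover_only`; with only a BLAT hit,
#' `blat_only`. Discordant sources (different chromosome, no overlap, or a
#' strand conflict) drop the call (`discordant`, no interval).
#'
#' @param blat Best BLAT hit (one-row data frame) or `NULL`.
#' @param lifted liftOver interval (one-row data frame with `seq_name`,
#'   `start`, `end`, `strand`) or `NULL`.
#' @return List with `interval` (one-row data frame or `NULL`) and
#'   `evidence` in `{"blat+liftover", "blat_only", "liftover_only",
#'   "discordant", "none"}`.
#' @export
resolve_orthology <- function(blat, lifted) {
  has_b <- !is.null(blat) && nrow(blat) > 0
  has_l <- !is.null(lifted) && nrow(lifted) > 0
  if (!has_b && !has_l) return(list(interval = NULL, evidence = "none"))
  if (has_b && !has_l) {
    iv <- data.frame(seq_name = blat$seq_name, start = blat$start,
                     end = blat$end, strand = blat$strand,
                     stringsAsFactors = FALSE)
    return(list(interval = iv, evidence = "blat_only"))
  }
  if (!has_b && has_l) {
    iv <- lifted[, c("seq_name", "start", "end", "strand")]
    rownames(iv) <- NULL
    return(list(interval = iv, evidence = "liftover_only"))
  }
  same_chr <- blat$seq_name == lifted$seq_name
  same_strand <- blat$strand == lifted$strand
  overlap <- min(blat$end, lifted$end) - max(blat$start, lifted$start)
  if (!same_chr || !same_strand || overlap < 1L)
    return(list(interval = NULL, evidence = "discordant"))
  iv <- data.frame(seq_name = blat$seq_name,
                   start = min(blat$start, lifted$start),
                   end = max(blat$end, lifted$end),
                   strand = blat$strand, stringsAsFactors = FALSE)
  list(interval = iv, evidence = "blat+liftover")
}

#' Resolve orthology calls for a set of miRNAs in both species
#'
#' Applies [select_best_blat_hit] and [resolve_orthology] per miRNA and
#' species. A call is retained only when an interval was resolved in both
#' chimpanzee and orang-utan (liftOver fills in for missing BLAT evidence;
#' discordant evidence drops the species and hence the call).
#'
#' @param mirna_ids Character vector of query ids.
#' @param blat_hits Named list (`chimp`, `orang`) of PSL data frames.
#' @param lifted Named list (`chimp`, `orang`) of interval data frames with
#'   a `name` column carrying the miRNA id.
#' @return Data frame of calls: `mirna_id`, per-species `evidence`,
#'   interval columns (`seq_name_chimp`, ...), and `retained`.
#' @export
resolve_orthology_set <- function(mirna_ids, blat_hits, lifted) {
  res <- lapply(mirna_ids, function(id) {
    row <- list(mirna_id = id)
    for (sp in c("chimp", "orang")) {
      h <- blat_hits[[sp]]
      h <- if (is.null(h)) NULL else h[h$query_id == id, , drop = FALSE]
      best <- select_best_blat_hit(h)
      lv <- lifted[[sp]]
      lv <- if (is.null(lv)) NULL else lv[lv$name == id, , drop = FALSE]
      if (!is.null(lv) && nrow(lv) > 1L) lv <- lv[1L, , drop = FALSE]
      call <- resolve_orthology(best, lv)
      row[[paste0("evidence_", sp)]] <- call$evidence
      iv <- call$interval
      row[[paste0("seq_name_", sp)]] <- if (is.null(iv)) NA_character_ else iv$seq_name
      row[[paste0("start_", sp)]] <- if (is.null(iv)) NA_integer_ else iv$start
      row[[paste0("end_", sp)]] <- if (is.null(iv)) NA_integer_ else iv$end
      row[[paste0("strand_", sp)]] <- if (is.null(iv)) NA_character_ else iv$strand
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$retained <- !is.na(out$start_chimp) & !is.na(out$start_orang)
  out
}

#' Remove many-to-one orthology groups
#'
#' Any group of two or more human miRNAs whose resolved intervals in the
#' same species overlap reciprocally by at least `min_overlap` (fraction of
#' each interval) is removed entirely — several query loci resolving to one
#' target locus violates the orthology assumption.
#'
#' @param calls Data frame from [resolve_orthology_set] (retained rows are
#'   examined).
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return List with `calls` (the surviving rows), `removed` (ids) and
#'   `n_removed`.
#' @export
exclude_many_to_one <- function(calls, min_overlap = 0.5) {
  live <- which(calls$retained %||% rep(TRUE, nrow(calls)))
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (sp in c("chimp", "orang")) {
    df <- data.frame(seq_name = calls[[paste0("seq_name_", sp)]][live],
                     start = calls[[paste0("start_", sp)]][live],
                     end = calls[[paste0("end_", sp)]][live])
    ok <- stats::complete.cases(df)
    if (!any(ok)) next
    gr <- as_granges(df[ok, , drop = FALSE])
    hits <- GenomicRanges::findOverlaps(gr, gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    sel <- qh < sh
    qh <- qh[sel]; sh <- sh[sel]
    if (!length(qh)) next
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr)[qh], IRanges::ranges(gr)[sh]))
    w1 <- IRanges::width(gr)[qh]; w2 <- IRanges::width(gr)[sh]
    recip <- ov >= min_overlap * w1 & ov >= min_overlap * w2
    idx <- live[ok]
    for (k in which(recip)) union_(idx[qh[k]], idx[sh[k]])
  }
  roots <- vapply(live, find, integer(1))
  grp_size <- table(roots)
  bad <- live[grp_size[as.character(roots)] >= 2L]
  keep <- setdiff(seq_len(n), bad)
  list(calls = calls[keep, , drop = FALSE],
       removed = calls$mirna_id[bad],
       n_removed = length(bad))
}

#' Trim an alignment to the human precursor span and apply quality filters
#'
#' The alignment is trimmed to the columns spanned by the human miRNA
#' precursor. It is rejected when a non-human row covers less than
#' `min_coverage` of the human precursor length, or when the human row
#' carries an internal gap longer than `max_internal_gap` nucleotides.
#'
#' @param aln A [triplet_alignment]; the human row may include flanking
#'   columns around the precursor.
#' @param human_span 1-based inclusive positions of the precursor within the
#'   ungapped human row (`c(start, end)`); defaults to the whole row.
#' @param min_coverage Coverage fraction (default 0.8).
#' @param max_internal_gap Longest tolerated internal human gap (default 20).
#' @return The trimmed [triplet_alignment], or a `curation_rejection`
#'   (list with `reason` in `{"coverage", "gap"}` and `detail`).
#' @export
trim_and_filter_alignment <- function(aln, human_span = NULL,
                                      min_coverage = 0.8,
                                      max_internal_gap = 20L) {
  m <- as.matrix(aln)
  hum <- m[1L, ]
  pos <- cumsum(hum != "-")
  n_bases <- pos[length(pos)]
  if (is.null(human_span)) human_span <- c(1L, n_bases)
  s <- human_span[1]; e <- human_span[2]
  stopifnot(s >= 1L, e <= n_bases, s <= e)
  # span: first column carrying base s through last column carrying base e;
  # internal human-gap columns inside the span are retained
  first <- min(which(pos == s & hum != "-"))
  last <- max(which(pos == e & hum != "-"))
  cols <- first:last
  mm <- m[, cols, drop = FALSE]
  pre_len <- e - s + 1L
  hrow <- mm[1L, ]
  runs <- rle(hrow == "-")
  internal <- runs$lengths[runs$values]
  if (length(internal) && max(internal) > max_internal_gap)
    return(structure(list(id = aln$id, reason = "gap",
                          detail = paste0("internal human gap of ",
                                          max(internal), " nt")),
                     class = "curation_rejection"))
  for (sp in c(2L, 3L)) {
    cov <- sum(mm[sp, ] != "-") / pre_len
    if (cov < min_coverage)
      return(structure(list(id = aln$id, reason = "coverage",
                            detail = sprintf("%s covers %.0f%% of human precursor",
                                             rownames(mm)[sp], 100 * cov)),
                       class = "curation_rejection"))
  }
  triplet_from_matrix(mm, id = aln$id)
}

#' @export
print.curation_rejection <- function(x, ...) {
  cat("rejected", x$id %||% "", "(", x$reason, "):", x$detail, "\n")
  invisible(x)
}

#' Filter triplets by folding minimum free energy
#'
#' The threshold is the 95th percentile (towards less-negative, less-stable
#' values) of the human reference MFE distribution: a hairpin beyond the 5%
#' right tail of real human miRNA energies is not a credible miRNA
#' structure. A triplet is rejected when any of its three sequences has an
#' MFE above the threshold.
#'
#' @param alignments Named list of [triplet_alignment] objects.
#' @param mfes Data frame (`id`, `mfe`) with ids `"<locus>|<species>"`.
#' @param human_reference_mfes Numeric vector (or `id`/`mfe` data frame) of
#'   MFEs for the full human miRNA complement.
#' @param tail Right-tail mass defining the threshold (default 0.05).
#' @return List with `kept`, `rejected` (named lists) and `threshold`.
#' @export
mfe_filter <- function(alignments, mfes, human_reference_mfes, tail = 0.05) {
  ref <- if (is.data.frame(human_reference_mfes)) human_reference_mfes$mfe
         else human_reference_mfes
  threshold <- quantile(ref, 1 - tail, names = FALSE)   # linear interpolation
  mfe_of <- setNames(mfes$mfe, mfes$id)
  kept <- list(); rejected <- list()
  for (id in names(alignments)) {
    keys <- paste(id, TRIO_SPECIES, sep = "|")
    missing <- keys[!keys %in% names(mfe_of)]
    if (length(missing))
      stop("missing MFE record for sequence: ", missing[1])
    if (any(mfe_of[keys] > threshold)) rejected[[id]] <- alignments[[id]]
    else kept[[id]] <- alignments[[id]]
  }
  list(kept = kept, rejected = rejected, threshold = threshold)
}

#' Curate ancestral repeats for use as neutral references
#'
#' Keeps ancestral repeats that survived reciprocal liftOver in all three
#' species, whose length lies within the interquartile band of human miRNA
#' precursor lengths (70-91 bp), and that lift to the same chromosome in
#' every species.
#'
#' @param ars Data frame with columns `ar_id`, `length`,
#'   `reciprocal_chimp`, `reciprocal_orang` (logical), `seq_name`
#'   (human), `seq_name_chimp`, `seq_name_orang`.
#' @param length_range Allowed length range (default `c(70, 91)`).
#' @return The surviving rows, with attribute `n_removed`.
#' @export
curate_ancestral_repeats <- function(ars, length_range = c(70L, 91L)) {
  same_chr <- ars$seq_name == ars$seq_name_chimp &
    ars$seq_name == ars$seq_name_orang
  ok <- ars$reciprocal_chimp & ars$reciprocal_orang &
    ars$length >= length_range[1] & ars$length <= length_range[2] &
    same_chr
  out <- ars[ok, , drop = FALSE]
  attr(out, "n_removed") <- sum(!ok)
  out
}
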