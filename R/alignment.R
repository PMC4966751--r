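#' Three-species alignment container
#'
#' A `triplet_alignment` holds the gapped rows of one aligned locus for human,
#' chimpanzee and orang-utan, in that fixed order. Rows are stored uppercase;
#' `-` marks gaps and `N` (or any non-ACGT letter) is treated as ambiguity by
#' the counting code.
#'
#' @param human,chimp,orang Gapped sequence strings of equal length.
#' @param id Optional locus identifier.
#' @return An object of class `triplet_alignment`.
#' @examples
#' triplet_alignment("ACGT", "ACGT", "ACTT", id = "mir-x")
#' @export
triplet_alignment <- function(human, chimp, orang, id = NULL) {
  seqs <- toupper(c(human = human, chimp = chimp, orang = orang))
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("alignment rows differ in length: ", paste(nchar(seqs), collapse = ", "))
  structure(list(id = id, seqs = seqs, width = w),
            class = "triplet_alignment")
}

#' @export
print.triplet_alignment <- function(x, ...) {
  cat("triplet_alignment", if (!is.null(x$id)) paste0("'", x$id, "'"),
      "width", x$width, "\n")
  for (sp in names(x$seqs)) {
    s <- x$seqs[[sp]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-6s %s\n", sp, s))
  }
  invisible(x)
}

#' @export
as.matrix.triplet_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$seqs), "", fixed = TRUE))
  rownames(m) <- names(x$seqs)
  m
}

# Rebuild a triplet_alignment from a 3 x W character matrix.
triplet_from_matrix <- function(m, id = NULL) {
  triplet_alignment(paste(m[1L, ], collapse = ""),
                    paste(m[2L, ], collapse = ""),
                    paste(m[3L, ], collapse = ""), id = id)
}

#' Read a three-species alignment
#'
#' Accepts aligned FASTA or ClustalW (`.aln`) files containing exactly three
#' records. Species are recognised from record names: `human`/`hsa`/`hg`,
#' `chimp`/`ptr`/`pan`, `orang`/`ppy`/`pon` (case-insensitive). Rows are
#' case-normalised to uppercase and returned in fixed species order.
#'
#' @param path Path to the alignment file.
#' @return A [triplet_alignment].
#' @export
read_alignment <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && grepl("^CLUSTAL", first)) {
    seqs <- .read_clustal(path)
  } else {
    xs <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(xs), names(xs))
  }
  if (length(seqs) != 3L)
    stop("expected exactly 3 records, found ", length(seqs))
  tags <- vapply(names(seqs), .species_tag, character(1))
  if (anyNA(tags) || anyDuplicated(tags))
    stop("could not assign records to human/chimp/orang; found tags: ",
         paste(names(seqs), collapse = ", "))
  seqs <- seqs[match(TRIO_SPECIES, tags)]
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows differ in length in ", path)
  id <- sub("^[^|]*\\|", "", names(seqs)[1])
  if (identical(id, names(seqs)[1])) id <- NULL
  triplet_alignment(seqs[[1]], seqs[[2]], seqs[[3]], id = id)
}

.species_tag <- function(nm) {
  # the leading token (before any '|') decides; locus ids after '|' may
  # themselves contain species prefixes like 'hsa-'
  probe <- function(x) {
    if (grepl("human|hsa|hg19", x)) return("human")
    if (grepl("chimp|ptr|pantro|pan_", x)) return("chimp")
    if (grepl("orang|ppy|ponabe|pongo", x)) return("orang")
    NA_character_
  }
  lead <- probe(tolower(sub("\\|.*$", "", nm)))
  if (!is.na(lead)) lead else probe(tolower(nm))
}

.read_clustal <- function(path) {
  lines <- readLines(path)
  lines <- lines[-1L]                              # header
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s", lines)]            # conservation rows
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[[`, character(1), 1L)
  chunk <- vapply(parts, `[[`, character(1), 2L)
  vapply(split(chunk, factor(ids, levels = unique(ids))),
         paste, character(1), collapse = "")
}

#' Write a three-species alignment as aligned FASTA
#'
#' @param aln A [triplet_alignment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  nm <- names(aln$seqs)
  if (!is.null(aln$id)) nm <- paste0(nm, "|", aln$id)
  xs <- Biostrings::BStringSet(setNames(unname(aln$seqs), nm))
  Biostrings::writeXStringSet(xs, path, width = 80L)
  invisible(path)
}
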