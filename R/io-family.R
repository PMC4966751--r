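#' Read a miRNA family file (miFam.dat layout)
#'
#' Parses the miRBase family file format: stanzas opened by `AC`/`ID` lines,
#' followed by `MI <accession> <mirna-name>` member lines and terminated by
#' `//`. The species of each member is taken from its name prefix
#' (`hsa-`, `ptr-`, `mmu-`, ...). Each miRNA belongs to exactly one family;
#' ids not present in the file are orphans (absent from the map).
#'
#' @param path Path to the family file.
#' @return A list of class `family_map` with elements `members` (data frame:
#'   `mirna_id`, `family_id`, `species_prefix`, `primate`) and `families`
#'   (named list of member id vectors).
#' @export
read_family_file <- function(path) {
  lines <- readLines(path)
  members <- list()
  fam <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^ID\\s", ln)) {
      fam <- trimws(sub("^ID\\s+", "", ln))
    } else if (grepl("^AC\\s", ln)) {
      if (is.null(fam)) fam <- trimws(sub("^AC\\s+", "", ln))
    } else if (grepl("^MI\\s", ln)) {
      if (is.null(fam))
        stop("family file parse error at line ", i, ": MI line outside a stanza")
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      mirna <- parts[[length(parts)]]
      members[[length(members) + 1L]] <- c(fam, mirna)
    } else if (grepl("^//", ln)) {
      fam <- NULL
    }
  }
  if (length(members)) {
    m <- do.call(rbind, members)
    prefix <- sub("-.*$", "", m[, 2L])
    members <- data.frame(
      mirna_id = m[, 2L], family_id = m[, 1L], species_prefix = prefix,
      primate = prefix %in% PRIMATE_PREFIXES, stringsAsFactors = FALSE
    )
  } else {
    members <- data.frame(mirna_id = character(), family_id = character(),
                          species_prefix = character(), primate = logical(),
                          stringsAsFactors = FALSE)
  }
  if (anyDuplicated(members$mirna_id))
    stop("family file: miRNA assigned to more than one family: ",
         members$mirna_id[duplicated(members$mirna_id)][1])
  structure(
    list(members = members,
         families = split(members$mirna_id, members$family_id)),
    class = "family_map"
  )
}

#' @export
print.family_map <- function(x, ...) {
  cat("family_map:", length(x$families), "families,",
      nrow(x$members), "members\n")
  invisible(x)
}
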