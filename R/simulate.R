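#' Configuration for the synthetic triplet-data generator
#'
#' Defines the conditions of a simulated three-species miRNA dataset:
#' per-category locus counts, per-branch substitution rates for precursors
#' and flanking regions, CpG hypermutability, weak-to-strong fixation bias,
#' fabricated folding energies, and the flank geometry. Defaults reproduce
#' the regime of the real curated dataset: 840 primate-specific and 374
#' conserved-family (ConFam) precursors of 70-91 bp, primate-specific human
#' branch rate 0.0056 against ConFam 0.0014, CpG sites mutating an order of
#' magnitude faster, a W>S fixation bias of 0.39, and hairpin minimum free
#' energies around -37.9 kcal/mol.
#'
#' @param n_mirnas Named integer vector: loci per category.
#' @param branch_rates Named list (one entry per category) of
#'   `c(human=, chimp=, orang=)` substitutions/site on each branch of the
#'   precursor. The orang-utan branch covers outgroup divergence and is
#'   roughly 2.5x the human branch by default.
#' @param flank_rates Same shape, for the 40-bp flanking regions.
#' @param neutral_rates `c(human=, chimp=, orang=)` for neutral reference
#'   loci (ancestral-repeat regime).
#' @param cpg_multiplier Rate multiplier (>= 1) at CpG dinucleotide sites.
#' @param ws_bias Probability in `[0, 1]` that a fixed change originating at
#'   a weak (A/T) site creates a strong (G/C) allele, and that a change at a
#'   strong site stays strong; 0.5 is unbiased.
#' @param mfe_mean,mfe_sd Normal parameters (kcal/mol) for fabricated
#'   per-sequence minimum free energies.
#' @param flank_length Flank width kept on each side (bp).
#' @param flank_extract Raw extraction width on each side for the genome
#'   fixtures (bp).
#' @param indel_rate Per-locus probability of injecting one gap run
#'   (disabled by default; used only to exercise gap/coverage filters).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_mirnas = c("primate-specific" = 840L, "ConFam" = 374L),
    branch_rates = list(
      "primate-specific" = c(human = 0.0056, chimp = 0.0066, orang = 0.014),
      "ConFam" = c(human = 0.0014, chimp = 0.0022, orang = 0.0035)
    ),
    flank_rates = list(
      "primate-specific" = c(human = 0.0065, chimp = 0.0070, orang = 0.016),
      "ConFam" = c(human = 0.0048, chimp = 0.0052, orang = 0.012)
    ),
    neutral_rates = c(human = 0.0053, chimp = 0.0059, orang = 0.013),
    cpg_multiplier = 10,
    ws_bias = 0.39,
    mfe_mean = -37.9,
    mfe_sd = 8,
    flank_length = 40L,
    flank_extract = 100L,
    indel_rate = 0,
    seed = 1L) {
  stopifnot(
    all(n_mirnas >= 0), length(n_mirnas) >= 1L, !is.null(names(n_mirnas)),
    all(names(n_mirnas) %in% names(branch_rates)),
    all(names(n_mirnas) %in% names(flank_rates)),
    all(unlist(branch_rates) >= 0), all(unlist(flank_rates) >= 0),
    all(neutral_rates >= 0), cpg_multiplier >= 1,
    ws_bias >= 0, ws_bias <= 1, mfe_sd >= 0,
    flank_length >= 1, flank_extract >= flank_length,
    indel_rate >= 0, indel_rate <= 1
  )
  structure(as.list(environment()), class = "simulation_config")
}

BASES <- c("A", "C", "G", "T")
.other_weak <- c(A = "T", T = "A")
.other_strong <- c(C = "G", G = "C")

.random_seq <- function(n) sample(BASES, n, replace = TRUE)

# CpG flags for a base vector; locus_id prevents dinucleotides from spanning
# locus boundaries.
.cpg_flags <- function(chars, locus_id = NULL) {
  n <- length(chars)
  if (n < 2L) return(rep(FALSE, n))
  nxt <- c(chars[-1L], "X")
  same <- if (is.null(locus_id)) rep(TRUE, n) else c(locus_id[-1L] == locus_id[-n], FALSE)
  is_c <- chars == "C" & nxt == "G" & same
  flag <- is_c
  flag[which(is_c) + 1L] <- TRUE
  flag
}

# One branch of per-site Bernoulli substitutions (no multiple hits).
# `rate` may be a scalar or per-site vector and is the *marginal* per-site
# rate: the CpG multiplier is a relative risk, renormalised so the mean
# substitution probability over the sequence stays at `rate`. Fixed changes
# at weak sites go weak->strong with probability ws_bias; at strong sites
# they stay strong with probability ws_bias (so with a balanced ancestor
# the realised W>S/(W>S + S>W) fraction equals ws_bias).
.evolve_branch <- function(anc, rate, cpg_multiplier, ws_bias, locus_id = NULL) {
  n <- length(anc)
  p <- rep_len(rate, n)
  if (cpg_multiplier != 1) {
    cpg <- .cpg_flags(anc, locus_id)
    w <- ifelse(cpg, cpg_multiplier, 1)
    p <- p * w / mean(w)
  }
  p <- pmin(p, 0.95)
  hit <- runif(n) < p
  idx <- which(hit)
  if (!length(idx)) return(anc)
  src <- anc[idx]
  strong <- src %in% c("C", "G")
  to_strong <- runif(length(idx)) < ws_bias
  derived <- character(length(idx))
  w_to_s <- !strong & to_strong
  w_to_w <- !strong & !to_strong
  s_to_s <- strong & to_strong
  s_to_w <- strong & !to_strong
  derived[w_to_s] <- sample(c("C", "G"), sum(w_to_s), replace = TRUE)
  derived[w_to_w] <- .other_weak[src[w_to_w]]
  derived[s_to_s] <- .other_strong[src[s_to_s]]
  derived[s_to_w] <- sample(c("A", "T"), sum(s_to_w), replace = TRUE)
  out <- anc
  out[idx] <- derived
  out
}

#' Simulate a three-species miRNA dataset with known parameters
#'
#' For each locus an ancestral sequence (precursor of 70-91 bp plus
#' flanks) is drawn with balanced base composition, and three descendant
#' sequences are produced by sprinkling independent per-site substitutions
#' on the human, chimp and orang-utan branches at the configured category
#' rates, with CpG sites mutating at `cpg_multiplier` times the base rate
#' and fixed changes drawn weak-to-strong with probability `ws_bias`. The
#' emitted orang-utan row is the ancestor plus its own branch noise, so
#' multiallelic columns arise naturally and exercise the orientation rule.
#' The generator also lays the loci out on a synthetic chromosome (cluster
#' pairs < 10 kb apart, isolated loci 60 kb apart), builds a matching gene
#' annotation, family file, fabricated folding energies, and true
#' per-branch substitution counts for recovery tests.
#'
#' @param config A [simulation_config].
#' @param genomes Also assemble full synthetic chromosome sequences per
#'   species? Memory-heavy for thousands of loci; enable for curation-level
#'   fixtures only.
#' @return A list of class `triplet_simulation`; see Details. Deterministic
#'   given `config$seed`.
#' @export
simulate_triplets <- function(config, genomes = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  withr_seed(config$seed, .simulate_triplets_impl(config, genomes))
}

.simulate_triplets_impl <- function(config, genomes) {
  cats <- rep(names(config$n_mirnas), config$n_mirnas)
  n <- length(cats)
  if (!n) stop("empty simulation: all n_mirnas are zero")
  widths <- sample(70:91, n, replace = TRUE)
  fe <- config$flank_extract
  fl <- config$flank_length
  region_w <- widths + 2L * fe
  locus_id <- rep.int(seq_len(n), region_w)
  total <- sum(region_w)
  anc <- .random_seq(total)

  # Per-site rates: flank rate outside the precursor, branch rate inside.
  off <- c(0L, cumsum(region_w))
  pre_lo <- off[-length(off)] + fe + 1L
  pre_hi <- pre_lo + widths - 1L
  in_pre <- logical(total)
  in_pre[unlist(mapply(seq.int, pre_lo, pre_hi, SIMPLIFY = FALSE))] <- TRUE

  rows <- list()
  for (sp in TRIO_SPECIES) {
    r_mir <- vapply(config$branch_rates, `[[`, numeric(1), sp)[cats]
    r_fl <- vapply(config$flank_rates, `[[`, numeric(1), sp)[cats]
    rate <- ifelse(in_pre, rep.int(r_mir, region_w), rep.int(r_fl, region_w))
    rows[[sp]] <- .evolve_branch(anc, rate, config$cpg_multiplier,
                                 config$ws_bias, locus_id)
  }

  ids <- sprintf("hsa-mir-s%05d", seq_len(n))

  # Vectorised per-locus assembly: position-within-locus index, then one
  # paste per species and substring splits at cumulative widths.
  pos_in <- sequence(region_w)
  w_rep <- rep.int(widths, region_w)
  in_flank <- (pos_in > fe - fl & pos_in <= fe) |
    (pos_in > fe + w_rep & pos_in <= fe + w_rep + fl)
  pre_ends <- cumsum(widths); pre_starts <- pre_ends - widths + 1L
  fl_ends <- cumsum(rep(2L * fl, n)); fl_starts <- fl_ends - 2L * fl + 1L
  split_rows <- function(chars, mask, starts, ends)
    substring(paste(chars[mask], collapse = ""), starts, ends)
  pre_str <- lapply(rows, split_rows, in_pre, pre_starts, pre_ends)
  fl_str <- lapply(rows, split_rows, in_flank, fl_starts, fl_ends)
  count_by <- function(chars, mask) {
    x <- integer(n)
    tt <- rowsum((chars != anc)[mask] + 0L, locus_id[mask])
    x[as.integer(rownames(tt))] <- tt[, 1L]
    x
  }
  truth <- data.frame(
    mirna_id = ids,
    m_human = count_by(rows$human, in_pre),
    m_chimp = count_by(rows$chimp, in_pre),
    m_orang = count_by(rows$orang, in_pre),
    flank_m_human = count_by(rows$human, in_flank),
    flank_m_chimp = count_by(rows$chimp, in_flank),
    stringsAsFactors = FALSE
  )

  # Optional gap injection for filter tests: one run of '-' per chosen
  # locus, placed internally in the human row (> 20 nt, triggers the gap
  # filter).
  gap_locus <- if (config$indel_rate > 0)
    which(runif(n) < config$indel_rate) else integer()
  for (i in gap_locus) {
    run <- sample(21:min(30, widths[i] - 2L), 1L)
    at <- sample(seq.int(2L, widths[i] - run), 1L)
    s <- pre_str$human[i]
    pre_str$human[i] <- paste0(substr(s, 1L, at - 1L),
                               strrep("-", run),
                               substr(s, at + run, widths[i]))
  }

  alignments <- mapply(triplet_alignment, pre_str$human, pre_str$chimp,
                       pre_str$orang, id = ids, SIMPLIFY = FALSE)
  flank_alignments <- mapply(triplet_alignment, fl_str$human, fl_str$chimp,
                             fl_str$orang, id = ids, SIMPLIFY = FALSE)
  names(alignments) <- names(flank_alignments) <- ids

  layout <- .layout_loci(ids, cats, widths, fe)
  labels <- layout$labels
  labels$conservation <- cats
  fam <- .make_families(ids, cats, labels)
  labels$copies <- fam$copies
  mfe <- data.frame(
    id = as.vector(t(outer(ids, TRIO_SPECIES, paste, sep = "|"))),
    mfe = rnorm(3L * n, config$mfe_mean, config$mfe_sd),
    stringsAsFactors = FALSE
  )
  seeds <- .make_seeds(ids, widths)

  genome_seqs <- NULL
  if (genomes)
    genome_seqs <- .assemble_genomes(layout$coords, anc, rows, off, region_w)

  structure(list(
    config = config,
    loci = cbind(layout$coords, width = widths, category = cats),
    labels = labels,
    alignments = alignments,
    flank_alignments = flank_alignments,
    truth = truth,
    mfe = mfe,
    family = fam$stanzas,
    genes = layout$genes,
    seeds = seeds,
    genomes = genome_seqs
  ), class = "triplet_simulation")
}

# Deterministic layout on one synthetic chromosome per species. Every 5th
# locus starts a cluster pair (gap 3 kb, same strand); others sit 60 kb
# apart. Every 3rd locus is buried in a synthetic gene (intron, with every
# 9th genic locus exonic and every 7th in a UTR); the rest are intergenic.
.layout_loci <- function(ids, cats, widths, fe) {
  n <- length(ids)
  species_shift <- c(human = 0L, chimp = 137L, orang = 251L)
  start_h <- integer(n)
  strand <- character(n)
  clustered <- character(n)
  # loci are laid out in chunks of 250 per chromosome so coordinates stay
  # within integer range at any dataset size
  chrom <- paste0("chr", (seq_len(n) - 1L) %/% 250L + 1L)
  cursor <- 10000L
  for (i in seq_len(n)) {
    new_chrom <- i > 1L && chrom[i] != chrom[i - 1L]
    if (new_chrom) cursor <- 10000L
    in_pair <- (i %% 5L == 0L) && i > 1L && !new_chrom
    gap <- if (in_pair) 3000L else 60000L
    cursor <- cursor + gap
    start_h[i] <- cursor
    strand[i] <- if (in_pair) strand[i - 1L] else if (i %% 7L == 0L) "-" else "+"
    clustered[i] <- if (in_pair) "clustered" else "non-clustered"
    if (in_pair) clustered[i - 1L] <- "clustered"
    cursor <- cursor + widths[i]
  }
  coords <- data.frame(mirna_id = ids, seq_name = chrom,
                       start = start_h, end = start_h + widths,
                       strand = strand, stringsAsFactors = FALSE)
  for (sp in c("chimp", "orang")) {
    coords[[paste0("start_", sp)]] <- start_h + species_shift[[sp]]
    coords[[paste0("end_", sp)]] <- start_h + widths + species_shift[[sp]]
  }
  genic <- seq_len(n) %% 3L == 0L
  gsub_ <- which(genic)
  part <- rep("intron", length(gsub_))
  part[gsub_ %% 9L == 0L] <- "exon"
  part[gsub_ %% 9L != 0L & gsub_ %% 7L == 0L] <- "UTR"
  genes <- list(
    genes = data.frame(
      seq_name = chrom[gsub_], start = start_h[gsub_] - 2000L,
      end = start_h[gsub_] + widths[gsub_] + 2000L, strand = strand[gsub_],
      gene_id = paste0("gene_", seq_along(gsub_)), stringsAsFactors = FALSE),
    parts = data.frame(
      seq_name = chrom[gsub_],
      start = ifelse(part == "intron", start_h[gsub_] - 2000L, start_h[gsub_]),
      end = ifelse(part == "intron",
                   start_h[gsub_] + widths[gsub_] + 2000L,
                   start_h[gsub_] + widths[gsub_]),
      strand = strand[gsub_], part = part, stringsAsFactors = FALSE)
  )
  context <- rep("intergenic", n)
  context[gsub_] <- paste0("genic:", part)
  labels <- data.frame(mirna_id = ids, clustered = clustered,
                       copies = NA_character_, conservation = NA_character_,
                       context = context, stringsAsFactors = FALSE)
  list(coords = coords, genes = genes, labels = labels)
}

# Family stanzas: primate-specific loci are orphans except every 4th, which
# gets a chimpanzee partner (multiple copy, still primate-only). ConFam loci
# each join a family with a mouse member.
.make_families <- function(ids, cats, labels) {
  copies <- rep("single", length(ids))
  stanzas <- list()
  k <- 0L
  for (i in seq_along(ids)) {
    if (cats[i] == "ConFam" || (cats[i] != "ConFam" && i %% 4L == 0L)) {
      k <- k + 1L
      partner <- if (cats[i] == "ConFam")
        sub("^hsa", "mmu", ids[i]) else sub("^hsa", "ptr", ids[i])
      stanzas[[k]] <- list(
        ac = sprintf("MIPF9%06d", k),
        id = sub("^hsa-", "", ids[i]),
        members = c(ids[i], partner)
      )
      copies[i] <- "multiple"
    }
  }
  list(stanzas = stanzas, copies = copies)
}

# One 5p mature per precursor; every other precursor also gets a 3p mature.
# Spans are 1-based inclusive positions within the precursor; the seed is
# mature positions 2-8.
.make_seeds <- function(ids, widths) {
  n <- length(ids)
  five <- data.frame(mirna_id = ids, mature_id = paste0(ids, "-5p"),
                     mature_start = 6L, mature_end = 27L,
                     start = 7L, end = 13L, stringsAsFactors = FALSE)
  has3 <- seq_len(n) %% 2L == 0L
  three <- data.frame(mirna_id = ids[has3], mature_id = paste0(ids[has3], "-3p"),
                      mature_start = widths[has3] - 27L,
                      mature_end = widths[has3] - 6L,
                      start = widths[has3] - 26L, end = widths[has3] - 20L,
                      stringsAsFactors = FALSE)
  out <- rbind(five, three)
  out[order(out$mirna_id, out$mature_id), , drop = FALSE]
}

# Assemble chromosome strings per species: random spacers between the
# simulated regions, minus-strand loci stored reverse-complemented.
.assemble_genomes <- function(coords, anc, rows, off, region_w) {
  n <- nrow(coords)
  out <- list()
  for (sp in TRIO_SPECIES) {
    seq_rows <- rows[[sp]]
    start_col <- if (sp == "human") "start" else paste0("start_", sp)
    starts <- coords[[start_col]]
    # region = precursor +/- flank_extract, recovered from the region width
    fe_i <- (region_w - (coords$end - coords$start)) %/% 2L
    region_start <- starts - fe_i
    chroms <- list()
    pieces <- character(0)
    cursor <- 0L
    cur_chr <- coords$seq_name[1]
    for (i in seq_len(n)) {
      if (coords$seq_name[i] != cur_chr) {
        chroms[[cur_chr]] <- paste(c(pieces, paste(.random_seq(500L), collapse = "")),
                                   collapse = "")
        pieces <- character(0); cursor <- 0L; cur_chr <- coords$seq_name[i]
      }
      pieces <- c(pieces, paste(.random_seq(region_start[i] - cursor), collapse = ""))
      reg <- seq_rows[seq.int(off[i] + 1L, off[i + 1L])]
      if (coords$strand[i] == "-") reg <- rev_comp_chars(reg)
      pieces <- c(pieces, paste(reg, collapse = ""))
      cursor <- region_start[i] + region_w[i]
    }
    chroms[[cur_chr]] <- paste(c(pieces, paste(.random_seq(500L), collapse = "")),
                               collapse = "")
    out[[sp]] <- unlist(chroms)
  }
  out
}

rev_comp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  rev(unname(comp[x]))
}

#' Simulate neutral reference triplets
#'
#' Generates `n` neutral loci (ancestral-repeat regime) of 70-91 bp with the
#' configured neutral branch rates, no flanks and no category structure.
#'
#' @param config A [simulation_config] (`neutral_rates` and `seed` are used;
#'   the CpG multiplier and W>S bias apply as configured).
#' @param n Number of reference loci.
#' @return A list of [triplet_alignment] objects, deterministic given
#'   `config$seed`.
#' @export
simulate_neutral_refs <- function(config, n) {
  stopifnot(inherits(config, "simulation_config"), n >= 1)
  withr_seed(config$seed + 1L, {
    widths <- sample(70:91, n, replace = TRUE)
    locus_id <- rep.int(seq_len(n), widths)
    anc <- .random_seq(sum(widths))
    rows <- lapply(setNames(TRIO_SPECIES, TRIO_SPECIES), function(sp)
      .evolve_branch(anc, config$neutral_rates[[sp]], config$cpg_multiplier,
                     config$ws_bias, locus_id))
    off <- c(0L, cumsum(widths))
    lapply(seq_len(n), function(i) {
      sel <- seq.int(off[i] + 1L, off[i + 1L])
      triplet_alignment(
        paste(rows$human[sel], collapse = ""),
        paste(rows$chimp[sel], collapse = ""),
        paste(rows$orang[sel], collapse = ""),
        id = sprintf("ar-s%05d", i))
    })
  })
}

#' @export
print.triplet_simulation <- function(x, ...) {
  cat("triplet_simulation:", nrow(x$loci), "loci (",
      paste(names(x$config$n_mirnas), x$config$n_mirnas, collapse = ", "),
      "), seed", x$config$seed, "\n")
  invisible(x)
}
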