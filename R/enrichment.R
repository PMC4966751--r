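#' Build per-miRNA target gene sets with the context-score filter
#'
#' Conserved predicted targets are always kept. Non-conserved targets are
#' kept only when `include_nonconserved` is set and the total context score
#' is at or below `score_cutoff` (-0.4 by default; more negative = stronger
#' predicted repression). Non-conserved records with a missing score are
#' dropped with a warning.
#'
#' @param table Target table (`mirna_id`, `gene_id`, `conserved`,
#'   `context_score`), e.g. from [read_targets_tsv].
#' @param include_nonconserved Include filtered non-conserved sites?
#' @param score_cutoff Context-score cutoff for non-conserved sites.
#' @return Named list: gene id vector per miRNA.
#' @export
filter_targets <- function(table, include_nonconserved = FALSE,
                           score_cutoff = -0.4) {
  nc <- !table$conserved
  bad <- nc & is.na(table$context_score)
  if (any(bad)) {
    warning(sum(bad), " non-conserved record(s) without context score dropped")
    table <- table[!bad, , drop = FALSE]
    nc <- !table$conserved
  }
  keep <- table$conserved |
    (include_nonconserved & nc & table$context_score <= score_cutoff)
  kept <- table[keep, , drop = FALSE]
  lapply(split(kept$gene_id, kept$mirna_id), unique)
}

# Vectorised one-sided Fisher (hypergeometric upper tail) across terms.
# q = study hits per term, m = background genes per term, n_bg = background
# size, k = study size.
.hyper_p <- function(q, m, n_bg, k) phyper(q - 1L, m, n_bg - m, k, lower.tail = FALSE)

#' Fisher over-representation test per functional term
#'
#' One-sided (over-representation) Fisher's exact test of the study gene
#' set against the background, per term of a gene-to-term map. Terms with
#' no study gene report `p = 1`.
#'
#' @param study_genes Character vector (subset of `background`).
#' @param background Character vector: the gene universe.
#' @param go_map Data frame (`gene_id`, `go_id`), restricted to the
#'   background internally.
#' @return Data frame `go_id`, `study_count`, `bg_count`, `odds_ratio`,
#'   `p`, ordered by `p`.
#' @export
fisher_enrichment <- function(study_genes, background, go_map) {
  if (!length(background)) stop("empty background")
  study_genes <- intersect(unique(study_genes), background)
  map <- go_map[go_map$gene_id %in% background, , drop = FALSE]
  terms <- sort(unique(map$go_id))
  inc <- .term_matrix(map, terms, background)
  .fisher_from_matrix(inc, background %in% study_genes, length(background),
                      length(study_genes), terms)
}

# terms x genes 0/1 incidence matrix over the background.
.term_matrix <- function(map, terms, background) {
  inc <- matrix(0L, nrow = length(terms), ncol = length(background),
                dimnames = list(terms, NULL))
  ti <- match(map$go_id, terms)
  gi <- match(map$gene_id, background)
  inc[cbind(ti, gi)] <- 1L
  inc
}

.fisher_from_matrix <- function(inc, study_ind, n_bg, k, terms) {
  q <- as.integer(inc %*% study_ind)
  m <- as.integer(rowSums(inc))
  p <- .hyper_p(q, m, n_bg, k)
  p[q == 0L] <- 1
  or_num <- q * (n_bg - m - k + q)
  or_den <- (m - q) * (k - q)
  out <- data.frame(go_id = terms, study_count = q, bg_count = m,
                    odds_ratio = ifelse(or_den > 0, or_num / or_den, Inf),
                    p = p, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$go_id), , drop = FALSE]
  attr(out, "study_size") <- k
  out
}

#' Permutation calibration of term enrichment
#'
#' Recomputes each term's one-sided Fisher p-value under `B` random
#' re-drawings of the study set — either random groups of `k` miRNAs from
#' the pool (rebuilding the union of their targets) or a matched number of
#' genes drawn from the background. A term is called significant when its
#' permuted p-value exceeds the observed one strictly in more than
#' `ceiling((1 - alpha) * B)` permutations (empirical p < `alpha`). The
#' add-one empirical estimator `(1 + #[perm p <= obs p]) / (B + 1)` is
#' reported alongside. Deterministic given `seed`.
#'
#' @param observed Result of [fisher_enrichment] for the real study set.
#' @param target_sets Named list from [filter_targets] (the miRNA universe
#'   and their gene sets).
#' @param background Gene universe.
#' @param go_map Gene-to-term map.
#' @param k Group size drawn per permutation (default 10).
#' @param B Number of permutations (default 1000).
#' @param alpha Empirical significance level (default 0.01).
#' @param mode `"mirna_groups"` (default) or `"matched_targets"`.
#' @param seed Integer seed.
#' @return `observed` with extra columns `exceed` (permutations with larger
#'   p), `empirical_p`, `significant`.
#' @export
permutation_calibration <- function(observed, target_sets, background, go_map,
                                    k = 10L, B = 1000L, alpha = 0.01,
                                    mode = c("mirna_groups", "matched_targets"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(B >= 1L)
  pool <- names(target_sets)
  if (mode == "mirna_groups") stopifnot(k <= length(pool))
  map <- go_map[go_map$gene_id %in% background, , drop = FALSE]
  terms <- observed$go_id
  inc <- .term_matrix(map, terms, background)
  n_bg <- length(background)
  obs_p <- observed$p
  exceed <- integer(length(terms))
  le <- integer(length(terms))
  withr_seed(seed, {
    for (b in seq_len(B)) {
      if (mode == "mirna_groups") {
        grp <- sample(pool, k)
        study <- unique(unlist(target_sets[grp], use.names = FALSE))
        study <- study[study %in% background]
      } else {
        n_draw <- attr(observed, "study_size") %||%
          stop("observed lacks a study_size attribute")
        study <- sample(background, max(1L, min(n_bg, n_draw)))
      }
      ind <- background %in% study
      q <- as.integer(inc %*% ind)
      m <- as.integer(rowSums(inc))
      p <- .hyper_p(q, m, n_bg, sum(ind))
      p[q == 0L] <- 1
      exceed <- exceed + (p > obs_p)
      le <- le + (p <= obs_p)
    }
  })
  out <- observed
  out$exceed <- exceed
  out$empirical_p <- (1 + le) / (B + 1)
  out$significant <- exceed > ceiling((1 - alpha) * B)
  attr(out, "B") <- B
  attr(out, "mode") <- mode
  out
}
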