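#' Count CpG-context transitions per branch
#'
#' A branch-specific substitution is counted as CpG-context when the
#' oriented ancestral dinucleotide is CpG and the change is the deamination
#' transition: C>T at the C (CpG>TpG) or, reading the reverse strand, G>A
#' at the G (CpG>CpA). The partner base of the dinucleotide (G for CpG>TpG,
#' C for CpG>CpA) must be conserved between human and chimpanzee.
#' Substitutions at sequence edges with no partner base count as non-CpG.
#'
#' @param aln A [triplet_alignment].
#' @param summary Optional precomputed [orient_and_count] result.
#' @return List of class `cpg_counts`: per branch (`human`, `chimp`)
#'   `cpg_transitions` and `non_cpg_substitutions`, plus `total` aggregates.
#' @export
count_cpg_transitions <- function(aln, summary = NULL) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  if (is.null(summary)) summary <- orient_and_count(m)
  d <- summary$detail
  h <- m[1L, ]; c_ <- m[2L, ]; o <- m[3L, ]
  w <- ncol(m)
  is_cpg <- logical(nrow(d))
  if (nrow(d)) for (k in seq_len(nrow(d))) {
    i <- d$column[k]
    if (d$ancestral[k] == "C" && d$derived[k] == "T" && i < w) {
      is_cpg[k] <- o[i + 1L] == "G" && h[i + 1L] == "G" && c_[i + 1L] == "G"
    } else if (d$ancestral[k] == "G" && d$derived[k] == "A" && i > 1L) {
      is_cpg[k] <- o[i - 1L] == "C" && h[i - 1L] == "C" && c_[i - 1L] == "C"
    }
  }
  per_branch <- function(br) {
    sel <- d$branch == br
    c(cpg_transitions = sum(is_cpg & sel),
      non_cpg_substitutions = sum(sel & !is_cpg))
  }
  structure(list(
    human = per_branch("human"),
    chimp = per_branch("chimp"),
    total = c(cpg_transitions = sum(is_cpg),
              non_cpg_substitutions = sum(!is_cpg))
  ), class = "cpg_counts")
}

.strong <- c("C", "G")

#' Partition oriented substitutions into weak/strong classes
#'
#' Classifies each oriented branch-specific change as strong-to-weak
#' (C/G > A/T), weak-to-strong (A/T > C/G) or within-class (S>S + W>W), and
#' computes the W>S bias `n_WS / (n_WS + n_SW)` — the index of GC-biased
#' gene conversion. Also tallies the 12 ordered ancestor-to-derived change
#' types. Computable per branch or aggregated over both lineages.
#'
#' @param aln A [triplet_alignment] (or 3-row matrix).
#' @param summary Optional precomputed [orient_and_count] result.
#' @param branch `"both"` (default), `"human"` or `"chimp"`.
#' @return List of class `ws_partition`: `n_SW`, `n_WS`, `n_SS_plus_WW`,
#'   `ws_bias` (`NA` when no W/S-informative change exists) and
#'   `type_counts` (named 12-vector, e.g. `"C>T"`).
#' @export
ws_partition <- function(aln, summary = NULL, branch = c("both", "human", "chimp")) {
  branch <- match.arg(branch)
  if (is.null(summary)) summary <- orient_and_count(aln)
  d <- summary$detail
  if (branch != "both") d <- d[d$branch == branch, , drop = FALSE]
  anc_s <- d$ancestral %in% .strong
  der_s <- d$derived %in% .strong
  n_sw <- sum(anc_s & !der_s)
  n_ws <- sum(!anc_s & der_s)
  n_within <- sum(anc_s == der_s)
  types <- paste0(rep(BASES, each = 3L), ">",
                  unlist(lapply(BASES, function(b) setdiff(BASES, b))))
  tc <- table(factor(paste0(d$ancestral, ">", d$derived), levels = types))
  bias <- if (n_ws + n_sw == 0) NA_real_ else n_ws / (n_ws + n_sw)
  structure(list(branch = branch, n_SW = n_sw, n_WS = n_ws,
                 n_SS_plus_WW = n_within, ws_bias = bias,
                 type_counts = as.integer(tc), type_names = types),
            class = "ws_partition")
}

#' @export
print.ws_partition <- function(x, ...) {
  cat(sprintf("ws_partition (%s): S>W %d, W>S %d, within %d, bias %.3f\n",
              x$branch, x$n_SW, x$n_WS, x$n_SS_plus_WW, x$ws_bias))
  invisible(x)
}

#' Fisher test comparing substitution-class proportions between two groups
#'
#' Two-sided Fisher's exact test on the 2x2 table of either CpG against
#' non-CpG substitution counts (`contrast = "cpg_vs_noncpg"`, inputs from
#' [count_cpg_transitions]) or S>W against W>S counts
#' (`contrast = "sw_vs_ws"`, inputs from [ws_partition]).
#'
#' @param a,b The two groups' count objects.
#' @param contrast Which 2x2 to build.
#' @param branch Branch slot used for `cpg_vs_noncpg` (default `total`).
#' @return List with `table` and `p` (degenerate margin: `p = 1` with a
#'   warning).
#' @export
proportion_test <- function(a, b, contrast = c("cpg_vs_noncpg", "sw_vs_ws"),
                            branch = "total") {
  contrast <- match.arg(contrast)
  if (contrast == "cpg_vs_noncpg") {
    tab <- rbind(a = a[[branch]], b = b[[branch]])
  } else {
    tab <- rbind(a = c(a$n_SW, a$n_WS), b = c(b$n_SW, b$n_WS))
    colnames(tab) <- c("S>W", "W>S")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin in proportion test; p set to 1")
    return(list(table = tab, p = 1))
  }
  list(table = tab, p = fisher.test(tab)$p.value)
}

#' Per-type substitution rates on one branch
#'
#' For each of the 12 ordered ancestor-to-derived change types, the rate is
#' the oriented count divided by the number of gap-free columns whose
#' oriented ancestral (orang-utan) base is the source base — a rate per
#' mutational opportunity. The four denominators partition the effective
#' length.
#'
#' @param aln A [triplet_alignment].
#' @param summary Optional precomputed [orient_and_count] result.
#' @param branch `"human"` (default) or `"chimp"`.
#' @return Data frame `type`, `count`, `opportunity`, `rate` (rate `NA`
#'   where the source base never occurs).
#' @export
per_type_rates <- function(aln, summary = NULL, branch = "human") {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  if (is.null(summary)) summary <- orient_and_count(m)
  h <- m[1L, ]; c_ <- m[2L, ]; o <- m[3L, ]
  valid <- h %in% BASES & c_ %in% BASES & o %in% BASES
  opp <- table(factor(o[valid], levels = BASES))
  d <- summary$detail
  d <- d[d$branch == branch, , drop = FALSE]
  types <- paste0(rep(BASES, each = 3L), ">",
                  unlist(lapply(BASES, function(b) setdiff(BASES, b))))
  counts <- table(factor(paste0(d$ancestral, ">", d$derived), levels = types))
  src <- substr(types, 1L, 1L)
  denom <- as.integer(opp[src])
  data.frame(type = types, count = as.integer(counts),
             opportunity = denom,
             rate = ifelse(denom > 0, as.integer(counts) / denom, NA_real_),
             stringsAsFactors = FALSE)
}
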