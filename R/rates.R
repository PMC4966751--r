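#' Orient substitutions with the orang-utan outgroup and count per branch
#'
#' Classifies every alignment column of a human/chimp/orang triplet. Columns
#' containing a gap or an ambiguity code in any row are excluded from the
#' effective length. Among the remaining columns, a human-chimp difference is
#' assigned to the branch of the species that differs from the orang-utan
#' allele (the outgroup carries the ancestral state); columns with three
#' distinct alleles are multiallelic and skipped; columns where human and
#' chimp agree but differ from orang-utan are changes on the orang-utan
#' branch (or ancestral) and are tallied only as a diagnostic — they never
#' enter the relative rate test.
#'
#' @param aln A [triplet_alignment] (or a 3-row character matrix).
#' @return An object of class `substitution_summary`: a list with
#'   `effective_length`, `m_human`, `m_chimp`, `n_multiallelic`,
#'   `n_orang_or_ancestral` and `detail`, a data frame of oriented
#'   branch-specific substitutions (`column`, `branch`, `ancestral`,
#'   `derived`).
#' @export
orient_and_count <- function(aln) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  h <- m[1L, ]; c_ <- m[2L, ]; o <- m[3L, ]
  bases <- c("A", "C", "G", "T")
  valid <- h %in% bases & c_ %in% bases & o %in% bases
  hv <- h[valid]; cv <- c_[valid]; ov <- o[valid]
  diff_hc <- hv != cv
  on_human <- diff_hc & ov == cv
  on_chimp <- diff_hc & ov == hv
  multi <- diff_hc & ov != hv & ov != cv
  orang_anc <- !diff_hc & hv != ov
  cols <- which(valid)
  detail <- data.frame(
    column = c(cols[on_human], cols[on_chimp]),
    branch = rep(c("human", "chimp"), c(sum(on_human), sum(on_chimp))),
    ancestral = c(ov[on_human], ov[on_chimp]),
    derived = c(hv[on_human], cv[on_chimp]),
    stringsAsFactors = FALSE
  )
  detail <- detail[order(detail$column), , drop = FALSE]
  rownames(detail) <- NULL
  structure(
    list(id = if (is.matrix(aln)) NULL else aln$id,
         effective_length = sum(valid),
         m_human = sum(on_human),
         m_chimp = sum(on_chimp),
         n_multiallelic = sum(multi),
         n_orang_or_ancestral = sum(orang_anc),
         detail = detail),
    class = "substitution_summary"
  )
}

#' @export
print.substitution_summary <- function(x, ...) {
  cat("substitution_summary: L =", x$effective_length,
      " human =", x$m_human, " chimp =", x$m_chimp,
      " multiallelic =", x$n_multiallelic, "\n")
  invisible(x)
}

# Round half-up at `digits` decimals (report convention; stats use full
# precision).
round_half_up <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Branch-specific substitution rate
#'
#' Rate = branch-specific substitutions / effective length (gap- and
#' indel-free sites). Reported values are conventionally rounded half-up to
#' 4 decimals; the full-precision value is returned unless `rounded = TRUE`.
#'
#' @param summary A `substitution_summary`, or an integer count.
#' @param branch `"human"` or `"chimp"` (ignored when `summary` is a count).
#' @param effective_length Required when `summary` is a bare count.
#' @param rounded Round half-up to 4 decimals?
#' @return The rate (substitutions/site), or `NA` when the effective length
#'   is zero.
#' @examples
#' substitution_rate(32, effective_length = 5558, rounded = TRUE)  # 0.0058
#' @export
substitution_rate <- function(summary, branch = c("human", "chimp"),
                              effective_length = NULL, rounded = FALSE) {
  if (inherits(summary, "substitution_summary")) {
    branch <- match.arg(branch)
    m <- if (branch == "human") summary$m_human else summary$m_chimp
    L <- summary$effective_length
  } else {
    m <- summary
    L <- effective_length
    if (is.null(L)) stop("effective_length required with a bare count")
  }
  if (L <= 0) return(NA_real_)
  r <- m / L
  if (rounded) round_half_up(r, 4L) else r
}

#' Tajima's relative rate test for two sister branches
#'
#' Chi-square form: with `m1` and `m2` branch-specific substitution counts
#' oriented by the outgroup, the statistic is `(m1 - m2)^2 / (m1 + m2)` on
#' 1 df. An exact two-sided binomial alternative (null: each of the
#' `m1 + m2` oriented changes falls on either branch with probability 1/2)
#' is available via `method = "binomial"`.
#'
#' @param m1,m2 Non-negative substitution counts (vectorised).
#' @param method `"chisq"` (default) or `"binomial"`.
#' @return Data frame with `m1`, `m2`, `chi2` (NA for the binomial method's
#'   rows' statistic is still reported), `p`.
#' @examples
#' tajima_rrt(14, 0)   # chi2 = 14, p ~ 1.8e-4
#' @export
tajima_rrt <- function(m1, m2, method = c("chisq", "binomial")) {
  method <- match.arg(method)
  stopifnot(all(m1 >= 0), all(m2 >= 0), length(m1) == length(m2))
  n <- m1 + m2
  chi2 <- ifelse(n == 0, 0, (m1 - m2)^2 / ifelse(n == 0, 1, n))
  if (method == "chisq") {
    p <- ifelse(n == 0, 1, pchisq(chi2, df = 1L, lower.tail = FALSE))
  } else {
    # two-sided exact binomial, p = P(|X - n/2| >= |m1 - n/2|), X ~ Bin(n, 1/2)
    p <- mapply(function(a, b) {
      if (a + b == 0) return(1)
      stats::binom.test(a, a + b, p = 0.5)$p.value
    }, m1, m2)
  }
  data.frame(m1 = m1, m2 = m2, chi2 = chi2, p = pmin(p, 1))
}

#' Relative rate tests for a batch of loci or categories
#'
#' Runs [tajima_rrt] per summary and flags nominal and Bonferroni
#' significance. With `N` tests the Bonferroni threshold is `alpha / N`
#' (e.g. 0.05/1214 = 0.000041 at two significant figures).
#'
#' @param summaries List of `substitution_summary` objects (or a data frame
#'   with `m_human`, `m_chimp` columns).
#' @param alpha Nominal significance level.
#' @param method Passed to [tajima_rrt].
#' @return Data frame (`id`, `m_human`, `m_chimp`, `chi2`, `p`,
#'   `significant_nominal`, `significant_bonferroni`) with attributes
#'   `bonferroni_threshold` and `n_tests`.
#' @export
rrt_batch <- function(summaries, alpha = 0.05, method = "chisq") {
  if (is.data.frame(summaries)) {
    ids <- summaries$id %||% as.character(seq_len(nrow(summaries)))
    m1 <- summaries$m_human; m2 <- summaries$m_chimp
  } else {
    ids <- vapply(seq_along(summaries), function(i)
      summaries[[i]]$id %||% as.character(i), character(1))
    m1 <- vapply(summaries, `[[`, numeric(1), "m_human")
    m2 <- vapply(summaries, `[[`, numeric(1), "m_chimp")
  }
  n_tests <- length(m1)
  stopifnot(n_tests >= 1L)
  res <- tajima_rrt(m1, m2, method = method)
  thr <- alpha / n_tests
  out <- data.frame(id = ids, res,
                    significant_nominal = res$p < alpha,
                    significant_bonferroni = res$p < thr,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "m1"] <- "m_human"
  names(out)[names(out) == "m2"] <- "m_chimp"
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "n_tests") <- n_tests
  out
}

#' Bootstrap the concatenated rate of a miRNA category
#'
#' Resamples the category's members with replacement (to the category's own
#' size), recomputing the concatenated rate `sum(m) / sum(L)` per branch for
#' each resample. Reports the bootstrap standard deviation and the 2.5/97.5
#' percentiles per branch. Deterministic given `seed`.
#'
#' @param members List of `substitution_summary` objects.
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return List of class `category_bootstrap`: observed rates, per-branch
#'   `sd`, `ci` (2.5/97.5 percentiles) and the `B`-vector of bootstrap rates.
#' @export
bootstrap_category <- function(members, B = 100L, seed = 1L) {
  stopifnot(length(members) >= 1L)
  m_h <- vapply(members, `[[`, numeric(1), "m_human")
  m_c <- vapply(members, `[[`, numeric(1), "m_chimp")
  L <- vapply(members, `[[`, numeric(1), "effective_length")
  n <- length(members)
  rate_h <- sum(m_h) / sum(L)
  rate_c <- sum(m_c) / sum(L)
  idx <- withr_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), nrow = n))
  Lb <- matrix(L[idx], nrow = n)
  boot_h <- colSums(matrix(m_h[idx], nrow = n)) / colSums(Lb)
  boot_c <- colSums(matrix(m_c[idx], nrow = n)) / colSums(Lb)
  qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  structure(list(
    n_members = n, B = B, seed = seed,
    rate_human = rate_h, rate_chimp = rate_c,
    sd = c(human = sd(boot_h), chimp = sd(boot_c)),
    ci = rbind(human = qs(boot_h), chimp = qs(boot_c)),
    boot = list(human = boot_h, chimp = boot_c)
  ), class = "category_bootstrap")
}

#' @export
print.category_bootstrap <- function(x, ...) {
  cat(sprintf(
    "category_bootstrap (n = %d, B = %d)\n  human %.4f (sd %.4f) [%.4f, %.4f]\n  chimp %.4f (sd %.4f) [%.4f, %.4f]\n",
    x$n_members, x$B, x$rate_human, x$sd["human"], x$ci["human", 1], x$ci["human", 2],
    x$rate_chimp, x$sd["chimp"], x$ci["chimp", 1], x$ci["chimp", 2]))
  invisible(x)
}

# Run expr with a temporary RNG state seeded at `seed`, restoring afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Compare two categories using reciprocal bootstrap tails
#'
#' Two category rates are declared `"different"` only when each observed
#' rate falls outside the other's bootstrap 2.5-97.5 percentile interval
#' (reciprocal-tail rule); otherwise `"not_distinguishable"`.
#'
#' @param a,b `category_bootstrap` objects.
#' @param branch `"human"` or `"chimp"`.
#' @return List with `verdict` and the two observed rates and intervals.
#' @export
compare_categories <- function(a, b, branch = c("human", "chimp")) {
  branch <- match.arg(branch)
  obs_a <- if (branch == "human") a$rate_human else a$rate_chimp
  obs_b <- if (branch == "human") b$rate_human else b$rate_chimp
  ci_a <- a$ci[branch, ]
  ci_b <- b$ci[branch, ]
  outside <- function(x, ci) x < ci[1] || x > ci[2]
  verdict <- if (outside(obs_a, ci_b) && outside(obs_b, ci_a))
    "different" else "not_distinguishable"
  list(verdict = verdict, branch = branch,
       rate_a = obs_a, rate_b = obs_b, ci_a = ci_a, ci_b = ci_b)
}

#' Substitution counts restricted to seed regions
#'
#' Maps seed spans, given as 1-based inclusive positions within the ungapped
#' human precursor row, onto alignment columns (walking over gaps in the
#' human row) and re-runs [orient_and_count] on the selected columns.
#'
#' @param aln A [triplet_alignment] of the precursor.
#' @param seed_spans Data frame with columns `start`, `end` (1-based,
#'   inclusive, in ungapped human precursor coordinates) and optionally
#'   `mature_id`.
#' @return A list of `substitution_summary`, one per seed.
#' @export
seed_region_rates <- function(aln, seed_spans) {
  m <- as.matrix(aln)
  hum <- m[1L, ]
  ungapped_pos <- cumsum(hum != "-")
  n_bases <- ungapped_pos[length(ungapped_pos)]
  lapply(seq_len(nrow(seed_spans)), function(i) {
    s <- seed_spans$start[i]; e <- seed_spans$end[i]
    if (s < 1L || e > n_bases || s > e)
      stop("seed span [", s, ", ", e, "] outside precursor of ", n_bases, " bases")
    cols <- which(hum != "-" & ungapped_pos >= s & ungapped_pos <= e)
    out <- orient_and_count(m[, cols, drop = FALSE])
    out$id <- seed_spans$mature_id[i] %||% aln$id
    out
  })
}

#' Linear model of per-miRNA rates on category labels
#'
#' Ordinary least squares of a per-miRNA substitution rate on indicator
#' variables for the four classification axes (clustering, copy number,
#' conservation, genomic context). The conservation-axis coefficient is the
#' quantity of interest: it asks whether primate-specific miRNAs evolve
#' faster once the other axes are controlled for.
#'
#' @param rates Numeric vector of per-miRNA rates.
#' @param labels Data frame with columns `clustered`, `copies`,
#'   `conservation`, `context` (factors or characters); rows match `rates`.
#' @return Coefficient table (data frame: `term`, `estimate`, `std_error`,
#'   `t_value`, `p_value`), with the fitted `lm` in attribute `fit`. Axes
#'   with a single level are dropped with a warning.
#' @export
rates_on_categories_regression <- function(rates, labels) {
  stopifnot(length(rates) == nrow(labels))
  axes <- c("clustered", "copies", "conservation", "context")
  stopifnot(all(axes %in% names(labels)))
  use <- axes[vapply(axes, function(a)
    length(unique(labels[[a]])) > 1L, logical(1))]
  dropped <- setdiff(axes, use)
  if (length(dropped))
    warning("axes with a single level dropped: ", paste(dropped, collapse = ", "))
  if (length(use) < 1L) stop("need at least one axis with >= 2 levels")
  dat <- data.frame(rate = rates, lapply(labels[use], factor))
  fit <- lm(rate ~ ., data = dat)
  cf <- summary(fit)$coefficients
  aliased <- is.na(coef(fit))
  if (any(aliased))
    warning("collinear indicators dropped: ",
            paste(names(aliased)[aliased], collapse = ", "))
  out <- data.frame(term = rownames(cf), estimate = cf[, 1],
                    std_error = cf[, 2], t_value = cf[, 3], p_value = cf[, 4],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fit") <- fit
  out
}
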