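# Column-pattern counts of a triplet alignment over its gap-free columns.
# The five classes determine the star-tree likelihood completely:
#   xxx  all three equal        yxx  human differs
#   xyx  chimp differs          xxy  orang differs
#   xyz  all three distinct
pattern_counts <- function(aln) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  h <- m[1L, ]; c_ <- m[2L, ]; o <- m[3L, ]
  valid <- h %in% BASES & c_ %in% BASES & o %in% BASES
  h <- h[valid]; c_ <- c_[valid]; o <- o[valid]
  hc <- h == c_; ho <- h == o; co <- c_ == o
  c(xxx = sum(hc & ho),
    yxx = sum(!hc & !ho & co),
    xyx = sum(!hc & ho),
    xxy = sum(hc & !ho),
    xyz = sum(!hc & !ho & !co))
}

# Class log-probabilities for branch lengths t = (human, chimp, orang)
# under a Jukes-Cantor model on the unrooted 3-taxon star tree with a
# uniform root. a_i = exp(-4 t_i / 3); f_s/f_d are the probabilities of
# observing the same/a specific different base across one branch.
.pattern_log_probs <- function(t) {
  a <- exp(-4 * t / 3)
  fs <- (1 + 3 * a) / 4
  fd <- (1 - a) / 4
  p_xxx <- 4 * (fs[1] * fs[2] * fs[3] + 3 * fd[1] * fd[2] * fd[3]) / 4
  p_yxx <- 12 * (fd[1] * fs[2] * fs[3] + fs[1] * fd[2] * fd[3] +
                   2 * fd[1] * fd[2] * fd[3]) / 4
  p_xyx <- 12 * (fs[1] * fd[2] * fs[3] + fd[1] * fs[2] * fd[3] +
                   2 * fd[1] * fd[2] * fd[3]) / 4
  p_xxy <- 12 * (fs[1] * fs[2] * fd[3] + fd[1] * fd[2] * fs[3] +
                   2 * fd[1] * fd[2] * fd[3]) / 4
  p_xyz <- 24 * (fd[1] * fs[2] * fd[3] + fs[1] * fd[2] * fd[3] +
                   fd[1] * fd[2] * fs[3] + fd[1] * fd[2] * fd[3]) / 4
  log(pmax(c(xxx = p_xxx, yxx = p_yxx, xyx = p_xyx, xxy = p_xxy,
             xyz = p_xyz), 1e-300))
}

.pattern_loglik <- function(counts, t) sum(counts * .pattern_log_probs(t))

#' Fit neutral branch lengths on a reference alignment
#'
#' Maximum-likelihood branch lengths (expected substitutions/site) for the
#' human, chimp and orang-utan branches of the unrooted 3-taxon star tree
#' under a Jukes-Cantor independent-sites model. Initialised from the
#' closed-form distance decomposition (`t_i = (d_ij + d_ik - d_jk) / 2` on
#' Jukes-Cantor-corrected pairwise distances) and refined numerically.
#'
#' @param ref A [triplet_alignment] with positive effective length.
#' @return List of class `branch_model`: `b_human`, `b_chimp`, `b_orang`,
#'   `loglik`, `effective_length`.
#' @export
fit_reference <- function(ref) {
  counts <- pattern_counts(ref)
  L <- sum(counts)
  if (L == 0L) stop("reference has zero effective length")
  m <- if (is.matrix(ref)) ref else as.matrix(ref)
  h <- m[1L, ]; c_ <- m[2L, ]; o <- m[3L, ]
  valid <- h %in% BASES & c_ %in% BASES & o %in% BASES
  pdist <- function(x, y) mean(x[valid] != y[valid])
  jc <- function(p) {
    p <- min(p, 0.74)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  d_hc <- jc(pdist(h, c_)); d_ho <- jc(pdist(h, o)); d_co <- jc(pdist(c_, o))
  t0 <- pmax(c((d_hc + d_ho - d_co) / 2,
               (d_hc + d_co - d_ho) / 2,
               (d_ho + d_co - d_hc) / 2), 1e-8)
  opt <- optim(log(t0), function(lt) -.pattern_loglik(counts, exp(lt)),
               method = "BFGS", control = list(maxit = 200))
  t_hat <- exp(opt$par)
  if (all(counts[-1L] == 0L)) t_hat <- c(0, 0, 0)   # identical rows
  structure(list(b_human = t_hat[1], b_chimp = t_hat[2], b_orang = t_hat[3],
                 loglik = -opt$value, effective_length = L, counts = counts),
            class = "branch_model")
}

#' @export
print.branch_model <- function(x, ...) {
  cat(sprintf("branch_model: human %.5f chimp %.5f orang %.5f (L = %d)\n",
              x$b_human, x$b_chimp, x$b_orang, x$effective_length))
  invisible(x)
}

#' Likelihood-ratio test for human-branch acceleration
#'
#' Tests whether a region evolves faster on the human branch than a neutral
#' reference. The reference and the test region are modelled jointly: the
#' reference follows free branch lengths, the test region follows the same
#' branch lengths times one shared scale factor, and under the alternative
#' the test region's human branch additionally carries a one-sided
#' acceleration multiplier `rho >= 1`. Re-estimating the reference branch
#' lengths under both models keeps the test calibrated even for references
#' of modest length; with a very long reference it reduces to comparing
#' against fixed neutral branch lengths. Because `rho = 1` sits on the
#' boundary of the alternative, the null distribution of the statistic is
#' the 50:50 mixture of a point mass at 0 and chi-square(1). The optimiser
#' is restarted from jittered starts, keeping the best likelihood.
#'
#' @param test A [triplet_alignment] with positive effective length.
#' @param ref_branches A `branch_model` from [fit_reference].
#' @param restarts Optimiser restarts (default 100).
#' @param seed Integer seed for the jittered starts.
#' @return List of class `acceleration_lrt`: `lnL0`, `lnL1`, `statistic`,
#'   `p`, `scale`, `rho`, `converged`. Log-likelihoods include the
#'   reference term.
#' @export
lrt_acceleration <- function(test, ref_branches, restarts = 100L, seed = 1L) {
  counts <- pattern_counts(test)
  if (sum(counts) == 0L) stop("test region has zero effective length")
  rc <- ref_branches$counts
  if (is.null(rc)) stop("ref_branches lacks pattern counts; refit with fit_reference()")
  tb <- pmax(c(ref_branches$b_human, ref_branches$b_chimp, ref_branches$b_orang),
             1e-6)
  # par = (log t_h, log t_c, log t_o, log scale[, log(rho - 1)])
  nll <- function(par, rho) {
    t <- exp(par[1:3]); s <- exp(par[4])
    -.pattern_loglik(rc, t) - .pattern_loglik(counts, s * t * c(rho, 1, 1))
  }
  nll0 <- function(par) nll(par, 1)
  nll1 <- function(par) nll(par[1:4], 1 + exp(par[5]))
  start0 <- c(log(tb), 0)
  withr_seed(seed, {
    best0 <- optim(start0, nll0, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
    best1 <- NULL
    for (r in seq_len(max(1L, restarts))) {
      start <- c(best0$par, log(0.25)) +
        if (r == 1L) rep(0, 5) else rnorm(5, 0, 0.5)
      o1 <- tryCatch(
        optim(start, nll1, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(o1) && (is.null(best1) || o1$value < best1$value)) best1 <- o1
    }
    lnL0 <- -best0$value
    # the boundary rho -> 1 reduces the alternative to the null
    lnL1 <- max(-best1$value, lnL0)
    stat <- max(0, 2 * (lnL1 - lnL0))
    p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1L, lower.tail = FALSE)
    structure(list(
      lnL0 = lnL0, lnL1 = lnL1, statistic = stat, p = p,
      scale = exp(best1$par[4]), rho = 1 + exp(best1$par[5]),
      converged = !is.null(best1) && best1$convergence == 0
    ), class = "acceleration_lrt")
  })
}

#' @export
print.acceleration_lrt <- function(x, ...) {
  cat(sprintf("acceleration_lrt: stat %.3f, p %.4g (scale %.3f, rho %.3f)\n",
              x$statistic, x$p, x$scale, x$rho))
  invisible(x)
}

#' Median acceleration p-value over random neutral references
#'
#' Draws `n_refs` neutral references with replacement, fits each, runs the
#' acceleration test of `test` against each, and returns the median
#' p-value with the per-draw table. Deterministic given `seed`.
#'
#' @param test A [triplet_alignment].
#' @param refs List of neutral reference [triplet_alignment] objects.
#' @param n_refs Number of reference draws (default 100; sampling is with
#'   replacement, so fewer distinct references are fine).
#' @param restarts Optimiser restarts per test.
#' @param seed Integer seed.
#' @return List with `median_p` and `detail` (data frame `ref`,
#'   `statistic`, `p`).
#' @export
median_p_over_references <- function(test, refs, n_refs = 100L,
                                     restarts = 100L, seed = 1L) {
  stopifnot(length(refs) >= 1L)
  draws <- withr_seed(seed, sample.int(length(refs), n_refs, replace = TRUE))
  res <- lapply(seq_along(draws), function(k) {
    bm <- fit_reference(refs[[draws[k]]])
    lrt <- lrt_acceleration(test, bm, restarts = restarts, seed = seed + k)
    data.frame(ref = draws[k], statistic = lrt$statistic, p = lrt$p)
  })
  detail <- do.call(rbind, res)
  list(median_p = median(detail$p), detail = detail)
}
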