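test_that("column orientation follows the outgroup rule", {
  # human differs, orang sides with chimp: human-branch substitution
  s <- orient_and_count(triplet_alignment("G", "A", "A"))
  expect_equal(c(s$m_human, s$m_chimp, s$n_multiallelic), c(1L, 0L, 0L))
  # three distinct alleles: multiallelic, skipped
  s <- orient_and_count(triplet_alignment("G", "T", "A"))
  expect_equal(c(s$m_human, s$m_chimp, s$n_multiallelic), c(0L, 0L, 1L))
  # human = chimp != orang: orang-branch/ancestral, diagnostics only
  s <- orient_and_count(triplet_alignment("G", "G", "A"))
  expect_equal(c(s$m_human, s$m_chimp, s$n_orang_or_ancestral), c(0L, 0L, 1L))
  # gaps and ambiguity codes drop the column from the effective length
  s <- orient_and_count(triplet_alignment("A-GN", "AAGA", "AAGA"))
  expect_equal(s$effective_length, 2L)
})

test_that("orientation equals the exhaustive 64-triplet-column oracle", {
  bases <- c("A", "C", "G", "T")
  cols <- expand.grid(h = bases, c = bases, o = bases, stringsAsFactors = FALSE)
  aln <- triplet_alignment(paste(cols$h, collapse = ""),
                           paste(cols$c, collapse = ""),
                           paste(cols$o, collapse = ""))
  s <- orient_and_count(aln)
  oracle <- table(factor(mapply(classify_column, cols$h, cols$c, cols$o),
                         levels = c("invariant", "human", "chimp",
                                    "multiallelic", "orang_or_ancestral",
                                    "excluded")))
  expect_equal(s$m_human, unname(oracle[["human"]]))
  expect_equal(s$m_chimp, unname(oracle[["chimp"]]))
  expect_equal(s$n_multiallelic, unname(oracle[["multiallelic"]]))
  expect_equal(s$n_orang_or_ancestral, unname(oracle[["orang_or_ancestral"]]))
  expect_equal(s$effective_length, 64L)
})

test_that("orientation matches the brute-force oracle on random gapped alignments", {
  set.seed(12)
  for (i in 1:25) {
    aln <- random_triplet(sample(40:120, 1))
    m <- as.matrix(aln)
    cls <- mapply(classify_column, m[1, ], m[2, ], m[3, ])
    s <- orient_and_count(aln)
    expect_equal(s$m_human, sum(cls == "human"))
    expect_equal(s$m_chimp, sum(cls == "chimp"))
    expect_equal(s$n_multiallelic, sum(cls == "multiallelic"))
    expect_equal(s$effective_length, sum(cls != "excluded"))
    expect_true(s$m_human + s$m_chimp + s$n_multiallelic <= s$effective_length)
  }
})

test_that("substitution rates divide counts by effective length", {
  expect_equal(substitution_rate(0, effective_length = 100), 0)
  expect_true(is.na(substitution_rate(0, effective_length = 0)))
  s <- orient_and_count(triplet_alignment("GAAA", "AAAA", "AAAA"))
  expect_equal(substitution_rate(s, "human"), 0.25)
  expect_equal(substitution_rate(s, "chimp"), 0)
})

test_that("Tajima's relative rate test matches the chi-square oracle", {
  # frozen from the chi-square df=1 upper tail
  r <- tajima_rrt(14, 0)
  expect_equal(r$chi2, 14)
  expect_equal(r$p, 1.828106e-4, tolerance = 1e-6)
  r <- tajima_rrt(3, 1)
  expect_equal(r$chi2, 1)
  expect_equal(r$p, 0.3173105, tolerance = 1e-6)
  r <- tajima_rrt(0, 0)
  expect_equal(c(r$chi2, r$p), c(0, 1))
})

test_that("the RRT is symmetric and monotone in the count imbalance", {
  for (m in list(c(5, 2), c(14, 0), c(30, 12))) {
    expect_equal(tajima_rrt(m[1], m[2])$p, tajima_rrt(m[2], m[1])$p)
    expect_equal(tajima_rrt(m[1], m[2], method = "binomial")$p,
                 tajima_rrt(m[2], m[1], method = "binomial")$p)
  }
  n <- 30L
  ps <- vapply(15:30, function(m1) tajima_rrt(m1, n - m1)$p, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("batch RRT reports the Bonferroni threshold", {
  summaries <- data.frame(m_human = c(10, 3, 0), m_chimp = c(2, 3, 0))
  res <- rrt_batch(summaries, alpha = 0.05)
  expect_equal(attr(res, "bonferroni_threshold"), 0.05 / 3)
  expect_equal(rrt_batch(summaries[1, , drop = FALSE]) |>
                 attr("bonferroni_threshold"), 0.05)
  # equal counts never flag
  eq <- data.frame(m_human = c(4, 4), m_chimp = c(4, 4))
  expect_false(any(rrt_batch(eq)$significant_nominal))
})

test_that("category bootstrap collapses on identical members and is seeded", {
  s <- orient_and_count(triplet_alignment(strrep("G", 10), strrep("A", 10),
                                          strrep("A", 10)))
  bt <- bootstrap_category(rep(list(s), 8), B = 50, seed = 2)
  expect_equal(unname(bt$sd), c(0, 0))
  expect_equal(unname(bt$ci["human", ]), c(1, 1))
  bt2 <- bootstrap_category(rep(list(s), 8), B = 50, seed = 2)
  expect_identical(bt$boot, bt2$boot)
})

test_that("bootstrap sd approximates the binomial standard error", {
  set.seed(77)
  L <- 80L; r <- 0.02; n <- 300L
  members <- lapply(rbinom(n, L, r), function(m)
    structure(list(effective_length = L, m_human = m, m_chimp = 0L),
              class = "substitution_summary"))
  bt <- bootstrap_category(members, B = 400, seed = 3)
  analytic <- sqrt(r * (1 - r) / (n * L))
  expect_lt(abs(bt$sd[["human"]] - analytic) / analytic, 0.3)
})

test_that("category comparison requires reciprocal tail exceedance", {
  mk <- function(rate, boot) structure(
    list(rate_human = rate, rate_chimp = rate,
         ci = rbind(human = quantile(boot, c(0.025, 0.975), names = FALSE),
                    chimp = quantile(boot, c(0.025, 0.975), names = FALSE)),
         boot = list(human = boot, chimp = boot)),
    class = "category_bootstrap")
  a <- mk(0.002, rnorm(200, 0.002, 0.0002))
  expect_equal(compare_categories(a, a)$verdict, "not_distinguishable")
  b <- mk(0.014, rnorm(200, 0.014, 0.0008))
  expect_equal(compare_categories(a, b)$verdict, "different")
  # one-sided exceedance only: b's interval is huge and swallows a's rate
  b_wide <- mk(0.014, c(rnorm(190, 0.014, 0.0008), rep(0.0001, 10)))
  expect_equal(compare_categories(a, b_wide)$verdict, "not_distinguishable")
})

test_that("seed-region counting maps precursor positions through gaps", {
  # identical rows: nothing in the seed
  aln <- triplet_alignment(strrep("A", 30), strrep("A", 30), strrep("A", 30))
  seeds <- data.frame(start = 3L, end = 9L, mature_id = "m")
  expect_equal(seed_region_rates(aln, seeds)[[1]]$m_human, 0L)

  # a human change at precursor position 4 is inside seed 2-8, not outside
  h <- strsplit(strrep("A", 30), "")[[1]]; h[4] <- "G"
  aln2 <- triplet_alignment(paste(h, collapse = ""), strrep("A", 30),
                            strrep("A", 30))
  seeds2 <- data.frame(start = 2L, end = 8L, mature_id = "m")
  in_seed <- seed_region_rates(aln2, seeds2)[[1]]
  expect_equal(in_seed$m_human, 1L)
  expect_equal(in_seed$effective_length, 7L)
  outside <- seed_region_rates(aln2, data.frame(start = 10L, end = 16L,
                                                mature_id = "m"))[[1]]
  expect_equal(outside$m_human, 0L)

  # human gap upstream of the seed shifts alignment columns; a coordinate
  # walk over the gapped row is the oracle
  hg <- c("A", "A", "-", "-", "A", "C", "G", "T", "A", "A")
  aln3 <- triplet_alignment(paste(hg, collapse = ""), "AATTACGTAA", "AATTACGTAA")
  span <- c(4L, 6L)   # ungapped human positions 4..6 = columns 6..8 = C,G,T
  walk <- which(hg != "-")[span[1]:span[2]]
  expect_equal(walk, 6:8)
  s3 <- seed_region_rates(aln3, data.frame(start = span[1], end = span[2],
                                           mature_id = "m"))[[1]]
  expect_equal(s3$effective_length, 3L)
  expect_equal(s3$m_human, 0L)   # C,G,T match in all rows

  expect_error(seed_region_rates(aln, data.frame(start = 25L, end = 35L,
                                                 mature_id = "m")),
               "outside")
})

test_that("the category regression recovers known offsets exactly", {
  labels <- expand.grid(
    clustered = c("clustered", "non-clustered"),
    copies = c("multiple", "single"),
    conservation = c("ConFam", "primate-specific"),
    context = "intergenic", stringsAsFactors = FALSE)
  labels <- labels[rep(1:8, 4), ]
  # noiseless generative model: conservation offset 0.004, clustering 0.001
  rate <- 0.002 + 0.004 * (labels$conservation == "primate-specific") +
    0.001 * (labels$clustered == "non-clustered")
  w <- capture_warnings(fit <- rates_on_categories_regression(rate, labels))
  expect_true(any(grepl("context", w)))   # single-level axis dropped
  est <- setNames(fit$estimate, fit$term)
  expect_equal(unname(est["conservationprimate-specific"]), 0.004,
               tolerance = 1e-10)
  expect_equal(unname(est["clusterednon-clustered"]), 0.001, tolerance = 1e-10)
  expect_equal(unname(est["copiessingle"]), 0, tolerance = 1e-10)

  # constant rates: every non-intercept coefficient is zero
  flat <- suppressWarnings(rates_on_categories_regression(rep(0.003, 32), labels))
  expect_true(all(abs(flat$estimate[-1]) < 1e-12))
})

test_that("a pure conservation effect is detected against noise", {
  set.seed(123)
  hits <- 0L
  for (rep in 1:20) {
    n <- 400L
    labels <- data.frame(
      clustered = sample(c("clustered", "non-clustered"), n, TRUE),
      copies = sample(c("multiple", "single"), n, TRUE),
      conservation = sample(c("ConFam", "primate-specific"), n, TRUE),
      context = sample(c("intergenic", "genic:intron"), n, TRUE))
    L <- 80L
    r <- ifelse(labels$conservation == "primate-specific", 0.0056, 0.0014)
    rate <- rbinom(n, L, r) / L
    fit <- rates_on_categories_regression(rate, labels)
    p <- setNames(fit$p_value, fit$term)
    hits <- hits + (p[["conservationprimate-specific"]] < 0.05)
  }
  expect_gte(hits, 19L)
})
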