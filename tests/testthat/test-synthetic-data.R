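test_that("zero branch rates give three identical rows everywhere", {
  cfg <- simulation_config(
    n_mirnas = c(x = 10L),
    branch_rates = list(x = c(human = 0, chimp = 0, orang = 0)),
    flank_rates = list(x = c(human = 0, chimp = 0, orang = 0)),
    neutral_rates = c(human = 0, chimp = 0, orang = 0), seed = 4L)
  sim <- simulate_triplets(cfg)
  for (a in sim$alignments)
    expect_length(unique(unname(a$seqs)), 1L)
  refs <- simulate_neutral_refs(cfg, 5L)
  for (a in refs) expect_length(unique(unname(a$seqs)), 1L)
  expect_true(all(sim$truth$m_human == 0))
})

test_that("oriented human counts recover the configured rate (binomial oracle)", {
  r <- 0.02
  cfg <- simulation_config(
    n_mirnas = c(x = 1000L),
    branch_rates = list(x = c(human = r, chimp = 0, orang = 0)),
    flank_rates = list(x = c(human = 0, chimp = 0, orang = 0)),
    cpg_multiplier = 1, seed = 11L)
  sim <- simulate_triplets(cfg)
  summ <- lapply(sim$alignments, orient_and_count)
  m <- sum(vapply(summ, `[[`, numeric(1), "m_human"))
  L <- sum(vapply(summ, `[[`, numeric(1), "effective_length"))
  # with chimp/orang frozen, counts are exactly Binomial(L, r)
  se <- sqrt(r * (1 - r) / L)
  expect_lt(abs(m / L - r), 3 * se)
  # and the oriented counts equal the generator's truth
  expect_equal(vapply(summ, `[[`, numeric(1), "m_human"),
               setNames(as.numeric(sim$truth$m_human), sim$truth$mirna_id))
})

test_that("an unbiased generator yields a W>S bias near one half", {
  cfg <- simulation_config(
    n_mirnas = c(x = 600L),
    branch_rates = list(x = c(human = 0.02, chimp = 0.02, orang = 0)),
    flank_rates = list(x = c(human = 0, chimp = 0, orang = 0)),
    cpg_multiplier = 1, ws_bias = 0.5, seed = 5L)
  sim <- simulate_triplets(cfg)
  wp <- ws_partition(concatenate_by_category(sim$alignments))
  n <- wp$n_WS + wp$n_SW
  expect_gt(n, 300)
  expect_lt(abs(wp$ws_bias - 0.5), 3 * sqrt(0.25 / n))
})

test_that("simulation output is deterministic given the seed", {
  cfg <- small_config(seed = 99L)
  s1 <- simulate_triplets(cfg, genomes = TRUE)
  s2 <- simulate_triplets(cfg, genomes = TRUE)
  expect_identical(lapply(s1$alignments, `[[`, "seqs"),
                   lapply(s2$alignments, `[[`, "seqs"))
  expect_identical(s1$mfe, s2$mfe)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(simulate_neutral_refs(cfg, 20L),
                   simulate_neutral_refs(cfg, 20L))
})

test_that("neutral references have precursor-like lengths", {
  refs <- simulate_neutral_refs(small_config(), 100L)
  expect_length(refs, 100L)
  w <- vapply(refs, `[[`, numeric(1), "width")
  expect_true(all(w >= 70 & w <= 91))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(ws_bias = 1.2))
  expect_error(simulation_config(cpg_multiplier = 0.5))
  expect_error(simulation_config(n_mirnas = c(a = -1L)))
  expect_error(simulation_config(
    n_mirnas = c(a = 1L),
    branch_rates = list(a = c(human = -0.01, chimp = 0, orang = 0))))
})

test_that("injected indels create filterable loci and fixtures stay consistent", {
  cfg <- small_config(n_ps = 30L, n_cf = 0L, seed = 21L, indel_rate = 0.3)
  sim <- simulate_triplets(cfg)
  gapped <- vapply(sim$alignments, function(a) grepl("-", a$seqs[["human"]]),
                   logical(1))
  expect_gt(sum(gapped), 0L)
  rej <- Filter(function(x) inherits(x, "curation_rejection"),
                lapply(sim$alignments, trim_and_filter_alignment))
  expect_setequal(names(rej), names(which(gapped)))
  expect_true(all(vapply(rej, `[[`, character(1), "reason") == "gap"))
})

test_that("the fixture tree round-trips through the format readers", {
  cfg <- small_config(n_ps = 12L, n_cf = 8L, seed = 13L)
  sim <- simulate_triplets(cfg, genomes = TRUE)
  dir <- withr::local_tempdir()
  write_fixture_tree(sim, dir)

  hits <- read_psl(file.path(dir, "blat_chimp.psl"))
  expect_equal(nrow(hits), 20L)
  expect_equal(hits$identity, rep(1, 20L))
  expect_equal(hits$start, sim$loci$start_chimp)

  bed <- read_bed6(file.path(dir, "liftover_orang.bed"))
  expect_equal(bed$start, sim$loci$start_orang)
  expect_equal(bed$name, sim$loci$mirna_id)

  ann <- read_mirna_gff3(file.path(dir, "mirnas.gff3"))
  expect_equal(ann$precursors$mirna_id, sim$loci$mirna_id)
  expect_equal(ann$precursors$start, sim$loci$start)

  fam <- read_family_file(file.path(dir, "families.dat"))
  expect_true(all(fam$members$mirna_id[fam$members$primate == FALSE] %in%
                    sub("^hsa", "mmu", sim$loci$mirna_id)))

  aln <- read_alignment(file.path(dir, "alignments",
                                  paste0(sim$loci$mirna_id[1], ".fa")))
  expect_identical(aln$seqs, sim$alignments[[1]]$seqs)

  # genome slices at the recorded coordinates reproduce the aligned rows
  iv <- sim$loci[3, ]
  g <- sim$genomes$human[["chr1"]]
  seq <- substr(g, iv$start + 1, iv$end)
  if (iv$strand == "-") seq <- mirtrio:::rev_comp(seq)
  expect_equal(seq, unname(sim$alignments[[3]]$seqs[["human"]]))
})
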