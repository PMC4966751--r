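make_hits <- function(...) do.call(rbind, list(...))
hit_row <- function(qname = "q", len = 70L, id = 1.0, qsize = 70L,
                    chr = "chr1", start = 1000L, strand = "+") {
  data.frame(query_id = qname, seq_name = chr, start = start,
             end = start + len, strand = strand, matched_length = len,
             identity = id, query_length = qsize, stringsAsFactors = FALSE)
}

test_that("best BLAT hit selection enforces coverage then length then identity", {
  # coverage filter: 0.70 of query dropped, 0.95 kept
  hits <- make_hits(hit_row(len = 66L, id = 0.9), hit_row(len = 49L, id = 1.0))
  expect_equal(select_best_blat_hit(hits)$matched_length, 66L)
  # equal-length hits ranked by identity
  hits <- make_hits(hit_row(id = 0.92, start = 5000L), hit_row(id = 0.98))
  expect_equal(select_best_blat_hit(hits)$identity, 0.98)
  # nothing survives the 80% rule
  expect_null(select_best_blat_hit(make_hits(hit_row(len = 40L))))
  expect_error(select_best_blat_hit(
    make_hits(hit_row("a"), hit_row("b"))), "mix query ids")
})

test_that("exact ties break deterministically and are order-invariant", {
  rows <- list(hit_row(chr = "chr7", start = 99L), hit_row(chr = "chr1", start = 500L),
               hit_row(chr = "chr1", start = 200L))
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1), c(2, 1, 3), c(1, 3, 2))
  picks <- lapply(perms, function(p) select_best_blat_hit(do.call(rbind, rows[p])))
  for (pk in picks) {
    expect_equal(pk$seq_name, "chr1")
    expect_equal(pk$start, 200L)
    expect_true(pk$ambiguous)
  }
})

test_that("BLAT and liftOver evidence reconciles per the overlap rule", {
  blat <- hit_row(start = 100L, len = 80L)          # [100, 180)
  lift <- data.frame(seq_name = "chr1", start = 95L, end = 178L, strand = "+")
  call <- resolve_orthology(blat, lift)
  expect_equal(call$evidence, "blat+liftover")
  expect_equal(c(call$interval$start, call$interval$end), c(95L, 180L))

  expect_equal(resolve_orthology(NULL, lift)$evidence, "liftover_only")
  expect_equal(resolve_orthology(blat, NULL)$evidence, "blat_only")

  lift7 <- data.frame(seq_name = "chr7", start = 95L, end = 178L, strand = "+")
  expect_equal(resolve_orthology(blat, lift7)$evidence, "discordant")
  expect_null(resolve_orthology(blat, lift7)$interval)
  lift_m <- data.frame(seq_name = "chr1", start = 95L, end = 178L, strand = "-")
  expect_equal(resolve_orthology(blat, lift_m)$evidence, "discordant")
})

test_that("many-to-one groups are removed entirely", {
  call_row <- function(id, s_chimp, s_orang = s_chimp + 5000L) {
    data.frame(mirna_id = id,
               seq_name_chimp = "chr1", start_chimp = s_chimp,
               end_chimp = s_chimp + 80L, strand_chimp = "+",
               seq_name_orang = "chr1", start_orang = s_orang,
               end_orang = s_orang + 80L, strand_orang = "+",
               retained = TRUE, stringsAsFactors = FALSE)
  }
  # two miRNAs on the same chimp locus: both removed
  calls <- rbind(call_row("a", 1000L, 9000L), call_row("b", 1000L, 50000L),
                 call_row("c", 30000L, 90000L))
  res <- exclude_many_to_one(calls)
  expect_setequal(res$removed, c("a", "b"))
  expect_equal(res$calls$mirna_id, "c")

  # unique assignments survive untouched
  calls_u <- rbind(call_row("a", 1000L), call_row("b", 30000L))
  expect_equal(exclude_many_to_one(calls_u)$n_removed, 0L)

  # three-way pile-up: chained overlaps remove all three (brute-force graph:
  # a-b and b-c overlap reciprocally, so {a,b,c} is one component)
  calls3 <- rbind(call_row("a", 1000L, 9000L), call_row("b", 1030L, 60000L),
                  call_row("c", 1060L, 120000L))
  ov_ab <- (1080 - 1030) / 80  # 62% reciprocal
  expect_gt(ov_ab, 0.5)
  expect_setequal(exclude_many_to_one(calls3)$removed, c("a", "b", "c"))
})

test_that("alignment trimming applies the coverage and internal-gap rules", {
  w <- 50L
  perfect <- triplet_alignment(strrep("A", w), strrep("A", w), strrep("A", w))
  expect_identical(as.matrix(trim_and_filter_alignment(perfect)),
                   as.matrix(perfect))

  # chimp covering 60% of the human precursor is rejected
  chimp60 <- paste0(strrep("-", 20L), strrep("A", 30L))
  rej <- trim_and_filter_alignment(
    triplet_alignment(strrep("A", w), chimp60, strrep("A", w)))
  expect_s3_class(rej, "curation_rejection")
  expect_equal(rej$reason, "coverage")

  # a 25-nt internal human gap is rejected; 20 nt is tolerated
  gap25 <- paste0(strrep("A", 10L), strrep("-", 25L), strrep("A", 15L))
  full <- strrep("A", 50L)
  rej2 <- trim_and_filter_alignment(triplet_alignment(gap25, full, full))
  expect_equal(rej2$reason, "gap")
  gap20 <- paste0(strrep("A", 10L), strrep("-", 20L), strrep("A", 20L))
  expect_s3_class(trim_and_filter_alignment(triplet_alignment(gap20, full, full)),
                  "triplet_alignment")

  # trimming to the human span drops flanking columns
  aln <- triplet_alignment("TTACGTACGTTT", "TTACGTACGTTT", "TTACGTACGTTT")
  tr <- trim_and_filter_alignment(aln, human_span = c(3L, 10L))
  expect_equal(tr$width, 8L)
  expect_equal(unname(tr$seqs[["human"]]), "ACGTACGT")
})

test_that("the MFE filter thresholds at the reference 95th percentile", {
  set.seed(31)
  ref <- rnorm(100, -37.9, 8)
  alns <- list(
    good = triplet_alignment("ACGT", "ACGT", "ACGT", id = "good"),
    weak = triplet_alignment("ACGT", "ACGT", "ACGT", id = "weak")
  )
  thr <- quantile(ref, 0.95, names = FALSE)
  mfes <- data.frame(
    id = c(t(outer(c("good", "weak"), c("human", "chimp", "orang"), paste, sep = "|"))),
    mfe = c(rep(thr - 10, 3), thr - 10, thr - 10, -2)   # weak orang hairpin
  )
  res <- mfe_filter(alns, mfes, ref)
  expect_equal(res$threshold, thr)
  expect_named(res$kept, "good")
  expect_named(res$rejected, "weak")

  mfes_missing <- mfes[-2, ]
  expect_error(mfe_filter(alns, mfes_missing, ref), "good\\|chimp")
})

test_that("flank extraction keeps the 40 bp adjacent to the precursor", {
  cfg <- small_config(n_ps = 10L, n_cf = 0L, seed = 17L)
  sim <- simulate_triplets(cfg, genomes = TRUE)
  i <- match("+", sim$loci$strand)
  iv <- function(sp) {
    if (sp == "human") data.frame(seq_name = sim$loci$seq_name[i],
                                  start = sim$loci$start[i],
                                  end = sim$loci$end[i],
                                  strand = sim$loci$strand[i])
    else data.frame(seq_name = sim$loci$seq_name[i],
                    start = sim$loci[[paste0("start_", sp)]][i],
                    end = sim$loci[[paste0("end_", sp)]][i],
                    strand = sim$loci$strand[i])
  }
  intervals <- list(human = iv("human"), chimp = iv("chimp"), orang = iv("orang"))
  fl <- extract_flank_alignment(intervals, sim$genomes,
                                id = sim$loci$mirna_id[i])
  expect_s3_class(fl, "triplet_alignment")
  expect_equal(fl$width, 80L)
  # the generator's own flank alignment is the ground truth
  expect_identical(fl$seqs, sim$flank_alignments[[i]]$seqs)
})

test_that("minus-strand flanks are taken in transcript orientation", {
  cfg <- small_config(n_ps = 10L, n_cf = 0L, seed = 18L)
  sim <- simulate_triplets(cfg, genomes = TRUE)
  i <- match("-", sim$loci$strand)
  intervals <- lapply(setNames(c("human", "chimp", "orang"),
                               c("human", "chimp", "orang")), function(sp) {
    if (sp == "human") data.frame(seq_name = sim$loci$seq_name[i],
                                  start = sim$loci$start[i],
                                  end = sim$loci$end[i], strand = "-")
    else data.frame(seq_name = sim$loci$seq_name[i],
                    start = sim$loci[[paste0("start_", sp)]][i],
                    end = sim$loci[[paste0("end_", sp)]][i], strand = "-")
  })
  fl <- extract_flank_alignment(intervals, sim$genomes)
  expect_identical(fl$seqs, sim$flank_alignments[[i]]$seqs)

  # reverse-complement oracle: the kept upstream human flank must equal the
  # reverse complement of the 40 bp genomic segment right of the locus
  g <- sim$genomes$human[[sim$loci$seq_name[i]]]
  seg <- substr(g, sim$loci$end[i] + 1, sim$loci$end[i] + 40)
  expect_equal(substr(fl$seqs[["human"]], 1, 40), mirtrio:::rev_comp(seg))
})

test_that("truncated or strand-discordant flanks are rejected", {
  # chimp locus at a contig edge: only ~15 bp of downstream flank exist, so
  # the aligned flank spans far less than 50% of the targeted 80 bp
  set.seed(41)
  core <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  flankL <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  flankR <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  genomes <- list(
    human = c(chr1 = paste0(flankL, core, flankR)),
    chimp = c(chr1 = paste0(core, substr(flankR, 1, 15))),
    orang = c(chr1 = paste0(flankL, core, flankR))
  )
  intervals <- list(
    human = data.frame(seq_name = "chr1", start = 100L, end = 180L, strand = "+"),
    chimp = data.frame(seq_name = "chr1", start = 0L, end = 80L, strand = "+"),
    orang = data.frame(seq_name = "chr1", start = 100L, end = 180L, strand = "+")
  )
  rej <- extract_flank_alignment(intervals, genomes)
  expect_s3_class(rej, "curation_rejection")
  expect_equal(rej$reason, "flank_coverage")

  # with a full chimp contig the same locus passes
  genomes$chimp <- genomes$human
  intervals$chimp <- intervals$human
  ok <- extract_flank_alignment(intervals, genomes)
  expect_s3_class(ok, "triplet_alignment")
  expect_equal(ok$width, 80L)

  rej2 <- extract_flank_alignment(intervals, genomes,
                                  precursor_strand = c(chimp = "-"))
  expect_equal(rej2$reason, "strand")
})

test_that("ancestral repeats are curated by length, reciprocity and chromosome", {
  ars <- data.frame(
    ar_id = c("a", "b", "c", "d"),
    length = c(65L, 80L, 85L, 75L),
    reciprocal_chimp = c(TRUE, TRUE, TRUE, FALSE),
    reciprocal_orang = TRUE,
    seq_name = "chr2",
    seq_name_chimp = c("chr2", "chr2", "chr5", "chr2"),
    seq_name_orang = "chr2", stringsAsFactors = FALSE
  )
  kept <- curate_ancestral_repeats(ars)
  expect_equal(kept$ar_id, "b")   # a: short, c: chromosome, d: reciprocity
  expect_equal(attr(kept, "n_removed"), 3L)
})

test_that("the curation funnel is monotone and reasons partition rejections", {
  cfg <- small_config(n_ps = 40L, n_cf = 0L, seed = 23L, indel_rate = 0.2)
  sim <- simulate_triplets(cfg)
  out <- lapply(sim$alignments, trim_and_filter_alignment)
  kept <- Filter(function(x) inherits(x, "triplet_alignment"), out)
  rej <- Filter(function(x) inherits(x, "curation_rejection"), out)
  expect_equal(length(kept) + length(rej), length(sim$alignments))
  expect_true(all(names(kept) %in% names(sim$alignments)))
})
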