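#' Configuration for a full pipeline run
#'
#' Collects stage toggles, thresholds and seeds in one object. Every
#' published threshold of the workflow is a named key with its standard
#' default: 80% alignment coverage, 20-nt internal gap limit, 5% MFE right
#' tail, 10-kb cluster gap, 50-kb intergenic distance, 70-91 bp neutral
#' reference lengths, 40-bp flanks with 50% coverage, 100 bootstrap
#' resamples and 1000 permutations.
#'
#' @param sim A [simulation_config] describing the dataset to generate.
#' @param stages Character vector of stages to run, in order, out of
#'   `simulate`, `curate`, `classify`, `rates`, `composition`, `lrt`,
#'   `enrich`.
#' @param min_coverage,max_internal_gap,mfe_tail,cluster_gap,
#'   intergenic_distance,flank_length,flank_min_coverage,ar_length_range
#'   Curation/classification thresholds (defaults above).
#' @param bootstrap_B,n_neutral_refs,lrt_n_refs,lrt_restarts,perm_B
#'   Resampling sizes.
#' @param seed Master seed for all stage-level randomness.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(),
                       stages = c("simulate", "curate", "classify", "rates",
                                  "composition", "lrt"),
                       min_coverage = 0.8, max_internal_gap = 20L,
                       mfe_tail = 0.05, cluster_gap = 10000L,
                       intergenic_distance = 50000L, flank_length = 40L,
                       flank_min_coverage = 0.5,
                       ar_length_range = c(70L, 91L),
                       bootstrap_B = 100L, n_neutral_refs = 100L,
                       lrt_n_refs = 20L, lrt_restarts = 5L,
                       perm_B = 1000L, seed = 1L) {
  stopifnot(inherits(sim, "simulation_config"),
            all(stages %in% c("simulate", "curate", "classify", "rates",
                              "composition", "lrt", "enrich")),
            min_coverage > 0, min_coverage <= 1, max_internal_gap >= 0,
            mfe_tail > 0, mfe_tail < 1, bootstrap_B >= 1, perm_B >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes the enabled stages in order: data simulation; curation
#' (human-anchored trimming with coverage/gap filters, then the MFE
#' filter); category classification; per-category substitution rates with
#' Tajima's relative rate test and bootstrap intervals; CpG / weak-strong
#' composition partitioning; the acceleration likelihood-ratio test of each
#' conservation category against neutral references; and optionally a
#' permutation-calibrated enrichment demo on fabricated targets. The run
#' report carries the filter funnel, a category rate table (one row per
#' category and axis, with bootstrap standard deviations), the RRT table
#' and a manifest of seeds, and is identical across runs with the same
#' configuration.
#'
#' @param config A [run_config].
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  report <- list(manifest = list(seed = config$seed,
                                 sim_seed = config$sim$seed,
                                 stages = st))
  sim <- simulate_triplets(config$sim)
  report$n_input <- nrow(sim$loci)
  alignments <- sim$alignments
  labels <- sim$labels

  if ("curate" %in% st) {
    kept <- list(); rejections <- list()
    for (id in names(alignments)) {
      res <- trim_and_filter_alignment(alignments[[id]],
                                       min_coverage = config$min_coverage,
                                       max_internal_gap = config$max_internal_gap)
      if (inherits(res, "curation_rejection")) rejections[[id]] <- res$reason
      else kept[[id]] <- res
    }
    ref_mfes <- sim$mfe$mfe[grepl("\\|human$", sim$mfe$id)]
    mf <- mfe_filter(kept, sim$mfe, ref_mfes, tail = config$mfe_tail)
    for (id in names(mf$rejected)) rejections[[id]] <- "mfe"
    alignments <- mf$kept
    reasons <- unlist(rejections)
    report$funnel <- list(
      input = report$n_input,
      kept = length(alignments),
      rejected = if (length(reasons)) table(reasons) else table(character()),
      mfe_threshold = mf$threshold
    )
    stopifnot(report$funnel$input ==
                report$funnel$kept + sum(report$funnel$rejected))
    labels <- labels[labels$mirna_id %in% names(alignments), , drop = FALSE]
  }

  if ("classify" %in% st) {
    cl <- assign_clusters(sim$loci[sim$loci$mirna_id %in% labels$mirna_id, ],
                          max_gap = config$cluster_gap)
    labels$clustered <- cl$clustered[match(labels$mirna_id, cl$mirna_id)]
    report$labels <- labels
    report$contingency <- list(
      copies_vs_cluster = category_contingency(labels, "copies", "clustered"),
      conservation_vs_cluster =
        category_contingency(labels, "conservation", "clustered")
    )
  }

  summaries <- lapply(alignments, orient_and_count)
  flank_summaries <- lapply(sim$flank_alignments[names(alignments)],
                            orient_and_count)

  if ("rates" %in% st) {
    axes <- list(conservation = unique(labels$conservation),
                 clustered = unique(labels$clustered),
                 copies = unique(labels$copies),
                 context = c("intergenic", "genic:exon", "genic:intron"))
    rows <- list()
    boots <- list()
    for (axis in names(axes)) for (lev in axes[[axis]]) {
      ids <- labels$mirna_id[labels[[axis]] == lev]
      mem <- summaries[ids]
      if (length(mem) < 2L) next
      bt <- bootstrap_category(mem, B = config$bootstrap_B,
                               seed = config$seed + length(boots))
      fbt <- bootstrap_category(flank_summaries[ids], B = config$bootstrap_B,
                                seed = config$seed + 1000L + length(boots))
      m1 <- sum(vapply(mem, `[[`, numeric(1), "m_human"))
      m2 <- sum(vapply(mem, `[[`, numeric(1), "m_chimp"))
      L <- sum(vapply(mem, `[[`, numeric(1), "effective_length"))
      rrt <- tajima_rrt(m1, m2)
      boots[[paste(axis, lev, sep = ":")]] <- bt
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, level = lev, n_mirnas = length(mem),
        effective_length = L, subs_human = m1, subs_chimp = m2,
        rate_human = round_half_up(bt$rate_human, 4),
        sd_human = round_half_up(bt$sd[["human"]], 4),
        rate_chimp = round_half_up(bt$rate_chimp, 4),
        sd_chimp = round_half_up(bt$sd[["chimp"]], 4),
        flank_rate_human = round_half_up(fbt$rate_human, 4),
        flank_rate_chimp = round_half_up(fbt$rate_chimp, 4),
        rrt_chi2 = rrt$chi2, rrt_p = rrt$p, stringsAsFactors = FALSE)
    }
    report$rate_table <- do.call(rbind, rows)
    report$bootstraps <- boots
    report$rrt <- rrt_batch(unname(summaries))
    cons <- axes$conservation
    if (length(cons) == 2L) {
      a <- boots[[paste0("conservation:", cons[1])]]
      b <- boots[[paste0("conservation:", cons[2])]]
      report$category_comparison <- compare_categories(a, b)
    }
    per_rate <- vapply(summaries, substitution_rate, numeric(1))
    lab_m <- labels[match(names(summaries), labels$mirna_id), ]
    report$regression <- tryCatch(
      rates_on_categories_regression(per_rate, lab_m),
      warning = function(w) suppressWarnings(
        rates_on_categories_regression(per_rate, lab_m)))
  }

  if ("composition" %in% st) {
    comp <- list()
    for (lev in unique(labels$conservation)) {
      ids <- labels$mirna_id[labels$conservation == lev]
      cat_aln <- concatenate_by_category(alignments[ids])
      s <- orient_and_count(cat_aln)
      comp[[lev]] <- list(cpg = count_cpg_transitions(cat_aln, s),
                          ws = ws_partition(cat_aln, s),
                          per_type = per_type_rates(cat_aln, s))
    }
    if (length(comp) == 2L) {
      comp$cpg_test <- proportion_test(comp[[1]]$cpg, comp[[2]]$cpg,
                                       "cpg_vs_noncpg")
      comp$ws_test <- proportion_test(comp[[1]]$ws, comp[[2]]$ws, "sw_vs_ws")
    }
    report$composition <- comp
  }

  if ("lrt" %in% st) {
    refs <- simulate_neutral_refs(config$sim, config$n_neutral_refs)
    lrt_res <- list()
    for (lev in unique(labels$conservation)) {
      ids <- labels$mirna_id[labels$conservation == lev]
      cat_aln <- concatenate_by_category(alignments[ids])
      lrt_res[[lev]] <- median_p_over_references(
        cat_aln, refs, n_refs = config$lrt_n_refs,
        restarts = config$lrt_restarts, seed = config$seed)$median_p
    }
    report$lrt_median_p <- unlist(lrt_res)
  }

  if ("enrich" %in% st) {
    report$enrichment <- withr_seed(config$seed + 7L, {
      genes <- sprintf("g%04d", 1:1500)
      mirnas <- names(alignments)
      targets <- do.call(rbind, lapply(mirnas, function(m) data.frame(
        mirna_id = m, gene_id = sample(genes, 25L), conserved = TRUE,
        context_score = -0.5, stringsAsFactors = FALSE)))
      go_map <- do.call(rbind, lapply(sprintf("GO:%07d", 1:60), function(t)
        data.frame(gene_id = sample(genes, 40L), go_id = t,
                   stringsAsFactors = FALSE)))
      sets <- filter_targets(targets)
      rate_h <- vapply(summaries, substitution_rate, numeric(1))
      top <- names(sort(rate_h, decreasing = TRUE))[1:10]
      study <- unique(unlist(sets[top], use.names = FALSE))
      obs <- fisher_enrichment(study, genes, go_map)
      permutation_calibration(obs, sets, genes, go_map, k = 10L,
                              B = config$perm_B, seed = config$seed + 8L)
    })
  }

  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", x$n_input, "simulated loci\n")
  if (!is.null(x$funnel))
    cat("  curation: kept", x$funnel$kept, "of", x$funnel$input, "\n")
  if (!is.null(x$rate_table)) {
    cat("  category rates:\n")
    print(x$rate_table[, c("axis", "level", "n_mirnas", "rate_human",
                           "rate_chimp")], row.names = FALSE)
  }
  if (!is.null(x$lrt_median_p)) {
    cat("  acceleration LRT median p:\n")
    print(x$lrt_median_p)
  }
  invisible(x)
}
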