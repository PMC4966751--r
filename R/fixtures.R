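#' Write a simulated dataset as an on-disk fixture tree
#'
#' Materialises a [simulate_triplets] result in the external formats the
#' pipeline parses: per-locus aligned FASTA, BLAT PSL and liftOver BED per
#' non-human species, a miRBase-style GFF3 of precursors/matures, a
#' miFam-layout family file, an MFE TSV, gene annotation TSVs, the truth
#' table, and (when genomes were assembled) per-species genome FASTA.
#'
#' @param sim A `triplet_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_tree <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aln_dir <- file.path(dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (id in names(sim$alignments))
    write_alignment(sim$alignments[[id]], file.path(aln_dir, paste0(id, ".fa")))

  loci <- sim$loci
  for (sp in c("chimp", "orang")) {
    s0 <- loci[[paste0("start_", sp)]]
    e0 <- loci[[paste0("end_", sp)]]
    w <- loci$width
    psl <- data.frame(
      matches = w, misMatches = 0L, repMatches = 0L, nCount = 0L,
      qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L, tBaseInsert = 0L,
      strand = loci$strand, qName = loci$mirna_id, qSize = w,
      qStart = 0L, qEnd = w, tName = loci$seq_name, tSize = 50000000L,
      tStart = s0, tEnd = e0, blockCount = 1L,
      blockSizes = paste0(w, ","), qStarts = "0,",
      tStarts = paste0(s0, ","), stringsAsFactors = FALSE
    )
    write.table(psl, file.path(dir, paste0("blat_", sp, ".psl")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    bed <- data.frame(loci$seq_name, s0, e0, loci$mirna_id, 0L, loci$strand)
    write.table(bed, file.path(dir, paste0("liftover_", sp, ".bed")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  .write_mirna_gff3(sim, file.path(dir, "mirnas.gff3"))
  .write_family_file(sim$family, file.path(dir, "families.dat"))
  write.table(sim$mfe, file.path(dir, "mfe.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genes$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genes$parts, file.path(dir, "gene_parts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (!is.null(sim$genomes)) {
    for (sp in names(sim$genomes)) {
      xs <- Biostrings::DNAStringSet(sim$genomes[[sp]])
      Biostrings::writeXStringSet(xs, file.path(dir, paste0("genome_", sp, ".fa")))
    }
  }
  invisible(dir)
}

.write_mirna_gff3 <- function(sim, path) {
  loci <- sim$loci
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(loci))) {
    id <- loci$mirna_id[i]
    acc <- sprintf("MI9%06d", i)
    writeLines(sprintf(
      "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      loci$seq_name[i], loci$start[i] + 1L, loci$end[i], loci$strand[i],
      acc, id), con)
    seeds_i <- sim$seeds[sim$seeds$mirna_id == id, , drop = FALSE]
    for (j in seq_len(nrow(seeds_i))) {
      # mature span in genome coordinates, strand-aware
      ms <- seeds_i$mature_start[j]; me <- seeds_i$mature_end[j]
      if (loci$strand[i] == "+") {
        g1 <- loci$start[i] + ms; g2 <- loci$start[i] + me
      } else {
        g1 <- loci$end[i] - me + 1L; g2 <- loci$end[i] - ms + 1L
      }
      writeLines(sprintf(
        "%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
        loci$seq_name[i], g1, g2, loci$strand[i],
        paste0(acc, "_", j), seeds_i$mature_id[j], acc), con)
    }
  }
  invisible(path)
}

.write_family_file <- function(stanzas, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in stanzas) {
    writeLines(paste("AC  ", s$ac), con)
    writeLines(paste("ID  ", s$id), con)
    for (k in seq_along(s$members))
      writeLines(sprintf("MI   MI9%06d  %s", k, s$members[k]), con)
    writeLines("//", con)
  }
  invisible(path)
}
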