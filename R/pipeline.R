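# Orchestration: simulate -> write standard-format files -> parse them back
# -> screen -> composition statistics -> census, with a run manifest that
# records the seed, the stage funnel and output digests. Every stage reads
# only what the previous stage wrote, so the run exercises the same format
# boundaries a run on real data would.

#' Run the simulate/screen/stats/census pipeline on a synthetic genome
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param evalue_cutoff,z_threshold Screen thresholds (defaults 1e-10 and 2).
#' @return A run manifest: list with `config`, `seed`, `funnel`, `screen`
#'   (the `hgt_screen` object), `stats` (GC ANOVA/Tukey, intron
#'   Kruskal-Wallis), `census` (count table and HGT crosstab), `outputs`
#'   (paths and md5 digests).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("hgtrun"),
                         evalue_cutoff = 1e-10, z_threshold = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  # --- simulate ------------------------------------------------------------
  genome <- simulate_genome(config)
  tracks <- simulate_coverage(genome)
  blast <- emit_blast_hits(genome)
  write_genome_fasta(genome, p("genome.fasta"))
  write_genome_gff3(genome, p("genes.gff3"))
  write_depth(tracks, p("depth.tsv"))
  write_blast6(blast$hits, p("hits.blast6"))
  write_tsv(blast$taxonomy_map, p("taxonomy_map.tsv"))
  write_tsv(genome$truth, p("truth.tsv"))

  # --- screen (from the files) --------------------------------------------
  genes <- parse_gff3(p("genes.gff3"))
  fasta <- Biostrings::readDNAStringSet(p("genome.fasta"))
  sc_len <- stats::setNames(Biostrings::width(fasta), names(fasta))
  depth <- parse_depth(p("depth.tsv"), scaffold_lengths = sc_len)
  hits <- parse_blast6(p("hits.blast6"), read_taxonomy_map(p("taxonomy_map.tsv")))
  screen <- hgt_screen(genes, hits, depth, evalue_cutoff = evalue_cutoff,
                       z_threshold = z_threshold)
  write_tsv(screen$candidates, p("candidates.tsv"))
  write_tsv(summarize_donor_taxa(screen), p("donors.tsv"))

  # --- composition statistics ---------------------------------------------
  cds <- gene_cds(list(genes = genes, seqs = as.character(fasta)))
  calls <- screen$calls
  fungal_ids <- calls$gene_id[calls$call == "fungal"]
  hgt_ids <- screen$final
  hgt_scaffolds <- unique(genes$scaffold_id[genes$gene_id %in% hgt_ids])
  neighbor_ids <- intersect(
    fungal_ids, genes$gene_id[genes$scaffold_id %in% hgt_scaffolds])
  group <- stats::setNames(rep("all_fungal", nrow(genes)), genes$gene_id)
  group[neighbor_ids] <- "neighbor_fungal"
  group[hgt_ids] <- "hgt"
  comp <- gene_composition(genes, cds, group)
  comp <- comp[comp$gene_id %in% c(fungal_ids, hgt_ids), ]
  stats_out <- list()
  if (length(hgt_ids) >= 2 && length(neighbor_ids) >= 2) {
    gc_groups <- list(hgt = comp$gc[comp$group == "hgt"],
                      neighbor_fungal = comp$gc[comp$group == "neighbor_fungal"],
                      all_fungal = comp$gc[comp$group != "hgt"])
    stats_out$gc_anova <- anova_oneway(gc_groups)
    stats_out$gc_tukey <- tukey_hsd(gc_groups)
    stats_out$intron_kw <- kruskal_wallis(list(
      hgt = comp$n_introns[comp$group == "hgt"],
      fungal = comp$n_introns[comp$group != "hgt"]))
  }
  write_tsv(comp, p("composition.tsv"))

  # --- census --------------------------------------------------------------
  truth <- genome$truth
  sm <- truth[!is.na(truth$sm_class), ]
  census <- NULL
  if (nrow(sm) > 0) {
    ledger <- data.frame(gene_id = sm$gene_id, genome_id = "synthetic",
                         sm_class = sm$sm_class, cluster_id = sm$cluster_id,
                         source = "antismash", stringsAsFactors = FALSE)
    census <- list(counts = tabulate_sm_counts(ledger),
                   crosstab = crosstab_hgt(ledger, screen$final))
    write_tsv(census$counts, p("table1.tsv"))
    write_tsv(census$crosstab, p("table2.tsv"))
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- list(config = config, seed = config$seed,
                   funnel = screen$funnel, screen = screen,
                   stats = stats_out, census = census,
                   truth = truth,
                   outputs = data.frame(
                     file = basename(outputs),
                     md5 = unname(tools::md5sum(outputs)),
                     stringsAsFactors = FALSE))
  class(manifest) <- "hgt_run"
  manifest
}

#' @export
print.hgt_run <- function(x, ...) {
  cat("hgtcensus pipeline run (seed ", x$seed, ")\n", sep = "")
  print.hgt_screen(x$screen)
  invisible(x)
}
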