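# Packaged reference tables for the three Basidiobolus isolates: per-genome
# SM core-gene counts, the published HGT x SM cross-tabulation, and the
# per-gene list of SM core genes with HGT evidence (coverage z-score, SM
# class, best-hit donor taxon). Shipped as plain TSV under extdata; the
# per-gene list and the cross-tabulation disagree by one NRPS gene for
# B. meristosporus CBS 931.73 (27 vs 26 rows), a known inconsistency of the
# source tables; counts are taken as authoritative and percentages are
# always recomputed.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "hgtcensus")
  if (p == "") stop("missing packaged table: ", file)
  p
}

#' Packaged SM core-gene counts per Basidiobolus genome
#' @return Data frame: `genome_id`, `Total`, `NRPS/NRPS-like`,
#'   `PKS/PKS-like`, `NRPS-PKS hybrids`, `TC`.
#' @export
load_sm_core_counts <- function() {
  utils::read.delim(ref_path("basidiobolus_sm_core_counts.tsv"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Packaged HGT x SM cross-tabulation per Basidiobolus genome
#' @return Data frame: `genome_id`, `class`, `hgt`, `total` (published
#'   counts; fractions recomputed downstream).
#' @export
load_hgt_sm_crosstab <- function() {
  utils::read.delim(ref_path("basidiobolus_hgt_sm_crosstab.tsv"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Packaged per-gene SM core genes with HGT evidence
#'
#' SM class labels are normalized to the package vocabulary (`NRPS-Like` ->
#' `NRPS-like`, `Terpene` -> `TC`).
#'
#' @return Data frame: `genome_id`, `gene_id`, `z`, `sm_class`,
#'   `donor_group`.
#' @export
load_hgt_sm_genes <- function() {
  df <- utils::read.delim(ref_path("basidiobolus_hgt_sm_genes.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  df$sm_class[df$sm_class == "NRPS-Like"] <- "NRPS-like"
  df$sm_class[df$sm_class == "Terpene"] <- "TC"
  df
}
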