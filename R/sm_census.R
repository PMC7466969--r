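# Secondary-metabolism core-gene census: merged antiSMASH/SMURF-style
# predictions, per-genome class counts, cross-tabulation against the HGT
# set, clade assignment of domains on reference phylogenies, domain
# architectures and presence/absence, and TPM expression summaries.

sm_class_vocabulary <- function() {
  c("NRPS", "NRPS-like", "PKS", "PKS-like", "NRPS-PKS hybrid", "TC", "DMAT")
}

# presentation pooling used by the count tables
sm_collapsed_class <- function(sm_class) {
  out <- character(length(sm_class))
  out[sm_class %in% c("NRPS", "NRPS-like")] <- "NRPS/NRPS-like"
  out[sm_class %in% c("PKS", "PKS-like")] <- "PKS/PKS-like"
  out[sm_class == "NRPS-PKS hybrid"] <- "NRPS-PKS hybrids"
  out[sm_class == "TC"] <- "TC"
  out[sm_class == "DMAT"] <- "DMAT"
  out
}

#' Merge antiSMASH- and SMURF-style SM core-gene predictions
#'
#' Union by `gene_id`. When both sources predict the same gene with
#' different class labels the antiSMASH label wins and the conflict is
#' reported; the provenance is recorded in a `source` column.
#'
#' @param antismash,smurf Data frames with columns `gene_id`, `genome_id`,
#'   `sm_class` and optionally `cluster_id`.
#' @return Data frame (the SM ledger) with `gene_id`, `genome_id`,
#'   `sm_class`, `cluster_id`, `source`; conflicts, if any, are attached as
#'   attribute `"conflicts"` and reported via `message()`.
#' @export
merge_sm_predictions <- function(antismash, smurf) {
  check <- function(df, nm) {
    if (!all(c("gene_id", "genome_id", "sm_class") %in% names(df)))
      stop(nm, " table needs columns gene_id, genome_id, sm_class")
    bad <- !df$sm_class %in% sm_class_vocabulary()
    if (any(bad))
      stop("unknown SM class '", df$sm_class[which(bad)[1]],
           "'; allowed: ", paste(sm_class_vocabulary(), collapse = ", "))
    if (is.null(df$cluster_id)) df$cluster_id <- NA_character_
    df[, c("gene_id", "genome_id", "sm_class", "cluster_id")]
  }
  a <- check(antismash, "antismash"); s <- check(smurf, "smurf")
  a$source <- "antismash"; s$source <- "smurf"
  both <- intersect(a$gene_id, s$gene_id)
  conflicts <- data.frame(gene_id = character(0), antismash = character(0),
                          smurf = character(0), stringsAsFactors = FALSE)
  if (length(both)) {
    ca <- a$sm_class[match(both, a$gene_id)]
    cs <- s$sm_class[match(both, s$gene_id)]
    disagree <- ca != cs
    if (any(disagree)) {
      conflicts <- data.frame(gene_id = both[disagree],
                              antismash = ca[disagree], smurf = cs[disagree],
                              stringsAsFactors = FALSE)
      message(nrow(conflicts), " class conflict(s); antiSMASH label kept")
    }
    a$source[a$gene_id %in% both] <- "both"
  }
  out <- rbind(a, s[!s$gene_id %in% both, ])
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

#' Per-genome SM core-gene count table
#'
#' Counts per genome per collapsed class (`NRPS/NRPS-like`, `PKS/PKS-like`,
#' `NRPS-PKS hybrids`, `TC`) plus a `Total` column.
#'
#' @param ledger SM ledger data frame with `genome_id` and `sm_class`.
#' @return Data frame, one row per genome.
#' @export
tabulate_sm_counts <- function(ledger) {
  cols <- c("NRPS/NRPS-like", "PKS/PKS-like", "NRPS-PKS hybrids", "TC")
  if (nrow(ledger) == 0) {
    out <- data.frame(genome_id = character(0), Total = integer(0))
    for (cl in cols) out[[cl]] <- integer(0)
    return(out[, c("genome_id", "Total", cols)])
  }
  coll <- sm_collapsed_class(ledger$sm_class)
  tab <- table(ledger$genome_id, factor(coll, levels = unique(c(cols, coll))))
  out <- data.frame(genome_id = rownames(tab), stringsAsFactors = FALSE)
  for (cl in colnames(tab)) out[[cl]] <- as.integer(tab[, cl])
  out$Total <- as.integer(rowSums(tab))
  rownames(out) <- NULL
  out[, c("genome_id", "Total", intersect(c(cols, setdiff(colnames(tab), cols)),
                                          colnames(tab)))]
}

#' Cross-tabulate SM core genes against the HGT set
#'
#' Per genome and collapsed class: how many SM core genes are in the final
#' HGT set, out of how many, with the fraction recomputed from the counts
#' and formatted `"n/m (p%)"`.
#'
#' @param ledger SM ledger data frame.
#' @param hgt_set Character vector of final HGT gene ids.
#' @return Data frame with one row per genome x class plus a `Total` class
#'   row per genome; columns `genome_id`, `class`, `hgt`, `total`,
#'   `fraction`, `formatted`. HGT genes absent from the ledger are collected
#'   in attribute `"non_sm_hgt"`.
#' @export
crosstab_hgt <- function(ledger, hgt_set) {
  cols <- c("NRPS/NRPS-like", "PKS/PKS-like", "NRPS-PKS hybrids", "TC")
  coll <- sm_collapsed_class(ledger$sm_class)
  is_hgt <- ledger$gene_id %in% hgt_set
  rows <- list(); k <- 0
  for (gen in unique(ledger$genome_id)) {
    sel <- ledger$genome_id == gen
    for (cl in c(cols, "Total")) {
      in_cl <- if (cl == "Total") sel else sel & coll == cl
      m <- sum(in_cl); nh <- sum(in_cl & is_hgt)
      k <- k + 1
      rows[[k]] <- data.frame(
        genome_id = gen, class = cl, hgt = nh, total = m,
        fraction = if (m > 0) nh / m else 0,
        formatted = sprintf("%d/%d (%d%%)", nh, m,
                            round(100 * if (m > 0) nh / m else 0)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  non_sm <- setdiff(hgt_set, ledger$gene_id)
  if (length(non_sm))
    message(length(non_sm), " HGT gene(s) without an SM class (non-SM HGT)")
  attr(out, "non_sm_hgt") <- non_sm
  out
}

#' Assign query tips to named reference clades on a phylogeny
#'
#' The tree is rooted on the supplied outgroup; each query is assigned to
#' the smallest named clade whose reference-tip MRCA subtree contains it,
#' and to `"unassigned"` when it descends from no named MRCA.
#'
#' @param tree An `ape` phylo object containing all reference and query tips.
#' @param clade_definitions Named list: clade name -> character vector of
#'   reference tip labels (>= 2 each, pairwise disjoint).
#' @param query_tips Character vector of query tip labels.
#' @param outgroup Optional tip label(s) to root on; the tree is used as-is
#'   when omitted.
#' @return Named character vector: query tip -> clade name.
#' @export
assign_clades <- function(tree, clade_definitions, query_tips, outgroup = NULL) {
  all_ref <- unlist(clade_definitions)
  if (anyDuplicated(all_ref))
    stop("reference tip in more than one clade: ",
         all_ref[duplicated(all_ref)][1])
  missing <- setdiff(all_ref, tree$tip.label)
  if (length(missing)) stop("reference tip missing from tree: ", missing[1])
  if (any(lengths(clade_definitions) < 2))
    stop("each clade needs >= 2 reference tips")
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  clade_tips <- lapply(clade_definitions, function(refs) {
    mrca <- ape::getMRCA(tree, refs)
    ape::extract.clade(tree, mrca)$tip.label
  })
  vapply(query_tips, function(q) {
    if (!q %in% tree$tip.label) stop("query tip missing from tree: ", q)
    containing <- names(clade_tips)[vapply(clade_tips, function(tp) q %in% tp,
                                           logical(1))]
    if (length(containing) == 0) return("unassigned")
    sizes <- vapply(clade_tips[containing], length, numeric(1))
    containing[which.min(sizes)]
  }, character(1))
}

#' Genome-by-clade abundance matrix of clade assignments
#'
#' @param assignments Named character vector from [assign_clades()].
#' @param genome Named character vector mapping query tip -> genome.
#' @return Integer matrix, genomes as rows, clades (including
#'   `"unassigned"`) as columns; row sums equal per-genome query counts.
#' @export
clade_abundance_matrix <- function(assignments, genome) {
  if (length(assignments) == 0)
    return(matrix(integer(0), 0, 0))
  g <- genome[names(assignments)]
  tab <- table(g, assignments)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Fraction-of-length layout of domains along a protein
#'
#' Maps each domain interval to `(start/length, end/length)` fractions,
#' preserving order. Overlapping domain envelopes keep the higher score and
#' report the drop.
#'
#' @param protein_length Protein length in aa.
#' @param domains Data frame with `domain_name`, `start`, `end` (0-based
#'   half-open on the protein) and `score`.
#' @return Data frame with `domain_name`, `start`, `end`, `frac_start`,
#'   `frac_end`, ordered by start.
#' @export
domain_architecture <- function(protein_length, domains) {
  if (any(domains$end > protein_length) || any(domains$start < 0))
    stop("domain interval outside protein length")
  d <- domains[order(domains$start, -domains$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  last_end <- -1
  for (i in seq_len(nrow(d))) {
    if (d$start[i] < last_end) {
      # overlap with the previously kept domain: lower score loses
      prev <- max(which(keep[seq_len(i - 1)]))
      if (d$score[i] > d$score[prev]) keep[prev] <- FALSE else keep[i] <- FALSE
      message("overlapping domain envelopes; kept the higher score")
    }
    if (keep[i]) last_end <- d$end[i]
  }
  d <- d[keep, , drop = FALSE]
  d$frac_start <- d$start / protein_length
  d$frac_end <- d$end / protein_length
  rownames(d) <- NULL
  d
}

#' Gene-by-domain presence/absence matrix
#'
#' @param gene_ids Character vector of gene/protein ids (matrix rows).
#' @param domain_hits Data frame from [parse_domtbl()].
#' @param domain_set Domains to report (default the PKS diagnostic set).
#' @param min_score Minimum hit score to count as present (default 0).
#' @return Logical matrix, genes x domains.
#' @export
domain_presence_matrix <- function(gene_ids, domain_hits,
                                   domain_set = c("KS", "AT", "KR", "DH", "PP"),
                                   min_score = 0) {
  m <- matrix(FALSE, length(gene_ids), length(domain_set),
              dimnames = list(gene_ids, domain_set))
  hits <- domain_hits[domain_hits$score >= min_score &
                        domain_hits$domain_name %in% domain_set &
                        domain_hits$query_id %in% gene_ids, , drop = FALSE]
  if (nrow(hits)) {
    m[cbind(hits$query_id, hits$domain_name)] <- TRUE
  }
  m
}

#' Transcripts-per-million normalization
#'
#' `rate_g = count_g / length_g; TPM_g = 1e6 * rate_g / sum(rates)`.
#'
#' @param counts Non-negative numeric vector of read counts (named by gene).
#' @param lengths Positive effective lengths, same order/names.
#' @return TPM vector summing to 1e6.
#' @export
tpm_normalize <- function(counts, lengths) {
  if (length(counts) != length(lengths)) stop("counts/lengths length mismatch")
  if (any(lengths <= 0)) stop("effective lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts are zero; TPM undefined")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Expression summary of SM core genes against housekeeping genes
#'
#' @param tpm Named TPM vector over all genes.
#' @param ledger SM ledger data frame.
#' @param housekeeping_ids Gene ids of constitutive housekeeping genes;
#'   ids absent from `tpm` are dropped with a warning.
#' @return Data frame per SM gene: `gene_id`, `sm_class`, `tpm`, `rank`
#'   (1 = highest TPM among all genes), `expressed` (TPM >= min housekeeping
#'   TPM).
#' @export
expression_report <- function(tpm, ledger, housekeeping_ids) {
  hk <- housekeeping_ids[housekeeping_ids %in% names(tpm)]
  dropped <- setdiff(housekeeping_ids, hk)
  if (length(dropped))
    warning("housekeeping id(s) absent from TPM table: ",
            paste(dropped, collapse = ", "))
  if (length(hk) == 0) stop("no housekeeping gene present in the TPM table")
  hk_min <- min(tpm[hk])
  ranks <- rank(-tpm, ties.method = "min")
  sm <- ledger[ledger$gene_id %in% names(tpm), , drop = FALSE]
  data.frame(gene_id = sm$gene_id, sm_class = sm$sm_class,
             tpm = unname(tpm[sm$gene_id]),
             rank = unname(ranks[sm$gene_id]),
             expressed = unname(tpm[sm$gene_id] >= hk_min),
             stringsAsFactors = FALSE)
}
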