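# Three-stage HGT candidate inference:
#   1. best-hit taxonomy screen: a gene is a candidate only if, at the
#      e-value cutoff, it has bacterial hits and no fungal (or other
#      non-bacterial) hits;
#   2. coverage z-score filter: candidates whose mean depth deviates from
#      the harboring scaffold by |z| >= 2 are treated as assembly artifacts;
#   3. genomic-context filter: candidates with no fungal-called gene
#      anywhere upstream or downstream on their scaffold are treated as
#      contaminant scaffolds.

#' Classify genes by their best homology hit
#'
#' Hits with e-value above the cutoff are discarded. The remaining hits give
#' `call = "fungal"` when at least one passing fungal hit exists (a single
#' fungal hit vetoes HGT candidacy); otherwise `"other"` when any passing
#' non-bacterial, non-fungal hit exists; otherwise `"bacterial"`; genes with
#' no passing hit are `"none"`. The best hit is the minimum e-value, ties
#' broken by maximum bitscore then input order, and `donor_group` is the
#' taxonomy group of the best bacterial hit. `top_taxa` lists up to ten
#' taxonomy groups of passing hits by ascending e-value.
#'
#' @param hits Data frame from [parse_blast6()] or [emit_blast_hits()].
#' @param gene_ids Optional universe of genes; genes without any hit row are
#'   reported with call `"none"`.
#' @param evalue_cutoff Passing-hit threshold (default 1e-10).
#' @return Data frame with `gene_id`, `call`, `best_subject`, `best_evalue`,
#'   `best_bitscore`, `donor_group`, and list-column `top_taxa`.
#' @export
classify_best_hits <- function(hits, gene_ids = NULL, evalue_cutoff = 1e-10) {
  pass <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  universe <- unique(c(if (!is.null(gene_ids)) gene_ids else character(0),
                       hits$query_id))
  out <- lapply(universe, function(g) {
    h <- pass[pass$query_id == g, , drop = FALSE]
    if (nrow(h) == 0) {
      return(data.frame(gene_id = g, call = "none",
                        best_subject = NA_character_, best_evalue = NA_real_,
                        best_bitscore = NA_real_, donor_group = NA_character_,
                        top_taxa = I(list(character(0))),
                        stringsAsFactors = FALSE))
    }
    ord <- order(h$evalue, -h$bitscore)
    h <- h[ord, , drop = FALSE]
    call <- if (any(h$superkingdom == "fungi")) "fungal"
    else if (any(!h$superkingdom %in% c("fungi", "bacteria"))) "other"
    else "bacterial"
    bact <- h[h$superkingdom == "bacteria", , drop = FALSE]
    donor <- if (call == "bacterial" && nrow(bact) > 0)
      bact$taxonomy_group[1] else NA_character_
    data.frame(gene_id = g, call = call,
               best_subject = h$subject_id[1], best_evalue = h$evalue[1],
               best_bitscore = h$bitscore[1], donor_group = donor,
               top_taxa = I(list(utils::head(h$taxonomy_group, 10))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' HGT candidates from best-hit calls
#'
#' A candidate is a gene whose passing hits are exclusively bacterial.
#'
#' @param calls Data frame from [classify_best_hits()].
#' @return Character vector of candidate gene ids.
#' @export
call_hgt_candidates <- function(calls) {
  calls$gene_id[calls$call == "bacterial"]
}

#' Coverage z-score of a gene against its harboring scaffold
#'
#' `z = (mean depth over the gene span - mean per-base depth of the whole
#' scaffold) / SD of per-base depth of the whole scaffold`. The scaffold
#' statistics include the gene's own bases, and the SD is the population
#' (denominator n) SD by default. Uniform scaffold coverage (SD 0) yields
#' z = 0 with a warning, since no deviation can be measured.
#'
#' @param track Integer depth vector for the scaffold.
#' @param start,end Gene span, 0-based half-open on the scaffold.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The z-score, a single number.
#' @export
coverage_zscore <- function(track, start, end, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (end > length(track) || start < 0 || end <= start)
    stop("gene span outside scaffold track")
  mu <- mean(track)
  n <- length(track)
  s2 <- sum((track - mu)^2) / if (sd_type == "population") n else n - 1
  s <- sqrt(s2)
  if (s == 0) {
    warning("scaffold has uniform coverage; z-score set to 0")
    return(0)
  }
  (mean(track[(start + 1L):end]) - mu) / s
}

#' Coverage filter: retain candidates with |z| below the threshold
#'
#' The removal rule is `|z| >= threshold` (strict retention), so a candidate
#' exactly at the threshold is removed.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param z Named numeric vector of z-scores (names = gene ids).
#' @param threshold Removal threshold in SD units (default 2).
#' @return Retained candidate ids.
#' @export
apply_coverage_filter <- function(candidates, z, threshold = 2) {
  missing <- setdiff(candidates, names(z))
  if (length(missing))
    stop("no z-score for candidate gene(s): ", paste(missing, collapse = ", "))
  candidates[abs(z[candidates]) < threshold]
}

#' Genomic-context filter: require a fungal gene on the same scaffold
#'
#' A candidate is retained iff at least one fungal-called gene lies anywhere
#' upstream or anywhere downstream of it on its scaffold. A candidate that is
#' the sole gene of its scaffold, or whose scaffold carries no fungal-called
#' gene at all (a contaminant scaffold), is removed.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param genes A `gene_models` data frame giving scaffold and span per gene.
#' @param calls Data frame from [classify_best_hits()].
#' @return Retained candidate ids.
#' @export
apply_context_filter <- function(candidates, genes, calls) {
  call_of <- stats::setNames(calls$call, calls$gene_id)
  keep <- vapply(candidates, function(g) {
    i <- match(g, genes$gene_id)
    if (is.na(i)) stop("candidate ", g, " absent from gene models")
    sc <- genes$scaffold_id[i]
    others <- genes[genes$scaffold_id == sc & genes$gene_id != g, , drop = FALSE]
    if (nrow(others) == 0) return(FALSE)
    up <- others$gene_id[others$start < genes$start[i]]
    down <- others$gene_id[others$start > genes$start[i]]
    any(call_of[up] == "fungal", na.rm = TRUE) ||
      any(call_of[down] == "fungal", na.rm = TRUE)
  }, logical(1))
  candidates[keep]
}

#' Run the full three-stage HGT screen
#'
#' @param genes A `gene_models` data frame.
#' @param hits Hit table with taxonomy columns.
#' @param depth Named list of per-scaffold depth vectors.
#' @param evalue_cutoff Best-hit screen cutoff (default 1e-10).
#' @param z_threshold Coverage-filter removal threshold (default 2).
#' @param sd_type SD convention for the z-score (see [coverage_zscore()]).
#' @return Object of class `hgt_screen`: list with `calls`, `candidates` (a
#'   data frame with gene_id, donor_group, z, passed_coverage,
#'   passed_context, final), `final` (retained gene ids) and `funnel`
#'   (named stage counts).
#' @export
hgt_screen <- function(genes, hits, depth, evalue_cutoff = 1e-10,
                       z_threshold = 2, sd_type = "population") {
  calls <- classify_best_hits(hits, gene_ids = genes$gene_id,
                              evalue_cutoff = evalue_cutoff)
  cand <- call_hgt_candidates(calls)
  z <- vapply(cand, function(g) {
    i <- match(g, genes$gene_id)
    sc <- genes$scaffold_id[i]
    if (!sc %in% names(depth)) stop("no coverage track for scaffold ", sc)
    coverage_zscore(depth[[sc]], genes$start[i], genes$end[i], sd_type = sd_type)
  }, numeric(1))
  cov_pass <- apply_coverage_filter(cand, z, threshold = z_threshold)
  ctx_pass <- apply_context_filter(cov_pass, genes, calls)
  candidates <- data.frame(
    gene_id = cand,
    donor_group = calls$donor_group[match(cand, calls$gene_id)],
    z = unname(z),
    passed_coverage = cand %in% cov_pass,
    stringsAsFactors = FALSE)
  # context evaluated on all candidates so the flags are independent
  ctx_all <- apply_context_filter(cand, genes, calls)
  candidates$passed_context <- cand %in% ctx_all
  candidates$final <- candidates$passed_coverage & candidates$passed_context
  out <- list(calls = calls, candidates = candidates,
              final = candidates$gene_id[candidates$final],
              funnel = c(genes = nrow(genes),
                         bacterial_only = length(cand),
                         coverage_pass = length(cov_pass),
                         context_pass = sum(candidates$final)))
  class(out) <- "hgt_screen"
  out
}

#' @export
print.hgt_screen <- function(x, ...) {
  cat("HGT screen funnel:\n")
  cat(sprintf("  genes screened      %6d\n", x$funnel[["genes"]]))
  cat(sprintf("  bacterial-only hits %6d\n", x$funnel[["bacterial_only"]]))
  cat(sprintf("  |z| < threshold     %6d\n", x$funnel[["coverage_pass"]]))
  cat(sprintf("  fungal context      %6d\n", x$funnel[["context_pass"]]))
  invisible(x)
}

#' @export
summary.hgt_screen <- function(object, ...) {
  cat("Final HGT set:", length(object$final), "genes\n")
  print(summarize_donor_taxa(object))
  invisible(object)
}

#' Donor-taxon summary of the final HGT set
#'
#' @param screen An `hgt_screen` object (or a data frame with `gene_id` and
#'   `donor_group` for the final set).
#' @return Data frame with `donor_group`, `count`, `proportion`, sorted by
#'   descending count; zero-count groups are omitted.
#' @export
summarize_donor_taxa <- function(screen) {
  df <- if (inherits(screen, "hgt_screen"))
    screen$candidates[screen$candidates$final, ] else screen
  if (nrow(df) == 0) {
    return(data.frame(donor_group = character(0), count = integer(0),
                      proportion = numeric(0)))
  }
  tab <- sort(table(df$donor_group), decreasing = TRUE)
  data.frame(donor_group = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
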