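# All genomic intervals are held internally as 0-based half-open [start, end).
# GFF3 and domtblout coordinates (1-based inclusive) are converted at the
# parse/write boundary and nowhere else.

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @return A two-column matrix with columns `start`, `end` (0-based half-open).
#' @keywords internal
from_gff_coords <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert 0-based half-open coordinates back to 1-based inclusive
#' @keywords internal
to_gff_coords <- function(start, end) {
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Parse gene models from a GFF3 file
#'
#' Reads gene/mRNA/exon/CDS features linked by `ID`/`Parent` attributes and
#' returns one record per gene for its canonical transcript, defined as the
#' transcript with the longest total CDS (ties broken lexicographically by
#' transcript ID). Coordinates are converted to 0-based half-open intervals.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame of class `gene_models` with one row per gene and
#'   columns `gene_id`, `transcript_id`, `scaffold_id`, `strand`, `start`,
#'   `end`, `cds_length`, `protein_length`, and a list-column `exons` holding
#'   a two-column integer matrix (`start`, `end`) of sorted, non-overlapping
#'   exon intervals per gene.
#' @export
parse_gff3 <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p) == 0) NA_character_ else as.character(p[[1]]), character(1))
  genes <- gff[gff$type == "gene", ]
  mrnas <- gff[gff$type == "mRNA", ]
  exons <- gff[gff$type == "exon", ]
  cdss  <- gff[gff$type == "CDS", ]
  if (nrow(genes) == 0) stop("no gene features in ", path)

  known <- c(genes$ID, mrnas$ID)
  for (feat in list(mrnas, exons, cdss)) {
    bad <- !is.na(feat$Parent) & !(feat$Parent %in% known)
    if (any(bad)) {
      stop("orphan Parent reference '", feat$Parent[which(bad)[1]],
           "' for feature of type ", feat$type[which(bad)[1]])
    }
  }
  orphan_mrna <- is.na(mrnas$Parent)
  if (any(orphan_mrna)) stop("mRNA without Parent: ", mrnas$ID[which(orphan_mrna)[1]])

  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- mrnas[mrnas$Parent == g$ID, , drop = FALSE]
    if (nrow(tx) == 0) next
    cds_len <- vapply(tx$ID, function(tid) {
      cc <- cdss[cdss$Parent == tid, , drop = FALSE]
      sum(cc$end - cc$start + 1L)
    }, numeric(1))
    ord <- order(-cds_len, tx$ID)
    tid <- tx$ID[ord[1]]
    ex <- exons[exons$Parent == tid, , drop = FALSE]
    if (nrow(ex) == 0) ex <- cdss[cdss$Parent == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in transcript ", tid)
    }
    em <- from_gff_coords(ex$start, ex$end)
    out[[i]] <- data.frame(
      gene_id = g$ID, transcript_id = tid,
      scaffold_id = as.character(g$seqid), strand = as.character(g$strand),
      start = g$start - 1L, end = g$end,
      cds_length = as.integer(cds_len[ord[1]]),
      stringsAsFactors = FALSE)
    out[[i]]$exons <- list(em)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res$protein_length <- res$cds_length %/% 3L
  rownames(res) <- NULL
  class(res) <- c("gene_models", "data.frame")
  validate_gene_models(res)
  res
}

#' @keywords internal
validate_gene_models <- function(gm) {
  for (i in seq_len(nrow(gm))) {
    ex <- gm$exons[[i]]
    if (nrow(ex) == 0) next
    if (is.unsorted(ex[, "start"])) stop("exons not sorted for ", gm$gene_id[i])
    if (any(ex[, "start"] < gm$start[i]) || any(ex[, "end"] > gm$end[i]))
      stop("exon outside gene span for ", gm$gene_id[i])
    if (nrow(ex) > 1 && any(ex[-1, "start"] < ex[-nrow(ex), "end"]))
      stop("overlapping exons for ", gm$gene_id[i])
  }
  bad_cds <- !is.na(gm$cds_length) & gm$cds_length > 0 & gm$cds_length %% 3L != 0L
  if (any(bad_cds)) stop("CDS length not a multiple of 3 for ",
                         gm$gene_id[which(bad_cds)[1]])
  invisible(gm)
}

#' Write gene models to a TSV table and read them back
#'
#' The exon structure is serialized as `start-end` pairs joined with `;` in
#' 0-based half-open coordinates, so write-then-read is the identity.
#'
#' @param gm A `gene_models` data frame.
#' @param path Output path.
#' @export
write_gene_models <- function(gm, path) {
  flat <- gm[, c("gene_id", "transcript_id", "scaffold_id", "strand",
                 "start", "end", "cds_length", "protein_length")]
  flat$exons <- vapply(gm$exons, function(ex)
    paste(paste0(ex[, "start"], "-", ex[, "end"]), collapse = ";"), character(1))
  write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  flat <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  exons <- lapply(strsplit(flat$exons, ";", fixed = TRUE), function(parts) {
    m <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE), as.integer))
    colnames(m) <- c("start", "end")
    m
  })
  flat$exons <- NULL
  flat$exons <- exons
  flat <- flat[, c("gene_id", "transcript_id", "scaffold_id", "strand",
                   "start", "end", "cds_length", "protein_length", "exons")]
  class(flat) <- c("gene_models", "data.frame")
  validate_gene_models(flat)
  flat
}

#' Read a subject-to-taxonomy map
#'
#' @param path TSV with columns `subject_id`, `taxonomy_group`, `superkingdom`.
#' @return A data frame with those three columns.
#' @export
read_taxonomy_map <- function(path) {
  tm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "taxonomy_group", "superkingdom")
  if (!all(need %in% names(tm))) stop("taxonomy map must have columns: ",
                                      paste(need, collapse = ", "))
  tm[, need]
}

#' Parse BLAST tabular (outfmt 6) hits and attach taxonomy
#'
#' All rows are retained; the e-value cutoff belongs to the downstream
#' classification, not the parser. Subjects absent from the taxonomy map are
#' assigned superkingdom `"other"` and taxonomy group `"unmapped"`, and a
#' message reports how many.
#'
#' @param path 12-column BLAST tabular file.
#' @param taxonomy_map Data frame as returned by [read_taxonomy_map()].
#' @return Data frame of hits with `query_id`, `subject_id`, `evalue`,
#'   `bitscore`, `taxonomy_group`, `superkingdom` (plus the remaining
#'   standard outfmt-6 columns).
#' @export
parse_blast6 <- function(path, taxonomy_map) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols),
                         stringsAsFactors = FALSE)
    out$evalue <- numeric(0); out$bitscore <- numeric(0)
    out$taxonomy_group <- character(0); out$superkingdom <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 12)) {
    stop("malformed BLAST tabular row (", nfield[which(nfield != 12)[1]],
         " columns, expected 12) at line ", which(nfield != 12)[1])
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(m, stringsAsFactors = FALSE)
  names(hits) <- cols
  for (numcol in c("pident", "length", "mismatch", "gapopen", "qstart",
                   "qend", "sstart", "send", "evalue", "bitscore")) {
    hits[[numcol]] <- as.numeric(hits[[numcol]])
  }
  if (any(hits$evalue < 0)) stop("negative e-value at line ",
                                 which(hits$evalue < 0)[1])
  idx <- match(hits$subject_id, taxonomy_map$subject_id)
  hits$taxonomy_group <- taxonomy_map$taxonomy_group[idx]
  hits$superkingdom <- taxonomy_map$superkingdom[idx]
  unmapped <- is.na(idx)
  if (any(unmapped)) {
    hits$taxonomy_group[unmapped] <- "unmapped"
    hits$superkingdom[unmapped] <- "other"
    message(sum(unmapped), " hit(s) with subjects absent from the taxonomy map",
            " assigned superkingdom 'other'")
  }
  hits
}

#' Parse samtools-depth style per-base coverage
#'
#' @param path TSV of `(scaffold, position, depth)` with 1-based positions.
#'   Positions may be sparse; missing positions are filled with depth 0.
#' @param scaffold_lengths Optional named integer vector of scaffold lengths.
#'   Scaffolds named here but absent from the file yield all-zero tracks; when
#'   omitted, each track's length is the largest observed position.
#' @return Named list of non-negative integer depth vectors, one per scaffold.
#' @export
parse_depth <- function(path, scaffold_lengths = NULL) {
  dt <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("scaffold", "pos", "depth")),
    error = function(e) data.frame(scaffold = character(0),
                                   pos = integer(0), depth = integer(0)))
  tracks <- list()
  if (nrow(dt) > 0) {
    for (sc in unique(dt$scaffold)) {
      d <- dt[dt$scaffold == sc, ]
      if (is.unsorted(d$pos, strictly = TRUE)) {
        stop("non-monotone positions within scaffold ", sc)
      }
      if (any(d$depth < 0)) stop("negative depth in scaffold ", sc)
      len <- if (!is.null(scaffold_lengths) && sc %in% names(scaffold_lengths))
        scaffold_lengths[[sc]] else max(d$pos)
      v <- integer(len)
      v[d$pos] <- as.integer(d$depth)
      tracks[[sc]] <- v
    }
  }
  if (!is.null(scaffold_lengths)) {
    for (sc in setdiff(names(scaffold_lengths), names(tracks))) {
      tracks[[sc]] <- integer(scaffold_lengths[[sc]])
    }
    tracks <- tracks[names(scaffold_lengths)]
  }
  tracks
}

#' Write a depth list back to samtools-depth TSV
#'
#' Zero-depth positions are omitted, matching `samtools depth` default output.
#' @param tracks Named list of integer depth vectors.
#' @param path Output path.
#' @export
write_depth <- function(tracks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sc in names(tracks)) {
    v <- tracks[[sc]]
    nz <- which(v > 0)
    if (length(nz)) {
      writeLines(paste(sc, nz, v[nz], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Parse a Newick tree
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object; duplicate tip labels or
#'   fewer than 2 tips are errors.
#' @export
parse_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (length(tr$tip.label) < 2) stop("tree has fewer than 2 tips")
  dup <- duplicated(tr$tip.label)
  if (any(dup)) stop("duplicate tip label: ", tr$tip.label[which(dup)[1]])
  tr
}

#' Parse an HMMER domtblout-like table of domain hits
#'
#' Expects whitespace-separated rows with columns `query_id`, `domain_name`,
#' `env_from`, `env_to`, `score` (a reduced domtblout projection). Envelope
#' coordinates, 1-based inclusive on the protein, are converted to 0-based
#' half-open.
#'
#' @param path Input table; `#` comment lines are skipped.
#' @return Data frame with `query_id`, `domain_name`, `start`, `end`, `score`,
#'   sorted by query then start.
#' @export
parse_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(data.frame(query_id = character(0), domain_name = character(0),
                      start = integer(0), end = integer(0), score = numeric(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 5)) {
    stop("domtbl row with fewer than 5 fields at line ",
         which(lengths(fields) < 5)[1])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:5))
  env_from <- as.integer(m[, 3]); env_to <- as.integer(m[, 4])
  if (any(env_from < 1) || any(env_to < 1)) stop("negative or zero envelope coordinate")
  if (any(env_to < env_from)) stop("envelope end before start")
  iv <- from_gff_coords(env_from, env_to)
  out <- data.frame(query_id = m[, 1], domain_name = m[, 2],
                    start = iv[, "start"], end = iv[, "end"],
                    score = as.numeric(m[, 5]), stringsAsFactors = FALSE)
  out[order(out$query_id, out$start), , drop = FALSE]
}

#' Write a data frame as a UTF-8 TSV with "." for missing values
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) if (is.list(df2[[j]]))
    df2[[j]] <- vapply(df2[[j]], paste, character(1), collapse = ",")
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}
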