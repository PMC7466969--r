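# Seeded generator for a fungal genome fixture with planted bacterial-origin
# (HGT) genes, contaminant scaffolds and coverage-deviant genes, plus the
# matching hit tables, depth tracks and SM labels. Defaults encode the study
# conditions: background GC 0.4865 vs 0.4911 for transferred genes,
# intronless fractions 36% vs 61%, fungal intron median 2, HGT median 0.

#' Simulation configuration
#'
#' @param seed Integer seed; every emitter is bit-reproducible under it.
#' @param n_scaffolds,genes_per_scaffold Genome layout (default 20 x 10 = 200
#'   genes).
#' @param hgt_fraction Per-gene probability of planting a bacterial-origin
#'   gene on a normal scaffold.
#' @param contaminant_scaffold_fraction Fraction of scaffolds that are
#'   bacterial contaminants (all their genes bacterial-only, depth scaled).
#' @param n_deviant_genes Number of fungal-context genes planted with locally
#'   scaled depth and bacterial-only hits ("errant assembly" genes that the
#'   coverage z filter should remove).
#' @param fungal_gc,hgt_gc Target mean GC of fungal and transferred CDS.
#' @param gene_gc_sd Between-gene SD of per-gene GC around the class mean
#'   (default 0.035, the gene-to-gene GC heterogeneity typical of fungal
#'   genomes); per-gene targets are clipped to `[0.25, 0.75]`.
#' @param fungal_intronless_fraction,hgt_intronless_fraction Probability of
#'   zero introns per class.
#' @param fungal_intron_median Target median intron count for fungal genes.
#' @param intron_lambda Poisson mean of the non-inflated intron-count
#'   component (3.0 puts the fungal median at 2 when 36% are intronless).
#' @param mean_depth Mean per-base read depth on normal scaffolds.
#' @param contaminant_depth_multiplier,deviant_depth_multiplier Depth scaling
#'   of contaminant scaffolds and of planted deviant genes.
#' @param mean_cds_codons Mean CDS length in codons (minimum 100).
#' @param mean_intron_length Mean intron length in nt (minimum 50).
#' @param intergenic_length Spacer between genes and at scaffold ends, nt.
#' @param donor_groups,donor_weights Bacterial donor taxonomy groups and
#'   their sampling weights.
#' @param noise_bacterial_hit_fraction Fraction of fungal genes that also
#'   receive a passing bacterial hit (they remain fungal-called).
#' @param sm_fraction Fraction of genes given a secondary-metabolism core
#'   class label.
#' @param composition_separation Strength of the codon-preference difference
#'   between transferred and fungal CDS; 0 (default) is the non-separable
#'   regime in which composition PCA shows no group structure.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 20L,
                       genes_per_scaffold = 10L,
                       hgt_fraction = 0.05,
                       contaminant_scaffold_fraction = 0.05,
                       n_deviant_genes = 2L,
                       fungal_gc = 0.4865,
                       hgt_gc = 0.4911,
                       gene_gc_sd = 0.035,
                       fungal_intronless_fraction = 0.36,
                       hgt_intronless_fraction = 0.61,
                       fungal_intron_median = 2L,
                       intron_lambda = 3.0,
                       mean_depth = 50,
                       contaminant_depth_multiplier = 5,
                       deviant_depth_multiplier = 5,
                       mean_cds_codons = 300,
                       mean_intron_length = 80,
                       intergenic_length = 300L,
                       donor_groups = c("proteobacteria", "firmicutes",
                                        "actinobacteria", "bacteroidetes"),
                       donor_weights = c(0.45, 0.2, 0.2, 0.15),
                       noise_bacterial_hit_fraction = 0,
                       sm_fraction = 0.15,
                       composition_separation = 0) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              genes_per_scaffold = as.integer(genes_per_scaffold),
              hgt_fraction = hgt_fraction,
              contaminant_scaffold_fraction = contaminant_scaffold_fraction,
              n_deviant_genes = as.integer(n_deviant_genes),
              fungal_gc = fungal_gc, hgt_gc = hgt_gc,
              gene_gc_sd = gene_gc_sd,
              fungal_intronless_fraction = fungal_intronless_fraction,
              hgt_intronless_fraction = hgt_intronless_fraction,
              fungal_intron_median = as.integer(fungal_intron_median),
              intron_lambda = intron_lambda,
              mean_depth = mean_depth,
              contaminant_depth_multiplier = contaminant_depth_multiplier,
              deviant_depth_multiplier = deviant_depth_multiplier,
              mean_cds_codons = mean_cds_codons,
              mean_intron_length = mean_intron_length,
              intergenic_length = as.integer(intergenic_length),
              donor_groups = donor_groups,
              donor_weights = donor_weights / sum(donor_weights),
              noise_bacterial_hit_fraction = noise_bacterial_hit_fraction,
              sm_fraction = sm_fraction,
              composition_separation = composition_separation)
  fracs <- c(cfg$hgt_fraction, cfg$contaminant_scaffold_fraction,
             cfg$fungal_intronless_fraction, cfg$hgt_intronless_fraction,
             cfg$noise_bacterial_hit_fraction, cfg$sm_fraction,
             cfg$fungal_gc, cfg$hgt_gc)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$mean_depth <= 0 || cfg$contaminant_depth_multiplier <= 0 ||
      cfg$deviant_depth_multiplier <= 0) stop("depth parameters must be positive")
  if (length(cfg$donor_groups) != length(cfg$donor_weights))
    stop("donor_groups and donor_weights must have equal length")
  class(cfg) <- "sim_config"
  cfg
}

# Zero-inflated Poisson: inflation mass solved from the target zero fraction.
zip_pi <- function(zero_fraction, lambda) {
  p0 <- exp(-lambda)
  if (zero_fraction < p0) stop("zero fraction below Poisson(", lambda, ") mass at 0")
  (zero_fraction - p0) / (1 - p0)
}

rzip <- function(n, zero_fraction, lambda) {
  pi0 <- zip_pi(zero_fraction, lambda)
  ifelse(runif(n) < pi0, 0L, rpois(n, lambda))
}

revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_bases <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# CDS with fixed ATG start and TAA stop; internal bases i.i.d. with the GC
# probability adjusted so per-gene expected GC equals `gc` exactly. With a
# codon-preference separation, internal codons are instead drawn from a
# class-specific weighted codon table.
random_cds <- function(n_codons, gc, codon_weights = NULL) {
  len <- 3L * n_codons
  if (is.null(codon_weights)) {
    # ATG + TAA contribute 1 G/C among 6 fixed bases
    gc_internal <- (len * gc - 1) / (len - 6)
    gc_internal <- min(max(gc_internal, 0), 1)
    paste0("ATG", random_bases(len - 6L, gc_internal), "TAA")
  } else {
    inner <- sample(names(codon_weights), n_codons - 2L, replace = TRUE,
                    prob = codon_weights)
    paste0("ATG", paste(inner, collapse = ""), "TAA")
  }
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# Codon table targeting a GC content, optionally tilted by a fixed alternating
# preference pattern whose strength is `separation`.
codon_table <- function(gc, separation = 0) {
  codons <- all_codons()
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  gcn <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
                numeric(1))
  w <- (gc / 2)^gcn * ((1 - gc) / 2)^(3 - gcn)
  tilt <- rep_len(c(1, -1), length(codons))
  w <- w * exp(separation * tilt)
  stats::setNames(w / sum(w), codons)
}

#' Simulate a fungal genome with planted HGT, contaminant and deviant genes
#'
#' Builds scaffold sequences, gene models (exon/intron structure drawn from a
#' zero-inflated Poisson intron model) and a per-gene truth table with labels
#' `fungal`, `hgt` (bacterial-origin genes on normal scaffolds), `contaminant`
#' (all genes of contaminant scaffolds) and `deviant` (planted coverage
#' deviants). Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_genome`: list with `config`, `genes`
#'   (a `gene_models` data frame), `truth` (gene_id, scaffold_id, label,
#'   donor_group, sm_class, cluster_id), and `seqs` (named character vector of
#'   scaffold sequences).
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n_sc <- cfg$n_scaffolds
  n_contam <- round(cfg$contaminant_scaffold_fraction * n_sc)
  if (cfg$contaminant_scaffold_fraction > 0 && n_contam == 0)
    stop("contaminant_scaffold_fraction too small for ", n_sc, " scaffolds")
  n_genes_normal <- (n_sc - n_contam) * cfg$genes_per_scaffold
  if (cfg$hgt_fraction > 0 && n_genes_normal * cfg$hgt_fraction < 1)
    stop("hgt_fraction too small to plant any HGT gene at this genome size")
  contam_sc <- if (n_contam > 0) sample(n_sc, n_contam) else integer(0)

  sc_names <- sprintf("scaffold_%02d", seq_len(n_sc))
  hgt_table <- codon_table(cfg$hgt_gc, cfg$composition_separation)

  gene_rows <- list(); truth_rows <- list(); seqs <- character(n_sc)
  gi <- 0L
  for (s in seq_len(n_sc)) {
    is_contam <- s %in% contam_sc
    cursor <- cfg$intergenic_length
    pieces <- list(random_bases(cfg$intergenic_length, cfg$fungal_gc))
    for (g in seq_len(cfg$genes_per_scaffold)) {
      gi <- gi + 1L
      label <- if (is_contam) "contaminant"
      else if (runif(1) < cfg$hgt_fraction) "hgt" else "fungal"
      bacterial_like <- label != "fungal"

      n_codons <- 100L + rpois(1, max(cfg$mean_cds_codons - 100, 1))
      cds_len <- 3L * n_codons
      zf <- if (bacterial_like) cfg$hgt_intronless_fraction
            else cfg$fungal_intronless_fraction
      n_introns <- rzip(1, zf, cfg$intron_lambda)
      n_introns <- min(n_introns, n_codons - 2L)
      intron_lens <- if (n_introns > 0)
        50L + rpois(n_introns, max(cfg$mean_intron_length - 50, 1)) else integer(0)

      if (bacterial_like && cfg$composition_separation > 0) {
        cds <- random_cds(n_codons, cfg$hgt_gc, hgt_table)
      } else {
        class_gc <- if (bacterial_like) cfg$hgt_gc else cfg$fungal_gc
        gene_gc <- min(max(rnorm(1, class_gc, cfg$gene_gc_sd), 0.25), 0.75)
        cds <- random_cds(n_codons, gene_gc)
      }

      cuts <- if (n_introns > 0) sort(sample(cds_len - 1L, n_introns)) else integer(0)
      exon_cds_bounds <- cbind(start = c(0L, cuts), end = c(cuts, cds_len))
      block <- character(0); rel <- matrix(integer(0), 0, 2)
      off <- 0L
      for (e in seq_len(n_introns + 1L)) {
        es <- exon_cds_bounds[e, 1]; ee <- exon_cds_bounds[e, 2]
        block <- c(block, substr(cds, es + 1L, ee))
        rel <- rbind(rel, c(off, off + (ee - es)))
        off <- off + (ee - es)
        if (e <= n_introns) {
          block <- c(block, random_bases(intron_lens[e], cfg$fungal_gc))
          off <- off + intron_lens[e]
        }
      }
      gene_seq <- paste(block, collapse = "")
      span <- nchar(gene_seq)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") {
        gene_seq <- revcomp(gene_seq)
        rel <- cbind(span - rel[, 2], span - rel[, 1])
        rel <- rel[order(rel[, 1]), , drop = FALSE]
      }
      colnames(rel) <- c("start", "end")

      gene_id <- sprintf("%s_g%03d", sc_names[s], g)
      gr <- data.frame(gene_id = gene_id,
                       transcript_id = paste0(gene_id, ".t1"),
                       scaffold_id = sc_names[s], strand = strand,
                       start = cursor, end = cursor + span,
                       cds_length = cds_len, protein_length = n_codons,
                       stringsAsFactors = FALSE)
      gr$exons <- list(rel + cursor)
      gene_rows[[gi]] <- gr
      truth_rows[[gi]] <- data.frame(
        gene_id = gene_id, scaffold_id = sc_names[s], label = label,
        donor_group = if (bacterial_like)
          sample(cfg$donor_groups, 1, prob = cfg$donor_weights) else NA_character_,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, gene_seq,
                  random_bases(cfg$intergenic_length, cfg$fungal_gc))
      cursor <- cursor + span + cfg$intergenic_length
    }
    seqs[s] <- paste(unlist(pieces), collapse = "")
  }
  names(seqs) <- sc_names
  genes <- do.call(rbind, gene_rows)
  class(genes) <- c("gene_models", "data.frame")
  truth <- do.call(rbind, truth_rows)

  # planted coverage deviants: fungal-flanked genes, relabeled
  if (cfg$n_deviant_genes > 0) {
    pool <- which(truth$label == "fungal")
    # avoid first/last gene of a scaffold so deviants keep fungal flanks
    keep <- pool[vapply(pool, function(i) {
      sc <- truth$scaffold_id[i]
      sum(truth$scaffold_id == sc & truth$label == "fungal") >= 3
    }, logical(1))]
    dev <- sample(keep, min(cfg$n_deviant_genes, length(keep)))
    truth$label[dev] <- "deviant"
    truth$donor_group[dev] <- sample(cfg$donor_groups, length(dev),
                                     replace = TRUE, prob = cfg$donor_weights)
  }

  # SM class labels for a configurable subset
  truth$sm_class <- NA_character_
  truth$cluster_id <- NA_character_
  n_sm <- round(cfg$sm_fraction * nrow(truth))
  if (n_sm > 0) {
    sm_idx <- sample(nrow(truth), n_sm)
    classes <- c("NRPS", "NRPS-like", "PKS", "PKS-like", "NRPS-PKS hybrid", "TC")
    truth$sm_class[sm_idx] <- sample(classes, n_sm, replace = TRUE,
                                     prob = c(0.35, 0.25, 0.08, 0.05, 0.02, 0.25))
    truth$cluster_id[sm_idx] <- sprintf("cluster_%03d", seq_len(n_sm))
  }

  out <- list(config = cfg, genes = genes, truth = truth, seqs = seqs)
  class(out) <- "synthetic_genome"
  out
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic genome:", length(x$seqs), "scaffolds,",
      nrow(x$genes), "genes\n")
  print(table(x$truth$label))
  invisible(x)
}

#' Extract the coding sequence of each gene (coding orientation)
#'
#' @param genome A `synthetic_genome`, or any list with `seqs` and `genes`.
#' @param genes Optional subset of gene ids.
#' @return Named character vector of CDS strings.
#' @export
gene_cds <- function(genome, genes = NULL) {
  gm <- genome$genes
  if (!is.null(genes)) gm <- gm[gm$gene_id %in% genes, ]
  out <- vapply(seq_len(nrow(gm)), function(i) {
    sc <- genome$seqs[[gm$scaffold_id[i]]]
    ex <- gm$exons[[i]]
    s <- paste(vapply(seq_len(nrow(ex)), function(e)
      substr(sc, ex[e, "start"] + 1L, ex[e, "end"]), character(1)),
      collapse = "")
    if (gm$strand[i] == "-") revcomp(s) else s
  }, character(1))
  stats::setNames(out, gm$gene_id)
}

#' Simulate per-base read coverage
#'
#' Depth is Poisson(`mean_depth`) per base on normal scaffolds, scaled by
#' `contaminant_depth_multiplier` on contaminant scaffolds, and scaled by
#' `deviant_depth_multiplier` over the spans of planted deviant genes.
#'
#' @param genome A `synthetic_genome`.
#' @return Named list of integer depth vectors, one per scaffold.
#' @export
simulate_coverage <- function(genome) {
  cfg <- genome$config
  set.seed(cfg$seed + 1L)
  contam_sc <- unique(genome$truth$scaffold_id[genome$truth$label == "contaminant"])
  tracks <- lapply(names(genome$seqs), function(sc) {
    len <- nchar(genome$seqs[[sc]])
    mu <- cfg$mean_depth * if (sc %in% contam_sc) cfg$contaminant_depth_multiplier else 1
    rpois(len, mu)
  })
  names(tracks) <- names(genome$seqs)
  dev_genes <- genome$truth$gene_id[genome$truth$label == "deviant"]
  gm <- genome$genes
  for (gid in dev_genes) {
    i <- which(gm$gene_id == gid)
    sc <- gm$scaffold_id[i]
    idx <- (gm$start[i] + 1L):gm$end[i]
    tracks[[sc]][idx] <- rpois(length(idx),
                               cfg$mean_depth * cfg$deviant_depth_multiplier)
  }
  tracks
}

#' Emit BLAST-style hits and the matching subject taxonomy map
#'
#' Fungal-labeled genes receive 1-3 fungal hits passing the 1e-10 cutoff;
#' bacterial-like genes (hgt, contaminant, deviant) receive only bacterial
#' hits whose best hit carries the planted donor group; a configurable noise
#' fraction of fungal genes additionally receives a passing bacterial hit.
#'
#' @param genome A `synthetic_genome`.
#' @return List with `hits` (data frame in [parse_blast6()] layout) and
#'   `taxonomy_map` (subject_id, taxonomy_group, superkingdom).
#' @export
emit_blast_hits <- function(genome) {
  cfg <- genome$config
  set.seed(cfg$seed + 2L)
  truth <- genome$truth
  rows <- list(); k <- 0L
  add_hit <- function(q, subj, group, kingdom, exponent) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(
      query_id = q, subject_id = subj,
      pident = round(runif(1, 40, 95), 1), length = sample(100:800, 1),
      mismatch = sample(5:200, 1), gapopen = sample(0:10, 1),
      qstart = 1, qend = 100, sstart = 1, send = 100,
      evalue = 10^exponent, bitscore = round(-10 * exponent + runif(1, 0, 50), 1),
      taxonomy_group = group, superkingdom = kingdom, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth))) {
    gid <- truth$gene_id[i]
    if (truth$label[i] == "fungal") {
      n <- 1L + rpois(1, 1)
      expo <- sort(runif(n, -100, -12))
      for (j in seq_len(n)) {
        add_hit(gid, sprintf("FUNGI_%05d", sample(99999L, 1)), "fungi",
                "fungi", expo[j])
      }
      if (runif(1) < cfg$noise_bacterial_hit_fraction) {
        grp <- sample(cfg$donor_groups, 1, prob = cfg$donor_weights)
        add_hit(gid, sprintf("BACT_%s_%05d", grp, sample(99999L, 1)), grp,
                "bacteria", runif(1, -60, -12))
      }
    } else {
      donor <- truth$donor_group[i]
      best_expo <- runif(1, -100, -40)
      add_hit(gid, sprintf("BACT_%s_%05d", donor, sample(99999L, 1)), donor,
              "bacteria", best_expo)
      n_extra <- rpois(1, 1)
      for (j in seq_len(n_extra)) {
        grp <- sample(cfg$donor_groups, 1, prob = cfg$donor_weights)
        add_hit(gid, sprintf("BACT_%s_%05d", grp, sample(99999L, 1)), grp,
                "bacteria", runif(1, min(best_expo + 5, -12), -12))
      }
    }
  }
  hits <- do.call(rbind, rows)
  taxmap <- unique(hits[, c("subject_id", "taxonomy_group", "superkingdom")])
  rownames(taxmap) <- NULL
  list(hits = hits, taxonomy_map = taxmap)
}

#' Write emitted hits as a 12-column BLAST tabular file
#' @param hits Hit data frame from [emit_blast_hits()].
#' @param path Output path.
#' @export
write_blast6 <- function(hits, path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- hits[, cols]
  df$evalue <- formatC(df$evalue, format = "e", digits = 2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write scaffold sequences as FASTA
#' @param genome A `synthetic_genome`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), path)
  invisible(path)
}

#' Write gene models as GFF3 (gene/mRNA/exon/CDS)
#' @param genome A `synthetic_genome` (or list with `genes`).
#' @param path Output path.
#' @export
write_genome_gff3 <- function(genome, path) {
  gm <- genome$genes
  con <- file(path, "wt"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(gm))) {
    g <- gm[i, ]
    g1 <- to_gff_coords(g$start, g$end)
    writeLines(c(
      paste(g$scaffold_id, "hgtcensus", "gene", g1[1], g1[2], ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$scaffold_id, "hgtcensus", "mRNA", g1[1], g1[2], ".", g$strand,
            ".", paste0("ID=", g$transcript_id, ";Parent=", g$gene_id),
            sep = "\t")), con)
    ex <- gm$exons[[i]]
    for (e in seq_len(nrow(ex))) {
      e1 <- to_gff_coords(ex[e, "start"], ex[e, "end"])
      writeLines(c(
        paste(g$scaffold_id, "hgtcensus", "exon", e1[1], e1[2], ".", g$strand,
              ".", paste0("ID=", g$transcript_id, ".exon", e,
                          ";Parent=", g$transcript_id), sep = "\t"),
        paste(g$scaffold_id, "hgtcensus", "CDS", e1[1], e1[2], ".", g$strand,
              "0", paste0("ID=", g$transcript_id, ".cds", e,
                          ";Parent=", g$transcript_id), sep = "\t")), con)
    }
  }
  invisible(path)
}

#' Render a synthetic CAS assay plate photograph
#'
#' Draws a dark background, a greenish-blue dish disk of the given diameter
#' and a centered yellow halo disk, with Gaussian speckle noise, and writes a
#' PNG. Identical bytes under identical arguments and seed.
#'
#' @param path Output PNG path.
#' @param halo_radius_cm Radius of the yellow halo (0 for none).
#' @param dish_diameter_cm Dish diameter in cm (default 5.5).
#' @param pixels_per_cm Image resolution.
#' @param seed Seed for the speckle noise.
#' @param noise_sd Standard deviation of the additive channel noise.
#' @return The path, invisibly.
#' @export
emit_plate_image <- function(path, halo_radius_cm, dish_diameter_cm = 5.5,
                             pixels_per_cm = 50, seed = 1L, noise_sd = 0.02) {
  if (halo_radius_cm < 0) stop("halo radius must be non-negative")
  if (halo_radius_cm > dish_diameter_cm / 2)
    stop("halo radius exceeds dish radius")
  set.seed(seed)
  npx <- ceiling(dish_diameter_cm * pixels_per_cm * 1.2)
  cx <- npx / 2; cy <- npx / 2
  r_dish <- dish_diameter_cm / 2 * pixels_per_cm
  r_halo <- halo_radius_cm * pixels_per_cm
  xs <- matrix(seq_len(npx), npx, npx)
  ys <- t(xs)
  d2 <- (xs - cx)^2 + (ys - cy)^2
  img <- array(0, dim = c(npx, npx, 3))
  bg <- c(0.08, 0.08, 0.08)        # bench background
  dish <- c(0.10, 0.55, 0.50)      # Fe-CAS greenish blue
  halo <- c(0.95, 0.85, 0.15)      # dechelated yellow
  for (ch in 1:3) {
    m <- matrix(bg[ch], npx, npx)
    m[d2 <= r_dish^2] <- dish[ch]
    if (r_halo > 0) m[d2 <= r_halo^2] <- halo[ch]
    img[, , ch] <- m
  }
  img <- img + array(rnorm(length(img), 0, noise_sd), dim = dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}
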