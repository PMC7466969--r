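# In-code fixtures: small hand-checkable files written at test time, plus a
# memoized default synthetic pipeline run shared across test files.

write_toy_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    # g1: 2 exons of 150 nt, one intron of 50 nt (151..200)
    "s1\ttoy\tgene\t1\t350\t.\t+\t.\tID=g1",
    "s1\ttoy\tmRNA\t1\t350\t.\t+\t.\tID=g1.t1;Parent=g1",
    "s1\ttoy\texon\t1\t150\t.\t+\t.\tID=g1.t1.e1;Parent=g1.t1",
    "s1\ttoy\texon\t201\t350\t.\t+\t.\tID=g1.t1.e2;Parent=g1.t1",
    "s1\ttoy\tCDS\t1\t150\t.\t+\t0\tID=g1.t1.c1;Parent=g1.t1",
    "s1\ttoy\tCDS\t201\t350\t.\t+\t0\tID=g1.t1.c2;Parent=g1.t1",
    # g2: single 300 nt exon
    "s1\ttoy\tgene\t400\t699\t.\t-\t.\tID=g2",
    "s1\ttoy\tmRNA\t400\t699\t.\t-\t.\tID=g2.t1;Parent=g2",
    "s1\ttoy\texon\t400\t699\t.\t-\t.\tID=g2.t1.e1;Parent=g2.t1",
    "s1\ttoy\tCDS\t400\t699\t.\t-\t0\tID=g2.t1.c1;Parent=g2.t1",
    # g3: 3 exons of 60 nt, two introns of 60 nt
    "s2\ttoy\tgene\t1\t300\t.\t+\t.\tID=g3",
    "s2\ttoy\tmRNA\t1\t300\t.\t+\t.\tID=g3.t1;Parent=g3",
    "s2\ttoy\texon\t1\t60\t.\t+\t.\tID=g3.t1.e1;Parent=g3.t1",
    "s2\ttoy\texon\t121\t180\t.\t+\t.\tID=g3.t1.e2;Parent=g3.t1",
    "s2\ttoy\texon\t241\t300\t.\t+\t.\tID=g3.t1.e3;Parent=g3.t1",
    "s2\ttoy\tCDS\t1\t60\t.\t+\t0\tID=g3.t1.c1;Parent=g3.t1",
    "s2\ttoy\tCDS\t121\t180\t.\t+\t0\tID=g3.t1.c2;Parent=g3.t1",
    "s2\ttoy\tCDS\t241\t300\t.\t+\t0\tID=g3.t1.c3;Parent=g3.t1")
  writeLines(lines, path)
  path
}

toy_taxonomy_map <- function() {
  data.frame(
    subject_id = c("FUN1", "FUN2", "BACT1", "BACT2", "ARCH1"),
    taxonomy_group = c("fungi", "fungi", "b-proteobacteria", "firmicutes",
                       "archaea"),
    superkingdom = c("fungi", "fungi", "bacteria", "bacteria", "other"),
    stringsAsFactors = FALSE)
}

write_toy_blast6 <- function(path = tempfile(fileext = ".tsv"),
                             rows = NULL) {
  if (is.null(rows)) {
    rows <- c(
      "g1\tFUN1\t90.0\t100\t10\t0\t1\t100\t1\t100\t1e-50\t200",
      "g1\tBACT1\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-80\t250",
      "g2\tBACT1\t70.0\t100\t30\t0\t1\t100\t1\t100\t1e-20\t120",
      "g2\tUNKNOWN1\t60.0\t100\t40\t0\t1\t100\t1\t100\t1e-30\t140",
      "g3\tUNKNOWN2\t60.0\t100\t40\t0\t1\t100\t1\t100\t1e-5\t40")
  }
  writeLines(rows, path)
  path
}

# memoized default pipeline run: 200 genes, 5% planted HGT, 1 contaminant
# scaffold, 2 planted coverage deviants, no noise, seed 42
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        run_pipeline(sim_config(seed = 42),
                     out_dir = file.path(tempdir(), "hgtcensus_default_run")))
    }
    cache
  }
})

# brute-force re-derivation of the three screen rules, written independently
# of the package internals (naive loops over data frames)
brute_force_screen <- function(genes, hits, depth, cutoff = 1e-10, zthr = 2) {
  final <- character(0)
  call_of <- list()
  for (g in genes$gene_id) {
    h <- hits[hits$query_id == g & hits$evalue <= cutoff, ]
    call_of[[g]] <-
      if (nrow(h) == 0) "none"
      else if ("fungi" %in% h$superkingdom) "fungal"
      else if (any(!h$superkingdom %in% c("fungi", "bacteria"))) "other"
      else "bacterial"
  }
  for (g in genes$gene_id) {
    if (call_of[[g]] != "bacterial") next
    i <- which(genes$gene_id == g)
    tr <- depth[[genes$scaffold_id[i]]]
    mu <- mean(tr); s <- sqrt(mean((tr - mu)^2))
    gm <- mean(tr[(genes$start[i] + 1):genes$end[i]])
    z <- if (s == 0) 0 else (gm - mu) / s
    if (abs(z) >= zthr) next
    sc_genes <- genes[genes$scaffold_id == genes$scaffold_id[i], ]
    fungal_elsewhere <- any(vapply(sc_genes$gene_id, function(o)
      o != g && call_of[[o]] == "fungal", logical(1)))
    if (fungal_elsewhere) final <- c(final, g)
  }
  final
}
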