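test_that("gc_content follows the N-exclusion definition and reverse-complement invariance", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATNNGC"), 0.5)
  expect_error(gc_content("NNNN"), "no unambiguous")
  set.seed(2)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(gc_content(s), gc_content(rc))
  }
})

test_that("intron stats: gaps between exons over gene-model span", {
  gm <- parse_gff3(write_toy_gff3())
  st <- intron_stats(gm)
  expect_equal(st$n_introns[st$gene_id == "g2"], 0)
  expect_equal(st$norm_intron_len[st$gene_id == "g2"], 0)
  expect_equal(st$n_introns[st$gene_id == "g1"], 1)
  expect_equal(st$norm_intron_len[st$gene_id == "g1"], 50 / 350)
  expect_equal(st$n_introns[st$gene_id == "g3"], 2)
  expect_equal(st$norm_intron_len[st$gene_id == "g3"], 120 / 300)
})

test_that("kmer_profile matches a brute-force dictionary count and the worked examples", {
  p <- kmer_profile("AAAAAA", 5)
  expect_equal(unname(p["AAAAA"]), 2 / 6)
  expect_equal(sum(p > 0), 1)
  p2 <- kmer_profile("ATGCA", 5)
  expect_equal(unname(p2["ATGCA"]), 1 / 5)

  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  p3 <- kmer_profile(s, 5)
  # naive O(n k) oracle
  counts <- new.env()
  for (i in 1:(300 - 4)) {
    w <- substr(s, i, i + 4)
    counts[[w]] <- (if (is.null(counts[[w]])) 0 else counts[[w]]) + 1
  }
  for (w in ls(counts)) expect_equal(unname(p3[w]) * 300, counts[[w]])
  expect_equal(sum(p3) * 300, 296)
  expect_error(kmer_profile("ATG", 5), "shorter")
})

test_that("codon_usage matches a frame walk, sums to 1/3, and rejects bad lengths", {
  cu <- codon_usage("ATGAAATAA")
  expect_equal(unname(cu[c("ATG", "AAA", "TAA")]), rep(1 / 9, 3))
  expect_equal(sum(cu), 1 / 3)
  cu2 <- codon_usage("ATGATG")
  expect_equal(unname(cu2["ATG"]), 2 / 6)
  expect_error(codon_usage("ATGA"), "multiple of 3")

  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  cu3 <- codon_usage(s)
  walk <- table(substring(s, seq(1, 900, 3), seq(3, 900, 3)))
  for (w in names(walk)) expect_equal(unname(cu3[w]) * 900, unname(walk[w]))
  # codon entries exactly invariant under self-concatenation
  expect_equal(codon_usage(paste0(s, s)), cu3)
  # 5-mer entries invariant within O(k/n)
  expect_lt(max(abs(kmer_profile(paste0(s, s)) - kmer_profile(s))), 5 / 900)
})

test_that("one-way ANOVA reproduces the hand SS decomposition and base-R aov", {
  expect_equal(anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))$statistic, 13.5)
  expect_equal(anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))$df, c(1L, 4L))
  same <- anova_oneway(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  sep <- anova_oneway(list(c(1, 1), c(2, 2)))
  expect_equal(sep$statistic, Inf)
  expect_equal(sep$p, 0)
  expect_error(anova_oneway(list(1, c(2, 3))), "n >= 2")

  set.seed(6)
  x <- rnorm(30); g <- factor(rep(1:3, each = 10))
  mine <- anova_oneway(split(x, g))
  ref <- summary(stats::aov(x ~ g))[[1]]
  expect_equal(mine$statistic, ref$`F value`[1])
  expect_equal(mine$p, ref$`Pr(>F)`[1])
})

test_that("ANOVA F on two groups equals the squared pooled t statistic", {
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(11, 0.5)
    f <- anova_oneway(list(a, b))$statistic
    t <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2)
  }
})

test_that("Tukey HSD matches base-R TukeyHSD and separates only the shifted group", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 11, 12))
  tk <- tukey_hsd(g)
  expect_gt(tk$p_adj[tk$group1 == "a" & tk$group2 == "b"], 0.99)
  expect_lt(max(tk$p_adj[tk$group2 == "c" | tk$group1 == "c"]), 0.01)

  set.seed(8)
  x <- rnorm(40); grp <- factor(rep(letters[1:4], each = 10))
  mine <- tukey_hsd(split(x, grp))
  ref <- stats::TukeyHSD(stats::aov(x ~ grp))$grp
  expect_equal(mine$p_adj, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_equal(mine$diff, unname(ref[, "diff"]))
})

test_that("Kruskal-Wallis reproduces the hand rank computation and the tie-corrected formula", {
  k <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(k$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(k$df, 1L)
  expect_equal(kruskal_wallis(list(c(1, 3, 2), c(2, 1, 3, 4)))$statistic,
               unname(stats::kruskal.test(
                 c(1, 3, 2, 2, 1, 3, 4),
                 factor(rep(1:2, c(3, 4))))$statistic))
  # heavy ties against the textbook sum(t^3 - t) correction, hand-applied
  x <- c(0, 0, 0, 1, 0, 0, 1, 1); g <- rep(1:2, each = 4)
  r <- rank(x)
  N <- 8; rs <- tapply(r, g, sum)
  h_raw <- 12 / (N * (N + 1)) * sum(rs^2 / 4) - 3 * (N + 1)
  ties <- table(x)
  h_exp <- h_raw / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(kruskal_wallis(split(x, g))$statistic, h_exp)
  expect_equal(kruskal_wallis(split(x, g))$statistic,
               unname(stats::kruskal.test(x, factor(g))$statistic))
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("PCA matches the covariance eigendecomposition, reconstructs, and keeps conventions", {
  # collinear points: PC1 carries all variance
  line <- cbind(1:5, 2 * (1:5))
  p <- composition_pca(line)
  expect_equal(p$var_fraction[1], 1)

  m <- matrix(c(1, 2, 3, 4, 2, 1, 4, 3, 5, 5, 1, 1), 4, 3)
  p2 <- composition_pca(m)
  ev <- eigen(stats::cov(sweep(m, 2, colMeans(m))))
  # eigen of covariance uses n-1; var fractions agree either way (the PCA
  # truncates null components, so compare the retained rank)
  r <- length(p2$var_fraction)
  expect_equal(p2$var_fraction, ev$values[seq_len(r)] / sum(ev$values),
               tolerance = 1e-9)
  for (j in seq_along(p2$var_fraction)) {
    expect_equal(abs(p2$loadings[, j]), abs(ev$vectors[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # sign convention: largest-magnitude loading entry positive
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
  }
  # orthonormal loadings, descending variance fractions summing to 1
  expect_equal(crossprod(p2$loadings), diag(ncol(p2$loadings)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(is.unsorted(rev(p2$var_fraction)))
  expect_equal(sum(p2$var_fraction), 1)
  # reconstruction
  rec <- p2$scores %*% t(p2$loadings) + rep(p2$center, each = nrow(m))
  expect_lt(max(abs(rec - m)), 1e-8)
  expect_error(composition_pca(matrix(3, 4, 2)), "constant")
})

test_that("ANOVA type-I error is near the nominal 0.05 under the null", {
  set.seed(9)
  reject <- logical(1000)
  for (i in 1:1000) {
    g <- list(rnorm(10), rnorm(10), rnorm(10))
    reject[i] <- anova_oneway(g)$p < 0.05
  }
  # binomial 99.9% band around 0.05 at 1000 reps is about +/- 0.023
  expect_gt(mean(reject), 0.027)
  expect_lt(mean(reject), 0.073)
})
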