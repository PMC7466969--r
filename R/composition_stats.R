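# Compositional evidence battery: GC content, intron statistics, 5-mer and
# codon-usage profiles, and the tests applied to them (one-way ANOVA + Tukey
# HSD, Kruskal-Wallis with tie correction, covariance PCA). The statistics
# are computed from the classical formulas; only the reference distributions
# (F, chi-squared, studentized range) come from base R.

#' GC content of a nucleotide sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` bases are excluded from both the
#' numerator and the denominator.
#'
#' @param sequence Character string over `A`, `C`, `G`, `T`, `N`.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  b <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  b <- b[b %in% c("A", "C", "G", "T")]
  if (length(b) == 0) stop("sequence has no unambiguous A/C/G/T bases")
  sum(b %in% c("G", "C")) / length(b)
}

#' Intron count and normalized intron length of gene models
#'
#' Introns are the gaps between consecutive exons of the canonical
#' transcript; normalized intron length is total intron nucleotides divided
#' by the gene-model span (transcript start to end, genomic).
#'
#' @param genes A `gene_models` data frame.
#' @return Data frame with `gene_id`, `n_introns`, `norm_intron_len`.
#' @export
intron_stats <- function(genes) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    n_int <- max(nrow(ex) - 1L, 0L)
    int_len <- if (n_int > 0) sum(ex[-1, "start"] - ex[-nrow(ex), "end"]) else 0L
    span <- genes$end[i] - genes$start[i]
    data.frame(gene_id = genes$gene_id[i], n_introns = n_int,
               norm_intron_len = int_len / span, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Length-normalized k-mer profile of a coding sequence
#'
#' Overlapping windows with step 1; counts are divided by the full CDS
#' length. Windows containing `N` are skipped, but the denominator stays the
#' full length.
#'
#' @param cds CDS string in coding orientation, length >= k.
#' @param k Word size (default 5).
#' @return Named numeric vector of length `4^k` in lexicographic A<C<G<T
#'   order.
#' @export
kmer_profile <- function(cds, k = 5L) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < k) stop("CDS shorter than k = ", k)
  bases <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  code <- unname(bases[strsplit(cds, "", fixed = TRUE)[[1]]])
  # rolling base-4 index over windows of length k; windows with N -> NA
  idx <- rep(0, n - k + 1L)
  valid <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    cj <- code[j:(n - k + j)]
    valid <- valid & !is.na(cj)
    idx <- idx * 4 + ifelse(is.na(cj), 0, cj)
  }
  counts <- tabulate(idx[valid] + 1L, nbins = 4L^k)
  kmers <- kmer_names(k)
  stats::setNames(counts / n, kmers)
}

#' @keywords internal
kmer_names <- function(k) {
  b <- c("A", "C", "G", "T")
  out <- b
  for (j in seq_len(k - 1L)) out <- as.vector(t(outer(out, b, paste0)))
  out
}

#' Length-normalized codon usage of a coding sequence
#'
#' In-frame, non-overlapping codon counts divided by the full CDS length in
#' nucleotides, so the 64 entries sum to exactly 1/3 for an N-free CDS.
#'
#' @param cds CDS string, length a multiple of 3.
#' @return Named numeric vector of length 64.
#' @export
codon_usage <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  names64 <- kmer_names(3)
  counts <- table(factor(codons, levels = names64))
  stats::setNames(as.numeric(counts) / n, names64)
}

#' Per-gene composition table for the screen's comparison groups
#'
#' @param genes A `gene_models` data frame.
#' @param cds Named character vector of CDS (coding orientation).
#' @param group Named character vector of group labels per gene (e.g. `hgt`,
#'   `neighbor_fungal`, `all_fungal`).
#' @return Data frame with `gene_id`, `group`, `gc`, `n_introns`,
#'   `norm_intron_len`.
#' @export
gene_composition <- function(genes, cds, group = NULL) {
  introns <- intron_stats(genes)
  gc <- vapply(cds[genes$gene_id], gc_content, numeric(1))
  out <- data.frame(gene_id = genes$gene_id,
                    gc = unname(gc),
                    stringsAsFactors = FALSE)
  out <- merge(out, introns, by = "gene_id", sort = FALSE)
  if (!is.null(group)) out$group <- unname(group[out$gene_id])
  out
}

#' One-way analysis of variance from the sum-of-squares decomposition
#'
#' @param groups List of two or more numeric vectors, each of length >= 2.
#' @return A `stat_result` list: `statistic` (F), `df` (`c(k-1, N-k)`), `p`.
#'   Zero within-group variance yields F = 0, p = 1 when all means are also
#'   equal, and F = Inf, p = 0 otherwise.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  n <- lengths(groups)
  N <- sum(n)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ss_within == 0) {
    f <- if (ss_between == 0) 0 else Inf
    p <- if (ss_between == 0) 1 else 0
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(statistic = f, df = c(df1, df2), p = p,
                 method = "one-way ANOVA"), class = "stat_result")
}

#' Tukey honest significant difference pairwise comparisons
#'
#' Studentized-range statistic per group pair with the pooled within-group
#' mean square; adjusted p from the studentized-range distribution.
#'
#' @param groups Named (or unnamed) list of numeric vectors, as for
#'   [anova_oneway()].
#' @return Data frame with `group1`, `group2`, `diff`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (N - k)
  means <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
    d <- means[j] - means[i]
    q <- if (se == 0) if (d == 0) 0 else Inf else abs(d) / se
    p <- if (is.infinite(q)) 0
    else stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               diff = d, p_adj = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' `H = (12 / (N (N+1))) * sum n_i (rbar_i - rbar)^2`, divided by the tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)`; p from the chi-squared
#' approximation on k-1 df.
#'
#' @param groups List of two or more numeric vectors, total n >= 3.
#' @return A `stat_result` list with `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  x <- unlist(groups)
  N <- length(x)
  if (N < 3) stop("need total n >= 3")
  if (length(unique(x)) == 1)
    stop("all values identical; Kruskal-Wallis statistic undefined")
  r <- rank(x)
  g <- rep(seq_along(groups), lengths(groups))
  rsums <- tapply(r, g, sum)
  n <- lengths(groups)
  h <- 12 / (N * (N + 1)) * sum(rsums^2 / n) - 3 * (N + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h <- h / correction
  df <- length(groups) - 1L
  structure(list(statistic = h, df = df,
                 p = stats::pchisq(h, df, lower.tail = FALSE),
                 method = "Kruskal-Wallis"), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 5),
      ", df = ", paste(x$df, collapse = ", "),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Principal component analysis of a composition matrix
#'
#' Columns are centered (and optionally scaled to unit variance) and the
#' decomposition is taken from the singular values of the centered matrix.
#' Loadings are orthonormal; variance fractions are descending and sum to 1;
#' each component's sign is fixed so its largest-magnitude loading entry is
#' positive.
#'
#' @param x Numeric matrix, n genes x p features, n >= 2.
#' @param scale. Scale columns to unit variance (default FALSE: length-
#'   normalized counts are already on a common scale). Constant columns are
#'   dropped before scaling.
#' @return List of class `composition_pca`: `scores` (n x r), `loadings`
#'   (p x r), `var_fraction` (length r), `center`, `scale`.
#' @export
composition_pca <- function(x, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sds <- rep(1, ncol(x))
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    keep <- sds > 0
    if (!any(keep)) stop("constant matrix: no variance to decompose")
    xc <- sweep(xc[, keep, drop = FALSE], 2, sds[keep], "/")
  }
  if (all(abs(xc) < .Machine$double.eps * 100))
    stop("constant matrix: no variance to decompose")
  sv <- svd(xc)
  r <- sum(sv$d > sv$d[1] * 1e-12)
  d <- sv$d[seq_len(r)]
  loadings <- sv$v[, seq_len(r), drop = FALSE]
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(d, r, r)
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(r)) {
    m <- which.max(abs(loadings[, j]))
    if (loadings[m, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(r))
  rownames(loadings) <- colnames(x)
  structure(list(scores = scores, loadings = loadings,
                 var_fraction = d^2 / sum(sv$d^2), center = ctr,
                 scale = if (scale.) sds else NULL),
            class = "composition_pca")
}

#' Permutation test for group-centroid separation in PC space
#'
#' Statistic: Euclidean distance between the two group centroids in the
#' first `n_pc` principal components; the null distribution is obtained by
#' permuting group labels.
#'
#' @param scores Score matrix from [composition_pca()].
#' @param group Two-level factor or character vector, one label per row.
#' @param n_pc Number of leading components to use (default 2).
#' @param n_perm Number of permutations (default 999).
#' @return List with `statistic`, `p`, `n_perm`.
#' @export
pca_group_separation <- function(scores, group, n_pc = 2, n_perm = 999) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("need exactly 2 groups")
  s <- scores[, seq_len(min(n_pc, ncol(scores))), drop = FALSE]
  centroid_dist <- function(lab) {
    c1 <- colMeans(s[lab == levels(group)[1], , drop = FALSE])
    c2 <- colMeans(s[lab == levels(group)[2], , drop = FALSE])
    sqrt(sum((c1 - c2)^2))
  }
  obs <- centroid_dist(group)
  perm <- vapply(seq_len(n_perm), function(i) centroid_dist(sample(group)),
                 numeric(1))
  list(statistic = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}
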