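.hyper_tails <- function(k, K, n, N) {
  # one-sided hypergeometric tails for k successes in a draw of n from a
  # universe of N containing K
  list(p_over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_under = stats::phyper(k, K, N - K, n))
}

#' One-sided term enrichment (Fisher / hypergeometric)
#'
#' For each term, tests whether the foreground gene set contains more
#' (`p_over = P[X >= k]`) or fewer (`p_under = P[X <= k]`) term genes than
#' expected under hypergeometric sampling from the universe. `p_adj` is the
#' Bonferroni correction of the requested direction over the tested terms.
#'
#' @param foreground Character vector of gene symbols, a subset of the
#'   universe.
#' @param term_map Named list: term id -> character vector of member genes.
#' @param universe Character vector of all gene symbols (the whole-genome
#'   background). Term genes outside it are dropped.
#' @param direction `"over"` or `"under"`: which tail Bonferroni adjusts.
#' @return Data.frame: term_id, k, K, n, N, p_over, p_under, p_adj.
#' @export
fisher_term_enrichment <- function(foreground, term_map, universe,
                                   direction = c("over", "under")) {
  direction <- match.arg(direction)
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  foreground <- unique(foreground)
  if (!all(foreground %in% universe))
    stop("foreground must be a subset of the universe")
  N <- length(universe)
  n <- length(foreground)
  res <- lapply(names(term_map), function(term) {
    members <- intersect(unique(term_map[[term]]), universe)
    K <- length(members)
    k <- length(intersect(members, foreground))
    t <- .hyper_tails(k, K, n, N)
    data.frame(term_id = term, k = k, K = K, n = n, N = N,
               p_over = t$p_over, p_under = t$p_under,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  p <- if (direction == "over") res$p_over else res$p_under
  res$p_adj <- pmin(1, p * nrow(res))
  rownames(res) <- NULL
  res
}

#' Signed significance score
#'
#' Transforms a pair of one-sided p-values into a single signed score:
#' `+(-log10 p_over)` when over-representation is the stronger signal,
#' `-(-log10 p_under)` otherwise, clipped at `cap` to keep Euclidean
#' distances finite. Used to build the group-by-term matrix fed to
#' [cluster_pvalue_profiles()].
#'
#' @param p_over,p_under Numeric vectors of one-sided p-values.
#' @param cap Absolute clip value (default 300).
#' @return Numeric vector of signed scores.
#' @export
signed_significance <- function(p_over, p_under, cap = 300) {
  s <- ifelse(p_over <= p_under, -log10(pmax(p_over, 1e-300)),
              log10(pmax(p_under, 1e-300)))
  pmin(pmax(s, -cap), cap)
}

#' Hierarchical clustering of significance profiles
#'
#' Agglomerative clustering of the rows of a gene-group x term significance
#' matrix using Euclidean distances and Ward's agglomeration (implemented as
#' Ward.D2, i.e. on squared Euclidean updates). Ties are resolved by
#' `stats::hclust`'s deterministic ordering.
#'
#' @param x Numeric matrix (rows = gene groups, columns = terms), finite.
#' @return An object of class `hclust`.
#' @export
cluster_pvalue_profiles <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(is.finite(x))) stop("matrix must be finite")
  if (nrow(x) < 2L) stop("need at least 2 rows to cluster")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}

.split_pairs <- function(expr, samples) {
  if (!all(c("sample_id", "patient_id", "condition") %in% names(samples)))
    stop("sample sheet needs sample_id, patient_id, condition")
  patients <- unique(samples$patient_id)
  norm <- tum <- character(length(patients))
  for (i in seq_along(patients)) {
    sub <- samples[samples$patient_id == patients[i], , drop = FALSE]
    if (sum(sub$condition == "normal") != 1L ||
        sum(sub$condition == "tumor") != 1L)
      stop("patient ", patients[i],
           " must have exactly one normal and one tumor sample")
    norm[i] <- sub$sample_id[sub$condition == "normal"]
    tum[i] <- sub$sample_id[sub$condition == "tumor"]
  }
  list(patients = patients, normal = expr[, norm, drop = FALSE],
       tumor = expr[, tum, drop = FALSE])
}

#' Paired test of a gene group's expression shift
#'
#' Per patient, the mean expression over the group's genes is computed in
#' the tumor and the normal sample; the per-patient differences
#' (tumor - normal) are tested with a one-sided paired t-test. With zero
#' variance in the differences the t statistic is undefined; the degenerate
#' rule returns p = 0.5 for all-zero differences and p = 0 or 1 according to
#' the sign of the constant difference versus the alternative.
#'
#' @param expr Genes x samples log-expression matrix (rownames = genes).
#' @param samples Sample sheet (sample_id, patient_id, condition).
#' @param gene_group Non-empty character vector of gene symbols.
#' @param alternative `"greater"` (higher in tumor) or `"less"`.
#' @return List with `t`, `p`, `n_pairs`, `mean_diff`.
#' @export
paired_group_test <- function(expr, samples, gene_group,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  gene_group <- intersect(gene_group, rownames(expr))
  if (!length(gene_group)) stop("gene_group is empty (or not in the matrix)")
  sp <- .split_pairs(expr, samples)
  if (length(sp$patients) < 2L) stop("need at least 2 patient pairs")
  d <- colMeans(sp$tumor[gene_group, , drop = FALSE]) -
    colMeans(sp$normal[gene_group, , drop = FALSE])
  if (stats::sd(d) == 0) {
    md <- mean(d)
    p <- if (md == 0) 0.5
    else if ((md > 0) == (alternative == "greater")) 0 else 1
    return(list(t = if (md == 0) 0 else sign(md) * Inf, p = p,
                n_pairs = length(d), mean_diff = md))
  }
  ht <- stats::t.test(d, alternative = alternative)
  list(t = unname(ht$statistic), p = ht$p.value, n_pairs = length(d),
       mean_diff = mean(d))
}

#' Paired differential expression
#'
#' Per-gene paired t-test on the tumor - normal differences across
#' patients, with Benjamini-Hochberg correction by default; genes with
#' adjusted p below `params$de_alpha` are split into up- and down-regulated
#' sets by the sign of the mean difference. An optional empirical-Bayes
#' moderation shrinks the per-gene variances toward their mean with
#' `prior_df` prior degrees of freedom (a lightweight analogue of moderated
#' t-statistics).
#'
#' @param expr Genes x samples log-expression matrix.
#' @param samples Sample sheet (sample_id, patient_id, condition).
#' @param params A [stats_params()].
#' @param adjust Multiple-testing method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @param moderate If `TRUE`, moderate the per-gene variances.
#' @param prior_df Prior degrees of freedom for moderation.
#' @return List with `table` (gene, mean_diff, t, p, p_adj), `up`, `down`
#'   (character vectors).
#' @export
differential_expression <- function(expr, samples, params = stats_params(),
                                    adjust = "BH", moderate = FALSE,
                                    prior_df = 4) {
  sp <- .split_pairs(expr, samples)
  d <- sp$tumor - sp$normal
  n <- ncol(d)
  if (n < 2L) stop("need at least 2 patient pairs")
  md <- rowMeans(d)
  s2 <- rowSums((d - md)^2) / (n - 1)
  df <- n - 1
  if (moderate) {
    s2 <- (prior_df * mean(s2) + df * s2) / (prior_df + df)
    df <- df + prior_df
  }
  se <- sqrt(s2 / n)
  t <- ifelse(se > 0, md / se, ifelse(md == 0, 0, sign(md) * Inf))
  p <- 2 * stats::pt(-abs(t), df)
  p_adj <- stats::p.adjust(p, method = adjust)
  tab <- data.frame(gene = rownames(expr), mean_diff = md, t = t, p = p,
                    p_adj = p_adj, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  sig <- tab$p_adj < params$de_alpha
  list(table = tab, up = tab$gene[sig & tab$mean_diff > 0],
       down = tab$gene[sig & tab$mean_diff < 0])
}

#' Hypergeometric overlap of a gene group with a DE set
#'
#' Tests whether the overlap `k = |group intersect de_set|` is larger
#' (`p_over`) or smaller (`p_under`) than expected when drawing `|de_set|`
#' genes from the universe. Also reports the representation fractions
#' plotted in group-overlap bar charts: the group's share of the universe
#' and of the DE set.
#'
#' @param group,de_set Character vectors, subsets of `universe`.
#' @param universe Character vector of all genes considered.
#' @return List with `k`, `K` (=|group|), `n` (=|de_set|), `N`, `p_over`,
#'   `p_under`, `frac_universe`, `frac_de`.
#' @export
group_overlap_test <- function(group, de_set, universe) {
  universe <- unique(universe)
  group <- unique(group); de_set <- unique(de_set)
  if (!length(group)) stop("group is empty")
  if (!all(group %in% universe) || !all(de_set %in% universe))
    stop("group and de_set must be subsets of the universe")
  k <- length(intersect(group, de_set))
  t <- .hyper_tails(k, length(group), length(de_set), length(universe))
  list(k = k, K = length(group), n = length(de_set), N = length(universe),
       p_over = t$p_over, p_under = t$p_under,
       frac_universe = length(group) / length(universe),
       frac_de = if (length(de_set)) k / length(de_set) else NA_real_)
}

#' Overlap of gene groups with a hypermethylated set
#'
#' Applies the hypergeometric overlap test of [group_overlap_test()] to each
#' gene group against a hypermethylated gene list, restricted to the genes
#' present on both platforms (the supplied universe). Significance is read
#' at `params$meth_alpha`.
#'
#' @param gene_groups Named list of character vectors.
#' @param hypermeth_set Character vector of hypermethylated genes.
#' @param universe Character vector: genes with both chromatin and
#'   methylation data.
#' @param params A [stats_params()].
#' @return Data.frame: group, k, K, n, N, p_over, p_under, frac_universe,
#'   frac_meth, significant.
#' @export
methylation_overlap_test <- function(gene_groups, hypermeth_set, universe,
                                     params = stats_params()) {
  universe <- unique(universe)
  hypermeth_set <- intersect(unique(hypermeth_set), universe)
  res <- lapply(names(gene_groups), function(g) {
    grp <- intersect(unique(gene_groups[[g]]), universe)
    r <- group_overlap_test(grp, hypermeth_set, universe)
    data.frame(group = g, k = r$k, K = r$K, n = r$n, N = r$N,
               p_over = r$p_over, p_under = r$p_under,
               frac_universe = r$frac_universe, frac_meth = r$frac_de,
               significant = r$p_over < params$meth_alpha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}
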