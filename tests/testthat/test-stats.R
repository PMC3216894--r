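test_that("term enrichment matches hand-computed hypergeometric tails", {
  universe <- sprintf("g%02d", 1:10)
  terms <- list(T1 = universe[1:5])
  fg <- universe[c(1, 2, 3, 4)]
  # N=10, K=5, n=4, k=4: p_over = C(5,4) C(5,0) / C(10,4) = 5/210
  res <- fisher_term_enrichment(fg, terms, universe)
  expect_equal(res$k, 4L)
  expect_equal(res$p_over, 5 / 210, tolerance = 1e-12)
  # foreground = universe: k = K, over-tail is certain
  res2 <- fisher_term_enrichment(universe, terms, universe)
  expect_equal(res2$p_over, 1)
  # Bonferroni caps at 1 and scales with the number of terms
  many <- setNames(rep(list(universe[1:5]), 30), paste0("T", 1:30))
  res3 <- fisher_term_enrichment(fg, many, universe)
  expect_equal(res3$p_adj, pmin(1, res3$p_over * 30))
  expect_error(fisher_term_enrichment(fg, terms, character()), "empty")
  expect_error(fisher_term_enrichment(c("nope"), terms, universe), "subset")
})

test_that("hypergeometric tails equal brute-force enumeration (N <= 30)", {
  for (N in c(1:10, 17, 24, 30)) {
    for (K in 0:N) {
      for (n in seq(0, N, by = max(1, N %/% 6))) {
        ks <- max(0, n - (N - K)):min(n, K)
        for (k in ks) {
          o <- oracle_hyper_tails(k, K, n, N)
          got <- chromtrans:::.hyper_tails(k, K, n, N)
          expect_equal(got$p_over, o$p_over, tolerance = 1e-12)
          expect_equal(got$p_under, o$p_under, tolerance = 1e-12)
          # tail identity: p_over + p_under = 1 + P[X = k]
          expect_equal(got$p_over + got$p_under, 1 + o$p_eq,
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("expected-count overlap is never called significant", {
  # k exactly at the expected proportion: the over-tail is at least ~0.5
  o <- chromtrans:::.hyper_tails(k = 2, K = 5, n = 4, N = 10)
  expect_gte(o$p_over, 0.5)
})

test_that("group overlap test reports tails and fractions", {
  U <- sprintf("g%02d", 1:20)
  # |U|=20, |group|=5, |de|=8, k=5
  r <- group_overlap_test(U[1:5], U[1:8], U)
  expect_equal(r$k, 5L)
  expect_equal(r$p_over, choose(8, 5) * choose(12, 0) / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(r$p_over, 0.003612, tolerance = 1e-3)
  expect_equal(r$frac_universe, 0.25)
  expect_equal(r$frac_de, 5 / 8)
  # disjoint group: minimal under-tail, p_over = 1
  r0 <- group_overlap_test(U[1:5], U[6:13], U)
  expect_equal(r0$k, 0L)
  expect_equal(r0$p_over, 1)
  # group = universe: certain overlap
  r1 <- group_overlap_test(U, U[1:8], U)
  expect_equal(r1$p_over, 1)
  expect_equal(r1$k, 8L)
  expect_error(group_overlap_test(character(), U[1:2], U), "empty")
})

test_that("methylation overlap wraps the same machinery per group", {
  U <- sprintf("g%03d", 1:100)
  groups <- list(hot = U[1:20], cold = U[21:40])
  hm <- U[1:15]  # strongly overlapping 'hot'
  res <- methylation_overlap_test(groups, hm, U)
  expect_equal(res$group, c("hot", "cold"))
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  # empty hypermethylated set: p_over = 1 everywhere
  res0 <- methylation_overlap_test(groups, character(), U)
  expect_true(all(res0$p_over == 1))
})

test_that("paired group test matches the closed-form t distribution", {
  genes <- c("a", "b")
  mk <- function(diffs) {
    n <- length(diffs)
    samples <- data.frame(
      sample_id = paste0(rep(sprintf("P%d", 1:n), each = 2), "_",
                         c("normal", "tumor")),
      patient_id = rep(sprintf("P%d", 1:n), each = 2),
      condition = rep(c("normal", "tumor"), n), stringsAsFactors = FALSE)
    expr <- matrix(0, 2, 2 * n,
                   dimnames = list(genes, samples$sample_id))
    expr[, samples$condition == "tumor"] <-
      matrix(rep(diffs, each = 2), nrow = 2)
    list(expr = expr, samples = samples)
  }
  d <- c(1, 2, 3, 4)
  m <- mk(d)
  r <- paired_group_test(m$expr, m$samples, genes, "greater")
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(r$t, t_hand, tolerance = 1e-10)
  expect_equal(r$p, stats::pt(t_hand, df = 3, lower.tail = FALSE),
               tolerance = 1e-10)
  # near-constant positive differences at n = 4 are clearly significant
  m2 <- mk(c(1, 1.0001, 0.9999, 1))
  expect_lt(paired_group_test(m2$expr, m2$samples, genes, "greater")$p, 0.01)
  # degenerate cases
  m3 <- mk(c(0, 0, 0))
  r3 <- paired_group_test(m3$expr, m3$samples, genes, "greater")
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 0.5)
  m4 <- mk(c(1, 1, 1))
  expect_equal(paired_group_test(m4$expr, m4$samples, genes, "greater")$p, 0)
  expect_equal(paired_group_test(m4$expr, m4$samples, genes, "less")$p, 1)
  expect_error(paired_group_test(m$expr, m$samples, "zz"), "empty")
})

test_that("null paired tests are uniformly distributed", {
  truth <- make_truth(sprintf("G%02d", 1:40), rep("NONE", 40))
  ps <- vapply(1:200, function(s) {
    sim <- simulate_expression(truth, n_pairs = 12, seed = 5000 + s)
    paired_group_test(sim$expr, sim$samples, rownames(sim$expr),
                      alternative = "greater")$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("differential expression detects planted shifts and controls nulls", {
  genes <- sprintf("G%03d", 1:300)
  truth <- make_truth(genes, rep("NONE", 300))
  # null: BH at alpha 0.001 yields (essentially) no calls
  sim0 <- simulate_expression(truth, n_pairs = 24, seed = 31)
  de0 <- differential_expression(sim0$expr, sim0$samples)
  expect_equal(length(de0$up) + length(de0$down), 0L)
  # 100 genes shifted +2 log2, n = 24, residual sd 0.5: nearly all detected
  shift <- setNames(rep(2, 100), genes[1:100])
  sim1 <- simulate_expression(truth, n_pairs = 24, effects = shift,
                              seed = 32)
  de1 <- differential_expression(sim1$expr, sim1$samples)
  expect_gte(sum(genes[1:100] %in% de1$up), 95)
  expect_equal(length(de1$down), 0L)
  # constant matrix: no calls either way
  simc <- sim0
  simc$expr[] <- 5
  dec <- differential_expression(simc$expr, simc$samples)
  expect_equal(length(dec$up) + length(dec$down), 0L)
})

test_that("paired t-tests agree with limma's paired fit on the same data", {
  skip_if_not_installed("limma")
  genes <- sprintf("G%03d", 1:150)
  truth <- make_truth(genes, rep("NONE", 150))
  shift <- setNames(rep(1.5, 40), genes[1:40])
  sim <- simulate_expression(truth, n_pairs = 10, effects = shift, seed = 77)
  de <- differential_expression(sim$expr, sim$samples)
  # limma paired design without moderation-free comparison: the ordinary
  # per-gene t equals lmFit coefficients / stdev.unscaled / sigma
  d <- sim$expr[, sim$samples$condition == "tumor"] -
    sim$expr[, sim$samples$condition == "normal"]
  fit <- limma::lmFit(d)
  t_limma <- fit$coefficients[, 1] / (fit$stdev.unscaled[, 1] *
                                        fit$sigma)
  expect_equal(unname(de$table$t), unname(t_limma), tolerance = 1e-8)
})

test_that("Ward clustering reproduces a hand-computed merge sequence", {
  # rows: a = 0, b ends in 2, c = 10, d ends in 13
  x <- rbind(a = c(0, 0, 0, 0), b = c(0, 0, 0, 2),
             c = c(10, 10, 10, 10), d = c(10, 10, 10, 13))
  hc <- cluster_pvalue_profiles(x)
  # hand Ward (D2): {a,b} at height 2, {c,d} at 3, then all at sqrt(820.5):
  # D(ab,c)^2 = (2*400 + 2*364 - 4)/3 = 508
  # D(ab,d)^2 = (2*469 + 2*421 - 4)/3 = 592
  # D(ab,cd)^2 = (3*508 + 3*592 - 2*9)/4 = 820.5
  expect_equal(hc$height, c(2, 3, sqrt(820.5)), tolerance = 1e-10)
  m <- hc$merge
  expect_true(all(m[1, ] %in% c(-1, -2)))
  expect_true(all(m[2, ] %in% c(-3, -4)))
  expect_equal(sort(m[3, ]), c(1, 2))
  # identical rows merge first at height 0
  y <- rbind(c(1, 1), c(1, 1), c(9, 9))
  hcy <- cluster_pvalue_profiles(y)
  expect_equal(hcy$height[1], 0)
  expect_true(all(hcy$merge[1, ] %in% c(-1, -2)))
  expect_error(cluster_pvalue_profiles(rbind(c(1, Inf), c(0, 0))), "finite")
})

test_that("signed significance scores encode direction and cap", {
  s <- signed_significance(c(1e-4, 0.9, 1e-320), c(0.9, 1e-3, 1))
  expect_equal(s[1], 4)
  expect_equal(s[2], -3)
  expect_equal(s[3], 300)
})
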