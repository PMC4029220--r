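test_that("ROC handles perfect separation, total ties, and the 2/3 case", {
  perfect <- rocAuc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1.0)
  ties <- rocAuc(rep(1, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(ties$auc, 0.5)
  mixed <- rocAuc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(mixed$auc, 2 / 3)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("ROC curve runs (0,0) to (1,1) with non-decreasing coordinates", {
  set.seed(2)
  roc <- rocAuc(rnorm(50), rbinom(50, 1, 0.4) == 1)
  pts <- roc$points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("AUC equals brute-force concordance on random inputs", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- rbinom(n, 1, 0.5) == 1
    if (all(labels) || !any(labels)) next
    expect_equal(rocAuc(scores, labels)$auc, oracleAUC(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("enrichment p-values match hypergeometric enumeration", {
  # 10-gene background, term annotates 5, all 5 targets annotated
  ann <- data.frame(gene = sprintf("G%d", 1:5), term = "T1",
                    namespace = "process")
  bg <- sprintf("G%d", 1:10)
  fe <- fisherEnrichment(sprintf("G%d", 1:5), ann, bg, alpha = 0.05)
  expect_equal(10^fe$terms$log10_p, 1 / 252, tolerance = 1e-9)
  expect_true(fe$enriched)

  # zero annotated targets -> p = 1
  fe0 <- fisherEnrichment(sprintf("G%d", 6:10), ann, bg)
  expect_equal(10^fe0$terms$log10_p, 1)
  expect_false(fe0$enriched)

  expect_error(fisherEnrichment("NOT_THERE", ann, bg), "subset")

  set.seed(12)
  for (rep in 1:20) {
    N <- sample(20:500, 1); K <- sample(1:(N - 1), 1); n <- sample(1:N, 1)
    bgx <- sprintf("g%04d", 1:N)
    annx <- data.frame(gene = bgx[1:K], term = "TT", namespace = "function")
    tg <- sample(bgx, n)
    k <- sum(tg %in% bgx[1:K])
    p <- 10^fisherEnrichment(tg, annx, bgx)$terms$log10_p
    expect_equal(p, oracleHyperUpper(k, K, N, n), tolerance = 1e-9)
  }
})

test_that("planted annotation modules are significant, scrambled ones are not", {
  set.seed(33)
  bg <- sprintf("g%03d", 1:200)
  module <- bg[1:12]
  ann <- data.frame(gene = module, term = "MOD", namespace = "process")
  fe <- fisherEnrichment(module, ann, bg)
  expect_true(fe$enriched)
  scrambled <- data.frame(gene = sample(bg, 12), term = "MOD",
                          namespace = "process")
  feS <- fisherEnrichment(module, scrambled, bg)
  expect_false(feS$enriched)
})

test_that("PPI prevalence traces core, neighbours and complex by definition", {
  genome <- sprintf("g%d", 1:20)
  ppi <- data.frame(from = c("g1", "g2", "g4"), to = c("g2", "g10", "g5"))
  out <- ppiPrevalence(list(TF1 = c("g1", "g2", "g3")), ppi, genome)
  expect_equal(sort(out$complexes$TF1$core), c("g1", "g2"))
  expect_equal(out$complexes$TF1$neighbours, "g10")
  expect_equal(out$summary$n_complex, 3L)

  none <- ppiPrevalence(list(TF1 = c("g1", "g2")),
                        data.frame(from = character(0), to = character(0)),
                        genome)
  expect_equal(none$summary$n_core, 0L)
  expect_equal(none$summary$log10_p, 0)
  expect_false(none$summary$prevalent)
})

test_that("planted complexes flag prevalence, scrambled PPI does not", {
  set.seed(8)
  genome <- sprintf("g%03d", 1:150)
  targets <- genome[1:10]
  cl <- t(combn(targets[1:6], 2))
  ppi <- data.frame(from = cl[, 1], to = cl[, 2])
  out <- ppiPrevalence(list(TF = targets), ppi, genome)
  expect_true(out$summary$prevalent)
  # hypergeometric recount oracle
  k <- out$summary$n_core; K <- out$summary$n_complex
  expect_equal(10^out$summary$log10_p,
               oracleHyperUpper(k, K, 150, 10), tolerance = 1e-9)
  scr <- data.frame(from = sample(genome[11:150], 15),
                    to = sample(genome[11:150], 15))
  scr <- scr[scr$from != scr$to, ]
  outS <- ppiPrevalence(list(TF = targets), scr, genome)
  expect_false(outS$summary$prevalent)
})

test_that("squared correlations behave on identical and orthogonal profiles", {
  mat <- rbind(a = c(1, 2, 1, 2), b = c(1, 2, 1, 2), c = c(1, 1, 2, 2))
  r2 <- funcbind:::.pairwiseR2(c("a", "b"), mat)
  expect_equal(r2, 1)
  r2o <- funcbind:::.pairwiseR2(c("a", "c"), mat)
  expect_equal(r2o, 0)
})

test_that("coherence rank-sum p equals exact enumeration for small samples", {
  set.seed(5)
  x <- c(0.91, 0.72, 0.55, 0.40)
  y <- c(0.35, 0.28, 0.15, 0.61)
  pGot <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                       exact = TRUE)$p.value)
  expect_equal(pGot, oracleRankSumGreater(x, y), tolerance = 1e-12)
  # and through the module surface: two planted sets, one clearly coherent
  tps <- 6
  mod <- rnorm(tps)
  mat <- rbind(
    a1 = mod + rnorm(tps, sd = 0.1), a2 = mod + rnorm(tps, sd = 0.1),
    a3 = mod + rnorm(tps, sd = 0.1),
    b1 = rnorm(tps), b2 = rnorm(tps), b3 = rnorm(tps))
  cmp <- expressionCoherenceCompare(
    targetsA = list(TF = c("a1", "a2", "a3")),
    targetsB = list(TF = c("b1", "b2", "b3")),
    conditions = list(c1 = mat), alpha = 0.2)
  expect_equal(cmp$summary$winner, "A")
})

test_that("coherence comparison skips TFs that lack usable genes", {
  mat <- rbind(a = rnorm(5), b = rnorm(5))
  cmp <- expressionCoherenceCompare(
    targetsA = list(TF1 = c("a", "b"), TF2 = c("zz", "yy")),
    targetsB = list(TF1 = c("a", "b"), TF2 = c("a", "b")),
    conditions = list(c1 = mat))
  expect_equal(cmp$summary$n_tfs, 1L)
  expect_true(is.na(
    cmp$detail$log10_q_A_higher[cmp$detail$tf == "TF2"]))
})

test_that("benchmark t-statistics reproduce the published random-assignment tests", {
  # printed summaries are the inputs; recomputed t must match to input rounding
  expect_equal(tStatistic(62, 44.8, 3.53, 50), -34.41, tolerance = 0.005 * 34.41)
  expect_equal(tStatistic(53, 17.68, 3.78, 50), -66.13, tolerance = 0.005 * 66.13)
  expect_equal(tStatistic(42, 31.84, 3.28, 50), -21.87, tolerance = 0.005 * 21.87)
  expect_equal(tStatistic(34, 13.82, 3.21, 50), -44.43, tolerance = 0.005 * 44.43)
  # observed equal to the random mean -> t = 0, not significant
  expect_equal(tStatistic(10, 10, 2, 50), 0)
})

test_that("random-assignment benchmark beats random for a strongly enriched result", {
  set.seed(44)
  bg <- sprintf("g%03d", 1:120)
  bindingSets <- list(TF1 = bg[1:20], TF2 = bg[21:40])
  functionalSets <- list(TF1 = bg[1:16], TF2 = bg[21:36])
  ann <- data.frame(gene = c(bg[1:16], bg[21:36]),
                    term = rep(c("T1", "T2"), each = 16),
                    namespace = "process")
  bench <- randomAssignmentBenchmark(
    functionalSets, bindingSets, metric = "enrichment",
    annotations = ann, background = bg, reps = 10, seed = 3)
  expect_equal(bench$observed, 2)
  expect_lte(bench$randomMean, 2)
  expect_equal(length(bench$randomCounts), 10L)
  expect_true(is.finite(bench$t) || bench$randomSd == 0)

  # removal bookkeeping: floor(0.18 * 20) = 3 removed per TF
  set.seed(1)
  rl <- funcbind:::.randomAssignment(bindingSets, 0.18)
  expect_equal(lengths(rl), c(TF1 = 17L, TF2 = 17L))
  # tiny TFs (floor = 0) are untouched
  rl2 <- funcbind:::.randomAssignment(list(T = bg[1:5]), 0.18)
  expect_equal(lengths(rl2), c(T = 5L))
})

test_that("coherence benchmark reports per-condition paired t outcomes", {
  set.seed(21)
  tps <- 6
  mods <- replicate(2, rnorm(tps))
  genes <- sprintf("m%d_%d", rep(1:2, each = 4), rep(1:4, 2))
  mat <- t(sapply(seq_along(genes), function(i)
    mods[, (i - 1) %/% 4 + 1] + rnorm(tps, sd = 0.2)))
  rownames(mat) <- genes
  noise <- matrix(rnorm(8 * tps), 8,
                  dimnames = list(sprintf("n%d", 1:8), NULL))
  mat <- rbind(mat, noise)
  bindingSets <- list(TF1 = c(genes[1:4], "n1", "n2"),
                      TF2 = c(genes[5:8], "n3", "n4"))
  functionalSets <- list(TF1 = genes[1:4], TF2 = genes[5:8])
  bench <- randomAssignmentBenchmark(
    functionalSets, bindingSets, metric = "coherence",
    conditions = list(c1 = mat, c2 = mat + rnorm(length(mat), sd = 0.01)),
    removalFraction = 0.34, reps = 6, seed = 9, alpha = 0.1)
  expect_equal(nrow(bench$perCondition), 2L)
  expect_true(all(c("t", "log10_p", "better_than_random") %in%
                  names(bench$perCondition)))
  expect_gte(bench$n_better, 0)
})
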