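test_that("one-sample t-statistic matches direct arithmetic and table summaries", {
  lens <- c(4, 4, 5, 3, 4)
  expect_equal(tStatistic(2, mean(lens), sd(lens), 5), 6.3245553, tolerance = 1e-6)
  expect_equal(tStatistic(4, mean(lens), sd(lens), 5), 0)
  # summary-statistic form used by the random-assignment benchmark
  expect_equal(tStatistic(62, 44.8, 3.53, 50), -34.4539, tolerance = 1e-4)
})

test_that("log-space t tail matches the arbitrary-precision oracle", {
  # expected values computed once with a 60-digit regularized incomplete
  # beta evaluation of P(T_df >= t), then frozen
  frozen <- rbind(
    c(4,    0.1,    -0.33481510059),
    c(4,    1,      -0.728273408129),
    c(4,    6.3246, -2.79613542324),
    c(4,    50,     -6.31991599428),
    c(4,    800,    -11.1352432171),
    c(49,   0.1,    -0.336887158484),
    c(49,   1,      -0.792872911766),
    c(49,   6.3246, -7.43294925154),
    c(49,   50,     -43.288612456),
    c(49,   800,    -102.088807648),
    c(9999, 0.1,    -0.337078710704),
    c(9999, 1,      -0.799512422379),
    c(9999, 6.3246, -9.87819971471),
    c(9999, 50,     -486.594824005),
    c(9999, 800,    -9066.26983592))
  got <- log10POneTailed(frozen[, 2], frozen[, 1])
  expect_equal(got, frozen[, 3], tolerance = 1e-6)

  expect_equal(log10POneTailed(0, 4), log10(0.5), tolerance = 1e-12)
  expect_true(is.finite(log10POneTailed(800, 9999)))
  expect_lt(log10POneTailed(800, 9999), -1000)
  expect_error(log10POneTailed(1, 0), "df")
})

test_that("log-space BH matches the brute-force step-up definition", {
  expect_equal(fdrCorrectLog10(log10(0.07)), log10(0.07))
  expect_equal(10^fdrCorrectLog10(log10(c(0.01, 0.02, 0.03, 0.04))),
               rep(0.04, 4))
  same <- log10(rep(0.02, 5))
  expect_equal(fdrCorrectLog10(same), same)
  expect_error(fdrCorrectLog10(c(-1, 0.5)), "<= 0")

  set.seed(42)
  for (rep in 1:20) {
    p <- runif(sample(2:200, 1))
    expect_equal(10^fdrCorrectLog10(log10(p)), oracleBH(p),
                 tolerance = 1e-12)
    expect_equal(10^fdrCorrectLog10(log10(p)), p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }
  # order preserved, adjusted >= raw, and correct far below underflow
  lp <- c(-5000, -2, -3000, -0.5)
  q <- fdrCorrectLog10(lp)
  expect_true(all(q >= lp))
  expect_true(all(q <= 0))
  expect_equal(q[1], -5000 + log10(4), tolerance = 1e-9)
})

test_that("scorePairs resolves evidence cases and gates on RCS", {
  net <- buildNetwork(data.frame(from = c("A", "B", "C", "D"),
                                 to = c("B", "C", "D", "E")))
  cand <- data.frame(tf = c("A", "A", "A"),
                     gene = c("B", "E", "ZZ"),
                     p_binding = c(0.001, 0.002, 0.003))
  res <- scorePairs(net, cand, R = 50, seed = 3, rcsThreshold = 5)
  expect_equal(res$evidence_case, c("direct", "hypostatic", "none"))
  expect_equal(res$observed_length, c(1L, 4L, NA_integer_))
  expect_equal(res$cascade[1], "A->B")
  expect_equal(res$cascade[2], "A->B->C->D->E")
  expect_true(is.na(res$cascade[3]))
  expect_false(res$functional[3])
  expect_equal(res$rcs[3], 0)
  expect_equal(res$rcs, -ifelse(is.na(res$log10_p_corrected), 0,
                                res$log10_p_corrected))
  # direct pair in a chain: null paths essentially never length 1 -> high RCS
  expect_true(res$functional[1])
})

test_that("observed length equal to a constant null gives p = 0.5", {
  # single-edge network: every resample is the same network, so the null
  # sample is constant at the observed length
  net <- buildNetwork(data.frame(from = "A", to = "B"))
  res <- scorePairs(net, data.frame(tf = "A", gene = "B", p_binding = 0.001),
                    R = 10, seed = 1)
  expect_equal(res$log10_p_raw, log10(0.5))
  expect_equal(res$rcs, -log10(0.5), tolerance = 1e-12)
  expect_false(res$functional)
})

test_that("scorePairs is a pure function: permuting candidates permutes results", {
  e <- randomDigraph(12, 30, seed = 10)
  net <- buildNetwork(e)
  cand <- data.frame(tf = rep(c("n01", "n02", "n03"), each = 3),
                     gene = rep(c("n08", "n09", "n10"), 3),
                     p_binding = 0.005)
  cand <- cand[cand$tf != cand$gene, ]
  r1 <- scorePairs(net, cand, R = 40, seed = 6, rcsThreshold = 2)
  perm <- sample(nrow(cand))
  r2 <- scorePairs(net, cand[perm, ], R = 40, seed = 6, rcsThreshold = 2)
  r2ord <- r2[match(paste(r1$tf, r1$gene), paste(r2$tf, r2$gene)), ]
  rownames(r2ord) <- NULL
  expect_equal(r1, r2ord)
})

test_that("RCS is monotone non-increasing in observed length for a fixed null", {
  lp <- vapply(1:6, function(obs) {
    st <- funcbind:::.log10PFromNull(obs, nullMean = 4.2, nullSd = 1.1,
                                     R = 100)
    st$log10p
  }, numeric(1))
  expect_true(all(diff(-lp) <= 0))
  expect_true(all(-lp >= 0))
})

test_that("degenerate zero-sd nulls follow the documented sentinel rules", {
  below <- funcbind:::.log10PFromNull(1, 6, 0, 50)
  expect_equal(below$log10p, -4000)
  equal <- funcbind:::.log10PFromNull(6, 6, 0, 50)
  expect_equal(equal$log10p, log10(0.5))
  above <- funcbind:::.log10PFromNull(9, 6, 0, 50)
  expect_equal(above$log10p, 0)
})
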