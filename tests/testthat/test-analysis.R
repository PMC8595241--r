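test_that("local sensitivity matches the closed form for an isolated effector", {
  # P isolated in the network; definition = {P: +1}; baseline tSignal 0.
  # Clamping P to g gives tSignal -g, so mean |delta| = mean |grid| and the
  # denominator is 2 - 0 = 2.
  net <- proteinNetwork(data.frame(source = "A", target = "B", sign = 1,
                                   weight = 1), nodes = c("A", "B", "P", "R"))
  d <- diseaseDefinition("d", c(P = 1))
  grid <- seq(-0.99, 0.99, length.out = 21)
  res <- localSensitivity(net, numeric(0), d, proteins = c("P", "R"),
                          grid = grid)
  expect_equal(res$sensitivity_pct[res$protein == "P"],
               100 * mean(abs(grid)) / 2, tolerance = 1e-9)
  # protein disconnected from every definition effector
  expect_equal(res$sensitivity_pct[res$protein == "R"], 0)
  expect_true(all(res$sensitivity_pct >= 0 & res$sensitivity_pct <= 100))
  expect_error(localSensitivity(net, numeric(0), d, proteins = "ZZ"),
               "not in the network")
})

test_that("upstream proteins carry sensitivity through the network", {
  fx <- synthNetworkWithDefinitions(seed = 7)
  mod <- mechtrial:::drugStimulus(fx$drugs[[1]])
  res <- localSensitivity(fx$network, mod, fx$definition)
  expect_true(all(res$sensitivity_pct >= 0 & res$sensitivity_pct <= 100))
  # definition proteins respond to their own clamping
  own <- res$sensitivity_pct[res$protein %in% fx$definition@proteins$protein]
  expect_true(all(own > 0))
})

test_that("sensitivity ranking is deterministic with threshold flags", {
  res <- data.frame(protein = c("a", "b", "c"),
                    sensitivity_pct = c(5, 20, 16), impact = FALSE)
  r <- rankSensitiveProteins(res)
  expect_equal(r$protein, c("b", "c", "a"))
  expect_equal(r$impact, c(TRUE, TRUE, FALSE))
  # permutation invariance
  r2 <- rankSensitiveProteins(res[c(3, 1, 2), ])
  expect_equal(r2, r)
  # all-zero: id order, no flags
  z <- data.frame(protein = c("b", "a", "c"), sensitivity_pct = 0,
                  impact = FALSE)
  rz <- rankSensitiveProteins(z)
  expect_equal(rz$protein, c("a", "b", "c"))
  expect_false(any(rz$impact))
  expect_equal(nrow(rankSensitiveProteins(res, topM = 2)), 2)
})

test_that("Hopkins statistic separates uniform from clustered data", {
  hs <- vapply(1:30, function(s)
    hopkinsStatistic(matrix(runif(150 * 3), 150, 3), seed = s), numeric(1))
  expect_lt(abs(mean(hs) - 0.5), 0.05)
  set.seed(2)
  blobs <- rbind(matrix(rnorm(50 * 3, 0, 0.05), 50, 3),
                 matrix(rnorm(50 * 3, 10, 0.05), 50, 3))
  expect_gt(hopkinsStatistic(blobs, seed = 1), 0.75)
  # zero-range dimension dropped with a warning
  expect_warning(hopkinsStatistic(cbind(blobs, 1), seed = 1), "zero-range")
  expect_error(hopkinsStatistic(matrix(1:6, 3, 2)), "at least 10")
})

test_that("silhouette and Jaccard validate separated blobs and ignore
           label permutations", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40 * 3, 0, 0.2), 40, 3),
             matrix(rnorm(40 * 3, 8, 0.2), 40, 3))
  lab <- rep(1:2, each = 40)
  expect_gt(silhouetteIndex(X, lab), 0.9)
  jac <- jaccardBootstrap(X, lab, B = 50, seed = 1)
  expect_true(all(jac > 0.9))
  # relabeling leaves both unchanged
  expect_equal(silhouetteIndex(X, 3 - lab), silhouetteIndex(X, lab))
  expect_equal(unname(sort(jaccardBootstrap(X, 3 - lab, B = 50, seed = 1))),
               unname(sort(jac)), tolerance = 0.05)
  expect_error(silhouetteIndex(X, rep(1, 80)), "single cluster")
  # random labels on structureless data: silhouette near zero
  sil <- vapply(1:30, function(s) {
    set.seed(s)
    silhouetteIndex(matrix(runif(60 * 3), 60, 3), sample(1:2, 60, TRUE))
  }, numeric(1))
  expect_lt(abs(mean(sil)), 0.05)
})

test_that("k selection recovers planted partitions and filters degeneracy", {
  hits <- vapply(1:20, function(s) {
    cr <- selectOptimalK(blobData(s, n = 30), seed = s)
    cr@k == 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  cr <- selectOptimalK(blobData(1, n = 30), seed = 1)
  expect_true(all(diff(cr@explainedVariance) <= 1e-12))
  expect_true(all(cr@explainedVariance <= 1))
  expect_equal(sort(unique(cr@labels)), 1:3)
  # identical rows: no valid clustering
  expect_error(selectOptimalK(matrix(1, 30, 4)), "identical")
  # row order invariance of the selected k
  X <- blobData(3, n = 30)
  perm <- sample(nrow(X))
  expect_equal(selectOptimalK(X[perm, ], seed = 2)@k,
               selectOptimalK(X, seed = 2)@k)
})

test_that("cluster comparison detects shifts and controls type-I error", {
  set.seed(10)
  # one cluster shifted by 3 SD, parametric branch (n >= 30 per group)
  x <- c(rnorm(100), rnorm(100, 3))
  rep1 <- compareClusters(data.frame(v = x), rep(1:2, each = 100))
  expect_lt(rep1$overall$p, 1e-6)
  expect_equal(rep1$overall$test, "anova")
  expect_true(all(rep1$perCluster$q >= rep1$perCluster$p - 1e-12))
  # small groups fall back to non-parametric tests
  rep2 <- compareClusters(data.frame(v = c(rnorm(20), rnorm(20, 3))),
                          rep(1:2, each = 20))
  expect_equal(rep2$overall$test, "kruskal")
  # zero-variance variable flagged undefined
  rep3 <- compareClusters(data.frame(v = rep(1, 60)), rep(1:2, each = 30))
  expect_equal(rep3$overall$test, "undefined")
  expect_error(compareClusters(data.frame(v = 1:3), c(1, 1, 1)),
               "at least 2 clusters")
  # null simulation: overall false-positive rate stays near nominal
  # (four independent null variables per simulation tighten the binomial
  # noise on the estimated rate)
  set.seed(77)
  fp <- vapply(1:100, function(i) {
    df <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60),
                     d = rnorm(60))
    r <- compareClusters(df, rep(1:2, each = 30))
    mean(r$overall$p < 0.05)
  }, numeric(1))
  expect_lte(mean(fp), 0.07)
})

test_that("BH adjustment follows the step-up rule", {
  r <- compareClusters(data.frame(a = c(rnorm(40), rnorm(40, 2)),
                                  b = rnorm(80)),
                       rep(1:2, each = 40))
  for (v in unique(r$perCluster$variable)) {
    fam <- r$perCluster[r$perCluster$variable == v, ]
    # independent step-up oracle: q_(i) = min_{j >= i} p_(j) * m / j
    ord <- order(fam$p)
    m <- nrow(fam)
    expected <- rev(cummin(rev(fam$p[ord] * m / seq_len(m))))
    expect_equal(fam$q[ord], pmin(expected, 1))
    # BH rejections include every Bonferroni rejection
    expect_true(all(fam$q[fam$p * m < 0.05] < 0.05))
  }
})
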