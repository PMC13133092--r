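test_that("Shannon entropy obeys its bounds and closed forms", {
  expect_equal(shannonEntropy(rep(0.25, 4)), log(4))
  expect_equal(shannonEntropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannonEntropy(rep(0.25, 4), base = "base2"), 2)
  # direct formula evaluation on a 4-class profile
  p <- c(0.519, 0.216, 0.209, 0.056)
  expect_equal(shannonEntropy(p), -sum(p * log(p)))
  expect_equal(shannonEntropy(p), 1.159, tolerance = 1e-3)
  expect_error(shannonEntropy(c(0.5, 0.6)), "sum to 1")
  expect_error(shannonEntropy(c(-0.1, 1.1)), "non-negative")
  # bounds over random simplices
  set.seed(2)
  for (i in 1:20) {
    q <- rexp(4); q <- q / sum(q)
    h <- shannonEntropy(q)
    expect_gte(h, 0); expect_lte(h, log(4) + 1e-12)
  }
})

test_that("entropy ordering ranks dispersed profiles first", {
  prof <- rbind(uniform = rep(0.25, 4),
                degenerate = c(1, 0, 0, 0),
                skewed = c(0.7, 0.1, 0.1, 0.1))
  ord <- entropyOrdering(prof)
  expect_equal(ord$class, c("uniform", "skewed", "degenerate"))
  # invariant to row permutation; ties broken lexicographically
  ord2 <- entropyOrdering(prof[c(3, 1, 2), ])
  expect_equal(ord2, ord)
  tie <- rbind(b = c(0.5, 0.5, 0, 0), a = c(0, 0, 0.5, 0.5))
  expect_equal(entropyOrdering(tie)$class, c("a", "b"))
})

test_that("baseline metrics are zero for identical sides and count mismatches", {
  s <- makeSide()
  sOS <- makeSide(os = list("protective", 0.001, 10.8, TRUE))
  pairs <- c(list(list(sig = s, int = s), list(sig = s, int = sOS)),
             lapply(1:6, function(i) {
               set.seed(i)
               list(sig = makeSide(rho = runif(1, -0.5, 0.5),
                                   micro_score = rnorm(1)),
                    int = makeSide(rho = runif(1, -0.5, 0.5),
                                   micro_score = rnorm(1),
                                   immune_class = "cold"))
             }))
  tab <- makeCircuitryTable(pairs)
  bm <- baselineMetrics(tab)
  expect_equal(bm$euclid18[1], 0)
  expect_equal(bm$cosine_dist[1], 0, tolerance = 1e-12)
  expect_equal(bm$surv_mismatch[1], 0L)
  expect_equal(bm$micro_absdiff[1], 0)
  # flipping only the OS direction: one survival mismatch, nothing else
  expect_equal(bm$surv_mismatch[2], 1L)
  expect_equal(bm$tn_mismatch[2], 0L)
  expect_equal(bm$immune_mismatch[2], 0L)
})

test_that("euclid18 equals the full-PC-space distance for each pair", {
  atlas <- simulateAtlas(simulationSpec(nCircuitries = 25, seed = 4))
  bm <- baselineMetrics(atlas$table)
  x <- buildLatentTensor(atlas$table)
  st <- standardizeTensor(x)
  model <- fitEmbedding(st)
  p18 <- projectLatent(model, x, 18)
  n <- nCircuitries(atlas$table)
  dPC <- unname(sqrt(rowSums((p18[seq_len(n), ] - p18[n + seq_len(n), ])^2)))
  expect_equal(bm$euclid18, dPC, tolerance = 1e-8)
})

test_that("the Spearman matrix matches a brute-force rank correlation", {
  set.seed(10)
  df <- data.frame(a = rnorm(40), b = rnorm(40))
  df$c <- df$a^3 + rnorm(40, sd = 0.01)       # strongly rank-correlated
  sm <- spearmanMatrix(df)
  expect_equal(sm, t(sm))
  expect_equal(unname(diag(sm)), rep(1, 3))
  # brute force: Pearson on average ranks
  brute <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(sm[i, j], brute(df[[i]], df[[j]]), tolerance = 1e-12)
  # rank invariance under monotone transforms
  expect_equal(unname(spearmanMatrix(cbind(df$a, exp(df$a)))[1, 2]), 1)
  # constant columns flag NA with a warning, never silently 0
  expect_warning(smc <- spearmanMatrix(cbind(df, k = 1)), "constant")
  expect_true(all(is.na(smc["k", c("a", "b", "c")])))
})

test_that("dbary correlates strongly with survival mismatch on synthetic data", {
  atlas <- simulateAtlas(simulationSpec(nCircuitries = 400, seed = 21))
  bm <- baselineMetrics(atlas$table)
  x <- buildLatentTensor(atlas$table)
  n <- nCircuitries(atlas$table)
  bm$dbary <- SigPolytope:::.dbaryFromTensor(
    x[seq_len(n), , drop = FALSE], x[n + seq_len(n), , drop = FALSE])
  sm <- spearmanMatrix(bm[c("dbary", "euclid18", "surv_mismatch",
                            "immune_mismatch", "tn_mismatch")])
  # survival discordance dominates the geometric metric; categorical
  # mismatches contribute far less
  expect_gt(sm["dbary", "surv_mismatch"], 0.5)
  expect_gt(sm["dbary", "surv_mismatch"], sm["dbary", "immune_mismatch"])
  expect_gt(sm["dbary", "surv_mismatch"], sm["dbary", "tn_mismatch"])
})

test_that("axis ablation: self-comparison is exact, survival dominates immune", {
  atlas <- simulateAtlas(simulationSpec(nCircuitries = 300, seed = 6))
  none <- axisAblation(atlas$table, "none")
  expect_equal(none$spearman, 1, tolerance = 1e-12)
  expect_equal(none$regimeAgreement, 1)
  surv <- axisAblation(atlas$table, "survival")
  imm <- axisAblation(atlas$table, "immune")
  expect_lt(surv$spearman, imm$spearman)
  expect_lt(surv$regimeAgreement, imm$regimeAgreement)
  expect_gt(imm$regimeAgreement, 0.8)
  # no-scaling variant runs and degrades the ranking only partially
  ns <- axisAblation(atlas$table, "none", scale = FALSE)
  expect_gt(ns$spearman, 0)
  expect_lt(ns$spearman, 1)
})

test_that("dropping a constant axis changes nothing", {
  # immune identical everywhere -> immune_code has zero variance
  pairs <- lapply(1:10, function(i) {
    set.seed(50 + i)
    s <- makeSide(rho = runif(1, -0.5, 0.5), micro_score = rnorm(1),
                  immune_class = "intermediate")
    i2 <- makeSide(rho = runif(1, -0.5, 0.5), micro_score = rnorm(1),
                   immune_class = "excluded")
    list(sig = s, int = i2)
  })
  tab <- makeCircuitryTable(pairs)
  ab <- axisAblation(tab, "immune")
  expect_equal(ab$spearman, 1, tolerance = 1e-9)
  expect_equal(ab$regimeAgreement, 1)
})
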