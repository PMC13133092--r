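test_that("distance regimes bin exactly as specified, boundaries upward", {
  got <- classifyDistanceRegime(c(0.20, 0.5, 1.49, 1.5, 2.49, 2.5, 7.16))
  expect_equal(as.character(got),
               c("high_concordance", "moderate_discordance",
                 "moderate_discordance", "strong_discordance",
                 "strong_discordance", "extreme_discordance",
                 "extreme_discordance"))
  expect_error(classifyDistanceRegime(-0.1), "domain error")
  expect_error(classifyDistanceRegime(1, thresholds = c(2, 1, 3)),
               "increasing")
})

test_that("regimes partition the half-line and are monotone", {
  d <- sort(c(runif(200, 0, 6), 0, 0.5, 1.5, 2.5, 40))
  reg <- classifyDistanceRegime(d)
  expect_false(anyNA(reg))
  expect_equal(sum(table(reg)), length(d))
  # monotone: regime index never decreases along sorted dbary
  expect_true(all(diff(as.integer(reg)) >= 0))
})

test_that("volume tier thresholds follow the type-7 quantile convention", {
  v <- 1:100
  expect_equal(volumeTierThresholds(v, c(1 / 3, 2 / 3)),
               unname(quantile(v, c(1 / 3, 2 / 3), type = 7)))
  expect_equal(volumeTierThresholds(rep(5, 10)), c(5, 5))
  # monotone in probs
  t1 <- volumeTierThresholds(v, c(0.2, 0.4))
  t2 <- volumeTierThresholds(v, c(0.5, 0.8))
  expect_true(all(t2 >= t1))
  # degenerate zeros are excluded
  expect_equal(volumeTierThresholds(c(0, 0, v)), volumeTierThresholds(v))
  expect_error(volumeTierThresholds(c(1, 2)), "insufficient")
})

test_that("the nine volume classes are exhaustive and mutually exclusive", {
  tiers <- c(10, 100)
  grid <- expand.grid(vs = c(1, 30, 300), ratio = c(1, 2, 5))
  cls <- classifyVolumeClass(grid$vs * grid$ratio, grid$vs, tiers)
  expect_equal(length(unique(cls$volumeClass)), 9)
  expect_false(anyNA(cls$volumeClass))
  expect_equal(as.character(cls$volumeClass[grid$vs == 30 & grid$ratio == 1]),
               "Intermediate/Symmetric")
  big <- classifyVolumeClass(4000, 400, tiers)
  expect_equal(as.character(big$volumeClass), "High/Strong asymmetric")
  # degenerate volumes fall into the Low tier
  degen <- classifyVolumeClass(0, 5, tiers)
  expect_equal(as.character(degen$tier), "Low")
  expect_error(classifyVolumeClass(1, 1, tiers, symmetryBands = c(3, 2)),
               "config error")
})

test_that("the four joint phenotypes combine regime and volume class", {
  expect_equal(as.character(jointGeometricPhenotype(
    "high_concordance", "Low", "Symmetric")), "concordant_low_dim")
  expect_equal(as.character(jointGeometricPhenotype(
    "high_concordance", "High", "Symmetric")), "concordant_high_dim")
  expect_equal(as.character(jointGeometricPhenotype(
    "extreme_discordance", "High", "Strong asymmetric")),
    "discordant_high_dim_asymmetric")
  expect_equal(as.character(jointGeometricPhenotype(
    "moderate_discordance", "Low", "Symmetric")), "discordant_low_dim")
  # Intermediate maps to the high-dimensional arm only when asymmetric
  expect_equal(as.character(jointGeometricPhenotype(
    "strong_discordance", "Intermediate", "Symmetric")),
    "discordant_low_dim")
  expect_equal(as.character(jointGeometricPhenotype(
    "strong_discordance", "Intermediate", "Mod asymmetric")),
    "discordant_high_dim_asymmetric")
})

test_that("concordance summary distinguishes convergent, divergent, mixed", {
  s <- makeSide()  # risky, up, pro-tumoral micro, hot
  conv <- makeCircuitryTable(list(list(sig = s, int = s)))
  expect_equal(as.character(concordanceSummary(conv)), "Only Convergent")

  div <- makeCircuitryTable(list(list(sig = s, int = opposeSide(s))))
  expect_equal(as.character(concordanceSummary(div)), "Only Divergent")

  mixedInt <- s
  mixedInt$immune_class <- "cold"   # agree everywhere except immune polarity
  mx <- makeCircuitryTable(list(list(sig = s, int = mixedInt)))
  expect_equal(as.character(concordanceSummary(mx)), "Mixed")

  # neutral axes are excluded: int neutral on some axes but agreeing on the
  # comparable ones stays Only Convergent
  neutralInt <- s
  neutralInt$immune_class <- "intermediate"
  neutralInt$tn_direction <- "ns"
  nx <- makeCircuitryTable(list(list(sig = s, int = neutralInt)))
  expect_equal(as.character(concordanceSummary(nx)), "Only Convergent")

  # no comparable axis at all -> explicit Indeterminate
  z <- makeSide(rho = 0, rho_adj_p = 1, tn_direction = "ns",
                tn_wilcoxon_p = 1, os = list("ns", 0.5, 1, FALSE),
                pfi = list("ns", 0.5, 1, FALSE), micro_score = 0,
                immune_class = "intermediate")
  iz <- makeCircuitryTable(list(list(sig = z, int = z)))
  expect_equal(as.character(concordanceSummary(iz)), "Indeterminate")
})

test_that("separation-with-convergence is expressible", {
  # both sides fully agree in sign structure but differ hugely in strength,
  # so the circuitry is geometrically extreme yet Only Convergent
  weak <- makeSide(rho = 0.1, rho_adj_p = 0.2, tn_wilcoxon_p = 0.3,
                   os = list("risk", 0.04, 4.2, TRUE),
                   pfi = list("risk", 0.04, 4.1, TRUE),
                   micro_score = 0.2, immune_class = "hot")
  deep <- makeSide(rho = 0.65, rho_adj_p = 1e-12, tn_wilcoxon_p = 1e-15,
                   os = list("risk", 1e-14, 60, TRUE),
                   dss = list("risk", 1e-12, 50, TRUE),
                   dfi = list("risk", 1e-10, 42, TRUE),
                   pfi = list("risk", 1e-13, 55, TRUE),
                   micro_score = 2.8, immune_class = "hot")
  pairs <- c(list(list(sig = weak, int = deep)),
             lapply(1:10, function(i) {
               set.seed(100 + i)
               s <- makeSide(rho = runif(1, -0.5, 0.5),
                             micro_score = rnorm(1, 0, 0.3),
                             os = list("risk", 0.04, 4, TRUE),
                             pfi = list("ns", 0.5, 0.4, FALSE))
               list(sig = s, int = s)
             }))
  tab <- makeCircuitryTable(pairs)
  geo <- runPipeline(tab, verbose = FALSE)
  expect_equal(geo$concordance_class[1], "Only Convergent")
  expect_equal(geo$distance_regime[1], "extreme_discordance")
})
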