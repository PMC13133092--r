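test_that("signed direction encoding maps the three states", {
  expect_equal(encodeDirection(c("risk", "up")), c(1, 1))
  expect_equal(encodeDirection(c("protective", "down")), c(-1, -1))
  expect_equal(encodeDirection(c("ns", "non-significant", "n.s.")),
               c(0, 0, 0))
  expect_error(encodeDirection("sideways"), "encoding error")
})

test_that("strength transform is -log10 with a cap", {
  expect_equal(encodeStrength(0.01), 2)
  expect_equal(encodeStrength(1), 0)
  expect_equal(encodeStrength(1e-400), 300)  # underflows to 0, hits the cap
  expect_equal(encodeStrength(0.25, "raw"), 0.25)
  expect_error(encodeStrength(-0.1), "domain error")
  expect_error(encodeStrength(1.5), "domain error")
})

test_that("survival blocks zero out when non-significant", {
  expect_equal(encodeSurvivalBlock("ns", 0.8, 0.06, FALSE), c(0, 0, 0))
  expect_equal(encodeSurvivalBlock("risk", 0.001, 10.8, TRUE),
               c(1, 3, 10.8))
  # -log10(0.05) computed independently: 1.3010299956639812
  expect_equal(encodeSurvivalBlock("protective", 0.05, 3.84, TRUE),
               c(-1, 1.3010299956639812, 3.84))
  expect_error(encodeSurvivalBlock("ns", 0.01, 5, TRUE), "consistency error")
})

test_that("immune classes map onto the signed codomain", {
  expect_equal(encodeImmuneClass(c("hot", "cold", "excluded", "intermediate")),
               c(1, -1, 0, 0))
  expect_equal(encodeImmuneClass("immune-hot"), 1)
  expect_error(encodeImmuneClass("lukewarm"), "unknown immune class")
})

test_that("latent vectors have 18 named coordinates in fixed order", {
  tab <- makeCircuitryTable(list(list(sig = makeSide(),
                                      int = opposeSide(makeSide()))))
  v <- buildLatentVector(tab, "CIRC-001", "sig")
  expect_length(v, 18)
  expect_identical(names(v), latentCoordinateNames())
  expect_equal(unname(v[c("rho", "tn_dir", "os_dir", "immune_code")]),
               c(0.4, 1, 1, 1))
  dirIdx <- c("tn_dir", "os_dir", "dss_dir", "dfi_dir", "pfi_dir",
              "immune_code")
  expect_true(all(v[dirIdx] %in% c(-1, 0, 1)))
  strengthIdx <- grep("strength|chi2", names(v))
  expect_true(all(v[strengthIdx] >= 0))
})

test_that("an all-neutral annotation encodes to the zero vector", {
  allNs <- makeSide(rho = 0, rho_adj_p = 1, tn_direction = "ns",
                    tn_wilcoxon_p = 1,
                    os = list("ns", 0.5, 1, FALSE),
                    pfi = list("ns", 0.5, 1, FALSE),
                    micro_score = 0, immune_class = "intermediate")
  tab <- makeCircuitryTable(list(list(sig = allNs, int = allNs)))
  v <- buildLatentVector(tab, "CIRC-001", "sig")
  expect_equal(unname(v), rep(0, 18))
})

test_that("flipping one significance flag zeroes exactly its 3 coordinates", {
  sig1 <- makeSide()                                   # os significant
  sig0 <- makeSide(os = list("ns", 0.001, 10.8, FALSE)) # os switched off
  tab <- makeCircuitryTable(list(list(sig = sig1, int = sig1),
                                 list(sig = sig0, int = sig0)))
  v1 <- buildLatentVector(tab, "CIRC-001", "sig")
  v0 <- buildLatentVector(tab, "CIRC-002", "sig")
  osIdx <- c("os_dir", "os_strength", "os_chi2")
  expect_equal(unname(v0[osIdx]), c(0, 0, 0))
  expect_equal(v1[setdiff(names(v1), osIdx)], v0[setdiff(names(v0), osIdx)])
})

test_that("the latent tensor is 2N x 18 with a bijective row index", {
  atlas <- simulateAtlas(simulationSpec(nCircuitries = 5, seed = 3))
  x <- buildLatentTensor(atlas$table)
  expect_equal(dim(x), c(10, 18))
  idx <- attr(x, "index")
  expect_equal(nrow(idx), 10)
  expect_equal(anyDuplicated(paste(idx$id, idx$side)), 0L)
  expect_setequal(idx$id, circuitryIds(atlas$table))

  # permuting the input records permutes rows identically
  d <- circuitryData(atlas$table)
  perm <- c(3, 1, 5, 2, 4)
  tabP <- CircuitryTable(d[perm, ])
  xP <- buildLatentTensor(tabP)
  for (i in seq_len(5)) {
    expect_equal(unname(xP[i, ]), unname(x[perm[i], ]))
    expect_equal(unname(xP[5 + i, ]), unname(x[5 + perm[i], ]))
  }
})
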