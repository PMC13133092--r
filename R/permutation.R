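#' @include AllClasses.R
NULL

# deterministic per-replicate substream seed: a counter-based mix of the base
# seed, so changing B leaves earlier replicates unchanged
.substreamSeed <- function(seed, b) {
  as.integer((as.double(seed) * 48271 + as.double(b) * 9973) %% 2147483647)
}

# within-stratum permutation of 1..n given stratum labels; strata of size 1
# stay fixed
.stratifiedPermutation <- function(strata) {
  perm <- seq_along(strata)
  for (s in unique(strata)) {
    i <- which(strata == s)
    if (length(i) > 1) perm[i] <- i[sample.int(length(i))]
  }
  perm
}

#' Stratified permutation null model
#'
#' Tests whether the observed concordance-discordance structure could arise
#' from random pairing of signature and interaction components. For each of
#' B replicates the interaction embeddings are randomly reassigned within
#' cancer-type strata (preserving cohort composition), the shared embedding
#' is recomputed from the permuted tensor, barycenter distances are
#' recalculated and circuitries reassigned to regimes. Three global
#' statistics are tracked (mean dbary, proportion extreme discordance,
#' proportion high concordance) and compared upper-tailed against their null
#' distributions with the bias-corrected estimator
#' `p = (k + 1) / (B + 1)`, `k = #\{null >= observed\}`, whose minimum
#' attainable value is `1 / (B + 1)`.
#'
#' @param table a [CircuitryTable-class].
#' @param param a [SigPolytopeParam-class]; `nPermutations` and `seed` drive
#'   the null. Each replicate uses a counter-derived substream seed so
#'   increasing B does not reshuffle earlier replicates.
#' @return a [PermutationResult-class].
#' @examples
#' tab <- simulateAtlas(simulationSpec(nCircuitries = 30, seed = 2))$table
#' permutationNull(tab, SigPolytopeParam(nPermutations = 19L, seed = 2))
#' @export
permutationNull <- function(table, param = SigPolytopeParam()) {
  stopifnot(methods::is(table, "CircuitryTable"))
  B <- param@nPermutations
  if (B < 1L) stop("config error: nPermutations must be >= 1", call. = FALSE)
  x <- buildLatentTensor(table, param)
  n <- nrow(x) / 2
  strata <- table@data$cancer_type
  if (max(table(strata)) < 2)
    stop("need at least one stratum with >= 2 circuitries", call. = FALSE)
  sig <- x[seq_len(n), , drop = FALSE]
  int <- x[n + seq_len(n), , drop = FALSE]
  thr <- param@distanceThresholds

  stats3 <- function(db) {
    reg <- classifyDistanceRegime(db, thr)
    c(mean_dbary = mean(db),
      prop_extreme = mean(reg == "extreme_discordance"),
      prop_high_concordance = mean(reg == "high_concordance"))
  }
  observed <- stats3(.dbaryFromTensor(sig, int, param@nComponents,
                                      scale = param@scaleColumns))
  draws <- matrix(NA_real_, B, 3,
                  dimnames = list(NULL, names(observed)))
  for (b in seq_len(B)) {
    set.seed(.substreamSeed(param@seed, b))
    perm <- .stratifiedPermutation(strata)
    db <- .dbaryFromTensor(sig, int[perm, , drop = FALSE],
                           param@nComponents, scale = param@scaleColumns)
    draws[b, ] <- stats3(db)
  }
  k <- colSums(sweep(draws, 2, observed, ">="))
  pv <- (k + 1) / (B + 1)
  methods::new("PermutationResult",
               B = B, observed = observed, nullDraws = draws,
               pValues = pv, seed = param@seed)
}

#' Bias-corrected empirical p-value
#'
#' The finite-sample permutation estimator `p = (k + 1) / (B + 1)`, which can
#' never return zero: with `k` of `B` null replicates at or beyond the
#' observed statistic, the smallest attainable value is `1 / (B + 1)`.
#'
#' @param k number of null replicates >= observed.
#' @param B number of permutation replicates.
#' @return the empirical p-value.
#' @examples
#' permutationPValue(1, 500)   # 2/501
#' permutationPValue(500, 500) # 1
#' @export
permutationPValue <- function(k, B) {
  if (any(B < 1) || any(k < 0) || any(k > B))
    stop("require 0 <= k <= B, B >= 1", call. = FALSE)
  (k + 1) / (B + 1)
}
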