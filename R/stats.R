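#' @include AllClasses.R
NULL

#' Shannon entropy of a class-proportion vector
#'
#' `H = -sum(p log p)` with the convention `0 log 0 = 0`, in natural log
#' units by default (base-2 optionally).
#'
#' @param proportions non-negative vector summing to 1 (tolerance 1e-9).
#' @param base `"natural"` or `"base2"`.
#' @return non-negative scalar; at most `log(length(proportions))`.
#' @examples
#' shannonEntropy(rep(0.25, 4))   # log(4)
#' shannonEntropy(c(1, 0, 0, 0))  # 0
#' @export
shannonEntropy <- function(proportions, base = c("natural", "base2")) {
  base <- match.arg(base)
  p <- as.numeric(proportions)
  if (any(!is.finite(p)) || any(p < 0))
    stop("domain error: proportions must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("domain error: proportions must sum to 1", call. = FALSE)
  nz <- p[p > 0]
  h <- -sum(nz * log(nz))
  if (base == "base2") h / log(2) else h
}

#' Entropy-based ordering of class profiles
#'
#' Ranks categorical classes by the Shannon entropy of their regime-
#' proportion profiles, most dispersed first; ties broken lexicographically
#' by class name.
#'
#' @param profiles matrix or data.frame, one row per class (rownames are the
#'   class labels), each row a proportion vector summing to 1.
#' @param base entropy log base.
#' @return data.frame with columns `class` and `entropy`, ordered by
#'   decreasing entropy.
#' @export
entropyOrdering <- function(profiles, base = c("natural", "base2")) {
  base <- match.arg(base)
  m <- as.matrix(profiles)
  if (is.null(rownames(m))) rownames(m) <- paste0("class", seq_len(nrow(m)))
  h <- apply(m, 1, shannonEntropy, base = base)
  ord <- order(-h, rownames(m))
  data.frame(class = rownames(m)[ord], entropy = unname(h[ord]),
             stringsAsFactors = FALSE)
}

#' Baseline vector-space discordance metrics
#'
#' Computes, per circuitry, the conventional discordance measures used to
#' benchmark the geometric metric: Euclidean and cosine distance between the
#' two sides' standardized 18-dimensional latent vectors, survival-direction
#' mismatch counts (over endpoints with defined directions on both sides),
#' immune classification mismatch, tumor-normal direction mismatch, and the
#' absolute microenvironment-score difference. A zero standardized vector
#' makes the cosine undefined; it is set to 1 (orthogonal-equivalent) and
#' flagged.
#'
#' @param table a [CircuitryTable-class].
#' @param param a [SigPolytopeParam-class].
#' @return data.frame with one row per circuitry: `id`, `euclid18`,
#'   `cosine_dist`, `cosine_degenerate`, `surv_mismatch`, `immune_mismatch`,
#'   `tn_mismatch`, `micro_absdiff`.
#' @export
baselineMetrics <- function(table, param = SigPolytopeParam()) {
  stopifnot(methods::is(table, "CircuitryTable"))
  d <- table@data
  n <- nrow(d)
  x <- buildLatentTensor(table, param)
  xs <- standardizeTensor(x, scale = param@scaleColumns)$x
  sig <- xs[seq_len(n), , drop = FALSE]
  int <- xs[n + seq_len(n), , drop = FALSE]
  diff_ <- sig - int
  euclid <- sqrt(rowSums(diff_^2))
  ns <- sqrt(rowSums(sig^2))
  ni <- sqrt(rowSums(int^2))
  degen <- ns == 0 | ni == 0
  cosd <- rep(1, n)
  cosd[!degen] <- 1 - rowSums(sig[!degen, , drop = FALSE] *
                              int[!degen, , drop = FALSE]) /
    (ns[!degen] * ni[!degen])
  cosd <- pmin(pmax(cosd, 0), 2)

  surv <- vapply(seq_len(n), function(i) {
    row <- d[i, , drop = FALSE]
    cnt <- 0L
    for (e in .SURV_ENDPOINTS) {
      ds <- if (isTRUE(row[[paste0("sig_", e, "_significant")]]))
        encodeDirection(row[[paste0("sig_", e, "_direction")]]) else 0
      di <- if (isTRUE(row[[paste0("int_", e, "_significant")]]))
        encodeDirection(row[[paste0("int_", e, "_direction")]]) else 0
      if (ds != 0 && di != 0 && ds != di) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
  tnS <- encodeDirection(d$sig_tn_direction)
  tnI <- encodeDirection(d$int_tn_direction)
  tn_mis <- as.integer(tnS != 0 & tnI != 0 & tnS != tnI)
  imm_mis <- as.integer(d$sig_immune_class != d$int_immune_class)
  data.frame(id = d$id,
             euclid18 = euclid,
             cosine_dist = cosd,
             cosine_degenerate = degen,
             surv_mismatch = surv,
             immune_mismatch = imm_mis,
             tn_mismatch = tn_mis,
             micro_absdiff = abs(d$sig_micro_score - d$int_micro_score),
             stringsAsFactors = FALSE)
}

#' Spearman correlation matrix of discordance metrics
#'
#' Symmetric rank-correlation matrix (average ranks for ties) across all
#' numeric metric columns, typically the baseline metrics joined with dbary.
#' Constant columns yield `NA` entries and a warning rather than a silent
#' zero.
#'
#' @param metrics data.frame or matrix of per-circuitry metrics; non-numeric
#'   columns are dropped.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(metrics) {
  m <- as.data.frame(metrics)
  m <- m[vapply(m, is.numeric, logical(1))]
  m <- as.matrix(m)
  if (nrow(m) < 3)
    stop("need at least 3 circuitries", call. = FALSE)
  const <- apply(m, 2, function(v) length(unique(v)) == 1)
  out <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (any(const)) {
    warning("constant metric column(s): ",
            paste(colnames(m)[const], collapse = ", "),
            "; correlations undefined (NA)")
    out[const, ] <- NA
    out[, const] <- NA
  }
  diag(out) <- 1
  out
}

# shared fast path: dbary for every circuitry from a (possibly reduced or
# re-paired) latent tensor, recomputing standardization + PCA + projection.
# By linearity the projected latent point equals the projected-vertex
# barycenter, so hulls are not needed for distances.
.dbaryFromTensor <- function(sigRows, intRows, nComponents = 3L,
                             scale = TRUE) {
  xs <- standardizeTensor(rbind(sigRows, intRows), scale = scale)
  model <- fitEmbedding(xs)
  n <- nrow(sigRows)
  k <- min(nComponents, ncol(sigRows))
  sc <- xs$x %*% model@loadings[, seq_len(k), drop = FALSE]
  ps <- sc[seq_len(n), , drop = FALSE]
  pi_ <- sc[n + seq_len(n), , drop = FALSE]
  sqrt(rowSums((ps - pi_)^2))
}

#' Axis-ablation robustness analysis
#'
#' Re-runs the embedding and barycenter-distance computation after deleting
#' an axis group (the 12 survival coordinates or the immune code) or after
#' switching off variance scaling, and compares the resulting geometric
#' ranking with the reference embedding: Spearman correlation of dbary and
#' the fraction of circuitries keeping their distance-regime label.
#'
#' @param table a [CircuitryTable-class].
#' @param drop `"none"`, `"survival"` or `"immune"`.
#' @param scale apply variance scaling in the ablated run (`FALSE`
#'   reproduces the no-scaling robustness variant).
#' @param param a [SigPolytopeParam-class].
#' @return list with `spearman`, `regimeAgreement`, `dbary`,
#'   `dbaryReference`.
#' @export
axisAblation <- function(table, drop = c("none", "survival", "immune"),
                         scale = TRUE, param = SigPolytopeParam()) {
  drop <- match.arg(drop)
  x <- buildLatentTensor(table, param)
  n <- nrow(x) / 2
  keep <- switch(drop,
    none = seq_len(ncol(x)),
    survival = setdiff(seq_len(ncol(x)), .SURV_COORD_IDX),
    immune = setdiff(seq_len(ncol(x)), .IMMUNE_COORD_IDX))
  if (length(keep) == 0) stop("config error: cannot drop all axes", call. = FALSE)
  ref <- .dbaryFromTensor(x[seq_len(n), , drop = FALSE],
                          x[n + seq_len(n), , drop = FALSE],
                          param@nComponents, scale = param@scaleColumns)
  abl <- .dbaryFromTensor(x[seq_len(n), keep, drop = FALSE],
                          x[n + seq_len(n), keep, drop = FALSE],
                          param@nComponents, scale = scale)
  regRef <- classifyDistanceRegime(ref, param@distanceThresholds)
  regAbl <- classifyDistanceRegime(abl, param@distanceThresholds)
  rho <- stats::cor(ref, abl, method = "spearman")
  list(spearman = rho,
       regimeAgreement = mean(as.character(regRef) == as.character(regAbl)),
       dbary = abl, dbaryReference = ref)
}
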