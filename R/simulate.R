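#' @include AllClasses.R
NULL

.MIXTURE_COMPONENTS <- c("concordant", "moderately_discordant",
                         "strongly_discordant", "extremely_discordant")

#' Default per-component effect scales of the atlas simulator
#'
#' One parameter block per mixture component, controlling how the
#' interaction side deviates from the signature side. The signed axis
#' families of a circuitry split into "weak" axes (correlation sign,
#' tumor-normal direction, microenvironment sign, immune polarity) and the
#' survival-endpoint directions, which dominate the standardized latent
#' variance. `flipWeak` is the per-axis flip probability of the weak axes,
#' `survFlips` the number of significant survival endpoints whose direction
#' is flipped (graded survival discordance), `minFlips` a guaranteed minimum
#' number of flipped axes (forced flips prefer weak axes, so mildly
#' discordant circuitries diverge on low-weight axes first),
#' `strengthJitter` the log-normal jitter on -log10 strengths,
#' `strengthShift` an additive strength shift on the interaction side, and
#' `survResampleProb` the probability of re-drawing an endpoint's
#' significance independently of the signature side (at rate `intSurvRate`
#' when given). With `opposeOrientation = TRUE`, endpoints newly turned on
#' for the interaction side take the direction opposing the signature's
#' dominant survival orientation, producing the deep, coherent opposition
#' typical of extremely discordant circuitries. The defaults were
#' chosen so that the four components separate into the four
#' barycenter-distance regimes under the fixed thresholds.
#'
#' @return named list of four parameter blocks.
#' @export
defaultEffectScales <- function() {
  list(
    concordant = list(flipWeak = 0.00, survFlips = 0L, minFlips = 0L,
                      strengthJitter = 0.03, strengthShift = 0,
                      survResampleProb = 0.00),
    moderately_discordant = list(flipWeak = 0.00, survFlips = 0L,
                                 minFlips = 2L, strengthJitter = 0.15,
                                 strengthShift = 0.05,
                                 survResampleProb = 0.02),
    strongly_discordant = list(flipWeak = 0.00, survFlips = 1L,
                               minFlips = 3L, strengthJitter = 0.25,
                               strengthShift = 0.3,
                               survResampleProb = 0.10),
    extremely_discordant = list(flipWeak = 0.95, survFlips = 4L,
                                minFlips = 6L, strengthJitter = 0.80,
                                strengthShift = 4.0,
                                survResampleProb = 0.90, intSurvRate = 0.85,
                                opposeOrientation = TRUE,
                                freshStrengths = TRUE)
  )
}

#' Specify a synthetic circuitry atlas
#'
#' @param nCircuitries number of circuitries to simulate.
#' @param nStrata number of cancer-type strata.
#' @param mixture proportions over the four concordance components (must sum
#'   to 1); the default mirrors an atlas dominated by extreme discordance.
#' @param effectScales per-component deviation parameters; see
#'   [defaultEffectScales()].
#' @param survivalSignificanceRate probability that a survival endpoint is
#'   significant on the signature side.
#' @param immuneDistribution probabilities of the four immune classes.
#' @param depth gamma `shape` and `rate` of the side-level significance
#'   depth that drives all -log10 p strengths of a side.
#' @param seed integer seed.
#' @return a validated `SimulationSpec` (list).
#' @export
simulationSpec <- function(nCircuitries,
                           nStrata = 8L,
                           mixture = c(concordant = 0.05,
                                       moderately_discordant = 0.20,
                                       strongly_discordant = 0.20,
                                       extremely_discordant = 0.55),
                           effectScales = defaultEffectScales(),
                           survivalSignificanceRate = 0.5,
                           immuneDistribution = c(hot = 0.25, cold = 0.25,
                                                  excluded = 0.25,
                                                  intermediate = 0.25),
                           depth = c(shape = 2, rate = 0.45),
                           seed = 1L) {
  mixture <- mixture[.MIXTURE_COMPONENTS]
  if (anyNA(mixture) || abs(sum(mixture) - 1) > 1e-9 || any(mixture < 0))
    stop("config error: mixture must be a 4-simplex over the components",
         call. = FALSE)
  if (abs(sum(immuneDistribution) - 1) > 1e-9 || any(immuneDistribution < 0))
    stop("config error: immuneDistribution must be a 4-simplex", call. = FALSE)
  if (survivalSignificanceRate < 0 || survivalSignificanceRate > 1)
    stop("config error: survivalSignificanceRate must be in [0,1]",
         call. = FALSE)
  stopifnot(nCircuitries >= 1, nStrata >= 1)
  if (length(depth) != 2 || any(depth <= 0))
    stop("config error: depth must be positive (shape, rate)", call. = FALSE)
  structure(list(nCircuitries = as.integer(nCircuitries),
                 nStrata = as.integer(nStrata),
                 mixture = mixture,
                 effectScales = effectScales,
                 survivalSignificanceRate = survivalSignificanceRate,
                 immuneDistribution = immuneDistribution,
                 depth = c(shape = unname(depth[1]), rate = unname(depth[2])),
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

# one signature-side annotation block, drawn from the marginal model. Each
# side carries a latent orientation (pro-tumoral/risk vs anti-tumoral/
# protective) and a significance depth: all signed axes (correlation sign,
# tumor-normal direction, survival directions, microenvironment sign,
# immune polarity) align with the orientation with high probability, and all
# -log10 p strengths share the depth factor. This emulates the coherent
# multi-layer phenotypic profiles of real circuitry annotations and gives
# the joint latent tensor a dominant, stable leading-variance structure.
# per-stratum generative profile: a dominant orientation, a significance-
# depth baseline and endpoint-specific significance rates. Cancer-type
# cohorts differ in which survival endpoints are informative and how deep
# their associations run; modelling this makes between-stratum variation
# dominate the embedding, so randomly re-paired sides within a stratum stay
# close and deliberate within-circuitry opposition is detectable against
# the stratified permutation null.
.drawStratumProfile <- function(spec) {
  list(ori = sample(c(1, -1), 1, prob = c(0.75, 0.25)),
       depthBase = stats::rgamma(1, shape = spec$depth[["shape"]],
                                 rate = spec$depth[["rate"]]),
       survRate = stats::setNames(
         ifelse(stats::runif(4) < spec$survivalSignificanceRate, 0.85, 0.15),
         .SURV_ENDPOINTS))
}

.drawSide <- function(spec, profile = NULL) {
  u2p <- function(u) pmax(10^(-u), 1e-280)
  if (is.null(profile)) profile <- .drawStratumProfile(spec)
  ori <- if (stats::runif(1) < 0.90) profile$ori else -profile$ori
  depth <- profile$depthBase * exp(stats::rnorm(1, 0, 0.30))
  uDraw <- function(floor_ = 0)
    floor_ + depth * exp(stats::rnorm(1, 0, 0.25))
  withOri <- function(p) if (stats::runif(1) < p) ori else -ori

  rhoSign <- withOri(0.85)
  out <- list(rho = rhoSign * stats::runif(1, 0.05, 0.7),
              rho_adj_p = u2p(uDraw()))
  if (stats::runif(1) < 0.10) {
    out$tn_direction <- "ns"
  } else {
    out$tn_direction <- if (withOri(0.80) == 1) "up" else "down"
  }
  out$tn_wilcoxon_p <- u2p(uDraw())
  for (e in .SURV_ENDPOINTS) {
    sig <- stats::runif(1) < profile$survRate[[e]]
    if (sig) {
      p <- u2p(uDraw(1.30103))
      out[[paste0(e, "_direction")]] <-
        if (withOri(0.90) == 1) "risk" else "protective"
    } else {
      p <- stats::runif(1, 0.05, 1)
      out[[paste0(e, "_direction")]] <- "ns"
    }
    out[[paste0(e, "_p")]] <- p
    out[[paste0(e, "_chi2")]] <- stats::qchisq(p, 1, lower.tail = FALSE)
    out[[paste0(e, "_significant")]] <- sig
  }
  out$micro_score <- stats::rnorm(1, mean = 0.8 * ori, sd = 0.6)
  imm <- spec$immuneDistribution
  if (stats::runif(1) < imm[["hot"]] + imm[["cold"]]) {
    # polar immune state, aligned with the orientation most of the time
    # (hot tumors treated as the pro-tumoral pole of the signed code)
    out$immune_class <- if (withOri(0.80) == 1) "hot" else "cold"
  } else {
    out$immune_class <- sample(c("excluded", "intermediate"), 1,
      prob = imm[c("excluded", "intermediate")] /
        max(sum(imm[c("excluded", "intermediate")]), 1e-12))
  }
  out
}

# interaction side as a controlled deviation of the signature side: a flip
# set over the circuitry's signed axes is drawn (with a guaranteed minimum,
# weak axes forced first), then strengths are jittered/shifted
.deriveIntSide <- function(sig, es, spec) {
  u2p <- function(u) pmax(10^(-pmax(u, 0)), 1e-280)
  p2u <- function(p) -log10(p)
  jitterU <- function(u) u * exp(stats::rnorm(1, 0, es$strengthJitter)) +
    stats::runif(1, 0, es$strengthShift)

  # dominant orientation of the signature side (fallback: micro sign);
  # flips are preferentially applied to axes currently aligned with it, so
  # their latent displacements add coherently instead of cancelling
  sigDirs <- vapply(.SURV_ENDPOINTS, function(e)
    if (isTRUE(sig[[paste0(e, "_significant")]]))
      encodeDirection(sig[[paste0(e, "_direction")]]) else 0, numeric(1))
  sigOri <- sign(sum(sigDirs))
  if (sigOri == 0) sigOri <- if (sig$micro_score >= 0) 1 else -1
  oppose <- isTRUE(es$opposeOrientation)
  intSurvRate <- es$intSurvRate %||% spec$survivalSignificanceRate

  weakAxes <- c("rho",
                if (sig$tn_direction != "ns") "tn",
                "micro",
                if (sig$immune_class %in% c("hot", "cold")) "immune")
  axisSign <- c(rho = sign(sig$rho),
                tn = if (sig$tn_direction == "ns") 0 else
                  encodeDirection(sig$tn_direction),
                micro = sign(sig$micro_score),
                immune = if (sig$immune_class == "hot") 1 else
                  if (sig$immune_class == "cold") -1 else 0)
  aligned <- names(axisSign)[axisSign == sigOri]
  survAxes <- paste0("surv_", .SURV_ENDPOINTS)[
    vapply(.SURV_ENDPOINTS, function(e) isTRUE(sig[[paste0(e, "_significant")]]),
           logical(1))]
  survAligned <- paste0("surv_", .SURV_ENDPOINTS)[
    sigDirs == sigOri & sigOri != 0]
  flips <- stats::setNames(stats::runif(length(weakAxes)) < es$flipWeak,
                           weakAxes)
  nSurv <- min(es$survFlips, length(survAxes))
  survPool <- c(intersect(survAligned, survAxes),
                setdiff(survAxes, survAligned))
  survFlipped <- utils::head(survPool, nSurv)
  flips <- c(flips, stats::setNames(survAxes %in% survFlipped, survAxes))
  deficit <- es$minFlips - sum(flips)
  if (deficit > 0) {
    # force additional flips among unflipped weak axes first: aligned axes
    # before unaligned, solid signed quanta (tumor-normal, immune) before
    # the weakly loading correlation sign
    wpool <- weakAxes[!flips[weakAxes]]
    wpool <- wpool[order(!wpool %in% aligned,
                         match(wpool, c("tn", "rho", "micro", "immune")))]
    spool <- survPool[!flips[survPool]]
    nw <- min(deficit, length(wpool))
    force_ <- c(utils::head(wpool, nw), utils::head(spool, deficit - nw))
    flips[force_] <- TRUE
  }
  flipped <- function(a) a %in% names(flips) && isTRUE(flips[[a]])

  int <- sig
  s <- if (flipped("rho")) -1 else 1
  int$rho <- max(min(s * sig$rho * exp(stats::rnorm(1, 0, es$strengthJitter)),
                     0.95), -0.95)
  int$rho_adj_p <- u2p(jitterU(p2u(sig$rho_adj_p)))
  if (flipped("tn"))
    int$tn_direction <- setdiff(c("up", "down"), sig$tn_direction)
  int$tn_wilcoxon_p <- u2p(jitterU(p2u(sig$tn_wilcoxon_p)))
  for (e in .SURV_ENDPOINTS) {
    sg <- sig[[paste0(e, "_significant")]]
    if (stats::runif(1) < es$survResampleProb)
      sg <- stats::runif(1) < intSurvRate
    if (sg) {
      dir <- sig[[paste0(e, "_direction")]]
      if (dir == "ns") {
        dir <- if (oppose) {
          if (sigOri > 0) "protective" else "risk"
        } else sample(c("risk", "protective"), 1)
      } else if (flipped(paste0("surv_", e)))
        dir <- setdiff(c("risk", "protective"), dir)
      u <- if (isTRUE(es$freshStrengths)) {
        # strengths independent of the signature side: matched pairs are
        # then more opposed than randomly re-paired sides, so extreme
        # discordance is enriched relative to the permutation null
        1.30103 + stats::rgamma(1, shape = spec$depth[["shape"]],
                                rate = spec$depth[["rate"]]) *
          exp(stats::rnorm(1, 0, es$strengthJitter)) +
          stats::runif(1, 0, es$strengthShift)
      } else jitterU(max(p2u(sig[[paste0(e, "_p")]]), 1.30103))
      p <- u2p(max(u, 1.30104))
      int[[paste0(e, "_direction")]] <- dir
      int[[paste0(e, "_p")]] <- p
    } else {
      int[[paste0(e, "_direction")]] <- "ns"
      p <- stats::runif(1, 0.05, 1)
      int[[paste0(e, "_p")]] <- p
    }
    int[[paste0(e, "_chi2")]] <- stats::qchisq(p, 1, lower.tail = FALSE)
    int[[paste0(e, "_significant")]] <- sg
  }
  s <- if (flipped("micro")) -1 else 1
  int$micro_score <- s * sig$micro_score +
    stats::rnorm(1, 0, max(es$strengthJitter, 0.02))
  if (flipped("immune")) {
    int$immune_class <- switch(sig$immune_class,
                               hot = "cold", cold = "hot",
                               excluded = "intermediate",
                               intermediate = "excluded")
  }
  int
}

.sideToColumns <- function(side, prefix) {
  stats::setNames(side, paste0(prefix, "_", names(side)))
}

#' Simulate a circuitry atlas with controllable concordance structure
#'
#' Draws, per circuitry, a signature-side annotation block from a marginal
#' model (signed directions, gamma-like positive strengths, chi-square
#' statistics consistent with the endpoint p-values, standard-normal
#' microenvironment score, categorical immune class) and derives the
#' interaction side from it according to the circuitry's mixture component:
#' concordant circuitries keep the signature's sign structure with small
#' jitter, while increasingly discordant components flip more signed axes
#' and perturb strengths more strongly. The generating component of each
#' circuitry is returned separately as ground truth.
#'
#' @param spec a [simulationSpec()].
#' @return list with `table` (a [CircuitryTable-class]) and `truth`
#'   (data.frame with `id` and `component`).
#' @examples
#' atlas <- simulateAtlas(simulationSpec(nCircuitries = 10, seed = 42))
#' table(atlas$truth$component)
#' @export
simulateAtlas <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  n <- spec$nCircuitries
  strataIdx <- sample.int(spec$nStrata, n, replace = TRUE)
  strata <- paste0("CT", sprintf("%02d", strataIdx))
  profiles <- lapply(seq_len(spec$nStrata),
                     function(s) .drawStratumProfile(spec))
  comp <- sample(.MIXTURE_COMPONENTS, n, replace = TRUE, prob = spec$mixture)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sig <- .drawSide(spec, profiles[[strataIdx[i]]])
    int <- .deriveIntSide(sig, spec$effectScales[[comp[i]]], spec)
    rows[[i]] <- c(list(id = sprintf("SIM-%05d", i),
                        cancer_type = strata[i],
                        superfamily = sample(c("Amino acid", "Carbohydrate",
                                               "Lipid", "Nucleotide",
                                               "Energy", "Cofactors"), 1),
                        pathway = sprintf("pathway_%02d", sample.int(20, 1)),
                        phenotype_layer = sample(c("stemness", "EMT",
                                                   "proliferation"), 1),
                        omic_layer_sig = sample(c("miRNA", "mRNA", "CpG",
                                                  "CNV"), 1),
                        omic_layer_int = sample(c("miRNA", "mRNA", "CpG",
                                                  "CNV"), 1)),
                   .sideToColumns(sig, "sig"),
                   .sideToColumns(int, "int"))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  tab <- CircuitryTable(df, dialect = "generic")
  methods::validObject(tab)
  list(table = tab,
       truth = data.frame(id = df$id, component = comp,
                          stringsAsFactors = FALSE))
}

#' Simulate an atlas under the null of random pairing
#'
#' Both sides are drawn independently from the marginal signature-side
#' model, within the same stratum structure, so the sig-int pairing carries
#' no signal; no ground-truth component labels exist by construction.
#'
#' @param spec a [simulationSpec()]; the mixture is ignored.
#' @return a [CircuitryTable-class].
#' @export
simulateNullAtlas <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  n <- spec$nCircuitries
  strataIdx <- sample.int(spec$nStrata, n, replace = TRUE)
  strata <- paste0("CT", sprintf("%02d", strataIdx))
  profiles <- lapply(seq_len(spec$nStrata),
                     function(s) .drawStratumProfile(spec))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- c(list(id = sprintf("NULL-%05d", i),
                        cancer_type = strata[i]),
                   .sideToColumns(.drawSide(spec, profiles[[strataIdx[i]]]),
                                  "sig"),
                   .sideToColumns(.drawSide(spec, profiles[[strataIdx[i]]]),
                                  "int"))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  tab <- CircuitryTable(df, dialect = "generic")
  methods::validObject(tab)
  tab
}
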