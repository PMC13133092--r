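# Programmatic fixtures shared across the suite.

# One fully annotated side as a named list of canonical column values.
# Every field can be overridden; defaults are a "risk-oriented" profile.
makeSide <- function(rho = 0.4, rho_adj_p = 0.01,
                     tn_direction = "up", tn_wilcoxon_p = 0.001,
                     os = list("risk", 0.001, 10.8, TRUE),
                     dss = list("ns", 0.8, 0.06, FALSE),
                     dfi = list("ns", 0.9, 0.02, FALSE),
                     pfi = list("risk", 0.01, 6.6, TRUE),
                     micro_score = 1.2, immune_class = "hot") {
  out <- list(rho = rho, rho_adj_p = rho_adj_p,
              tn_direction = tn_direction, tn_wilcoxon_p = tn_wilcoxon_p)
  for (e in c("os", "dss", "dfi", "pfi")) {
    b <- get(e)
    out[[paste0(e, "_direction")]] <- b[[1]]
    out[[paste0(e, "_p")]] <- b[[2]]
    out[[paste0(e, "_chi2")]] <- b[[3]]
    out[[paste0(e, "_significant")]] <- b[[4]]
  }
  out$micro_score <- micro_score
  out$immune_class <- immune_class
  out
}

# flip every signed annotation of a side (used to build maximally opposed
# circuitries)
opposeSide <- function(side) {
  flipDir <- function(x, a, b) if (x == a) b else if (x == b) a else x
  side$rho <- -side$rho
  side$tn_direction <- flipDir(side$tn_direction, "up", "down")
  for (e in c("os", "dss", "dfi", "pfi")) {
    d <- paste0(e, "_direction")
    side[[d]] <- flipDir(side[[d]], "risk", "protective")
  }
  side$micro_score <- -side$micro_score
  side$immune_class <- flipDir(side$immune_class, "hot", "cold")
  side
}

# Build a canonical data.frame for a list of (sig, int) side pairs.
makeTableDF <- function(pairs, cancer_type = NULL) {
  n <- length(pairs)
  if (is.null(cancer_type)) cancer_type <- rep("BRCA", n)
  rows <- lapply(seq_len(n), function(i) {
    sig <- pairs[[i]]$sig
    int <- pairs[[i]]$int
    c(list(id = sprintf("CIRC-%03d", i), cancer_type = cancer_type[i]),
      stats::setNames(sig, paste0("sig_", names(sig))),
      stats::setNames(int, paste0("int_", names(int))))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

makeCircuitryTable <- function(pairs, cancer_type = NULL) {
  CircuitryTable(makeTableDF(pairs, cancer_type))
}

# A small mixed table: identical pair, mildly jittered pair, opposed pair,
# plus noise pairs so that standardization/PCA are well conditioned.
makeMixedTable <- function(nNoise = 9, seed = 404) {
  set.seed(seed)
  noise <- lapply(seq_len(nNoise), function(i) {
    s <- makeSide(rho = round(runif(1, -0.6, 0.6), 3),
                  rho_adj_p = 10^-runif(1, 0.2, 4),
                  tn_direction = sample(c("up", "down", "ns"), 1),
                  tn_wilcoxon_p = 10^-runif(1, 0.2, 4),
                  os = list(sample(c("risk", "protective"), 1),
                            10^-runif(1, 1.5, 4), runif(1, 4, 20), TRUE),
                  micro_score = rnorm(1),
                  immune_class = sample(c("hot", "cold", "excluded",
                                          "intermediate"), 1))
    i2 <- makeSide(rho = round(runif(1, -0.6, 0.6), 3),
                   micro_score = rnorm(1),
                   immune_class = sample(c("hot", "cold"), 1))
    list(sig = s, int = i2)
  })
  s0 <- makeSide()
  jit <- makeSide(rho = 0.38, micro_score = 1.1)
  pairs <- c(list(list(sig = s0, int = s0),
                  list(sig = s0, int = jit),
                  list(sig = s0, int = opposeSide(s0))),
             noise)
  makeCircuitryTable(pairs,
                     cancer_type = rep(c("BRCA", "LGG"),
                                       length.out = length(pairs)))
}

# Minimal OFF parser for mesh round-trip checks.
readOFF <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  nv <- counts[1]; nf <- counts[2]
  verts <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  faces <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l)
    as.integer(strsplit(l, " ")[[1]])[-1] + 1L))
  list(vertices = verts, faces = faces)
}

# Monte-Carlo volume of the convex hull of a 3-D point cloud by rejection
# sampling in the bounding box (independent oracle for hull volumes).
# Membership test: a point is inside the hull iff it is on the inner side of
# every outward-oriented facet plane.
mcHullVolume <- function(pts, facets, nSamples = 20000) {
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  samp <- cbind(runif(nSamples, lo[1], hi[1]),
                runif(nSamples, lo[2], hi[2]),
                runif(nSamples, lo[3], hi[3]))
  a <- pts[facets[, 1], , drop = FALSE]
  b <- pts[facets[, 2], , drop = FALSE]
  cc <- pts[facets[, 3], , drop = FALSE]
  ab <- b - a; ac <- cc - a
  nrm <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  inside <- rep(TRUE, nSamples)
  for (f in seq_len(nrow(nrm))) {
    d <- (samp[, 1] - a[f, 1]) * nrm[f, 1] +
         (samp[, 2] - a[f, 2]) * nrm[f, 2] +
         (samp[, 3] - a[f, 3]) * nrm[f, 3]
    inside <- inside & d <= 1e-12
  }
  phat <- mean(inside)
  boxVol <- prod(hi - lo)
  list(volume = phat * boxVol,
       se = boxVol * sqrt(phat * (1 - phat) / nSamples))
}
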