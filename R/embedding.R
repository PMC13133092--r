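#' @include AllClasses.R
NULL

#' Globally center and scale the latent tensor
#'
#' Subtracts the column mean and divides by the sample standard deviation
#' (denominator n - 1) of each latent dimension, pooled over all rows of the
#' joint tensor. Zero-variance columns are centered and divided by a scale of
#' 1, so a constant column becomes all zeros and contributes no variance
#' while avoiding divide-by-zero degeneracies.
#'
#' @param tensor numeric matrix (rows = side vectors, columns = latent
#'   dimensions), at least 2 rows.
#' @param scale logical; `FALSE` gives the centering-only variant used for
#'   the no-scaling robustness check.
#' @return list with `x` (standardized matrix), `means`, `scales`.
#' @examples
#' standardizeTensor(rbind(c(0, 5), c(2, 5)))
#' @export
standardizeTensor <- function(tensor, scale = TRUE) {
  x <- as.matrix(tensor)
  if (nrow(x) < 2)
    stop("insufficient data: standardization needs at least 2 rows",
         call. = FALSE)
  if (any(!is.finite(x)))
    stop("numeric error: non-finite entries in latent tensor", call. = FALSE)
  mu <- colMeans(x)
  if (scale) {
    sd_ <- apply(x, 2, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  } else {
    sd_ <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  list(x = xs, means = mu, scales = sd_)
}

#' Fit the joint PCA embedding
#'
#' Computes the full eigendecomposition of the covariance of the standardized
#' tensor, retaining all components. Loadings carry a deterministic sign
#' convention (the largest-magnitude entry of each column is made positive),
#' so repeated fits on identical input are bit-stable.
#'
#' @param standardized output of [standardizeTensor()], or a pre-standardized
#'   matrix.
#' @param nComponentsDefault default projection dimension recorded on the
#'   model (3).
#' @return an [EmbeddingModel-class].
#' @examples
#' tab <- simulateAtlas(simulationSpec(nCircuitries = 20, seed = 1))$table
#' x <- buildLatentTensor(tab)
#' fitEmbedding(standardizeTensor(x))
#' @export
fitEmbedding <- function(standardized, nComponentsDefault = 3L) {
  if (is.matrix(standardized))
    standardized <- c(list(x = standardized),
                      list(means = rep(0, ncol(standardized)),
                           scales = rep(1, ncol(standardized)),
                           scaled = TRUE))
  xs <- standardized$x
  if (any(!is.finite(xs)))
    stop("numeric error: non-finite entries", call. = FALSE)
  n <- nrow(xs)
  cv <- crossprod(xs) / (n - 1)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  load <- eig$vectors
  # pin the arbitrary eigenvector signs
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(xs), paste0("PC", seq_len(ncol(load))))
  methods::new("EmbeddingModel",
               means = as.numeric(standardized$means),
               scales = as.numeric(standardized$scales),
               loadings = load,
               eigenvalues = ev,
               nComponentsDefault = as.integer(nComponentsDefault),
               scaled = !all(standardized$scales == 1))
}

#' Project latent vectors into the embedding
#'
#' Applies the model's standardization `(x - means) / scales` followed by the
#' loading rotation, returning the leading `nComponents` coordinates.
#' Projection is linear, so the projection of a mean equals the mean of the
#' projections (barycenter/projection commutation).
#'
#' @param model an [EmbeddingModel-class].
#' @param vectors numeric matrix (k x 18) or a single vector on the original
#'   latent scale.
#' @param nComponents number of leading components to return (default: the
#'   model default).
#' @return k x nComponents score matrix.
#' @export
projectLatent <- function(model, vectors, nComponents = NULL) {
  stopifnot(methods::is(model, "EmbeddingModel"))
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  p <- length(model@means)
  if (ncol(vectors) != p)
    stop("shape error: expected ", p, " columns, got ", ncol(vectors),
         call. = FALSE)
  k <- if (is.null(nComponents)) model@nComponentsDefault else as.integer(nComponents)
  if (k < 1 || k > p) stop("shape error: nComponents out of range", call. = FALSE)
  xs <- sweep(sweep(as.matrix(vectors), 2, model@means), 2, model@scales, "/")
  xs %*% model@loadings[, seq_len(k), drop = FALSE]
}

#' Serialize / restore an embedding model as JSON
#'
#' Freezing the fitted coordinate system allows an embedding to be re-applied
#' to new circuitries without refitting.
#'
#' @param model an [EmbeddingModel-class].
#' @param path JSON file path.
#' @return `writeEmbeddingModel` invisibly returns `path`;
#'   `readEmbeddingModel` returns the restored model.
#' @export
writeEmbeddingModel <- function(model, path) {
  stopifnot(methods::is(model, "EmbeddingModel"))
  obj <- list(coordinates = colnames(model@loadings) %||% NULL,
              names = rownames(model@loadings),
              means = model@means, scales = model@scales,
              loadings = model@loadings, eigenvalues = model@eigenvalues,
              nComponentsDefault = model@nComponentsDefault,
              scaled = model@scaled)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname writeEmbeddingModel
#' @export
readEmbeddingModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- as.matrix(obj$loadings)
  dimnames(load) <- list(obj$names, paste0("PC", seq_len(ncol(load))))
  methods::new("EmbeddingModel",
               means = as.numeric(obj$means), scales = as.numeric(obj$scales),
               loadings = load, eigenvalues = as.numeric(obj$eigenvalues),
               nComponentsDefault = as.integer(obj$nComponentsDefault),
               scaled = isTRUE(obj$scaled))
}
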