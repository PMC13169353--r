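#' Principal component analysis of contact coordinates
#'
#' Diagonalizes the sample covariance matrix (1/(N-1) normalization) of the
#' mean-centered binary contact matrix `X`. Loadings are the orthonormal
#' eigenvectors ordered by decreasing eigenvalue; each loading's sign is fixed
#' so its largest-magnitude coefficient is positive. Constant (zero-variance)
#' columns are allowed and contribute zero-eigenvalue directions.
#'
#' @param ct a `ContactTrajectory`.
#' @return object of class `PCABasis`: list with `mean_vector`, `loadings`
#'   (D x D matrix, one loading per column), `eigenvalues` (non-increasing,
#'   clipped at 0), `D`, `n_frames_fit`, plus `pair_index` and `n_residues`
#'   carried through for contact-space back-mapping.
#' @export
fit_contact_pca <- function(ct) {
  X <- ct$X
  if (nrow(X) < 2) stop("need at least 2 frames to fit a PCA")
  mu <- colMeans(X)
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    pivot <- which.max(abs(V[, k]))
    if (V[pivot, k] < 0) V[, k] <- -V[, k]
  }
  out <- list(mean_vector = mu, loadings = V, eigenvalues = lambda,
              D = ncol(X), n_frames_fit = nrow(X),
              pair_index = ct$pair_index, n_residues = ct$n_residues)
  class(out) <- "PCABasis"
  out
}

#' @export
print.PCABasis <- function(x, ...) {
  cat(sprintf("PCABasis: D = %d contacts, fit on %d frames; top eigenvalues: %s\n",
              x$D, x$n_frames_fit,
              paste(sprintf("%.3g", utils::head(x$eigenvalues, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Project contact frames onto principal components
#'
#' PC score of frame f on component i is the dot product of the mean-centered
#' contact vector with loading i.
#'
#' @param ct a `ContactTrajectory` with the same contact dimension as `basis`.
#' @param basis a `PCABasis`.
#' @param k number of components to keep (default all).
#' @return object of class `ScoreMatrix`: list with `scores`
#'   (frames x k), `k`, and the frame `labels` carried from `ct`.
#' @export
project_onto_pcs <- function(ct, basis, k = basis$D) {
  if (ncol(ct$X) != basis$D)
    stop("contact dimension mismatch: trajectory has ", ncol(ct$X),
         ", basis has ", basis$D)
  stopifnot(k >= 1, k <= basis$D)
  scores <- sweep(ct$X, 2, basis$mean_vector) %*% basis$loadings[, seq_len(k),
                                                                 drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- list(scores = scores, k = k, labels = ct$labels,
              frame_ids = ct$frame_ids)
  class(out) <- "ScoreMatrix"
  out
}

#' Fraction of total variance captured by the top k components
#'
#' @param basis a `PCABasis`.
#' @param k number of leading components.
#' @return fraction in \code{[0, 1]}.
#' @export
variance_explained <- function(basis, k) {
  stopifnot(k >= 1, k <= basis$D)
  tot <- sum(basis$eigenvalues)
  if (tot <= 0) stop("degenerate ensemble: total contact variance is zero")
  sum(basis$eigenvalues[seq_len(k)]) / tot
}

#' Loading scaled by its fluctuation amplitude
#'
#' Returns loading i multiplied by its eigenvalue (`"lambda"`, the default
#' convention here), by the eigenvalue's square root (`"sqrt-lambda"`, the
#' standard-deviation convention), or unscaled.
#'
#' @param basis a `PCABasis`.
#' @param i component index.
#' @param scale scaling convention.
#' @return length-D numeric vector.
#' @export
scaled_loading <- function(basis, i, scale = c("lambda", "sqrt-lambda", "none")) {
  scale <- match.arg(scale)
  stopifnot(i >= 1, i <= basis$D)
  fac <- switch(scale, lambda = basis$eigenvalues[i],
                `sqrt-lambda` = sqrt(basis$eigenvalues[i]), none = 1)
  basis$loadings[, i] * fac
}

#' Render a contact-space vector as a signed symmetric contact map
#'
#' Entry (i, j) = (j, i) of the map holds the vector coefficient of dynamic
#' pair (i, j); all non-dynamic pairs are zero. Negative entries correspond to
#' breaking of contacts and positive entries to formation of contacts along
#' the mode.
#'
#' @param vec numeric vector, one coefficient per dynamic pair.
#' @param pair_index data.frame with columns `i`, `j`.
#' @param n_residues matrix dimension.
#' @param source label describing the mode (e.g. `"PC1"`, `"LD1_salt"`).
#' @return object of class `ContactDisplacementMap`: list with `matrix`,
#'   `n_residues`, `source`.
#' @export
loading_to_contact_map <- function(vec, pair_index, n_residues,
                                   source = "loading") {
  if (length(vec) != nrow(pair_index))
    stop("vector length (", length(vec), ") does not match pair count (",
         nrow(pair_index), ")")
  m <- matrix(0, n_residues, n_residues)
  m[cbind(pair_index$i, pair_index$j)] <- vec
  m[cbind(pair_index$j, pair_index$i)] <- vec
  out <- list(matrix = m, n_residues = n_residues, source = source)
  class(out) <- "ContactDisplacementMap"
  out
}

#' Extract the contact-space vector of a contact map
#'
#' Inverse of [loading_to_contact_map()] over the same pair index.
#'
#' @param map a `ContactDisplacementMap` or plain symmetric matrix.
#' @param pair_index data.frame with columns `i`, `j`.
#' @return numeric vector of per-pair coefficients.
#' @export
contact_map_to_vector <- function(map, pair_index) {
  m <- if (inherits(map, "ContactDisplacementMap")) map$matrix else map
  m[cbind(pair_index$i, pair_index$j)]
}
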