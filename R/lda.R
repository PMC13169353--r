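#' Fisher linear discriminant analysis of PC scores
#'
#' Fits the Fisher discriminant directions that maximize between-class over
#' within-class scatter of truncated PC scores, as a coordinate transform
#' (no classifier, priors or posteriors). Each discriminant LD_l is a linear
#' combination of PC scores, `LD_l = sum_j PC_j * C[l, j]`; rows of `C` are
#' unit length and the sign of each row is fixed so the first-listed class
#' has the lower mean score (so the first class sits to the left on LD1).
#'
#' When the within-class scatter matrix is numerically singular, a ridge of
#' `1e-6 * trace(S_w) / k` is added to its diagonal with a warning.
#'
#' @param scores a `ScoreMatrix` (frames x k PC scores).
#' @param labels per-frame class labels for one condition: factor or
#'   character vector (class order = factor levels, or order of first
#'   appearance for characters); every class needs >= 2 frames.
#' @param n_discriminants number of discriminants to keep; defaults to (and
#'   cannot exceed) `min(n_classes - 1, k)`.
#' @param condition name of the labelled condition (e.g. `"salt"`),
#'   recorded in the model.
#' @return object of class `LDAModel`: list with `C`
#'   (n_discriminants x k coefficient matrix), `eigenvalues` (discriminative
#'   ratios), `classes`, `class_means_on_LD` (class x discriminant),
#'   `condition`, `k`.
#' @export
fit_lda <- function(scores, labels, n_discriminants = NULL,
                    condition = "condition") {
  X <- scores$scores
  k <- ncol(X)
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  labels <- droplevels(labels)
  if (length(labels) != nrow(X))
    stop("one label per frame required (", nrow(X), " frames, ",
         length(labels), " labels)")
  classes <- levels(labels)
  g <- length(classes)
  if (g < 2) stop("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2)) stop("every class needs at least 2 frames")
  if (g > k + 1)
    stop("more classes (", g, ") than PC dimensions + 1 (", k + 1,
         "); increase the number of retained PCs")
  mu <- colMeans(X)
  Sw <- matrix(0, k, k)
  Sb <- matrix(0, k, k)
  for (cl in classes) {
    Xc <- X[labels == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    dc <- sweep(Xc, 2, mc)
    Sw <- Sw + crossprod(dc)
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - mu)
  }
  if (rcond(Sw) < 1e-12) {
    eps <- 1e-6 * sum(diag(Sw)) / k
    warning("within-class scatter numerically singular; ",
            "adding ridge epsilon = ", format(eps))
    Sw <- Sw + diag(eps, k)
  }
  # generalized symmetric eigenproblem Sb c = rho Sw c via Cholesky whitening
  R <- chol(Sw)
  Ri <- backsolve(R, diag(k))
  K <- crossprod(Ri, Sb %*% Ri)
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  m <- n_discriminants %||% min(g - 1, k)
  if (m > min(g - 1, k))
    stop("n_discriminants cannot exceed min(n_classes - 1, k) = ",
         min(g - 1, k))
  C <- t(Ri %*% e$vectors[, seq_len(m), drop = FALSE])
  C <- C / sqrt(rowSums(C^2))
  # sign convention: first-listed class lower than the remaining classes
  ld_means <- function(C) {
    L <- X %*% t(C)
    t(vapply(classes, function(cl) colMeans(L[labels == cl, , drop = FALSE]),
             numeric(m)))
  }
  cm <- ld_means(C)
  if (m == 1) cm <- matrix(cm, nrow = g)
  for (l in seq_len(m))
    if (cm[1, l] > mean(cm[-1, l])) {
      C[l, ] <- -C[l, ]
      cm[, l] <- -cm[, l]
    }
  dimnames(cm) <- list(classes, paste0("LD", seq_len(m)))
  rownames(C) <- paste0("LD", seq_len(m))
  colnames(C) <- paste0("PC", seq_len(k))
  out <- list(C = C, eigenvalues = pmax(e$values[seq_len(m)], 0),
              classes = classes, class_means_on_LD = cm,
              condition = condition, k = k, n_discriminants = m)
  class(out) <- "LDAModel"
  out
}

#' @export
print.LDAModel <- function(x, ...) {
  cat(sprintf("LDAModel (%s): %d discriminant(s) over %d PCs; classes: %s\n",
              x$condition, x$n_discriminants, x$k,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Discriminant scores of frames
#'
#' `LD[f, l] = sum_j scores[f, j] * C[l, j]`.
#'
#' @param model an `LDAModel`.
#' @param scores a `ScoreMatrix` with the same PC dimension the model was
#'   fit on.
#' @return frames x n_discriminants numeric matrix.
#' @export
lda_scores <- function(model, scores) {
  X <- scores$scores
  if (ncol(X) != model$k)
    stop("PC dimension mismatch: scores have ", ncol(X), ", model expects ",
         model$k)
  L <- X %*% t(model$C)
  colnames(L) <- rownames(model$C)
  L
}

#' Back-map a discriminant loading to contact space
#'
#' The contact-space vector of discriminant l is the coefficient-weighted sum
#' of PC loadings, `sum_k C[l, k] * d^(k)`, rendered as a signed symmetric
#' contact displacement map (negative = breaking, positive = forming
#' contacts as the score increases).
#'
#' @param model an `LDAModel`.
#' @param basis the `PCABasis` the scores came from; must supply at least
#'   `model$k` loadings.
#' @param l discriminant index.
#' @return a `ContactDisplacementMap`.
#' @export
ld_loading_in_contact_space <- function(model, basis, l = 1) {
  stopifnot(l >= 1, l <= model$n_discriminants)
  if (basis$D < model$k)
    stop("basis supplies ", basis$D, " loadings but model uses ", model$k)
  v <- basis$loadings[, seq_len(model$k), drop = FALSE] %*% model$C[l, ]
  loading_to_contact_map(as.numeric(v), basis$pair_index, basis$n_residues,
                         source = sprintf("LD%d_%s", l, model$condition))
}

#' Per-class Gaussian-kernel score densities on a shared grid
#'
#' Kernel density estimate of one discriminant's scores for each class, using
#' a common bandwidth (Silverman's rule on the pooled scores) and a common
#' grid spanning the pooled range plus three bandwidths. Each class's density
#' is renormalized to integrate to exactly 1 over the grid (trapezoid rule).
#'
#' @param ld numeric vector of scores for one discriminant.
#' @param labels per-frame class labels (>= 2 frames per class).
#' @param n_grid grid resolution (default 512).
#' @param bw bandwidth override; default Silverman on pooled scores.
#' @return object of class `DensityEstimate`: list with `grid`, `density`
#'   (class x grid matrix), `bw`, `classes`.
#' @export
class_score_density <- function(ld, labels, n_grid = 512, bw = NULL) {
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  labels <- droplevels(labels)
  if (any(table(labels) < 2)) stop("every class needs at least 2 frames")
  bw <- bw %||% stats::bw.nrd0(ld)
  if (bw <= 0) stop("degenerate scores: zero bandwidth")
  grid <- seq(min(ld) - 3 * bw, max(ld) + 3 * bw, length.out = n_grid)
  dens <- matrix(0, nlevels(labels), n_grid,
                 dimnames = list(levels(labels), NULL))
  for (cl in levels(labels)) {
    x <- ld[labels == cl]
    if (stats::sd(x) == 0)
      warning("class '", cl, "' has zero score variance (degenerate spike)")
    d <- stats::density(x, bw = bw, from = grid[1], to = grid[n_grid],
                        n = n_grid)
    y <- d$y / trapz(grid, d$y)
    dens[cl, ] <- y
  }
  out <- list(grid = grid, density = dens, bw = bw, classes = levels(labels))
  class(out) <- "DensityEstimate"
  out
}

#' Overlap coefficient between two class densities
#'
#' Trapezoid-rule integral of the pointwise minimum of two densities sharing
#' one grid: 1 for identical distributions, 0 for disjoint supports.
#'
#' @param dens a `DensityEstimate`, or a numeric density vector (then `b` and
#'   `grid` must be given).
#' @param a,b class names or indices into `dens`, or (when `dens` is a
#'   vector) `a` is ignored and `b` is the second density vector.
#' @param grid shared grid when passing raw vectors.
#' @return overlap coefficient in \code{[0, 1]}.
#' @export
overlap_coefficient <- function(dens, a = 1, b = 2, grid = NULL) {
  if (inherits(dens, "DensityEstimate")) {
    fa <- dens$density[a, ]
    fb <- dens$density[b, ]
    grid <- dens$grid
  } else {
    fa <- dens
    fb <- b
    if (is.null(grid)) stop("grid required when passing raw density vectors")
    if (length(fa) != length(fb) || length(fa) != length(grid))
      stop("densities and grid must share one length")
  }
  trapz(grid, pmin(fa, fb))
}
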