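score_matrix <- function(X, labels = NULL) {
  out <- list(scores = as.matrix(X), k = ncol(X), labels = labels)
  class(out) <- "ScoreMatrix"
  out
}

test_that("two separated 1-D clouds give the axis discriminant", {
  set.seed(41)
  x <- c(rnorm(50, -1, 0.2), rnorm(50, 1, 0.2))
  lab <- rep(c("low", "high"), each = 50)
  m <- fit_lda(score_matrix(cbind(x)), lab, condition = "salt")
  expect_equal(abs(m$C[1, 1]), 1)
  L <- lda_scores(m, score_matrix(cbind(x)))
  # sign convention: first-listed class ("low") has the lower mean score
  expect_lt(mean(L[lab == "low", 1]), mean(L[lab == "high", 1]))
})

test_that("a shift planted on PC3 dominates the discriminant coefficients", {
  set.seed(42)
  n <- 400
  X <- matrix(rnorm(n * 8), n, 8)
  lab <- rep(c("a", "b"), each = n / 2)
  X[lab == "b", 3] <- X[lab == "b", 3] + 4
  m <- fit_lda(score_matrix(X), lab)
  expect_equal(unname(which.max(abs(m$C[1, ]))), 3L)
  expect_gt(abs(m$C[1, 3]), 0.9)
})

test_that("LDA directions agree with MASS::lda up to scale and sign", {
  skip_if_not_installed("MASS")
  set.seed(43)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4) %*% matrix(rnorm(16), 4, 4)
  lab <- rep(c("a", "b"), each = n / 2)
  X[lab == "b", ] <- X[lab == "b", ] + rep(c(1, 2, 0, -1), each = n / 2)
  ours <- fit_lda(score_matrix(X), lab)
  ref <- MASS::lda(X, grouping = lab)$scaling[, 1]
  ref <- ref / sqrt(sum(ref^2))
  cosine <- abs(sum(ours$C[1, ] * ref))
  expect_gt(cosine, 1 - 1e-6)
})

test_that("discriminant count follows the class count", {
  set.seed(44)
  X <- matrix(rnorm(300 * 8), 300, 8)
  lab <- rep(c("b1", "b2", "pip2"), each = 100)
  X[lab == "b2", 1] <- X[lab == "b2", 1] + 3
  X[lab == "pip2", 2] <- X[lab == "pip2", 2] + 3
  m <- fit_lda(score_matrix(X), lab, condition = "membrane")
  expect_equal(m$n_discriminants, 2L)
  expect_error(fit_lda(score_matrix(X), lab, n_discriminants = 3), "exceed")
  # more classes than dimensions + 1 is an error
  expect_error(fit_lda(score_matrix(X[, 1, drop = FALSE]),
                       rep(c("a", "b", "c"), each = 100)), "classes")
})

test_that("lda_scores is the stated linear transform", {
  set.seed(45)
  X <- matrix(rnorm(100 * 3), 100, 3)
  lab <- rep(c("a", "b"), each = 50)
  X[lab == "b", 1] <- X[lab == "b", 1] + 3
  m <- fit_lda(score_matrix(X), lab)
  L <- lda_scores(m, score_matrix(X))
  expect_equal(L, X %*% t(m$C), ignore_attr = TRUE)
  # zero score row maps to zero
  expect_equal(as.numeric(lda_scores(m, score_matrix(matrix(0, 1, 3)))), 0)
  # identity coefficients reproduce PC scores
  m2 <- m
  m2$C <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(as.numeric(lda_scores(m2, score_matrix(X))), X[, 1])
  expect_error(lda_scores(m, score_matrix(X[, 1:2])), "mismatch")
})

test_that("singular within-class scatter is ridge-regularized with a warning", {
  set.seed(46)
  x <- rnorm(100)
  X <- cbind(x, x)  # perfectly collinear -> singular S_w
  lab <- rep(c("a", "b"), each = 50)
  X[lab == "b", ] <- X[lab == "b", ] + 2
  expect_warning(m <- fit_lda(score_matrix(X), lab), "ridge")
  expect_true(all(is.finite(m$C)))
})

test_that("LD loadings back-map to contact space consistently", {
  spec <- redox_spec(n_frames = 400, seed = 47)
  g <- generate_switching_ensemble(spec)
  cp <- contact_pipeline(g$trajectory)
  b <- fit_contact_pca(cp$ct)
  k <- min(8, b$D)
  sc <- project_onto_pcs(cp$ct, b, k)
  m <- fit_lda(sc, g$labeling$redox, condition = "redox")
  # unit coefficient on PC1 reproduces PC1's own map
  m1 <- m
  m1$C <- matrix(c(1, rep(0, k - 1)), 1, k)
  map1 <- ld_loading_in_contact_space(m1, b, 1)
  expect_equal(contact_map_to_vector(map1, b$pair_index),
               b$loadings[, 1], ignore_attr = TRUE)
  # orthonormal loadings: coefficient vector (0.6, 0.8) gives unit map norm
  m2 <- m
  m2$C <- matrix(c(0.6, 0.8, rep(0, k - 2)), 1, k)
  v <- contact_map_to_vector(ld_loading_in_contact_space(m2, b, 1),
                             b$pair_index)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-8)
  # real model: map mass concentrates on the planted contact set
  map <- ld_loading_in_contact_space(m, b, 1)
  vals <- contact_map_to_vector(map, cp$pair_index)
  cols <- planted_pair_cols(cp, g$truth$planted_pairs)
  expect_gt(sum(vals[cols]^2) / sum(vals^2), 0.9)
  # breaking-contacts convention: wt listed first sits lower on LD1, and
  # the planted contacts (present in wt, lost in analog) share one sign
  expect_equal(length(unique(sign(vals[cols]))), 1)
})

test_that("class densities integrate to one and respect known overlaps", {
  set.seed(48)
  x <- c(rnorm(4000, 0, 1), rnorm(4000, 10, 1))
  lab <- rep(c("a", "b"), each = 4000)
  d <- class_score_density(x, lab)
  for (cl in 1:2) {
    integ <- sum(diff(d$grid) * (head(d$density[cl, ], -1) +
                                   tail(d$density[cl, ], -1)) / 2)
    expect_equal(integ, 1, tolerance = 1e-6)
  }
  expect_lt(overlap_coefficient(d), 0.01)
  # identical classes overlap completely
  d2 <- class_score_density(c(x[1:1000], x[1:1000]),
                            rep(c("a", "b"), each = 1000))
  expect_equal(overlap_coefficient(d2), 1, tolerance = 1e-6)
  # Gaussian closed form: N(0,1) vs N(2,1) -> 2*pnorm(-1)
  y <- c(rnorm(20000, 0, 1), rnorm(20000, 2, 1))
  d3 <- class_score_density(y, rep(c("a", "b"), each = 20000))
  expect_lt(abs(overlap_coefficient(d3) - 2 * pnorm(-1)), 0.01)
})

test_that("uninformative extra PCs barely change the class separation", {
  set.seed(49)
  spec <- redox_spec(n_frames = 800, seed = 49)
  g <- generate_switching_ensemble(spec)
  cp <- contact_pipeline(g$trajectory)
  b <- fit_contact_pca(cp$ct)
  lab <- g$labeling$redox
  sep <- function(k) {
    sc <- project_onto_pcs(cp$ct, b, k)
    L <- lda_scores(fit_lda(sc, lab), sc)[, 1]
    abs(mean(L[lab == "wt"]) - mean(L[lab == "analog"])) /
      sqrt(mean(tapply(L, lab, var)))
  }
  k0 <- min(8, b$D)
  s8 <- sep(k0)
  s9 <- sep(min(k0 + 2, b$D))
  expect_lt(abs(s9 - s8) / s8, 0.05)
  # separation is strong on this planted contrast
  expect_gt(s8, 5)
})

test_that("LD scores are invariant under joint rotation of scores and basis", {
  set.seed(50)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4)
  lab <- rep(c("a", "b"), each = n / 2)
  X[lab == "b", ] <- X[lab == "b", ] + rep(c(2, 1, 0, 0), each = n / 2)
  m1 <- fit_lda(score_matrix(X), lab)
  L1 <- lda_scores(m1, score_matrix(X))
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  m2 <- fit_lda(score_matrix(X %*% Q), lab)
  L2 <- lda_scores(m2, score_matrix(X %*% Q))
  expect_equal(abs(cor(L1[, 1], L2[, 1])), 1, tolerance = 1e-8)
})
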