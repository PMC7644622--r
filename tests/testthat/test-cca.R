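test_that("PCA reduction reconstructs low-rank data and is deterministic", {
  set.seed(2)
  A <- matrix(rnorm(60 * 3), 60, 3)
  B <- matrix(rnorm(3 * 20), 3, 20)
  X <- A %*% B
  pc <- reduce_pca(X, 3)
  recon <- pc$scores %*% t(pc$loadings)
  recon <- sweep(recon, 2, pc$center, "+")
  expect_equal(recon, X, tolerance = 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_equal(unname(crossprod(pc$loadings)), diag(3), tolerance = 1e-8)

  # dominant planted direction is captured by PC1
  z <- rnorm(200)
  Xd <- outer(z, rnorm(30)) * 5 + matrix(rnorm(200 * 30, sd = 0.1), 200, 30)
  expect_gt(abs(cor(reduce_pca(Xd, 2)$scores[, 1], z)), 0.99)

  # duplicated rows get identical scores
  Xdup <- rbind(X, X[1:5, ])
  sc <- reduce_pca(Xdup, 3)$scores
  expect_equal(sc[61:65, ], sc[1:5, ], tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(reduce_pca(X, 100), "n_components")
})

test_that("CCA satisfies its structural invariants", {
  set.seed(3)
  U <- matrix(rnorm(80 * 4), 80, 4)
  V <- U %*% matrix(rnorm(16), 4, 4) + matrix(rnorm(80 * 4, sd = 0.7), 80, 4)
  fit <- fit_cca(U, V)
  K <- length(fit$r)
  expect_true(all(diff(fit$r) <= 1e-12))
  for (k in seq_len(K)) {
    expect_equal(cor(fit$scores_u[, k], fit$scores_v[, k]), fit$r[k],
                 tolerance = 1e-8)
    expect_equal(sd(fit$scores_u[, k]), 1, tolerance = 1e-8)
    expect_equal(sd(fit$scores_v[, k]), 1, tolerance = 1e-8)
  }
  cu <- cor(fit$scores_u); cv <- cor(fit$scores_v)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-6)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-6)
  # scores are the stated linear combinations of the inputs
  expect_equal(scale(U, scale = FALSE) %*% fit$weights_u, fit$scores_u,
               tolerance = 1e-8, ignore_attr = TRUE)

  # identical blocks: perfect correlation on every mode
  fit_id <- fit_cca(U, U)
  expect_equal(fit_id$r, rep(1, 4), tolerance = 1e-8)

  # independent blocks at large n: small leading correlation
  set.seed(4)
  fit0 <- fit_cca(matrix(rnorm(1000 * 2), 1000, 2),
                  matrix(rnorm(1000 * 2), 1000, 2))
  expect_lt(fit0$r[1], 0.15)

  expect_error(fit_cca(cbind(U, 0), V), "zero-variance")
})

test_that("canonical correlations are invariant to invertible within-block maps", {
  set.seed(5)
  U <- matrix(rnorm(60 * 3), 60, 3)
  V <- matrix(rnorm(60 * 3), 60, 3) + U
  M <- matrix(rnorm(9), 3, 3) + diag(3) * 2
  expect_equal(fit_cca(U %*% M, V)$r, fit_cca(U, V)$r, tolerance = 1e-8)
})

test_that("leading canonical correlation matches direct numerical maximization", {
  set.seed(6)
  U <- matrix(rnorm(50 * 2), 50, 2)
  V <- 0.5 * U + matrix(rnorm(50 * 2), 50, 2)
  r1 <- fit_cca(U, V)$r[1]
  # independent oracle: maximize corr(U a, V b) over unit circles
  Uc <- scale(U, scale = FALSE); Vc <- scale(V, scale = FALSE)
  obj <- function(th) -cor(Uc %*% c(cos(th[1]), sin(th[1])),
                           Vc %*% c(cos(th[2]), sin(th[2])))
  best <- max(vapply(seq_len(24), function(i) {
    th0 <- runif(2, 0, pi)
    -stats::optim(th0, obj, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))$value
  }, numeric(1)))
  expect_equal(r1, best, tolerance = 1e-6)
})

test_that("mode orientation flips jointly, is idempotent, and leaves r unchanged", {
  set.seed(7)
  U <- matrix(rnorm(60 * 3), 60, 3)
  V <- U + matrix(rnorm(60 * 3), 60, 3)
  X <- V %*% matrix(rnorm(3 * 10), 3, 10)  # feature block for strengths
  fit <- fit_cca(U, V)
  st <- canonical_strengths(X, fit$scores_v[, 1])$strength

  # reference equal to current strengths: no flip
  f1 <- orient_mode(fit, strengths = st, reference = st)
  expect_identical(f1$flipped[1], FALSE)
  # negated reference: joint flip of both scores, r unchanged
  f2 <- orient_mode(fit, strengths = st, reference = -st)
  expect_true(f2$flipped[1])
  expect_equal(f2$scores_u[, 1], -fit$scores_u[, 1])
  expect_equal(f2$scores_v[, 1], -fit$scores_v[, 1])
  expect_equal(f2$r, fit$r)
  expect_equal(cor(f2$scores_u[, 1], f2$scores_v[, 1]), f2$r[1],
               tolerance = 1e-8)
  # orienting twice with the same reference is idempotent
  f3 <- orient_mode(orient_mode(fit, X = X), X = X)
  expect_equal(f3$scores_v, orient_mode(fit, X = X)$scores_v)
  # default convention: nonpositive mean connection strength
  f4 <- orient_mode(fit, X = X)
  expect_lte(mean(canonical_strengths(X, f4$scores_v[, 1])$strength), 0)
})

test_that("variance explained follows its definition", {
  set.seed(8)
  U <- matrix(rnorm(100 * 2), 100, 2)
  V <- U + matrix(rnorm(100 * 2, sd = 0.5), 100, 2)
  fit <- fit_cca(U, V)
  s <- fit$scores_v[, 1]
  # every column equal to the score: proportion 1
  Xeq <- cbind(s, s, s)
  expect_equal(variance_explained(fit, Xeq)$proportion, 1, tolerance = 1e-10)
  # single column: proportion equals the squared correlation
  x1 <- s + rnorm(100)
  expect_equal(variance_explained(fit, cbind(x1))$proportion, cor(x1, s)^2,
               tolerance = 1e-12)
  # independent features: proportion near the 1/(n-1) null scale
  Xind <- matrix(rnorm(100 * 400), 100, 400)
  ve <- variance_explained(fit, Xind)$proportion
  expect_lt(ve, 5 / (100 - 1))
  expect_gt(ve, 0.2 / (100 - 1))
  # zero-variance feature excluded with a message
  expect_message(out <- variance_explained(fit, cbind(x1, rep(1, 100))),
                 "zero-variance")
  expect_equal(out$n_excluded, 1)
})

test_that("tidy and glance methods summarize fits", {
  set.seed(9)
  U <- matrix(rnorm(40 * 2), 40, 2)
  fit <- fit_cca(U, U + matrix(rnorm(80), 40, 2))
  td <- tidy(fit)
  expect_equal(td$canonical_r, fit$r)
  expect_equal(glance(fit)$r1, fit$r[1])
})
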