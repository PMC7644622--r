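#' Principal component reduction of a data block
#'
#' Column-centered PCA (optionally z-scored with `standardize = TRUE`)
#' keeping `n_components` components, the dimensionality-reduction step
#' applied to each block before CCA. Features are kept on their native
#' scale by default: dosages and fFA values are centered only.
#'
#' @param X Subjects x features numeric matrix.
#' @param n_components Number of components, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param standardize Z-score features before the decomposition.
#' @return A `pca_reduction`: list with `scores` (subjects x components),
#'   `loadings` (features x components, orthonormal), `explained_variance`
#'   (fractions, nonincreasing), `center`, `scale` and `n_components`.
#' @export
reduce_pca <- function(X, n_components = 100, standardize = FALSE) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1 || n_components > kmax) {
    stop("`n_components` must lie in [1, ", kmax,
         "] for a ", nrow(X), " x ", ncol(X), " matrix", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize, rank. = n_components)
  ev <- pc$sdev^2
  structure(
    list(
      scores = pc$x,
      loadings = pc$rotation,
      explained_variance = ev / sum(ev),
      center = pc$center,
      scale = if (standardize) pc$scale else NULL,
      n_components = as.integer(n_components)
    ),
    class = "pca_reduction"
  )
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf("<pca_reduction> %d components, first explains %.1f%% of variance\n",
              x$n_components, 100 * x$explained_variance[1]))
  invisible(x)
}

# Core CCA by QR + SVD on centered blocks. Returns the fit together with the
# orthonormal bases Qu/Qv, which permutation_test_modes() re-uses (permuting
# subject rows commutes with centering and with the QR factorization).
cca_core <- function(U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  n <- nrow(U)
  if (nrow(V) != n) stop("U and V must have the same subjects", call. = FALSE)
  if (n < 4) stop("CCA needs at least 4 subjects", call. = FALSE)
  for (blk in list(list(U, "U"), list(V, "V"))) {
    sds <- apply(blk[[1]], 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance column(s) in block ", blk[[2]], ": ",
           paste(utils::head(which(sds == 0), 5), collapse = ", "), call. = FALSE)
    }
  }
  Uc <- scale(U, center = TRUE, scale = FALSE)
  Vc <- scale(V, center = TRUE, scale = FALSE)
  qu <- qr(Uc); qv <- qr(Vc)
  if (qu$rank < ncol(U)) stop("block U is rank deficient after centering", call. = FALSE)
  if (qv$rank < ncol(V)) stop("block V is rank deficient after centering", call. = FALSE)
  Qu <- qr.Q(qu); Qv <- qr.Q(qv)
  s <- svd(crossprod(Qu, Qv))
  K <- min(ncol(U), ncol(V))
  r <- pmin(pmax(s$d[seq_len(K)], 0), 1)

  sol_w <- function(qrobj, rot) {
    w <- matrix(0, nrow(qr.R(qrobj)), K)
    w[qrobj$pivot, ] <- backsolve(qr.R(qrobj), rot[, seq_len(K), drop = FALSE])
    w * sqrt(n - 1)
  }
  wu <- sol_w(qu, s$u)
  wv <- sol_w(qv, s$v)
  scores_u <- Qu %*% s$u[, seq_len(K), drop = FALSE] * sqrt(n - 1)
  scores_v <- Qv %*% s$v[, seq_len(K), drop = FALSE] * sqrt(n - 1)
  rownames(scores_u) <- rownames(scores_v) <- rownames(U)
  rownames(wu) <- colnames(U); rownames(wv) <- colnames(V)

  structure(
    list(
      r = r, weights_u = wu, weights_v = wv,
      scores_u = scores_u, scores_v = scores_v,
      n = n, k_u = ncol(U), k_v = ncol(V),
      flipped = rep(FALSE, K),
      Qu = Qu, Qv = Qv
    ),
    class = "cca_fit"
  )
}

#' Fit canonical correlation analysis on two reduced blocks
#'
#' Computes all `min(K_u, K_v)` modes of covariation between a genetic and
#' a connectomic block via QR orthogonalization and SVD. Canonical
#' correlations are nonincreasing; canonical scores are standardized to
#' unit variance, mutually uncorrelated within each block, and satisfy
#' `cor(scores_u[, k], scores_v[, k]) == r[k]`.
#'
#' @param U,V Subjects x components matrices (same subject order), typically
#'   PCA scores from [reduce_pca()].
#' @return A `cca_fit` with elements `r`, `weights_u`, `weights_v`,
#'   `scores_u`, `scores_v`.
#' @export
#' @examples
#' set.seed(1)
#' U <- matrix(rnorm(200), 50, 4)
#' fit <- fit_cca(U, U[, c(2, 1, 3, 4)] + matrix(rnorm(200, sd = .5), 50))
#' fit$r
fit_cca <- function(U, V) {
  cca_core(U, V)
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("<cca_fit> n = %d, %d x %d components, %d mode(s)\n",
              x$n, x$k_u, x$k_v, length(x$r)))
  cat("  canonical r:", paste(sprintf("%.3f", utils::head(x$r, 5)), collapse = ", "),
      if (length(x$r) > 5) "..." else "", "\n")
  invisible(x)
}

#' Fix the arbitrary sign of a CCA mode
#'
#' CCA solutions are sign-indeterminate: both score vectors of a mode can be
#' negated jointly without changing anything. This orients mode `mode` so
#' that the inner product of its connectomic canonical strengths with a
#' reference vector is nonnegative, flipping scores and weights of both
#' blocks together (the canonical correlation is unchanged). The default
#' reference, `rep(-1, length(strengths))`, enforces a nonpositive mean
#' connection strength — higher canonical scores then go with globally
#' weaker connectivity, the convention used throughout the package.
#'
#' @param fit A `cca_fit`.
#' @param X Adjusted connectomic block used to compute strengths when
#'   `strengths` is not supplied.
#' @param strengths Optional precomputed strength vector for the mode.
#' @param reference Reference vector aligned with the strengths; default
#'   all `-1`.
#' @param mode Mode index to orient.
#' @return The fit with the mode (possibly) flipped; `fit$flipped[mode]`
#'   records whether a flip happened.
#' @export
orient_mode <- function(fit, X = NULL, strengths = NULL, reference = NULL,
                        mode = 1) {
  stopifnot(inherits(fit, "cca_fit"))
  if (is.null(strengths)) {
    if (is.null(X)) stop("supply `X` or `strengths` to orient a mode", call. = FALSE)
    strengths <- strength_vector(X, fit$scores_v[, mode])
  }
  if (is.null(reference)) reference <- rep(-1, length(strengths))
  if (length(reference) != length(strengths)) {
    stop("`reference` must align with the strength vector", call. = FALSE)
  }
  ip <- sum(strengths * reference, na.rm = TRUE)
  if (ip == 0) {
    message("orient_mode: zero inner product with reference; no flip applied")
    return(fit)
  }
  if (ip < 0) {
    fit$scores_u[, mode] <- -fit$scores_u[, mode]
    fit$scores_v[, mode] <- -fit$scores_v[, mode]
    fit$weights_u[, mode] <- -fit$weights_u[, mode]
    fit$weights_v[, mode] <- -fit$weights_v[, mode]
    fit$flipped[mode] <- !fit$flipped[mode]
  }
  fit
}

#' Proportion of block variance explained by a canonical score
#'
#' Defined as the mean over features of the squared Pearson correlation
#' between the feature and the mode's canonical score, computed on the
#' pre-PCA (adjusted) block. Zero-variance features are excluded from the
#' mean with a message.
#'
#' @param fit A `cca_fit`.
#' @param X Pre-PCA adjusted block (subjects x features).
#' @param mode Mode index.
#' @param block `"v"` (connectomic, default) or `"u"` (genetic): which
#'   block's score `X` is correlated against.
#' @return Tibble with `mode`, `block`, `proportion`, `n_features`,
#'   `n_excluded`.
#' @export
variance_explained <- function(fit, X, mode = 1, block = c("v", "u")) {
  stopifnot(inherits(fit, "cca_fit"))
  block <- match.arg(block)
  score <- if (block == "v") fit$scores_v[, mode] else fit$scores_u[, mode]
  st <- strength_vector(X, score)
  excl <- sum(is.na(st))
  if (excl > 0) {
    message("variance_explained: excluded ", excl, " zero-variance feature(s)")
  }
  tibble::tibble(
    mode = mode, block = block,
    proportion = mean(st^2, na.rm = TRUE),
    n_features = sum(!is.na(st)), n_excluded = excl
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CCA fit into one row per mode
#'
#' @param x A `cca_fit`.
#' @param ... Unused.
#' @return Tibble with `mode` and `canonical_r`.
#' @export
tidy.cca_fit <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$r), canonical_r = x$r)
}

#' One-row summary of a CCA fit
#'
#' @param x A `cca_fit`.
#' @param ... Unused.
#' @export
glance.cca_fit <- function(x, ...) {
  tibble::tibble(n = x$n, k_u = x$k_u, k_v = x$k_v,
                 n_modes = length(x$r), r1 = x$r[1])
}
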