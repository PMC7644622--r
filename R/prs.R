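#' High-resolution p-threshold grid for PRS scanning
#'
#' Thresholds run from `5e-8` upward in steps of `5e-5`, truncated at
#' `upper_bound` (the optimal threshold of the base study); the bound itself
#' is appended when it does not fall on the grid. An `upper_bound` below
#' `5e-8` yields the single-point grid `c(upper_bound)`.
#'
#' @param upper_bound Largest threshold to scan, in `(0, 1]`.
#' @return Strictly increasing numeric vector of thresholds.
#' @export
#' @examples
#' build_threshold_grid(1.3e-4)
build_threshold_grid <- function(upper_bound) {
  if (length(upper_bound) != 1 || !is.finite(upper_bound) ||
      upper_bound <= 0 || upper_bound > 1) {
    stop("`upper_bound` must lie in (0, 1]", call. = FALSE)
  }
  base <- 5e-8
  step <- 5e-5
  if (upper_bound < base) return(upper_bound)
  k <- floor((upper_bound - base) / step + 1e-12)
  grid <- base + step * seq.int(0, k)
  if (utils::tail(grid, 1) < upper_bound - 1e-15) grid <- c(grid, upper_bound)
  grid
}

#' Greedy LD clumping of summary statistics
#'
#' Standard clumping pass of clumping-and-thresholding scoring: SNPs are
#' visited by ascending p-value; a SNP is dropped when its `r_squared` with
#' an already-kept SNP exceeds `r2`. With no LD table the input is returned
#' unchanged (independent SNPs).
#'
#' @param sumstats Tibble with `snp_id`, `beta`, `p` (and anything else,
#'   carried through).
#' @param ld Optional pairwise LD tibble: `index_snp_id`, `proxy_snp_id`,
#'   `r_squared` (treated as symmetric).
#' @param r2 Clumping threshold (drop if `r_squared > r2`).
#' @return Pruned summary-statistics tibble.
#' @export
clump_sumstats <- function(sumstats, ld = NULL, r2 = 0.1) {
  sumstats <- tibble::as_tibble(sumstats)
  stopifnot(all(c("snp_id", "p") %in% names(sumstats)))
  if (anyDuplicated(sumstats$snp_id)) {
    stop("duplicate snp_id in summary statistics", call. = FALSE)
  }
  if (is.null(ld) || nrow(ld) == 0) return(sumstats)
  ld <- tibble::as_tibble(ld)
  pairs <- dplyr::bind_rows(
    tibble::tibble(a = ld$index_snp_id, b = ld$proxy_snp_id, r2 = ld$r_squared),
    tibble::tibble(a = ld$proxy_snp_id, b = ld$index_snp_id, r2 = ld$r_squared)
  )
  ord <- order(sumstats$p, sumstats$snp_id)
  kept <- character(0)
  dropped <- character(0)
  for (i in ord) {
    id <- sumstats$snp_id[i]
    if (id %in% dropped) next
    kept <- c(kept, id)
    hits <- pairs$b[pairs$a == id & pairs$r2 > r2]
    dropped <- union(dropped, setdiff(hits, kept))
  }
  sumstats[sumstats$snp_id %in% kept, , drop = FALSE]
}

# align sumstats to genotype columns; drops effect-allele mismatches with a
# message, returns dosage submatrix (missing imputed as 2 * sample MAF) and
# the matched sumstats
match_sumstats <- function(genotypes, sumstats) {
  stopifnot(inherits(genotypes, "genotype_table"))
  ss <- tibble::as_tibble(sumstats)
  stopifnot(all(c("snp_id", "beta", "p") %in% names(ss)))
  ss <- ss[ss$snp_id %in% colnames(genotypes$dosages), , drop = FALSE]
  if ("effect_allele" %in% names(ss)) {
    geno_allele <- dplyr::distinct(genotypes$snp_info,
                                   .data$snp_id, .data$effect_allele)
    merged <- dplyr::left_join(ss, geno_allele, by = "snp_id",
                               suffix = c("", ".geno"))
    bad <- !is.na(merged$effect_allele.geno) &
      merged$effect_allele != merged$effect_allele.geno
    if (any(bad)) {
      message("score_prs: dropped ", sum(bad),
              " SNP(s) with mismatched effect allele")
      ss <- ss[!bad, , drop = FALSE]
    }
  }
  D <- genotypes$dosages[, ss$snp_id, drop = FALSE]
  if (anyNA(D)) {
    maf <- colMeans(D, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(D)) > 0)) D[is.na(D[, j]), j] <- 2 * maf[j]
  }
  list(dosages = D, sumstats = ss)
}

#' Clumping-and-thresholding polygenic risk score
#'
#' `score_i = sum over SNPs with p <= threshold of beta_j * dosage_ij`,
#' where the dosage counts the effect allele. SNPs whose effect allele does
#' not match the genotype coding are dropped with a message; missing
#' dosages are imputed as twice the sample allele frequency.
#'
#' @param genotypes A `genotype_table`.
#' @param sumstats Summary statistics (`snp_id`, `effect_allele`, `beta`,
#'   `p`), normally pre-clumped with [clump_sumstats()].
#' @param threshold Inclusion p-value threshold (inclusive `<=`).
#' @return Named per-subject score vector (all zero, with a warning, when
#'   no SNP passes).
#' @export
score_prs <- function(genotypes, sumstats, threshold) {
  m <- match_sumstats(genotypes, sumstats)
  use <- m$sumstats$p <= threshold
  if (!any(use)) {
    warning("no SNP passes threshold ", format(threshold),
            "; returning all-zero scores", call. = FALSE)
    return(stats::setNames(numeric(nrow(m$dosages)), rownames(m$dosages)))
  }
  drop(m$dosages[, use, drop = FALSE] %*% m$sumstats$beta[use])
}

#' Incremental variance explained by a PRS beyond covariates
#'
#' `delta R^2 = R^2(target ~ PRS + GAFs) - R^2(target ~ GAFs)`; the
#' p-value is the two-tailed t-test of the PRS coefficient in the full
#' model.
#'
#' @param target Numeric response (the connectomic canonical score).
#' @param prs Per-subject polygenic score.
#' @param gafs Optional covariate matrix / data frame (genetic ancestry
#'   factors).
#' @return Tibble with `delta_r2`, `p_value`, `r2_full`, `r2_null`, `n`.
#' @export
delta_r2 <- function(target, prs, gafs = NULL) {
  n <- length(target)
  stopifnot(length(prs) == n)
  if (stats::sd(prs) == 0) stop("PRS has zero variance", call. = FALSE)
  if (!is.null(gafs)) {
    G <- as.matrix(gafs)
    stopifnot(nrow(G) == n)
    full <- stats::lm(target ~ prs + G)
    null <- stats::lm(target ~ G)
    if (anyNA(stats::coef(full))) {
      stop("PRS is collinear with the covariates", call. = FALSE)
    }
    r2f <- summary(full)$r.squared
    r2n <- summary(null)$r.squared
  } else {
    full <- stats::lm(target ~ prs)
    r2f <- summary(full)$r.squared
    r2n <- 0
  }
  pv <- summary(full)$coefficients["prs", "Pr(>|t|)"]
  tibble::tibble(delta_r2 = r2f - r2n, p_value = pv,
                 r2_full = r2f, r2_null = r2n, n = n)
}

#' Scan a PRS threshold grid against a target
#'
#' Computes the C+T score and [delta_r2()] at every threshold of the grid
#' and records the best-fitting threshold (maximal delta R^2).
#'
#' @param target Response vector (connectomic canonical score).
#' @param genotypes A `genotype_table`.
#' @param sumstats Summary statistics (pre-clump with [clump_sumstats()] if
#'   an LD table exists).
#' @param gafs Optional covariates included in both models.
#' @param grid Threshold grid from [build_threshold_grid()].
#' @return A `prs_result`: list with `profile` (tibble: `threshold`,
#'   `n_snps`, `delta_r2`, `p_value`), `best` (one-row tibble), `scores`
#'   (subjects x thresholds matrix).
#' @export
prs_scan <- function(target, genotypes, sumstats, gafs = NULL,
                     grid = build_threshold_grid(1)) {
  m <- match_sumstats(genotypes, sumstats)
  n <- nrow(m$dosages)
  stopifnot(length(target) == n)
  rows <- vector("list", length(grid))
  scores <- matrix(NA_real_, n, length(grid),
                   dimnames = list(rownames(m$dosages), format(grid)))
  for (t in seq_along(grid)) {
    use <- m$sumstats$p <= grid[t]
    s <- if (any(use)) {
      drop(m$dosages[, use, drop = FALSE] %*% m$sumstats$beta[use])
    } else numeric(n)
    scores[, t] <- s
    if (any(use) && stats::sd(s) > 0) {
      dr <- delta_r2(target, s, gafs)
      rows[[t]] <- tibble::tibble(threshold = grid[t], n_snps = sum(use),
                                  delta_r2 = dr$delta_r2, p_value = dr$p_value)
    } else {
      rows[[t]] <- tibble::tibble(threshold = grid[t], n_snps = sum(use),
                                  delta_r2 = NA_real_, p_value = NA_real_)
    }
  }
  profile <- dplyr::bind_rows(rows)
  ok <- which(!is.na(profile$delta_r2))
  best <- if (length(ok) > 0) profile[ok[which.max(profile$delta_r2[ok])], ] else
    profile[0, ]
  structure(list(profile = profile, best = best, scores = scores,
                 gafs = gafs, target = target),
            class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("<prs_result> %d thresholds\n", nrow(x$profile)))
  if (nrow(x$best) > 0) {
    cat(sprintf("  best: threshold %.3g, delta R^2 = %.4f (p = %.3g)\n",
                x$best$threshold, x$best$delta_r2, x$best$p_value))
  }
  invisible(x)
}

#' Tidy the per-threshold PRS profile
#'
#' @param x A `prs_result`.
#' @param ... Unused.
#' @export
tidy.prs_result <- function(x, ...) x$profile

#' One-row summary of the best PRS threshold
#'
#' @param x A `prs_result`.
#' @param ... Unused.
#' @export
glance.prs_result <- function(x, ...) x$best

#' Permutation correction of the PRS threshold scan
#'
#' The observed statistic is the best (smallest) association p-value over
#' the threshold grid. For each permutation the target rows are shuffled,
#' the whole scan is repeated and its best p recorded; the corrected
#' two-tailed p-value is `(1 + #(best_p_b <= best_p_obs)) / (B + 1)`,
#' which accounts for the multiplicity of testing many thresholds.
#'
#' Computation uses the partial-correlation identity: with covariates
#' residualized out of both sides, the full-model PRS t-test equals the
#' t-test of the partial correlation, so each permutation reduces to a set
#' of inner products.
#'
#' @inheritParams prs_scan
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return List with `corrected_p`, `best_threshold`, `best_p`,
#'   `observed` (per-threshold tibble: `threshold`, `partial_r`,
#'   `p_value`), `B`.
#' @export
prs_permutation_test <- function(target, genotypes, sumstats, gafs = NULL,
                                 grid = build_threshold_grid(1),
                                 B = 10000, seed = NULL) {
  if (B < 1) stop("`B` must be at least 1", call. = FALSE)
  m <- match_sumstats(genotypes, sumstats)
  n <- nrow(m$dosages)
  stopifnot(length(target) == n)
  design <- if (is.null(gafs)) matrix(1, n, 1) else cbind(1, as.matrix(gafs))
  qd <- qr(design)
  k <- qd$rank
  df <- n - k - 1

  normalize <- function(x) {
    nr <- sqrt(sum(x^2))
    if (nr == 0) return(NULL)
    x / nr
  }
  S <- matrix(0, n, length(grid))
  keep <- logical(length(grid))
  for (t in seq_along(grid)) {
    use <- m$sumstats$p <= grid[t]
    if (!any(use)) next
    s <- drop(m$dosages[, use, drop = FALSE] %*% m$sumstats$beta[use])
    sn <- normalize(qr.resid(qd, s))
    if (is.null(sn)) next
    S[, t] <- sn
    keep[t] <- TRUE
  }
  if (!any(keep)) stop("no threshold yields a non-degenerate PRS", call. = FALSE)
  S <- S[, keep, drop = FALSE]

  p_of_r <- function(r) 2 * stats::pt(-abs(r) * sqrt(df / pmax(1 - r^2, 1e-300)), df)
  yr <- normalize(qr.resid(qd, target))
  if (is.null(yr)) stop("target has zero residual variance", call. = FALSE)
  r_obs <- drop(crossprod(S, yr))
  p_obs <- p_of_r(r_obs)
  best_i <- which.max(abs(r_obs))

  if (!is.null(seed)) set.seed(as.integer(seed))
  count <- 0L
  max_abs_obs <- abs(r_obs[best_i])
  for (b in seq_len(B)) {
    yp <- normalize(qr.resid(qd, target[sample.int(n)]))
    if (is.null(yp)) next
    if (max(abs(drop(crossprod(S, yp)))) >= max_abs_obs - 1e-14) count <- count + 1L
  }

  list(
    corrected_p = (1 + count) / (B + 1),
    best_threshold = grid[keep][best_i],
    best_p = p_obs[best_i],
    observed = tibble::tibble(threshold = grid[keep], partial_r = r_obs,
                              p_value = p_obs),
    B = B
  )
}
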