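# Fast per-feature correlations with a score vector. Returns NA for
# zero-variance features.
strength_vector <- function(X, score) {
  X <- as.matrix(X)
  if (nrow(X) != length(score)) {
    stop("score length does not match the number of subjects", call. = FALSE)
  }
  suppressWarnings(drop(stats::cor(X, score)))
}

#' Canonical strengths of features against a canonical score
#'
#' The canonical strength of a feature is its Pearson correlation with the
#' relevant canonical score (genetic strengths: SNP dosage vs genetic
#' score; connection strengths: connection vs connectomic score).
#' Zero-variance features receive `NA` and are flagged.
#'
#' @param X Subjects x features block aligned with `score`.
#' @param score Canonical score vector.
#' @return Tibble with `feature` and `strength` (`NA` for zero-variance
#'   features).
#' @export
canonical_strengths <- function(X, score) {
  st <- strength_vector(X, score)
  if (anyNA(st)) {
    message("canonical_strengths: ", sum(is.na(st)),
            " zero-variance feature(s) flagged NA")
  }
  nm <- colnames(as.matrix(X))
  if (is.null(nm)) nm <- sprintf("f%05d", seq_along(st))
  tibble::tibble(feature = nm, strength = as.numeric(st))
}

# standardize columns to zero mean / unit norm-sqrt(n-1); zero-variance
# columns become all-zero and are reported in the "na" attribute
scale_block <- function(X) {
  X <- as.matrix(X)
  cm <- colMeans(X)
  Xc <- sweep(X, 2, cm)
  sds <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  bad <- sds == 0
  sds[bad] <- 1
  Xs <- sweep(Xc, 2, sds, "/")
  attr(Xs, "na") <- bad
  Xs
}

#' Max-statistic permutation test for CCA modes
#'
#' Calibrates mode significance against a null built by randomly permuting
#' the subject rows of one block relative to the other and refitting CCA;
#' the maximum absolute canonical correlation across modes of each
#' permuted fit is recorded. Comparing every observed mode against this
#' max-r distribution controls the familywise error across modes. P-values
#' use the add-one convention `p_k = (1 + #(maxnull >= r_k)) / (B + 1)`, so
#' the smallest attainable p is `1 / (B + 1)`.
#'
#' When `Xu` / `Xv` (the pre-PCA adjusted blocks) are supplied, the
#' mode-1 canonical strengths are also recomputed within every permutation,
#' giving per-feature permutation p-values (streamed exceedance counters)
#' and a per-permutation null of the variance-explained summary.
#'
#' @param U,V Reduced blocks as for [fit_cca()].
#' @param B Number of permutations (`>= 1`).
#' @param seed Integer seed for the permutation stream.
#' @param perms Optional explicit permutations (list of index vectors or a
#'   `B x n` matrix), e.g. the full enumeration for small n; overrides `B`
#'   and `seed`.
#' @param Xu,Xv Optional adjusted genetic / connectomic blocks for strength
#'   nulls.
#' @param permute Which block's rows are shuffled (`"v"`, default, or
#'   `"u"`); the max-r null is invariant to this choice.
#' @return A `cca_perm`: list with `fit` (the observed [fit_cca()]),
#'   `modes` (tibble: `mode`, `canonical_r`, `p`), `null_max_r` (length
#'   `B`), and when blocks were supplied `strengths` (per-block tibbles
#'   `feature`, `strength`, `p`) and `null_variance_explained` (per-block
#'   length-`B` vectors for mode 1).
#' @export
permutation_test_modes <- function(U, V, B = 10000, seed = NULL, perms = NULL,
                                   Xu = NULL, Xv = NULL,
                                   permute = c("v", "u")) {
  permute <- match.arg(permute)
  if (permute == "u") {
    swapped <- permutation_test_modes(V, U, B = B, seed = seed, perms = perms,
                                      Xu = Xv, Xv = Xu, permute = "v")
    # swap the block labelling back
    fit <- swapped$fit
    out_fit <- fit
    out_fit$weights_u <- fit$weights_v; out_fit$weights_v <- fit$weights_u
    out_fit$scores_u <- fit$scores_v; out_fit$scores_v <- fit$scores_u
    out_fit$k_u <- fit$k_v; out_fit$k_v <- fit$k_u
    out_fit$Qu <- fit$Qv; out_fit$Qv <- fit$Qu
    swapped$fit <- out_fit
    if (!is.null(swapped$strengths)) {
      swapped$strengths <- swapped$strengths[c("v", "u")]
      names(swapped$strengths) <- c("u", "v")
      swapped$null_variance_explained <- swapped$null_variance_explained[c("v", "u")]
      names(swapped$null_variance_explained) <- c("u", "v")
    }
    return(swapped)
  }

  fit <- cca_core(U, V)
  n <- fit$n
  if (!is.null(perms)) {
    if (is.matrix(perms)) perms <- lapply(seq_len(nrow(perms)), function(i) perms[i, ])
    B <- length(perms)
  }
  if (B < 1) stop("`B` must be at least 1", call. = FALSE)
  if (is.null(perms) && !is.null(seed)) set.seed(as.integer(seed))

  with_strengths <- !is.null(Xu) || !is.null(Xv)
  prep <- function(X, score) {
    if (is.null(X)) return(NULL)
    Xs <- scale_block(X)
    obs <- strength_vector(X, score)
    list(Xs = Xs, obs = obs, obs_abs = abs(obs), na = attr(Xs, "na"),
         count = numeric(ncol(Xs)), ve = numeric(B))
  }
  side_u <- if (with_strengths) prep(Xu, fit$scores_u[, 1]) else NULL
  side_v <- if (with_strengths) prep(Xv, fit$scores_v[, 1]) else NULL

  Qu <- fit$Qu; Qv <- fit$Qv
  sq <- sqrt(n - 1)
  null_max_r <- numeric(B)
  for (b in seq_len(B)) {
    perm <- if (!is.null(perms)) perms[[b]] else sample.int(n)
    s <- svd(crossprod(Qu, Qv[perm, , drop = FALSE]))
    null_max_r[b] <- s$d[1]
    if (with_strengths) {
      if (!is.null(side_u)) {
        su0 <- Qu %*% s$u[, 1] # unit-norm genetic score, original row order
        st <- drop(crossprod(side_u$Xs, su0)) / sq
        side_u$count <- side_u$count + (abs(st) >= side_u$obs_abs - 1e-14)
        side_u$ve[b] <- mean(st[!side_u$na]^2)
      }
      if (!is.null(side_v)) {
        # scores of the permuted fit re-expressed in original row order: the
        # permuted pairing of X rows with scores equals this unpermuted pair
        sv0 <- Qv %*% s$v[, 1]
        st <- drop(crossprod(side_v$Xs, sv0)) / sq
        side_v$count <- side_v$count + (abs(st) >= side_v$obs_abs - 1e-14)
        side_v$ve[b] <- mean(st[!side_v$na]^2)
      }
    }
  }

  p_modes <- vapply(fit$r, function(rk) (1 + sum(null_max_r >= rk)) / (B + 1),
                    numeric(1))
  strengths <- NULL
  null_ve <- NULL
  if (with_strengths) {
    mk <- function(side, X) {
      if (is.null(side)) return(NULL)
      nm <- colnames(as.matrix(X))
      if (is.null(nm)) nm <- sprintf("f%05d", seq_along(side$obs))
      p <- as.numeric((1 + side$count) / (B + 1))
      p[side$na] <- NA_real_
      tibble::tibble(feature = nm, strength = as.numeric(side$obs), p = p)
    }
    strengths <- list(u = mk(side_u, Xu), v = mk(side_v, Xv))
    null_ve <- list(u = if (!is.null(side_u)) side_u$ve else NULL,
                    v = if (!is.null(side_v)) side_v$ve else NULL)
  }

  structure(
    list(
      fit = fit,
      modes = tibble::tibble(mode = seq_along(fit$r), canonical_r = fit$r,
                             p = p_modes),
      null_max_r = null_max_r, B = B, seed = seed,
      strengths = strengths, null_variance_explained = null_ve
    ),
    class = "cca_perm"
  )
}

#' @export
print.cca_perm <- function(x, ...) {
  cat(sprintf("<cca_perm> B = %d permutations\n", x$B))
  print(utils::head(x$modes, 3))
  invisible(x)
}

#' Tidy the permutation-calibrated modes
#'
#' @param x A `cca_perm`.
#' @param ... Unused.
#' @export
tidy.cca_perm <- function(x, ...) x$modes

#' Per-feature permutation p-values from exceedance counts
#'
#' Add-one permutation p per feature against its own null:
#' `p_j = (1 + #(|null strength| >= |observed|)) / (B + 1)`. With
#' `pooled = TRUE` all features share the pooled null exceedance count.
#'
#' @param observed Observed strength vector (`NA` for zero-variance
#'   features, which stay `NA`).
#' @param exceed_counts Per-feature exceedance counts over `B`
#'   permutations (as streamed by [permutation_test_modes()]).
#' @param B Number of permutations.
#' @param pooled Use a single pooled count for all features.
#' @return Numeric p-value vector.
#' @export
strength_pvalues <- function(observed, exceed_counts, B, pooled = FALSE) {
  if (length(observed) != length(exceed_counts)) {
    stop("`observed` and `exceed_counts` lengths differ", call. = FALSE)
  }
  if (pooled) exceed_counts <- rep(sum(exceed_counts), length(exceed_counts))
  p <- (1 + exceed_counts) / (B + 1)
  p[is.na(observed)] <- NA_real_
  p
}

#' Grouped Benjamini-Hochberg FDR correction
#'
#' Standard BH step-up applied independently within each group: all
#' connection strengths form one group, genetic strengths are corrected
#' within each phenotype (a SNP annotated to several phenotypes is tested
#' within each).
#'
#' @param pvals P-value vector (`NA` allowed, passed through).
#' @param groups Optional group labels (same length); `NULL` treats all
#'   p-values as one group.
#' @return Vector of q-values.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(pvals, groups = NULL) {
  if (is.null(groups)) return(stats::p.adjust(pvals, method = "BH"))
  if (length(groups) != length(pvals)) {
    stop("`groups` must align with `pvals`", call. = FALSE)
  }
  q <- rep(NA_real_, length(pvals))
  for (gr in unique(groups)) {
    i <- which(groups == gr)
    q[i] <- stats::p.adjust(pvals[i], method = "BH")
  }
  q
}

#' Ratio of observed to null variance explained
#'
#' Effect-size summary for a mode: the observed proportion of feature
#' variance explained by the canonical score divided by the mean of the
#' same proportion over the permutation null.
#'
#' @param observed Observed proportion (e.g. from [variance_explained()]).
#' @param null_values Per-permutation null proportions.
#' @return Single ratio.
#' @export
null_variance_ratio <- function(observed, null_values) {
  m <- mean(null_values)
  if (!is.finite(m) || m == 0) {
    stop("null variance-explained mean is zero or undefined", call. = FALSE)
  }
  observed / m
}

#' Assemble the full strength table with permutation p and grouped FDR q
#'
#' Combines the genetic and connectomic strength results of a
#' [permutation_test_modes()] run into one tidy table. Connections form a
#' single FDR group; SNPs are expanded to one row per phenotype annotation
#' and corrected within phenotype.
#'
#' @param perm A `cca_perm` run with both `Xu` and `Xv`.
#' @param snp_info Tibble mapping `snp_id` to `phenotype` (one row per
#'   annotation), e.g. `genotype_table$snp_info` or [snp_annotations()].
#' @param edges Edge index tibble (from [edge_index()] or the attribute of
#'   [vectorize_connectomes()]).
#' @return Tibble with `feature`, `block` (`"genetic"`/`"connectomic"`),
#'   `group`, `strength`, `p`, `q` and, for connections, `node_i`/`node_j`.
#' @export
strength_table <- function(perm, snp_info = NULL, edges = NULL) {
  stopifnot(inherits(perm, "cca_perm"), !is.null(perm$strengths))
  conn <- perm$strengths$v
  conn$block <- "connectomic"
  conn$group <- "connection"
  if (!is.null(edges)) {
    conn <- dplyr::left_join(conn, edges[, c("edge_id", "node_i", "node_j")],
                             by = c(feature = "edge_id"))
  }
  gen <- perm$strengths$u
  gen$block <- "genetic"
  if (!is.null(snp_info)) {
    gen <- dplyr::inner_join(
      gen, dplyr::distinct(snp_info[, c("snp_id", "phenotype")]),
      by = c(feature = "snp_id"), relationship = "many-to-many"
    )
    gen$group <- gen$phenotype
    gen$phenotype <- NULL
  } else {
    gen$group <- "genetic"
  }
  out <- dplyr::bind_rows(gen, conn)
  out$q <- bh_fdr(out$p, out$group)
  out[, c("feature", "block", "group", "strength", "p", "q",
          intersect(c("node_i", "node_j"), names(out)))]
}
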