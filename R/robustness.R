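#' Run the core adjust -> PCA -> CCA -> strengths pipeline
#'
#' The single code path every analysis scenario goes through: residualize
#' the connection matrix on the confounds, reduce both blocks by PCA, fit
#' CCA, orient mode 1 to the nonpositive-mean-strength convention and
#' compute the canonical strengths of mode 1 on both sides. Robustness
#' scenarios are expressed purely as input transformations (row/column
#' subsets, extra adjustment) around this function.
#'
#' @param dosages Subjects x SNPs dosage matrix.
#' @param edge_data Subjects x connections matrix (from
#'   [vectorize_connectomes()]).
#' @param covariates Covariate table aligned with the rows.
#' @param n_components PCA components per block (capped at the block's
#'   admissible maximum).
#' @param standardize Z-score features before PCA.
#' @param adjust_genetic Also residualize the genotype block on the GAF
#'   columns (ancestry adjustment of the SNPs).
#' @return A `cca_pipeline`: list with `fit` (oriented `cca_fit`),
#'   `strengths_genetic`, `strengths_connection` (tibbles), `Xu`, `Xv`
#'   (the blocks that entered PCA), `pca_u`, `pca_v`, `n_components`.
#' @export
run_cca_pipeline <- function(dosages, edge_data, covariates,
                             n_components = 100, standardize = FALSE,
                             adjust_genetic = FALSE) {
  dosages <- as.matrix(dosages)
  edge_data <- as.matrix(edge_data)
  Xv <- adjust_confounds(edge_data, covariates)
  Xu <- if (adjust_genetic) {
    gaf_cols <- grep("^gaf", names(covariates), value = TRUE)
    if (length(gaf_cols) == 0) stop("no GAF columns to adjust the SNPs for",
                                    call. = FALSE)
    adjust_confounds(dosages, covariates, covariate_cols = gaf_cols)
  } else dosages
  kmax_u <- min(nrow(Xu) - 1L, ncol(Xu))
  kmax_v <- min(nrow(Xv) - 1L, ncol(Xv))
  pu <- reduce_pca(Xu, min(n_components, kmax_u), standardize = standardize)
  pv <- reduce_pca(Xv, min(n_components, kmax_v), standardize = standardize)
  fit <- fit_cca(pu$scores, pv$scores)
  fit <- orient_mode(fit, X = Xv)
  structure(
    list(
      fit = fit,
      strengths_genetic = canonical_strengths(Xu, fit$scores_u[, 1]),
      strengths_connection = canonical_strengths(Xv, fit$scores_v[, 1]),
      Xu = Xu, Xv = Xv, pca_u = pu, pca_v = pv,
      n_components = n_components
    ),
    class = "cca_pipeline"
  )
}

#' @export
print.cca_pipeline <- function(x, ...) {
  cat(sprintf("<cca_pipeline> n = %d, r1 = %.3f (%d + %d components)\n",
              x$fit$n, x$fit$r[1], x$fit$k_u, x$fit$k_v))
  invisible(x)
}

# correlation between two strength vectors after sign alignment (CCA sign
# is arbitrary; the reproduced mode is flipped to maximize the correlation)
aligned_strength_cor <- function(orig, repro) {
  ok <- !is.na(orig) & !is.na(repro)
  r <- stats::cor(orig[ok], repro[ok])
  abs(r)
}

#' Split-half reproducibility of the mode
#'
#' Splits the subjects into two random disjoint halves, reruns the full
#' pipeline in each, and correlates the half-sample canonical strengths
#' (both sides, sign-aligned) with the full-sample strengths.
#'
#' @inheritParams run_cca_pipeline
#' @param seed Integer seed for the split.
#' @param full Optional precomputed full-sample `cca_pipeline` (recomputed
#'   when `NULL`).
#' @return Tibble with one row per half: `scenario`, `n`, `cor_genetic`,
#'   `cor_connection`.
#' @export
split_half <- function(dosages, edge_data, covariates, n_components = 100,
                       seed = NULL, full = NULL) {
  n <- nrow(dosages)
  if (n < 40) stop("split-half needs at least 40 subjects", call. = FALSE)
  if (is.null(full)) {
    full <- run_cca_pipeline(dosages, edge_data, covariates, n_components)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- sample.int(n)
  halves <- list(half_a = sort(idx[seq_len(floor(n / 2))]),
                 half_b = sort(idx[(floor(n / 2) + 1):n]))
  rows <- lapply(names(halves), function(nm) {
    i <- halves[[nm]]
    sub <- run_cca_pipeline(dosages[i, , drop = FALSE],
                            edge_data[i, , drop = FALSE],
                            covariates[i, , drop = FALSE], n_components)
    tibble::tibble(
      scenario = nm, n = length(i),
      cor_genetic = aligned_strength_cor(full$strengths_genetic$strength,
                                         sub$strengths_genetic$strength),
      cor_connection = aligned_strength_cor(full$strengths_connection$strength,
                                            sub$strengths_connection$strength)
    )
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity of the mode to the number of principal components
#'
#' Reruns the pipeline for each component count in `k_values` and
#' correlates the resulting mode-1 strengths with the baseline run.
#' Invalid counts are skipped with a warning.
#'
#' @inheritParams run_cca_pipeline
#' @param k_values Component counts to test.
#' @param baseline Baseline component count.
#' @return Tibble with `n_components`, `cor_genetic`, `cor_connection`.
#' @export
pc_sensitivity <- function(dosages, edge_data, covariates,
                           k_values = seq(50, 150, by = 25), baseline = 100) {
  base <- run_cca_pipeline(dosages, edge_data, covariates, baseline)
  kmax <- min(nrow(dosages) - 1L, ncol(dosages), ncol(edge_data))
  rows <- lapply(k_values, function(k) {
    if (k < 1 || k > kmax) {
      warning("skipping invalid component count ", k, call. = FALSE)
      return(NULL)
    }
    run <- run_cca_pipeline(dosages, edge_data, covariates, k)
    tibble::tibble(
      n_components = k,
      cor_genetic = aligned_strength_cor(base$strengths_genetic$strength,
                                         run$strengths_genetic$strength),
      cor_connection = aligned_strength_cor(base$strengths_connection$strength,
                                            run$strengths_connection$strength)
    )
  })
  dplyr::bind_rows(rows)
}

#' Rerun the mode with a subset of SNPs
#'
#' Restricts the genotype block to the given SNPs (for example, all SNPs
#' annotated to one group of psychiatric phenotypes), reruns the pipeline,
#' and correlates the reproduced canonical connection strengths with the
#' original network. The permutation p shuffles the connection (edge)
#' labels of the reproduced strength vector.
#'
#' @inheritParams run_cca_pipeline
#' @param snp_ids SNP ids to keep (at least 2).
#' @param B Permutations for the network-correlation p-value.
#' @param seed Integer seed.
#' @param full Optional precomputed full `cca_pipeline`.
#' @return Tibble with `n_snps`, `cor_connection`, `p`.
#' @export
snp_subset_rerun <- function(dosages, edge_data, covariates, snp_ids,
                             n_components = 100, B = 999, seed = NULL,
                             full = NULL) {
  snp_ids <- intersect(snp_ids, colnames(dosages))
  if (length(snp_ids) < 2) stop("subset selects fewer than 2 SNPs", call. = FALSE)
  if (is.null(full)) {
    full <- run_cca_pipeline(dosages, edge_data, covariates, n_components)
  }
  sub <- run_cca_pipeline(dosages[, snp_ids, drop = FALSE], edge_data,
                          covariates, n_components)
  s0 <- full$strengths_connection$strength
  s1 <- sub$strengths_connection$strength
  r <- aligned_strength_cor(s0, s1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  null_r <- vapply(seq_len(B), function(b) {
    abs(stats::cor(s0, sample(s1)))
  }, numeric(1))
  tibble::tibble(
    n_snps = length(snp_ids), cor_connection = r,
    p = (1 + sum(null_r >= r)) / (B + 1)
  )
}

#' Rerun the mode after excluding flagged subjects
#'
#' E.g. participants exhibiting behaviors related to psychiatric
#' vulnerability; the reported correlations say whether those subjects
#' drive the mode.
#'
#' @inheritParams run_cca_pipeline
#' @param exclude Logical vector (length = subjects) flagging exclusions.
#' @param full Optional precomputed full `cca_pipeline`.
#' @return Tibble with `n_excluded`, `n_remaining`, `cor_genetic`,
#'   `cor_connection`.
#' @export
exclude_subjects_rerun <- function(dosages, edge_data, covariates, exclude,
                                   n_components = 100, full = NULL) {
  stopifnot(length(exclude) == nrow(dosages))
  keep <- which(!exclude)
  if (length(keep) < 30) stop("fewer than 30 subjects remain", call. = FALSE)
  if (is.null(full)) {
    full <- run_cca_pipeline(dosages, edge_data, covariates, n_components)
  }
  sub <- run_cca_pipeline(dosages[keep, , drop = FALSE],
                          edge_data[keep, , drop = FALSE],
                          covariates[keep, , drop = FALSE], n_components)
  tibble::tibble(
    n_excluded = sum(exclude), n_remaining = length(keep),
    cor_genetic = aligned_strength_cor(full$strengths_genetic$strength,
                                       sub$strengths_genetic$strength),
    cor_connection = aligned_strength_cor(full$strengths_connection$strength,
                                          sub$strengths_connection$strength)
  )
}

#' Correlation of canonical scores with mean connectivity
#'
#' Per-subject mean over all connection strengths correlated with the
#' connectomic canonical score; a negative correlation means high canonical
#' scores go with globally weaker connectivity (hypoconnectivity). The
#' permutation p shuffles the scores.
#'
#' @param edge_data Subjects x connections matrix (raw connection
#'   strengths).
#' @param conn_score Connectomic canonical score.
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return Tibble with `r` and `p` (two-tailed permutation p).
#' @export
mean_connectivity_correlation <- function(edge_data, conn_score, B = 999,
                                          seed = NULL) {
  mc <- rowMeans(as.matrix(edge_data))
  r <- stats::cor(mc, conn_score)
  if (!is.null(seed)) set.seed(as.integer(seed))
  null_r <- vapply(seq_len(B), function(b) {
    abs(stats::cor(mc, conn_score[sample.int(length(conn_score))]))
  }, numeric(1))
  tibble::tibble(r = r, p = (1 + sum(null_r >= abs(r))) / (B + 1))
}

#' Hubs of hypo- and hyperconnectivity
#'
#' Per node, the sum (default) or mean of canonical connection strengths
#' over incident connections significant at `q < q_threshold`. Nodes with
#' a negative total are hypoconnectivity hubs (their connectivity decreases
#' with increasing canonical score), positive totals hyperconnectivity
#' hubs; nodes with no significant incident connection — or an exact zero
#' total — are classed `"none"`.
#'
#' @param strengths Strength table carrying `strength`, `q`, `node_i`,
#'   `node_j` for the connection block (e.g. [strength_table()] filtered to
#'   `block == "connectomic"`, or any tibble with those columns).
#' @param n_nodes Number of nodes.
#' @param q_threshold FDR threshold for including a connection.
#' @param method `"sum"` (default) or `"mean"` aggregation.
#' @return Tibble with `node`, `n_significant`, `total_strength`, `class`.
#' @export
compute_hubs <- function(strengths, n_nodes, q_threshold = 0.05,
                         method = c("sum", "mean")) {
  method <- match.arg(method)
  stopifnot(all(c("strength", "q", "node_i", "node_j") %in% names(strengths)))
  sig <- strengths[!is.na(strengths$q) & strengths$q < q_threshold, , drop = FALSE]
  long <- dplyr::bind_rows(
    tibble::tibble(node = sig$node_i, strength = sig$strength),
    tibble::tibble(node = sig$node_j, strength = sig$strength)
  )
  agg <- long |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(
      n_significant = dplyr::n(),
      total_strength = if (method == "sum") sum(.data$strength) else
        mean(.data$strength),
      .groups = "drop"
    )
  out <- dplyr::left_join(tibble::tibble(node = seq_len(n_nodes)), agg,
                          by = "node")
  out$n_significant[is.na(out$n_significant)] <- 0L
  out$total_strength[is.na(out$total_strength)] <- 0
  out$class <- dplyr::case_when(
    out$n_significant == 0 ~ "none",
    out$total_strength < 0 ~ "hypo",
    out$total_strength > 0 ~ "hyper",
    TRUE ~ "none"
  )
  attr(out, "method") <- method
  out
}
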