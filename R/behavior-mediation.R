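# one-tailed p for H1: r > 0, from the t transform of a Pearson correlation
cor_p_greater <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  stats::pt(t, n - 2, lower.tail = FALSE)
}

#' Correlate a connectomic canonical score with adjusted behaviors
#'
#' Pearson correlation on pairwise-complete observations per variable, with
#' a one-tailed p-value for the vulnerability direction (H1: `r > 0`,
#' since behaviors are encoded so that higher values mean higher
#' psychiatric vulnerability). Variables with fewer than three complete
#' pairs are skipped with a message.
#'
#' @param conn_score Connectomic canonical score (aligned with behavior
#'   rows).
#' @param behaviors_adj Tibble of adjusted behavior values (columns other
#'   than `subject_id`), e.g. from [adjust_behaviors()].
#' @return Tibble with `variable`, `n`, `r`, `p_one_tailed`.
#' @export
behavior_correlations <- function(conn_score, behaviors_adj) {
  vars <- setdiff(names(behaviors_adj), "subject_id")
  rows <- lapply(vars, function(nm) {
    y <- behaviors_adj[[nm]]
    ok <- !is.na(y) & !is.na(conn_score)
    if (sum(ok) < 3) {
      message("behavior_correlations: skipping `", nm,
              "` (fewer than 3 complete pairs)")
      return(NULL)
    }
    if (stats::sd(y[ok]) == 0 || stats::sd(conn_score[ok]) == 0) {
      message("behavior_correlations: skipping `", nm, "` (zero variance)")
      return(NULL)
    }
    r <- stats::cor(conn_score[ok], y[ok])
    tibble::tibble(variable = nm, n = sum(ok), r = r,
                   p_one_tailed = cor_p_greater(r, sum(ok)))
  })
  dplyr::bind_rows(rows)
}

#' Permutation-based combined probability test for dependent p-values
#'
#' Fisher's statistic `T = -2 * sum(log p_i)` aggregated over a set of
#' one-tailed p-values, calibrated by permutation so that dependence among
#' the tests (behaviors are correlated with each other) is respected: for
#' each permutation `recompute_fn` receives a shuffled subject index and
#' must return the full recomputed p-value set, preserving inter-variable
#' dependence. The combined p is `(1 + #(T_b >= T_obs)) / (B + 1)`.
#' Zero p-values are clamped to `1 / (B + 1)` with a warning before taking
#' logs.
#'
#' @param p_obs Observed one-tailed p-values.
#' @param recompute_fn Function of one argument (a permutation of
#'   `seq_len(n_units)`) returning the recomputed p-value vector.
#' @param n_units Number of exchangeable units (subjects) to shuffle.
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return A `combined_test`: list with `statistic` (T_obs), `p`
#'   (combined p), `p_inputs`, `null_statistics`, `B`.
#' @export
combined_probability_test <- function(p_obs, recompute_fn, n_units,
                                      B = 1000, seed = NULL) {
  if (B < 1) stop("`B` must be at least 1", call. = FALSE)
  clamp <- function(p) {
    if (any(p <= 0, na.rm = TRUE)) {
      warning("p-value(s) of 0 clamped to 1/(B+1)", call. = FALSE)
    }
    pmax(p, 1 / (B + 1))
  }
  p_obs <- clamp(p_obs[!is.na(p_obs)])
  if (length(p_obs) == 0) stop("no p-values to combine", call. = FALSE)
  t_obs <- -2 * sum(log(p_obs))
  if (!is.null(seed)) set.seed(as.integer(seed))
  t_null <- vapply(seq_len(B), function(b) {
    p_b <- recompute_fn(sample.int(n_units))
    p_b <- clamp(p_b[!is.na(p_b)])
    -2 * sum(log(p_b))
  }, numeric(1))
  structure(
    list(statistic = t_obs, p = (1 + sum(t_null >= t_obs)) / (B + 1),
         p_inputs = p_obs, null_statistics = t_null, B = B),
    class = "combined_test"
  )
}

#' @export
print.combined_test <- function(x, ...) {
  cat(sprintf("<combined_test> T = %.2f over %d p-values, B = %d, combined p = %.4g\n",
              x$statistic, length(x$p_inputs), x$B, x$p))
  invisible(x)
}

#' Combined test of behavior-score correlations
#'
#' Wraps [behavior_correlations()] and [combined_probability_test()]: the
#' connectomic canonical score is shuffled against the (jointly held)
#' behavior rows, preserving the dependence between behaviors.
#'
#' @inheritParams behavior_correlations
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return List with `correlations` (observed tibble) and `test`
#'   (`combined_test`).
#' @export
behavior_combined_test <- function(conn_score, behaviors_adj, B = 1000,
                                   seed = NULL) {
  obs <- behavior_correlations(conn_score, behaviors_adj)
  if (nrow(obs) == 0) stop("no usable behavior variables", call. = FALSE)
  vars <- obs$variable
  recompute <- function(perm) {
    s <- conn_score[perm]
    vapply(vars, function(nm) {
      y <- behaviors_adj[[nm]]
      ok <- !is.na(y) & !is.na(s)
      if (sum(ok) < 3 || stats::sd(y[ok]) == 0 || stats::sd(s[ok]) == 0) {
        return(NA_real_)
      }
      cor_p_greater(stats::cor(s[ok], y[ok]), sum(ok))
    }, numeric(1))
  }
  test <- combined_probability_test(obs$p_one_tailed, recompute,
                                    n_units = length(conn_score),
                                    B = B, seed = seed)
  list(correlations = obs, test = test)
}

# closed-form single-mediator OLS mediation; equivalent to lm() fits,
# verified against them in the test suite
fast_mediate <- function(x, m, y) {
  n <- length(y)
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  sxx <- sum(xc^2); smm <- sum(mc^2); sxm <- sum(xc * mc)
  sxy <- sum(xc * yc); smy <- sum(mc * yc)
  if (sxx == 0 || smm == 0 || sum(yc^2) == 0) {
    stop("zero variance in x, m or y", call. = FALSE)
  }
  det <- sxx * smm - sxm^2
  if (det <= 0) stop("x and m are collinear", call. = FALSE)
  b <- (sxx * smy - sxm * sxy) / det
  cprime <- (smm * sxy - sxm * smy) / det
  resid2 <- yc - cprime * xc - b * mc
  s2 <- sum(resid2^2) / (n - 3)
  se_b <- sqrt(s2 * sxx / det)
  se_c <- sqrt(s2 * smm / det)
  a <- sxm / sxx
  resid1 <- mc - a * xc
  se_a <- sqrt(sum(resid1^2) / (n - 2) / sxx)
  indirect <- a * b
  se_ind <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  list(a = a, se_a = se_a, b = b, se_b = se_b, cprime = cprime, se_c = se_c,
       indirect = indirect, se_indirect = se_ind,
       p_one_tailed = stats::pnorm(indirect / se_ind, lower.tail = FALSE),
       total = sxy / sxx, n = n)
}

#' Single-mediator mediation of genetic risk through the connectome
#'
#' Two-equation OLS mediation: `a` from `m ~ x`, `b` and `c'` from
#' `y ~ x + m`, indirect effect `a * b` with the Sobel standard error
#' `sqrt(a^2 se_b^2 + b^2 se_a^2)` and a one-tailed p for a positive
#' indirect effect. For continuous outcomes the decomposition
#' `total = c' + a * b` holds exactly. Here `x` is the genetic canonical
#' score, `m` the connectomic canonical score and `y` an age/sex-adjusted
#' behavior; dichotomous behaviors enter through their adjusted
#' (residualized) continuous form so OLS applies throughout.
#'
#' @param x Independent variable (genetic canonical score).
#' @param m Mediator (connectomic canonical score).
#' @param y Outcome (adjusted behavior; `NA` rows dropped listwise).
#' @return One-row tibble: `a`, `se_a`, `b`, `se_b`, `cprime`, `se_cprime`,
#'   `indirect`, `se_indirect`, `p_one_tailed`, `total`, `n`.
#' @export
mediate <- function(x, m, y) {
  ok <- !is.na(x) & !is.na(m) & !is.na(y)
  if (sum(ok) < 5) stop("fewer than 5 complete cases", call. = FALSE)
  f <- fast_mediate(x[ok], m[ok], y[ok])
  tibble::tibble(
    a = f$a, se_a = f$se_a, b = f$b, se_b = f$se_b,
    cprime = f$cprime, se_cprime = f$se_c,
    indirect = f$indirect, se_indirect = f$se_indirect,
    p_one_tailed = f$p_one_tailed, total = f$total, n = f$n
  )
}

#' Mediation of all behavior variables
#'
#' @inheritParams mediate
#' @param behaviors_adj Tibble of adjusted behaviors.
#' @return Tibble with one row per usable variable (prefixed by
#'   `variable`).
#' @export
mediate_behaviors <- function(x, m, behaviors_adj) {
  vars <- setdiff(names(behaviors_adj), "subject_id")
  rows <- lapply(vars, function(nm) {
    y <- behaviors_adj[[nm]]
    res <- tryCatch(mediate(x, m, y), error = function(e) NULL)
    if (is.null(res)) {
      message("mediate_behaviors: skipping `", nm, "`")
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(variable = nm), res)
  })
  dplyr::bind_rows(rows)
}

#' Combined permutation test of mediation across behaviors
#'
#' Aggregates the per-variable one-tailed indirect-effect p-values with the
#' same permutation-based Fisher machinery as
#' [combined_probability_test()]. The null shuffles the mediator rows
#' jointly against the `(x, y)` pairs — the minimal scheme that breaks both
#' the `a` and `b` paths while preserving the direct x-y relation.
#'
#' @inheritParams mediate_behaviors
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return List with `mediation` (observed tibble) and `test`
#'   (`combined_test`).
#' @export
combined_mediation_test <- function(x, m, behaviors_adj, B = 1000,
                                    seed = NULL) {
  obs <- mediate_behaviors(x, m, behaviors_adj)
  if (nrow(obs) == 0) stop("no usable behavior variables", call. = FALSE)
  vars <- obs$variable
  recompute <- function(perm) {
    mp <- m[perm]
    vapply(vars, function(nm) {
      y <- behaviors_adj[[nm]]
      ok <- !is.na(x) & !is.na(mp) & !is.na(y)
      if (sum(ok) < 5) return(NA_real_)
      out <- tryCatch(fast_mediate(x[ok], mp[ok], y[ok])$p_one_tailed,
                      error = function(e) NA_real_)
      out
    }, numeric(1))
  }
  test <- combined_probability_test(obs$p_one_tailed, recompute,
                                    n_units = length(m), B = B, seed = seed)
  list(mediation = obs, test = test)
}
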