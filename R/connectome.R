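#' Canonical edge index for an n-node symmetric connectome
#'
#' Row-major upper-triangle ordering: `(1,2), (1,3), ..., (1,n), (2,3), ...`.
#' Internal edge positions are 1-based row numbers of this table; node labels
#' are 1-based.
#'
#' @param n_nodes Number of nodes.
#' @param labels Optional character node labels (length `n_nodes`).
#' @return Tibble with `edge_id` (character, `e%06d`), `node_i`, `node_j`
#'   (integer, `i < j`) and, when labels are given, `label_i`/`label_j`.
#' @export
#' @examples
#' edge_index(4)$edge_id
edge_index <- function(n_nodes, labels = NULL) {
  stopifnot(n_nodes >= 2)
  pairs <- do.call(rbind, lapply(seq_len(n_nodes - 1), function(i) {
    cbind(i, seq.int(i + 1, n_nodes))
  }))
  out <- tibble::tibble(
    edge_id = sprintf("e%06d", seq_len(nrow(pairs))),
    node_i = as.integer(pairs[, 1]),
    node_j = as.integer(pairs[, 2])
  )
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_nodes)
    out$label_i <- labels[out$node_i]
    out$label_j <- labels[out$node_j]
  }
  out
}

new_connectome_set <- function(edge_data, n_nodes, nodes = NULL) {
  if (is.null(nodes)) nodes <- sprintf("region_%03d", seq_len(n_nodes))
  structure(
    list(edge_data = edge_data, n_nodes = as.integer(n_nodes), nodes = nodes,
         edges = edge_index(n_nodes)),
    class = "connectome_set"
  )
}

#' Build a connectome set from per-subject symmetric matrices
#'
#' Validates each matrix (symmetric within `tol`, finite, zero/ignored
#' diagonal, consistent dimension) and stores the vectorized upper triangle.
#'
#' @param matrices Named list of `n_nodes x n_nodes` numeric matrices (names
#'   are subject ids).
#' @param nodes Optional node labels.
#' @param tol Symmetry tolerance (default `1e-10`).
#' @return A `connectome_set`.
#' @export
connectome_set <- function(matrices, nodes = NULL, tol = 1e-10) {
  stopifnot(is.list(matrices), length(matrices) > 0)
  if (is.null(names(matrices))) {
    names(matrices) <- sprintf("S%04d", seq_along(matrices))
  }
  n_nodes <- nrow(matrices[[1]])
  ei <- edge_index(n_nodes)
  idx <- cbind(ei$node_i, ei$node_j)
  edge_data <- matrix(NA_real_, length(matrices), nrow(ei),
                      dimnames = list(names(matrices), ei$edge_id))
  for (s in seq_along(matrices)) {
    m <- matrices[[s]]
    id <- names(matrices)[s]
    if (!is.matrix(m) || nrow(m) != n_nodes || ncol(m) != n_nodes) {
      stop("connectome for subject ", id, " is not ", n_nodes, " x ", n_nodes,
           call. = FALSE)
    }
    if (any(!is.finite(m[idx])) || any(!is.finite(m[idx[, 2:1]]))) {
      stop("connectome for subject ", id, " contains non-finite entries",
           call. = FALSE)
    }
    d <- abs(m - t(m))
    if (max(d) > tol) {
      worst <- arrayInd(which.max(d), dim(d))
      stop(sprintf(
        "connectome for subject %s is asymmetric: |[%d,%d] - [%d,%d]| = %.3g exceeds %g",
        id, worst[1], worst[2], worst[2], worst[1], max(d), tol), call. = FALSE)
    }
    edge_data[s, ] <- m[idx]
  }
  new_connectome_set(edge_data, n_nodes, nodes)
}

#' @export
print.connectome_set <- function(x, ...) {
  cat(sprintf("<connectome_set> %d subjects, %d nodes, %d connections\n",
              nrow(x$edge_data), x$n_nodes, ncol(x$edge_data)))
  invisible(x)
}

#' Vectorize a connectome set to a subjects x connections matrix
#'
#' @param connectomes A `connectome_set`.
#' @return Numeric matrix (subjects x `n_nodes*(n_nodes-1)/2`) with edge ids
#'   as column names; the edge index tibble is attached as attribute
#'   `"edges"`.
#' @export
vectorize_connectomes <- function(connectomes) {
  stopifnot(inherits(connectomes, "connectome_set"))
  out <- connectomes$edge_data
  attr(out, "edges") <- connectomes$edges
  out
}

#' Restore per-subject symmetric matrices from vectorized connections
#'
#' Inverse of [vectorize_connectomes()]: rebuilds symmetric matrices with a
#' zero diagonal.
#'
#' @param edge_data Subjects x connections matrix in canonical edge order.
#' @param n_nodes Number of nodes.
#' @return Named list of symmetric `n_nodes x n_nodes` matrices.
#' @export
devectorize_connectomes <- function(edge_data, n_nodes) {
  ei <- edge_index(n_nodes)
  stopifnot(ncol(edge_data) == nrow(ei))
  idx <- cbind(ei$node_i, ei$node_j)
  subj <- rownames(edge_data)
  if (is.null(subj)) subj <- sprintf("S%04d", seq_len(nrow(edge_data)))
  out <- lapply(seq_len(nrow(edge_data)), function(s) {
    m <- matrix(0, n_nodes, n_nodes)
    m[idx] <- edge_data[s, ]
    m[idx[, 2:1]] <- edge_data[s, ]
    m
  })
  setNames(out, subj)
}

build_confound_design <- function(covariates, covariate_cols = NULL) {
  stopifnot(is.data.frame(covariates))
  df <- as.data.frame(covariates)
  drop <- intersect("subject_id", names(df))
  df <- df[, setdiff(names(df), drop), drop = FALSE]
  if (!is.null(covariate_cols)) {
    missing_cols <- setdiff(covariate_cols, names(df))
    if (length(missing_cols) > 0) {
      stop("unknown covariate columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    df <- df[, covariate_cols, drop = FALSE]
  }
  if (anyNA(df)) stop("covariates contain missing values", call. = FALSE)
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  }
  stats::model.matrix(~ ., data = df)
}

#' Residualize a feature matrix on study confounds
#'
#' Per-feature ordinary-least-squares residualization on age, sex, scanner
#' (one-hot with a dropped reference level) and genetic ancestry factors,
#' with an intercept. Residual columns have exactly zero mean and zero
#' sample correlation with every covariate column (up to numerical
#' round-off, well inside `1e-8`).
#'
#' @param X Subjects x features numeric matrix (rows aligned with
#'   `covariates`).
#' @param covariates Covariate data frame; a `subject_id` column is ignored,
#'   character/logical columns are treated as categorical.
#' @param covariate_cols Optional subset of covariate columns to adjust for
#'   (e.g. GAFs only, used when also adjusting the genotype block).
#' @return Residual matrix with the dimnames of `X`.
#' @export
adjust_confounds <- function(X, covariates, covariate_cols = NULL) {
  X <- as.matrix(X)
  design <- build_confound_design(covariates, covariate_cols)
  if (nrow(design) != nrow(X)) {
    stop("covariate rows do not align with the feature matrix", call. = FALSE)
  }
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[(qd$rank + 1):ncol(design)]]
    stop("confound design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qd, X)
  dimnames(res) <- dimnames(X)
  res
}

new_behavior_table <- function(data, info) {
  stopifnot(is.data.frame(data), is.data.frame(info),
            "subject_id" %in% names(data),
            all(info$name %in% names(data)))
  structure(list(data = tibble::as_tibble(data), info = tibble::as_tibble(info)),
            class = "behavior_table")
}

#' Construct a behavior table
#'
#' @param data Tibble with a `subject_id` column and one numeric column per
#'   behavior (missing values allowed; dichotomous variables coded 0/1).
#' @param info Tibble with one row per behavior: `name`, `type`
#'   (`"continuous"` or `"dichotomous"`), optional `vulnerability_sign`.
#' @return A `behavior_table`.
#' @export
behavior_table <- function(data, info) {
  info <- tibble::as_tibble(info)
  stopifnot(all(c("name", "type") %in% names(info)),
            all(info$type %in% c("continuous", "dichotomous")))
  if (!"vulnerability_sign" %in% names(info)) info$vulnerability_sign <- 1
  for (nm in info$name[info$type == "dichotomous"]) {
    lev <- unique(stats::na.omit(data[[nm]]))
    if (length(lev) > 2) {
      stop("dichotomous behavior `", nm, "` has more than two observed levels",
           call. = FALSE)
    }
  }
  new_behavior_table(data, info)
}

#' @export
print.behavior_table <- function(x, ...) {
  cat(sprintf("<behavior_table> %d subjects, %d variables (%d dichotomous)\n",
              nrow(x$data), nrow(x$info), sum(x$info$type == "dichotomous")))
  invisible(x)
}

#' Filter behavior variables by observation count and minority prevalence
#'
#' Keeps variables with strictly more than ten non-missing observations;
#' dichotomous variables additionally need their minority level to cover at
#' least 5% of non-missing observations.
#'
#' @param behaviors A [behavior_table()].
#' @param min_obs Observation threshold; variables with `<= min_obs`
#'   non-missing values are dropped.
#' @param min_minority Minimum minority-level fraction for dichotomous
#'   variables.
#' @return Filtered `behavior_table` (possibly with zero variables).
#' @export
filter_behaviors <- function(behaviors, min_obs = 10, min_minority = 0.05) {
  stopifnot(inherits(behaviors, "behavior_table"))
  keep <- vapply(seq_len(nrow(behaviors$info)), function(j) {
    nm <- behaviors$info$name[j]
    y <- behaviors$data[[nm]]
    y <- y[!is.na(y)]
    if (length(y) <= min_obs) return(FALSE)
    if (behaviors$info$type[j] == "dichotomous") {
      tab <- table(y)
      if (length(tab) < 2) return(FALSE)
      if (min(tab) / length(y) < min_minority) return(FALSE)
    }
    TRUE
  }, logical(1))
  dropped <- behaviors$info$name[!keep]
  if (length(dropped) > 0) {
    message("filter_behaviors: dropped ", length(dropped), " variable(s): ",
            paste(dropped, collapse = ", "))
  }
  new_behavior_table(
    behaviors$data[, c("subject_id", behaviors$info$name[keep]), drop = FALSE],
    behaviors$info[keep, , drop = FALSE]
  )
}

#' Adjust behavior variables for age and sex
#'
#' Continuous variables are replaced by OLS residuals of `y ~ age + sex`;
#' dichotomous variables by response residuals `y - fitted` from a logistic
#' regression on the same terms (deviance residuals behind
#' `logistic_residual = "deviance"`). Each variable uses its own non-missing
#' rows; missing rows stay missing. When the logistic fit fails to converge
#' or separates, the variable falls back to linear-probability-model
#' residuals with a warning.
#'
#' @param behaviors A [behavior_table()] (normally already filtered).
#' @param covariates Covariate table with `age` and `sex` aligned to
#'   `behaviors$data` rows.
#' @param logistic_residual `"response"` (default) or `"deviance"`.
#' @return Tibble with `subject_id` and one adjusted column per behavior.
#' @export
adjust_behaviors <- function(behaviors, covariates,
                             logistic_residual = c("response", "deviance")) {
  stopifnot(inherits(behaviors, "behavior_table"))
  logistic_residual <- match.arg(logistic_residual)
  stopifnot(nrow(covariates) == nrow(behaviors$data),
            all(c("age", "sex") %in% names(covariates)))
  out <- tibble::tibble(subject_id = behaviors$data$subject_id)
  for (j in seq_len(nrow(behaviors$info))) {
    nm <- behaviors$info$name[j]
    y <- behaviors$data[[nm]]
    ok <- !is.na(y)
    adj <- rep(NA_real_, length(y))
    if (sum(ok) >= 3) {
      df <- data.frame(y = y[ok], age = covariates$age[ok], sex = covariates$sex[ok])
      if (behaviors$info$type[j] == "continuous") {
        adj[ok] <- stats::residuals(stats::lm(y ~ age + sex, data = df))
      } else {
        yy <- df$y
        if (!all(yy %in% c(0, 1))) yy <- as.integer(factor(yy)) - 1L
        df$y <- yy
        fit <- suppressWarnings(
          stats::glm(y ~ age + sex, family = stats::binomial(), data = df))
        fitted_p <- stats::fitted(fit)
        separated <- any(fitted_p < 1e-8 | fitted_p > 1 - 1e-8)
        if (!fit$converged || separated) {
          warning("logistic adjustment for `", nm,
                  "` did not converge; using linear-probability residuals",
                  call. = FALSE)
          adj[ok] <- stats::residuals(stats::lm(y ~ age + sex, data = df))
        } else if (logistic_residual == "response") {
          adj[ok] <- df$y - fitted_p
        } else {
          adj[ok] <- stats::residuals(fit, type = "deviance")
        }
      }
    }
    out[[nm]] <- adj
  }
  out
}
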