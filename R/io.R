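# All files are UTF-8 tab-separated with '.' decimals and 'NA' missing.
# read_tsv_strict() turns any parsing problem into an error naming the
# column and line.
read_tsv_strict <- function(path, col_types) {
  out <- suppressWarnings(readr::read_tsv(path, col_types = col_types,
                                          na = "NA", progress = FALSE))
  pb <- readr::problems(out)
  if (nrow(pb) > 0) {
    col <- suppressWarnings(as.integer(pb$col[1]))
    col_name <- if (!is.na(col) && col <= ncol(out)) names(out)[col] else
      as.character(pb$col[1])
    stop(sprintf("schema violation in %s: column %s, line %d (%s, got '%s')",
                 basename(path), col_name, pb$row[1],
                 pb$expected[1], pb$actual[1]),
         call. = FALSE)
  }
  out
}

#' Write / read a genotype table
#'
#' `genotypes.tsv` holds the dosage matrix (first column `subject_id`, one
#' column per SNP id); `snp_info.tsv` holds the SNP metadata (one row per
#' SNP-phenotype annotation).
#'
#' @param genotypes A `genotype_table`.
#' @param dir Output directory (created if needed).
#' @return `write_genotype_table()` the directory invisibly;
#'   `read_genotype_table()` a `genotype_table`.
#' @export
write_genotype_table <- function(genotypes, dir) {
  stopifnot(inherits(genotypes, "genotype_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dos <- tibble::as_tibble(genotypes$dosages)
  dos <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(genotypes$dosages)),
                          dos)
  readr::write_tsv(dos, file.path(dir, "genotypes.tsv"), na = "NA")
  readr::write_tsv(genotypes$snp_info, file.path(dir, "snp_info.tsv"), na = "NA")
  invisible(dir)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(dir) {
  dos <- read_tsv_strict(file.path(dir, "genotypes.tsv"),
                         readr::cols(subject_id = readr::col_character(),
                                     .default = readr::col_double()))
  info <- read_tsv_strict(
    file.path(dir, "snp_info.tsv"),
    readr::cols(snp_id = readr::col_character(),
                effect_allele = readr::col_character(),
                phenotype = readr::col_character(),
                phenotype_group = readr::col_character(),
                gwas_p = readr::col_double())
  )
  M <- as.matrix(dos[, -1, drop = FALSE])
  rownames(M) <- dos$subject_id
  n_missing <- sum(is.na(M))
  if (n_missing > 0) message("read_genotype_table: ", n_missing, " missing dosage(s)")
  maf <- colMeans(M, na.rm = TRUE) / 2
  structure(list(dosages = M, snp_info = info, maf = maf, ld_block = NULL),
            class = "genotype_table")
}

#' Write / read a connectome set as per-subject square TSV files
#'
#' Each subject gets one `n_nodes x n_nodes` symmetric square TSV (node
#' labels as header, zero diagonal); `manifest.tsv` maps `subject_id` to
#' file name and `edge_index.tsv` documents the canonical edge ordering
#' (1-based node labels). Reading validates symmetry and halts naming the
#' offending subject.
#'
#' @param connectomes A `connectome_set`.
#' @param dir Output directory.
#' @return `write_connectomes()` the directory invisibly;
#'   `read_connectomes()` a `connectome_set`.
#' @export
write_connectomes <- function(connectomes, dir) {
  stopifnot(inherits(connectomes, "connectome_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mats <- devectorize_connectomes(connectomes$edge_data, connectomes$n_nodes)
  files <- sprintf("connectome_%s.tsv", names(mats))
  for (s in seq_along(mats)) {
    m <- tibble::as_tibble(mats[[s]], .name_repair = ~ connectomes$nodes)
    readr::write_tsv(m, file.path(dir, files[s]), na = "NA")
  }
  readr::write_tsv(tibble::tibble(subject_id = names(mats), file = files),
                   file.path(dir, "manifest.tsv"))
  readr::write_tsv(connectomes$edges, file.path(dir, "edge_index.tsv"))
  invisible(dir)
}

#' @rdname write_connectomes
#' @export
read_connectomes <- function(dir) {
  manifest <- read_tsv_strict(file.path(dir, "manifest.tsv"),
                              readr::cols(subject_id = readr::col_character(),
                                          file = readr::col_character()))
  mats <- lapply(seq_len(nrow(manifest)), function(s) {
    m <- read_tsv_strict(file.path(dir, manifest$file[s]),
                         readr::cols(.default = readr::col_double()))
    as.matrix(m)
  })
  names(mats) <- manifest$subject_id
  nodes <- colnames(mats[[1]])
  cs <- connectome_set(mats, nodes = nodes)
  cs
}

#' Write / read a covariate table
#'
#' @param covariates Covariate tibble (`subject_id`, `age`, `sex`,
#'   `scanner`, GAF columns).
#' @param path File path.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path, na = "NA")
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  read_tsv_strict(path, readr::cols(subject_id = readr::col_character(),
                                    scanner = readr::col_character(),
                                    .default = readr::col_double()))
}

#' Write / read a behavior table
#'
#' The file carries a `type` header row (second line, `continuous` or
#' `dichotomous` per variable) between the column names and the data.
#'
#' @param behaviors A `behavior_table`.
#' @param path File path.
#' @export
write_behaviors <- function(behaviors, path) {
  stopifnot(inherits(behaviors, "behavior_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  vars <- behaviors$info$name
  writeLines(paste(c("subject_id", vars), collapse = "\t"), con)
  writeLines(paste(c("type", behaviors$info$type), collapse = "\t"), con)
  dat <- behaviors$data[, c("subject_id", vars), drop = FALSE]
  body <- do.call(paste, c(lapply(dat, function(x) {
    ifelse(is.na(x), "NA", format(x, digits = 17, trim = TRUE, scientific = FALSE))
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_behaviors
#' @export
read_behaviors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  types <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (types[1] != "type") {
    stop("behavior file lacks the `type` header row", call. = FALSE)
  }
  dat <- read_tsv_strict(I(paste(lines[-2], collapse = "\n")),
                         readr::cols(subject_id = readr::col_character(),
                                     .default = readr::col_double()))
  behavior_table(dat, tibble::tibble(name = header[-1], type = types[-1]))
}

#' Write / read GWAS summary statistics (SNP, A1, BETA, P)
#'
#' @param sumstats Tibble with `snp_id`, `effect_allele`, `beta`, `p`.
#' @param path File path.
#' @export
write_sumstats <- function(sumstats, path) {
  # 17 significant digits: the text round trip preserves doubles to the ulp
  out <- tibble::tibble(SNP = sumstats$snp_id, A1 = sumstats$effect_allele,
                        BETA = sprintf("%.17g", sumstats$beta),
                        P = sprintf("%.17g", sumstats$p))
  out$BETA[is.na(sumstats$beta)] <- NA
  out$P[is.na(sumstats$p)] <- NA
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  raw <- read_tsv_strict(path, readr::cols(SNP = readr::col_character(),
                                           A1 = readr::col_character(),
                                           BETA = readr::col_double(),
                                           P = readr::col_double()))
  tibble::tibble(snp_id = raw$SNP, effect_allele = raw$A1,
                 beta = raw$BETA, p = raw$P)
}

#' Write / read a strength table
#'
#' @param strengths Tibble from [strength_table()].
#' @param path File path.
#' @export
write_strengths <- function(strengths, path) {
  readr::write_tsv(strengths, path, na = "NA")
  invisible(path)
}

#' @rdname write_strengths
#' @export
read_strengths <- function(path) {
  read_tsv_strict(path, readr::cols(feature = readr::col_character(),
                                    block = readr::col_character(),
                                    group = readr::col_character(),
                                    .default = readr::col_double()))
}

#' Write ground truth as JSON
#'
#' @param truth A `ground_truth`.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth[c("causal_snp_ids", "signal_connection_ids",
                 "true_genetic_weights", "true_connection_effects",
                 "latent_g", "latent_m", "rho")]
  out$behavior_paths <- truth$behavior_paths
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic-study pipeline end to end
#'
#' Simulates a study, writes all inputs, then executes SNP selection,
#' connectome preparation, CCA, permutation inference, PRS, behavior /
#' mediation analysis, and a light robustness pass, writing each stage's
#' artifacts plus a provenance manifest (`manifest.json` with stage list,
#' seeds and a configuration hash). Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Run directory (created).
#' @param n_components PCA components per block.
#' @param B_modes,B_prs,B_behavior Permutation counts for mode inference,
#'   the PRS threshold scan and the behavior/mediation combined tests.
#' @param write_inputs Also write the simulated input files (slow for
#'   study-sized configs because of the per-subject connectome files).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_study_pipeline <- function(config = sim_config(), out_dir,
                               n_components = 100,
                               B_modes = 10000, B_prs = 10000,
                               B_behavior = 1000,
                               write_inputs = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- sim_seeds(config$seed)
  stages <- character(0)
  log_stage <- function(s) stages <<- c(stages, s)

  study <- simulate_study(config)
  log_stage("simulate")
  if (write_inputs) {
    write_genotype_table(study$genotypes, file.path(out_dir, "inputs"))
    write_connectomes(study$connectomes, file.path(out_dir, "inputs", "connectomes"))
    write_covariates(study$covariates, file.path(out_dir, "inputs", "covariates.tsv"))
    write_behaviors(study$behaviors, file.path(out_dir, "inputs", "behaviors.tsv"))
    write_sumstats(study$sumstats, file.path(out_dir, "inputs", "sumstats.tsv"))
    write_ground_truth(study$truth, file.path(out_dir, "inputs", "ground_truth.json"))
  }

  selected <- select_snps(study$genotypes$snp_info,
                          colnames(study$genotypes$dosages))
  readr::write_tsv(selected[, c("snp_id", "provenance")],
                   file.path(out_dir, "selected_snps.tsv"))
  log_stage("select-snps")

  dosages <- study$genotypes$dosages[, selected$snp_id, drop = FALSE]
  edge_data <- vectorize_connectomes(study$connectomes)
  edges <- attr(edge_data, "edges")
  behaviors_f <- filter_behaviors(study$behaviors)
  behaviors_adj <- adjust_behaviors(behaviors_f, study$covariates)
  log_stage("prep")

  pipe <- run_cca_pipeline(dosages, edge_data, study$covariates, n_components)
  log_stage("cca")

  perm <- permutation_test_modes(pipe$pca_u$scores, pipe$pca_v$scores,
                                 B = B_modes, seed = seeds[["pipeline"]],
                                 Xu = pipe$Xu, Xv = pipe$Xv)
  # carry the pipeline's orientation into the reported strengths
  if (pipe$fit$flipped[1]) {
    perm$strengths$u$strength <- -perm$strengths$u$strength
    perm$strengths$v$strength <- -perm$strengths$v$strength
  }
  st <- strength_table(perm, snp_info = study$genotypes$snp_info, edges = edges)
  write_strengths(st, file.path(out_dir, "strengths.tsv"))
  jsonlite::write_json(perm$modes, file.path(out_dir, "modes.json"),
                       dataframe = "rows", digits = NA)
  log_stage("permtest")

  conn_score <- pipe$fit$scores_v[, 1]
  gafs <- as.matrix(study$covariates[, grep("^gaf", names(study$covariates)),
                                     drop = FALSE])
  grid <- build_threshold_grid(0.05)
  prs_fit <- prs_scan(conn_score, study$genotypes, study$sumstats, gafs, grid)
  prs_perm <- prs_permutation_test(conn_score, study$genotypes, study$sumstats,
                                   gafs, grid, B = B_prs,
                                   seed = seeds[["pipeline"]] %% 100000L + 1L)
  readr::write_tsv(prs_fit$profile, file.path(out_dir, "prs_profile.tsv"))
  log_stage("prs")

  beh <- behavior_combined_test(conn_score, behaviors_adj, B = B_behavior,
                                seed = seeds[["pipeline"]] %% 100000L + 2L)
  med <- combined_mediation_test(pipe$fit$scores_u[, 1], conn_score,
                                 behaviors_adj, B = B_behavior,
                                 seed = seeds[["pipeline"]] %% 100000L + 3L)
  readr::write_tsv(beh$correlations, file.path(out_dir, "behavior_correlations.tsv"))
  readr::write_tsv(med$mediation, file.path(out_dir, "mediation.tsv"))
  log_stage("behavior")

  mean_conn <- mean_connectivity_correlation(edge_data, conn_score, B = 999,
                                             seed = seeds[["pipeline"]] %% 100000L + 4L)
  hubs <- compute_hubs(st[st$block == "connectomic", ], config$n_nodes)
  readr::write_tsv(hubs, file.path(out_dir, "hubs.tsv"))
  log_stage("robustness")

  results <- list(
    study = study, selected = selected, pipeline = pipe, permutation = perm,
    strengths = st, prs = prs_fit, prs_permutation = prs_perm,
    behavior = beh, mediation = med, mean_connectivity = mean_conn,
    hubs = hubs
  )
  manifest <- list(
    package = "neurocca",
    version = as.character(utils::packageVersion("neurocca")),
    stages = stages,
    seed = config$seed,
    derived_seeds = as.list(seeds),
    config_hash = rlang::hash(unclass(config)),
    n_components = n_components,
    permutations = list(modes = B_modes, prs = B_prs, behavior = B_behavior)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
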