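#' @importFrom stats rnorm runif rbinom plogis qlogis qnorm pnorm setNames sd
NULL

# Phenotype pool used to annotate synthetic SNPs. Groups mirror the GWAS
# catalog categories a risk-SNP screen would draw from, plus control
# phenotypes (diseases with a genetic basis but no expected connectome link).
sim_phenotype_pool <- function() {
  tibble::tribble(
    ~phenotype, ~phenotype_group, ~weight,
    "schizophrenia", "psychiatric", 4,
    "bipolar disorder", "psychiatric", 3,
    "major depressive disorder", "psychiatric", 3,
    "autism spectrum disorder", "psychiatric", 2,
    "attention-deficit hyperactivity disorder", "psychiatric", 2,
    "alcohol use disorder", "psychiatric", 2,
    "cross-disorder", "psychiatric", 2,
    "anxiety disorder", "psychiatric", 1,
    "epilepsy", "neurological", 1.5,
    "migraine without aura", "neurological", 1,
    "parkinson disease", "neurological", 1,
    "alzheimer disease", "neurological", 1,
    "educational attainment", "behavior-cognition", 2,
    "cognitive performance", "behavior-cognition", 1.5,
    "risk-taking behavior", "behavior-cognition", 1,
    "white matter hyperintensity", "brain-morphology-function", 1,
    "subcortical volume", "brain-morphology-function", 1,
    "asthma", "control", 1,
    "type 2 diabetes", "control", 1
  )
}

#' Simulate a genotype dosage matrix with SNP metadata
#'
#' Draws per-SNP minor allele frequencies uniformly from
#' `config$maf_range`, then dosages as `Binomial(2, MAF)` effect-allele
#' counts (two independent haplotypes). Each SNP is annotated with one or
#' occasionally two catalog phenotypes and a synthetic genome-wide
#' significant GWAS p-value (`< 5e-8`), so the metadata doubles as a
#' GWAS-catalog table for [select_snps()]. With `config$ld_blocks` set,
#' haplotypes within a block share a latent Gaussian factor
#' (block-exchangeable LD); SNPs are otherwise independent.
#'
#' @param config A [sim_config()].
#' @return A `genotype_table`: list with `dosages` (subjects x SNPs integer
#'   matrix, dimnames set), `snp_info` (tibble, one row per SNP-phenotype
#'   annotation: `snp_id`, `effect_allele`, `phenotype`, `phenotype_group`,
#'   `gwas_p`), `maf` (named vector of simulated frequencies) and
#'   `ld_block` (named block ids, or NULL).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- sim_seeds(config$seed)
  set.seed(seeds[["genotypes"]])

  n <- config$n_subjects
  p <- config$n_snps
  snp_ids <- sprintf("rs%06d", seq_len(p))
  subj_ids <- sprintf("S%04d", seq_len(n))
  maf <- runif(p, config$maf_range[1], config$maf_range[2])

  ld_block <- NULL
  if (is.null(config$ld_blocks)) {
    dos <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  } else {
    # Gaussian-copula haplotypes: alleles within a block share a factor with
    # loading sqrt(r); pairwise haplotype correlation ~ r on the latent scale.
    k <- config$ld_blocks$size
    r <- config$ld_blocks$r2
    block <- rep(seq_len(ceiling(p / k)), each = k)[seq_len(p)]
    ld_block <- setNames(block, snp_ids)
    thr <- qnorm(maf)
    hap <- function() {
      shared <- matrix(rnorm(n * max(block)), n, max(block))[, block, drop = FALSE]
      z <- sqrt(r) * shared + sqrt(1 - r) * matrix(rnorm(n * p), n, p)
      (z < rep(thr, each = n)) + 0L
    }
    dos <- hap() + hap()
  }
  dimnames(dos) <- list(subj_ids, snp_ids)

  # risk loci: causal SNPs come in LD blocks so the genetic latent lives in
  # variance-dominant directions that a keep-K PCA retains
  risk_locus <- rep(NA_integer_, p)
  if (!is.null(config$causal_ld) && config$n_causal_snps > 0 &&
      is.null(config$ld_blocks)) {
    s_blk <- config$causal_ld$size
    r_blk <- config$causal_ld$r2
    n_loci <- ceiling(config$n_causal_snps / s_blk)
    locus_snps <- sort(sample.int(p, min(p, n_loci * s_blk)))
    blk_of <- rep(seq_len(n_loci), each = s_blk)[seq_along(locus_snps)]
    risk_locus[locus_snps] <- blk_of
    thr <- qnorm(maf[locus_snps])
    hap_blk <- function() {
      shared <- matrix(rnorm(n * n_loci), n, n_loci)[, blk_of, drop = FALSE]
      z <- sqrt(r_blk) * shared +
        sqrt(1 - r_blk) * matrix(rnorm(n * length(locus_snps)), n)
      (z < rep(thr, each = n)) + 0L
    }
    dos[, locus_snps] <- hap_blk() + hap_blk()
  }

  pool <- sim_phenotype_pool()
  pheno_idx <- sample.int(nrow(pool), p, replace = TRUE, prob = pool$weight)
  # risk-locus SNPs are annotated to psychiatric phenotypes
  psych <- which(pool$phenotype_group == "psychiatric")
  at_risk <- !is.na(risk_locus)
  if (any(at_risk)) {
    pheno_idx[at_risk] <- sample(psych, sum(at_risk), replace = TRUE,
                                 prob = pool$weight[psych])
  }
  info <- tibble::tibble(
    snp_id = snp_ids,
    effect_allele = sample(c("A", "C", "G", "T"), p, replace = TRUE),
    phenotype = pool$phenotype[pheno_idx],
    phenotype_group = pool$phenotype_group[pheno_idx],
    gwas_p = 10^(-runif(p, 7.5, 30))
  )
  # ~5% of SNPs pick up a second phenotype annotation (pleiotropy).
  extra <- which(runif(p) < 0.05)
  if (length(extra) > 0) {
    idx2 <- sample.int(nrow(pool), length(extra), replace = TRUE, prob = pool$weight)
    info2 <- info[extra, ]
    info2$phenotype <- pool$phenotype[idx2]
    info2$phenotype_group <- pool$phenotype_group[idx2]
    info2$gwas_p <- 10^(-runif(length(extra), 7.5, 30))
    info <- dplyr::distinct(
      dplyr::arrange(dplyr::bind_rows(info, info2), .data$snp_id, .data$phenotype),
      .data$snp_id, .data$phenotype, .keep_all = TRUE
    )
  }

  structure(
    list(dosages = dos, snp_info = info, maf = setNames(maf, snp_ids),
         ld_block = ld_block, risk_locus = setNames(risk_locus, snp_ids)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d subjects x %d SNPs (%d phenotype annotations)\n",
              nrow(x$dosages), ncol(x$dosages), nrow(x$snp_info)))
  invisible(x)
}

#' Plant a joint genome-connectome mode and simulate connectomes
#'
#' Builds the genetic latent `g` as a standardized sparse weighted sum of
#' causal-SNP dosages (causal SNPs are drawn preferentially from
#' psychiatric-annotated SNPs), then a connectomic latent
#' `m = rho * g + sqrt(1 - rho^2) * e` so that the population correlation of
#' the two latents equals `rho`. Connection strengths are baseline fFA
#' (`Uniform(0.2, 0.8)`, the tractography floor guarantees retained
#' connections exceed 0.2) plus `effect * m` on signal connections, linear
#' age/sex/scanner/GAF confound effects, and i.i.d. Gaussian noise.
#' Matrices are symmetric with zero diagonal by construction.
#'
#' @param config A [sim_config()].
#' @param genotypes Output of [simulate_genotypes()] under the same config.
#' @return List with `connectomes` (a [connectome_set()]), `covariates`
#'   (tibble: `subject_id`, `age`, `sex`, `scanner`, `gaf_*`) and `truth`
#'   (a `ground_truth` list recording causal SNP ids, signal edge ids, true
#'   weights/effects and the per-subject latents).
#' @export
simulate_joint_mode <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_table"))
  seeds <- sim_seeds(config$seed)
  set.seed(seeds[["structure"]])

  n <- config$n_subjects
  dos <- genotypes$dosages
  stopifnot(nrow(dos) == n)
  snp_ids <- colnames(dos)

  k <- config$n_causal_snps
  if (!is.null(genotypes$risk_locus) && any(!is.na(genotypes$risk_locus))) {
    # risk-locus causal set with locus-level weights: every SNP in a locus
    # shares the locus weight (the latent is a locus signal its SNPs tag)
    locus_snps <- names(genotypes$risk_locus)[!is.na(genotypes$risk_locus)]
    causal <- locus_snps[seq_len(min(k, length(locus_snps)))]
    blk <- genotypes$risk_locus[causal]
    w_blk <- setNames(rnorm(length(unique(blk))), unique(blk))
    w <- setNames(w_blk[as.character(blk)], causal)
  } else {
    # isotropic sparse weights; prefer psychiatric annotations so
    # phenotype-subset reruns can isolate the planted signal
    psych <- unique(genotypes$snp_info$snp_id[
      genotypes$snp_info$phenotype_group == "psychiatric"])
    causal <- if (length(psych) >= k) sort(sample(psych, k)) else {
      sort(c(psych, sample(setdiff(snp_ids, psych), k - length(psych))))
    }
    w <- setNames(rnorm(k), causal)
  }

  # standardize dosages by their population moments so monomorphic sample
  # draws cannot produce NaN
  maf_c <- genotypes$maf[causal]
  mu_c <- 2 * maf_c
  sd_c <- sqrt(2 * maf_c * (1 - maf_c))
  Zg <- sweep(sweep(dos[, causal, drop = FALSE], 2, mu_c), 2, sd_c, "/")
  g_raw <- drop(Zg %*% w)
  g <- as.numeric(scale(g_raw))

  e <- as.numeric(scale(rnorm(n)))
  m_raw <- config$rho * g + sqrt(1 - config$rho^2) * e
  m <- as.numeric(scale(m_raw))

  # covariates
  age <- pmin(pmax(rnorm(n, 12.8, 4.87), 3), 21)
  sex <- rbinom(n, 1, 0.5)
  scanner <- sample(sprintf("site%d", seq_len(config$n_scanners)), n, replace = TRUE)
  gafs <- if (config$n_gafs > 0) {
    matrix(rnorm(n * config$n_gafs), n, config$n_gafs,
           dimnames = list(NULL, sprintf("gaf_%d", seq_len(config$n_gafs))))
  } else NULL
  covariates <- tibble::tibble(
    subject_id = rownames(dos), age = age, sex = sex, scanner = scanner
  )
  if (!is.null(gafs)) covariates <- dplyr::bind_cols(covariates, tibble::as_tibble(gafs))

  # edges
  ei <- edge_index(config$n_nodes)
  n_edges <- nrow(ei)
  baseline <- runif(n_edges, 0.2, 0.8)
  effect <- numeric(n_edges)
  sig <- sort(sample.int(n_edges, config$n_signal_connections))
  mag <- pmax(rnorm(length(sig), config$connection_effect_mean,
                    config$connection_effect_sd), 1e-3)
  sgn <- ifelse(runif(length(sig)) < config$prop_hypo, -1, 1)
  effect[sig] <- sgn * mag

  Z <- cbind(age = as.numeric(scale(age)), sex = sex - mean(sex))
  if (config$n_scanners > 1) {
    sc <- stats::model.matrix(~ scanner)[, -1, drop = FALSE]
    Z <- cbind(Z, sc)
  }
  if (!is.null(gafs)) Z <- cbind(Z, gafs)
  Bconf <- matrix(rnorm(ncol(Z) * n_edges, 0, config$confound_effect_sd),
                  ncol(Z), n_edges)

  edges <- matrix(baseline, n, n_edges, byrow = TRUE) +
    tcrossprod(m, effect) +
    Z %*% Bconf +
    matrix(rnorm(n * n_edges, 0, config$noise_sd), n, n_edges)
  edges <- pmax(edges, 0)
  rownames(edges) <- rownames(dos)
  colnames(edges) <- ei$edge_id

  connectomes <- new_connectome_set(edges, config$n_nodes)

  truth <- structure(
    list(
      causal_snp_ids = causal,
      signal_connection_ids = ei$edge_id[sig],
      true_genetic_weights = w,
      true_connection_effects = setNames(effect[sig], ei$edge_id[sig]),
      latent_g = setNames(g, rownames(dos)),
      latent_m = setNames(m, rownames(dos)),
      behavior_paths = NULL,
      snp_info = genotypes$snp_info,
      maf = genotypes$maf,
      covariates = covariates,
      rho = config$rho
    ),
    class = "ground_truth"
  )

  list(connectomes = connectomes, covariates = covariates, truth = truth)
}

#' Simulate behavior variables downstream of the planted latents
#'
#' Continuous behaviors follow `y = c' * g + b * m + small age/sex effects +
#' noise`; dichotomous behaviors apply a logistic link to the same linear
#' predictor with an intercept chosen to keep prevalence within
#' `[0.1, 0.9]`. All variables are encoded so that higher values mean higher
#' psychiatric vulnerability. Only a `behavior_obs_fraction` subsample of
#' subjects has observed values (the questionnaire subsample); the rest are
#' missing. Path coefficients per variable are recorded in the returned
#' table's `info` and mirrored into `truth$behavior_paths` by
#' [simulate_study()].
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_joint_mode()] (supplies the
#'   latents and covariates).
#' @return A `behavior_table`: list with `data` (tibble `subject_id` +
#'   one column per behavior, `NA` for unobserved subjects) and `info`
#'   (tibble: `name`, `type`, `a`, `b`, `cprime`, `vulnerability_sign`).
#' @export
simulate_behaviors <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  seeds <- sim_seeds(config$seed)
  set.seed(seeds[["behaviors"]])

  g <- truth$latent_g
  m <- truth$latent_m
  n <- length(g)
  cov <- truth$covariates
  age_z <- as.numeric(scale(cov$age))
  sex_c <- cov$sex - mean(cov$sex)

  nb <- config$n_behaviors
  is_null <- rep(FALSE, nb)
  if (config$n_null_behaviors > 0) {
    is_null[sample.int(nb, config$n_null_behaviors)] <- TRUE
  }
  is_dich <- rep(FALSE, nb)
  if (config$n_dichotomous > 0) is_dich[sample.int(nb, config$n_dichotomous)] <- TRUE

  obs <- sort(sample.int(n, max(3, round(config$behavior_obs_fraction * n))))
  vals <- matrix(NA_real_, n, nb)
  b_vec <- ifelse(is_null, 0, config$mediation_b)
  c_vec <- ifelse(is_null, 0, config$mediation_cprime)

  for (j in seq_len(nb)) {
    eta <- c_vec[j] * g + b_vec[j] * m +
      config$behavior_age_effect * age_z + config$behavior_sex_effect * sex_c
    if (is_dich[j]) {
      prev <- runif(1, 0.15, 0.5)
      y <- rbinom(n, 1, plogis(qlogis(prev) + eta))
      # keep the realized minority level within the stable band
      if (mean(y) < 0.1 || mean(y) > 0.9) {
        y <- rbinom(n, 1, plogis(qlogis(0.3) + eta))
      }
      vals[, j] <- y
    } else {
      vals[, j] <- eta + rnorm(n, 0, config$behavior_noise_sd)
    }
  }
  vals[-obs, ] <- NA_real_

  names_b <- sprintf("behavior_%02d", seq_len(nb))
  colnames(vals) <- names_b
  data <- dplyr::bind_cols(
    tibble::tibble(subject_id = names(g)), tibble::as_tibble(vals)
  )
  info <- tibble::tibble(
    name = names_b,
    type = ifelse(is_dich, "dichotomous", "continuous"),
    a = config$mediation_a,
    b = b_vec,
    cprime = c_vec,
    vulnerability_sign = 1
  )
  new_behavior_table(data, info)
}

#' Simulate GWAS summary statistics for a PRS base phenotype
#'
#' Per-allele effects are the causal weights of the planted genetic latent
#' scaled to `gwas_effect_scale` per dosage SD (zero for non-causal SNPs),
#' plus Gaussian estimation noise with standard error
#' `1 / sqrt(2 * maf * (1 - maf) * gwas_base_n)`. P-values are the matching
#' two-sided Wald p, so causal SNPs are enriched at small p and non-causal
#' SNP p-values are uniform.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_joint_mode()].
#' @return Tibble with `snp_id`, `effect_allele`, `beta`, `p` and the base
#'   `phenotype` label.
#' @export
simulate_sumstats <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  seeds <- sim_seeds(config$seed)
  set.seed(seeds[["sumstats"]])

  info <- dplyr::distinct(truth$snp_info, .data$snp_id, .keep_all = TRUE)
  maf <- truth$maf[info$snp_id]
  sd_dos <- sqrt(2 * maf * (1 - maf))

  beta_std <- setNames(numeric(nrow(info)), info$snp_id)
  beta_std[truth$causal_snp_ids] <-
    truth$true_genetic_weights * config$gwas_effect_scale
  beta_true <- beta_std / sd_dos

  se <- if (is.finite(config$gwas_base_n)) {
    1 / sqrt(2 * maf * (1 - maf) * config$gwas_base_n)
  } else rep(0, length(maf))
  beta_hat <- beta_true + rnorm(length(beta_true)) * se
  z <- ifelse(se > 0, beta_hat / se, sign(beta_hat) * Inf)
  p <- pmax(2 * pnorm(-abs(z)), 1e-300)
  p[!is.finite(z)] <- 1e-300
  p[beta_hat == 0 & se == 0] <- 1

  tibble::tibble(
    snp_id = info$snp_id,
    effect_allele = info$effect_allele,
    beta = as.numeric(beta_hat),
    p = as.numeric(p),
    phenotype = "cross-disorder"
  )
}

#' Simulate a complete synthetic study
#'
#' Runs all generators in order and returns every pipeline input plus the
#' ground truth.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `genotypes`, `connectomes`, `covariates`,
#'   `behaviors`, `sumstats` and `truth`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_subjects = 60, n_snps = 40,
#'                                    n_nodes = 12, n_causal_snps = 8,
#'                                    n_signal_connections = 10, seed = 7))
#' names(study)
simulate_study <- function(config = sim_config()) {
  genotypes <- simulate_genotypes(config)
  joint <- simulate_joint_mode(config, genotypes)
  behaviors <- simulate_behaviors(config, joint$truth)
  truth <- joint$truth
  truth$behavior_paths <- behaviors$info[, c("name", "a", "b", "cprime")]
  sumstats <- simulate_sumstats(config, truth)
  list(
    config = config,
    genotypes = genotypes,
    connectomes = joint$connectomes,
    covariates = joint$covariates,
    behaviors = behaviors,
    sumstats = sumstats,
    truth = truth
  )
}
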