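#' Configuration for a synthetic genome-connectome study
#'
#' Builds and validates the configuration driving [simulate_study()] and the
#' individual generators. Defaults emulate the design of a pediatric
#' imaging-genetics cohort: 678 subjects, 1877 risk SNPs drawn from GWAS
#' catalog phenotypes, a 120-region structural connectome of mean fascicle
#' fractional anisotropy (fFA), and a single planted mode of
#' genome-connectome covariation with canonical correlation `rho`.
#'
#' @param n_subjects Number of subjects.
#' @param n_snps Number of SNPs in the dosage matrix.
#' @param n_nodes Number of parcellation regions (even, at least 10). A
#'   120-node parcellation yields `choose(120, 2) = 7140` unique connections.
#' @param n_causal_snps Number of SNPs carrying weight in the planted genetic
#'   latent (at most `n_snps`).
#' @param n_signal_connections Number of connections loaded by the planted
#'   connectomic latent (at most `n_nodes * (n_nodes - 1) / 2`).
#' @param rho Planted canonical correlation between the genetic and
#'   connectomic latents, in `[0, 1]`. `rho = 1` is rejected when
#'   `noise_sd > 0` (unattainable).
#' @param maf_range Length-2 numeric, minor-allele-frequency bounds in
#'   `(0, 0.5]` with `maf_range[1] < maf_range[2]`.
#' @param confound_effect_sd SD of per-edge linear confound coefficients
#'   (age, sex, scanner, GAFs) on the fFA scale; 0 disables confounds.
#' @param connection_effect_mean,connection_effect_sd Mean and SD of the
#'   absolute per-edge loading of the connectomic latent, in fFA units. The
#'   effect-size distribution for individual connections is a modelling
#'   choice exposed here, not an empirical quantity.
#' @param prop_hypo Fraction of signal connections with a negative loading
#'   (hypoconnectivity with increasing latent score).
#' @param mediation_a Path from genetic to connectomic latent used for
#'   bookkeeping; defaults to `rho`, which is the population value for
#'   standardized latents.
#' @param mediation_b,mediation_cprime Default mediated (`b`) and direct
#'   (`c'`) path coefficients for signal behaviors.
#' @param noise_sd SD of i.i.d. edge noise (fFA units), positive.
#' @param n_behaviors,n_null_behaviors Total behaviors and how many of them
#'   carry no genetic/connectomic effect.
#' @param n_dichotomous How many behaviors are dichotomous (logistic link).
#' @param behavior_obs_fraction Fraction of subjects with observed behavior
#'   data (the questionnaire subsample); remaining rows are missing.
#' @param behavior_noise_sd SD of residual noise on continuous behaviors.
#' @param behavior_age_effect,behavior_sex_effect Linear age (per SD) and
#'   sex effects planted on the behavior linear predictor, removed later by
#'   [adjust_behaviors()].
#' @param n_scanners Number of scanner sites (categorical confound).
#' @param n_gafs Number of genetic ancestry factors (continuous confounds).
#' @param gwas_base_n Effective sample size of the synthetic base GWAS used
#'   to scale summary-statistic standard errors; `Inf` gives noise-free
#'   betas.
#' @param gwas_effect_scale Per-SD effect scale of causal SNPs in the
#'   synthetic base GWAS.
#' @param causal_ld Either `list(size =, r2 =)` (default: 10 SNPs per locus
#'   at latent correlation 0.8) organizing the causal SNPs into LD blocks
#'   ("risk loci") with locus-level latent weights, or `NULL` for fully
#'   independent causal SNPs with isotropic sparse weights. Locus structure
#'   is what lets a keep-K principal-component reduction retain the genetic
#'   latent; an isotropic sparse direction over many independent SNPs is
#'   almost entirely lost by the projection.
#' @param ld_blocks Optional list `list(size =, r2 =)` switching on a
#'   block-exchangeable LD structure (blocks of `size` SNPs with pairwise
#'   haplotype correlation targeting `r2`). `NULL` (default) simulates
#'   independent SNPs.
#' @param seed Integer master seed; per-generator sub-seeds are derived from
#'   it (see [sim_seeds()]).
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 100, n_snps = 50, n_nodes = 12, seed = 1)
#' cfg$rho
sim_config <- function(n_subjects = 678,
                       n_snps = 1877,
                       n_nodes = 120,
                       n_causal_snps = 100,
                       n_signal_connections = 200,
                       rho = 0.74,
                       maf_range = c(0.05, 0.5),
                       confound_effect_sd = 0.01,
                       connection_effect_mean = 0.03,
                       connection_effect_sd = 0.01,
                       prop_hypo = 0.7,
                       mediation_a = NULL,
                       mediation_b = 0.3,
                       mediation_cprime = 0.2,
                       noise_sd = 0.02,
                       n_behaviors = 12,
                       n_null_behaviors = 4,
                       n_dichotomous = 4,
                       behavior_obs_fraction = 117 / 678,
                       behavior_noise_sd = 1,
                       behavior_age_effect = 0.15,
                       behavior_sex_effect = 0.2,
                       n_scanners = 3,
                       n_gafs = 4,
                       gwas_base_n = 5e4,
                       gwas_effect_scale = 0.05,
                       causal_ld = list(size = 10, r2 = 0.8),
                       ld_blocks = NULL,
                       seed = 1L) {
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)

  chk_count <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
      stop_cfg(sprintf("`%s` must be a single integer >= %d", name, min))
    }
  }
  chk_count(n_subjects, "n_subjects")
  chk_count(n_snps, "n_snps")
  chk_count(n_nodes, "n_nodes", min = 10)
  if (n_nodes %% 2 != 0) stop_cfg("`n_nodes` must be even")
  chk_count(n_causal_snps, "n_causal_snps", min = 0)
  if (n_causal_snps > n_snps) stop_cfg("`n_causal_snps` exceeds `n_snps`")
  n_edges <- n_nodes * (n_nodes - 1) / 2
  chk_count(n_signal_connections, "n_signal_connections", min = 0)
  if (n_signal_connections > n_edges) {
    stop_cfg("`n_signal_connections` exceeds the number of unique connections")
  }
  if (length(rho) != 1 || !is.finite(rho) || rho < 0 || rho > 1) {
    stop_cfg("`rho` must lie in [0, 1]")
  }
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_cfg("`maf_range` must satisfy 0 < low <= high <= 0.5")
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) stop_cfg("`noise_sd` must be positive")
  if (rho == 1 && noise_sd > 0) {
    stop_cfg("a planted correlation of exactly 1 is unattainable with noise_sd > 0")
  }
  if (confound_effect_sd < 0) stop_cfg("`confound_effect_sd` must be nonnegative")
  if (n_null_behaviors > n_behaviors) stop_cfg("`n_null_behaviors` exceeds `n_behaviors`")
  if (n_dichotomous > n_behaviors) stop_cfg("`n_dichotomous` exceeds `n_behaviors`")
  if (behavior_obs_fraction <= 0 || behavior_obs_fraction > 1) {
    stop_cfg("`behavior_obs_fraction` must lie in (0, 1]")
  }
  chk_count(n_scanners, "n_scanners")
  chk_count(n_gafs, "n_gafs", min = 0)
  for (nm in c("causal_ld", "ld_blocks")) {
    blk <- get(nm)
    if (!is.null(blk)) {
      if (!is.list(blk) || is.null(blk$size) || is.null(blk$r2) ||
          blk$size < 1 || blk$r2 < 0 || blk$r2 > 1) {
        stop_cfg(sprintf("`%s` must be list(size = k >= 1, r2 in [0, 1])", nm))
      }
    }
  }
  if (is.null(mediation_a)) mediation_a <- rho

  structure(
    list(
      n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
      n_nodes = as.integer(n_nodes), n_causal_snps = as.integer(n_causal_snps),
      n_signal_connections = as.integer(n_signal_connections), rho = rho,
      maf_range = maf_range, confound_effect_sd = confound_effect_sd,
      connection_effect_mean = connection_effect_mean,
      connection_effect_sd = connection_effect_sd, prop_hypo = prop_hypo,
      mediation_a = mediation_a, mediation_b = mediation_b,
      mediation_cprime = mediation_cprime, noise_sd = noise_sd,
      n_behaviors = as.integer(n_behaviors),
      n_null_behaviors = as.integer(n_null_behaviors),
      n_dichotomous = as.integer(n_dichotomous),
      behavior_obs_fraction = behavior_obs_fraction,
      behavior_noise_sd = behavior_noise_sd,
      behavior_age_effect = behavior_age_effect,
      behavior_sex_effect = behavior_sex_effect,
      n_scanners = as.integer(n_scanners), n_gafs = as.integer(n_gafs),
      gwas_base_n = gwas_base_n, gwas_effect_scale = gwas_effect_scale,
      causal_ld = causal_ld, ld_blocks = ld_blocks, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Derive named sub-seeds from a master seed
#'
#' One master integer seed drives the whole study; each sub-generator sets
#' its own derived seed so components are independently reproducible (for
#' example, regenerating behaviors does not disturb the genotypes).
#' Sub-seeds are drawn by a fixed-order `sample.int` under the master seed.
#'
#' @param seed Integer master seed.
#' @return Named integer vector of sub-seeds.
#' @export
sim_seeds <- function(seed) {
  stages <- c("genotypes", "structure", "behaviors", "sumstats", "pipeline")
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  subjects: %d, SNPs: %d (%d causal), nodes: %d (%d signal edges)\n",
              x$n_subjects, x$n_snps, x$n_causal_snps, x$n_nodes,
              x$n_signal_connections))
  cat(sprintf("  planted rho: %.3f, edge noise sd: %.3g, seed: %d\n",
              x$rho, x$noise_sd, x$seed))
  invisible(x)
}
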