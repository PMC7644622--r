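test_that("config validation rejects impossible settings", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(rho = 1.2), "rho")
  expect_error(sim_config(rho = 1, noise_sd = 0.1), "unattainable")
  expect_error(sim_config(n_snps = 10, n_causal_snps = 20), "exceeds")
  expect_error(sim_config(n_nodes = 15), "even")
  expect_error(sim_config(n_nodes = 12, n_signal_connections = 100), "connections")
})

test_that("genotype simulation is reproducible and respects allele frequencies", {
  cfg <- tiny_cfg()
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$snp_info, g2$snp_info)
  expect_true(all(g1$dosages %in% 0:2))
  expect_true(all(g1$snp_info$gwas_p < 5e-8))

  # symmetric MAF: mean dosage approximately 1
  cfg_h <- sim_config(n_subjects = 400, n_snps = 50, n_nodes = 12,
                      n_causal_snps = 5, n_signal_connections = 5,
                      maf_range = c(0.5, 0.5), seed = 9)
  gh <- simulate_genotypes(cfg_h)
  # binomial(2, .5) over 400*50 draws: se of the grand mean ~ 0.005
  expect_lt(abs(mean(gh$dosages) - 1), 0.02)
})

test_that("planted latent correlation matches rho", {
  cfg <- sim_config(n_subjects = 2000, n_snps = 80, n_nodes = 12,
                    n_causal_snps = 20, n_signal_connections = 15,
                    rho = 0.7, seed = 11)
  jm <- simulate_joint_mode(cfg, simulate_genotypes(cfg))
  r <- cor(jm$truth$latent_g, jm$truth$latent_m)
  expect_lt(abs(r - 0.7), 0.05)

  cfg0 <- sim_config(n_subjects = 2000, n_snps = 80, n_nodes = 12,
                     n_causal_snps = 20, n_signal_connections = 15,
                     rho = 0, seed = 12)
  jm0 <- simulate_joint_mode(cfg0, simulate_genotypes(cfg0))
  expect_lt(abs(cor(jm0$truth$latent_g, jm0$truth$latent_m)), 3 / sqrt(2000))
})

test_that("connectomes are symmetric with zero diagonal and honest ground truth", {
  study <- tiny_study()
  mats <- devectorize_connectomes(study$connectomes$edge_data,
                                  study$config$n_nodes)
  m <- mats[[1]]
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, nrow(m)))
  expect_true(all(study$truth$causal_snp_ids %in%
                    colnames(study$genotypes$dosages)))
  ei <- edge_index(study$config$n_nodes)
  expect_true(all(study$truth$signal_connection_ids %in% ei$edge_id))
})

test_that("confound-free simulation leaves edges unrelated to covariates", {
  cfg <- sim_config(n_subjects = 500, n_snps = 40, n_nodes = 12,
                    n_causal_snps = 5, n_signal_connections = 5,
                    confound_effect_sd = 0, seed = 21)
  jm <- simulate_joint_mode(cfg, simulate_genotypes(cfg))
  ed <- vectorize_connectomes(jm$connectomes)
  r_age <- abs(cor(ed, jm$covariates$age))
  expect_lt(max(r_age), 4.5 / sqrt(500))
})

test_that("behavior generator reproduces the planted path model", {
  # deterministic linear map: b only, no noise, no covariate effects
  cfg <- sim_config(n_subjects = 300, n_snps = 40, n_nodes = 12,
                    n_causal_snps = 5, n_signal_connections = 5,
                    mediation_b = 0.5, mediation_cprime = 0,
                    behavior_noise_sd = 0, behavior_age_effect = 0,
                    behavior_sex_effect = 0, n_dichotomous = 0,
                    n_null_behaviors = 0, behavior_obs_fraction = 1, seed = 31)
  study <- simulate_study(cfg)
  y <- study$behaviors$data$behavior_01
  r_pure <- cor(y - 0 * study$truth$latent_g, study$truth$latent_m)
  # y = 0.5 m exactly up to the c' = 0 term
  expect_equal(cor(y, study$truth$latent_m), 1, tolerance = 1e-10)
  expect_equal(r_pure, 1, tolerance = 1e-10)

  # regression oracle recovers (c', b) within 2 SE
  cfg2 <- sim_config(n_subjects = 1000, n_snps = 40, n_nodes = 12,
                     n_causal_snps = 5, n_signal_connections = 5,
                     mediation_b = 0.3, mediation_cprime = 0.2,
                     behavior_age_effect = 0, behavior_sex_effect = 0,
                     n_dichotomous = 0, n_null_behaviors = 0,
                     behavior_obs_fraction = 1, seed = 32)
  st2 <- simulate_study(cfg2)
  fit <- lm(st2$behaviors$data$behavior_01 ~ st2$truth$latent_g +
              st2$truth$latent_m)
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf[2, 1] - 0.2), 2 * cf[2, 2])
  expect_lt(abs(cf[3, 1] - 0.3), 2 * cf[3, 2])
})

test_that("null behaviors are unrelated to the connectomic latent", {
  study <- tiny_study()
  null_vars <- study$truth$behavior_paths$name[study$truth$behavior_paths$b == 0]
  expect_gt(length(null_vars), 0)
  for (nm in null_vars[1]) {
    y <- study$behaviors$data[[nm]]
    ok <- !is.na(y)
    expect_lt(abs(cor(y[ok], study$truth$latent_m[ok])), 4 / sqrt(sum(ok)))
  }
})

test_that("summary statistics carry the planted effects and a uniform null", {
  cfg <- sim_config(n_subjects = 50, n_snps = 1200, n_nodes = 12,
                    n_causal_snps = 100, n_signal_connections = 5, seed = 41)
  geno <- simulate_genotypes(cfg)
  jm <- simulate_joint_mode(cfg, geno)
  ss <- simulate_sumstats(cfg, jm$truth)
  expect_identical(ss, simulate_sumstats(cfg, jm$truth))

  # noise-free limit: betas equal the true per-allele weights
  cfg_inf <- sim_config(n_subjects = 50, n_snps = 200, n_nodes = 12,
                        n_causal_snps = 20, n_signal_connections = 5,
                        gwas_base_n = Inf, seed = 42)
  geno_i <- simulate_genotypes(cfg_inf)
  jm_i <- simulate_joint_mode(cfg_inf, geno_i)
  ss_i <- simulate_sumstats(cfg_inf, jm_i$truth)
  causal <- jm_i$truth$causal_snp_ids
  maf <- jm_i$truth$maf[causal]
  expected <- jm_i$truth$true_genetic_weights * cfg_inf$gwas_effect_scale /
    sqrt(2 * maf * (1 - maf))
  got <- ss_i$beta[match(causal, ss_i$snp_id)]
  expect_equal(got, unname(expected), tolerance = 1e-12)

  # non-causal p-values uniform (KS at alpha = 0.01), causal enriched at small p
  null_p <- ss$p[!ss$snp_id %in% jm$truth$causal_snp_ids]
  expect_gt(stats::ks.test(null_p, "punif")$p.value, 0.01)
  causal_p <- ss$p[ss$snp_id %in% jm$truth$causal_snp_ids]
  expect_lt(median(causal_p), median(null_p))
})

test_that("block-LD generator produces correlated dosages within blocks", {
  cfg <- sim_config(n_subjects = 600, n_snps = 40, n_nodes = 12,
                    n_causal_snps = 5, n_signal_connections = 5,
                    ld_blocks = list(size = 5, r2 = 0.8), seed = 51)
  g <- simulate_genotypes(cfg)
  cm <- cor(g$dosages)
  # thresholded haplotypes attenuate the latent correlation, more so at low MAF
  within <- cm[1:5, 1:5][upper.tri(diag(5))]
  between <- cm[1:5, 6:10]
  expect_gt(min(within), 0.15)
  expect_gt(mean(within), 0.3)
  expect_lt(max(abs(between)), 0.25)
})
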