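mk_geno <- function(dosages, alleles = NULL) {
  p <- ncol(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("snp%d", seq_len(p))
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("s%d", seq_len(nrow(dosages)))
  }
  if (is.null(alleles)) alleles <- rep("A", p)
  structure(
    list(dosages = dosages,
         snp_info = tibble::tibble(snp_id = colnames(dosages),
                                   effect_allele = alleles,
                                   phenotype = "x", phenotype_group = "psychiatric",
                                   gwas_p = 1e-9),
         maf = colMeans(dosages, na.rm = TRUE) / 2, ld_block = NULL),
    class = "genotype_table"
  )
}

test_that("threshold grid follows the base/step/upper-bound rule", {
  g <- build_threshold_grid(1.3e-4)
  expect_equal(g, c(5e-8, 5.005e-5, 1.0005e-4, 1.3e-4), tolerance = 1e-12)
  expect_equal(build_threshold_grid(5e-8), 5e-8)
  expect_equal(build_threshold_grid(1e-9), 1e-9)  # below base: single point
  full <- build_threshold_grid(1.0)
  expect_equal(full[1:2], c(5e-8, 5.005e-5), tolerance = 1e-15)
  expect_equal(diff(full)[2], 5e-5, tolerance = 1e-15)
  expect_true(all(diff(full) > 0))
  expect_equal(max(full), 1.0)
  expect_error(build_threshold_grid(0), "upper_bound")
})

test_that("greedy clumping keeps the most significant SNP per LD cluster", {
  ss <- tibble::tibble(snp_id = c("a", "b"), effect_allele = "A",
                       beta = c(0.1, 0.2), p = c(1e-8, 1e-4))
  expect_equal(clump_sumstats(ss), ss)  # no LD table: unchanged
  ld <- tibble::tibble(index_snp_id = "a", proxy_snp_id = "b", r_squared = 0.5)
  expect_equal(clump_sumstats(ss, ld)$snp_id, "a")
  # five blocks of four: exactly one survivor per block
  ids <- sprintf("s%02d", 1:20)
  blk <- rep(1:5, each = 4)
  ss5 <- tibble::tibble(snp_id = ids, effect_allele = "A",
                        beta = 0.1, p = runif(20))
  pairs <- subset(expand.grid(i = 1:20, j = 1:20), i < j & blk[i] == blk[j])
  ld5 <- tibble::tibble(index_snp_id = ids[pairs$i], proxy_snp_id = ids[pairs$j],
                        r_squared = 0.5)
  kept <- clump_sumstats(ss5, ld5)
  expect_equal(nrow(kept), 5)
  expect_equal(sort(unique(blk[match(kept$snp_id, ids)])), 1:5)
})

test_that("PRS scoring matches hand-computed weighted dosage sums", {
  g1 <- mk_geno(matrix(c(0, 1, 2), 3, 1))
  ss1 <- tibble::tibble(snp_id = "snp1", effect_allele = "A", beta = 0.5, p = 1e-8)
  expect_equal(unname(score_prs(g1, ss1, 0.05)), c(0, 0.5, 1.0))

  g3 <- mk_geno(matrix(c(2, 1, 0), 1, 3, byrow = TRUE))
  ss3 <- tibble::tibble(snp_id = c("snp1", "snp2", "snp3"), effect_allele = "A",
                        beta = c(0.2, -0.1, 0.4), p = c(1e-9, 1e-9, 1e-9))
  expect_equal(unname(score_prs(g3, ss3, 0.05)), 0.3)

  expect_warning(z <- score_prs(g3, ss3, 1e-12), "no SNP")
  expect_equal(unname(z), 0)

  # inclusive threshold comparison
  ss_eq <- ss1; ss_eq$p <- 0.05
  expect_equal(unname(score_prs(g1, ss_eq, 0.05)), c(0, 0.5, 1.0))
})

test_that("allele mismatches are dropped and missing dosages imputed at 2*MAF", {
  D <- matrix(c(0, 1, 2, NA, 2, 0, 1, 1), 4, 2)
  g <- mk_geno(D, alleles = c("A", "G"))
  ss <- tibble::tibble(snp_id = c("snp1", "snp2"), effect_allele = c("A", "T"),
                       beta = c(1, 1), p = c(1e-9, 1e-9))
  expect_message(s <- score_prs(g, ss, 0.05), "mismatched")
  # snp2 dropped; snp1 NA imputed as 2 * (mean(0,1,2)/2) = 1
  expect_equal(unname(s), c(0, 1, 2, 1))
})

test_that("scores are additive over disjoint SNP sets and scale with betas", {
  set.seed(20)
  D <- matrix(rbinom(50 * 6, 2, 0.3), 50, 6,
              dimnames = list(NULL, sprintf("snp%d", 1:6)))
  g <- mk_geno(D)
  ss <- tibble::tibble(snp_id = colnames(D), effect_allele = "A",
                       beta = rnorm(6), p = rep(1e-9, 6))
  s_all <- score_prs(g, ss, 0.05)
  s_a <- score_prs(g, ss[1:3, ], 0.05)
  s_b <- score_prs(g, ss[4:6, ], 0.05)
  expect_equal(s_all, s_a + s_b, tolerance = 1e-12)
  ss2 <- ss; ss2$beta <- 3 * ss$beta
  expect_equal(score_prs(g, ss2, 0.05), 3 * s_all, tolerance = 1e-12)
})

test_that("delta R2 follows the full-minus-null definition and its invariances", {
  set.seed(21)
  n <- 300
  gaf <- matrix(rnorm(n * 2), n, 2)
  prs <- rnorm(n)
  target <- prs
  suppressWarnings(  # lm warns on the deliberately perfect fit
    expect_equal(delta_r2(target, prs)$delta_r2, 1, tolerance = 1e-12))

  y0 <- rnorm(n)
  dr0 <- delta_r2(y0, prs, gaf)
  expect_lt(dr0$delta_r2, 0.03)

  # invariant to affine transforms of the covariates
  y <- 0.4 * prs + gaf %*% c(0.3, -0.2) + rnorm(n)
  A <- matrix(c(2, 1, 0, -3), 2, 2)
  d1 <- delta_r2(y, prs, gaf)
  d2 <- delta_r2(y, prs, sweep(gaf %*% A, 2, c(5, -1), "+"))
  expect_equal(d1$delta_r2, d2$delta_r2, tolerance = 1e-10)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-8)

  expect_error(delta_r2(y, gaf[, 1], gaf), "collinear")
})

test_that("permutation scan matches the per-threshold model p and its floor", {
  set.seed(22)
  cfg <- sim_config(n_subjects = 150, n_snps = 80, n_nodes = 12,
                    n_causal_snps = 15, n_signal_connections = 10, seed = 60,
                    behavior_obs_fraction = 1)
  study <- simulate_study(cfg)
  gafs <- as.matrix(study$covariates[, grep("^gaf", names(study$covariates))])
  target <- study$truth$latent_m
  grid <- build_threshold_grid(1e-4)
  # fast partial-correlation path equals the lm-based delta_r2 p-value
  pp <- prs_permutation_test(target, study$genotypes, study$sumstats, gafs,
                             grid, B = 49, seed = 1)
  s_best <- score_prs(study$genotypes, study$sumstats, pp$best_threshold)
  expect_equal(pp$best_p, delta_r2(target, s_best, gafs)$p_value,
               tolerance = 1e-10)
  # strong planted association: corrected p at the floor
  expect_equal(pp$corrected_p, 1 / 50)
  # corrected p can never undercut the attainable floor
  expect_gte(pp$corrected_p, 1 / (pp$B + 1))
})

test_that("a single-threshold grid reduces to the plain permutation p", {
  set.seed(23)
  n <- 120
  D <- matrix(rbinom(n * 10, 2, 0.3), n, 10,
              dimnames = list(NULL, sprintf("snp%d", 1:10)))
  g <- mk_geno(D)
  ss <- tibble::tibble(snp_id = colnames(D), effect_allele = "A",
                       beta = rnorm(10), p = rep(1e-9, 10))
  target <- rnorm(n)
  pp <- prs_permutation_test(target, g, ss, NULL, grid = 5e-8, B = 199, seed = 4)
  # direct permutation oracle with the same stream
  s <- score_prs(g, ss, 5e-8)
  r_obs <- abs(cor(target, s))
  set.seed(4)
  cnt <- sum(vapply(1:199, function(b) {
    abs(cor(target[sample.int(n)], s)) >= r_obs - 1e-14
  }, logical(1)))
  expect_equal(pp$corrected_p, (1 + cnt) / 200)
})
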