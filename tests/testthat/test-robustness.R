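pipe_inputs <- function() {
  study <- tiny_study()
  list(study = study,
       dos = study$genotypes$dosages,
       ed = vectorize_connectomes(study$connectomes),
       cov = study$covariates)
}

test_that("rerun scenarios reduce to identity when nothing changes", {
  inp <- pipe_inputs()
  full <- run_cca_pipeline(inp$dos, inp$ed, inp$cov, 12)
  ex <- exclude_subjects_rerun(inp$dos, inp$ed, inp$cov,
                               rep(FALSE, nrow(inp$dos)), 12, full = full)
  expect_equal(ex$cor_genetic, 1, tolerance = 1e-10)
  expect_equal(ex$cor_connection, 1, tolerance = 1e-10)

  sub <- snp_subset_rerun(inp$dos, inp$ed, inp$cov, colnames(inp$dos), 12,
                          B = 99, seed = 1, full = full)
  expect_equal(sub$cor_connection, 1, tolerance = 1e-10)
  expect_equal(sub$p, 1 / 100)
})

test_that("pc sensitivity reports the baseline as perfect and skips invalid K", {
  inp <- pipe_inputs()
  expect_warning(
    pc <- pc_sensitivity(inp$dos, inp$ed, inp$cov,
                         k_values = c(12, 8, 1000), baseline = 12),
    "invalid")
  expect_equal(pc$cor_connection[pc$n_components == 12], 1, tolerance = 1e-10)
  expect_equal(nrow(pc), 2)
  # a strong planted mode survives changing K
  expect_gt(pc$cor_connection[pc$n_components == 8], 0.8)
})

test_that("split-half reproduces a strong planted mode and the size guard holds", {
  inp <- pipe_inputs()
  sh <- split_half(inp$dos, inp$ed, inp$cov, 12, seed = 3)
  expect_equal(nrow(sh), 2)
  expect_equal(sum(sh$n), nrow(inp$dos))
  expect_gt(min(sh$cor_connection), 0.5)
  expect_error(split_half(inp$dos[1:20, ], inp$ed[1:20, ], inp$cov[1:20, ], 5),
               "40 subjects")

  # duplicated subjects: any random half carries the full information
  dos2 <- rbind(inp$dos, inp$dos)
  ed2 <- rbind(inp$ed, inp$ed)
  cov2 <- dplyr::bind_rows(inp$cov, inp$cov)
  sh2 <- split_half(dos2, ed2, cov2, 12, seed = 3)
  expect_gt(min(sh2$cor_connection), 0.8)
})

test_that("a causal-free SNP subset loses the planted network", {
  inp <- pipe_inputs()
  causal <- inp$study$truth$causal_snp_ids
  non_causal <- setdiff(colnames(inp$dos), causal)
  full <- run_cca_pipeline(inp$dos, inp$ed, inp$cov, 12)
  sub_causal <- snp_subset_rerun(inp$dos, inp$ed, inp$cov, causal, 10,
                                 B = 99, seed = 4, full = full)
  sub_none <- snp_subset_rerun(inp$dos, inp$ed, inp$cov, non_causal[1:30], 10,
                               B = 99, seed = 5, full = full)
  expect_gt(sub_causal$cor_connection, 0.8)
  expect_lt(sub_none$cor_connection, sub_causal$cor_connection)
  expect_error(snp_subset_rerun(inp$dos, inp$ed, inp$cov, "nope", 10),
               "fewer than 2")
})

test_that("ancestry adjustment of the genotype block runs through the same pipeline", {
  inp <- pipe_inputs()
  full <- run_cca_pipeline(inp$dos, inp$ed, inp$cov, 12)
  adj <- run_cca_pipeline(inp$dos, inp$ed, inp$cov, 12, adjust_genetic = TRUE)
  r <- abs(cor(full$strengths_connection$strength,
               adj$strengths_connection$strength))
  expect_gt(r, 0.9)  # GAFs are independent of the planted mode here
})

test_that("mean connectivity correlation recovers planted hypoconnectivity", {
  inp <- pipe_inputs()
  mc_self <- mean_connectivity_correlation(inp$ed, rowMeans(inp$ed), B = 49,
                                           seed = 6)
  expect_equal(mc_self$r, 1, tolerance = 1e-12)

  pipe <- run_cca_pipeline(inp$dos, inp$ed, inp$cov, 12)
  mc <- mean_connectivity_correlation(inp$ed, pipe$fit$scores_v[, 1], B = 199,
                                      seed = 7)
  # 70% of planted effects are negative and the mode is oriented negative-mean
  expect_lt(mc$r, 0)
  expect_lt(mc$p, 0.05)
})

test_that("hub classification sums significant incident strengths with a tie rule", {
  st <- tibble::tibble(
    strength = c(-0.3, -0.2, 0.4, -0.4, 0.5, 0.6),
    q = c(0.01, 0.02, 0.01, 0.01, 0.2, NA),
    node_i = c(1L, 1L, 2L, 2L, 3L, 4L),
    node_j = c(5L, 6L, 5L, 6L, 6L, 5L)
  )
  hubs <- compute_hubs(st, n_nodes = 6)
  expect_equal(hubs$total_strength[hubs$node == 1], -0.5)
  expect_equal(hubs$class[hubs$node == 1], "hypo")
  expect_equal(hubs$total_strength[hubs$node == 2], 0)
  expect_equal(hubs$class[hubs$node == 2], "none")   # exact tie
  expect_equal(hubs$class[hubs$node == 3], "none")   # nothing significant
  expect_equal(hubs$class[hubs$node == 4], "none")   # NA q ignored
  # node 5 sees -0.3 (from 1) and 0.4 (from 2): sum 0.1, hyper
  expect_equal(hubs$total_strength[hubs$node == 5], 0.1, tolerance = 1e-12)
  expect_equal(hubs$class[hubs$node == 5], "hyper")
  # mean aggregation available behind the flag
  hm <- compute_hubs(st, 6, method = "mean")
  expect_equal(hm$total_strength[hm$node == 1], -0.25)
  expect_equal(attr(hm, "method"), "mean")
})

test_that("planted hypoconnectivity edges concentrate hypo hubs on loaded nodes", {
  cfg <- sim_config(n_subjects = 250, n_snps = 60, n_nodes = 14,
                    n_causal_snps = 10, n_signal_connections = 25,
                    rho = 0.85, prop_hypo = 1, behavior_obs_fraction = 1,
                    seed = 77)
  study <- simulate_study(cfg)
  ed <- vectorize_connectomes(study$connectomes)
  pipe <- run_cca_pipeline(study$genotypes$dosages, ed, study$covariates, 12)
  pm <- permutation_test_modes(pipe$pca_u$scores, pipe$pca_v$scores, B = 199,
                               seed = 8, Xv = pipe$Xv)
  st <- strength_table(pm, edges = attr(ed, "edges"))
  # apply the nonpositive-mean orientation convention before classifying
  if (mean(st$strength[st$block == "connectomic"], na.rm = TRUE) > 0) {
    st$strength <- -st$strength
  }
  hubs <- compute_hubs(st[st$block == "connectomic", ], cfg$n_nodes)
  ei <- edge_index(cfg$n_nodes)
  loaded <- ei[ei$edge_id %in% study$truth$signal_connection_ids, ]
  loaded_nodes <- unique(c(loaded$node_i, loaded$node_j))
  expect_true(all(hubs$class[hubs$n_significant > 0 &
                               hubs$node %in% loaded_nodes] == "hypo"))
})
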