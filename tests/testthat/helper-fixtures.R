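# Shared fixtures: one small planted study reused across test files, plus a
# permutation enumerator and an independent CCA oracle (stats::cancor).

tiny_cfg <- function(...) {
  sim_config(
    n_subjects = 300, n_snps = 60, n_nodes = 16, n_causal_snps = 10,
    n_signal_connections = 20, rho = 0.8, behavior_obs_fraction = 1,
    seed = 42, ...
  )
}

# memoised small study so test files do not regenerate it
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(tiny_cfg())
    cache
  }
})

# all permutations of 1..n (n small), used by the exhaustive-null oracle
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# independent canonical-correlation oracle
cancor_r <- function(U, V) {
  stats::cancor(scale(U, scale = FALSE), scale(V, scale = FALSE))$cor
}
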