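# Shared fixture builders; everything is generated in code under fixed seeds.

rand_spd <- function(n, seed = NULL, jitter = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  crossprod(A) / n + diag(jitter, n)
}

rand_sym_mat <- function(n, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(rnorm(n * n, sd = sd), n, n)
  (G + t(G)) / 2
}

## Deterministic correlated block used for the Ledoit-Wolf oracle test; the
## expected values frozen in test-connectivity.R were computed with
## scikit-learn's LedoitWolf estimator on this exact matrix.
lw_fixture <- function() {
  set.seed(99)
  n <- 40; p <- 5
  Sig <- 0.3 + 0.7 * diag(p)
  L <- t(chol(Sig))
  round(L %*% matrix(rnorm(p * n), p, n), 6)
}

## Small synthetic study reused across tests (true covariances: fast).
small_cov_study <- function(seed = 3, n_subjects = 6, n_regions = 28) {
  cfg <- generator_config(n_subjects = n_subjects, n_regions = n_regions,
                          n_targets = 4L, seed = seed)
  gen_connectivity_dataset(cfg, what = "covariance")
}
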