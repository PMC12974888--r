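test_that("z-scoring standardizes each region with the population denominator", {
  X <- rbind(r1 = c(1, 2, 3), r2 = c(5, 5, 8))
  Z <- zscore_timeseries(X)
  expect_equal(unname(Z[1, ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_equal(unname(sqrt(rowMeans(Z^2))), c(1, 1), tolerance = 1e-12)
  # an already-standardized row passes through
  expect_lt(max(abs(zscore_timeseries(Z) - Z)), 1e-12)
  Xbad <- rbind(ok = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(zscore_timeseries(Xbad), "flat")
})

test_that("epoch splicing yields five 96-volume blocks at the standard design", {
  defs <- default_epochs()
  expect_equal(defs$length, rep(96L, 5))
  set.seed(1)
  scans <- list(task = matrix(rnorm(4 * 886), 4, dimnames = list(paste0("R", 1:4), NULL)),
                washout = matrix(rnorm(4 * 246), 4, dimnames = list(paste0("R", 1:4), NULL)))
  blocks <- splice_epochs(scans, defs, discard_initial = 6)
  expect_named(blocks, c("Baseline", "EarlyLearning", "LateLearning",
                         "EarlyWashout", "LateWashout"))
  expect_true(all(vapply(blocks, ncol, integer(1)) == 96L))
  expect_equal(blocks$Baseline, scans$task[, 7:102])
  expect_equal(blocks$LateWashout, scans$washout[, (246 - 95):246])
  # discard 0 with start 0 gives the first raw volumes
  b0 <- splice_epochs(scans, defs[1, ], discard_initial = 0)
  expect_equal(b0$Baseline, scans$task[, 1:96])
  short <- list(task = scans$task[, 1:100], washout = scans$washout)
  expect_error(splice_epochs(short, defs), "exceeds")
  # trial-volume bookkeeping at 2 volumes/trial: trials 1-48 <-> volumes 1-96
  expect_equal(trial_volumes(1:48), 1:96)
  expect_equal(trial_volumes(3L), c(5L, 6L))
})

test_that("Ledoit-Wolf estimate matches the scikit-learn oracle", {
  ## expected values computed once with sklearn.covariance.LedoitWolf on the
  ## deterministic lw_fixture() block
  S <- ledoit_wolf_cov(lw_fixture())
  expect_equal(attr(S, "shrinkage"), 0.368143069992321, tolerance = 1e-12)
  expect_equal(S[1, 1], 0.781797365743, tolerance = 1e-9)
  expect_equal(S[1, 2], 0.179894202038, tolerance = 1e-9)
  expect_equal(S[4, 5], 0.300484801253, tolerance = 1e-9)
  expect_equal(S[3, 3], 0.900682878638, tolerance = 1e-9)
})

test_that("Ledoit-Wolf shrinkage is bounded and the estimate is SPD when p > n", {
  set.seed(42)
  X <- matrix(rnorm(120 * 96), 120, 96)
  S <- ledoit_wolf_cov(X)
  a <- attr(S, "shrinkage")
  expect_true(a >= 0 && a <= 1)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # iid unit noise with many volumes: diagonal near 1, off-diagonal near 0
  Xn <- matrix(rnorm(10 * 5000), 10, 5000)
  Sn <- ledoit_wolf_cov(Xn)
  expect_lt(max(abs(diag(Sn) - 1)), 0.1)
  expect_lt(max(abs(Sn[upper.tri(Sn)])), 0.1)
  expect_error(ledoit_wolf_cov(matrix(1, 3, 1)), "2 volumes")
})

test_that("nuisance component regression removes exactly the retained subspace", {
  set.seed(7)
  nuis <- matrix(rnorm(6 * 200), 6, 200)
  pc <- prcomp(t(nuis))
  # a target equal to nuisance PC1 is annihilated
  tgt <- rbind(pc1 = pc$x[, 1])
  out <- nuisance_regress_components(tgt, nuis, 3)
  expect_lt(max(abs(out)), 1e-10)
  # residuals are orthogonal to every retained component
  tgt2 <- matrix(rnorm(4 * 200), 4, 200)
  out2 <- nuisance_regress_components(tgt2, nuis, 3)
  Z <- attr(out2, "components")
  expect_lt(max(abs(cor(t(out2), Z))), 1e-10)
  # a target orthogonal to the nuisance subspace is unchanged (beyond the mean)
  ortho <- rbind(o = residuals(lm(rnorm(200) ~ pc$x[, 1:3])))
  out3 <- nuisance_regress_components(ortho, nuis, 3)
  expect_lt(max(abs(out3 - (ortho - rowMeans(ortho)))), 1e-10)
  # planted mixture: signal + 0.5 * PC2 -> residual recovers the signal
  sig <- residuals(lm(rnorm(200) ~ pc$x[, 1:3]))
  mix <- rbind(m = sig + 0.5 * pc$x[, 2])
  out4 <- nuisance_regress_components(mix, nuis, 3)
  expect_gt(cor(as.numeric(out4), sig), 0.99)
  expect_error(nuisance_regress_components(tgt2, nuis, 10), "exceeds")
  rank1 <- matrix(rep(rnorm(200), each = 5), 5, 200)
  expect_error(nuisance_regress_components(tgt2, rank1, 3), "rank-deficient")
})

test_that("epoch mean activation is the per-region time average", {
  X <- rbind(a = rep(0, 96), b = rep(2.5, 96))
  expect_equal(epoch_mean_activation(X), c(a = 0, b = 2.5))
  set.seed(8)
  X2 <- matrix(rnorm(3 * 96), 3, dimnames = list(c("x", "y", "z"), NULL))
  off <- c(x = 0.3, y = -0.2, z = 0)
  expect_equal(epoch_mean_activation(X2 + off), rowMeans(X2) + off, tolerance = 1e-12)
})

test_that("seed contrasts recover planted changes and match a brute-force network oracle", {
  set.seed(9)
  regions <- paste0("R", 1:12)
  networks <- setNames(rep(c("NetA", "NetB", "NetC"), each = 4), regions)
  n_subj <- 6
  make_cov <- function(boost) {
    S <- rand_spd(12, jitter = 1)
    dimnames(S) <- list(regions, regions)
    S["R1", ] <- S["R1", ] + boost
    S[, "R1"] <- S[, "R1"] + boost
    S
  }
  covs <- list(); meta <- NULL
  for (s in 1:n_subj) for (e in c("e1", "e2")) {
    covs <- c(covs, list(make_cov(if (e == "e1") 0.8 else 0)))
    meta <- rbind(meta, data.frame(subject = paste0("s", s), epoch = e))
  }
  sc <- seed_contrast(covs, meta, "R1", "e1", "e2", networks)
  expect_true(all(sc$t[setdiff(regions, "R1")] > 0))
  # identical epoch sets give zero everywhere
  sc0 <- seed_contrast(covs, meta, "R1", "e1", "e1", networks)
  expect_true(all(abs(sc0$t) < 1e-12))
  # network summary equals an independently coded paired t on subject means
  oracle_net <- function(nl) {
    rs <- setdiff(regions[networks[regions] == nl], "R1")
    d <- sapply(1:n_subj, function(s) {
      i1 <- which(meta$subject == paste0("s", s) & meta$epoch == "e1")
      i2 <- which(meta$subject == paste0("s", s) & meta$epoch == "e2")
      mean(covs[[i1]]["R1", rs]) - mean(covs[[i2]]["R1", rs])
    })
    unname(t.test(d)$statistic)
  }
  for (nl in c("NetA", "NetB", "NetC")) {
    expect_equal(sc$network$t[sc$network$network == nl], oracle_net(nl),
                 tolerance = 1e-10)
  }
  # invariant to subject order
  perm <- c(4:6, 1:3)
  idx <- unlist(lapply(perm, function(s) which(meta$subject == paste0("s", s))))
  sc_p <- seed_contrast(covs[idx], meta[idx, ], "R1", "e1", "e2", networks)
  expect_equal(sc$t, sc_p$t, tolerance = 1e-12)
  expect_error(seed_contrast(covs, meta, "R99", "e1", "e2", networks), "unknown seed")
})
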