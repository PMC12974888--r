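## Independent oracle: base R aov with an Error() stratum for the two-way
## within-subject design.
aov_oracle_2x5 <- function(y3d) {
  n <- dim(y3d)[1]
  df <- expand.grid(subject = factor(seq_len(n)), day = factor(1:2),
                    epoch = factor(1:5))
  df$y <- as.vector(y3d)
  fit <- summary(stats::aov(y ~ day * epoch + Error(subject / (day * epoch)),
                            data = df))
  get_f <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(day = get_f("Error: subject:day", "day"),
    epoch = get_f("Error: subject:epoch", "epoch"),
    interaction = get_f("Error: subject:day:epoch", "day:epoch"))
}

test_that("region-wise 2x5 rmANOVA matches the aov oracle with the design dfs", {
  set.seed(11)
  n <- 6; R <- 3
  ecc <- array(rnorm(n * 2 * 5 * R), dim = c(n, 2, 5, R),
               dimnames = list(paste0("s", 1:n), c("d1", "d2"),
                               fcmanifold:::EPOCH_LEVELS, paste0("r", 1:R)))
  res <- rm_anova_2x5(ecc)
  for (r in 1:R) {
    o <- aov_oracle_2x5(ecc[, , , r])
    expect_equal(res$F_day[r], unname(o["day"]), tolerance = 1e-10)
    expect_equal(res$F_epoch[r], unname(o["epoch"]), tolerance = 1e-10)
    expect_equal(res$F_interaction[r], unname(o["interaction"]), tolerance = 1e-10)
  }
  df <- attr(res, "df")
  expect_equal(df$epoch, c(4, 4 * (n - 1)))
  expect_equal(df$day, c(1, n - 1))
  expect_equal(df$interaction, c(4, 4 * (n - 1)))
  # with n = 32 subjects the Epoch effect has (4, 124) df
  ecc32 <- array(rnorm(32 * 2 * 5), dim = c(32, 2, 5, 1),
                 dimnames = list(paste0("s", 1:32), c("d1", "d2"),
                                 fcmanifold:::EPOCH_LEVELS, "r1"))
  expect_equal(attr(rm_anova_2x5(ecc32), "df")$epoch, c(4, 124))
  # a large planted epoch effect is overwhelming
  eff <- ecc
  eff[, , "EarlyLearning", 1] <- eff[, , "EarlyLearning", 1] + 10
  expect_lt(rm_anova_2x5(eff)$p_epoch[1], 1e-6)
})

test_that("rmANOVA type-I rate on pure noise stays at the nominal level", {
  set.seed(12)
  n <- 8; R <- 500
  ecc <- array(rnorm(n * 2 * 5 * R), dim = c(n, 2, 5, R),
               dimnames = list(paste0("s", 1:n), c("d1", "d2"),
                               fcmanifold:::EPOCH_LEVELS, paste0("r", 1:R)))
  res <- rm_anova_2x5(ecc)
  hits <- sum(res$p_epoch < 0.05)
  expect_gte(hits, qbinom(0.025, R, 0.05))
  expect_lte(hits, qbinom(0.975, R, 0.05))
})

test_that("one-way rmANOVA matches aov and has (k-1, (k-1)(n-1)) dfs", {
  set.seed(13)
  Y <- matrix(rnorm(8 * 7), 8, 7)
  res <- rm_anova_1way(Y)
  df <- data.frame(subject = factor(rep(1:8, 7)), cond = factor(rep(1:7, each = 8)),
                   y = as.vector(Y))
  fit <- summary(stats::aov(y ~ cond + Error(subject / cond), data = df))
  o <- fit[["Error: subject:cond"]][[1]]["cond", "F value"]
  expect_equal(res$F, o, tolerance = 1e-10)
  expect_equal(c(res$df1, res$df2), c(6, 42))
})

test_that("BH FDR control matches the brute-force step-up search", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_true(all(!fdr_bh(rep(1, 10), 0.05)$reject))
  brute <- function(p, q) {
    m <- length(p); o <- order(p)
    k <- max(c(0, which(p[o] <= q * seq_len(m) / m)))
    rej <- logical(m)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  set.seed(14)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_identical(fdr_bh(p, 0.05)$reject, brute(p, 0.05))
  }
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("paired epoch contrasts match t.test and are antisymmetric", {
  set.seed(15)
  n <- 7; R <- 4
  ecc <- array(rnorm(n * 2 * 5 * R), dim = c(n, 2, 5, R),
               dimnames = list(paste0("s", 1:n), c("d1", "d2"),
                               fcmanifold:::EPOCH_LEVELS, paste0("r", 1:R)))
  con <- paired_contrast(ecc, "EarlyLearning", "Baseline")
  for (r in 1:R) {
    a <- rowMeans(cbind(ecc[, "d1", "EarlyLearning", r], ecc[, "d2", "EarlyLearning", r]))
    b <- rowMeans(cbind(ecc[, "d1", "Baseline", r], ecc[, "d2", "Baseline", r]))
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(con$t[r], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(con$p[r], tt$p.value, tolerance = 1e-10)
  }
  flip <- paired_contrast(ecc, "Baseline", "EarlyLearning")
  expect_equal(con$t, -flip$t, tolerance = 1e-12)
  same <- paired_contrast(ecc, "Baseline", "Baseline")
  expect_true(all(same$t == 0))
})

test_that("k-means ensembles recover separated blobs with deterministic relabelling", {
  set.seed(16)
  centers <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10), c(-10, -10, 0))
  truth <- rep(1:4, times = c(8, 6, 5, 4))
  X <- centers[truth, ] + matrix(rnorm(length(truth) * 3, sd = 0.3),
                                 ncol = 3)
  rownames(X) <- sprintf("R%02d", seq_along(truth))
  ens <- kmeans_ensembles(X, k = 4, seed = 1,
                          networks = setNames(paste0("N", truth), rownames(X)))
  # exact recovery: clusters coincide with the blobs
  expect_equal(length(unique(tapply(ens$cluster, truth, function(v) v[1]))), 4)
  expect_true(all(tapply(ens$cluster, truth, function(v) length(unique(v))) == 1))
  # relabelled by descending size
  expect_equal(as.vector(table(ens$cluster)), c(8, 6, 5, 4))
  expect_equal(unname(ens$labels), paste0("N", 1:4))
  # determinism and k = 1
  ens2 <- kmeans_ensembles(X, k = 4, seed = 1)
  expect_identical(ens$cluster, ens2$cluster)
  expect_true(all(kmeans_ensembles(X, k = 1, seed = 1)$cluster == 1))
  expect_error(kmeans_ensembles(X[1:3, ], k = 4), "exceeds")
})

test_that("similarity profiles follow the correlation definitions", {
  set.seed(17)
  n <- 5; R <- 8
  ecc <- array(rnorm(n * 2 * 5 * R), dim = c(n, 2, 5, R),
               dimnames = list(paste0("s", 1:n), c("d1", "d2"),
                               fcmanifold:::EPOCH_LEVELS, paste0("r", 1:R)))
  # identical pattern -> r = 1; negated -> r = -1
  for (s in 1:n) {
    ecc[s, "d2", "EarlyLearning", ] <- ecc[s, "d1", "EarlyLearning", ]
    ecc[s, "d1", "LateLearning", ] <- -ecc[s, "d1", "EarlyLearning", ]
  }
  prof <- rsa_profile(ecc, paste0("r", 1:R))
  expect_equal(unname(prof[, "d2_EarlyLearning"]), rep(1, n), tolerance = 1e-12)
  expect_equal(unname(prof[, "d1_LateLearning"]), rep(-1, n), tolerance = 1e-12)
  # spearman equals pearson on rank-transformed data
  prof_sp <- rsa_profile(ecc, paste0("r", 1:R), metric = "spearman")
  ecc_rank <- ecc
  for (s in 1:n) for (d in 1:2) for (e in 1:5) {
    ecc_rank[s, d, e, ] <- rank(ecc[s, d, e, ])
  }
  prof_rk <- rsa_profile(ecc_rank, paste0("r", 1:R), metric = "pearson")
  expect_equal(unclass(prof_sp), unclass(prof_rk), tolerance = 1e-12)
  expect_error(rsa_profile(ecc, paste0("r", 1:2)), "at least 3")
})

test_that("reinstatement one-tailed p is half the two-tailed p for positive t", {
  set.seed(18)
  Y <- matrix(rnorm(6 * 7), 6, 7,
              dimnames = list(NULL, fcmanifold:::RSA_EPOCHS))
  Y[, "d2_EarlyLearning"] <- Y[, "d2_EarlyLearning"] + 2
  class(Y) <- c("similarity_profile", class(Y))
  rt <- reinstatement_test(Y)
  for (i in seq_len(nrow(rt$contrasts))) {
    ep <- rt$contrasts$epoch[i]
    tt <- t.test(unclass(Y)[, "d2_EarlyLearning"], unclass(Y)[, ep], paired = TRUE)
    if (tt$statistic > 0) {
      expect_equal(rt$contrasts$p[i], tt$p.value / 2, tolerance = 1e-10)
    }
  }
  expect_equal(rt$omnibus$df1, 6)
})

test_that("network correlations reduce to the obvious special cases", {
  set.seed(19)
  n <- 8
  delta <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, paste0("R", 1:6)))
  networks <- setNames(c("A", "A", "B", "B", "B", "C"), paste0("R", 1:6))
  scores <- rowMeans(delta[, c("R1", "R2")])
  nc <- network_correlation(delta, networks, scores)
  expect_equal(nc$r[nc$network == "A"], 1, tolerance = 1e-12)
  # a single-region network equals that region's correlation
  expect_equal(nc$r[nc$network == "C"], cor(delta[, "R6"], scores), tolerance = 1e-12)
  expect_error(network_correlation(delta, networks, rep(1, n)), "constant")
})

test_that("spin permutations are seed-deterministic, hemisphere-safe bijections", {
  parc <- gen_parcellation(24, 4, seed = 3)
  P1 <- spin_permutations(parc, n_perm = 20, seed = 5)
  P2 <- spin_permutations(parc, n_perm = 20, seed = 5)
  expect_identical(P1, P2)
  for (i in 1:20) expect_true(all(sort(P1[i, ]) == 1:24))
  # regions never cross the midline
  hemi <- parc$hemisphere
  for (i in 1:20) expect_true(all(hemi[P1[i, ]] == hemi))
  set.seed(20)
  delta <- matrix(rnorm(10 * 24), 10, 24, dimnames = list(NULL, parc$region))
  networks <- setNames(parc$network, parc$region)
  scores <- rnorm(10)
  st1 <- spin_test(delta, scores, networks, parc, n_perm = 50, seed = 9)
  st2 <- spin_test(delta, scores, networks, parc, n_perm = 50, seed = 9)
  expect_s3_class(st1, "spin_test")
  expect_identical(st1$result, st2$result)
  expect_true(all(st1$result$p > 0 & st1$result$p <= 1))
  # label-permutation fallback is flagged when coordinates are missing
  parc_nc <- parc[, c("region", "network", "hemisphere")]
  stf <- spin_test(delta, rnorm(10), networks, parc_nc, n_perm = 50, seed = 9,
                   fallback = "labels")
  expect_equal(stf$method, "label_permutation")
  expect_error(spin_test(delta, rnorm(10), networks, parc_nc, n_perm = 50,
                         seed = 9), "fallback")
})
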