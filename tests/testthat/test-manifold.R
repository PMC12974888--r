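test_that("row thresholding keeps the top off-diagonal fraction with deterministic ties", {
  set.seed(1)
  M <- matrix(runif(64), 8, 8)
  full <- row_threshold(M, density = 1)
  expect_equal(full - diag(diag(full)), M - diag(diag(M)) * 0 - diag(diag(M)),
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_true(all(diag(full) == 0))
  # n = 11 at 10% keeps exactly ceil(0.1 * 10) = 1 survivor per row
  M11 <- matrix(runif(121), 11, 11)
  thr <- row_threshold(M11, 0.10)
  expect_true(all(rowSums(thr != 0) == 1))
  expect_equal(apply(thr, 1, max), apply(M11 - diag(Inf, 11), 1, max))
  # ties break toward the lower region index
  Mt <- matrix(0, 4, 4); Mt[1, 2:4] <- c(5, 5, 5)
  thr_t <- row_threshold(Mt, 0.34)  # k = ceil(.34*3) = 2
  expect_equal(which(thr_t[1, ] != 0), c(2L, 3L))
  expect_error(row_threshold(M, 0), "density")
})

test_that("cosine affinity matches the brute-force definition", {
  M <- rbind(a = c(1, 2, 0, 0), b = c(2, 4, 0, 0), c = c(0, 0, 3, 1))
  A <- cosine_affinity(M)
  expect_equal(A["a", "b"], 1, tolerance = 1e-12)
  expect_equal(A["a", "c"], 0, tolerance = 1e-12)
  expect_equal(diag(A), setNames(rep(1, 3), c("a", "b", "c")))
  set.seed(2)
  R <- matrix(rnorm(7 * 9), 7, 9)
  A2 <- cosine_affinity(R)
  for (i in 1:6) for (j in (i + 1):7) {
    expect_equal(A2[i, j],
                 sum(R[i, ] * R[j, ]) / sqrt(sum(R[i, ]^2) * sum(R[j, ]^2)),
                 tolerance = 1e-12)
  }
  Rz <- R; Rz[3, ] <- 0; rownames(Rz) <- paste0("G", 1:7)
  expect_error(cosine_affinity(Rz), "G3")
})

test_that("PCA embedding reports oracle variance ratios and is permutation-equivariant", {
  set.seed(3)
  A <- cosine_affinity(row_threshold(rand_spd(20, seed = 4, jitter = 1), 0.2))
  emb <- pca_embed(A, 3)
  Ac <- scale(A, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Ac), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(emb$variance_explained[1:3], (ev / sum(ev))[1:3], tolerance = 1e-10)
  expect_true(all(diff(emb$variance_explained) <= 1e-12))
  expect_lte(sum(emb$variance_explained), 1 + 1e-12)
  # permuting regions permutes the embedding rows
  p <- sample(20)
  emb_p <- pca_embed(A[p, p], 3)
  expect_equal(abs(emb_p$coordinates), abs(emb$coordinates[p, ]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # near-rank-1 perturbation loads on the first component
  v <- rnorm(20)
  A1 <- diag(20) * 0.01 + tcrossprod(v)
  e1 <- pca_embed((A1 + t(A1)) / 2, 2)
  expect_gt(e1$variance_explained[1], 0.99)
  expect_error(pca_embed(A, 21), "exceeds")
})

test_that("template construction is symmetric in subjects and reduces to a single baseline", {
  S <- rand_spd(15, seed = 5, jitter = 1)
  tpl1 <- build_template(list(list(S, S)))
  direct <- pca_embed(cosine_affinity(row_threshold((S + t(S)) / 2, 0.10)), 3)
  expect_equal(tpl1$embedding$coordinates, direct$coordinates, tolerance = 1e-7)
  subs <- lapply(1:4, function(i) list(rand_spd(10, seed = 30 + i, jitter = 1),
                                       rand_spd(10, seed = 40 + i, jitter = 1)))
  tplA <- build_template(subs)
  tplB <- build_template(subs[c(3, 1, 4, 2)])
  expect_equal(tplA$matrix, tplB$matrix, tolerance = 1e-7)
  # planted block structure: same-network regions sit closer in embedding space
  study <- small_cov_study(seed = 6)
  cen <- center_covariances(study$data, study$meta$subject)
  bl <- lapply(unique(study$meta$subject), function(s)
    cen$centered[study$meta$key[study$meta$subject == s & study$meta$epoch == "Baseline"]])
  tpl <- build_template(bl)
  X <- tpl$embedding$coordinates
  nets <- study$parcellation$network
  D <- as.matrix(dist(X))
  same <- outer(nets, nets, `==`); diag(same) <- NA
  expect_lt(mean(D[same & !is.na(same)]), mean(D[!same & !is.na(same)]))
})

test_that("Procrustes alignment undoes an orthogonal rotation without scaling", {
  set.seed(7)
  tpl <- pca_embed(cosine_affinity(row_threshold(rand_spd(12, seed = 8, jitter = 1), 0.3)), 3)
  tpl$aligned <- TRUE
  # source = template: alignment changes nothing
  out0 <- procrustes_align(tpl, tpl)
  expect_equal(out0$coordinates, tpl$coordinates, tolerance = 1e-10)
  # random rotation + translation is fully recovered
  qrR <- qr.Q(qr(matrix(rnorm(9), 3)))
  src <- tpl
  src$coordinates <- sweep(tpl$coordinates %*% qrR, 2, c(1, -2, 0.5), `+`)
  out <- procrustes_align(src, tpl)
  expect_lt(max(abs(out$coordinates - tpl$coordinates)), 1e-8)
  expect_true(out$aligned)
  # alignment never increases the Frobenius misfit
  src2 <- tpl
  src2$coordinates <- tpl$coordinates + matrix(rnorm(36, sd = 0.2), 12, 3)
  out2 <- procrustes_align(src2, tpl)
  expect_lte(sum((out2$coordinates - tpl$coordinates)^2),
             sum((src2$coordinates - tpl$coordinates)^2) + 1e-12)
  bad <- tpl; bad$coordinates <- bad$coordinates[1:5, ]
  expect_error(procrustes_align(bad, tpl), "mismatch")
})

test_that("eccentricity is the Euclidean distance from the template centroid", {
  emb <- structure(list(coordinates = rbind(p0 = c(0, 0, 0), p1 = c(3, 4, 0)),
                        variance_explained = c(0.5, 0.3, 0.2),
                        aligned = TRUE, regions = c("p0", "p1")),
                   class = "fc_embedding")
  e <- eccentricity(emb, centroid = c(0, 0, 0))
  expect_equal(e, c(p0 = 0, p1 = 5))
  emb2 <- emb; emb2$coordinates <- emb$coordinates * 2.5
  expect_equal(eccentricity(emb2, c(0, 0, 0)), e * 2.5)
  embu <- emb; embu$aligned <- FALSE
  expect_error(eccentricity(embu), "aligned")
})

test_that("additional embedding components leave the eccentricity map strongly correlated", {
  study <- small_cov_study(seed = 9, n_subjects = 5)
  cen <- center_covariances(study$data, study$meta$subject)
  bl <- lapply(unique(study$meta$subject), function(s)
    cen$centered[study$meta$key[study$meta$subject == s & study$meta$epoch == "Baseline"]])
  ecc_k <- function(k) {
    tpl <- build_template(bl, n_components = k)
    colMeans(eccentricity_stack(cen$centered, tpl, n_components = k))
  }
  e3 <- ecc_k(3)
  for (k in c(5, 10)) expect_gt(cor(e3, ecc_k(k)), 0.7)
})
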