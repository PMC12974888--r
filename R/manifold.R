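# Connectivity-manifold construction: row thresholding, cosine affinity,
# PCA embedding, template building, Procrustes alignment, and per-region
# eccentricity.

#' Row-wise thresholding of a connectivity matrix
#'
#' Keeps, in each row, the `k = ceiling(density * (n - 1))` largest
#' off-diagonal entries and zeroes the rest (the diagonal is excluded from
#' the competition and set to zero). Ties at the cutoff are broken in favour
#' of the lower region index, making the output deterministic.
#'
#' @param M A square numeric matrix.
#' @param density Fraction of off-diagonal connections to keep per row
#'   (default 0.10).
#' @return The thresholded matrix.
#' @export
row_threshold <- function(M, density = 0.10) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]", call. = FALSE)
  n <- nrow(M)
  k <- ceiling(density * (n - 1))
  out <- matrix(0, n, n, dimnames = dimnames(M))
  for (i in seq_len(n)) {
    vals <- M[i, ]
    vals[i] <- -Inf
    keep <- order(-vals, seq_len(n))[seq_len(k)]   # ties -> lower index first
    out[i, keep] <- M[i, keep]
  }
  out
}

#' Cosine affinity between connectivity profiles
#'
#' Computes the cosine similarity between every pair of rows of a
#' (thresholded) connectivity matrix. The diagonal is exactly 1. Negative
#' affinities are retained as-is.
#'
#' @param M A matrix whose rows are region connectivity profiles; no row may
#'   be all-zero.
#' @return A symmetric affinity matrix with entries in `[-1, 1]`.
#' @export
cosine_affinity <- function(M) {
  stopifnot(is.matrix(M))
  nrm <- sqrt(rowSums(M^2))
  zero <- which(nrm == 0)
  if (length(zero)) {
    ids <- if (!is.null(rownames(M))) rownames(M)[zero] else as.character(zero)
    stop("all-zero connectivity profile for region(s): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  A <- tcrossprod(M / nrm)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(rownames(M), rownames(M))
  A
}

#' PCA embedding of an affinity matrix
#'
#' Column-centred principal component analysis of the affinity matrix; each
#' region's coordinates are its scores on the leading components. Eigenvector
#' sign ambiguity is removed by flipping each component so that its
#' largest-magnitude loading is positive.
#'
#' @param affinity A symmetric affinity matrix.
#' @param n_components Number of components to retain (default 3).
#' @return An object of class `"fc_embedding"`: a list with `coordinates`
#'   (regions x components), `variance_explained` (all components),
#'   `aligned` (logical), and `regions`.
#' @export
pca_embed <- function(affinity, n_components = 3L) {
  stopifnot(is.matrix(affinity), nrow(affinity) == ncol(affinity))
  if (n_components > nrow(affinity)) {
    stop("n_components exceeds the number of regions", call. = FALSE)
  }
  pc <- stats::prcomp(affinity, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(affinity)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(list(coordinates = coords, variance_explained = ve,
                 aligned = FALSE, regions = rownames(affinity)),
            class = "fc_embedding")
}

#' @export
print.fc_embedding <- function(x, ...) {
  cat(sprintf("<fc_embedding> %d regions x %d components (%saligned)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              if (isTRUE(x$aligned)) "" else "un"))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(ncol(x$coordinates))]),
                    collapse = ", ")))
  invisible(x)
}

#' Build the template baseline manifold
#'
#' Given each subject's two centered Baseline covariance matrices (Day 1 and
#' Day 2), computes the geometric mean per subject, then the geometric mean
#' across subjects, and embeds the result (row thresholding, cosine affinity,
#' PCA). The template defines the common reference space that individual
#' epoch manifolds are aligned to.
#'
#' @param baseline_covs A list (one element per subject) of lists of that
#'   subject's baseline SPD matrices.
#' @param density Row-threshold density (default 0.10).
#' @param n_components Number of components (default 3).
#' @return A list of class `"fc_template"` with `embedding` (an aligned
#'   `"fc_embedding"`), `matrix` (the template SPD matrix), and `centroid`.
#' @export
build_template <- function(baseline_covs, density = 0.10, n_components = 3L) {
  stopifnot(is.list(baseline_covs), length(baseline_covs) >= 1)
  subj_means <- lapply(baseline_covs, function(covs) {
    if (!is.list(covs)) covs <- list(covs)
    spd_geometric_mean(covs)
  })
  template_mat <- spd_geometric_mean(subj_means)
  emb <- pca_embed(cosine_affinity(row_threshold(template_mat, density)),
                   n_components = n_components)
  emb$aligned <- TRUE                 # the template defines the common space
  structure(list(embedding = emb, matrix = template_mat,
                 centroid = colMeans(emb$coordinates)),
            class = "fc_template")
}

#' Procrustes alignment of an embedding to a template
#'
#' Centers both coordinate sets, finds the orthogonal rotation/reflection
#' minimizing the Frobenius misfit to the template (no isotropic scaling, so
#' eccentricity magnitudes are preserved), and re-expresses the source in the
#' template's space (template centroid added back).
#'
#' @param source An `"fc_embedding"` to align.
#' @param template An `"fc_embedding"` or `"fc_template"` defining the target
#'   space.
#' @return The aligned `"fc_embedding"` (with `aligned = TRUE` and attribute
#'   `"rotation"`).
#' @export
procrustes_align <- function(source, template) {
  if (inherits(template, "fc_template")) template <- template$embedding
  stopifnot(inherits(source, "fc_embedding"), inherits(template, "fc_embedding"))
  Xs <- source$coordinates; Xt <- template$coordinates
  if (!all(dim(Xs) == dim(Xt))) stop("embedding shape mismatch", call. = FALSE)
  cs <- colMeans(Xs); ct <- colMeans(Xt)
  Xs_c <- sweep(Xs, 2, cs); Xt_c <- sweep(Xt, 2, ct)
  s <- svd(crossprod(Xs_c, Xt_c))
  R <- s$u %*% t(s$v)
  aligned <- sweep(Xs_c %*% R, 2, ct, `+`)
  dimnames(aligned) <- dimnames(Xt)
  out <- source
  out$coordinates <- aligned
  out$aligned <- TRUE
  attr(out, "rotation") <- R
  out
}

#' Manifold eccentricity
#'
#' The Euclidean distance of each region's aligned manifold coordinates from
#' the template centroid (the origin of the template space). Low eccentricity
#' marks integrated regions with diverse cross-network connectivity; high
#' eccentricity marks segregated, within-network-specialised regions.
#'
#' @param emb An aligned `"fc_embedding"`.
#' @param centroid Reference point (defaults to the origin; pass the template
#'   centroid for spaces whose centre is not at zero).
#' @return A named non-negative numeric vector, one value per region.
#' @export
eccentricity <- function(emb, centroid = NULL) {
  stopifnot(inherits(emb, "fc_embedding"))
  if (!isTRUE(emb$aligned)) {
    stop("embedding must be aligned to the template before eccentricity is computed",
         call. = FALSE)
  }
  X <- emb$coordinates
  if (is.null(centroid)) centroid <- rep(0, ncol(X))
  if (length(centroid) != ncol(X)) stop("centroid length mismatch", call. = FALSE)
  e <- sqrt(rowSums(sweep(X, 2, centroid)^2))
  setNames(e, rownames(X))
}

#' Embed and align a set of covariance matrices
#'
#' Convenience wrapper running threshold -> affinity -> PCA -> Procrustes for
#' every matrix in a list, returning the per-region eccentricity matrix.
#'
#' @param covs A list of centered SPD matrices.
#' @param template An `"fc_template"`.
#' @param density,n_components Manifold parameters (defaults 0.10 and 3).
#' @return A matrix of eccentricities, `length(covs)` rows (named after
#'   `covs`) by regions.
#' @export
eccentricity_stack <- function(covs, template, density = 0.10, n_components = 3L) {
  ecc <- vapply(covs, function(S) {
    emb <- pca_embed(cosine_affinity(row_threshold(S, density)), n_components)
    eccentricity(procrustes_align(emb, template), template$centroid)
  }, numeric(nrow(template$embedding$coordinates)))
  t(ecc)
}
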