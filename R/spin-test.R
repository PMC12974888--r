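# Spatial permutation ("spin") testing for network-level map correlations.
# Null maps are built by applying a random 3-D rotation to the regions'
# unit-sphere centroids (mirrored across hemispheres) and reassigning each
# region the value of its nearest rotated neighbour under a greedy one-to-one
# matching; this preserves the spatial autocorrelation of the map.

## One uniformly distributed rotation matrix (det +1) via QR of a Gaussian.
random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_out)
  Q <- Q %*% diag(sign(diag(qr.R(qr_out))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Greedy one-to-one assignment: repeatedly match the globally closest
## (original, rotated) pair. Returns perm with perm[i] = index of the region
## whose value region i receives.
greedy_assign <- function(D) {
  n <- nrow(D)
  perm <- integer(n)
  D_work <- D
  for (step in seq_len(n)) {
    k <- which.min(D_work)
    i <- (k - 1) %% n + 1
    j <- (k - 1) %/% n + 1
    perm[i] <- j
    D_work[i, ] <- Inf
    D_work[, j] <- Inf
  }
  perm
}

#' Generate spin permutations from a parcellation
#'
#' Builds `n_perm` permutation vectors by rotating the parcellation's
#' unit-sphere centroids. Hemispheres are rotated with mirrored rotations
#' (`M R M`, `M = diag(-1, 1, 1)`) and matched independently, so regions
#' never cross the midline. Regions without coordinates (e.g. subcortex)
#' would make a rotation undefined; the parcellation must provide `x`, `y`,
#' `z` for all rows.
#'
#' @param parcellation A data.frame with columns `region`, `hemisphere`
#'   (`"L"`/`"R"`), and unit-sphere centroid coordinates `x`, `y`, `z`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return An `n_perm` x regions integer matrix of permutation indices.
#' @export
spin_permutations <- function(parcellation, n_perm = 1000L, seed = 1L) {
  req <- c("region", "hemisphere", "x", "y", "z")
  if (!all(req %in% names(parcellation))) {
    stop("parcellation must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyNA(parcellation[, c("x", "y", "z")])) {
    stop("missing centroid coordinates; use permute_labels fallback", call. = FALSE)
  }
  n <- nrow(parcellation)
  XYZ <- as.matrix(parcellation[, c("x", "y", "z")])
  hemi <- parcellation$hemisphere
  M <- diag(c(-1, 1, 1))
  with_seed(seed, {
    perms <- matrix(0L, n_perm, n)
    for (p in seq_len(n_perm)) {
      R_right <- random_rotation()
      R_left <- M %*% R_right %*% M
      for (h in unique(hemi)) {
        idx <- which(hemi == h)
        R_h <- if (h == "L") R_left else R_right
        rot <- XYZ[idx, , drop = FALSE] %*% t(R_h)
        D <- as.matrix(stats::dist(rbind(XYZ[idx, , drop = FALSE], rot)))
        D <- D[seq_along(idx), length(idx) + seq_along(idx), drop = FALSE]
        perms[p, idx] <- idx[greedy_assign(D)]
      }
    }
    perms
  })
}

#' Spin test for network-level map correlations
#'
#' Tests the per-network correlations between a subjects x regions change map
#' and a per-subject score (see [network_correlation()]) against a spatial
#' null obtained by spinning the region values. P-values use the add-one
#' convention `p = (1 + #\{|null| >= |obs|\}) / (1 + n_perm)` and are
#' BH-corrected across networks.
#'
#' @param delta A subjects x regions matrix of per-region changes.
#' @param scores Per-subject scores.
#' @param networks Named vector region -> network label.
#' @param parcellation Parcellation table with centroids (see
#'   [spin_permutations()]). Ignored when `perms` is supplied.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param q FDR level across networks (default 0.05).
#' @param perms Optional precomputed permutation matrix (reused across maps).
#' @param fallback If `"labels"`, missing centroid coordinates fall back to
#'   plain region-label permutation (flagged in the result) instead of
#'   failing; `"error"` (default) stops.
#' @return A list of class `"spin_test"`: data.frame `result` (network, r, p,
#'   p_adjusted, significant), matrix `null` (n_perm x networks), and
#'   `method`.
#' @export
spin_test <- function(delta, scores, networks, parcellation = NULL,
                      n_perm = 1000L, seed = 1L, q = 0.05, perms = NULL,
                      fallback = c("error", "labels")) {
  fallback <- match.arg(fallback)
  obs <- network_correlation(delta, networks, scores)
  method <- "spin"
  if (is.null(perms)) {
    coords_ok <- !is.null(parcellation) &&
      all(c("x", "y", "z") %in% names(parcellation)) &&
      !anyNA(parcellation[, c("x", "y", "z")])
    if (coords_ok) {
      perms <- spin_permutations(parcellation, n_perm = n_perm, seed = seed)
    } else if (fallback == "labels") {
      method <- "label_permutation"
      n <- ncol(delta)
      perms <- with_seed(seed, t(replicate(n_perm, sample.int(n))))
    } else {
      stop("parcellation lacks centroid coordinates (set fallback = \"labels\" to permute labels)",
           call. = FALSE)
    }
  }
  nets <- networks[colnames(delta)]
  levs <- obs$network
  ind <- vapply(levs, function(nl) as.numeric(nets == nl), numeric(length(nets)))
  ind <- sweep(ind, 2, colSums(ind), `/`)      # regions x networks averaging matrix
  null <- matrix(NA_real_, nrow(perms), length(levs), dimnames = list(NULL, levs))
  sc <- scores - mean(scores)
  for (p in seq_len(nrow(perms))) {
    Dp <- delta[, perms[p, ], drop = FALSE]
    Mnet <- Dp %*% ind                          # subjects x networks
    null[p, ] <- suppressWarnings(stats::cor(Mnet, sc))
  }
  null[is.na(null)] <- 0
  pvals <- vapply(seq_along(levs), function(j) {
    (1 + sum(abs(null[, j]) >= abs(obs$r[j]))) / (1 + nrow(perms))
  }, numeric(1))
  adj <- fdr_bh(pvals, q)
  structure(list(
    result = data.frame(network = levs, r = obs$r, p = pvals,
                        p_adjusted = adj$p_adjusted, significant = adj$reject,
                        stringsAsFactors = FALSE),
    null = null, method = method, n_perm = nrow(perms)),
    class = "spin_test")
}
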