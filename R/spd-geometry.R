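# Affine-invariant Riemannian operations on symmetric positive-definite (SPD)
# matrices. Functional-connectivity covariance estimates live on the SPD
# manifold; all centering and averaging here uses the affine-invariant metric,
# under which distances are preserved by congruence transforms M %*% S %*% t(M).

#' Symmetrize a square matrix
#'
#' Returns `(M + t(M)) / 2`. Used throughout to remove floating-point
#' asymmetry accumulated by repeated matrix products.
#'
#' @param M A square numeric matrix.
#' @return A symmetric matrix of the same dimension.
#' @keywords internal
sym_part <- function(M) (M + t(M)) / 2

#' Validate an SPD matrix
#'
#' Checks that `S` is a square numeric matrix, symmetric to within a relative
#' tolerance, and has strictly positive eigenvalues.
#'
#' @param S Matrix to validate.
#' @param tol Relative symmetry tolerance (default `1e-8` on the scale of the
#'   largest absolute entry).
#' @param arg Name used in error messages.
#' @return Invisibly, the symmetrized matrix.
#' @export
validate_spd <- function(S, tol = 1e-8, arg = deparse(substitute(S))) {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S)) {
    stop(sprintf("'%s' must be a square numeric matrix", arg), call. = FALSE)
  }
  scale <- max(abs(S), 1e-300)
  if (max(abs(S - t(S))) > tol * scale) {
    stop(sprintf("'%s' is not symmetric (relative asymmetry > %g)", arg, tol),
         call. = FALSE)
  }
  ev <- eigen(sym_part(S), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("'%s' is not positive definite (min eigenvalue %g)", arg, min(ev)),
         call. = FALSE)
  }
  invisible(sym_part(S))
}

## Shared eigendecomposition backbone. Eigenvalues positive but below
## floor_frac * max(ev) are floored (with a warning) before f() is applied;
## non-positive eigenvalues are an error when require_spd is TRUE.
spd_eig_fun <- function(S, f, require_spd = TRUE, floor_frac = 1e-10,
                        arg = "S") {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop(sprintf("'%s' must be a square matrix", arg), call. = FALSE)
  }
  if (max(abs(S - t(S))) > 1e-8 * max(abs(S), 1e-300)) {
    stop(sprintf("'%s' is not symmetric", arg), call. = FALSE)
  }
  e <- eigen(sym_part(S), symmetric = TRUE)
  ev <- e$values
  if (require_spd) {
    if (min(ev) <= 0) {
      stop(sprintf("'%s' is not positive definite (min eigenvalue %g)",
                   arg, min(ev)), call. = FALSE)
    }
    floor_val <- floor_frac * max(ev)
    if (min(ev) < floor_val) {
      warning(sprintf("'%s': %d eigenvalue(s) below %g floored before transform",
                      arg, sum(ev < floor_val), floor_val), call. = FALSE)
      ev <- pmax(ev, floor_val)
    }
  }
  out <- sym_part(e$vectors %*% (f(ev) * t(e$vectors)))
  dimnames(out) <- dimnames(S)
  out
}

#' Matrix power of an SPD matrix
#'
#' Computes `S^p` through the eigendecomposition `S = U diag(d) U'`, i.e.
#' `U diag(d^p) U'`. For `p > 0` the result is again SPD; for any real `p`
#' the result is symmetric.
#'
#' @param S An SPD matrix.
#' @param p Real exponent (e.g. `1/2`, `-1/2`).
#' @return A symmetric matrix; SPD whenever `S` is SPD.
#' @examples
#' spd_power(diag(c(4, 9)), 1/2)  # diag(2, 3)
#' @export
spd_power <- function(S, p) {
  stopifnot(is.numeric(p), length(p) == 1)
  spd_eig_fun(S, function(d) d^p, arg = deparse(substitute(S)))
}

#' Matrix logarithm of an SPD matrix
#'
#' The principal logarithm `U diag(log d) U'`. Maps the SPD cone onto the
#' space of symmetric matrices; inverse of [sym_exp()].
#'
#' @param S An SPD matrix.
#' @return A symmetric matrix.
#' @export
spd_log <- function(S) {
  spd_eig_fun(S, log, arg = deparse(substitute(S)))
}

#' Matrix exponential of a symmetric matrix
#'
#' `U diag(exp d) U'` for symmetric input; the result is always SPD.
#'
#' @param T_mat A symmetric matrix.
#' @return An SPD matrix.
#' @export
sym_exp <- function(T_mat) {
  spd_eig_fun(T_mat, exp, require_spd = FALSE,
              arg = deparse(substitute(T_mat)))
}

#' Affine-invariant distance between two SPD matrices
#'
#' `||log(A^{-1/2} B A^{-1/2})||_F`, computed via Cholesky whitening. The
#' distance is symmetric in its arguments, zero iff `A == B`, and invariant
#' under joint congruence `A -> M A M'`, `B -> M B M'`.
#'
#' @param A,B SPD matrices of common dimension.
#' @return A non-negative scalar.
#' @export
affine_distance <- function(A, B) {
  validate_spd(A, arg = "A"); validate_spd(B, arg = "B")
  if (!all(dim(A) == dim(B))) stop("dimension mismatch between A and B", call. = FALSE)
  L <- t(chol(sym_part(A)))          # lower triangular, A = L L'
  W <- forwardsolve(L, t(forwardsolve(L, B)))
  ev <- eigen(sym_part(W), symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

#' Pairwise affine-invariant distance matrix
#'
#' @param mats A list of SPD matrices of common dimension.
#' @return A symmetric `length(mats)` x `length(mats)` distance matrix.
#' @export
affine_distance_matrix <- function(mats) {
  n <- length(mats)
  chols <- lapply(mats, function(S) t(chol(sym_part(S))))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Li <- chols[[i]]
    for (j in (i + 1):n) {
      W <- forwardsolve(Li, t(forwardsolve(Li, mats[[j]])))
      ev <- eigen(sym_part(W), symmetric = TRUE, only.values = TRUE)$values
      D[i, j] <- D[j, i] <- sqrt(sum(log(ev)^2))
    }
  }
  D
}

#' Karcher (Fréchet) geometric mean of SPD matrices
#'
#' The point `M` minimizing the summed squared affine-invariant distances to
#' the inputs, characterized by the first-order condition
#' `sum_k log(M^{-1/2} S_k M^{-1/2}) = 0`. Solved by fixed-point iteration
#' `M <- M^{1/2} exp(mean_k log(M^{-1/2} S_k M^{-1/2})) M^{1/2}` with unit
#' step, initialized at the log-Euclidean mean `exp(mean_k log S_k)`.
#'
#' @param mats A non-empty list of SPD matrices of common dimension.
#' @param tol Convergence tolerance on the Frobenius norm of the mean tangent
#'   vector (default `1e-8`).
#' @param max_iter Maximum number of fixed-point iterations (default 50).
#' @return The SPD geometric mean.
#' @examples
#' M <- spd_geometric_mean(list(diag(c(1, 4)), diag(c(4, 1))))  # diag(2, 2)
#' @export
spd_geometric_mean <- function(mats, tol = 1e-8, max_iter = 50L) {
  if (!is.list(mats) || length(mats) == 0) {
    stop("'mats' must be a non-empty list of SPD matrices", call. = FALSE)
  }
  dims <- vapply(mats, function(S) nrow(S), integer(1))
  if (length(unique(dims)) != 1) stop("matrices differ in dimension", call. = FALSE)
  if (length(mats) == 1) return(sym_part(mats[[1]]))
  logs <- lapply(mats, spd_log)
  M <- sym_exp(Reduce(`+`, logs) / length(logs))
  for (iter in seq_len(max_iter)) {
    Mh <- spd_power(M, 1/2)
    Mih <- spd_power(M, -1/2)
    Tbar <- Reduce(`+`, lapply(mats, function(S) spd_log(sym_part(Mih %*% S %*% Mih))))
    Tbar <- Tbar / length(mats)
    resid <- sqrt(sum(Tbar^2))
    if (resid <= tol) return(M)
    M <- sym_part(Mh %*% sym_exp(Tbar) %*% Mh)
  }
  stop(sprintf("Karcher mean did not converge in %d iterations (residual %g)",
               max_iter, resid), call. = FALSE)
}

#' Project an SPD matrix onto the tangent space at a base point
#'
#' Returns the tangent vector
#' `T = base^{1/2} log(base^{-1/2} S base^{-1/2}) base^{1/2}`, a symmetric
#' matrix representing the displacement of `S` from `base`. Inverted by
#' [tangent_retract()].
#'
#' @param S An SPD matrix.
#' @param base The SPD base point.
#' @return A symmetric matrix (tangent vector at `base`).
#' @export
tangent_project <- function(S, base) {
  if (!all(dim(S) == dim(base))) stop("dimension mismatch", call. = FALSE)
  Bh <- spd_power(base, 1/2)
  Bih <- spd_power(base, -1/2)
  sym_part(Bh %*% spd_log(sym_part(Bih %*% S %*% Bih)) %*% Bh)
}

#' Map a tangent vector back to the SPD manifold
#'
#' The exponential map
#' `S = base^{1/2} exp(base^{-1/2} T base^{-1/2}) base^{1/2}`; the inverse of
#' [tangent_project()] at the same base point. Always returns an SPD matrix.
#'
#' @param T_mat A symmetric tangent vector.
#' @param base The SPD base point.
#' @return An SPD matrix.
#' @export
tangent_retract <- function(T_mat, base) {
  if (!all(dim(T_mat) == dim(base))) stop("dimension mismatch", call. = FALSE)
  Bh <- spd_power(base, 1/2)
  Bih <- spd_power(base, -1/2)
  sym_part(Bh %*% sym_exp(sym_part(Bih %*% T_mat %*% Bih)) %*% Bh)
}

#' Transport map between two SPD base points
#'
#' Constructs `G = target^{1/2} %*% source^{-1/2}`, the congruence that
#' carries tangent vectors at `source` to tangent vectors at `target` while
#' preserving the affine-invariant norm.
#'
#' @param source,target SPD matrices of common dimension.
#' @return A list of class `"transport_map"` with elements `G`, `source`,
#'   `target`.
#' @export
transport_map <- function(source, target) {
  validate_spd(source, arg = "source"); validate_spd(target, arg = "target")
  if (!all(dim(source) == dim(target))) stop("dimension mismatch", call. = FALSE)
  structure(list(G = spd_power(target, 1/2) %*% spd_power(source, -1/2),
                 source = source, target = target),
            class = "transport_map")
}

#' Parallel transport of a tangent vector
#'
#' Applies `T' = G %*% T %*% t(G)` for a [transport_map()] `G`. The
#' affine-invariant (whitened) Frobenius norm is preserved:
#' `||source^{-1/2} T source^{-1/2}||_F == ||target^{-1/2} T' target^{-1/2}||_F`.
#'
#' @param T_mat A symmetric tangent vector at `map$source`.
#' @param map A `"transport_map"` object.
#' @return The transported symmetric tangent vector at `map$target`.
#' @export
parallel_transport <- function(T_mat, map) {
  if (!inherits(map, "transport_map")) stop("'map' must be a transport_map", call. = FALSE)
  if (!all(dim(T_mat) == dim(map$G))) stop("dimension mismatch", call. = FALSE)
  sym_part(map$G %*% T_mat %*% t(map$G))
}

#' Riemannian centering of a covariance dataset
#'
#' Removes stable subject-specific structure from a collection of per-epoch
#' covariance matrices. For each subject `i`, the geometric mean of that
#' subject's epochs (`S_bar_i`) and the grand geometric mean over all
#' matrices (`S_bar_gm`) are computed. Every matrix is then (1) projected to
#' the tangent space at its subject mean, (2) parallel-transported to the
#' grand mean via `G = S_bar_gm^{1/2} S_bar_i^{-1/2}`, and (3) retracted back
#' to the manifold at the grand mean. After centering, the geometric mean of
#' each subject's matrices equals the grand mean, so only epoch-specific
#' displacements remain.
#'
#' @param covs A list of SPD matrices (one per subject/epoch observation).
#' @param subject A vector of subject identifiers, one per element of `covs`.
#' @param tol,max_iter Passed to [spd_geometric_mean()].
#' @return A list with elements `centered` (list of SPD matrices, same order
#'   and names as `covs`), `grand_mean`, and `subject_means` (named list).
#' @export
center_covariances <- function(covs, subject, tol = 1e-8, max_iter = 50L) {
  if (length(covs) != length(subject)) {
    stop("'subject' must have one entry per covariance matrix", call. = FALSE)
  }
  subject <- as.character(subject)
  grand_mean <- tryCatch(
    spd_geometric_mean(covs, tol = tol, max_iter = max_iter),
    error = function(e) stop("grand mean estimation failed: ", conditionMessage(e),
                             call. = FALSE))
  subj_ids <- unique(subject)
  subject_means <- setNames(vector("list", length(subj_ids)), subj_ids)
  centered <- vector("list", length(covs))
  names(centered) <- names(covs)
  gm_h <- spd_power(grand_mean, 1/2)
  gm_ih <- spd_power(grand_mean, -1/2)
  for (s in subj_ids) {
    idx <- which(subject == s)
    Si <- tryCatch(
      spd_geometric_mean(covs[idx], tol = tol, max_iter = max_iter),
      error = function(e) stop(sprintf("subject '%s': mean estimation failed: %s",
                                       s, conditionMessage(e)), call. = FALSE))
    subject_means[[s]] <- Si
    Si_h <- spd_power(Si, 1/2)
    Si_ih <- spd_power(Si, -1/2)
    G <- gm_h %*% Si_ih
    for (k in idx) {
      Tk <- tryCatch(
        sym_part(Si_h %*% spd_log(sym_part(Si_ih %*% covs[[k]] %*% Si_ih)) %*% Si_h),
        error = function(e) stop(sprintf("subject '%s', observation %d: %s",
                                         s, k, conditionMessage(e)), call. = FALSE))
      Tc <- sym_part(G %*% Tk %*% t(G))
      centered[[k]] <- sym_part(gm_h %*% sym_exp(sym_part(gm_ih %*% Tc %*% gm_ih)) %*% gm_h)
      dimnames(centered[[k]]) <- dimnames(covs[[k]])
    }
  }
  list(centered = centered, grand_mean = grand_mean, subject_means = subject_means)
}

#' Mean silhouette width of a labelled distance matrix
#'
#' Convenience wrapper around [cluster::silhouette()] used to quantify how
#' strongly a set of covariance matrices clusters by a grouping label (e.g.
#' subject identity) under the affine-invariant distance.
#'
#' @param D A symmetric distance matrix.
#' @param labels Grouping labels, one per row of `D`.
#' @return Mean silhouette width (scalar in `[-1, 1]`).
#' @export
silhouette_by_label <- function(D, labels) {
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(D)) stop("label length must match distance matrix", call. = FALSE)
  sil <- cluster::silhouette(labels, dmatrix = D)
  mean(sil[, "sil_width"])
}
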