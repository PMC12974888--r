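# From parcellated BOLD time series to per-epoch covariance matrices and
# seed-level contrast maps. Time series are stored as regions x volumes
# matrices with region ids as rownames.

#' Z-score region time series
#'
#' Standardizes each region (row) to mean 0 and standard deviation 1 using
#' the population (`n`) denominator.
#'
#' @param ts A regions x volumes numeric matrix with region ids as rownames.
#' @return The standardized matrix.
#' @export
zscore_timeseries <- function(ts) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (anyNA(ts)) stop("time series contain missing values", call. = FALSE)
  mu <- rowMeans(ts)
  cen <- ts - mu
  sdp <- sqrt(rowMeans(cen^2))
  zero <- which(sdp == 0)
  if (length(zero)) {
    ids <- if (!is.null(rownames(ts))) rownames(ts)[zero] else as.character(zero)
    stop("zero-variance region(s): ", paste(ids, collapse = ", "), call. = FALSE)
  }
  cen / sdp
}

#' Define the standard task epochs
#'
#' Builds the five equal-length task epochs used throughout the pipeline:
#' Baseline, Early Learning and Late Learning from the task scan, Early and
#' Late Washout from the washout scan. Start volumes are 0-based offsets into
#' the scan counted *after* discarding the initial volumes. Baseline and
#' Early Washout take the first `epoch_volumes` post-discard volumes of their
#' block; Late Learning and Late Washout take the last.
#'
#' @param baseline_trials,learning_trials,washout_trials Trials per block
#'   (defaults 120/320/120).
#' @param volumes_per_trial Imaging volumes per trial (default 2: 4 s trials
#'   at a 2 s sampling interval).
#' @param epoch_volumes Volumes per epoch (default 96 = 48 trials).
#' @return A data.frame with columns `name`, `scan`, `start`, `length`.
#' @export
default_epochs <- function(baseline_trials = 120L, learning_trials = 320L,
                           washout_trials = 120L, volumes_per_trial = 2L,
                           epoch_volumes = 96L) {
  bl <- baseline_trials * volumes_per_trial
  lr <- learning_trials * volumes_per_trial
  wo <- washout_trials * volumes_per_trial
  if (epoch_volumes > min(bl, wo) || 2L * epoch_volumes > lr) {
    stop("epoch length exceeds block length", call. = FALSE)
  }
  data.frame(
    name  = c("Baseline", "EarlyLearning", "LateLearning", "EarlyWashout", "LateWashout"),
    scan  = c("task", "task", "task", "washout", "washout"),
    start = c(0L, bl, bl + lr - epoch_volumes, 0L, wo - epoch_volumes),
    length = epoch_volumes,
    stringsAsFactors = FALSE
  )
}

#' Splice scans into task epochs
#'
#' Cuts per-scan region time series into the epoch blocks defined by an epoch
#' table (see [default_epochs()]), discarding the first `discard_initial`
#' volumes of each scan before applying the 0-based epoch windows.
#'
#' @param scans A named list of regions x volumes matrices, one per scan
#'   (names must cover `unique(epochs$scan)`).
#' @param epochs An epoch-definition data.frame (`name`, `scan`, `start`,
#'   `length`).
#' @param discard_initial Number of initial volumes dropped per scan
#'   (default 6).
#' @return A named list of regions x `length` matrices, one per epoch.
#' @export
splice_epochs <- function(scans, epochs = default_epochs(), discard_initial = 6L) {
  stopifnot(is.list(scans), is.data.frame(epochs))
  out <- vector("list", nrow(epochs))
  names(out) <- epochs$name
  for (i in seq_len(nrow(epochs))) {
    sc <- epochs$scan[i]
    if (is.null(scans[[sc]])) stop("missing scan '", sc, "'", call. = FALSE)
    X <- scans[[sc]]
    cols <- discard_initial + epochs$start[i] + seq_len(epochs$length[i])
    if (max(cols) > ncol(X)) {
      stop(sprintf("epoch '%s' window [%d, %d] exceeds scan '%s' length %d",
                   epochs$name[i], min(cols), max(cols), sc, ncol(X)),
           call. = FALSE)
    }
    out[[i]] <- X[, cols, drop = FALSE]
  }
  out
}

#' Map trial indices to volume indices within an epoch block
#'
#' With `volumes_per_trial` volumes per trial, trial `t` (1-based within the
#' epoch) occupies volumes `(t-1)*vpt + 1 .. t*vpt` (1-based) of the block.
#'
#' @param trials Integer trial indices (1-based, within epoch).
#' @param volumes_per_trial Volumes per trial (default 2).
#' @return An integer vector of 1-based volume indices.
#' @export
trial_volumes <- function(trials, volumes_per_trial = 2L) {
  as.integer(t(outer((trials - 1L) * volumes_per_trial, seq_len(volumes_per_trial), `+`)))
}

#' Ledoit–Wolf shrinkage covariance estimator
#'
#' Shrinks the sample covariance toward a scaled identity with the
#' analytically estimated optimal intensity of Ledoit & Wolf's
#' well-conditioned estimator: `(1 - a) * S + a * mu * I`, where
#' `mu = tr(S)/p` and `a` minimizes expected quadratic loss. The estimate is
#' positive definite even when regions outnumber volumes, which is the
#' regime of 96-volume epochs over hundreds of regions.
#'
#' @param block A regions x volumes numeric matrix (observations in columns).
#' @return An SPD covariance matrix with attribute `"shrinkage"` (the
#'   intensity in `[0, 1]`).
#' @export
ledoit_wolf_cov <- function(block) {
  stopifnot(is.matrix(block), is.numeric(block))
  p <- nrow(block); n <- ncol(block)
  if (n < 2) stop("at least 2 volumes are required", call. = FALSE)
  X <- block - rowMeans(block)              # p x n, demeaned per region
  S <- tcrossprod(X) / n
  mu <- sum(diag(S)) / p
  delta2 <- sum((S - diag(mu, p))^2) / p
  if (delta2 == 0) {
    out <- diag(mu, p)
    attr(out, "shrinkage") <- 0
    dimnames(out) <- list(rownames(block), rownames(block))
    return(out)
  }
  # sum_i ||x_i x_i' - S||_F^2 = sum_i (x_i . x_i)^2 - n ||S||_F^2
  xnorm4 <- sum(colSums(X^2)^2)
  beta2 <- min((xnorm4 - n * sum(S^2)) / (n^2 * p), delta2)
  a <- beta2 / delta2
  out <- sym_part((1 - a) * S + diag(a * mu, p))
  dimnames(out) <- list(rownames(block), rownames(block))
  attr(out, "shrinkage") <- a
  out
}

#' Regress nuisance principal components out of target time series
#'
#' Extracts the top `n_components` principal components of the nuisance
#' region set (time courses as observations), z-scores them, and regresses
#' them (with an intercept) out of every target region's time series.
#' Residual target series are orthogonal to the retained components.
#'
#' @param targets Regions x volumes matrix to be cleaned.
#' @param nuisance Regions x volumes matrix providing the nuisance signals.
#' @param n_components Number of nuisance components to remove (default 3).
#' @return The cleaned `targets` matrix (intercept removed), with attribute
#'   `"components"` holding the volumes x `n_components` regressor matrix.
#' @export
nuisance_regress_components <- function(targets, nuisance, n_components = 3L) {
  stopifnot(is.matrix(targets), is.matrix(nuisance),
            ncol(targets) == ncol(nuisance))
  if (nrow(nuisance) == 0) stop("nuisance set is empty", call. = FALSE)
  if (n_components > nrow(nuisance)) {
    stop("n_components exceeds nuisance region count", call. = FALSE)
  }
  pc <- stats::prcomp(t(nuisance), center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > 1e-12 * pc$sdev[1]) < n_components) {
    stop("nuisance set is rank-deficient for the requested components", call. = FALSE)
  }
  Z <- scale(pc$x[, seq_len(n_components), drop = FALSE])  # volumes x k, z-scored
  X <- cbind(1, Z)
  beta <- solve(crossprod(X), crossprod(X, t(targets)))
  cleaned <- t(t(targets) - X %*% beta)
  dimnames(cleaned) <- dimnames(targets)
  attr(cleaned, "components") <- Z
  cleaned
}

#' Mean activation per region within an epoch block
#'
#' Arithmetic mean of each region's (z-scored) time series over the epoch's
#' volumes; the univariate activation control for connectivity effects.
#'
#' @param block A regions x volumes matrix.
#' @return A named numeric vector of per-region means.
#' @export
epoch_mean_activation <- function(block) {
  stopifnot(is.matrix(block))
  rowMeans(block)
}

#' Seed connectivity contrast between epoch sets
#'
#' For a seed region, averages its covariance row over the epochs in
#' `epochs_a` and `epochs_b` within each subject, then runs per-region paired
#' t-tests of the A-vs-B difference across subjects. Network-level summaries
#' are the paired t-statistics of the subject-level mean seed-to-network
#' connectivity change (seed's self-entry excluded).
#'
#' @param covs A list of SPD matrices (centered covariances) with region
#'   dimnames.
#' @param meta A data.frame aligned with `covs` carrying at least columns
#'   `subject` and `epoch` (epoch keys such as `"d1_EarlyLearning"`).
#' @param seed Seed region id (must appear in the matrices' rownames).
#' @param epochs_a,epochs_b Character vectors of epoch keys to average for
#'   each condition.
#' @param networks A named vector mapping region id to network label.
#' @return A list of class `"seed_contrast"` with per-region `t`, `p`, the
#'   mean difference `delta`, and a data.frame `network` of per-network
#'   t-statistics.
#' @export
seed_contrast <- function(covs, meta, seed, epochs_a, epochs_b, networks) {
  regions <- rownames(covs[[1]])
  if (is.null(regions)) stop("covariances must carry region dimnames", call. = FALSE)
  if (!seed %in% regions) stop("unknown seed region '", seed, "'", call. = FALSE)
  subjects <- unique(meta$subject)
  row_mean <- function(subj, eps) {
    idx <- which(meta$subject == subj & meta$epoch %in% eps)
    if (length(idx) != length(eps)) {
      stop(sprintf("subject '%s' is missing epochs: %s", subj,
                   paste(setdiff(eps, meta$epoch[meta$subject == subj]), collapse = ", ")),
           call. = FALSE)
    }
    rowMeans(vapply(idx, function(k) covs[[k]][seed, ], numeric(length(regions))))
  }
  A <- t(vapply(subjects, row_mean, numeric(length(regions)), eps = epochs_a))
  B <- t(vapply(subjects, row_mean, numeric(length(regions)), eps = epochs_b))
  D <- A - B                                  # subjects x regions
  n <- length(subjects)
  dbar <- colMeans(D)
  dsd <- apply(D, 2, stats::sd)
  tstat <- ifelse(dsd == 0, 0, dbar / (dsd / sqrt(n)))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
  keep <- setdiff(regions, seed)
  net_levels <- sort(unique(networks[keep]))
  net_t <- vapply(net_levels, function(nl) {
    rs <- keep[networks[keep] == nl]
    m <- rowMeans(D[, rs, drop = FALSE])      # subject-level mean change
    s <- stats::sd(m)
    if (s == 0) 0 else mean(m) / (s / sqrt(n))
  }, numeric(1))
  structure(list(seed = seed, regions = regions,
                 t = setNames(tstat, regions), p = setNames(pval, regions),
                 delta = setNames(dbar, regions),
                 network = data.frame(network = net_levels, t = unname(net_t),
                                      stringsAsFactors = FALSE)),
            class = "seed_contrast")
}
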