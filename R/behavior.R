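# Behavioural pipeline for the two-day visuomotor rotation task: trial QC,
# 8-trial binning, initial error, savings, adaptation proxy, recall ratio,
# and a functional-PCA learning score.
#
# Trial tables are data.frames with columns subject, day, block
# ("Baseline"/"Learning"/"Washout"), trial, error_deg, rt_ms.

#' Trial quality control
#'
#' Flags trials with reaction times strictly below 100 ms or strictly above
#' 2000 ms, or with no movement initiation within the 2.6 s response window
#' (`rt_ms` of `NA`). Flagged trials are retained in the table (column
#' `excluded`), never deleted.
#'
#' @param trials A trial table.
#' @param rt_min,rt_max Reaction-time bounds in ms (defaults 100 and 2000;
#'   trials at exactly the bound are kept).
#' @return The trial table with a logical `excluded` column, plus an
#'   attribute `"exclusion_report"` summarising counts per subject.
#' @export
trial_qc <- function(trials, rt_min = 100, rt_max = 2000) {
  stopifnot(all(c("subject", "day", "block", "trial", "error_deg", "rt_ms") %in%
                  names(trials)))
  if (any(abs(trials$error_deg) > 180, na.rm = TRUE)) {
    stop("angular errors must lie in [-180, 180] degrees", call. = FALSE)
  }
  excl <- is.na(trials$rt_ms) | trials$rt_ms < rt_min | trials$rt_ms > rt_max
  trials$excluded <- excl
  rep <- stats::aggregate(excluded ~ subject, data = trials, FUN = sum)
  rep$total <- as.vector(table(trials$subject)[as.character(rep$subject)])
  attr(trials, "exclusion_report") <- rep
  trials
}

#' Bin a trial error sequence into fixed-size bins
#'
#' Averages consecutive trials into `bin_size`-trial bins, ignoring excluded
#' trials within each bin. Bins whose trials are all excluded yield `NA`
#' (interpolated later, before smoothing). A trailing partial bin (when the
#' trial count is not divisible by `bin_size`) is averaged over the trials it
#' contains.
#'
#' @param errors Numeric vector of angular errors in trial order.
#' @param excluded Optional logical vector flagging excluded trials.
#' @param bin_size Trials per bin (default 8).
#' @return A numeric vector of bin means.
#' @export
bin_curve <- function(errors, excluded = NULL, bin_size = 8L) {
  if (is.null(excluded)) excluded <- rep(FALSE, length(errors))
  stopifnot(length(excluded) == length(errors))
  idx <- ceiling(seq_along(errors) / bin_size)
  vals <- ifelse(excluded, NA_real_, errors)
  out <- tapply(vals, idx, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  as.numeric(out)
}

#' Initial error of a learning block
#'
#' Median angular error over the first 16 trials (two full cycles of the
#' eight targets) of a learning block.
#'
#' @param errors Angular errors of the learning block, in trial order.
#' @return The median of the first 16 trials, in degrees.
#' @export
initial_error <- function(errors) {
  if (length(errors) < 16) stop("at least 16 learning trials are required", call. = FALSE)
  stats::median(errors[1:16])
}

#' Behavioural savings
#'
#' Day 1 initial error minus Day 2 initial error; positive values indicate
#' faster relearning, negative values worse relearning.
#'
#' @param d1_initial,d2_initial Initial errors (degrees) for the two days.
#' @return Savings in degrees.
#' @export
savings <- function(d1_initial, d2_initial) d1_initial - d2_initial

#' Adaptation-performance proxy
#'
#' `A = 45 - |error|` for the 45-degree rotation: 45 at perfect compensation,
#' 0 at no compensation, negative if error exceeds the imposed rotation.
#'
#' @param error Signed angular error(s) in degrees.
#' @param rotation Imposed rotation magnitude (default 45).
#' @return The adaptation proxy, same length as `error`.
#' @export
adaptation_proxy <- function(error, rotation = 45) rotation - abs(error)

#' Recall ratio
#'
#' `RR = A_d2_early / A_d1_late`, the early Day 2 adaptation relative to late
#' Day 1 adaptation. `RR` near 1 indicates near-complete recall of the
#' learned state; below 1 partial recall. When late Day 1 adaptation falls
#' below the stability threshold the ratio is undefined (`NA`), and the
#' subject is excluded from RR correlations only.
#'
#' @param a_d1_late Late Day 1 adaptation proxy (degrees).
#' @param a_d2_early Early Day 2 adaptation proxy (degrees).
#' @param stability_threshold Minimum denominator (default 5 degrees).
#' @return The recall ratio, or `NA` when undefined.
#' @export
recall_ratio <- function(a_d1_late, a_d2_early, stability_threshold = 5) {
  ifelse(a_d1_late < stability_threshold, NA_real_, a_d2_early / a_d1_late)
}

## Penalized B-spline smoothing matrix pieces shared by fpca_learning_score:
## basis on [0, 1] with n_basis cubic functions and the second-derivative
## penalty Gram matrix by trapezoidal quadrature.
bspline_basis <- function(tgrid, n_basis = 17L, order = 4L) {
  n_interior <- n_basis - order
  if (n_interior < 0) stop("n_basis must be at least the spline order", call. = FALSE)
  interior <- if (n_interior > 0) seq(0, 1, length.out = n_interior + 2)[-c(1, n_interior + 2)]
              else numeric(0)
  knots <- c(rep(0, order), interior, rep(1, order))
  splines::splineDesign(knots, tgrid, ord = order, outer.ok = FALSE)
}

bspline_penalty <- function(n_basis = 17L, order = 4L, n_quad = 501L) {
  n_interior <- n_basis - order
  interior <- if (n_interior > 0) seq(0, 1, length.out = n_interior + 2)[-c(1, n_interior + 2)]
              else numeric(0)
  knots <- c(rep(0, order), interior, rep(1, order))
  tq <- seq(0, 1, length.out = n_quad)
  D2 <- splines::splineDesign(knots, tq, ord = order, derivs = rep(2L, n_quad))
  h <- tq[2] - tq[1]
  w <- rep(h, n_quad); w[c(1, n_quad)] <- h / 2
  crossprod(D2, D2 * w)
}

#' Functional PCA learning score
#'
#' Represents each subject's binned two-day learning curve as a smooth
#' function (cubic B-spline basis, 17 basis functions, second-derivative
#' roughness penalty with the weight chosen by generalized cross-validation
#' over a log-spaced grid), then performs functional PCA across subjects on
#' the smoothed curves. The first component's subject loadings, sign-fixed so
#' that higher scores correspond to lower overall angular error, are the
#' Learning Scores. Bins with no valid trials are linearly interpolated from
#' their neighbours before smoothing.
#'
#' @param curves A subjects x bins matrix of binned angular errors (rownames
#'   = subject ids). At least 3 subjects.
#' @param n_basis Number of B-spline basis functions (default 17).
#' @param lambda_grid Candidate roughness penalties (default
#'   `10^seq(-8, 2, length.out = 21)`).
#' @return A list of class `"fpca_scores"`: `scores` (fPC1 loadings, named),
#'   `all_scores` (subjects x components), `harmonics` (bins x components),
#'   `variance_explained`, `mean_curve`, `lambda`, `smoothed` (subjects x
#'   bins).
#' @export
fpca_learning_score <- function(curves, n_basis = 17L,
                                lambda_grid = 10^seq(-8, 2, length.out = 21)) {
  stopifnot(is.matrix(curves))
  if (nrow(curves) < 3) stop("at least 3 subjects are required", call. = FALSE)
  nb <- ncol(curves)
  if (nb < n_basis) {
    stop(sprintf("only %d bins for %d basis functions; reduce n_basis", nb, n_basis),
         call. = FALSE)
  }
  ## interpolate empty bins
  for (i in seq_len(nrow(curves))) {
    if (anyNA(curves[i, ])) {
      ok <- which(!is.na(curves[i, ]))
      if (length(ok) < 2) stop("subject ", rownames(curves)[i],
                               " has fewer than 2 valid bins", call. = FALSE)
      curves[i, ] <- stats::approx(ok, curves[i, ok], xout = seq_len(nb),
                                   rule = 2)$y
    }
  }
  tgrid <- (seq_len(nb) - 0.5) / nb
  B <- bspline_basis(tgrid, n_basis)
  P <- bspline_penalty(n_basis)
  BtB <- crossprod(B)
  ## GCV over the lambda grid, averaged across subjects
  gcv <- vapply(lambda_grid, function(lam) {
    H <- B %*% solve(BtB + lam * P, t(B))
    tr_h <- sum(diag(H))
    fits <- curves %*% t(H)
    mean(rowSums((curves - fits)^2)) * nb / (nb - tr_h)^2
  }, numeric(1))
  lambda <- lambda_grid[which.min(gcv)]
  coefs <- t(solve(BtB + lambda * P, t(B) %*% t(curves)))   # subjects x n_basis
  smoothed <- coefs %*% t(B)                                # subjects x bins
  ## fPCA: PCA of the smoothed curves under the (uniform) quadrature weight.
  mean_curve <- colMeans(smoothed)
  Xc <- sweep(smoothed, 2, mean_curve)
  h <- 1 / nb
  sv <- svd(Xc * sqrt(h))
  n_comp <- min(nrow(curves) - 1L, nb)
  eigvals <- sv$d^2 / (nrow(curves) - 1)
  ve <- eigvals / sum(eigvals)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))         # weighted scores
  harmonics <- sv$v / sqrt(h)                                # orthonormal in L2
  scores <- scores[, seq_len(n_comp), drop = FALSE]
  harmonics <- harmonics[, seq_len(n_comp), drop = FALSE]
  ## sign conventions: fPC1 so higher score = lower mean error; others so the
  ## largest-|value| harmonic point is positive.
  mean_err <- rowMeans(curves)
  if (stats::sd(scores[, 1]) > 0 && stats::cor(scores[, 1], mean_err) > 0) {
    scores[, 1] <- -scores[, 1]; harmonics[, 1] <- -harmonics[, 1]
  }
  if (n_comp > 1) for (j in 2:n_comp) {
    if (harmonics[which.max(abs(harmonics[, j])), j] < 0) {
      scores[, j] <- -scores[, j]; harmonics[, j] <- -harmonics[, j]
    }
  }
  rownames(scores) <- rownames(curves)
  structure(list(scores = setNames(scores[, 1], rownames(curves)),
                 all_scores = scores, harmonics = harmonics,
                 variance_explained = ve[seq_len(n_comp)],
                 mean_curve = mean_curve, lambda = lambda,
                 smoothed = smoothed),
            class = "fpca_scores")
}

#' Median split into fast and slow learners
#'
#' Subjects with scores strictly greater than the median are labelled
#' `"fast"`, the rest `"slow"`; with an even number of distinct-valued
#' subjects this yields equal halves. The split is invariant to input order.
#'
#' @param scores A named numeric vector of Learning Scores.
#' @return A named character vector (`"fast"`/`"slow"`).
#' @export
median_split <- function(scores) {
  med <- stats::median(scores)
  setNames(ifelse(scores > med, "fast", "slow"), names(scores))
}

#' Behavioural scores for every subject
#'
#' Runs the full behavioural pipeline on a QC'd trial table: binned curves,
#' initial errors, savings, adaptation proxies for the imaging epochs (late
#' Day 1 learning and early Day 2 learning, 48 trials each by default),
#' recall ratio, fPCA Learning Score, and the fast/slow median split.
#'
#' @param trials A trial table (with or without prior [trial_qc()]).
#' @param epoch_trials Number of trials in the early/late windows
#'   (default 48, matching the imaging epochs).
#' @param bin_size Trials per bin (default 8).
#' @param rotation Imposed rotation (default 45 degrees).
#' @return A list of class `"behavior_scores"`: data.frame `scores` (one row
#'   per subject), the `fpca` fit, and the binned `curves` matrix.
#' @export
behavior_scores <- function(trials, epoch_trials = 48L, bin_size = 8L,
                            rotation = 45) {
  if (!"excluded" %in% names(trials)) trials <- trial_qc(trials)
  subjects <- unique(as.character(trials$subject))
  block_errors <- function(s, d, b) {
    rows <- trials$subject == s & trials$day == d & trials$block == b
    tr <- trials[rows, ]
    tr <- tr[order(tr$trial), ]
    tr
  }
  curves <- NULL
  per_subj <- lapply(subjects, function(s) {
    segs <- list()
    for (d in 1:2) for (b in c("Baseline", "Learning", "Washout")) {
      tr <- block_errors(s, d, b)
      segs[[paste(d, b)]] <- bin_curve(tr$error_deg, tr$excluded, bin_size)
    }
    unlist(segs, use.names = FALSE)
  })
  curves <- do.call(rbind, per_subj)
  rownames(curves) <- subjects

  get_clean <- function(s, d, b) {
    tr <- block_errors(s, d, b)
    tr$error_deg[!tr$excluded]
  }
  d1_init <- vapply(subjects, function(s) initial_error(get_clean(s, 1, "Learning")), numeric(1))
  d2_init <- vapply(subjects, function(s) initial_error(get_clean(s, 2, "Learning")), numeric(1))
  a_d1_late <- vapply(subjects, function(s) {
    e <- get_clean(s, 1, "Learning")
    mean(adaptation_proxy(utils::tail(e, epoch_trials), rotation))
  }, numeric(1))
  a_d2_early <- vapply(subjects, function(s) {
    e <- get_clean(s, 2, "Learning")
    mean(adaptation_proxy(utils::head(e, epoch_trials), rotation))
  }, numeric(1))
  rr <- recall_ratio(a_d1_late, a_d2_early)
  fp <- fpca_learning_score(curves)
  groups <- median_split(fp$scores)
  scores <- data.frame(subject = subjects,
                       learning_score = unname(fp$scores),
                       d1_initial_error = unname(d1_init),
                       d2_initial_error = unname(d2_init),
                       savings = unname(savings(d1_init, d2_init)),
                       a_d1_late = unname(a_d1_late),
                       a_d2_early = unname(a_d2_early),
                       recall_ratio = unname(rr),
                       group = unname(groups[subjects]),
                       stringsAsFactors = FALSE)
  structure(list(scores = scores, fpca = fp, curves = curves),
            class = "behavior_scores")
}
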