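# Region- and network-level statistics on eccentricity maps: mass-univariate
# repeated-measures ANOVA, FDR, paired contrasts, functional ensembles,
# reinstatement RSA, and network-score correlations.
#
# Eccentricity data are carried as a 4-D array [subject, day, epoch, region]
# with dimnames; epochs use the canonical order Baseline, EarlyLearning,
# LateLearning, EarlyWashout, LateWashout.

EPOCH_LEVELS <- c("Baseline", "EarlyLearning", "LateLearning",
                  "EarlyWashout", "LateWashout")

## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's RNG afterwards. Keeps stochastic routines reproducible without
## clobbering global state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Assemble an eccentricity array
#'
#' Stacks per-observation eccentricity vectors into the canonical
#' `[subject, day, epoch, region]` array used by the inference functions.
#'
#' @param ecc A matrix of eccentricities (observations x regions), e.g. from
#'   [eccentricity_stack()].
#' @param meta A data.frame aligned with the rows of `ecc` carrying columns
#'   `subject`, `day` (1 or 2), and `epoch` (one of the five epoch names).
#' @return A 4-D named array; errors if any subject/day/epoch cell is missing
#'   or duplicated.
#' @export
ecc_array <- function(ecc, meta) {
  subjects <- unique(as.character(meta$subject))
  regions <- colnames(ecc)
  out <- array(NA_real_,
               dim = c(length(subjects), 2, length(EPOCH_LEVELS), ncol(ecc)),
               dimnames = list(subjects, c("d1", "d2"), EPOCH_LEVELS, regions))
  for (i in seq_len(nrow(ecc))) {
    s <- as.character(meta$subject[i]); d <- paste0("d", meta$day[i])
    e <- as.character(meta$epoch[i])
    if (!is.na(out[s, d, e, 1])) stop("duplicate cell: ", s, "/", d, "/", e, call. = FALSE)
    out[s, d, e, ] <- ecc[i, ]
  }
  if (anyNA(out)) stop("incomplete design: missing subject/day/epoch cells", call. = FALSE)
  out
}

## Two-way within-subject ANOVA sums of squares for one region.
## y: [subject, day, epoch] array (balanced, one observation per cell).
rm_anova_cell <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  gm <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  ss_sa <- b * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + gm)^2)
  ss_sb <- a * sum((sweep(sweep(m_sb, 1, m_s), 2, m_b) + gm)^2)
  resid <- y
  for (s in seq_len(n)) for (d in seq_len(a)) for (e in seq_len(b)) {
    resid[s, d, e] <- y[s, d, e] - m_sa[s, d] - m_sb[s, e] - m_ab[d, e] +
      m_s[s] + m_a[d] + m_b[e] - gm
  }
  ss_sab <- sum(resid^2)
  list(
    F_day = (ss_a / (a - 1)) / (ss_sa / ((n - 1) * (a - 1))),
    F_epoch = (ss_b / (b - 1)) / (ss_sb / ((n - 1) * (b - 1))),
    F_interaction = (ss_ab / ((a - 1) * (b - 1))) / (ss_sab / ((n - 1) * (a - 1) * (b - 1))),
    df = list(day = c(a - 1, (n - 1) * (a - 1)),
              epoch = c(b - 1, (n - 1) * (b - 1)),
              interaction = c((a - 1) * (b - 1), (n - 1) * (a - 1) * (b - 1)))
  )
}

#' Region-wise 2 x 5 repeated-measures ANOVA
#'
#' For every region, a two-way within-subject ANOVA of eccentricity with
#' factors Day (2 levels) and Epoch (5 levels), using the classical
#' effect-by-subject interaction error terms and no sphericity correction.
#' With `n` subjects the Epoch effect has `(4, 4(n-1))` degrees of freedom.
#'
#' @param ecc A `[subject, day, epoch, region]` array (see [ecc_array()]).
#' @return A data.frame with one row per region: F and p for the Day, Epoch,
#'   and Day x Epoch effects, plus a `df` attribute.
#' @export
rm_anova_2x5 <- function(ecc) {
  stopifnot(length(dim(ecc)) == 4)
  if (anyNA(ecc)) stop("missing cells in the design", call. = FALSE)
  regions <- dimnames(ecc)[[4]]
  res <- lapply(seq_along(regions), function(r) rm_anova_cell(ecc[, , , r]))
  df <- res[[1]]$df
  out <- data.frame(
    region = regions,
    F_day = vapply(res, `[[`, numeric(1), "F_day"),
    F_epoch = vapply(res, `[[`, numeric(1), "F_epoch"),
    F_interaction = vapply(res, `[[`, numeric(1), "F_interaction"),
    stringsAsFactors = FALSE
  )
  out$p_day <- stats::pf(out$F_day, df$day[1], df$day[2], lower.tail = FALSE)
  out$p_epoch <- stats::pf(out$F_epoch, df$epoch[1], df$epoch[2], lower.tail = FALSE)
  out$p_interaction <- stats::pf(out$F_interaction, df$interaction[1],
                                 df$interaction[2], lower.tail = FALSE)
  attr(out, "df") <- df
  out
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA over the columns of a subjects x conditions matrix
#' (e.g. the 7-epoch similarity profiles); error term is the
#' condition-by-subject interaction, giving `(k-1, (k-1)(n-1))` degrees of
#' freedom.
#'
#' @param Y A subjects x conditions numeric matrix.
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_1way <- function(Y) {
  stopifnot(is.matrix(Y), nrow(Y) >= 2, ncol(Y) >= 2)
  if (anyNA(Y)) stop("missing cells in the design", call. = FALSE)
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  m_c <- colMeans(Y); m_s <- rowMeans(Y)
  ss_c <- n * sum((m_c - gm)^2)
  ss_err <- sum((Y - outer(m_s, m_c, `+`) + gm)^2)
  Fv <- (ss_c / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = Fv, df1 = k - 1, df2 = (k - 1) * (n - 1),
       p = stats::pf(Fv, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

#' Benjamini–Hochberg FDR control
#'
#' Step-up procedure at level `q`; returns both the rejection mask and the
#' BH-adjusted p-values.
#'
#' @param p A vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A list with `reject` (logical) and `p_adjusted`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  list(reject = !is.na(p_adj) & p_adj <= q, p_adjusted = p_adj)
}

#' Paired epoch contrast on eccentricity
#'
#' Averages each subject's eccentricity over the epochs in `epochs_a` and
#' `epochs_b` (and across days when `average_days = TRUE`), then runs a
#' two-sided paired t-test per region.
#'
#' @param ecc A `[subject, day, epoch, region]` array.
#' @param epochs_a,epochs_b Epoch names to contrast.
#' @param average_days Average across the two days first (default TRUE).
#' @param day Day (`"d1"` or `"d2"`) used when `average_days = FALSE`.
#' @return A data.frame with per-region `t`, `p`, and mean difference
#'   `delta`.
#' @export
paired_contrast <- function(ecc, epochs_a, epochs_b, average_days = TRUE,
                            day = "d1") {
  n <- dim(ecc)[1]
  if (n < 3) stop("at least 3 subjects are required", call. = FALSE)
  pick <- function(eps) {
    if (average_days) {
      apply(ecc[, , eps, , drop = FALSE], c(1, 4), mean)
    } else {
      apply(ecc[, day, eps, , drop = FALSE], c(1, 4), mean)
    }
  }
  D <- pick(epochs_a) - pick(epochs_b)     # subjects x regions
  dbar <- colMeans(D)
  dsd <- apply(D, 2, stats::sd)
  tstat <- ifelse(dsd == 0, 0, dbar / (dsd / sqrt(n)))
  data.frame(region = dimnames(ecc)[[4]],
             t = unname(tstat),
             p = unname(2 * stats::pt(-abs(tstat), df = n - 1)),
             delta = unname(dbar),
             stringsAsFactors = FALSE)
}

#' Functional ensembles by k-means on template coordinates
#'
#' Clusters the template-manifold coordinates of (significant) regions into
#' `k` functional ensembles. The best-inertia solution over `n_restarts`
#' seeded restarts is kept; cluster ids are relabelled deterministically by
#' descending cluster size (ties broken by the lowest member region index),
#' and each cluster is annotated with its modal network label.
#'
#' @param coords A regions x components coordinate matrix (rownames = region
#'   ids).
#' @param k Number of ensembles (default 4).
#' @param seed RNG seed for the restarts.
#' @param n_restarts Number of random restarts (default 25).
#' @param networks Optional named vector region -> network label.
#' @return A list of class `"fc_ensembles"`: `cluster` (named integer
#'   vector), `centers`, `labels` (modal network per cluster, if networks
#'   given), `inertia`.
#' @export
kmeans_ensembles <- function(coords, k = 4L, seed = 1L, n_restarts = 25L,
                             networks = NULL) {
  stopifnot(is.matrix(coords))
  if (k > nrow(coords)) stop("k exceeds the number of regions", call. = FALSE)
  km <- with_seed(seed, stats::kmeans(coords, centers = k, nstart = n_restarts,
                                      iter.max = 100L))
  cl <- km$cluster
  sizes <- tabulate(cl, nbins = k)
  first_member <- vapply(seq_len(k), function(j) min(which(cl == j)), integer(1))
  new_order <- order(-sizes, first_member)
  relabel <- integer(k); relabel[new_order] <- seq_len(k)
  cl <- relabel[cl]
  names(cl) <- rownames(coords)
  labels <- NULL
  if (!is.null(networks)) {
    labels <- vapply(seq_len(k), function(j) {
      tab <- sort(table(networks[names(cl)[cl == j]]), decreasing = TRUE)
      names(tab)[1]
    }, character(1))
  }
  structure(list(cluster = cl, centers = km$centers[new_order, , drop = FALSE],
                 labels = labels, inertia = km$tot.withinss, k = k),
            class = "fc_ensembles")
}

## The seven learning-related epochs following Day 1 Early Learning, in
## canonical order.
RSA_EPOCHS <- c("d1_LateLearning", "d1_EarlyWashout", "d1_LateWashout",
                "d2_EarlyLearning", "d2_LateLearning", "d2_EarlyWashout",
                "d2_LateWashout")

#' Reinstatement similarity profile
#'
#' For each subject, the spatial correlation (Pearson by default, Spearman as
#' a rank-based control) between the regional eccentricity pattern of Day 1
#' Early Learning and each of the seven subsequent learning-related epochs,
#' restricted to an ensemble's regions.
#'
#' @param ecc A `[subject, day, epoch, region]` array.
#' @param regions Region ids of the ensemble (at least 3).
#' @param metric `"pearson"` or `"spearman"`.
#' @return A subjects x 7 matrix of correlations (columns in canonical epoch
#'   order), class `"similarity_profile"`.
#' @export
rsa_profile <- function(ecc, regions, metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  if (length(regions) < 3) stop("ensemble must contain at least 3 regions", call. = FALSE)
  subjects <- dimnames(ecc)[[1]]
  out <- matrix(NA_real_, length(subjects), length(RSA_EPOCHS),
                dimnames = list(subjects, RSA_EPOCHS))
  for (s in seq_along(subjects)) {
    ref <- ecc[s, "d1", "EarlyLearning", regions]
    if (stats::sd(ref) == 0) {
      stop("constant eccentricity pattern for subject ", subjects[s], call. = FALSE)
    }
    for (j in seq_along(RSA_EPOCHS)) {
      parts <- strsplit(RSA_EPOCHS[j], "_", fixed = TRUE)[[1]]
      v <- ecc[s, parts[1], parts[2], regions]
      if (stats::sd(v) == 0) {
        stop("constant eccentricity pattern for subject ", subjects[s],
             " in epoch ", RSA_EPOCHS[j], call. = FALSE)
      }
      out[s, j] <- stats::cor(ref, v, method = metric)
    }
  }
  class(out) <- c("similarity_profile", class(out))
  out
}

#' Reinstatement test on similarity profiles
#'
#' Omnibus one-way repeated-measures ANOVA over the seven epochs, followed by
#' one-tailed paired t-tests of the hypothesis that similarity to Day 2 Early
#' (re)Learning exceeds similarity to each other epoch. One-tailed p-values
#' are not multiplicity-corrected across the six comparisons.
#'
#' @param profiles A subjects x 7 `"similarity_profile"` matrix.
#' @return A list with `omnibus` (from [rm_anova_1way()]) and `contrasts`
#'   (data.frame with per-epoch one-tailed `t` and `p`).
#' @export
reinstatement_test <- function(profiles) {
  Y <- unclass(profiles)
  stopifnot(is.matrix(Y), ncol(Y) == length(RSA_EPOCHS), nrow(Y) >= 3)
  omnibus <- rm_anova_1way(Y)
  target <- Y[, "d2_EarlyLearning"]
  others <- setdiff(colnames(Y), "d2_EarlyLearning")
  n <- nrow(Y)
  con <- t(vapply(others, function(ep) {
    d <- target - Y[, ep]
    s <- stats::sd(d)
    tv <- if (s == 0) 0 else mean(d) / (s / sqrt(n))
    c(t = tv, p = stats::pt(tv, df = n - 1, lower.tail = FALSE))
  }, numeric(2)))
  list(omnibus = omnibus,
       contrasts = data.frame(epoch = others, t = con[, 1], p = con[, 2],
                              row.names = NULL, stringsAsFactors = FALSE))
}

#' Network-level correlation with subject scores
#'
#' Averages a per-region map within each network for every subject, then
#' correlates the network means with a per-subject score (e.g. the Learning
#' Score) across subjects.
#'
#' @param delta A subjects x regions matrix (e.g. eccentricity change).
#' @param networks A named vector region -> network label covering the
#'   columns of `delta`.
#' @param scores A numeric vector of subject scores.
#' @return A data.frame with per-network `r` and subject count `n`.
#' @export
network_correlation <- function(delta, networks, scores) {
  stopifnot(is.matrix(delta), length(scores) == nrow(delta))
  if (nrow(delta) < 4) stop("at least 4 subjects are required", call. = FALSE)
  if (stats::sd(scores) == 0) stop("scores are constant", call. = FALSE)
  nets <- networks[colnames(delta)]
  levs <- sort(unique(nets))
  r <- vapply(levs, function(nl) {
    m <- rowMeans(delta[, nets == nl, drop = FALSE])
    stats::cor(m, scores)
  }, numeric(1))
  data.frame(network = levs, r = unname(r), n = nrow(delta),
             stringsAsFactors = FALSE)
}
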