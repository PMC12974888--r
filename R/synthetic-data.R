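# Seeded synthetic-data generator emulating the two-day, five-epoch
# visuomotor-rotation study: per-subject stable covariance signatures, shared
# epoch-specific covariance perturbations (optionally with a planted
# Day1-early / Day2-early reinstatement), Gaussian region time series, and
# exponential-decay learning curves with subject-varying rates.
#
# Effects are composed additively in the tangent space at the base covariance
# and retracted through the exponential map, so every generated covariance is
# SPD by construction for any effect scale.

YEO7 <- c("Visual", "Somatomotor", "DorsAttn", "SalVentAttn",
          "Limbic", "Control", "Default")

#' Generator configuration
#'
#' Collects the parameters of the synthetic study in one validated list.
#' Defaults reproduce the desk-scale study conditions used throughout the
#' package's validation: 24 subjects, 100 regions in 7 networks, 2 days x 5
#' epochs of 96 volumes, strong stable subject effects, weak shared epoch
#' effects, a planted graded connectivity "contraction" (dissolution of the
#' targets' community profile toward diffuse cross-network coupling) in 10
#' default-mode regions during Early Learning, and an exact
#' Day1-early/Day2-early reinstatement.
#'
#' @param n_subjects,n_regions,n_networks Study dimensions.
#' @param volumes Volumes per epoch (default 96).
#' @param sigma_subject SD of the entries of each subject's stable tangent
#'   effect (default 0.10).
#' @param sigma_epoch SD of the entries of each epoch's shared tangent effect
#'   (default 0.01).
#' @param sigma_noise SD of the per-subject-per-epoch idiosyncratic tangent
#'   noise (default 0.01).
#' @param effect Planted effect type: `"contraction"` dissolves a graded
#'   share of each target region's community coupling into diffuse
#'   cross-network coupling during Early Learning (integration),
#'   `"expansion"` reinforces within-network coupling (segregation),
#'   `"none"` plants nothing.
#' @param effect_size Scale of the planted perturbation (default 0.20; at
#'   0.20 and above the dropped community edges fall to the between-network
#'   base level).
#' @param n_targets Number of planted target regions (default 10, drawn from
#'   the Default network).
#' @param reinstatement If TRUE (default) the Day 2 Early Learning epoch
#'   effect equals the Day 1 Early Learning effect exactly.
#' @param epoch_shuffle If TRUE, each subject receives the ten epoch effects
#'   in an independently permuted order; epochs become exchangeable across
#'   subjects (a null condition for epoch-level inference).
#' @param ar1 AR(1) coefficient of the region time series (default 0:
#'   temporally white, matching the pipeline's assumptions).
#' @param baseline_trials,learning_trials,washout_trials Behavioural block
#'   lengths (defaults 120/320/120).
#' @param rho_meanlog,rho_sdlog Log-normal parameters of the per-trial
#'   learning rate (defaults `log(0.015)` and 0.4).
#' @param savings_factor Day 2 learning-rate multiplier (default 1.5; 1 means
#'   no expected savings).
#' @param behavior_noise_sd Trial-level error noise in degrees (default 4).
#' @param baseline_noise_sd Baseline-trial error SD (default 3).
#' @param rt_contamination Fraction of reaction times outside the QC bounds
#'   (default 0.01).
#' @param seed Mandatory RNG seed.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 24L, n_regions = 100L,
                             n_networks = 7L, volumes = 96L,
                             sigma_subject = 0.10, sigma_epoch = 0.01,
                             sigma_noise = 0.01,
                             effect = c("contraction", "expansion", "none"),
                             effect_size = 0.20, n_targets = 10L,
                             reinstatement = TRUE, epoch_shuffle = FALSE,
                             ar1 = 0,
                             baseline_trials = 120L, learning_trials = 320L,
                             washout_trials = 120L,
                             rho_meanlog = log(0.015), rho_sdlog = 0.4,
                             savings_factor = 1.5,
                             behavior_noise_sd = 4, baseline_noise_sd = 3,
                             rt_contamination = 0.01,
                             seed) {
  if (missing(seed) || !is.numeric(seed)) stop("a numeric seed is mandatory", call. = FALSE)
  effect <- match.arg(effect)
  scales <- c(sigma_subject, sigma_epoch, sigma_noise, effect_size,
              behavior_noise_sd, baseline_noise_sd, rt_contamination)
  if (any(scales < 0)) stop("all scales must be non-negative", call. = FALSE)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic parcellation table
#'
#' Assigns regions to networks in balanced round-robin order, alternates
#' hemispheres within each network, and draws unit-sphere centroids uniformly
#' within each hemisphere (left: `x < 0`; right: `x > 0`).
#'
#' @param n_regions,n_networks Table dimensions (networks named after the
#'   seven canonical resting-state systems when `n_networks == 7`).
#' @param seed RNG seed.
#' @return A data.frame with columns `region`, `network`, `hemisphere`, `x`,
#'   `y`, `z`.
#' @export
gen_parcellation <- function(n_regions, n_networks = 7L, seed = 1L) {
  nets <- if (n_networks == 7L) YEO7 else paste0("Net", seq_len(n_networks))
  network <- nets[((seq_len(n_regions) - 1L) %% n_networks) + 1L]
  network <- network[order(match(network, nets))]
  hemisphere <- character(n_regions)
  for (nl in nets) {
    idx <- which(network == nl)
    hemisphere[idx] <- rep(c("L", "R"), length.out = length(idx))
  }
  xyz <- with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n_regions), ncol = 3)
    m <- m / sqrt(rowSums(m^2))
    m[, 1] <- abs(m[, 1]) * ifelse(hemisphere == "L", -1, 1)
    m / sqrt(rowSums(m^2))
  })
  data.frame(region = sprintf("R%03d", seq_len(n_regions)),
             network = network, hemisphere = hemisphere,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

## Base covariance: elevated within-network blocks plus a small seeded
## symmetric jitter that breaks exact block degeneracy (kept well inside the
## PD margin of the block structure). Within-network coupling differs by
## network: real cortical networks have heterogeneous coherence, and the
## spread of block strengths separates the affinity matrix's eigenvalues so
## the leading principal components span a stable subspace across epochs
## (equal blocks would make the retained 3-component subspace an arbitrary
## pick among degenerate network contrasts).
WITHIN_BY_NETWORK <- c(Visual = 0.60, Somatomotor = 0.55, Default = 0.50,
                       DorsAttn = 0.22, SalVentAttn = 0.20, Limbic = 0.18,
                       Control = 0.16)

base_covariance <- function(parcellation, within = NULL, between = 0.05,
                            jitter = 0.01, seed = 1L) {
  n <- nrow(parcellation)
  nets <- unique(parcellation$network)
  if (is.null(within)) {
    within <- if (all(nets %in% names(WITHIN_BY_NETWORK))) WITHIN_BY_NETWORK[nets]
              else setNames(seq(0.60, 0.26, length.out = length(nets)), nets)
  } else if (length(within) == 1) {
    within <- setNames(rep(within, length(nets)), nets)
  }
  same <- outer(parcellation$network, parcellation$network, `==`)
  w_row <- within[parcellation$network]
  S <- matrix(between, n, n)
  S[same] <- outer(w_row, w_row, function(a, b) (a + b) / 2)[same]
  diag(S) <- 1
  J <- with_seed(seed + 1L, {
    G <- matrix(stats::rnorm(n * n, sd = jitter), n, n)
    (G + t(G)) / 2
  })
  diag(J) <- 0
  S <- S + J
  dimnames(S) <- list(parcellation$region, parcellation$region)
  validate_spd(S, arg = "base covariance")
  S
}

rand_sym <- function(n, sd) {
  G <- matrix(stats::rnorm(n * n, sd = sd * sqrt(2)), n, n)
  (G + t(G)) / 2
}

## Planted tangent-space effect. "Contraction" (integration) reroutes each
## target region's dominant connections: its within-network coupling is
## reduced to the between-network base level while its coupling to a spread
## of regions across a graded number (2..6) of other networks - a distinct
## set and rotation per target - is raised to between + effect_size. The
## spread value is kept below the within-network level, so the spread
## partners' own top-connection profiles are unchanged and the effect stays
## confined to the targets. The graded, target-specific rerouting pulls the
## targets toward the manifold centroid AND imprints a reproducible spatial
## pattern across them, which is what reinstatement RSA detects when the two
## days' Early Learning effects are identical. "Expansion" (segregation)
## raises the target's within-network coupling, sharpening its own-network
## profile.
planted_effect <- function(parcellation, targets, effect, effect_size,
                           within = 0.50, between = 0.05) {
  n <- nrow(parcellation)
  E <- matrix(0, n, n)
  if (effect == "none" || effect_size == 0 || length(targets) == 0) return(E)
  tidx <- match(targets, parcellation$region)
  net <- parcellation$network
  nets <- unique(net)
  if (effect == "contraction") {
    mate_drop <- (within - between) * min(effect_size / 0.20, 1)
    K <- length(tidx)
    ## Graded profile dissolution: target k retains r_k of its K-1
    ## within-network target edges (r graded from about half down to none),
    ## the rest dropping to the between-network base level. The retained
    ## target-target graph is realised deterministically by Havel-Hakimi so
    ## each node's degree is controlled exactly despite edge symmetry. A
    ## target with few retained edges loses its coherent community profile
    ## and its thresholded connectivity spreads diffusely over the
    ## background - the integrated, centroid-ward state - while a target
    ## with many retained edges contracts only mildly. The graded retained
    ## degree imprints a reproducible eccentricity pattern across targets.
    ## gentle grading: even the most contracted target keeps some community
    ## edges, so the network's block coherence (and with it the stability of
    ## the retained principal subspace) is preserved across epochs
    r_deg <- pmin(round(seq(0.65 * (K - 1), 0.2 * (K - 1), length.out = K)), K - 1L)
    if (sum(r_deg) %% 2 == 1) r_deg[1] <- r_deg[1] + 1L
    keep <- havel_hakimi(r_deg)
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      if (!keep[a, b]) {
        E[tidx[a], tidx[b]] <- -mate_drop
        E[tidx[b], tidx[a]] <- -mate_drop
      }
    }
    ## The freed connectivity is steered diffusely toward the weakly
    ## clustered networks: a small gain toward every region outside the
    ## strong communities. Those edges dominate the background (so the
    ## contracted profile reliably spreads across networks) yet stay small
    ## within the receiving regions' own neighbourhoods, so no other strong
    ## community is entered and the perturbation remains confined to the
    ## targets.
    strong <- names(WITHIN_BY_NETWORK)[WITHIN_BY_NETWORK >= 0.3]
    weak_idx <- which(!(net %in% strong))
    gain <- 0.4 * effect_size
    for (t in tidx) {
      E[t, weak_idx] <- E[t, weak_idx] + gain
      E[weak_idx, t] <- E[weak_idx, t] + gain
    }
    ## non-target same-network mates (if any) stay untouched, so the
    ## perturbation is confined to the target set itself
  } else {
    for (t in tidx) {
      mask <- net == net[t]
      mask[t] <- FALSE
      E[t, mask] <- effect_size
      E[mask, t] <- effect_size
    }
  }
  E
}

## Deterministic Havel-Hakimi realisation of a degree sequence; returns the
## adjacency matrix (in input node order) of a simple graph with the given
## degrees, which must be graphical.
havel_hakimi <- function(deg) {
  K <- length(deg)
  A <- matrix(FALSE, K, K)
  rem <- deg
  repeat {
    if (all(rem == 0)) break
    i <- order(-rem, seq_len(K))[1]
    d <- rem[i]
    rem[i] <- 0L
    cand <- setdiff(order(-rem, seq_len(K)), i)
    cand <- cand[!A[i, cand]][seq_len(d)]
    if (anyNA(cand)) stop("degree sequence is not graphical", call. = FALSE)
    A[i, cand] <- A[cand, i] <- TRUE
    rem[cand] <- rem[cand] - 1L
    if (any(rem < 0)) stop("degree sequence is not graphical", call. = FALSE)
  }
  A
}

EPOCH_KEYS <- as.vector(outer(c("d1", "d2"), EPOCH_LEVELS,
                              function(d, e) paste(d, e, sep = "_")))

#' Generate the synthetic connectivity dataset
#'
#' Draws, for every subject and epoch, a covariance
#' `Sigma_ij = retract(D_i + E_j + N_ij, Sigma0)` — a stable subject effect
#' `D_i`, a shared epoch effect `E_j` (with the planted Early-Learning
#' perturbation and optional exact reinstatement), and idiosyncratic noise
#' `N_ij`, all symmetric tangent vectors at the block-structured base
#' covariance `Sigma0` — and samples zero-mean Gaussian region time series
#' with that covariance.
#'
#' @param cfg A [generator_config()].
#' @param what `"timeseries"` (default) returns sampled epoch blocks;
#'   `"covariance"` returns the exact per-observation covariances (no
#'   sampling noise), which is faster for geometry-level experiments.
#' @return A list of class `"synthetic_dataset"` with elements `data` (named
#'   list of regions x volumes matrices, or SPD matrices), `meta` (data.frame
#'   `key`, `subject`, `day`, `epoch`), `parcellation`, and `ground_truth`
#'   (base covariance, subject/epoch tangent effects, targets, config).
#' @export
gen_connectivity_dataset <- function(cfg, what = c("timeseries", "covariance")) {
  stopifnot(inherits(cfg, "generator_config"))
  what <- match.arg(what)
  parc <- gen_parcellation(cfg$n_regions, cfg$n_networks, seed = cfg$seed)
  n <- cfg$n_regions
  Sigma0 <- base_covariance(parc, seed = cfg$seed)
  def_net0 <- if (cfg$n_networks == 7L) "Default" else utils::tail(unique(parc$network), 1)
  targets0 <- utils::head(parc$region[parc$network == def_net0], cfg$n_targets)
  S0h <- spd_power(Sigma0, 1/2)
  S0ih <- spd_power(Sigma0, -1/2)
  targets <- targets0
  plant <- planted_effect(parc, targets, cfg$effect, cfg$effect_size)

  out <- with_seed(cfg$seed, {
    subj_eff <- lapply(seq_len(cfg$n_subjects), function(i) rand_sym(n, cfg$sigma_subject))
    epoch_eff <- setNames(lapply(EPOCH_KEYS, function(k) rand_sym(n, cfg$sigma_epoch)),
                          EPOCH_KEYS)
    for (k in c("d1_EarlyLearning", "d2_EarlyLearning")) {
      epoch_eff[[k]] <- epoch_eff[[k]] + plant
    }
    if (cfg$reinstatement) epoch_eff[["d2_EarlyLearning"]] <- epoch_eff[["d1_EarlyLearning"]]
    subj_orders <- lapply(seq_len(cfg$n_subjects), function(i) {
      if (cfg$epoch_shuffle) sample(length(EPOCH_KEYS)) else seq_along(EPOCH_KEYS)
    })
    data <- list(); meta <- list(); ix <- 0L
    for (i in seq_len(cfg$n_subjects)) {
      sid <- sprintf("sub-%02d", i)
      for (j in seq_along(EPOCH_KEYS)) {
        key <- EPOCH_KEYS[j]
        Ej <- epoch_eff[[subj_orders[[i]][j]]]
        Tij <- subj_eff[[i]] + Ej + rand_sym(n, cfg$sigma_noise)
        Sij <- sym_part(S0h %*% sym_exp(sym_part(S0ih %*% Tij %*% S0ih)) %*% S0h)
        dimnames(Sij) <- dimnames(Sigma0)
        ix <- ix + 1L
        obs_key <- paste(sid, key, sep = "_")
        if (what == "covariance") {
          data[[obs_key]] <- Sij
        } else {
          L <- t(chol(Sij))
          Z <- matrix(stats::rnorm(n * cfg$volumes), n, cfg$volumes)
          if (cfg$ar1 > 0) {
            for (tcol in 2:cfg$volumes) {
              Z[, tcol] <- cfg$ar1 * Z[, tcol - 1] + sqrt(1 - cfg$ar1^2) * Z[, tcol]
            }
          }
          X <- L %*% Z
          rownames(X) <- parc$region
          data[[obs_key]] <- X
        }
        parts <- strsplit(key, "_", fixed = TRUE)[[1]]
        meta[[ix]] <- data.frame(key = obs_key, subject = sid,
                                 day = as.integer(sub("d", "", parts[1])),
                                 epoch = parts[2], stringsAsFactors = FALSE)
      }
    }
    list(data = data, meta = do.call(rbind, meta),
         subj_eff = subj_eff, epoch_eff = epoch_eff)
  })
  structure(list(
    data = out$data, meta = out$meta, parcellation = parc,
    ground_truth = list(base_covariance = Sigma0,
                        subject_effects = out$subj_eff,
                        epoch_effects = out$epoch_eff,
                        targets = targets,
                        planted = plant,
                        config = cfg),
    what = what),
    class = "synthetic_dataset")
}

#' Generate synthetic learning curves
#'
#' Per subject, draws a log-normal learning rate `rho_i` and builds the
#' two-day trial table: baseline errors near zero, learning-block errors
#' decaying as `45 * exp(-rho_i * (t - 1))` plus noise, and a washout
#' aftereffect of opposite sign decaying twice as fast. Day 2 rates are
#' multiplied by the savings factor. Reaction times are drawn within the QC
#' bounds except for a configurable contamination fraction.
#'
#' @param cfg A [generator_config()].
#' @return A list with `trials` (trial table) and `rho` (named per-subject
#'   Day 1 learning rates).
#' @export
gen_learning_curves <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 7L, {
    subjects <- sprintf("sub-%02d", seq_len(cfg$n_subjects))
    rho <- stats::rlnorm(cfg$n_subjects, cfg$rho_meanlog, cfg$rho_sdlog)
    names(rho) <- subjects
    rows <- list(); ix <- 0L
    draw_rt <- function(k) {
      rt <- stats::runif(k, 300, 900)
      bad <- stats::runif(k) < cfg$rt_contamination
      rt[bad] <- ifelse(stats::runif(sum(bad)) < 0.5, 50, 2500)
      rt
    }
    clamp <- function(e) pmax(pmin(e, 180), -180)
    for (i in seq_along(subjects)) {
      for (d in 1:2) {
        r <- rho[i] * if (d == 2) cfg$savings_factor else 1
        blocks <- list(
          Baseline = stats::rnorm(cfg$baseline_trials, 0, cfg$baseline_noise_sd),
          Learning = 45 * exp(-r * (seq_len(cfg$learning_trials) - 1)) +
            stats::rnorm(cfg$learning_trials, 0, cfg$behavior_noise_sd),
          Washout = -45 * exp(-2 * r * (seq_len(cfg$washout_trials) - 1)) +
            stats::rnorm(cfg$washout_trials, 0, cfg$behavior_noise_sd)
        )
        for (b in names(blocks)) {
          k <- length(blocks[[b]])
          ix <- ix + 1L
          rows[[ix]] <- data.frame(subject = subjects[i], day = d, block = b,
                                   trial = seq_len(k),
                                   error_deg = clamp(blocks[[b]]),
                                   rt_ms = draw_rt(k), stringsAsFactors = FALSE)
        }
      }
    }
    list(trials = do.call(rbind, rows), rho = rho)
  })
}

#' Simulate a complete synthetic study
#'
#' Couples the connectivity generator and the behavioural generator under one
#' seed so that learning rates and neural effects refer to the same subjects.
#' Optionally writes the study to disk in the file dialects the readers
#' consume (per-scan time-series TSVs, parcellation TSV, trial table TSV, and
#' a ground-truth JSON).
#'
#' @param cfg A [generator_config()].
#' @param dir Optional output directory; created if missing.
#' @param what Passed to [gen_connectivity_dataset()] (file output requires
#'   `"timeseries"`).
#' @return A list of class `"synthetic_study"`: the `"synthetic_dataset"`
#'   fields plus `trials`, `rho`, and (when written) `files`.
#' @export
simulate_study <- function(cfg, dir = NULL, what = "timeseries") {
  ds <- gen_connectivity_dataset(cfg, what = what)
  beh <- gen_learning_curves(cfg)
  study <- structure(c(ds, list(trials = beh$trials, rho = beh$rho)),
                     class = c("synthetic_study", "synthetic_dataset"))
  if (!is.null(dir)) {
    if (what != "timeseries") stop("file output requires what = \"timeseries\"", call. = FALSE)
    study$files <- write_study(study, dir)
  }
  study
}

#' Build a small frozen fixture dataset
#'
#' Deterministic miniature study (default 6 subjects x 21 regions) written to
#' `dir`; regenerating with the same name yields byte-identical files.
#'
#' @param name Fixture preset (`"mini"`).
#' @param dir Output directory.
#' @return The `"synthetic_study"` object (with `files`).
#' @export
make_fixture <- function(name = "mini", dir) {
  cfg <- switch(name,
    mini = generator_config(n_subjects = 6L, n_regions = 21L, n_targets = 3L,
                            seed = 42L),
    stop("unknown fixture '", name, "'", call. = FALSE))
  simulate_study(cfg, dir = dir)
}
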