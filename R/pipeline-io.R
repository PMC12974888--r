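# Configuration, file I/O, and the end-to-end runner stringing the stages
# together: QC -> covariances -> centering -> template -> alignment ->
# eccentricity -> rmANOVA/FDR -> ensembles -> RSA -> behaviour -> network
# correlations / spin tests.
#
# File dialects (all plain text, diff-able):
#   time series  sub-XX_day-D_scan-S.tsv   regions x volumes, first column
#                                          "region", header v1..vT
#   parcellation parcellation.tsv          region, network, hemisphere, x, y, z
#   trials       trials.tsv                subject, day, block, trial,
#                                          error_deg, rt_ms
#   ground truth ground_truth.json

#' Analysis configuration
#'
#' Parameters of the analysis pipeline with the study's standard values:
#' 10% row-threshold density, 3 manifold components, k = 4 ensembles, FDR
#' q = 0.05, 1000 spin permutations, Pearson RSA metric.
#'
#' @param density Row-threshold density.
#' @param n_components Manifold components.
#' @param k_ensembles k for the functional ensembles.
#' @param q FDR level.
#' @param n_perm Spin-test permutations.
#' @param metric RSA similarity metric.
#' @param discard_initial Volumes discarded at the start of each scan.
#' @param seed Seed for the stochastic stages (k-means restarts, spin test).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(density = 0.10, n_components = 3L, k_ensembles = 4L,
                       q = 0.05, n_perm = 1000L, metric = "pearson",
                       discard_initial = 6L, seed = 1L) {
  stopifnot(density > 0, density <= 1, n_components >= 1, k_ensembles >= 1,
            q > 0, q < 1, n_perm >= 1)
  metric <- match.arg(metric, c("pearson", "spearman"))
  structure(list(density = density, n_components = n_components,
                 k_ensembles = k_ensembles, q = q, n_perm = n_perm,
                 metric = metric, discard_initial = discard_initial,
                 seed = seed),
            class = "run_config")
}

#' Write a region time-series matrix
#'
#' @param ts Regions x volumes matrix with region rownames.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  df <- data.frame(region = rownames(ts),
                   signif(ts, 7), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("region", paste0("v", seq_len(ncol(ts))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region time-series matrix
#'
#' @param path A time-series TSV (first column `region`, then volumes).
#' @return A regions x volumes numeric matrix with region rownames.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty time-series file: ", path, call. = FALSE)
  if (names(df)[1] != "region") {
    stop("malformed header in ", path, ": first column must be 'region'", call. = FALSE)
  }
  if (anyDuplicated(df$region)) {
    stop("duplicate region ids in ", path, ": ",
         paste(unique(df$region[duplicated(df$region)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric or missing values in ", path, call. = FALSE)
  rownames(m) <- df$region
  m
}

#' Read a parcellation table
#'
#' @param path A parcellation TSV (`region`, `network`, `hemisphere`, and
#'   optional centroid columns `x`, `y`, `z`).
#' @return A validated data.frame.
#' @export
read_parcellation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty parcellation file: ", path, call. = FALSE)
  req <- c("region", "network", "hemisphere")
  if (!all(req %in% names(df))) {
    stop("parcellation must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$region)) stop("duplicate region ids in parcellation", call. = FALSE)
  df
}

#' Read a behavioural trial table
#'
#' @param path A trials TSV.
#' @return A validated trial data.frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty trial file: ", path, call. = FALSE)
  req <- c("subject", "day", "block", "trial", "error_deg", "rt_ms")
  if (!all(req %in% names(df))) {
    stop("trial table must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  df
}

## Assemble full scans from a synthetic study's epoch blocks (non-epoch
## volumes filled with unit-variance noise; the pipeline only reads the
## epoch windows) and write the study to disk.
write_study <- function(study, dir) {
  cfg <- study$ground_truth$config
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  epochs <- default_epochs(cfg$baseline_trials, cfg$learning_trials,
                           cfg$washout_trials, epoch_volumes = cfg$volumes)
  discard <- 6L
  scan_len <- c(task = discard + 2L * (cfg$baseline_trials + cfg$learning_trials),
                washout = discard + 2L * cfg$washout_trials)
  files <- character(0)
  regions <- study$parcellation$region
  subjects <- unique(study$meta$subject)
  with_seed(cfg$seed + 13L, {
    for (s in subjects) {
      for (d in 1:2) {
        for (sc in c("task", "washout")) {
          X <- matrix(stats::rnorm(length(regions) * scan_len[[sc]]),
                      nrow = length(regions))
          rownames(X) <- regions
          eps <- epochs[epochs$scan == sc, ]
          for (i in seq_len(nrow(eps))) {
            key <- paste(s, paste0("d", d), eps$name[i], sep = "_")
            cols <- discard + eps$start[i] + seq_len(eps$length[i])
            X[, cols] <- study$data[[key]]
          }
          path <- file.path(dir, sprintf("%s_day-%d_scan-%s.tsv", s, d, sc))
          write_timeseries(X, path)
          files <- c(files, path)
        }
      }
    }
  })
  pp <- file.path(dir, "parcellation.tsv")
  utils::write.table(study$parcellation, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  tp <- file.path(dir, "trials.tsv")
  tr <- study$trials
  tr$error_deg <- signif(tr$error_deg, 7); tr$rt_ms <- signif(tr$rt_ms, 7)
  utils::write.table(tr, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  gp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(targets = study$ground_truth$targets,
                            rho = as.list(study$rho),
                            seed = cfg$seed,
                            effect = cfg$effect,
                            effect_size = cfg$effect_size),
                       gp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(files, pp, tp, gp)
}

#' Read a study directory into epoch blocks
#'
#' Reads every `sub-*_day-*_scan-*.tsv` in `dir`, checks region-id
#' consistency against the parcellation, and splices each scan into the
#' standard epochs.
#'
#' @param dir Directory written by [simulate_study()] (or following the same
#'   naming convention).
#' @param epochs Epoch-definition table (default [default_epochs()]).
#' @param discard_initial Initial volumes discarded per scan (default 6).
#' @return A list with `data` (named epoch blocks), `meta`, `parcellation`,
#'   and `trials` (NULL when absent).
#' @export
read_study <- function(dir, epochs = default_epochs(), discard_initial = 6L) {
  parc <- read_parcellation(file.path(dir, "parcellation.tsv"))
  files <- list.files(dir, pattern = "^sub-.*_day-[12]_scan-(task|washout)\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no time-series files in ", dir, call. = FALSE)
  info <- regmatches(basename(files),
                     regexec("^(sub-[^_]+)_day-([12])_scan-(task|washout)\\.tsv$",
                             basename(files)))
  keys <- vapply(info, function(m) paste(m[2], m[3], sep = "_"), character(1))
  data <- list(); meta <- list(); ix <- 0L
  for (sk in unique(keys)) {
    idx <- which(keys == sk)
    scans <- list()
    for (i in idx) {
      ts <- read_timeseries(files[i])
      missing_regions <- setdiff(rownames(ts), parc$region)
      if (length(missing_regions)) {
        stop("region(s) absent from parcellation: ",
             paste(missing_regions, collapse = ", "), call. = FALSE)
      }
      scans[[info[[i]][4]]] <- ts
    }
    blocks <- splice_epochs(scans, epochs, discard_initial)
    parts <- strsplit(sk, "_", fixed = TRUE)[[1]]
    for (e in names(blocks)) {
      ix <- ix + 1L
      key <- paste(parts[1], paste0("d", parts[2]), e, sep = "_")
      data[[key]] <- blocks[[e]]
      meta[[ix]] <- data.frame(key = key, subject = parts[1],
                               day = as.integer(parts[2]), epoch = e,
                               stringsAsFactors = FALSE)
    }
  }
  trials_path <- file.path(dir, "trials.tsv")
  trials <- if (file.exists(trials_path)) read_trials(trials_path) else NULL
  list(data = data, meta = do.call(rbind, meta), parcellation = parc,
       trials = trials)
}

#' Run the full analysis pipeline
#'
#' Executes every stage of the manifold-eccentricity analysis on an
#' in-memory study (a `"synthetic_study"` or the result of [read_study()]):
#' z-scoring and Ledoit–Wolf covariance per epoch, Riemannian centering per
#' subject, template-manifold construction from the centered baselines,
#' Procrustes alignment and eccentricity for every observation, region-wise
#' Day x Epoch rmANOVA with FDR, k-means functional ensembles on the
#' significant regions' template coordinates, reinstatement RSA per ensemble,
#' behavioural scoring, and network-level Learning-Score correlations with
#' spin-test inference. Behavioural stages are skipped (with a notice) when
#' the study carries no trial table.
#'
#' @param study Study object with `data` (epoch time-series blocks or SPD
#'   matrices), `meta`, `parcellation`, and optionally `trials`.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, result tables and a JSON
#'   run manifest are written there.
#' @param verbose Print stage progress (default FALSE).
#' @return A list of class `"fc_results"` (see components in the
#'   implementation: `ecc`, `anova`, `significant`, `ensembles`, `rsa`,
#'   `behavior`, `network_correlation`, `spin`, `manifest`, ...).
#' @export
run_pipeline <- function(study, config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, expr) {
    st <- Sys.time()
    if (verbose) message("stage: ", stage)
    val <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    val
  }
  meta <- study$meta
  networks <- setNames(study$parcellation$network, study$parcellation$region)

  covs <- tick("covariance", {
    is_cov <- identical(study$what, "covariance") ||
      (nrow(study$data[[1]]) == ncol(study$data[[1]]) &&
         isTRUE(all.equal(study$data[[1]], t(study$data[[1]]))))
    if (is_cov) study$data
    else lapply(study$data, function(X) ledoit_wolf_cov(zscore_timeseries(X)))
  })
  cen <- tick("centering", center_covariances(covs, meta$subject))
  template <- tick("template", {
    bl <- lapply(unique(meta$subject), function(s) {
      keys <- meta$key[meta$subject == s & meta$epoch == "Baseline"]
      cen$centered[keys]
    })
    build_template(bl, density = config$density,
                   n_components = config$n_components)
  })
  ecc_mat <- tick("eccentricity",
                  eccentricity_stack(cen$centered, template,
                                     density = config$density,
                                     n_components = config$n_components))
  ecc <- ecc_array(ecc_mat, meta)
  anova_res <- tick("rmanova", rm_anova_2x5(ecc))
  fdr <- fdr_bh(anova_res$p_epoch, config$q)
  anova_res$significant <- fdr$reject
  anova_res$p_epoch_adjusted <- fdr$p_adjusted
  significant <- anova_res$region[fdr$reject]

  ensembles <- tick("ensembles", {
    regs <- if (length(significant) >= 2L * config$k_ensembles) significant
            else anova_res$region
    kmeans_ensembles(template$embedding$coordinates[regs, , drop = FALSE],
                     k = config$k_ensembles, seed = config$seed,
                     networks = networks)
  })

  rsa <- tick("rsa", {
    lapply(seq_len(ensembles$k), function(j) {
      regs <- names(ensembles$cluster)[ensembles$cluster == j]
      if (length(regs) < 3) return(NULL)
      prof <- rsa_profile(ecc, regs, metric = config$metric)
      list(regions = regs,
           label = if (!is.null(ensembles$labels)) ensembles$labels[j] else NA,
           profile = prof, test = reinstatement_test(prof))
    })
  })

  behavior <- NULL
  if (!is.null(study$trials)) {
    behavior <- tick("behavior", behavior_scores(trial_qc(study$trials)))
  } else if (verbose) {
    message("no trial table: behavioural stages skipped")
  }

  netcor <- NULL; spin <- NULL
  if (!is.null(behavior)) {
    subjects <- dimnames(ecc)[[1]]
    sc <- behavior$scores$learning_score[match(subjects, behavior$scores$subject)]
    delta <- ecc[, "d1", "EarlyLearning", ] - ecc[, "d1", "Baseline", ]
    netcor <- tick("network_correlation", network_correlation(delta, networks, sc))
    spin <- tick("spin", {
      has_xyz <- all(c("x", "y", "z") %in% names(study$parcellation))
      spin_test(delta, sc, networks,
                parcellation = study$parcellation, n_perm = config$n_perm,
                seed = config$seed,
                fallback = if (has_xyz) "error" else "labels")
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fcmanifold")),
    config = unclass(config),
    n_subjects = length(unique(meta$subject)),
    n_regions = ncol(ecc_mat),
    timings = timings,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  res <- structure(list(
    ecc = ecc, ecc_matrix = ecc_mat, meta = meta, template = template,
    centered = cen, anova = anova_res, significant = significant,
    ensembles = ensembles, rsa = rsa, behavior = behavior,
    network_correlation = netcor, spin = spin,
    parcellation = study$parcellation, config = config, manifest = manifest),
    class = "fc_results")
  if (!is.null(out_dir)) res$manifest$files <- write_results(res, out_dir)
  res
}

## Long-format result tables + manifest, written atomically enough for a
## single process: manifest last, after all tables exist.
write_results <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wf <- function(df, name) {
    p <- file.path(out_dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character(0)
  ecc_long <- do.call(rbind, lapply(seq_len(nrow(res$ecc_matrix)), function(i) {
    data.frame(key = rownames(res$ecc_matrix)[i],
               region = colnames(res$ecc_matrix),
               eccentricity = res$ecc_matrix[i, ], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  files <- c(files, wf(ecc_long, "eccentricity.tsv"))
  files <- c(files, wf(res$anova, "anova.tsv"))
  ens <- data.frame(region = names(res$ensembles$cluster),
                    cluster = unname(res$ensembles$cluster),
                    stringsAsFactors = FALSE)
  files <- c(files, wf(ens, "ensembles.tsv"))
  for (j in seq_along(res$rsa)) {
    if (is.null(res$rsa[[j]])) next
    prof <- as.data.frame(unclass(res$rsa[[j]]$profile))
    prof <- cbind(subject = rownames(prof), prof, row.names = NULL)
    files <- c(files, wf(prof, sprintf("rsa_ensemble%d.tsv", j)))
  }
  if (!is.null(res$behavior)) {
    files <- c(files, wf(res$behavior$scores, "behavior_scores.tsv"))
  }
  if (!is.null(res$spin)) {
    files <- c(files, wf(res$spin$result, "network_spin.tsv"))
  }
  manifest <- res$manifest
  manifest$files <- NULL
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(files, mp)
}

#' Summarise pipeline results
#'
#' Human-readable report: counts and network percentages of significant
#' regions, per-ensemble reinstatement RSA outcomes, and network-level
#' Learning-Score correlations. Regenerable from the stored result object
#' alone.
#'
#' @param res An `"fc_results"` object.
#' @return Invisibly, a list with `network_table` and `rsa_table`.
#' @export
report <- function(res) {
  stopifnot(inherits(res, "fc_results"))
  networks <- setNames(res$parcellation$network, res$parcellation$region)
  cat(sprintf("Significant regions (Epoch main effect, q = %g): %d of %d\n",
              res$config$q, length(res$significant), nrow(res$anova)))
  if (length(res$significant)) {
    tab <- table(networks[res$significant])
    net_table <- data.frame(network = names(tab), n = as.vector(tab),
                            percent = round(100 * as.vector(tab) / sum(tab), 1),
                            stringsAsFactors = FALSE)
    print(net_table, row.names = FALSE)
  } else {
    net_table <- data.frame(network = character(0), n = integer(0),
                            percent = numeric(0))
    cat("  zero significant regions\n")
  }
  rsa_rows <- list()
  for (j in seq_along(res$rsa)) {
    r <- res$rsa[[j]]
    if (is.null(r)) next
    peak <- colnames(r$profile)[which.max(colMeans(r$profile))]
    rsa_rows[[j]] <- data.frame(
      ensemble = j, label = r$label, n_regions = length(r$regions),
      omnibus_F = r$test$omnibus$F, omnibus_p = r$test$omnibus$p,
      peak_epoch = peak, stringsAsFactors = FALSE)
  }
  rsa_table <- do.call(rbind, rsa_rows)
  if (!is.null(rsa_table)) {
    cat("\nReinstatement RSA by ensemble:\n")
    print(rsa_table, row.names = FALSE)
  }
  if (!is.null(res$spin)) {
    cat("\nNetwork correlations with Learning Score (spin test):\n")
    print(res$spin$result, row.names = FALSE)
  }
  invisible(list(network_table = net_table, rsa_table = rsa_table))
}
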