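#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()] and the two
#' simulation studies. Every stage seed is derived from `seed`; the full
#' configuration is echoed into the output directory for provenance.
#'
#' @param seed master seed.
#' @param n_trials trials per session.
#' @param n_branches,branch_length_range,spine_density synthetic-tree
#'   geometry (see [generate_synthetic_tree()]).
#' @param params a [simulation_params()] list.
#' @param subtract_method bAP subtraction method (see
#'   [subtract_alternative()]).
#' @param preprocess run baseline/dF/F estimation on raw-wrapped traces
#'   (TRUE) or use the simulator's dF/F directly.
#' @param correlation_measure `"noise"`, `"signal"`, or `"trace"` -- the
#'   pairwise statistic used for distance fits.
#' @param n_splits signal-correlation split repetitions.
#' @param n_shuffles permutation/bootstrap iterations for the per-mask
#'   selectivity stage.
#' @param selectivity_filter keep only masks with ANOVA p below this value
#'   in signal-correlation analyses (`NULL` disables the filter).
#' @param outdir output directory (`NULL` = no files written).
#' @return configuration list.
#' @export
pipeline_config <- function(seed = 1L, n_trials = 300,
                            n_branches = 6, branch_length_range = c(40, 70),
                            spine_density = 0.22,
                            params = simulation_params(),
                            subtract_method = "deconv_soma",
                            preprocess = TRUE,
                            correlation_measure = "noise",
                            n_splits = 100,
                            n_shuffles = 200,
                            selectivity_filter = NULL,
                            outdir = NULL) {
  list(seed = seed, n_trials = n_trials, n_branches = n_branches,
       branch_length_range = branch_length_range,
       spine_density = spine_density, params = params,
       subtract_method = subtract_method, preprocess = preprocess,
       correlation_measure = correlation_measure, n_splits = n_splits,
       n_shuffles = n_shuffles,
       selectivity_filter = selectivity_filter, outdir = outdir)
}

#' Read/write a pipeline configuration as YAML
#'
#' @param config configuration list from [pipeline_config()].
#' @param path YAML path.
#' @return `read_config` returns the configuration; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- config
  cfg$params <- unclass(cfg$params)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$params
  cfg$params <- simulation_params(
    transformation = p$transformation,
    a_pre = p$a_pre, lambda_pre = p$lambda_pre, a_s = p$a_s, a_c = p$a_c,
    a_coop = p$a_coop, lambda_coop = p$lambda_coop, n_nl = p$n_nl,
    K_nl = p$K_nl, tau_nl_ms = p$tau_nl * 1000, r = p$r, n_g = p$n_g,
    K_g = p$K_g, lambda_decay = p$lambda_decay, tau_s_mean = p$tau_s_mean,
    tau_s_sd = p$tau_s_sd, tau_c = p$tau_c, f_max = p$f_max,
    sigma_s = p$sigma_s, sigma_c = p$sigma_c, mean_rate = p$mean_rate,
    lag = p$lag, sample_rate = p$sample_rate)
  if (cfg$params$transformation == "full_nonlinear") {
    cfg$params$a_coop <- p$a_coop
    cfg$params$r <- p$r
  }
  cfg
}

# simulate one session under a config (geometry, trials, forward model)
simulate_config_session <- function(config, session_seed) {
  geom <- generate_synthetic_tree(
    n_branches = config$n_branches,
    branch_length_range = config$branch_length_range,
    spine_density_per_um = config$spine_density,
    seed = derive_seed(session_seed, "geometry"))
  trials <- synth_trials(n_trials = config$n_trials,
                         seed = derive_seed(session_seed, "trials"))
  sim <- simulate_session(geom, trials, config$params,
                          seed = derive_seed(session_seed, "forward"))
  sim$geometry <- geom
  sim
}

# preprocess (optional) + bAP-subtract a simulated session; returns the
# analysis-ready dF/F matrix plus the fit table
prepare_session_traces <- function(sim, config, session_seed) {
  dff <- sim$traces$dff
  if (isTRUE(config$preprocess)) {
    raw <- as_raw_fluorescence(sim$traces, f0 = 100)
    pp <- preprocess_session(raw$F, m = 1)
    dff <- pp$dff
    colnames(dff) <- colnames(sim$traces$dff)
  }
  sub <- subtract_session(dff, ref_index = 1,
                          method = config$subtract_method,
                          sample_rate = sim$traces$sample_rate,
                          seed = derive_seed(session_seed, "subtract"))
  list(dff_raw = dff, dff = sub$residual, fits = sub$fits)
}

# pairwise stats (spine-spine) of one prepared session
session_spine_pairs <- function(sim, dff, config, session_seed) {
  pt <- mask_pair_distances(sim$tree, sim$masks)
  pt <- pt[pt$kind_a == "spine" & pt$kind_b == "spine", , drop = FALSE]
  ps <- session_pair_stats(dff[, -1, drop = FALSE], sim$traces$times,
                           sim$trials,
                           pt, n_splits = config$n_splits,
                           seed = derive_seed(session_seed, "pairs"))
  ps$r <- switch(config$correlation_measure,
                 noise = ps$r_noise,
                 signal = ps$r_signal,
                 trace = {
                   ids <- colnames(dff)
                   cm <- suppressWarnings(stats::cor(dff))
                   cm[cbind(match(ps$mask_a, ids), match(ps$mask_b, ids))]
                 },
                 stop("unknown correlation measure"))
  ps
}

#' Run the full pipeline on one simulated session
#'
#' simulate -> (preprocess) -> bAP-subtract -> independence grid ->
#' selectivity -> pairwise spatial statistics. Deterministic given
#' `config$seed`; when `config$outdir` is set, every stage writes its table
#' and a JSON manifest records the configuration and seeds.
#'
#' @param config configuration from [pipeline_config()].
#' @return list with `sim`, `dff` (subtracted), `fits`, `independence`,
#'   `selectivity`, `pairs`, `distance_fit`, `log` (per-stage counts).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  log <- list()
  sim <- simulate_config_session(config, seed)
  log$n_masks <- ncol(sim$traces$dff)
  log$n_trials <- nrow(sim$trials)
  log$n_excluded_trials <- sum(!sim$trials$correct | sim$trials$early_lick)

  prep <- prepare_session_traces(sim, config, seed)

  ind <- threshold_grid(prep$dff_raw[, 2], prep$dff_raw[, 1],
                        mask_sigma = pmax(sim$traces$sigma[2], 1e-6),
                        ref_sigma = pmax(sim$traces$sigma[1], 1e-6))

  sel <- lapply(seq_len(ncol(prep$dff))[-1], function(j) {
    s <- mask_selectivity(prep$dff[, j], sim$traces$times, sim$trials,
                          n_shuffles = config$n_shuffles,
                          seed = derive_seed(seed, paste0("sel", j)))
    data.frame(mask_id = colnames(prep$dff)[j], p_anova = s$p_anova,
               angle = s$angle, angle_se = s$angle_se,
               selective = s$selective, trial_type = s$trial_type)
  })
  sel <- do.call(rbind, sel)

  pairs <- session_spine_pairs(sim, prep$dff, config, seed)
  if (!is.null(config$selectivity_filter)) {
    keep_ids <- sel$mask_id[sel$p_anova < config$selectivity_filter]
    n0 <- nrow(pairs)
    pairs <- pairs[pairs$mask_a %in% keep_ids & pairs$mask_b %in% keep_ids, ]
    log$n_pairs_dropped_by_selectivity <- n0 - nrow(pairs)
  }
  log$n_pairs <- nrow(pairs)
  dist_fit <- tryCatch(fit_distance_model(pairs, seed = derive_seed(seed, "fit")),
                       error = function(e) NULL)

  out <- list(sim = sim, dff = prep$dff, fits = prep$fits,
              independence = ind, selectivity = sel, pairs = pairs,
              distance_fit = dist_fit, log = log, config = config)
  if (!is.null(config$outdir)) write_pipeline_output(out, config$outdir)
  out
}

write_pipeline_output <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out$fits, file.path(outdir, "bap_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(out$independence, file.path(outdir, "independence.csv"),
                   row.names = FALSE)
  utils::write.csv(out$selectivity, file.path(outdir, "selectivity.csv"),
                   row.names = FALSE)
  utils::write.csv(out$pairs, file.path(outdir, "pairs.csv"),
                   row.names = FALSE)
  write_config(out$config, file.path(outdir, "config.yaml"))
  manifest <- list(seed = out$config$seed, log = out$log,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Length-constant recovery study
#'
#' Simulates `n_sessions` sessions for a distance-dependent process
#' (presynaptic clustering: `a_pre = 0.5, a_coop = 0`; postsynaptic
#' cooperativity: `a_coop = 0.5, a_pre = 0`; null: both 0) at a given
#' length constant, runs preprocessing and bAP subtraction, pools the
#' pairwise spine correlations over sessions, and fits the
#' exponential-linear distance model. With stationary (untuned) inputs the
#' distance structure lives in the trial-to-trial co-fluctuations, so the
#' default pairwise measure is the noise correlation.
#'
#' @param process `"presynaptic_clustering"`, `"postsynaptic_cooperativity"`
#'   or `"null"`.
#' @param lambda_um the simulated length constant (um); ignored for
#'   `"null"`.
#' @param n_sessions number of simulated sessions.
#' @param config base configuration ([pipeline_config()]); its `params`
#'   amplitudes/length constants are overridden per `process`.
#' @param n_boot bootstrap iterations for the lambda error (over sessions).
#' @param seed master seed.
#' @return list with `lambda_hat`, `lambda_se`, `fit`, `curve`,
#'   `session_pairs`, `distance_test` (shuffle p), `process`, `lambda_um`.
#' @export
run_length_constant_recovery <- function(process = c("presynaptic_clustering",
                                                     "postsynaptic_cooperativity",
                                                     "null"),
                                         lambda_um = 10, n_sessions = 5,
                                         config = pipeline_config(),
                                         n_boot = 100, seed = 1L) {
  process <- match.arg(process)
  p <- config$params
  if (process == "presynaptic_clustering") {
    p$a_pre <- 0.5; p$a_coop <- 0; p$lambda_pre <- lambda_um
  } else if (process == "postsynaptic_cooperativity") {
    p$a_pre <- 0; p$a_coop <- 0.5; p$lambda_coop <- lambda_um
  } else {
    p$a_pre <- 0; p$a_coop <- 0
  }
  config$params <- p
  session_pairs <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    ss <- derive_seed(seed, paste0("session", s))
    sim <- simulate_config_session(config, ss)
    prep <- prepare_session_traces(sim, config, ss)
    session_pairs[[s]] <- session_spine_pairs(sim, prep$dff, config, ss)
  }
  pooled <- do.call(rbind, session_pairs)
  dm <- fit_distance_model(pooled, seed = derive_seed(seed, "fit"))
  se <- if (n_sessions >= 2) {
    bootstrap_lambda_se(session_pairs, n_boot = n_boot,
                        seed = derive_seed(seed, "boot"))$lambda_se
  } else NA_real_
  dt <- distance_effect_test(dm$pairs, n_shuffles = 1000,
                             seed = derive_seed(seed, "shuffle"))
  list(lambda_hat = dm$fit$lambda, lambda_se = se, fit = dm$fit,
       curve = dm$curve, session_pairs = session_pairs,
       distance_test = dt, process = process, lambda_um = lambda_um)
}

#' Subtraction-accuracy benchmark
#'
#' For each combination of spike-to-fluorescence transformation and input
#' lag, simulates one session and compares, for every subtraction method,
#' the inferred input-output correlation (Pearson correlation between the
#' bAP-subtracted spine trace and the soma dF/F) against the true
#' spike-train correlation between that spine and the soma.
#'
#' @param transformations character vector of transformation variants.
#' @param lags input lags (s).
#' @param methods subtraction methods (see [subtract_alternative()]).
#' @param config base configuration.
#' @param seed master seed.
#' @return long data.frame: `transformation`, `lag`, `method`, `mask_id`,
#'   `true_corr`, `inferred_corr`.
#' @export
run_subtraction_benchmark <- function(transformations = c("linear",
                                                          "indicator_nonlinear",
                                                          "full_nonlinear"),
                                      lags = 0,
                                      methods = c("deconv_soma", "nonneg",
                                                  "regress_soma",
                                                  "regress_dendrite",
                                                  "deconv_dendrite"),
                                      config = pipeline_config(),
                                      seed = 1L) {
  out <- list()
  k <- 0
  for (tf in transformations) for (lg in lags) {
    p <- config$params
    cfgp <- simulation_params(
      transformation = tf, a_pre = p$a_pre, lambda_pre = p$lambda_pre,
      a_s = p$a_s, a_c = p$a_c, a_coop = p$a_coop,
      lambda_coop = p$lambda_coop, n_nl = p$n_nl, K_nl = p$K_nl,
      tau_nl_ms = p$tau_nl * 1000, r = p$r, n_g = p$n_g, K_g = p$K_g,
      lambda_decay = p$lambda_decay, tau_s_mean = p$tau_s_mean,
      tau_s_sd = p$tau_s_sd, tau_c = p$tau_c, f_max = p$f_max,
      sigma_s = p$sigma_s, sigma_c = p$sigma_c, mean_rate = p$mean_rate,
      lag = lg, sample_rate = p$sample_rate)
    cfg <- config
    cfg$params <- cfgp
    # sessions are matched across lags (same geometry, trials and trains;
    # only the spine-train shift differs) so lag effects are paired
    ss <- derive_seed(seed, tf)
    sim <- simulate_config_session(cfg, ss)
    dff <- sim$traces$dff
    soma <- dff[, 1]
    # dendrite reference: a 30-um segment trace synthesized as the local
    # average of member-spine fluorescence plus the soma-driven component
    segs <- segment_dendrite(sim$tree, 30)
    dend <- synth_dendrite_trace(sim, segs)
    for (me in methods) {
      sub <- vapply(seq_len(ncol(dff))[-1], function(j) {
        r <- subtract_alternative(dff[, j], ref_dff = soma,
                                  dendrite_dff = dend[, closest_segment(sim, segs, j - 1)],
                                  method = me,
                                  sample_rate = cfgp$sample_rate,
                                  seed = derive_seed(ss, paste0(me, j)))
        suppressWarnings(stats::cor(r$residual, soma))
      }, numeric(1))
      k <- k + 1
      out[[k]] <- data.frame(transformation = tf, lag = lg, method = me,
                             mask_id = colnames(dff)[-1],
                             true_corr = sim$ground_truth$io_corr,
                             inferred_corr = sub)
    }
  }
  do.call(rbind, out)
}

# synthesize 30-um dendrite segment traces from a simulated session: soma
# (bAP) component plus the mean fluorescence of the spines in each segment
synth_dendrite_trace <- function(sim, segs) {
  dff <- sim$traces$dff
  spine_masks <- sim$masks[sim$masks$kind == "spine", ]
  D <- node_distances(sim$tree)
  seg_pts <- lapply(seq_len(nrow(segs)), function(i)
    resolve_attachment(sim$tree, segs$node_id[i], segs$offset[i]))
  sp_pts <- lapply(seq_len(nrow(spine_masks)), function(i)
    resolve_attachment(sim$tree, spine_masks$node_id[i],
                       spine_masks$offset[i]))
  out <- matrix(0, nrow(dff), nrow(segs))
  for (s in seq_len(nrow(segs))) {
    d <- vapply(sp_pts, function(p)
      point_tree_distance(sim$tree, D, seg_pts[[s]], p)$d, numeric(1))
    members <- which(d <= segs$segment_length[s] / 2 + 2)
    local <- if (length(members)) {
      rowMeans(dff[, 1 + members, drop = FALSE])
    } else 0
    out[, s] <- 0.7 * dff[, 1] + 0.3 * local
  }
  out
}

# index of the dendrite segment closest (tree metric) to spine i
closest_segment <- function(sim, segs, spine_index) {
  spine_masks <- sim$masks[sim$masks$kind == "spine", ]
  D <- node_distances(sim$tree)
  sp <- resolve_attachment(sim$tree, spine_masks$node_id[spine_index],
                           spine_masks$offset[spine_index])
  d <- vapply(seq_len(nrow(segs)), function(s) {
    point_tree_distance(sim$tree, D,
                        resolve_attachment(sim$tree, segs$node_id[s],
                                           segs$offset[s]), sp)$d
  }, numeric(1))
  which.min(d)
}
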