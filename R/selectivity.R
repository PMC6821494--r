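#' Per-trial epoch responses of one mask
#'
#' Averages the dF/F of each included trial (correct, no early lick) in each
#' of the five epochs S, D1, D2, R1, R2. Sample counts are equalized across
#' epochs: every epoch of a trial contributes the same number of samples as
#' its smallest 1-s epoch, with the surplus samples of the 1.25-s sample
#' epoch dropped by seeded random subsampling (approximately 1 s worth of
#' samples is drawn from the sample epoch).
#'
#' @param trace dF/F trace of one mask.
#' @param times sample times (s).
#' @param trials trial table (see [synth_trials()]).
#' @param seed RNG seed for the subsampling.
#' @return data.frame with columns `trial`, `type`, `epoch`, `response`.
#' @export
epoch_responses <- function(trace, times, trials, seed = 1L) {
  keep <- trials$correct & !trials$early_lick &
    trials$sample_on >= times[1] & trials$r2_off <= times[length(times)]
  trials <- trials[keep, , drop = FALSE]
  if (!nrow(trials)) stop("no valid trials overlap the trace")
  rng <- local_rng(seed)
  en <- epoch_names()
  out <- vector("list", nrow(trials))
  for (ti in seq_len(nrow(trials))) {
    tt <- trials[ti, ]
    b <- trial_epoch_bounds(tt)
    idx <- lapply(seq_len(5), function(e) {
      which(times >= b$on[e] & times < b$off[e])
    })
    n_eq <- min(lengths(idx)[-1])
    if (n_eq < 1) stop("trial ", tt$trial, " has an empty epoch")
    resp <- vapply(seq_len(5), function(e) {
      ii <- idx[[e]]
      if (length(ii) > n_eq) {
        ii <- ii[sort(sample.int(length(ii), n_eq))]
      }
      mean(trace[ii])
    }, numeric(1))
    out[[ti]] <- data.frame(trial = tt$trial, type = tt$type, epoch = en,
                            response = resp)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# one-way F statistic across the 10 epoch x trial-type groups
f_statistic <- function(response, group) {
  mu <- mean(response)
  gm <- tapply(response, group, mean)
  gn <- tapply(response, group, length)
  k <- length(gm)
  ss_b <- sum(gn * (gm - mu)^2)
  ss_w <- sum((response - gm[group])^2)
  df_b <- k - 1
  df_w <- length(response) - k
  if (ss_w <= 0 || df_w <= 0) return(NA_real_)
  (ss_b / df_b) / (ss_w / df_w)
}

#' Permutation ANOVA for task-associated selectivity
#'
#' One-way F statistic across the 10 groups (5 epochs x 2 trial types); the
#' p-value is the proportion of F statistics from shuffles of the group
#' labels that exceed the observed F. Degenerate responses (no variance)
#' give p = 1 by convention.
#'
#' @param responses epoch responses from [epoch_responses()].
#' @param n_shuffles number of label shuffles.
#' @param seed RNG seed.
#' @return permutation p-value in `[0, 1]`.
#' @export
anova_shuffle <- function(responses, n_shuffles = 1000, seed = 1L) {
  group <- paste(responses$epoch, responses$type)
  if (length(unique(group)) < 2) stop("need at least two groups")
  f_obs <- f_statistic(responses$response, group)
  if (!is.finite(f_obs)) return(1)
  set.seed(as.integer(seed %% 2147483647L))
  f_null <- vapply(seq_len(n_shuffles), function(i) {
    f_statistic(responses$response, sample(group))
  }, numeric(1))
  mean(f_null[is.finite(f_null)] > f_obs)
}

#' Epoch angle of mean sample/delay/response responses
#'
#' The three mean responses are treated as magnitudes of vectors at 90
#' degrees (sample), 210 degrees (delay) and 330 degrees (response); the
#' angle of the vector average summarizes epoch selectivity on a circle.
#'
#' @param mean_s,mean_d,mean_r mean responses in the sample, delay (D1/D2
#'   pooled) and response (R1/R2 pooled) epochs, pooled over both correct
#'   trial types.
#' @return angle in degrees, in `[0, 360)`; `NA` for a zero vector sum.
#' @export
epoch_angle <- function(mean_s, mean_d, mean_r) {
  ax <- deg2rad(c(90, 210, 330))
  vx <- sum(c(mean_s, mean_d, mean_r) * cos(ax))
  vy <- sum(c(mean_s, mean_d, mean_r) * sin(ax))
  if (abs(vx) < 1e-12 && abs(vy) < 1e-12) return(NA_real_)
  (rad2deg(atan2(vy, vx)) + 360) %% 360
}

# collapse per-trial epoch responses to the S/D/R means and the angle
angle_from_responses <- function(responses) {
  s <- mean(responses$response[responses$epoch == "S"])
  d <- mean(responses$response[responses$epoch %in% c("D1", "D2")])
  r <- mean(responses$response[responses$epoch %in% c("R1", "R2")])
  epoch_angle(s, d, r)
}

#' Bootstrap standard error of the epoch angle
#'
#' Circular standard deviation of the epoch angle over bootstrap resamples
#' of trials.
#'
#' @param responses epoch responses from [epoch_responses()].
#' @param n_boot bootstrap iterations.
#' @param seed RNG seed.
#' @return circular SD of the bootstrap angles, degrees.
#' @export
bootstrap_angle_se <- function(responses, n_boot = 1000, seed = 1L) {
  ids <- unique(responses$trial)
  if (length(ids) < 5) stop("need at least 5 trials")
  set.seed(as.integer(seed %% 2147483647L))
  by_trial <- split(responses, responses$trial)
  angs <- vapply(seq_len(n_boot), function(i) {
    take <- sample(as.character(ids), length(ids), replace = TRUE)
    angle_from_responses(do.call(rbind, by_trial[take]))
  }, numeric(1))
  angs <- angs[is.finite(angs)]
  if (!length(angs)) return(NA_real_)
  circ_sd_deg(angs)
}

#' Permutation test for the epoch-angle difference of two masks
#'
#' The observed statistic is the absolute circular difference of the two
#' masks' epoch angles. The null exchanges trial identity between the masks
#' (each trial's responses are swapped with probability 1/2); p is the
#' proportion of permuted differences at least as large as observed.
#'
#' @param responses_a,responses_b epoch responses of the two masks over the
#'   same trials.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list with `delta` (degrees, in `[0, 180]`) and `p`.
#' @export
delta_angle_test <- function(responses_a, responses_b, n_perm = 1000,
                             seed = 1L) {
  ids <- sort(unique(responses_a$trial))
  if (!identical(ids, sort(unique(responses_b$trial)))) {
    stop("masks must share the session's trials")
  }
  if (length(ids) < 5) stop("need at least 5 shared trials")
  obs <- circ_diff_deg(angle_from_responses(responses_a),
                       angle_from_responses(responses_b))
  a_by <- split(responses_a, responses_a$trial)
  b_by <- split(responses_b, responses_b$trial)
  set.seed(as.integer(seed %% 2147483647L))
  deltas <- vapply(seq_len(n_perm), function(i) {
    swap <- stats::runif(length(ids)) < 0.5
    pa <- a_by[as.character(ids)]
    pb <- b_by[as.character(ids)]
    tmp <- pa[swap]
    pa[swap] <- pb[swap]
    pb[swap] <- tmp
    circ_diff_deg(angle_from_responses(do.call(rbind, pa)),
                  angle_from_responses(do.call(rbind, pb)))
  }, numeric(1))
  list(delta = obs, p = mean(deltas >= obs, na.rm = TRUE))
}

#' Trial-type selectivity of a mask
#'
#' Each epoch is tested for a difference between right and left correct
#' trials by a two-sided permutation test of the mean difference, Bonferroni
#' corrected over the five epochs. A mask is categorized `"right"` when it
#' responds significantly more on right trials only, `"left"` for left
#' only, `"both"` when the preferred side differs across epochs, `"none"`
#' otherwise.
#'
#' @param responses epoch responses from [epoch_responses()].
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param alpha significance level before correction.
#' @return list with `category` and a per-epoch data.frame (`epoch`,
#'   `delta` = right - left, `p` raw, `p_adj` Bonferroni).
#' @export
trial_type_selectivity <- function(responses, n_perm = 1000, seed = 1L,
                                   alpha = 0.05) {
  if (length(unique(responses$type)) < 2) stop("both trial types required")
  en <- epoch_names()
  set.seed(as.integer(seed %% 2147483647L))
  res <- lapply(en, function(e) {
    sub <- responses[responses$epoch == e, ]
    obs <- mean(sub$response[sub$type == "right"]) -
      mean(sub$response[sub$type == "left"])
    perm <- vapply(seq_len(n_perm), function(i) {
      ty <- sample(sub$type)
      mean(sub$response[ty == "right"]) - mean(sub$response[ty == "left"])
    }, numeric(1))
    data.frame(epoch = e, delta = obs, p = mean(abs(perm) >= abs(obs)))
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- pmin(1, tab$p * length(en))
  sig <- tab$p_adj < alpha
  right <- any(sig & tab$delta > 0)
  left <- any(sig & tab$delta < 0)
  category <- if (right && left) "both" else if (right) "right"
    else if (left) "left" else "none"
  list(category = category, epochs = tab)
}

#' Circular mean of epoch angles with a bootstrap confidence interval
#'
#' @param angles epoch angles in degrees (one per mask/segment).
#' @param n_boot bootstrap iterations (resampling segments).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return list with `mean` (degrees), `ci` (length 2, degrees) and the
#'   half-widths `ci_halfwidth` relative to the mean.
#' @export
circular_mean_ci <- function(angles, n_boot = 1000, seed = 1L,
                             level = 0.95) {
  angles <- angles[is.finite(angles)]
  if (length(angles) < 2) stop("need at least 2 angles")
  m <- circ_mean_deg(angles)
  set.seed(as.integer(seed %% 2147483647L))
  boots <- vapply(seq_len(n_boot), function(i) {
    circ_mean_deg(sample(angles, length(angles), replace = TRUE))
  }, numeric(1))
  dev <- ((boots - m + 180) %% 360) - 180
  qs <- stats::quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(mean = m, ci = (m + qs + 360) %% 360, ci_halfwidth = qs)
}

#' Full selectivity analysis of one mask
#'
#' Runs [epoch_responses()], the permutation ANOVA, the epoch angle and its
#' bootstrap SE, and the trial-type categorization. A mask is flagged
#' epoch-selective when the ANOVA p is below `p_threshold` and the angle SE
#' below `se_threshold` degrees.
#'
#' @param trace dF/F trace (typically bAP-subtracted).
#' @param times sample times (s).
#' @param trials trial table.
#' @param n_shuffles permutations/bootstrap iterations.
#' @param seed RNG seed.
#' @param p_threshold ANOVA significance threshold.
#' @param se_threshold angle-SE threshold (degrees).
#' @return list with `responses`, `p_anova`, `angle`, `angle_se`,
#'   `selective`, `trial_type`.
#' @export
mask_selectivity <- function(trace, times, trials, n_shuffles = 1000,
                             seed = 1L, p_threshold = 0.01,
                             se_threshold = 30) {
  resp <- epoch_responses(trace, times, trials,
                          seed = derive_seed(seed, "epochs"))
  p_anova <- anova_shuffle(resp, n_shuffles,
                           seed = derive_seed(seed, "anova"))
  ang <- angle_from_responses(resp)
  se <- bootstrap_angle_se(resp, n_shuffles,
                           seed = derive_seed(seed, "boot"))
  tt <- trial_type_selectivity(resp, n_shuffles,
                               seed = derive_seed(seed, "type"))
  list(responses = resp, p_anova = p_anova, angle = ang, angle_se = se,
       selective = is.finite(ang) && !is.na(p_anova) && !is.na(se) &&
         p_anova < p_threshold && se < se_threshold,
       trial_type = tt$category, trial_type_epochs = tt$epochs)
}
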