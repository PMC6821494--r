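make_trials <- function(n = 30, seed = 1) {
  tr <- synth_trials(n, p_correct = 1, p_early_lick = 0, seed = seed)
  tr
}

test_that("epoch responses average the right samples with equalized counts", {
  trials <- make_trials(10)
  t_end <- max(trials$r2_off) + 2
  times <- seq(0, t_end, by = 1 / 14.5)
  resp <- epoch_responses(rep(2.5, length(times)), times, trials)
  expect_true(all(abs(resp$response - 2.5) < 1e-12))
  expect_equal(nrow(resp), 10 * 5)

  # indicator trace: 1 only during sample epochs
  tr1 <- numeric(length(times))
  for (i in seq_len(nrow(trials))) {
    tr1[times >= trials$sample_on[i] & times < trials$sample_off[i]] <- 1
  }
  r1 <- epoch_responses(tr1, times, trials)
  expect_true(all(r1$response[r1$epoch == "S"] == 1))
  expect_true(all(r1$response[r1$epoch != "S"] == 0))

  # step profile per epoch is recovered exactly (no subsampling noise for a
  # constant-per-epoch trace)
  lv <- c(S = 0.1, D1 = 0.5, D2 = 0.9, R1 = -0.2, R2 = 0.3)
  tr2 <- numeric(length(times))
  for (i in seq_len(nrow(trials))) {
    b <- trial_epoch_bounds(trials[i, ])
    for (e in 1:5) tr2[times >= b$on[e] & times < b$off[e]] <- lv[e]
  }
  r2 <- epoch_responses(tr2, times, trials)
  agg <- tapply(r2$response, r2$epoch, mean)
  expect_equal(as.numeric(agg[names(lv)]), as.numeric(lv), tolerance = 1e-12)
  expect_error(epoch_responses(tr2, times, trials[0, ]), "no valid trials")
})

test_that("permutation ANOVA detects strong effects and is calibrated under the null", {
  trials <- make_trials(24)
  t_end <- max(trials$r2_off) + 2
  times <- seq(0, t_end, by = 1 / 14.5)
  tuning <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0), 5, 2) # strong S tuning
  tt <- tuned_traces(trials, list(tuning), indep_sd = 0.05, seed = 2)
  resp <- epoch_responses(tt$dff[, 1], tt$times, trials)
  expect_lte(anova_shuffle(resp, n_shuffles = 500, seed = 1), 0.002)

  # degenerate constant responses
  respc <- epoch_responses(rep(1, length(times)), times, trials)
  expect_equal(anova_shuffle(respc, 100, seed = 1), 1)

  # null calibration: p-values approximately uniform
  null_tun <- matrix(0, 5, 2)
  ps <- vapply(1:120, function(i) {
    ttn <- tuned_traces(trials, list(null_tun), indep_sd = 0.2, seed = 100 + i)
    rn <- epoch_responses(ttn$dff[, 1], ttn$times, trials, seed = i)
    anova_shuffle(rn, n_shuffles = 200, seed = i)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(ps < 0.05), 0.05 + 0.05) # rejection near nominal
})

test_that("epoch angle places responses on axes 120 degrees apart", {
  expect_equal(epoch_angle(1, 0, 0), 90)
  expect_equal(epoch_angle(0, 1, 0), 210)
  expect_equal(epoch_angle(0, 0, 1), 330)
  expect_true(is.na(epoch_angle(1, 1, 1)))
  # bisector of the sample and delay axes via the 2D vector-sum oracle
  ax <- c(90, 210, 330) * pi / 180
  v <- colSums(c(1, 1, 0) * cbind(cos(ax), sin(ax)))
  oracle <- (atan2(v[2], v[1]) * 180 / pi + 360) %% 360
  expect_equal(epoch_angle(1, 1, 0), oracle)
  expect_equal(epoch_angle(1, 1, 0), 150)
  # rotation equivariance: cycling the magnitudes rotates the angle by 120
  a1 <- epoch_angle(1, 0.4, 0.1)
  a2 <- epoch_angle(0.1, 1, 0.4)
  expect_equal((a2 - a1) %% 360, 120, tolerance = 1e-9)
})

test_that("bootstrap angle SE reflects tuning strength and trial count", {
  trials <- make_trials(30)
  tun <- matrix(c(1, 0, 0, 0, 0), 5, 2)
  noiseless <- tuned_traces(trials, list(tun), indep_sd = 0, seed = 3)
  r0 <- epoch_responses(noiseless$dff[, 1], noiseless$times, trials)
  expect_lt(bootstrap_angle_se(r0, n_boot = 200, seed = 1), 1)

  noise <- tuned_traces(trials, list(matrix(0, 5, 2)), indep_sd = 0.3,
                        seed = 4)
  rn <- epoch_responses(noise$dff[, 1], noise$times, trials)
  expect_gt(bootstrap_angle_se(rn, n_boot = 200, seed = 1), 60)

  # SE shrinks with trial count at fixed noise
  weak <- matrix(c(0.15, 0, 0, 0, 0), 5, 2)
  tr20 <- make_trials(20, seed = 5)
  tr200 <- make_trials(200, seed = 6)
  se20 <- bootstrap_angle_se(epoch_responses(
    tuned_traces(tr20, list(weak), indep_sd = 0.3, seed = 7)$dff[, 1],
    tuned_traces(tr20, list(weak), indep_sd = 0.3, seed = 7)$times, tr20),
    n_boot = 200, seed = 1)
  se200 <- bootstrap_angle_se(epoch_responses(
    tuned_traces(tr200, list(weak), indep_sd = 0.3, seed = 8)$dff[, 1],
    tuned_traces(tr200, list(weak), indep_sd = 0.3, seed = 8)$times, tr200),
    n_boot = 200, seed = 1)
  expect_lt(se200, se20)
})

test_that("delta-angle permutation test separates orthogonal tuning", {
  trials <- make_trials(40)
  tun_s <- matrix(c(1, 0, 0, 0, 0), 5, 2)
  tun_d <- matrix(c(0, 1, 1, 0, 0), 5, 2)
  tt <- tuned_traces(trials, list(tun_s, tun_d), indep_sd = 0.1, seed = 9)
  ra <- epoch_responses(tt$dff[, 1], tt$times, trials)
  rb <- epoch_responses(tt$dff[, 2], tt$times, trials)
  self <- delta_angle_test(ra, ra, n_perm = 200, seed = 1)
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)
  ortho <- delta_angle_test(ra, rb, n_perm = 500, seed = 1)
  expect_equal(ortho$delta, 120, tolerance = 10)
  expect_lt(ortho$p, 0.01)
})

test_that("trial-type categorization follows the per-epoch permutation tests", {
  trials <- make_trials(40)
  right_only <- matrix(0, 5, 2)
  right_only[1, 2] <- 1 # larger response on right trials in the sample epoch
  tt <- tuned_traces(trials, list(right_only), indep_sd = 0.05, seed = 10)
  resp <- epoch_responses(tt$dff[, 1], tt$times, trials)
  out <- trial_type_selectivity(resp, n_perm = 400, seed = 1)
  expect_equal(out$category, "right")

  both <- matrix(0, 5, 2)
  both[1, 2] <- 1 # right in S
  both[4, 1] <- 1 # left in R1
  tb <- tuned_traces(trials, list(both), indep_sd = 0.05, seed = 11)
  rb <- epoch_responses(tb$dff[, 1], tb$times, trials)
  expect_equal(trial_type_selectivity(rb, 400, seed = 1)$category, "both")

  # null: no category in the vast majority of runs
  cats <- vapply(1:40, function(i) {
    tn <- tuned_traces(trials, list(matrix(0, 5, 2)), indep_sd = 0.2,
                       seed = 200 + i)
    rn <- epoch_responses(tn$dff[, 1], tn$times, trials, seed = i)
    trial_type_selectivity(rn, 200, seed = i)$category
  }, character(1))
  expect_gte(mean(cats == "none"), 0.85)
})

test_that("circular mean and bootstrap CI behave on the circle", {
  cm <- circular_mean_ci(c(45, 45, 45), n_boot = 100, seed = 1)
  expect_equal(cm$mean, 45)
  expect_equal(diff(cm$ci_halfwidth), 0)
  wrap <- circular_mean_ci(c(10, 350), n_boot = 100, seed = 1)
  expect_equal(wrap$mean, 0, tolerance = 1e-9)
  # coverage under concentrated circular noise
  hits <- vapply(1:100, function(i) {
    set.seed(i)
    ang <- (30 + rnorm(25, 0, 20)) %% 360
    ci <- circular_mean_ci(ang, n_boot = 300, seed = i)
    d <- ((30 - ci$mean + 180) %% 360) - 180
    d >= ci$ci_halfwidth[1] && d <= ci$ci_halfwidth[2]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("mask selectivity combines the pieces with the stated thresholds", {
  trials <- make_trials(30)
  tun <- matrix(c(1, 0, 0, 0, 0), 5, 2)
  tt <- tuned_traces(trials, list(tun), indep_sd = 0.05, seed = 12)
  sel <- mask_selectivity(tt$dff[, 1], tt$times, trials, n_shuffles = 300,
                          seed = 2)
  expect_true(sel$selective)
  expect_lt(sel$p_anova, 0.01)
  expect_lt(sel$angle_se, 30)
  expect_equal(sel$angle, 90, tolerance = 5)
})
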