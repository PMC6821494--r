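# build a pair table directly for the binning/fit/test operations
pair_table <- function(traversal, r, mask_a = NULL, mask_b = NULL,
                       euclidean = NULL, relation = "within") {
  n <- length(traversal)
  if (is.null(mask_a)) {
    mask_a <- sprintf("m%03d", seq_len(n) * 2 - 1)
    mask_b <- sprintf("m%03d", seq_len(n) * 2)
  }
  data.frame(mask_a = mask_a, mask_b = mask_b, traversal = traversal,
             euclidean = if (is.null(euclidean)) traversal else euclidean,
             branch_relation = relation, r = r)
}

test_that("split-trial signal correlation isolates tuning from shared noise", {
  trials <- synth_trials(200, p_correct = 1, p_early_lick = 0, seed = 1)
  tun <- matrix(c(1, 0.2, 0, -0.3, 0.5, 0, 0.8, 0.1, -0.1, 0.4), 5, 2)
  # identical tuning, independent per-trial noise -> r_signal ~ 1
  tt <- tuned_traces(trials, list(tun, tun), shared_sd = 0, indep_sd = 0.15,
                     seed = 2)
  rs <- signal_correlation(tt$dff[, 1], tt$dff[, 2], tt$times, trials,
                           n_splits = 100, seed = 3)
  expect_gt(rs, 0.95)
  # sign-flipped tuning -> r_signal ~ -1
  tf <- tuned_traces(trials, list(tun, -tun), shared_sd = 0, indep_sd = 0.15,
                     seed = 4)
  rsf <- signal_correlation(tf$dff[, 1], tf$dff[, 2], tf$times, trials,
                            n_splits = 100, seed = 5)
  expect_lt(rsf, -0.9)
})

test_that("split-half decontamination: common noise produces no signal correlation", {
  # 500 untuned pairs, each sharing its own trial-epoch noise at rho = 0.5;
  # a single pair's split-half estimate has an irreducible SD of ~0.17 from
  # the 10-condition limit, so the claim is about the mean over pairs
  trials <- synth_trials(200, p_correct = 1, p_early_lick = 0, seed = 6)
  cn <- common_noise_traces(trials, n_pairs = 500, rho = 0.5, seed = 7)
  rs <- signal_correlation_matrix(cn$dff, cn$times, trials,
                                  n_splits = 60, seed = 8)
  expect_lt(abs(mean(rs[cn$pair_index])), 0.02)
  rn <- noise_correlation_matrix(cn$dff, cn$times, trials)
  expect_equal(mean(rn[cn$pair_index]), 0.5, tolerance = 0.05)
})

test_that("noise correlation averages within-condition correlations", {
  trials <- synth_trials(150, p_correct = 1, p_early_lick = 0, seed = 9)
  flat <- matrix(0, 5, 2)
  ti <- tuned_traces(trials, list(flat, flat), shared_sd = 0,
                     indep_sd = 0.2, seed = 10)
  expect_lt(abs(noise_correlation(ti$dff[, 1], ti$dff[, 2], ti$times,
                                  trials)), 0.1)
  expect_equal(noise_correlation(ti$dff[, 1], ti$dff[, 1], ti$times, trials),
               1, tolerance = 1e-9)
})

test_that("distance bins use the printed edges, right-open, capped at 245", {
  p <- pair_table(c(1, 2.7, 4.4, 12, 244.9, 300), r = rep(0.1, 6))
  b <- bin_by_distance(p)
  expect_equal(nrow(b), 5) # 300 um dropped
  expect_equal(b$bin, c(1, 2, 2, 5, 10))
  expect_error(bin_by_distance(pair_table(-1, 0.1)), "negative")
})

test_that("member-disjoint SEM resampling handles shared masks", {
  # disjoint pairs: matches the plain SEM
  set.seed(1)
  r <- rnorm(20, 0.3, 0.1)
  p <- pair_table(rep(5, 20), r)
  bs <- binned_sem(bin_by_distance(p), n_draws = 50, seed = 2)
  expect_equal(bs$sem, sd(r) / sqrt(20), tolerance = 1e-9)
  expect_equal(bs$n_drawn, 20)
  # star graph: hub mask shared by every pair -> one pair per draw
  ph <- pair_table(rep(5, 4), rnorm(4), mask_a = rep("hub", 4),
                   mask_b = paste0("leaf", 1:4))
  bh <- binned_sem(bin_by_distance(ph), n_draws = 20, seed = 3)
  expect_equal(bh$n_drawn, 1)
  expect_true(is.na(bh$sem) | is.nan(bh$sem))
})

test_that("exponential-linear fit recovers parameters and flags degeneracy", {
  x <- c(1.3, 3.5, 6, 9.5, 16, 26, 44, 72, 115, 190)
  y <- 0.5 * exp(-x / 10) + x * (-0.001) + 0.1
  fit <- fit_exp_linear(x, y, seed = 1)
  expect_equal(fit$A, 0.5, tolerance = 1e-3)
  expect_equal(fit$lambda, 10, tolerance = 10 * 1e-3)
  expect_equal(fit$L, -0.001, tolerance = 1e-5)
  expect_equal(fit$B, 0.1, tolerance = 1e-3)
  expect_true(fit$identifiable)

  lin <- fit_exp_linear(x, 0.002 * x + 0.05, seed = 1)
  expect_false(lin$identifiable && lin$A > 0.01)
  expect_error(fit_exp_linear(x[1:4], y[1:4]), "at least 5")

  # noisy recovery: median over repeats within 30%
  lams <- vapply(1:15, function(i) {
    set.seed(i)
    yn <- 0.5 * exp(-x / 10) - 0.001 * x + 0.1 + rnorm(length(x), 0, 0.02)
    fit_exp_linear(x, yn, seed = i)$lambda_raw
  }, numeric(1))
  expect_lt(abs(median(lams) - 10) / 10, 0.3)
})

test_that("lambda bootstrap over sessions reflects heterogeneity", {
  x <- c(1.3, 3.5, 6, 9.5, 16, 26, 44, 72, 115, 190)
  mk <- function(lam, seed) {
    set.seed(seed)
    pair_table(rep(x, each = 4),
               0.5 * exp(-rep(x, each = 4) / lam) + 0.1 +
                 rnorm(length(x) * 4, 0, 0.01),
               mask_a = sprintf("a%03d", 1:40), mask_b = sprintf("b%03d", 1:40))
  }
  same <- list(mk(10, 1), mk(10, 1), mk(10, 1))
  bs <- bootstrap_lambda_se(same, n_boot = 30, seed = 2)
  expect_lt(bs$lambda_se, 0.5)
  hetero <- list(mk(5, 1), mk(20, 2), mk(60, 3))
  bh <- bootstrap_lambda_se(hetero, n_boot = 30, seed = 2)
  expect_gt(bh$lambda_se, bs$lambda_se)
  expect_warning(single <- bootstrap_lambda_se(hetero[1], 10, 1), "single")
  expect_true(is.na(single$lambda_se))
})

test_that("distance-effect shuffle test detects structure and stays calibrated", {
  x <- rep(c(1.3, 3.5, 6, 9.5, 16, 26, 44, 72, 115, 190), each = 20)
  set.seed(3)
  strong <- bin_by_distance(pair_table(x, 0.5 * exp(-x / 10) +
                                         rnorm(length(x), 0, 0.05),
                                       mask_a = sprintf("a%d", seq_along(x)),
                                       mask_b = sprintf("b%d", seq_along(x))))
  expect_lt(distance_effect_test(strong, 500, seed = 1)$p, 0.01)
  flat <- strong
  flat$r <- 0.2
  expect_gte(distance_effect_test(flat, 200, seed = 1)$p, 0.99)
  # calibration: shuffled-distance nulls give roughly uniform p
  ps <- vapply(1:25, function(i) {
    set.seed(i)
    null <- strong
    null$r <- rnorm(nrow(null), 0.2, 0.05)
    distance_effect_test(null, 200, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  one_bin <- strong[strong$bin == 1, ]
  expect_error(distance_effect_test(one_bin), "two populated bins")
})

test_that("branch comparison uses member-disjoint permutations", {
  set.seed(4)
  n <- 60
  rel <- rep(c("within", "across_one"), each = n / 2)
  r <- ifelse(rel == "within", 0.5, 0.2) + rnorm(n, 0, 0.05)
  p <- pair_table(runif(n, 1, 9), r,
                  mask_a = sprintf("a%d", 1:n), mask_b = sprintf("b%d", 1:n),
                  relation = rel)
  out <- branch_comparison(p, "short", n_perm = 400, seed = 1)
  expect_gt(out$mean_within, out$mean_across)
  expect_lt(out$p, 0.05)
  # label-randomized null: p should not be extreme
  pr <- p
  set.seed(5)
  pr$branch_relation <- sample(pr$branch_relation)
  pr$r <- rnorm(n, 0.3, 0.05)
  pnull <- branch_comparison(pr, "short", n_perm = 400, seed = 1)$p
  expect_gt(pnull, 0.01)
  all_within <- p[p$branch_relation == "within", ]
  expect_error(branch_comparison(all_within, "all_distances"), "non-empty")
})

test_that("motion control compares Euclid-close traversal-far pairs to matched bins", {
  x <- rep(c(35, 40, 50, 60), each = 10)
  set.seed(6)
  p <- pair_table(x, 0.2 + rnorm(length(x), 0, 0.01),
                  mask_a = sprintf("a%d", seq_along(x)),
                  mask_b = sprintf("b%d", seq_along(x)),
                  euclidean = x) # all far in both metrics
  # inject a motion artifact: 8 pairs close in space, far along the tree
  art <- pair_table(rep(45, 8), 0.5 + rnorm(8, 0, 0.01),
                    mask_a = sprintf("c%d", 1:8),
                    mask_b = sprintf("d%d", 1:8), euclidean = rep(5, 8))
  out <- motion_control(rbind(p, art))
  expect_equal(out$n, 8)
  expect_gt(out$difference, 0.2)
  clean <- motion_control(p)
  expect_true(clean$flagged)
  # simulator geometry: no Euclidean coupling, subset matches bins
  sim <- small_session(seed = 51, n_trials = 30, n_branches = 5)
  pt <- mask_pair_distances(sim$tree, sim$masks)
  pt <- pt[pt$kind_a == "spine" & pt$kind_b == "spine", ]
  cm <- suppressWarnings(cor(sim$traces$dff[, -1]))
  ids <- colnames(sim$traces$dff)[-1]
  pt$r <- cm[cbind(match(pt$mask_a, ids), match(pt$mask_b, ids))]
  mc <- motion_control(pt)
  if (!mc$flagged) expect_lt(abs(mc$difference), 0.1)
})

test_that("session pair statistics attach correlations to the geometry table", {
  sim <- small_session(seed = 61, n_trials = 40)
  pt <- mask_pair_distances(sim$tree, sim$masks)
  pt <- pt[pt$kind_a == "spine" & pt$kind_b == "spine", ]
  ps <- session_pair_stats(sim$traces$dff[, -1], sim$traces$times,
                           sim$trials, pt, n_splits = 20, seed = 1)
  expect_true(all(c("r_signal", "r_noise", "pair_class") %in% names(ps)))
  expect_true(all(abs(ps$r_noise) <= 1))
  expect_true(all(ps$pair_class == "spine-spine"))
  # nearby spines co-fluctuate more than distant ones (noise correlations)
  near <- ps$r_noise[ps$traversal < 10]
  far <- ps$r_noise[ps$traversal > 60]
  expect_gt(mean(near), mean(far))
})
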