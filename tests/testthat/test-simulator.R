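test_that("distance weights follow exp(-x/lambda) with identity limit", {
  x <- matrix(c(0, 10, 10, 0), 2)
  expect_equal(distance_weight_matrix(x, 10)[1, 2], exp(-1))
  expect_equal(distance_weight_matrix(x, 10)[1, 1], 1)
  expect_true(all(abs(distance_weight_matrix(x, 1e9) - 1) < 1e-7))
  expect_equal(distance_weight_matrix(x, 0), diag(2))
  expect_error(distance_weight_matrix(-x, 10), "non-negative")
})

test_that("covariance blending is a convex elementwise combination", {
  q <- matrix(c(1, 0.2, 0.2, 1), 2)
  U <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(blend_covariance(q, U, 0), q)
  expect_equal(blend_covariance(q, U, 1), U)
  expect_equal(blend_covariance(q, U, 0.5)[1, 2], 0.4)
  expect_error(blend_covariance(q, U, 1.5), "a_pre")
})

# alternating-projections oracle (Higham): project onto PSD cone and unit
# diagonal until convergence
oracle_ncm <- function(A, iters = 500) {
  Y <- A
  S <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(iters)) {
    R <- Y - S
    e <- eigen(R, symmetric = TRUE)
    Xp <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
    S <- Xp - R
    Y <- Xp
    diag(Y) <- 1
  }
  Y
}

test_that("nearest correlation matrix matches the alternating-projections oracle", {
  ok <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(nearest_correlation_matrix(ok), ok, tolerance = 1e-10)

  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_equal(unname(nearest_correlation_matrix(bad)),
               oracle_ncm(bad), tolerance = 1e-4)
  expect_equal(unname(nearest_correlation_matrix(bad)),
               matrix(1, 2, 2), tolerance = 1e-3)

  set.seed(7)
  M <- matrix(rnorm(100), 10)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  out <- nearest_correlation_matrix(M)
  expect_gte(min(eigen(out, symmetric = TRUE)$values), -1e-8)
  expect_equal(unname(diag(out)), rep(1, 10))
  expect_error(nearest_correlation_matrix(matrix(rnorm(9), 3)), "symmetric")
})

test_that("random base covariance is PSD, reproducible, and spans 0-0.8 after blending", {
  q <- random_base_covariance(200, seed = 2)
  expect_gte(min(eigen(q, symmetric = TRUE)$values), -1e-10)
  expect_identical(q, random_base_covariance(200, seed = 2))
  expect_false(identical(q, random_base_covariance(200, seed = 3)))
  # blend with distances of 200 points on a 300-um line, defaults
  pos <- seq(0, 300, length.out = 200)
  U <- distance_weight_matrix(abs(outer(pos, pos, "-")), 10)
  l <- blend_covariance(q, U, 0.5)
  off <- l[upper.tri(l)]
  expect_lte(min(off), 0.1)
  expect_gte(max(off), 0.7)
})

test_that("correlated Poisson trains match target rates and correlations", {
  n <- 6
  dur <- 3600
  dt <- 1 / 14.5
  tr <- correlated_poisson_trains(diag(n), rates = 1.5, duration = dur,
                                  dt = dt, seed = 4)
  rate <- colSums(tr$events) / dur
  se <- sqrt(1.5 / dur)
  expect_true(all(abs(rate - 1.5) < 3.5 * se))
  cc <- cor(tr$events)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.03)

  # strongly correlated pair
  C <- matrix(c(1, 0.8, 0.8, 1), 2)
  tr2 <- correlated_poisson_trains(C, 1.5, dur, dt, seed = 5)
  r <- cor(tr2$events)[1, 2]
  expect_lt(abs(r - 0.8), 3 * (1 - 0.8^2) / sqrt(dur / dt))

  tr0 <- correlated_poisson_trains(diag(2), 0, 100, dt, seed = 6)
  expect_true(all(tr0$events == 0))

  Cbad <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_error(correlated_poisson_trains(Cbad, 1.5, 100, dt, seed = 1),
               "infeasible")
})

test_that("empirical spike correlations converge to the target matrix", {
  set.seed(11)
  n <- 50
  pos <- sort(runif(n, 0, 250))
  q <- random_base_covariance(n, seed = 3)
  U <- distance_weight_matrix(abs(outer(pos, pos, "-")), 10)
  l <- nearest_correlation_matrix(blend_covariance(q, U, 0.5))
  tr <- correlated_poisson_trains(l, 1.5, duration = 7200, dt = 1 / 14.5,
                                  seed = 8)
  emp <- cor(tr$events)
  mae <- mean(abs(emp[upper.tri(emp)] - l[upper.tri(l)]))
  expect_lt(mae, 0.05)
})

test_that("spike correlations decay with distance at the configured length constant", {
  set.seed(12)
  n <- 80
  pos <- sort(runif(n, 0, 250))
  x <- abs(outer(pos, pos, "-"))
  q <- random_base_covariance(n, seed = 9)
  l <- nearest_correlation_matrix(blend_covariance(
    q, distance_weight_matrix(x, 10), 0.5))
  tr <- correlated_poisson_trains(l, 1.5, duration = 7200, dt = 1 / 14.5,
                                  seed = 10)
  emp <- cor(tr$events)
  pairs <- data.frame(traversal = x[upper.tri(x)], r = emp[upper.tri(emp)],
                      mask_a = rep(seq_len(n), n)[upper.tri(x)],
                      mask_b = rep(seq_len(n), each = n)[upper.tri(x)])
  fit <- fit_distance_model(pairs, seed = 2)$fit
  expect_lt(abs(fit$lambda - 10) / 10, 0.3)
})

test_that("linear depolarization adds the three printed terms", {
  x <- matrix(c(0, 10, 10, 0), 2)
  p <- simulation_params()
  e_sp <- matrix(0L, 5, 2)
  e_sp[3, 1] <- 1L
  soma <- integer(5)
  dep <- linear_depolarization(e_sp, soma, x, p)
  expect_equal(dep[3, 1], p$a_s + 0) # own spike, no soma, neighbor silent
  expect_equal(dep[3, 2], p$a_coop * p$a_s * exp(-1)) # neighbor at lambda_coop
  soma2 <- c(0L, 1L, 0L, 0L, 0L)
  dep2 <- linear_depolarization(matrix(0L, 5, 2), soma2, x, p)
  expect_equal(dep2[2, ], rep(p$a_c, 2)) # bAP depolarizes every spine
  expect_error(linear_depolarization(e_sp, integer(4), x, p), "time base")
})

test_that("nonlinear component gates on depolarization and spike history", {
  p <- simulation_params()
  e <- matrix(c(0L, 1L, 0L, 0L, 0L), 5, 1)
  pp <- matrix(p$K_nl, 5, 1) # at half-unblock
  q <- nonlinear_component(e, pp, p)
  expect_equal(q[2, 1], p$a_s / 2 * 1) # m = a_s/2, h(0) = 1
  # saturation: huge depolarization gives m -> a_s
  q2 <- nonlinear_component(e, matrix(1e6, 5, 1), p)
  expect_equal(q2[2, 1], p$a_s, tolerance = 1e-9)
  # no spikes in the trailing window -> q = 0
  expect_equal(q[c(1, 4, 5), 1], rep(0, 3))
  expect_equal(spine_calcium(1, 0.5, 3), 2.5)
  expect_equal(spine_calcium(matrix(2), matrix(9), 0), matrix(2))
})

test_that("decay constants are distance-correlated, positive, centered on the mean", {
  x <- abs(outer(seq(0, 100, 5), seq(0, 100, 5), "-"))
  tau_inf <- sample_decay_constants(x, 0.24, Inf, spread = 0.08, seed = 1)
  expect_equal(length(unique(round(tau_inf, 12))), 1) # one shared deviation
  tau0a <- sample_decay_constants(x, 0.24, 0, spread = 0.08, seed = 1)
  expect_gt(length(unique(tau0a)), 10) # independent deviations
  expect_true(all(tau0a >= 0.05))
  means <- vapply(1:400, function(s) {
    mean(sample_decay_constants(x[1:4, 1:4], 0.24, 32, 0.08, seed = s))
  }, numeric(1))
  expect_equal(mean(means), 0.24, tolerance = 0.01)
})

test_that("indicator chain: half-saturation, linear variant, kernel decay", {
  p <- simulation_params()
  ca <- c(p$K_g, rep(0, 20))
  f <- indicator_fluorescence(ca, 0.24, p)
  expect_equal(f[1], 0.5) # g = K_g at the impulse
  flin <- indicator_fluorescence(ca, 0.24, p, linear = TRUE)
  dt <- 1 / p$sample_rate
  # discrete convolution oracle for the linear variant
  kern <- exp(-(0:20) * dt / 0.24)
  oracle <- as.numeric(stats::convolve(ca, rev(kern), type = "open"))[1:21]
  expect_equal(flin, oracle, tolerance = 1e-9)
  expect_equal(flin[2] / flin[1], exp(-dt / 0.24), tolerance = 1e-9)
})

test_that("scaling anchors the 99.5th percentile exactly and noise has the set SD", {
  set.seed(3)
  f <- matrix(abs(rnorm(60000)), ncol = 6)
  sn <- scale_and_noise(f, f[, 1], f_max = 16, sigma_s = 0.2, sigma_c = 0.05,
                        seed = 9)
  expect_equal(quantile(sn$spines_clean, 0.995, names = FALSE), 16,
               tolerance = 1e-9)
  expect_equal(sd(sn$spines - sn$spines_clean), 0.2, tolerance = 0.01)
  sn0 <- scale_and_noise(f, f[, 1], 16, 0, 0, seed = 9)
  expect_identical(sn0$spines, sn0$spines_clean)
  expect_error(scale_and_noise(matrix(0, 5, 2), rep(0, 5), 16, 0.2, 0.05),
               "scale undefined")
  # scaling invariance: a positive gain before scaling changes nothing
  sn2 <- scale_and_noise(3.7 * f, 3.7 * f[, 1], 16, 0, 0, seed = 9)
  expect_equal(sn2$spines, sn0$spines, tolerance = 1e-12)
})

test_that("sessions are reproducible and the variant algebra holds", {
  geom <- generate_synthetic_tree(n_branches = 2,
                                  branch_length_range = c(30, 40),
                                  spine_density_per_um = 0.3, seed = 2)
  trials <- synth_trials(20, seed = 3)
  p_full <- simulation_params()
  s1 <- simulate_session(geom, trials, p_full, seed = 11)
  s2 <- simulate_session(geom, trials, p_full, seed = 11)
  expect_identical(s1$traces$dff, s2$traces$dff)

  # indicator-nonlinear preset == full nonlinear with a_coop = 0, r = 0
  p_ind <- simulation_params("indicator_nonlinear")
  p_red <- simulation_params()
  p_red$a_coop <- 0
  p_red$r <- 0
  si <- simulate_session(geom, trials, p_ind, seed = 11)
  sr <- simulate_session(geom, trials, p_red, seed = 11)
  expect_identical(si$traces$dff, sr$traces$dff)

  # linear variant: fluorescence is linear in calcium (zero noise to check)
  p_lin <- simulation_params("linear", sigma_s = 0, sigma_c = 0)
  sl <- simulate_session(geom, trials, p_lin, seed = 11)
  ca <- sl$ground_truth$ca
  f1 <- sl$traces$dff[, 2]
  g <- exp_filter <- as.numeric(stats::filter(ca[, 1],
                                              exp(-1 / (14.5 * sl$ground_truth$tau_s[1])),
                                              method = "recursive"))
  expect_equal(cor(f1, g), 1, tolerance = 1e-12)

  # lambda = 0 null: ground-truth correlations have no distance structure
  p_null <- simulation_params()
  p_null$a_pre <- 0
  p_null$a_coop <- 0
  sn <- simulate_session(geom, trials, p_null, seed = 11)
  ct <- sn$ground_truth$true_corr[-1, -1]
  x <- sn$distances[-1, -1]
  expect_lt(abs(cor(ct[upper.tri(ct)], x[upper.tri(x)])), 0.1)

  expect_error(simulate_session(geom, NULL, p_full, seed = 1), "trials or duration")
})
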