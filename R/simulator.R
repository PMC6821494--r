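#' Simulation parameters for the spike-to-fluorescence forward model
#'
#' Bundles every parameter of the forward model. Defaults are the
#' "Full Nonlinear" parameter set: `a_pre = 0.5`, `lambda_pre = 10` um,
#' `a_s = 1`, `a_c = 3`, `a_coop = 0.5`, `lambda_coop = 10` um, `n_nl = 2`,
#' `K_nl = 5`, `tau_nl_ms = 100`, `r = 3`, `n_g = 2`, `K_g = 12`,
#' `lambda_decay = 32` um, `tau_s_mean = 0.24` s, `tau_c = 0.4` s,
#' `f_max = 16` dF/F. The "Indicator Nonlinear" variant is the same set with
#' `a_coop = 0, r = 0`; the "Linear" variant additionally omits the
#' stationary indicator nonlinearity so that fluorescence is the calcium
#' trace convolved with the decay kernel.
#'
#' @param transformation spike-to-fluorescence transformation variant.
#' @param a_pre amplitude of distance-dependent presynaptic correlation, in
#'   `[0, 1]`.
#' @param lambda_pre length constant (um) of presynaptic correlations.
#' @param a_s depolarization per presynaptic spike.
#' @param a_c depolarization per back-propagating action potential.
#' @param a_coop overall cooperativity between spines.
#' @param lambda_coop length constant (um) of cooperativity.
#' @param n_nl Hill coefficient of voltage-dependent unblock (>= 1).
#' @param K_nl depolarization of half unblock.
#' @param tau_nl_ms decay time constant (ms) of the nonlinear component.
#' @param r relative strength of the nonlinear component.
#' @param n_g indicator Hill coefficient (>= 1).
#' @param K_g indicator half-saturation.
#' @param lambda_decay length constant (um) of the spatial covariance of
#'   spine decay constants.
#' @param tau_s_mean mean spine fluorescence decay constant (s).
#' @param tau_s_sd SD of spine decay constants across spines (s).
#' @param tau_c soma decay constant (s).
#' @param f_max dF/F value matched by the 99.5th percentile of scaled spine
#'   fluorescence.
#' @param sigma_s,sigma_c SD of additive Gaussian noise on spine and soma
#'   fluorescence (dF/F units).
#' @param mean_rate mean spike rate (Hz) of every generated train.
#' @param lag temporal shift (s) of spine spike trains relative to the soma
#'   train (positive = spines delayed).
#' @param sample_rate imaging sample rate (Hz); the simulation time step is
#'   one sample period.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(transformation = c("full_nonlinear",
                                                 "indicator_nonlinear",
                                                 "linear"),
                              a_pre = 0.5, lambda_pre = 10,
                              a_s = 1, a_c = 3,
                              a_coop = 0.5, lambda_coop = 10,
                              n_nl = 2, K_nl = 5, tau_nl_ms = 100,
                              r = 3, n_g = 2, K_g = 12,
                              lambda_decay = 32,
                              tau_s_mean = 0.24, tau_s_sd = 0.08,
                              tau_c = 0.4, f_max = 16,
                              sigma_s = 0.2, sigma_c = 0.05,
                              mean_rate = 1.5, lag = 0,
                              sample_rate = 14.5) {
  transformation <- match.arg(transformation)
  if (transformation != "full_nonlinear") {
    a_coop <- 0
    r <- 0
  }
  p <- list(transformation = transformation,
            a_pre = a_pre, lambda_pre = lambda_pre,
            a_s = a_s, a_c = a_c, a_coop = a_coop, lambda_coop = lambda_coop,
            n_nl = n_nl, K_nl = K_nl, tau_nl = tau_nl_ms / 1000,
            r = r, n_g = n_g, K_g = K_g,
            lambda_decay = lambda_decay,
            tau_s_mean = tau_s_mean, tau_s_sd = tau_s_sd, tau_c = tau_c,
            f_max = f_max, sigma_s = sigma_s, sigma_c = sigma_c,
            mean_rate = mean_rate, lag = lag, sample_rate = sample_rate)
  if (any(c(lambda_pre, lambda_coop, lambda_decay) < 0)) {
    stop("length constants must be >= 0")
  }
  if (n_nl < 1 || n_g < 1) stop("Hill coefficients must be >= 1")
  if (mean_rate < 0) stop("mean_rate must be >= 0")
  if (a_pre < 0 || a_pre > 1) stop("a_pre must be in [0, 1]")
  class(p) <- "simulation_params"
  p
}

#' Distance weight matrix
#'
#' `U[i, j] = exp(-x[i, j] / lambda)`. The `lambda = 0` limit is the
#' identity matrix (weight 1 at zero distance, 0 elsewhere).
#'
#' @param distances symmetric non-negative distance matrix (um).
#' @param lambda length constant (um), >= 0.
#' @return weight matrix with unit diagonal.
#' @export
distance_weight_matrix <- function(distances, lambda) {
  if (any(distances < 0)) stop("distances must be non-negative")
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0) {
    U <- (distances == 0) * 1
  } else {
    U <- exp(-distances / lambda)
  }
  diag(U) <- 1
  U
}

#' Blend a base covariance with a distance weight matrix
#'
#' `l = q * (1 - a_pre) + U * a_pre`, elementwise.
#'
#' @param q base correlation/covariance matrix.
#' @param U distance weight matrix (same shape).
#' @param a_pre blend amplitude in `[0, 1]`.
#' @return blended matrix.
#' @export
blend_covariance <- function(q, U, a_pre) {
  if (!all(dim(q) == dim(U))) stop("q and U must have the same shape")
  if (a_pre < 0 || a_pre > 1) stop("a_pre must be in [0, 1]")
  q * (1 - a_pre) + U * a_pre
}

#' Nearest correlation matrix
#'
#' The positive-semidefinite matrix with unit diagonal closest (Frobenius)
#' to the input, via Higham's alternating-projections method.
#'
#' @param l symmetric matrix.
#' @param tol eigenvalue tolerance.
#' @return nearest correlation matrix.
#' @export
nearest_correlation_matrix <- function(l, tol = 1e-8) {
  if (!isSymmetric(unname(l), tol = 1e-8)) stop("input must be symmetric")
  l <- (l + t(l)) / 2
  ev <- eigen(l, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol && max(abs(diag(l) - 1)) < 1e-12) return(l)
  as.matrix(Matrix::nearPD(l, corr = TRUE, eig.tol = tol,
                           conv.tol = 1e-10, maxit = 200)$mat)
}

#' Random base correlation matrix
#'
#' One-factor-plus-diagonal construction: right-skewed loadings
#' `u = v^2, v ~ U(0, 1)` give
#' `q[i, j] = u_i u_j / sqrt((u_i^2 + d)(u_j^2 + d))` with `d = 0.3`, a
#' positive-semidefinite unit-diagonal matrix whose off-diagonal entries
#' span approximately 0 to 0.77 (right-skewed, as cortical pairwise spike
#' correlations are) so that correlations after distance blending cover
#' roughly 0-0.8.
#'
#' @param n matrix dimension (>= 2).
#' @param seed integer RNG seed.
#' @return `n x n` correlation matrix.
#' @export
random_base_covariance <- function(n, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  rng <- local_rng(seed)
  u <- rng$unif(n, 0, 1)^2
  d <- 0.3
  s <- u / sqrt(u^2 + d)
  q <- outer(s, s)
  diag(q) <- 1
  q
}

# P(X > z1, Y > z2) for standard bivariate normal with correlation rho
bvn_upper <- function(z1, z2, rho) {
  if (abs(rho) < 1e-12) return((1 - stats::pnorm(z1)) * (1 - stats::pnorm(z2)))
  if (rho > 1 - 1e-9) return(1 - stats::pnorm(max(z1, z2)))
  if (rho < -1 + 1e-9) return(max(0, 1 - stats::pnorm(z1) - stats::pnorm(z2)))
  stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((rho * x - z2) / sqrt(1 - rho^2))
  }, z1, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
}

# map target binary (Bernoulli) correlations to latent Gaussian
# correlations by inverting the dichotomized-Gaussian moment relation on a
# spline grid (all trains share the marginal probability p)
latent_correlation <- function(rho_target, p) {
  z <- stats::qnorm(1 - p)
  grid <- seq(-0.999, 0.999, length.out = 81)
  pb <- vapply(grid, function(r) bvn_upper(z, z, r), numeric(1))
  rho_grid <- (pb - p^2) / (p * (1 - p))
  rho_max <- max(rho_grid)
  rho_min <- min(rho_grid)
  if (any(rho_target > rho_max + 1e-6) || any(rho_target < rho_min - 1e-6)) {
    bad <- which(rho_target > rho_max + 1e-6 | rho_target < rho_min - 1e-6)
    stop("target correlation infeasible for Bernoulli marginals at pair index ",
         bad[1], " (target ", signif(rho_target[bad[1]], 3), ")")
  }
  stats::approx(rho_grid, grid, xout = pmin(pmax(rho_target, rho_min), rho_max),
                rule = 2, ties = list("ordered", mean))$y
}

#' Generate correlated Poisson spike trains
#'
#' Dichotomized-Gaussian construction: a latent multivariate normal sample
#' is thresholded so every train is Bernoulli per time bin with
#' `P(spike) = rate * dt` and the binary pairwise correlations match the
#' target correlation matrix (matched first two moments). Targets that are
#' infeasible for the Bernoulli marginals raise an error naming the pair;
#' small indefiniteness of the implied latent matrix is repaired with the
#' nearest correlation matrix.
#'
#' @param correlation target pairwise correlation matrix (unit diagonal).
#' @param rates per-train mean rates (Hz); recycled to the matrix dimension.
#' @param duration simulated duration (s).
#' @param dt time bin (s); `rates * dt` must be well below 1.
#' @param seed integer RNG seed.
#' @param rate_gain optional `n_bins x n_trains` multiplicative rate gain
#'   (e.g. trial-epoch tuning); thresholds are adjusted per bin.
#' @return list with `events` (`n_bins x n_trains` 0/1 matrix), `times`,
#'   `dt`, and `rates`.
#' @export
correlated_poisson_trains <- function(correlation, rates, duration, dt,
                                      seed = 1L, rate_gain = NULL) {
  n <- nrow(correlation)
  rates <- rep_len(rates, n)
  if (any(rates < 0)) stop("rates must be >= 0")
  n_bins <- floor(duration / dt)
  times <- (seq_len(n_bins) - 1) * dt
  events <- matrix(0L, n_bins, n)
  active <- rates > 0
  if (any(active)) {
    p <- rates[active] * dt
    if (any(p > 0.5)) stop("rates * dt too large for a Bernoulli bin model")
    if (length(unique(p)) > 1) {
      stop("trains must share a common rate in this construction")
    }
    p0 <- p[1]
    sub <- correlation[active, active, drop = FALSE]
    lat <- matrix(0, sum(active), sum(active))
    off <- upper.tri(sub)
    lat[off] <- latent_correlation(sub[off], p0)
    lat <- lat + t(lat)
    diag(lat) <- 1
    lat <- nearest_correlation_matrix(lat)
    ch <- chol(lat + diag(1e-10, nrow(lat)))
    rng <- local_rng(seed)
    Z <- matrix(rng$norm(n_bins * sum(active)), n_bins) %*% ch
    if (is.null(rate_gain)) {
      z0 <- stats::qnorm(1 - p0)
      events[, active] <- (Z > z0) * 1L
    } else {
      pg <- pmin(0.9, t(t(matrix(rate_gain[, active], n_bins)) * 1) * p0)
      events[, active] <- (Z > stats::qnorm(1 - pg)) * 1L
    }
  }
  list(events = events, times = times, dt = dt, rates = rates)
}

#' Linear depolarization component at each spine
#'
#' `p_i(t) = a_s e_i(t) + a_c e_c(t) + a_coop sum_j w_ij a_s e_j(t)` with
#' `w_ij = exp(-x_ij / lambda_coop)` and the sum over all other spines j.
#'
#' @param spine_events `n_bins x n_spines` spike matrix.
#' @param soma_events length-`n_bins` soma spike vector.
#' @param distances spine-by-spine traversal distance matrix (um).
#' @param params a [simulation_params()].
#' @return `n_bins x n_spines` matrix of depolarization.
#' @export
linear_depolarization <- function(spine_events, soma_events, distances,
                                  params) {
  if (nrow(spine_events) != length(soma_events)) {
    stop("spine and soma trains must share the time base")
  }
  p <- params$a_s * spine_events +
    params$a_c * matrix(soma_events, nrow(spine_events), ncol(spine_events))
  if (params$a_coop > 0) {
    W <- distance_weight_matrix(distances, params$lambda_coop)
    diag(W) <- 0 # a spine does not cooperate with itself
    p <- p + params$a_coop * params$a_s * (spine_events %*% W)
  }
  p
}

#' Nonlinear (voltage-dependent unblock) component
#'
#' `q_i(t) = m_i(t) * sum_{t'=0}^{tau_nl} h(t') e_i(t - t')` with
#' `m_i(t) = a_s p^n_nl / (p^n_nl + K_nl^n_nl)` and `h(t') = exp(-t'/tau_nl)`.
#' The window is `floor(tau_nl / dt)` bins.
#'
#' @param spine_events `n_bins x n_spines` spike matrix.
#' @param p matrix of linear depolarization from [linear_depolarization()].
#' @param params a [simulation_params()].
#' @return matrix `q` of the same shape.
#' @export
nonlinear_component <- function(spine_events, p, params) {
  dt <- 1 / params$sample_rate
  nw <- floor(params$tau_nl / dt)
  acc <- spine_events * 1
  if (nw >= 1) {
    n <- nrow(spine_events)
    for (k in seq_len(nw)) {
      h <- exp(-k * dt / params$tau_nl)
      acc[(k + 1):n, ] <- acc[(k + 1):n, ] +
        h * spine_events[1:(n - k), , drop = FALSE]
    }
  }
  m <- params$a_s * p^params$n_nl / (p^params$n_nl + params$K_nl^params$n_nl)
  m[p <= 0] <- 0
  m * acc
}

#' Spine calcium
#'
#' `Ca_i(t) = p_i(t) + r q_i(t)`.
#'
#' @param p linear component.
#' @param q nonlinear component.
#' @param r relative strength of the nonlinear component.
#' @return calcium matrix.
#' @export
spine_calcium <- function(p, q, r) p + r * q

#' Sample distance-correlated spine decay constants
#'
#' Decay constants are `tau_mean` plus deviations drawn from a multivariate
#' normal with covariance `spread^2 * exp(-x_ij / lambda_decay)`, truncated
#' below at `floor_s` to keep every constant positive.
#'
#' @param distances spine-by-spine traversal distance matrix (um).
#' @param tau_mean mean decay constant (s).
#' @param lambda_decay spatial length constant (um); 0 gives independent
#'   deviations, `Inf` a single shared deviation.
#' @param spread SD of the deviations (s).
#' @param seed integer RNG seed.
#' @param floor_s lower truncation (s).
#' @return vector of per-spine decay constants (s).
#' @export
sample_decay_constants <- function(distances, tau_mean, lambda_decay,
                                   spread = 0.08, seed = 1L,
                                   floor_s = 0.05) {
  if (lambda_decay < 0) stop("lambda_decay must be >= 0")
  n <- nrow(distances)
  rng <- local_rng(seed)
  if (is.infinite(lambda_decay)) {
    dev <- rep(rng$norm(1, 0, spread), n)
  } else {
    C <- distance_weight_matrix(distances, lambda_decay)
    ch <- tryCatch(chol(C + diag(1e-9, n)), error = function(e) {
      chol(nearest_correlation_matrix(C) + diag(1e-9, n))
    })
    dev <- spread * as.numeric(rng$norm(n) %*% ch)
  }
  pmax(floor_s, tau_mean + dev)
}

#' Indicator fluorescence from a calcium trace
#'
#' `g(t) = Ca(t) * k(t)` (convolution with `k(t) = exp(-t / tau)`), then the
#' stationary indicator nonlinearity `f = g^n_g / (g^n_g + K_g^n_g)`. The
#' `"linear"` transformation omits the nonlinearity so that `f = g`.
#'
#' @param ca calcium trace (vector).
#' @param tau decay constant (s) of the convolution kernel.
#' @param params a [simulation_params()].
#' @param linear if `TRUE`, skip the stationary nonlinearity.
#' @return fluorescence trace (pre-scaling).
#' @export
indicator_fluorescence <- function(ca, tau, params, linear = FALSE) {
  if (tau <= 0) stop("tau must be > 0")
  g <- exp_filter(ca, tau, 1 / params$sample_rate)
  if (linear) return(g)
  g^params$n_g / (g^params$n_g + params$K_g^params$n_g)
}

#' Scale fluorescence to a dF/F anchor and add noise
#'
#' All spine traces are scaled by one factor so that the 99.5th percentile
#' of the pooled spine samples equals `f_max` exactly; the soma trace gets
#' the same factor. Zero-mean Gaussian noise of SD `sigma_s` (spines) and
#' `sigma_c` (soma) is then added.
#'
#' @param f_spines `n_bins x n_spines` pre-scaling fluorescence.
#' @param f_soma soma pre-scaling fluorescence vector.
#' @param f_max dF/F anchor for the 99.5th percentile.
#' @param sigma_s,sigma_c noise SDs (dF/F).
#' @param seed integer RNG seed.
#' @return list with `spines`, `soma` (noisy, dF/F scale), `spines_clean`,
#'   `soma_clean`, and `scale`.
#' @export
scale_and_noise <- function(f_spines, f_soma, f_max, sigma_s, sigma_c,
                            seed = 1L) {
  anchor <- stats::quantile(f_spines, 0.995, names = FALSE)
  if (!is.finite(anchor) || anchor <= 0) {
    stop("scale undefined: pooled spine fluorescence has no positive signal")
  }
  sc <- f_max / anchor
  spines_clean <- f_spines * sc
  soma_clean <- f_soma * sc
  rng <- local_rng(seed)
  spines <- spines_clean
  if (sigma_s > 0) {
    spines <- spines + matrix(rng$norm(length(spines), 0, sigma_s),
                              nrow(spines_clean))
  }
  soma <- soma_clean
  if (sigma_c > 0) soma <- soma + rng$norm(length(soma), 0, sigma_c)
  list(spines = spines, soma = soma, spines_clean = spines_clean,
       soma_clean = soma_clean, scale = sc)
}

# shift a matrix of spike trains by k bins (positive = delayed), zero-padded
shift_trains <- function(E, k) {
  if (k == 0) return(E)
  n <- nrow(E)
  out <- matrix(0L, n, ncol(E))
  if (k > 0) {
    out[(k + 1):n, ] <- E[1:(n - k), ]
  } else {
    out[1:(n + k), ] <- E[(-k + 1):n, ]
  }
  out
}

#' Simulate a full imaging session
#'
#' Runs the complete forward model on a morphology: distance-dependent
#' correlated Poisson spike trains for all spines plus the soma (the soma is
#' one row of the same correlation matrix), linear and nonlinear
#' depolarization, per-spine distance-correlated decay constants, the
#' indicator chain, scaling to the dF/F anchor and additive noise. The soma
#' trace uses the linear chain (`Ca = a_c * e_c` convolved with `tau_c`);
#' its nonlinear component is undefined in the model.
#'
#' @param geometry list with `tree` and `masks` as returned by
#'   [generate_synthetic_tree()].
#' @param trials trial table from [synth_trials()] (defines the session
#'   duration; pass `NULL` with `duration` instead for untriggered runs).
#' @param params a [simulation_params()].
#' @param seed integer RNG seed; all internal draws derive from it.
#' @param duration session duration (s) when `trials` is `NULL`.
#' @param tuning optional `n_spines x 10` rate-gain matrix (5 epochs x 2
#'   trial types, columns ordered S/D1/D2/R1/R2 for left then right) applied
#'   multiplicatively to the spike rate inside trial epochs.
#' @return list with `traces` (list: `times`, `dff` `n_bins x (1 + n_spines)`
#'   matrix with the soma first, `sigma` per mask, `mask_ids`), `spikes`,
#'   `ground_truth` (true correlation matrix including the soma row,
#'   per-spine `tau_s`, `p`, `q`, `ca`, true input-output correlations) and
#'   `distances` (spine + soma traversal distance matrix).
#' @export
simulate_session <- function(geometry, trials, params, seed = 1L,
                             duration = NULL, tuning = NULL) {
  if (!inherits(params, "simulation_params")) stop("params must be simulation_params")
  masks <- geometry$masks
  spines <- masks[masks$kind == "spine", , drop = FALSE]
  soma <- masks[masks$kind == "soma", , drop = FALSE]
  if (nrow(soma) != 1) stop("geometry must contain exactly one soma mask")
  n_sp <- nrow(spines)
  dt <- 1 / params$sample_rate
  if (is.null(duration)) {
    if (is.null(trials)) stop("need trials or duration")
    duration <- max(trials$r2_off) + 5
  }

  ord <- rbind(soma, spines)
  D <- node_distances(geometry$tree)
  pts <- lapply(seq_len(nrow(ord)), function(i)
    resolve_attachment(geometry$tree, ord$node_id[i], ord$offset[i]))
  n_all <- nrow(ord)
  x <- matrix(0, n_all, n_all)
  for (i in seq_len(n_all - 1)) for (j in (i + 1):n_all) {
    x[i, j] <- x[j, i] <- point_tree_distance(geometry$tree, D,
                                              pts[[i]], pts[[j]])$d
  }

  q0 <- random_base_covariance(n_all, derive_seed(seed, "base_cov"))
  U <- distance_weight_matrix(x, params$lambda_pre)
  l <- blend_covariance(q0, U, params$a_pre)
  corr <- nearest_correlation_matrix(l)

  gain <- NULL
  if (!is.null(tuning)) {
    gain <- tuning_gain_matrix(tuning, trials, duration, dt, n_all)
  }
  tr <- correlated_poisson_trains(corr, params$mean_rate, duration, dt,
                                  seed = derive_seed(seed, "trains"),
                                  rate_gain = gain)
  soma_events <- tr$events[, 1]
  spine_events <- tr$events[, -1, drop = FALSE]
  lag_bins <- round(params$lag / dt)
  spine_events <- shift_trains(spine_events, lag_bins)

  x_sp <- x[-1, -1, drop = FALSE]
  p <- linear_depolarization(spine_events, soma_events, x_sp, params)
  qc <- if (params$r > 0) nonlinear_component(spine_events, p, params)
        else matrix(0, nrow(p), ncol(p))
  ca <- spine_calcium(p, qc, params$r)

  tau_s <- sample_decay_constants(x_sp, params$tau_s_mean,
                                  params$lambda_decay, params$tau_s_sd,
                                  seed = derive_seed(seed, "tau"))
  lin <- params$transformation == "linear"
  f_sp <- vapply(seq_len(n_sp), function(i) {
    indicator_fluorescence(ca[, i], tau_s[i], params, linear = lin)
  }, numeric(nrow(ca)))
  ca_soma <- params$a_c * soma_events
  f_soma <- indicator_fluorescence(ca_soma, params$tau_c, params,
                                   linear = TRUE)

  sn <- scale_and_noise(f_sp, f_soma, params$f_max, params$sigma_s,
                        params$sigma_c, seed = derive_seed(seed, "noise"))

  dff <- cbind(sn$soma, sn$spines)
  colnames(dff) <- c(soma$mask_id, spines$mask_id)
  traces <- list(times = tr$times, dff = dff,
                 sigma = c(params$sigma_c, rep(params$sigma_s, n_sp)),
                 mask_ids = colnames(dff), sample_rate = params$sample_rate)
  gt <- list(true_corr = corr, tau_s = tau_s, p = p, q = qc, ca = ca,
             io_corr = corr[1, -1],
             dff_clean = cbind(sn$soma_clean, sn$spines_clean),
             scale = sn$scale)
  list(traces = traces, spikes = list(soma = soma_events,
                                      spines = spine_events,
                                      times = tr$times, dt = dt),
       ground_truth = gt, distances = x, mask_ids = colnames(dff),
       masks = ord, tree = geometry$tree, trials = trials)
}

# expand a per-spine x 10-condition gain matrix to a bins x trains gain
# matrix on the session clock (train 1 = soma, gain 1)
tuning_gain_matrix <- function(tuning, trials, duration, dt, n_all) {
  n_bins <- floor(duration / dt)
  gain <- matrix(1, n_bins, n_all)
  if (is.null(trials)) stop("tuning requires a trial table")
  cond_cols <- condition_columns()
  for (ti in seq_len(nrow(trials))) {
    tt <- trials[ti, ]
    bounds <- trial_epoch_bounds(tt)
    for (e in seq_len(5)) {
      cc <- cond_cols[[tt$type]][e]
      i0 <- max(1L, floor(bounds$on[e] / dt) + 1L)
      i1 <- min(n_bins, ceiling(bounds$off[e] / dt))
      if (i1 >= i0) {
        gain[i0:i1, -1] <- matrix(tuning[, cc], i1 - i0 + 1L, nrow(tuning),
                                  byrow = TRUE)
      }
    }
  }
  gain
}

condition_columns <- function() {
  list(left = 1:5, right = 6:10)
}
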