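# exact non-negative AR(1) deconvolution by pool-adjacent-violators
# (OASIS with no sparsity penalty): minimizes ||c - y||^2 subject to
# s_t = c_t - gamma c_{t-1} >= 0
oasis_ar1 <- function(y, gamma) {
  n <- length(y)
  if (n == 0) return(list(c = numeric(0), s = numeric(0)))
  vv <- numeric(n); ww <- numeric(n); tt <- integer(n); ll <- integer(n)
  vv[1] <- y[1]; ww[1] <- 1; tt[1] <- 1L; ll[1] <- 1L
  np <- 1L
  for (t in seq_len(n)[-1]) {
    np <- np + 1L
    vv[np] <- y[t]; ww[np] <- 1; tt[np] <- t; ll[np] <- 1L
    while (np > 1L && vv[np] < vv[np - 1L] * gamma^ll[np - 1L]) {
      g <- gamma^ll[np - 1L]
      vv[np - 1L] <- (ww[np - 1L] * vv[np - 1L] + g * ww[np] * vv[np]) /
        (ww[np - 1L] + g^2 * ww[np])
      ww[np - 1L] <- ww[np - 1L] + g^2 * ww[np]
      ll[np - 1L] <- ll[np - 1L] + ll[np]
      np <- np - 1L
    }
  }
  cc <- numeric(n)
  for (k in seq_len(np)) {
    v <- max(0, vv[k])
    idx <- tt[k]:(tt[k] + ll[k] - 1L)
    cc[idx] <- v * gamma^(seq_along(idx) - 1)
  }
  s <- cc - gamma * c(0, cc[-n])
  s[s < 0] <- 0 # numeric guard; PAVA already enforces s >= 0
  list(c = cc, s = s)
}

# AR(1) coefficient from the trace autocovariance: for an AR(1) signal plus
# white noise, acov(k+1)/acov(k) = gamma for k >= 1
estimate_ar1_coef <- function(y) {
  n <- length(y)
  ac <- stats::acf(y, lag.max = 2, plot = FALSE, demean = TRUE,
                   type = "covariance")$acf[, 1, 1]
  if (length(ac) < 3 || !is.finite(ac[2]) || ac[2] <= 0 || ac[3] <= 0) {
    return(NA_real_)
  }
  g <- ac[3] / ac[2]
  if (!is.finite(g) || g <= 0 || g >= 1) NA_real_ else g
}

#' Deconvolve the global reference trace
#'
#' Sparse non-negative deconvolution of the reference dF/F against an AR(1)
#' kernel (constrained spike inference with autoregressive order 1). The AR
#' coefficient is estimated from the trace autocovariance ratio at lags 1-2,
#' which is unbiased for an AR(1) signal in white noise, so no shrinkage is
#' applied by default (`fudge = 1`). A multiplicative `fudge` factor (e.g.
#' 0.5, as used with spectral AR estimators that over-estimate the
#' coefficient on slow drifts) is exposed; values below 1 shorten the
#' assumed kernel and smear events over transient tails.
#'
#' @param ref_dff reference dF/F trace.
#' @param gamma optional AR(1) coefficient; estimated when `NULL`.
#' @param fudge multiplier applied to the estimated AR coefficient.
#' @param sample_rate samples per second (used for the fallback coefficient
#'   `exp(-dt / 0.4)` when the estimate fails).
#' @return list with `events` (non-negative deconvolved amplitudes),
#'   `reconstruction` (the fitted AR(1) trace), and `gamma`.
#' @export
deconvolve_reference <- function(ref_dff, gamma = NULL, fudge = 1,
                                 sample_rate = 14.5) {
  if (any(!is.finite(ref_dff))) stop("non-finite values in reference trace")
  if (all(ref_dff == 0)) {
    return(list(events = numeric(length(ref_dff)),
                reconstruction = numeric(length(ref_dff)),
                gamma = NA_real_))
  }
  if (is.null(gamma)) {
    gamma <- estimate_ar1_coef(ref_dff)
    if (is.na(gamma)) gamma <- exp(-1 / (sample_rate * 0.4))
    gamma <- gamma * fudge
  }
  gamma <- min(max(gamma, 1e-6), 1 - 1e-6)
  fit <- oasis_ar1(ref_dff, gamma)
  list(events = fit$s, reconstruction = fit$c, gamma = gamma)
}

# convolution of the deconvolved reference with exp(-t/tau); the profiled
# least-squares amplitude is closed-form given tau
bap_profile_loss <- function(mask_dff, deconv_ref, tau, dt, a_max) {
  conv <- exp_filter(deconv_ref, tau, dt)
  cc <- sum(conv * conv)
  if (cc == 0) {
    return(list(loss = sum(mask_dff^2), a = 0, conv = conv))
  }
  a <- min(a_max, max(0, sum(conv * mask_dff) / cc))
  list(loss = sum((a * conv - mask_dff)^2), a = a, conv = conv)
}

#' Fit and subtract the bAP component of one mask
#'
#' Fits `model(t) = a * (ref(t) convolved with exp(-t / tau))`, where
#' `ref(t)` is the deconvolved reference, by least squares over
#' `a in [0, a_max]`, `tau in tau_bounds`. The amplitude is profiled out in
#' closed form and the decay constant found by a global log-spaced grid
#' search refined with golden-section optimization, so the fit is
#' deterministic. The residual `mask - model` is the bAP-subtracted signal.
#'
#' @param mask_dff mask dF/F trace.
#' @param deconv_ref deconvolved reference event trace
#'   (`deconvolve_reference()$events`).
#' @param sample_rate samples per second.
#' @param tau_bounds decay-constant bounds (s).
#' @param a_max amplitude upper bound.
#' @param n_grid size of the initial log-spaced tau grid.
#' @return a `bap_fit` list: `a`, `tau`, `model`, `residual`, `loss`,
#'   `method`, `converged`.
#' @export
fit_bap_component <- function(mask_dff, deconv_ref, sample_rate = 14.5,
                              tau_bounds = c(0.05, 2), a_max = 100,
                              n_grid = 25) {
  if (length(mask_dff) != length(deconv_ref)) stop("trace length mismatch")
  dt <- 1 / sample_rate
  if (all(deconv_ref == 0)) {
    fit <- list(a = 0, tau = mean(tau_bounds),
                model = numeric(length(mask_dff)), residual = mask_dff,
                loss = sum(mask_dff^2), method = "deconv_soma",
                converged = TRUE)
    class(fit) <- "bap_fit"
    return(fit)
  }
  taus <- exp(seq(log(tau_bounds[1]), log(tau_bounds[2]),
                  length.out = n_grid))
  losses <- vapply(taus, function(tt) {
    bap_profile_loss(mask_dff, deconv_ref, tt, dt, a_max)$loss
  }, numeric(1))
  k <- which.min(losses)
  lo <- taus[max(1, k - 1)]
  hi <- taus[min(n_grid, k + 1)]
  op <- stats::optimize(function(tt) {
    bap_profile_loss(mask_dff, deconv_ref, tt, dt, a_max)$loss
  }, interval = c(lo, hi), tol = 1e-5)
  tau <- if (op$objective < losses[k]) op$minimum else taus[k]
  pl <- bap_profile_loss(mask_dff, deconv_ref, tau, dt, a_max)
  model <- pl$a * pl$conv
  fit <- list(a = pl$a, tau = tau, model = model,
              residual = mask_dff - model, loss = pl$loss,
              method = "deconv_soma", converged = is.finite(pl$loss))
  class(fit) <- "bap_fit"
  fit
}

#' @export
print.bap_fit <- function(x, ...) {
  cat(sprintf("bap_fit (%s): a = %.3g, tau = %.3g s, loss = %.4g\n",
              x$method, x$a, x$tau, x$loss))
  invisible(x)
}

# robust (bisquare IRLS) regression residuals of mask on a reference
robust_regression_residual <- function(mask_dff, ref_dff) {
  fit <- MASS::rlm(mask_dff ~ ref_dff, psi = MASS::psi.bisquare, maxit = 50)
  as.numeric(stats::residuals(fit))
}

# smoothed empirical CDF over a sample: Laplace smoothing keeps values
# strictly inside (0, 1), and exponential tails beyond the sample range keep
# -log penalties growing for ever more extreme residuals
smoothed_ecdf <- function(sample) {
  sample <- sort(sample)
  n <- length(sample)
  s <- max(stats::sd(sample), 1e-6)
  lo <- sample[1]
  hi <- sample[n]
  function(x) {
    k <- findInterval(x, sample)
    p <- (k + 1) / (n + 2)
    below <- x < lo
    p[below] <- (1 / (n + 2)) * exp((x[below] - lo) / s)
    above <- x > hi
    p[above] <- 1 - (1 / (n + 2)) * exp(-(x[above] - hi) / s)
    p
  }
}

# Alternative 1: deconvolution fit with a shot-noise-calibrated objective.
# The subtracted trace s = mask - model is scored by
#   y = -log(cdf_neg(s))      s < 0   (left tail of the raw-trace negatives)
#   y = -log(1 - cdf_pos(s))  s >= 0  (right tail of the Alt-2 residual
#                                      positives)
# so negative residuals beyond shot-noise expectation are penalized heavily.
nonneg_fit_subtract <- function(mask_dff, deconv_ref, sample_rate, seed,
                                tau_bounds = c(0.05, 2), a_max = 100) {
  dt <- 1 / sample_rate
  alt2 <- mask_dff # fallback when no variation
  ref_rec <- exp_filter(deconv_ref, 0.3, dt)
  if (stats::sd(ref_rec) > 0) {
    alt2 <- robust_regression_residual(mask_dff, ref_rec)
  }
  neg <- mask_dff[mask_dff < 0]
  pos <- alt2[alt2 >= 0]
  if (!length(neg)) neg <- -abs(stats::sd(mask_dff))
  if (!length(pos)) pos <- abs(stats::sd(mask_dff))
  cdf_neg <- smoothed_ecdf(neg)
  cdf_pos <- smoothed_ecdf(pos)
  objective <- function(par) {
    conv <- exp_filter(deconv_ref, par[2], dt)
    s <- mask_dff - par[1] * conv
    isneg <- s < 0
    sum(-log(cdf_neg(s[isneg]))) + sum(-log(1 - cdf_pos(s[!isneg])))
  }
  de <- de_optim(objective, lower = c(0, tau_bounds[1]),
                 upper = c(a_max, tau_bounds[2]), seed = seed,
                 n_pop = 15L, n_gen = 60L)
  conv <- exp_filter(deconv_ref, de$par[2], dt)
  list(residual = mask_dff - de$par[1] * conv, a = de$par[1],
       tau = de$par[2], loss = de$value)
}

#' Alternative bAP subtraction methods
#'
#' Five subtraction variants:
#' `"deconv_soma"` -- deconvolution of the soma/trunk reference plus
#' per-mask kernel fit ([fit_bap_component()]);
#' `"nonneg"` -- the same model fitted under an objective that penalizes
#' negative residuals beyond shot-noise expectation (Alternative 1);
#' `"regress_soma"` -- residuals of a robust regression of the mask on the
#' soma dF/F (Alternative 2);
#' `"regress_dendrite"` -- robust regression on the closest dendrite
#' segment (Alternative 3);
#' `"deconv_dendrite"` -- the deconvolution fit with the dendrite segment
#' as reference (Alternative 4).
#'
#' @param mask_dff mask dF/F trace.
#' @param ref_dff soma/trunk reference dF/F (needed by soma-referenced
#'   methods).
#' @param dendrite_dff dF/F of the closest 30 um dendrite segment (needed
#'   by dendrite-referenced methods).
#' @param method one of `"deconv_soma"`, `"nonneg"`, `"regress_soma"`,
#'   `"regress_dendrite"`, `"deconv_dendrite"`.
#' @param sample_rate samples per second.
#' @param seed RNG seed for the Alternative-1 global fit.
#' @param deconv optional precomputed [deconvolve_reference()] result for
#'   the soma reference (recomputed when `NULL`).
#' @param deconv_dend optional precomputed deconvolution of `dendrite_dff`.
#' @return list with `residual` (the subtracted trace), `method`, and the
#'   fit details where applicable.
#' @export
subtract_alternative <- function(mask_dff, ref_dff = NULL,
                                 dendrite_dff = NULL,
                                 method = c("deconv_soma", "nonneg",
                                            "regress_soma",
                                            "regress_dendrite",
                                            "deconv_dendrite"),
                                 sample_rate = 14.5, seed = 1L,
                                 deconv = NULL, deconv_dend = NULL) {
  method <- match.arg(method)
  need_ref <- method %in% c("deconv_soma", "nonneg", "regress_soma")
  if (need_ref && is.null(ref_dff) && is.null(deconv)) {
    stop("method ", method, " requires the soma/trunk reference")
  }
  if (method %in% c("regress_dendrite", "deconv_dendrite") &&
      is.null(dendrite_dff) && is.null(deconv_dend)) {
    stop("method ", method, " requires the closest dendrite segment trace")
  }
  if (method == "deconv_soma") {
    if (is.null(deconv)) deconv <- deconvolve_reference(ref_dff,
                                                        sample_rate = sample_rate)
    fit <- fit_bap_component(mask_dff, deconv$events, sample_rate)
    return(list(residual = fit$residual, method = method, fit = fit))
  }
  if (method == "deconv_dendrite") {
    if (is.null(deconv_dend)) {
      deconv_dend <- deconvolve_reference(dendrite_dff,
                                          sample_rate = sample_rate)
    }
    fit <- fit_bap_component(mask_dff, deconv_dend$events, sample_rate)
    fit$method <- method
    return(list(residual = fit$residual, method = method, fit = fit))
  }
  if (method == "nonneg") {
    if (is.null(deconv)) deconv <- deconvolve_reference(ref_dff,
                                                        sample_rate = sample_rate)
    fit <- nonneg_fit_subtract(mask_dff, deconv$events, sample_rate, seed)
    return(list(residual = fit$residual, method = method, fit = fit))
  }
  refx <- if (method == "regress_soma") ref_dff else dendrite_dff
  list(residual = robust_regression_residual(mask_dff, refx),
       method = method, fit = NULL)
}

#' Subtract the bAP component from every mask of a session
#'
#' Deconvolves the reference once and applies the chosen subtraction method
#' to each mask trace.
#'
#' @param dff `n_bins x n_masks` dF/F matrix.
#' @param ref_index column index of the global reference (soma/trunk).
#' @param method subtraction method, see [subtract_alternative()], or
#'   `"none"` to pass raw traces through unchanged.
#' @param dendrite_index optional column index of the dendrite reference for
#'   dendrite-referenced methods.
#' @param sample_rate samples per second.
#' @param seed RNG seed (Alternative 1 only).
#' @return list with `residual` (matrix, reference column left as is),
#'   `fits` (per-mask fit summaries: `a`, `tau`, `loss`) and `method`.
#' @export
subtract_session <- function(dff, ref_index = 1, method = "deconv_soma",
                             dendrite_index = NULL, sample_rate = 14.5,
                             seed = 1L) {
  if (method == "none") {
    return(list(residual = dff,
                fits = data.frame(mask = colnames(dff), a = NA_real_,
                                  tau = NA_real_, loss = NA_real_),
                method = "none"))
  }
  ref <- dff[, ref_index]
  deconv <- NULL
  deconv_dend <- NULL
  if (method %in% c("deconv_soma", "nonneg")) {
    deconv <- deconvolve_reference(ref, sample_rate = sample_rate)
  }
  if (method %in% c("regress_dendrite", "deconv_dendrite")) {
    if (is.null(dendrite_index)) stop("dendrite_index required for ", method)
    if (method == "deconv_dendrite") {
      deconv_dend <- deconvolve_reference(dff[, dendrite_index],
                                          sample_rate = sample_rate)
    }
  }
  out <- dff
  fits <- data.frame(mask = colnames(dff), a = NA_real_, tau = NA_real_,
                     loss = NA_real_)
  for (j in seq_len(ncol(dff))) {
    if (j == ref_index) next
    dend <- if (!is.null(dendrite_index)) dff[, dendrite_index] else NULL
    sub <- subtract_alternative(dff[, j], ref_dff = ref, dendrite_dff = dend,
                                method = method, sample_rate = sample_rate,
                                seed = derive_seed(seed, paste0("mask", j)),
                                deconv = deconv, deconv_dend = deconv_dend)
    out[, j] <- sub$residual
    if (!is.null(sub$fit)) {
      fits$a[j] <- sub$fit$a
      fits$tau[j] <- sub$fit$tau
      fits$loss[j] <- sub$fit$loss
    }
  }
  list(residual = out, fits = fits, method = method)
}
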