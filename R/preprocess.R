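#' Photon-noise slope from unit traces
#'
#' Because single-pixel (or single-mask) fluorescence is photon shot-noise
#' limited, variance is proportional to mean: `var = mean / m` in
#' fluorescence units, i.e. the photon count is `N = m * F`. The slope of a
#' least-squares fit of variance versus mean across units estimates the
#' inverse gain; `m` is returned as `mean / variance` slope so that
#' `N = m * F` counts photons.
#'
#' @param samples matrix of traces, one column per unit (pixel or mask).
#' @return `m`, the photons-per-fluorescence-unit factor (> 0).
#' @export
estimate_variance_mean_slope <- function(samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 2) stop("need at least 2 units")
  mu <- colMeans(samples)
  v <- apply(samples, 2, stats::var)
  if (max(mu) - min(mu) < .Machine$double.eps * 100 || all(v == 0)) {
    stop("degenerate input: unit means equal or variances all zero")
  }
  # least-squares slope of variance vs mean through the point cloud
  g <- stats::coef(stats::lm(v ~ mu))[2]
  if (!is.finite(g) || g <= 0) stop("variance-mean fit gave non-positive slope")
  unname(1 / g)
}

# mode of a Gaussian kernel density estimate (Silverman bandwidth);
# degenerate windows (no spread) return their single value
kde_mode <- function(x) {
  if (diff(range(x)) == 0) return(x[1])
  d <- stats::density(x, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

#' Sliding-window baseline estimate
#'
#' The baseline `f0(t)` is the mode of a Gaussian kernel density estimate of
#' the fluorescence distribution in a sliding window (default 2000 samples,
#' about 2 minutes at ~14.5 Hz). The window is evaluated every `stride`
#' samples and linearly interpolated in between. Traces shorter than the
#' window use one global estimate.
#'
#' @param F raw fluorescence trace.
#' @param window window length in samples.
#' @param stride evaluation stride in samples.
#' @return baseline vector `f0(t)` of the same length as `F`.
#' @export
estimate_baseline <- function(F, window = 2000, stride = 500) {
  if (any(!is.finite(F))) stop("non-finite values in fluorescence trace")
  n <- length(F)
  if (n < 1) stop("empty trace")
  if (n <= window) return(rep(kde_mode(F), n))
  centers <- unique(c(seq(window / 2, n - window / 2, by = stride),
                      n - window / 2))
  vals <- vapply(centers, function(cc) {
    i0 <- max(1, round(cc - window / 2))
    i1 <- min(n, round(cc + window / 2))
    kde_mode(F[i0:i1])
  }, numeric(1))
  stats::approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Fractional fluorescence change
#'
#' `dF/F = (F - f0) / f0`.
#'
#' @param F raw fluorescence trace.
#' @param f0 baseline (scalar or vector), must be positive.
#' @return dF/F trace.
#' @export
compute_dff <- function(F, f0) {
  if (any(f0 <= 0)) stop("baseline must be positive")
  (F - f0) / f0
}

#' Per-sample shot-noise SD in dF/F units
#'
#' With `N(t) = m * F(t)` photons, the photon-noise SD of `F` is
#' `sqrt(N)/m` fluorescence units; divided by the baseline this gives
#' `sigma(t) = sqrt(N) / (m * f0)` in dF/F units (equal to `1/sqrt(N)` when
#' `F = f0`). Photon counts are floored at 1.
#'
#' @param F raw fluorescence trace.
#' @param m photons per fluorescence unit (see
#'   [estimate_variance_mean_slope()]).
#' @param f0 baseline (scalar or vector).
#' @return vector of per-sample noise SDs (dF/F units).
#' @export
shot_noise_sigma <- function(F, m, f0) {
  if (m <= 0) stop("m must be > 0")
  if (any(f0 <= 0)) stop("baseline must be positive")
  N <- pmax(m * F, 1)
  sqrt(N) / (m * f0)
}

#' Serialize or load a noise model
#'
#' @param model list with elements `m` and optionally per-mask baselines.
#' @param path JSON path.
#' @return `read_noise_model` returns the model list; `write_noise_model`
#'   returns `path` invisibly.
#' @export
write_noise_model <- function(model, path) {
  jsonlite::write_json(model, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_noise_model
#' @export
read_noise_model <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Wrap simulated dF/F traces as raw fluorescence
#'
#' Converts simulator output to photon-count-proportional raw traces
#' `F = f0 * (1 + dff)` with a per-mask baseline, so the preprocessing
#' stage (baseline, dF/F, noise) can be exercised on synthetic sessions.
#'
#' @param traces simulator `traces` element (`simulate_session()$traces`).
#' @param f0 baseline fluorescence per mask (scalar or vector, arbitrary
#'   digital units).
#' @return list like `traces` with an added `F` matrix and `f0` vector.
#' @export
as_raw_fluorescence <- function(traces, f0 = 100) {
  f0 <- rep_len(f0, ncol(traces$dff))
  traces$F <- sweep(1 + traces$dff, 2, f0, `*`)
  traces$f0 <- f0
  traces
}

#' Run preprocessing over a session's raw traces
#'
#' Estimates the baseline per mask, computes dF/F and, when a photon-noise
#' slope `m` is supplied, per-sample shot-noise SDs.
#'
#' @param F `n_bins x n_masks` raw fluorescence matrix.
#' @param m optional photons-per-unit slope; when `NULL`, estimated from the
#'   mask traces themselves via [estimate_variance_mean_slope()].
#' @param window,stride baseline window parameters (samples).
#' @return list with `f0`, `dff`, `sigma` matrices and `m`.
#' @export
preprocess_session <- function(F, m = NULL, window = 2000, stride = 500) {
  F <- as.matrix(F)
  if (is.null(m)) m <- estimate_variance_mean_slope(F)
  f0 <- apply(F, 2, estimate_baseline, window = window, stride = stride)
  dff <- (F - f0) / f0
  sigma <- sqrt(pmax(m * F, 1)) / (m * f0)
  list(f0 = f0, dff = dff, sigma = sigma, m = m)
}
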