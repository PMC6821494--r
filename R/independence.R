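#' Probability a signal exceeds a threshold under shot noise
#'
#' `P(t) = 0.5 * (1 + erf((x(t) - u) / (sigma * sqrt(2))))`, i.e. the
#' Gaussian probability that the true signal underlying the noisy sample
#' `x(t)` lies above the threshold `u` given per-sample noise SD `sigma`.
#'
#' @param x dF/F samples.
#' @param u threshold (dF/F).
#' @param sigma noise SD (scalar or per-sample vector), > 0.
#' @return vector of probabilities in `[0, 1]`.
#' @export
prob_above_threshold <- function(x, u, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  stats::pnorm((x - u) / sigma)
}

#' False-positive probability of a threshold crossing
#'
#' Probability that pure noise (true signal at zero) is read as above the
#' threshold. The default `"noise_tail"` reading returns
#' `0.5 * (1 + erf((0 - u) / (sigma sqrt 2)))`, the upper-tail mass of the
#' noise distribution beyond `u`, which vanishes at high thresholds. The
#' `"literal"` variant fixes the sample at the threshold and sets `u = 0`,
#' `0.5 * (1 + erf(u / (sigma sqrt 2)))`; it is retained for comparison but
#' exceeds 0.5 for any positive threshold.
#'
#' @param u threshold (dF/F).
#' @param sigma noise SD, > 0.
#' @param variant `"noise_tail"` (default) or `"literal"`.
#' @return probability.
#' @export
false_positive_probability <- function(u, sigma,
                                       variant = c("noise_tail", "literal")) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  variant <- match.arg(variant)
  if (variant == "noise_tail") stats::pnorm(-u / sigma)
  else stats::pnorm(u / sigma)
}

#' Independent and co-active probabilities
#'
#' `P_independent(t) = P_mask(t) * (1 - P_ref(t))` and
#' `P_coactive(t) = P_mask(t) * P_ref(t)`; they decompose `P_mask` exactly.
#'
#' @param p_mask per-sample probability the mask signal is above threshold.
#' @param p_ref per-sample probability the reference is above threshold.
#' @return list with `independent` and `coactive` vectors.
#' @export
independence_probabilities <- function(p_mask, p_ref) {
  if (length(p_mask) != length(p_ref)) stop("length mismatch")
  list(independent = p_mask * (1 - p_ref), coactive = p_mask * p_ref)
}

#' Proportion of mask activity independent of the reference
#'
#' Ratio of time-averaged probabilities:
#' `mean(P_independent) / (mean(P_independent) + mean(P_coactive))`.
#'
#' @param p_independent,p_coactive per-sample probabilities.
#' @return scalar in `[0, 1]`, `NA` (with a warning) when the mask is never
#'   active.
#' @export
proportion_independent <- function(p_independent, p_coactive) {
  if (!length(p_independent)) stop("empty traces")
  den <- mean(p_independent) + mean(p_coactive)
  if (den == 0) {
    warning("mask never active: proportion independent undefined")
    return(NA_real_)
  }
  mean(p_independent) / den
}

#' Shot-noise false-positive analogue of the proportion independent
#'
#' `(mean(P_FPR_independent) - mean(P_FPR_coactive)) /
#'  (mean(P_coactive) + mean(P_FPR_independent))`.
#'
#' @param p_coactive per-sample co-active probabilities of the data.
#' @param p_fpr_independent,p_fpr_coactive per-sample false-positive
#'   analogues computed with [false_positive_probability()] in place of the
#'   data probabilities.
#' @return scalar; `NA` with a warning on a zero denominator.
#' @export
proportion_independent_fpr <- function(p_coactive, p_fpr_independent,
                                       p_fpr_coactive) {
  den <- mean(p_coactive) + mean(p_fpr_independent)
  if (den == 0) {
    warning("zero denominator: FPR proportion undefined")
    return(NA_real_)
  }
  (mean(p_fpr_independent) - mean(p_fpr_coactive)) / den
}

#' Temporal exclusion window on the reference probability
#'
#' Replaces every value of `P_ref` by the maximum over a preceding
#' (`direction = "after_ref"`: excludes activity *after* reference events)
#' or following (`direction = "before_ref"`) time window, so that mask
#' activity shortly after/before a reference event is not counted as
#' independent.
#'
#' @param p_ref per-sample reference probabilities.
#' @param window_s window duration (s), >= 0.
#' @param direction `"after_ref"` (window looks back) or `"before_ref"`
#'   (window looks forward).
#' @param sample_rate samples per second.
#' @return adjusted `P_ref'` with `P_ref' >= P_ref` elementwise.
#' @export
apply_exclusion_window <- function(p_ref, window_s,
                                   direction = c("after_ref", "before_ref"),
                                   sample_rate = 14.5) {
  if (window_s < 0) stop("window must be >= 0")
  direction <- match.arg(direction)
  w <- round(window_s * sample_rate)
  running_max(p_ref, w,
              direction = if (direction == "after_ref") "before" else "after")
}

#' Independence estimate for one mask at one threshold pair
#'
#' @param mask_dff,ref_dff dF/F traces (raw, without bAP subtraction).
#' @param mask_sigma,ref_sigma per-sample shot-noise SDs.
#' @param u_mask,u_ref thresholds (dF/F).
#' @param exclusion_s optional exclusion window duration (s).
#' @param exclusion_direction `"after_ref"` or `"before_ref"`.
#' @param sample_rate samples per second.
#' @param fpr_variant see [false_positive_probability()].
#' @return list with per-sample probability traces, `proportion_independent`
#'   and `proportion_independent_fpr`.
#' @export
independence_estimate <- function(mask_dff, ref_dff, mask_sigma, ref_sigma,
                                  u_mask, u_ref, exclusion_s = 0,
                                  exclusion_direction = "after_ref",
                                  sample_rate = 14.5,
                                  fpr_variant = "noise_tail") {
  p_mask <- prob_above_threshold(mask_dff, u_mask, mask_sigma)
  p_ref <- prob_above_threshold(ref_dff, u_ref, ref_sigma)
  if (exclusion_s > 0) {
    p_ref <- apply_exclusion_window(p_ref, exclusion_s, exclusion_direction,
                                    sample_rate)
  }
  pp <- independence_probabilities(p_mask, p_ref)
  pf_mask <- false_positive_probability(u_mask, mask_sigma, fpr_variant)
  pf_ref <- false_positive_probability(u_ref, ref_sigma, fpr_variant)
  pf_mask <- rep_len(pf_mask, length(p_mask))
  pf_ref <- rep_len(pf_ref, length(p_ref))
  ppf <- independence_probabilities(pf_mask, pf_ref)
  list(p_mask = p_mask, p_ref = p_ref,
       p_independent = pp$independent, p_coactive = pp$coactive,
       p_fpr_independent = ppf$independent, p_fpr_coactive = ppf$coactive,
       proportion_independent = proportion_independent(pp$independent,
                                                       pp$coactive),
       proportion_independent_fpr = proportion_independent_fpr(
         pp$coactive, ppf$independent, ppf$coactive),
       u_mask = u_mask, u_ref = u_ref)
}

#' Proportion independent over a grid of thresholds
#'
#' Evaluates [independence_estimate()] over all combinations of mask and
#' reference thresholds. Default grids are geometrically spaced over
#' `[0.05, 4]` dF/F (mask) and `[0.05, 1]` dF/F (reference); the reference
#' default includes the 0.15 dF/F operating point (roughly 1-2 somatic
#' spikes).
#'
#' @inheritParams independence_estimate
#' @param u_mask_grid,u_ref_grid threshold grids (dF/F).
#' @return data.frame with `u_mask`, `u_ref`, `proportion_independent`,
#'   `proportion_independent_fpr`.
#' @export
threshold_grid <- function(mask_dff, ref_dff, mask_sigma, ref_sigma,
                           u_mask_grid = exp(seq(log(0.05), log(4),
                                                 length.out = 12)),
                           u_ref_grid = c(0.05, 0.1, 0.15, 0.3, 0.6, 1),
                           exclusion_s = 0,
                           exclusion_direction = "after_ref",
                           sample_rate = 14.5,
                           fpr_variant = "noise_tail") {
  if (!length(u_mask_grid) || !length(u_ref_grid)) stop("empty grid")
  grid <- expand.grid(u_mask = u_mask_grid, u_ref = u_ref_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    est <- independence_estimate(mask_dff, ref_dff, mask_sigma, ref_sigma,
                                 grid$u_mask[i], grid$u_ref[i], exclusion_s,
                                 exclusion_direction, sample_rate,
                                 fpr_variant)
    data.frame(u_mask = grid$u_mask[i], u_ref = grid$u_ref[i],
               proportion_independent = est$proportion_independent,
               proportion_independent_fpr = est$proportion_independent_fpr)
  })
  do.call(rbind, res)
}
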