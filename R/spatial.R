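#' Printed exponential distance-bin edges (um)
#' @export
distance_bin_edges <- function() c(0, 2.7, 4.5, 7.4, 12, 20, 33, 55, 90, 148, 245)

# per-trial, per-epoch response array for all masks at once:
# list(resp = array[trial, epoch, mask], type, trials)
response_array <- function(dff, times, trials, seed = 1L) {
  keep <- trials$correct & !trials$early_lick &
    trials$sample_on >= times[1] & trials$r2_off <= times[length(times)]
  trials <- trials[keep, , drop = FALSE]
  if (!nrow(trials)) stop("no valid trials overlap the traces")
  rng <- local_rng(seed)
  n_tr <- nrow(trials)
  n_m <- ncol(dff)
  resp <- array(NA_real_, c(n_tr, 5, n_m))
  for (ti in seq_len(n_tr)) {
    b <- trial_epoch_bounds(trials[ti, ])
    idx <- lapply(seq_len(5), function(e) which(times >= b$on[e] & times < b$off[e]))
    n_eq <- min(lengths(idx)[-1])
    if (n_eq < 1) stop("trial ", trials$trial[ti], " has an empty epoch")
    for (e in seq_len(5)) {
      ii <- idx[[e]]
      if (length(ii) > n_eq) ii <- ii[sort(sample.int(length(ii), n_eq))]
      resp[ti, e, ] <- colMeans(dff[ii, , drop = FALSE])
    }
  }
  list(resp = resp, type = trials$type, trials = trials$trial)
}

# 10-condition (5 epochs x 2 types) mean matrix from a trial subset
condition_means <- function(ra, trial_rows) {
  out <- matrix(NA_real_, 10, dim(ra$resp)[3])
  k <- 0
  for (ty in c("left", "right")) for (e in seq_len(5)) {
    k <- k + 1
    rows <- trial_rows[ra$type[trial_rows] == ty]
    if (length(rows)) {
      out[k, ] <- colMeans(ra$resp[rows, e, , drop = FALSE], dims = 1)
    }
  }
  out
}

#' Split-trial signal correlation matrix
#'
#' Pearson correlation between the two masks' 10-condition mean response
#' vectors, each computed from a non-overlapping random half of the trials,
#' repeated `n_splits` times and averaged. Using disjoint trial halves
#' removes noise-correlation contamination from the signal-correlation
#' estimate.
#'
#' @param dff `n_bins x n_masks` dF/F matrix (typically bAP-subtracted).
#' @param times sample times (s).
#' @param trials trial table.
#' @param n_splits number of random half splits.
#' @param seed RNG seed.
#' @return `n_masks x n_masks` matrix of signal correlations.
#' @export
signal_correlation_matrix <- function(dff, times, trials, n_splits = 100,
                                      seed = 1L) {
  ra <- response_array(dff, times, trials, seed = derive_seed(seed, "resp"))
  n_tr <- length(ra$trials)
  by_type <- split(seq_len(n_tr), ra$type)
  if (any(lengths(by_type) < 4) || length(by_type) < 2) {
    stop("each condition needs at least 2 trials per half")
  }
  set.seed(as.integer(derive_seed(seed, "splits") %% 2147483647L))
  n_m <- dim(ra$resp)[3]
  acc <- matrix(0, n_m, n_m)
  for (s in seq_len(n_splits)) {
    h1 <- unlist(lapply(by_type, function(ix) {
      sample(ix, floor(length(ix) / 2))
    }), use.names = FALSE)
    h2 <- setdiff(seq_len(n_tr), h1)
    m1 <- condition_means(ra, h1)
    m2 <- condition_means(ra, h2)
    if (anyNA(m1) || anyNA(m2)) stop("a condition has no trials in a half")
    r <- suppressWarnings(stats::cor(m1, m2))
    r[!is.finite(r)] <- 0
    acc <- acc + (r + t(r)) / 2
  }
  acc / n_splits
}

#' Noise correlation matrix
#'
#' Mean over the 10 conditions of the Pearson correlation between masks'
#' responses across trials within one condition. Conditions with fewer than
#' `min_trials` trials are excluded with a warning; an error is raised when
#' all conditions are excluded.
#'
#' @inheritParams signal_correlation_matrix
#' @param min_trials minimum trials per condition.
#' @return `n_masks x n_masks` matrix of noise correlations.
#' @export
noise_correlation_matrix <- function(dff, times, trials, min_trials = 3,
                                     seed = 1L) {
  ra <- response_array(dff, times, trials, seed = derive_seed(seed, "resp"))
  n_m <- dim(ra$resp)[3]
  acc <- matrix(0, n_m, n_m)
  used <- 0
  for (ty in c("left", "right")) for (e in seq_len(5)) {
    rows <- which(ra$type == ty)
    if (length(rows) < min_trials) {
      warning("condition ", ty, "/", epoch_names()[e],
              " excluded: fewer than ", min_trials, " trials")
      next
    }
    r <- suppressWarnings(stats::cor(ra$resp[rows, e, ]))
    r[!is.finite(r)] <- 0
    acc <- acc + r
    used <- used + 1
  }
  if (used == 0) stop("all conditions excluded")
  acc / used
}

#' Pairwise signal correlation of two traces
#'
#' @param trace_a,trace_b dF/F traces.
#' @inheritParams signal_correlation_matrix
#' @return scalar correlation.
#' @export
signal_correlation <- function(trace_a, trace_b, times, trials,
                               n_splits = 100, seed = 1L) {
  signal_correlation_matrix(cbind(trace_a, trace_b), times, trials,
                            n_splits, seed)[1, 2]
}

#' Pairwise noise correlation of two traces
#'
#' @param trace_a,trace_b dF/F traces.
#' @inheritParams noise_correlation_matrix
#' @return scalar correlation.
#' @export
noise_correlation <- function(trace_a, trace_b, times, trials,
                              min_trials = 3, seed = 1L) {
  noise_correlation_matrix(cbind(trace_a, trace_b), times, trials,
                           min_trials, seed)[1, 2]
}

#' Assign pairs to exponential distance bins
#'
#' Left-closed, right-open bins at the printed edges; pairs at or beyond
#' the final edge (245 um) are excluded.
#'
#' @param pairs data.frame with a `traversal` distance column (um).
#' @param edges bin edges (um).
#' @return `pairs` with a `bin` column, excluded rows dropped; bin edges in
#'   `attr(, "edges")`.
#' @export
bin_by_distance <- function(pairs, edges = distance_bin_edges()) {
  if (any(pairs$traversal < 0)) stop("negative distances")
  bin <- findInterval(pairs$traversal, edges, left.open = FALSE)
  keep <- pairs$traversal < edges[length(edges)]
  out <- pairs[keep, , drop = FALSE]
  out$bin <- bin[keep]
  attr(out, "edges") <- edges
  out
}

# one random maximal set of pairs in which every mask appears at most once
draw_disjoint_pairs <- function(mask_a, mask_b) {
  ord <- sample.int(length(mask_a))
  used <- character(0)
  take <- logical(length(mask_a))
  for (i in ord) {
    if (!(mask_a[i] %in% used) && !(mask_b[i] %in% used)) {
      take[i] <- TRUE
      used <- c(used, mask_a[i], mask_b[i])
    }
  }
  which(take)
}

#' Per-bin SEM by resampling non-overlapping pair members
#'
#' For each bin, repeatedly draws a maximal random subset of pairs in which
#' every mask appears at most once, computes `sd(r)/sqrt(n)` over the draw,
#' and reports the mean over draws. This avoids understating the SEM when
#' pairs share members.
#'
#' @param pairs binned pairs ([bin_by_distance()]) with columns `mask_a`,
#'   `mask_b`, `r`, `bin`.
#' @param n_draws number of draws.
#' @param seed RNG seed.
#' @return data.frame with `bin`, `n_pairs`, `mean_r`, `sem`, and the mean
#'   member count per draw `n_drawn`.
#' @export
binned_sem <- function(pairs, n_draws = 100, seed = 1L) {
  set.seed(as.integer(seed %% 2147483647L))
  bins <- sort(unique(pairs$bin))
  out <- lapply(bins, function(b) {
    sub <- pairs[pairs$bin == b, ]
    sems <- numeric(n_draws)
    ns <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      idx <- draw_disjoint_pairs(sub$mask_a, sub$mask_b)
      ns[d] <- length(idx)
      sems[d] <- if (length(idx) >= 2) {
        stats::sd(sub$r[idx]) / sqrt(length(idx))
      } else NA_real_
    }
    data.frame(bin = b, n_pairs = nrow(sub), mean_r = mean(sub$r),
               sem = mean(sems, na.rm = TRUE), n_drawn = mean(ns))
  })
  do.call(rbind, out)
}

#' Fit the exponential-linear distance model
#'
#' `y = A * exp(-x / lambda) + x * L + B`, fitted by seeded differential
#' evolution (L2 loss) with a local polish. Bounds: `A in [0, 1]`,
#' `lambda in [0.5, 200]` um, `L in [-0.02, 0.02]` per um, `B in [-1, 1]`.
#' When the fitted amplitude is indistinguishable from zero the length
#' constant is flagged unidentifiable.
#'
#' @param x bin centers (um).
#' @param y bin mean correlations.
#' @param seed RNG seed.
#' @param weights optional per-bin weights (e.g. `1/sem^2`).
#' @return list with `A`, `lambda`, `L`, `B`, `loss`, `identifiable`.
#' @export
fit_exp_linear <- function(x, y, seed = 1L, weights = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 bins to fit 4 parameters")
  w <- if (is.null(weights)) rep(1, length(x)) else weights[ok]
  fn <- function(par) {
    sum(w * (y - (par[1] * exp(-x / par[2]) + x * par[3] + par[4]))^2)
  }
  de <- de_optim(fn, lower = c(0, 0.5, -0.02, -1),
                 upper = c(1, 200, 0.02, 1), seed = seed,
                 n_pop = 40L, n_gen = 250L)
  A <- de$par[1]
  identifiable <- A > 1e-3 && de$par[2] < 199
  list(A = A, lambda = if (identifiable) de$par[2] else NA_real_,
       lambda_raw = de$par[2], L = de$par[3], B = de$par[4],
       loss = de$value, identifiable = identifiable)
}

# bin centers = mean member distance per bin, plus bin means
binned_curve <- function(pairs) {
  bins <- sort(unique(pairs$bin))
  data.frame(
    bin = bins,
    center = vapply(bins, function(b) mean(pairs$traversal[pairs$bin == b]),
                    numeric(1)),
    mean_r = vapply(bins, function(b) mean(pairs$r[pairs$bin == b]),
                    numeric(1)),
    n = vapply(bins, function(b) sum(pairs$bin == b), numeric(1)))
}

#' Fit the distance model to pooled pairs
#'
#' Bins the pairs, computes bin centers (mean member distance) and means,
#' and fits [fit_exp_linear()].
#'
#' @param pairs pair table with `traversal` and `r` columns.
#' @param edges distance bin edges.
#' @param seed RNG seed.
#' @return list with `fit`, `curve` (binned means) and `pairs` (binned).
#' @export
fit_distance_model <- function(pairs, edges = distance_bin_edges(),
                               seed = 1L) {
  bp <- bin_by_distance(pairs, edges)
  curve <- binned_curve(bp)
  fit <- fit_exp_linear(curve$center, curve$mean_r, seed = seed)
  list(fit = fit, curve = curve, pairs = bp)
}

#' Bootstrap error of the length constant across sessions
#'
#' Resamples sessions with replacement, pools their pairs, re-bins and
#' refits the exponential-linear model; returns the SD of the fitted length
#' constants.
#'
#' @param session_pairs list of per-session pair tables.
#' @param n_boot bootstrap iterations.
#' @param seed RNG seed.
#' @param edges distance bin edges.
#' @return list with `lambda_se` and the bootstrap `lambdas`. With a single
#'   session the result is flagged (`lambda_se = NA`).
#' @export
bootstrap_lambda_se <- function(session_pairs, n_boot = 300, seed = 1L,
                                edges = distance_bin_edges()) {
  if (length(session_pairs) < 2) {
    warning("single session: no resampling unit, lambda_se undefined")
    return(list(lambda_se = NA_real_, lambdas = numeric(0)))
  }
  set.seed(as.integer(seed %% 2147483647L))
  picks <- matrix(sample.int(length(session_pairs),
                             length(session_pairs) * n_boot, replace = TRUE),
                  nrow = n_boot)
  lambdas <- vapply(seq_len(n_boot), function(b) {
    pooled <- do.call(rbind, session_pairs[picks[b, ]])
    fit <- tryCatch(
      fit_distance_model(pooled, edges, seed = derive_seed(seed, paste0("b", b)))$fit,
      error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$lambda_raw
  }, numeric(1))
  list(lambda_se = stats::sd(lambdas, na.rm = TRUE), lambdas = lambdas)
}

#' Shuffle test for a distance effect on pairwise correlations
#'
#' Statistic: variance of the bin mean correlations. Null: distances are
#' shuffled among pairs (bins reassigned), `n_shuffles` times; p is the
#' proportion of shuffled statistics at least as large as observed.
#'
#' @param pairs binned pair table (`bin`, `r`).
#' @param n_shuffles shuffles.
#' @param seed RNG seed.
#' @return list with `statistic` and `p`.
#' @export
distance_effect_test <- function(pairs, n_shuffles = 1000, seed = 1L) {
  if (length(unique(pairs$bin)) < 2) stop("need at least two populated bins")
  stat <- function(bins, r) stats::var(tapply(r, bins, mean))
  obs <- stat(pairs$bin, pairs$r)
  set.seed(as.integer(seed %% 2147483647L))
  null <- vapply(seq_len(n_shuffles), function(i) {
    stat(sample(pairs$bin), pairs$r)
  }, numeric(1))
  list(statistic = obs, p = mean(null >= obs))
}

#' Within- versus across-branch comparison of pairwise correlations
#'
#' Compares mean pairwise correlation within a branch against across
#' branches, either over all distances (`mode = "all_distances"`, within =
#' branch relation `"within"`, across = everything else) or restricted to
#' short pairs (`mode = "short"`, traversal distance < 10 um, relations
#' `"within"` vs `"across_one"` branch point). The permutation p-value
#' draws, at each iteration, a maximal pair subset in which every mask is
#' used at most once, computes the group difference with true and with
#' shuffled labels, and reports the proportion of iterations where the
#' shuffled difference is at least as large (one-sided: within > across).
#'
#' @param pairs pair table with `mask_a`, `mask_b`, `traversal`,
#'   `branch_relation`, `r`.
#' @param mode `"all_distances"` or `"short"`.
#' @param n_perm permutation iterations.
#' @param seed RNG seed.
#' @param short_max_um distance cutoff for `mode = "short"`.
#' @return list with `mean_within`, `mean_across`, `n_within`, `n_across`,
#'   `p`.
#' @export
branch_comparison <- function(pairs, mode = c("all_distances", "short"),
                              n_perm = 1000, seed = 1L, short_max_um = 10) {
  mode <- match.arg(mode)
  if (mode == "short") {
    pairs <- pairs[pairs$traversal < short_max_um &
                     pairs$branch_relation %in% c("within", "across_one"), ]
  }
  within <- pairs$branch_relation == "within"
  if (!sum(within) || !sum(!within)) {
    stop("both within and across groups must be non-empty")
  }
  set.seed(as.integer(seed %% 2147483647L))
  hits <- 0
  used <- 0
  for (i in seq_len(n_perm)) {
    idx <- draw_disjoint_pairs(pairs$mask_a, pairs$mask_b)
    g <- within[idx]
    if (!sum(g) || !sum(!g)) next
    d_true <- mean(pairs$r[idx][g]) - mean(pairs$r[idx][!g])
    gs <- sample(g)
    d_shuf <- mean(pairs$r[idx][gs]) - mean(pairs$r[idx][!gs])
    hits <- hits + (d_shuf >= d_true)
    used <- used + 1
  }
  list(mean_within = mean(pairs$r[within]),
       mean_across = mean(pairs$r[!within]),
       n_within = sum(within), n_across = sum(!within),
       p = if (used) hits / used else NA_real_)
}

#' Motion-artifact control: Euclid-close but traversal-far pairs
#'
#' Pairs that are close in space (Euclidean distance below `euclid_max`) but
#' far along the tree (traversal above `trav_min`) would show elevated
#' correlations under shared motion artifacts. Their mean correlation is
#' compared with the mean of all pairs in the same traversal-distance bins.
#'
#' @param pairs pair table with `traversal`, `euclidean`, `r`.
#' @param euclid_max,trav_min selection cutoffs (um).
#' @param edges distance bin edges.
#' @return list with `n`, `subset_mean`, `matched_mean`, `difference`, and
#'   `flagged` (TRUE when no pair qualifies).
#' @export
motion_control <- function(pairs, euclid_max = 15, trav_min = 30,
                           edges = distance_bin_edges()) {
  bp <- bin_by_distance(pairs, edges)
  sel <- bp$euclidean < euclid_max & bp$traversal > trav_min
  if (!sum(sel)) {
    return(list(n = 0, subset_mean = NA_real_, matched_mean = NA_real_,
                difference = NA_real_, flagged = TRUE))
  }
  bin_means <- tapply(bp$r, bp$bin, mean)
  matched <- mean(bin_means[as.character(bp$bin[sel])])
  list(n = sum(sel), subset_mean = mean(bp$r[sel]), matched_mean = matched,
       difference = mean(bp$r[sel]) - matched, flagged = FALSE)
}

#' Pairwise statistics of one session
#'
#' Combines the geometric pair table (distances, branch relation) with
#' signal and noise correlations computed from the (typically
#' bAP-subtracted) traces.
#'
#' @param dff `n_bins x n_masks` dF/F matrix, columns named by mask id.
#' @param times sample times (s).
#' @param trials trial table.
#' @param pair_table output of [mask_pair_distances()].
#' @param n_splits split repetitions for the signal correlation.
#' @param seed RNG seed.
#' @return pair table with added `r_signal`, `r_noise`, `pair_class`.
#' @export
session_pair_stats <- function(dff, times, trials, pair_table,
                               n_splits = 100, seed = 1L) {
  ids <- colnames(dff)
  keep <- pair_table$mask_a %in% ids & pair_table$mask_b %in% ids
  pt <- pair_table[keep, , drop = FALSE]
  rs <- signal_correlation_matrix(dff, times, trials, n_splits, seed)
  rn <- noise_correlation_matrix(dff, times, trials, seed = seed)
  ia <- match(pt$mask_a, ids)
  ib <- match(pt$mask_b, ids)
  pt$r_signal <- rs[cbind(ia, ib)]
  pt$r_noise <- rn[cbind(ia, ib)]
  cls <- function(ka, kb) {
    k <- sort(c(ka, kb))
    if (all(k == "spine")) "spine-spine"
    else if (all(k == "dendrite_segment")) "dendrite-dendrite"
    else if (setequal(k, c("dendrite_segment", "spine"))) "spine-dendrite"
    else paste(k, collapse = "-")
  }
  pt$pair_class <- mapply(cls, pt$kind_a, pt$kind_b)
  pt
}
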