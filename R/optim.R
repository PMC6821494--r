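# Minimal differential evolution (rand/1/bin) for low-dimensional bounded
# global fits. Deterministic given `seed`. Returns the best parameter vector
# and objective value after `n_gen` generations, with a local polish via
# L-BFGS-B from the best point.
de_optim <- function(fn, lower, upper, seed = 1L, n_pop = 15L, n_gen = 150L,
                     cr = 0.9, f = 0.8, polish = TRUE) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  set.seed(as.integer(seed %% 2147483647L))
  pop <- matrix(stats::runif(n_pop * d, lower, upper), n_pop, d, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  for (g in seq_len(n_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3L)
      trial <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      mask <- stats::runif(d) < cr
      mask[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(mask, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ct <- fn(trial)
      if (is.finite(ct) && ct <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- ct
      }
    }
  }
  best <- which.min(cost)
  par <- pop[best, ]
  val <- cost[best]
  if (polish) {
    op <- tryCatch(
      stats::optim(par, fn, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value) && op$value < val) {
      par <- op$par
      val <- op$value
    }
  }
  list(par = par, value = val)
}
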