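# small seeded-RNG wrapper so every generator call site is explicit about
# which distribution it draws from; sets the global RNG once
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647L))
  list(
    norm = function(n, mean = 0, sd = 1) stats::rnorm(n, mean, sd),
    unif = function(n, min = 0, max = 1) stats::runif(n, min, max),
    pois = function(lambda) stats::rpois(1L, lambda),
    int  = function(n) sample.int(n, 1L)
  )
}

# derive a reproducible child seed from a base seed and a stage label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1103515245 + h) %% 2147483647)
}

# running maximum over a trailing (`direction = "before"`) or leading
# (`direction = "after"`) window of w samples, excluding the sample itself
# from the shifted contributions only when w = 0
running_max <- function(x, w, direction = c("before", "after")) {
  direction <- match.arg(direction)
  if (w < 0) stop("window must be >= 0")
  if (w == 0) return(x)
  n <- length(x)
  out <- x
  for (k in seq_len(w)) {
    if (direction == "before") {
      shifted <- c(rep(-Inf, k), x[seq_len(n - k)])
    } else {
      shifted <- c(x[(k + 1):n], rep(-Inf, k))
    }
    out <- pmax(out, shifted)
  }
  out
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# circular mean of angles in degrees, in [0, 360)
circ_mean_deg <- function(a) {
  r <- deg2rad(a)
  (rad2deg(atan2(mean(sin(r)), mean(cos(r)))) + 360) %% 360
}

# circular standard deviation (degrees): sqrt(-2 log Rbar)
circ_sd_deg <- function(a) {
  r <- deg2rad(a)
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(1, rbar)
  rad2deg(sqrt(-2 * log(max(rbar, .Machine$double.eps))))
}

# absolute circular difference in [0, 180]
circ_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# exponential decay filter: y = x convolved with exp(-t/tau) sampled at dt
# (recursive AR(1) filter, kernel value 1 at lag 0)
exp_filter <- function(x, tau, dt) {
  g <- exp(-dt / tau)
  as.numeric(stats::filter(x, g, method = "recursive", init = 0))
}
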