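# shared fixture builders (all generated in code; no files)

# straight line tree along x with n nodes spaced `step` um apart
line_tree <- function(n = 10, step = 2) {
  dendrite_tree(data.frame(
    node_id = seq_len(n),
    parent_id = c(-1L, seq_len(n - 1)),
    x = (seq_len(n) - 1) * step, y = 0, z = 0, radius = 1))
}

# Y-shaped tree: stem of `n_stem` nodes then two arms of `n_arm` nodes
y_tree <- function(n_stem = 3, n_arm = 3, step = 2) {
  ids <- seq_len(n_stem + 2 * n_arm)
  stem <- data.frame(node_id = seq_len(n_stem),
                     parent_id = c(-1L, seq_len(n_stem - 1)),
                     x = (seq_len(n_stem) - 1) * step, y = 0, z = 0,
                     radius = 1)
  a1 <- data.frame(node_id = n_stem + seq_len(n_arm),
                   parent_id = c(n_stem, n_stem + seq_len(n_arm - 1)),
                   x = stem$x[n_stem] + seq_len(n_arm) * step,
                   y = seq_len(n_arm) * step, z = 0, radius = 1)
  a2 <- data.frame(node_id = n_stem + n_arm + seq_len(n_arm),
                   parent_id = c(n_stem, n_stem + n_arm + seq_len(n_arm - 1)),
                   x = stem$x[n_stem] + seq_len(n_arm) * step,
                   y = -seq_len(n_arm) * step, z = 0, radius = 1)
  dendrite_tree(rbind(stem, a1, a2))
}

# mask at a node (offset toward parent optional)
node_mask <- function(id, node, offset = 0, kind = "spine", branch = 1L) {
  data.frame(mask_id = id, kind = kind, node_id = node, offset = offset,
             segment_length = 0, branch_id = branch)
}

# independent tree-distance oracle: walk both nodes to the root, sum edge
# lengths up to the lowest common ancestor
oracle_tree_distance <- function(tree, a, b) {
  nd <- tree$nodes
  chain <- function(v) {
    out <- v
    repeat {
      p <- nd$parent_id[match(v, nd$node_id)]
      if (p == -1L) break
      out <- c(out, p)
      v <- p
    }
    out
  }
  ca <- chain(a); cb <- chain(b)
  lca <- intersect(ca, cb)[1]
  up_len <- function(ch) {
    ix <- seq_len(match(lca, ch) - 1L)
    if (!length(ix)) return(0)
    sum(tree$edge_length[as.character(ch[ix])])
  }
  up_len(ca) + up_len(cb)
}

# small simulated session for cross-module tests
small_session <- function(seed = 1L, n_trials = 40, params = NULL,
                          n_branches = 3, density = 0.3) {
  geom <- generate_synthetic_tree(n_branches = n_branches,
                                  branch_length_range = c(30, 50),
                                  spine_density_per_um = density,
                                  seed = seed)
  trials <- synth_trials(n_trials = n_trials, seed = seed + 1)
  if (is.null(params)) params <- simulation_params()
  simulate_session(geom, trials, params, seed = seed + 2)
}

# untuned dF/F traces for many mask pairs: masks 2k-1 and 2k share a
# per-trial-epoch noise source with correlation rho; responses are constant
# within an epoch (vectorized construction)
common_noise_traces <- function(trials, n_pairs, rho = 0.5,
                                sample_rate = 14.5, seed = 1L) {
  set.seed(seed)
  times <- seq(0, max(trials$r2_off) + 2, by = 1 / sample_rate)
  n_m <- 2L * n_pairs
  n_te <- nrow(trials) * 5L
  shared <- matrix(rnorm(n_te * n_pairs), n_te, n_pairs)
  indep <- matrix(rnorm(n_te * n_m), n_te, n_m)
  a <- sqrt(rho)
  b <- sqrt(1 - rho)
  resp <- a * shared[, rep(seq_len(n_pairs), each = 2)] + b * indep
  dff <- matrix(0, length(times), n_m)
  k <- 0L
  for (ti in seq_len(nrow(trials))) {
    bnd <- trial_epoch_bounds(trials[ti, ])
    for (e in seq_len(5)) {
      k <- k + 1L
      sel <- which(times >= bnd$on[e] & times < bnd$off[e])
      dff[sel, ] <- matrix(resp[k, ], length(sel), n_m, byrow = TRUE)
    }
  }
  list(times = times, dff = dff,
       pair_index = cbind(seq(1, n_m - 1, 2), seq(2, n_m, 2)))
}

# synthetic dF/F traces with explicit per-condition tuning plus shared and
# independent per-trial noise, on a regular time base covering the trials
tuned_traces <- function(trials, tuning_list, shared_sd = 0, indep_sd = 0.1,
                         sample_rate = 14.5, seed = 1L) {
  set.seed(seed)
  t_end <- max(trials$r2_off) + 2
  times <- seq(0, t_end, by = 1 / sample_rate)
  n_m <- length(tuning_list)
  dff <- matrix(0, length(times), n_m)
  for (ti in seq_len(nrow(trials))) {
    tt <- trials[ti, ]
    b <- trial_epoch_bounds(tt)
    for (e in seq_len(5)) {
      sel <- times >= b$on[e] & times < b$off[e]
      shared <- rnorm(1, 0, shared_sd) # per trial-epoch response
      for (m in seq_len(n_m)) {
        tun <- tuning_list[[m]]
        lvl <- tun[e, if (tt$type == "left") 1 else 2]
        dff[sel, m] <- lvl + shared + rnorm(1, 0, indep_sd)
      }
    }
  }
  list(times = times, dff = dff)
}
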