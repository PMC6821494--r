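#' Generate a synthetic trial table
#'
#' Trials of a delayed-response task: a 1.25 s sample epoch (stimulus within
#' reach), early and late delay (1 s each), then early and late response
#' (1 s each) after the go cue, separated by an inter-trial interval.
#'
#' @param n_trials number of trials.
#' @param first_start start time (s) of the first trial.
#' @param iti inter-trial interval (s) between the end of the late response
#'   epoch and the next trial start.
#' @param p_correct probability a trial is correct.
#' @param p_early_lick probability of an early lick (trial excluded from
#'   selectivity analyses).
#' @param seed integer RNG seed.
#' @return data.frame with columns `trial`, `start`, `type`, `correct`,
#'   `early_lick` and epoch boundaries `sample_on`, `sample_off`, `d1_off`,
#'   `d2_off`, `r1_off`, `r2_off` (seconds).
#' @export
synth_trials <- function(n_trials = 60, first_start = 5, iti = 1.75,
                         p_correct = 0.85, p_early_lick = 0.05, seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  rng <- local_rng(seed)
  period <- 1.25 + 4 + iti
  start <- first_start + (seq_len(n_trials) - 1) * period
  type <- ifelse(rng$unif(n_trials) < 0.5, "left", "right")
  # guarantee both types occur
  if (all(type == type[1]) && n_trials > 1) {
    type[1] <- setdiff(c("left", "right"), type[1])
  }
  data.frame(
    trial = seq_len(n_trials), start = start, type = type,
    correct = rng$unif(n_trials) < p_correct,
    early_lick = rng$unif(n_trials) < p_early_lick,
    sample_on = start, sample_off = start + 1.25,
    d1_off = start + 2.25, d2_off = start + 3.25,
    r1_off = start + 4.25, r2_off = start + 5.25)
}

# epoch on/off times of one trial row, ordered S, D1, D2, R1, R2
trial_epoch_bounds <- function(tt) {
  list(on = c(tt$sample_on, tt$sample_off, tt$d1_off, tt$d2_off, tt$r1_off),
       off = c(tt$sample_off, tt$d1_off, tt$d2_off, tt$r1_off, tt$r2_off))
}

epoch_names <- function() c("S", "D1", "D2", "R1", "R2")

#' Read or write a trial table as CSV
#'
#' @param trials trial table (see [synth_trials()] for columns).
#' @param path CSV path.
#' @return `read_trials` returns the trial table; `write_trials` returns
#'   `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path)
  needed <- c("trial", "start", "type", "correct", "early_lick",
              "sample_on", "sample_off", "d1_off", "d2_off", "r1_off",
              "r2_off")
  if (!all(needed %in% names(tr))) {
    stop("trial table must have columns: ", paste(needed, collapse = ", "))
  }
  tr
}

#' Read or write a mask table as CSV
#'
#' Columns: `mask_id`, `kind` (one of soma, trunk, dendrite_segment, spine,
#' bouton), `node_id`, `offset` (um along the edge above the node),
#' `segment_length` (um, 0 for spines/soma), `branch_id`.
#'
#' @param masks mask table.
#' @param path CSV path.
#' @return `read_masks` returns the mask table; `write_masks` returns
#'   `path` invisibly.
#' @export
write_masks <- function(masks, path) {
  utils::write.csv(masks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  mk <- utils::read.csv(path)
  needed <- c("mask_id", "kind", "node_id", "offset", "segment_length",
              "branch_id")
  if (!all(needed %in% names(mk))) {
    stop("mask table must have columns: ", paste(needed, collapse = ", "))
  }
  mk
}
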