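# Shared fixtures and independent oracles for the test suite.

# small, fast ensemble config
small_config <- function(states = data.frame(fret_mean = 0.3, weight = 1),
                         n_molecules = 20L, n_frames = 200L, seed = 42L, ...) {
  trace_sim_config(states = states, n_molecules = n_molecules,
                   n_frames = n_frames, seed = seed, ...)
}

# exhaustive penalized least-squares segmentation oracle: enumerates all
# segmentations with up to `max_cp` change points (minimum segment length
# `min_size`) and returns the objective minimizer. Independent of the
# package's dynamic-programming path.
exhaustive_steps <- function(x, penalty, max_cp = 2L, min_size = 2L) {
  n <- length(x)
  S <- cumsum(c(0, x))
  Q <- cumsum(c(0, x^2))
  segcost <- function(a, b) (Q[b + 1] - Q[a]) - (S[b + 1] - S[a])^2 / (b - a + 1)
  best <- list(objective = segcost(1, n), change_points = integer(0))
  if (max_cp >= 1L) {
    for (c1 in seq(min_size, n - min_size)) {
      obj <- segcost(1, c1) + segcost(c1 + 1, n) + penalty
      if (obj < best$objective)
        best <- list(objective = obj, change_points = c1 + 1L)
    }
  }
  if (max_cp >= 2L && n >= 3L * min_size) {
    for (c1 in seq(min_size, n - 2L * min_size)) {
      base1 <- segcost(1, c1)
      for (c2 in seq(c1 + min_size, n - min_size)) {
        obj <- base1 + segcost(c1 + 1, c2) + segcost(c2 + 1, n) + 2 * penalty
        if (obj < best$objective)
          best <- list(objective = obj, change_points = c(c1, c2) + 1L)
      }
    }
  }
  best
}

# noiseless piecewise-constant intensity trace as a raw trace data.frame
manual_trace <- function(E_per_frame, total = 100, bleach_at = NULL,
                         molecule_id = "manual") {
  n <- length(E_per_frame)
  I_A <- E_per_frame * total
  I_D <- (1 - E_per_frame) * total
  if (!is.null(bleach_at)) {
    dark <- seq(bleach_at, n)
    I_A[dark] <- 0
    I_D[dark] <- 0
  }
  data.frame(molecule_id = molecule_id, frame = seq_len(n),
             time_s = (seq_len(n) - 1) * 0.1, I_D = I_D, I_A = I_A,
             stringsAsFactors = FALSE)
}
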