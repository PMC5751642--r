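# Shared fixtures: tiny configurations and deterministic recordings used
# across test files.

# small, fast simulation config for pipeline-level tests
tiny_config <- function(seed = 1L, ...) {
  simulation_config(n_subjects = 4L, n_evenings = 3L,
                    ema_completion_rate = 0.6, seed = seed, ...)
}

# deterministic periodic recording (no RNG), optionally time-shifted
periodic_recording <- function(n = 3000L, offset = 0L, rate = 100L) {
  idx <- offset + seq_len(n) - 1L
  ph <- 2 * pi * 1.8 * idx / rate
  slow <- 2 * pi * 0.5 * idx / rate
  acc <- cbind(0.1 * sin(3 * 2 * pi * idx / rate),
               0.5 * cos(ph) + 0.2 * cos(2 * ph),
               0.3 * cos(2 * ph))
  att <- cbind(0.08 * sin(slow), 0.06 * cos(slow), 0.01 * sin(ph))
  gait_recording("sx", "ex", 0L, rate, acc, att)
}

# recording whose six channels are all constant
constant_recording <- function(value = 2, n = 256L) {
  m <- matrix(value, n, 3)
  gait_recording("sc", "ec", 0L, 100L, m, m)
}

# central finite-difference Jacobian of the forward map
fd_jacobian <- function(model, X, h = 1e-6) {
  theta <- get_params(model)
  sapply(seq_along(theta), function(k) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (forward(set_params(model, tp), X) -
       forward(set_params(model, tm), X)) / (2 * h)
  })
}
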