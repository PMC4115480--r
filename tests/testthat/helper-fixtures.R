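# shared fixtures: small kinetics sets and noiseless traces built in code

kin_brd4_like <- function() frap_kinetics(y0 = 0.05, A1 = 0.54, t1 = 2,
                                          A2 = 0.36, t2 = 12)

quiet_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_cells = 1, noise_sd = 0, cell_cv = 0, seed = 42,
                   duration_s = 30)
  do.call(frap_sim_spec, utils::modifyList(defaults, args))
}

# independent dense-grid oracle for the half-recovery time: coarse scan to
# bracket the crossing, then a fine grid at `fine` resolution inside the
# bracket; shares no code with the bisection
grid_thalf <- function(k, fine = 1e-5) {
  y_half <- k$y0 + (k$A1 + k$A2) / 2
  upper <- k$t2
  while (recovery_value(k, upper) < y_half) upper <- upper * 2
  coarse <- seq(0, upper, length.out = 2001)
  i <- which(recovery_value(k, coarse) >= y_half)[1]
  lo <- coarse[max(i - 1, 1)]
  hi <- coarse[i]
  fine_grid <- seq(lo, hi, by = fine)
  fine_grid[which(recovery_value(k, fine_grid) >= y_half)[1]]
}

# random constrained kinetics draw for property tests
random_kinetics <- function() {
  y0 <- runif(1, 0, 0.3)
  A <- runif(1, 0.2, 1 - y0)
  split <- runif(1)
  t1 <- runif(1, 0.2, 10)
  ratio <- runif(1, 1, 20)
  frap_kinetics(y0, split * A, t1, (1 - split) * A, t1 * ratio)
}
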