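# shared fixtures built in code

# minimal counting-process table from vectors
toy_intervals <- function(cluster, start, stop, status, ...) {
  data.frame(cluster_id = cluster, start = start, stop = stop,
             status = status, ..., stringsAsFactors = FALSE)
}

# the canonical two-subject single-event dataset: subject A has the
# event at t = 1 with x = 1, subject B is at risk until t = 2 with x = 0
two_subject_data <- function() {
  toy_intervals(c("A", "B"), c(0, 0), c(1, 2), c(1L, 0L), x = c(1, 0))
}

# small random recurrent-event interval set with known seed
random_intervals <- function(seed, n_patients = 60, lambda0 = 0.15,
                             beta_score = log(1.17), beta_td = log(1.04),
                             max_months = 18, dropout = 0.05) {
  sp <- cohort_spec(n_patients = n_patients, seed = seed,
                    baseline_hazard = lambda0,
                    log_hr = c(score = beta_score, female = 0),
                    td_log_hr = c(female = beta_td),
                    max_months = max_months, dropout_rate = dropout)
  cv <- simulate_covariates(sp)
  sim <- simulate_recurrent_events(sp, cv)
  build_intervals(sim$events, sim$follow_up,
                  cv[, c("patient_id", "score", "female")], scope = "ALL6")
}

# coordinate grid-refinement maximizer, independent of the Newton path;
# deterministic, accurate to ~1e-8 in each coordinate
grid_maximize <- function(f, p, center = rep(0, p), width = 4,
                          iters = 45, pts = 13) {
  for (it in seq_len(iters)) {
    for (sweep in 1:2) for (j in seq_len(p)) {
      grid <- center[j] + seq(-width, width, length.out = pts)
      vals <- vapply(grid, function(b) {
        z <- center; z[j] <- b; f(z)
      }, numeric(1))
      center[j] <- grid[which.max(vals)]
    }
    width <- width * 0.6
  }
  center
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    ea <- rep(0, p); ea[a] <- h
    eb <- rep(0, p); eb[b] <- h
    H[a, b] <- (f(x + ea + eb) - f(x + ea - eb) -
                  f(x - ea + eb) + f(x - ea - eb)) / (4 * h^2)
  }
  H
}
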