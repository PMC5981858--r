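# Fixtures shared across test files; everything is generated in code.

# Pure sinusoidal flow: amplitude A, period T seconds, duration at fs Hz.
sine_flow <- function(A = 0.5, period = 4, duration = 60, fs = 100) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  tibble::tibble(time_s = t, flow_lps = A * sin(2 * pi * t / period))
}

# Noise-free subject parameter set (deterministic waveform).
quiet_params <- function(period_s = 4, duty = 0.5, tv_L = 0.5,
                         frc_scale = 1, exp_peak_frac = 0.45) {
  list(period_s = period_s, duty = duty, tv_L = tv_L, frc_scale = frc_scale,
       exp_peak_frac = exp_peak_frac, noise_sd = 0, drift_amp = 0)
}

# Cached small separable feature table (built once per test run).
cached_toy_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) tbl <<- toy_feature_table(n_per_class = 5, trials = 2,
                                                duration_s = 30, seed = 11)
    tbl
  }
})

# Penalized log-likelihood of the ridge-logistic model, written independently
# of the package internals, for oracle comparisons.
oracle_objective <- function(beta, X, y, w, R) {
  lp <- pmin(pmax(drop(cbind(1, X) %*% beta), -30), 30)
  p <- pmin(pmax(1 / (1 + exp(-lp)), 1e-12), 1 - 1e-12)
  sum(w * (y * log(p) + (1 - y) * log(1 - p))) - R * sum(beta[-1]^2)
}

oracle_fit <- function(X, y, w, R) {
  gr <- function(beta) {
    lp <- pmin(pmax(drop(cbind(1, X) %*% beta), -30), 30)
    p <- 1 / (1 + exp(-lp))
    -(drop(crossprod(cbind(1, X), w * (y - p))) - 2 * R * c(0, beta[-1]))
  }
  optim(rep(0, ncol(X) + 1),
        fn = function(b) -oracle_objective(b, X, y, w, R), gr = gr,
        method = "BFGS", control = list(reltol = 1e-15, maxit = 2000))$par
}
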