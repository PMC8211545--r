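# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# cosine detrended trace on the standard 45-min grid
cosine_trace <- function(hours = 96, amp = 5, period = 24, peak_h = 6,
                         noise_sd = 0, dt = 0.75, sigma_noise = 0,
                         seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, hours, by = dt)
  x <- amp * cos(2 * pi * (t - peak_h) / period)
  if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
  as_detrended_trace(t, x, sigma_noise = sigma_noise, ...)
}

# small noiseless simulator configuration: one subgroup, no stochastic
# emission, deterministic phase dynamics
quiet_config <- function(n_cells = 1L, tau0 = 24, tau_sd = 0, k = 0,
                         g = 0, seed = 1L, init_phase_sd_h = 0, ...) {
  sg <- default_subgroups()[1L, ]
  sg$n_cells <- n_cells
  sg$tau0 <- tau0
  sg$tau_sd <- tau_sd
  sg$k <- k
  sg$k_spread <- 0
  sg$k_amp <- 0
  sg$g <- g
  sg$sigma_add <- 0
  sg$shot_scale <- 0
  sg$baseline_drift <- 0
  cell_sim_config(subgroups = sg, n_brains = 1L, seed = seed,
                  phase_noise = 0, init_phase_sd_h = init_phase_sd_h,
                  transient_amp_rel = 0, ...)
}

# uniform small frame stack
flat_stack <- function(n_frames = 10, value = 1, shape = c(4L, 5L),
                       dt_h = 0.25, exposure_min = 15) {
  frame_stack(array(value, c(shape, n_frames)),
              timestamps_h = (seq_len(n_frames) - 1L) * dt_h,
              exposure_min = exposure_min)
}

# activity record with a 24-h square-wave Poisson rate
rhythmic_fly <- function(days = 8, high = 2, low = 0.05, seed = 1,
                         period_h = 24) {
  set.seed(seed)
  n <- days * 1440L
  zt <- ((seq_len(n) - 1L) / 60) %% period_h
  rate <- ifelse(zt < period_h / 2, high, low)
  activity_record("fly1", rpois(n, rate))
}
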