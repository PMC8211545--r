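#' Subgroup parameters for the oscillator ensemble simulator
#'
#' Default parameters for the five circadian neuron subgroups. Cell
#' counts follow the control-arm recordings (18/19/18/27/18 cells for
#' s-LNv/l-LNv/LNd/DN1/DN3 across six brains). Light coupling `k` is
#' strong for the CRY-rich lateral ventral neurons, intermediate for LNd
#' and DN1, and zero for the cell-autonomously light-blind DN3, which
#' instead couples to the network mean phase (`g`). Damping rates and
#' amplitudes are synthetic calibrations chosen to reproduce qualitative
#' orderings (LNvs most light-labile, DN1 highest amplitude, DN3
#' network-following), not measured constants.
#'
#' @return A data.frame with one row per subgroup and columns
#'   `subgroup`, `n_cells`, `tau0` (intrinsic period mean, h), `tau_sd`
#'   (h), `k` (light coupling, geometric mean, 1/h), `k_spread`
#'   (half-width of the log-uniform per-cell spread of `k`;
#'   heterogeneous shift speeds are what desynchronize a subgroup
#'   during re-entrainment), `k_amp` (rate of light-driven amplitude
#'   suppression when light falls at a conflicting circadian phase,
#'   1/h), `g` (network coupling, 1/h),
#'   `lambda_dd`, `lambda_ll` (amplitude decay, 1/h), `b0` (baseline,
#'   photons/min), `baseline_drift` (photons/min/day), `A0` (amplitude,
#'   photons/min), `sigma_add` (additive noise SD) and `shot_scale`
#'   (shot-noise scale).
#' @export
default_subgroups <- function() {
  data.frame(
    subgroup = c("s-LNv", "l-LNv", "LNd", "DN1", "DN3"),
    n_cells = c(18L, 19L, 18L, 27L, 18L),
    tau0 = c(23.9, 23.9, 24.0, 24.1, 24.9),
    tau_sd = c(0.15, 0.18, 0.3, 0.3, 0.10),
    k = c(0.18, 0.18, 0.42, 0.42, 0),
    k_spread = c(1.1, 1.1, 0.2, 0.2, 0),
    k_amp = c(12, 12, 1.0, 1.0, 0),
    g = c(0.005, 0.005, 0.12, 0.08, 0.012),
    lambda_dd = c(0.012, 0.012, 0.010, 0.008, 0.012),
    lambda_ll = c(0.06, 0.06, 0.05, 0.03, 0.03),
    b0 = c(20, 25, 20, 30, 15),
    baseline_drift = c(-0.5, -0.5, -0.5, -0.5, -0.5),
    A0 = c(60, 55, 60, 90, 45),
    sigma_add = c(1.5, 1.5, 1.5, 1.5, 1.5),
    shot_scale = c(0.15, 0.15, 0.15, 0.15, 0.15),
    stringsAsFactors = FALSE)
}

#' Configuration for the cell-ensemble simulator
#'
#' @param subgroups Per-subgroup parameter table as returned by
#'   [default_subgroups()] (rows may be dropped, counts or rates
#'   edited).
#' @param n_brains Number of brains; cells are dealt round-robin across
#'   brains and network coupling acts within a brain.
#' @param sampling_interval Sample cadence in hours (0.75 h = 45-min
#'   bins).
#' @param reporter `"PER"` or `"TIM"`. The TIM reporter advances the
#'   emitted phase by `tim_advance_h` and scales amplitude by
#'   `tim_amp_scale` (the TIM reporter peaks a few hours before PER with
#'   lower amplitude).
#' @param tim_advance_h,tim_amp_scale TIM reporter phase advance (h) and
#'   amplitude scale.
#' @param init_phase_sd_h SD of initial cell phases around the entrained
#'   phase, hours.
#' @param phase_noise Phase diffusion, rad/sqrt(h), at full amplitude.
#'   The effective diffusion scales as `A0/A`: an amplitude-suppressed
#'   oscillator has a poorly defined phase that wanders, which is what
#'   scatters a subgroup whose cells are damped by mistimed light (set 0
#'   for deterministic phase dynamics).
#' @param lambda_relax Amplitude relaxation rate toward `A0` under
#'   entrained LD, 1/h.
#' @param transient_amp_rel,transient_tau_h Initial post-dissection
#'   baseline transient: amplitude relative to `A0` and decay constant
#'   (h); elevated and decaying over roughly the first 12 h.
#' @param dt_h Integration step (h) of the fixed-step explicit scheme.
#' @param seed Integer seed; identical config + seed gives identical
#'   output.
#' @return An object of class `cell_sim_config`.
#' @export
cell_sim_config <- function(subgroups = default_subgroups(), n_brains = 6L,
                            sampling_interval = 0.75, reporter = "PER",
                            tim_advance_h = 3, tim_amp_scale = 0.6,
                            init_phase_sd_h = 0.5, phase_noise = 0.02,
                            lambda_relax = 0.02,
                            transient_amp_rel = 3, transient_tau_h = 4,
                            dt_h = 0.05, seed = 1L) {
  stopifnot(is.data.frame(subgroups), nrow(subgroups) >= 1L,
            all(subgroups$n_cells >= 1L),
            all(subgroups$tau0 >= 16 & subgroups$tau0 <= 32),
            sampling_interval > 0, dt_h > 0,
            all(subgroups$k >= 0), all(subgroups$g >= 0),
            all(subgroups$lambda_dd >= 0), all(subgroups$lambda_ll >= 0))
  if (!all(is.finite(as.matrix(subgroups[vapply(subgroups, is.numeric,
                                                TRUE)]))))
    stop("non-finite simulation parameters")
  structure(list(subgroups = subgroups, n_brains = as.integer(n_brains),
                 sampling_interval = sampling_interval, reporter = reporter,
                 tim_advance_h = tim_advance_h,
                 tim_amp_scale = tim_amp_scale,
                 init_phase_sd_h = init_phase_sd_h,
                 phase_noise = phase_noise,
                 lambda_relax = lambda_relax,
                 transient_amp_rel = transient_amp_rel,
                 transient_tau_h = transient_tau_h,
                 dt_h = dt_h, seed = as.integer(seed)),
            class = "cell_sim_config")
}

# Per-time regime from the schedule's epoch labels: "DD" -> darkness-only
# damping, "LL" -> constant-light damping, anything else -> entrained LD.
schedule_regime <- function(schedule, t) {
  iv <- schedule$intervals
  j <- findInterval(pmin(t, schedule$total_h - 1e-12) + 1e-12, iv$start_h)
  j[j < 1L] <- 1L
  lab <- iv$epoch_label[j]
  ifelse(lab == "DD", "dd", ifelse(lab == "LL", "ll", "ld"))
}

#' Simulate an ensemble of circadian oscillator cells
#'
#' Integrates, per cell, a damped phase-amplitude (Poincare-style)
#' oscillator under a light schedule:
#' \deqn{d\phi_i/dt = 2\pi/\tau_i + k\,L(t)\,\sin(\phi_{target}(t) -
#'   \phi_i) + g\,\sin(\Phi(t) - \phi_i)}
#' where \eqn{L(t)} is the schedule's light state, \eqn{\phi_{target}} is
#' the phase locked to the current day's (possibly shifted) lights-on,
#' and \eqn{\Phi} is the mean phase of the cell's brain network.
#' Amplitude relaxes toward `A0` under entrained LD, decays at
#' `lambda_dd` in darkness-only epochs and at `lambda_ll` under constant
#' light. The emitted signal is
#' \eqn{y = b(t) + A_i(t)\,(1 + \cos\phi_i)/2 + \epsilon}, sampled every
#' `sampling_interval` hours, with shot-like noise (SD proportional to
#' the square root of the mean signal) plus additive Gaussian noise, and
#' an elevated decaying baseline transient over the first hours of
#' culture.
#'
#' @param config A [cell_sim_config()].
#' @param schedule A `light_schedule` of at least 2 days.
#' @return A list with elements `traces` (list of [cell_trace()]) and
#'   `truth` (ground truth: `cells` data.frame of per-cell parameters
#'   including `tau_h`; `phase` and `amplitude` matrices, sample times x
#'   cells, phase unwrapped in radians; `t_h` sample times).
#' @export
simulate_cell_ensemble <- function(config, schedule) {
  stopifnot(inherits(config, "cell_sim_config"),
            inherits(schedule, "light_schedule"))
  if (schedule$total_h < 48) stop("schedule must span at least 2 days")
  set.seed(config$seed)
  sg <- config$subgroups
  n_cells <- sum(sg$n_cells)
  idx <- rep(seq_len(nrow(sg)), sg$n_cells)
  brain <- ((seq_len(n_cells) - 1L) %% config$n_brains) + 1L
  # periods and couplings are quantile-stratified within each subgroup so
  # that a small ensemble is representative of its stated heterogeneity
  # (the draw order across cells is still random via the shuffle below)
  rank_in_group <- unlist(lapply(sg$n_cells, function(n)
    sample.int(n)), use.names = FALSE)
  p_in_group <- (rank_in_group - 0.5) / sg$n_cells[idx]
  tau <- sg$tau0[idx] + sg$tau_sd[idx] * stats::qnorm(p_in_group)
  tau <- pmin(pmax(tau, 16), 32)
  A0 <- sg$A0[idx] * exp(stats::rnorm(n_cells, 0, 0.15))
  b0 <- sg$b0[idx] * exp(stats::rnorm(n_cells, 0, 0.1))

  dt <- config$dt_h
  n_steps <- floor(schedule$total_h / dt + 1e-9)
  t_grid <- (0:n_steps) * dt
  L <- as.integer(light_state(schedule, t_grid) == "light")
  regime <- schedule_regime(schedule, t_grid)
  on <- lights_on_times(schedule)
  day_of <- pmin(floor(t_grid / 24 + 1e-9), nrow(on) - 1L)
  phi_target <- 2 * pi * (t_grid - on$lights_on_h[day_of + 1L]) / 24

  every <- round(config$sampling_interval / dt)
  if (abs(every * dt - config$sampling_interval) > 1e-9)
    stop("`sampling_interval` must be a multiple of `dt_h`")
  samp_steps <- seq(1L, n_steps + 1L, by = every)
  n_samp <- length(samp_steps)

  phi <- phi_target[1L] +
    stats::rnorm(n_cells, 0, 2 * pi * config$init_phase_sd_h / 24)
  A <- A0 * exp(stats::rnorm(n_cells, 0, 0.1))
  k_spread <- if ("k_spread" %in% names(sg)) sg$k_spread[idx] else 0
  k_rank <- unlist(lapply(sg$n_cells, function(n) sample.int(n)),
                   use.names = FALSE)
  k <- sg$k[idx] *
    exp(k_spread * (2 * (k_rank - 0.5) / sg$n_cells[idx] - 1))
  k_amp <- if ("k_amp" %in% names(sg)) sg$k_amp[idx] else 0
  g <- sg$g[idx]
  blind <- sg$k[idx] == 0 & g > 0
  lam_dd <- sg$lambda_dd[idx]; lam_ll <- sg$lambda_ll[idx]

  phase_m <- matrix(NA_real_, n_samp, n_cells)
  amp_m <- matrix(NA_real_, n_samp, n_cells)
  s_ptr <- 1L
  for (s in seq_len(n_steps + 1L)) {
    if (s_ptr <= n_samp && s == samp_steps[s_ptr]) {
      phase_m[s_ptr, ] <- phi
      amp_m[s_ptr, ] <- A
      s_ptr <- s_ptr + 1L
    }
    if (s > n_steps) break
    # network mean phase per brain
    zc <- cos(phi); zs <- sin(phi)
    mc <- rowsum(zc, brain); ms <- rowsum(zs, brain)
    Phi <- atan2(ms, mc)[brain]
    dphi <- 2 * pi / tau +
      k * L[s] * sin(phi_target[s] - phi) + g * sin(Phi - phi)
    # light-blind cells' oscillation is sustained by resonant network
    # drive: efficacy falls off with the cell's phase lag to the network
    # mean, so a network running near their intrinsic period both
    # tightens their lags and homogenizes their amplitudes
    A_tgt <- ifelse(blind, A0 * pmax(0.1, cos(Phi - phi))^3, A0)
    dA <- switch(regime[s],
                 ld = config$lambda_relax * (A_tgt - A),
                 dd = -lam_dd * A,
                 ll = -lam_ll * A)
    # mistimed light suppresses amplitude (largest half a cycle off)
    if (L[s] == 1L)
      dA <- dA - k_amp * (1 - cos(phi_target[s] - phi)) / 2 * A
    phi <- phi + dt * dphi
    if (config$phase_noise > 0)
      phi <- phi + sqrt(dt) * config$phase_noise *
        pmin(A0 / pmax(A, 1e-6), 20) * stats::rnorm(n_cells)
    A <- pmax(A + dt * dA, 0)
  }

  t_samp <- t_grid[samp_steps]
  tim <- identical(config$reporter, "TIM")
  phase_off <- if (tim) 2 * pi * config$tim_advance_h / 24 else 0
  amp_scale <- if (tim) config$tim_amp_scale else 1
  baseline <- outer(t_samp, seq_len(n_cells), function(tt, i)
    b0[i] + sg$baseline_drift[idx[i]] * tt / 24) +
    matrix(rep(sg$A0[idx], each = n_samp) * config$transient_amp_rel *
             exp(-rep(t_samp, n_cells) / config$transient_tau_h),
           n_samp, n_cells)
  mean_sig <- baseline +
    amp_scale * amp_m * (1 + cos(phase_m + phase_off)) / 2
  shot_sd <- matrix(rep(sg$shot_scale[idx], each = n_samp), n_samp, n_cells) *
    sqrt(pmax(mean_sig, 0))
  add_sd <- matrix(rep(sg$sigma_add[idx], each = n_samp), n_samp, n_cells)
  y <- mean_sig + matrix(stats::rnorm(n_samp * n_cells), n_samp, n_cells) *
    sqrt(shot_sd^2 + add_sd^2)

  cells <- data.frame(
    cell_id = sprintf("%s_b%d_c%03d", sg$subgroup[idx], brain,
                      seq_len(n_cells)),
    brain_id = sprintf("brain%d", brain),
    subgroup = sg$subgroup[idx], tau_h = tau, A0 = A0, b0 = b0,
    stringsAsFactors = FALSE)
  traces <- lapply(seq_len(n_cells), function(i)
    cell_trace(t_samp, y[, i], cell_id = cells$cell_id[i],
               brain_id = cells$brain_id[i], subgroup = cells$subgroup[i],
               reporter = config$reporter))
  list(traces = traces,
       truth = list(cells = cells, t_h = t_samp, phase = phase_m,
                    amplitude = amp_m, mean_signal = mean_sig,
                    lights_on = on))
}
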