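#' Ground-truth parameters for a simulated neuron
#'
#' Bundles the intrinsic-parameter ground truth used by [simulate_sweep_set()].
#' The analytic rheobase of the underlying leaky integrate-and-fire (LIF)
#' model, `(v_threshold - rmp) / r_input`, is derived and stored so tests can
#' compare recovered values against a closed form.
#'
#' @param rmp Resting membrane potential (mV).
#' @param r_input Input resistance (MOhm), must be > 0.
#' @param tau Membrane time constant (ms), must be > 0.
#' @param sag_fraction Asymptotic fractional sag rebound, in `[0, 1)`.
#' @param v_threshold Spike threshold voltage (mV), must exceed `rmp`.
#' @param seed Integer seed making every simulation from this truth
#'   deterministic.
#' @return An object of class `ephys_truth`: a list with the fields above plus
#'   `rheobase_true` (pA).
#' @examples
#' tr <- ephys_truth(rmp = -70, r_input = 100, tau = 20,
#'                   sag_fraction = 0.2, v_threshold = -50)
#' tr$rheobase_true  # 200 pA
#' @export
ephys_truth <- function(rmp = -70, r_input = 150, tau = 20,
                        sag_fraction = 0.1, v_threshold = -50, seed = 1L) {
  stopifnot(is.numeric(rmp), is.numeric(r_input), is.numeric(tau))
  if (r_input <= 0) stop("r_input must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  if (sag_fraction < 0 || sag_fraction >= 1)
    stop("sag_fraction must be in [0, 1)")
  if (v_threshold <= rmp) stop("v_threshold must exceed rmp")
  out <- list(rmp = rmp, r_input = r_input, tau = tau,
              sag_fraction = sag_fraction, v_threshold = v_threshold,
              seed = as.integer(seed),
              # pA: mV / (MOhm * 1e-3 mV/pA/MOhm)
              rheobase_true = (v_threshold - rmp) / (r_input * 1e-3))
  class(out) <- "ephys_truth"
  out
}

#' Single current-clamp sweep
#'
#' @param voltage Membrane voltage series (mV).
#' @param current Injected current series (pA), same length as `voltage`.
#' @param sampling_rate Sampling rate (Hz).
#' @param stim_start,stim_end Stimulus window (s).
#' @param stim_amplitude Commanded step amplitude (pA).
#' @param bridge_balance Bridge balance (MOhm); `NA` marks missing amplifier
#'   metadata.
#' @param bias_current Bias (leak) current (pA).
#' @return An object of class `sweep`.
#' @export
new_sweep <- function(voltage, current, sampling_rate, stim_start, stim_end,
                  stim_amplitude, bridge_balance = 10, bias_current = 0) {
  if (length(voltage) != length(current))
    stop("voltage and current series must have equal length")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  dur <- length(voltage) / sampling_rate
  if (!(0 <= stim_start && stim_start < stim_end && stim_end <= dur + 1e-9))
    stop("require 0 <= stim_start < stim_end <= duration")
  structure(list(voltage = as.numeric(voltage), current = as.numeric(current),
                 sampling_rate = sampling_rate, stim_start = stim_start,
                 stim_end = stim_end, stim_amplitude = stim_amplitude,
                 bridge_balance = bridge_balance, bias_current = bias_current),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %.0f pA step [%.3f, %.3f] s, %d samples @ %g kHz\n",
              x$stim_amplitude, x$stim_start, x$stim_end,
              length(x$voltage), x$sampling_rate / 1000))
  invisible(x)
}

#' Default square-pulse stimulus protocol
#'
#' A long-step protocol straddling the analytic rheobase of `truth`:
#' hyperpolarizing steps at -100/-70/-30 pA (for input resistance, tau and
#' sag) and a depolarizing series from one grid step below rheobase to
#' `rheobase + 60` pA in `grid_pa` increments. The actual stimulus table of
#' the original recordings is not published; this stand-in covers every
#' feature the extraction layer measures.
#'
#' @param truth An [ephys_truth()].
#' @param grid_pa Depolarizing grid spacing (pA).
#' @param duration_s Step duration (s).
#' @return data.frame with columns `amplitude_pa`, `duration_s`.
#' @export
default_protocol <- function(truth, grid_pa = 10, duration_s = 1) {
  rb <- grid_pa * ceiling(truth$rheobase_true / grid_pa)
  dep <- seq(rb - grid_pa, rb + 60, by = grid_pa)
  data.frame(amplitude_pa = c(-100, -70, -30, dep),
             duration_s = duration_s)
}

# Stereotyped action-potential waveform constants (ms / mV). The waveform is
# piecewise linear: threshold -> peak over ap_rise_ms, peak -> threshold -
# ap_ahp_mv over ap_fall_ms, then the LIF resumes from the reset voltage.
.ap_shape <- list(peak_mv = 30, rise_ms = 1, fall_ms = 1.25, ahp_mv = 5)

#' Simulate a set of current-clamp sweeps from a LIF neuron
#'
#' Generates square-pulse responses from a leaky integrate-and-fire model with
#' membrane time constant `tau` and input resistance `r_input`. Hyperpolarizing
#' steps include an h-current-like slow rebound implementing voltage sag: the
#' membrane first charges (single exponential, time constant `tau`) toward an
#' overshoot deflection `I * R / (1 - sag_fraction)`, then a slow exponential
#' (time constant `tau_slow_s`, engaged at `7 * tau`) relaxes it to the Ohmic
#' steady state `I * R`, so the measured sag ratio
#' `(V_min - V_ss) / (V_min - baseline)` converges to `sag_fraction` for steps
#' much longer than `tau_slow_s`. When the depolarizing membrane crosses
#' `v_threshold` a stereotyped action potential (1 ms linear rise to +30 mV,
#' repolarization to 5 mV below threshold) is spliced in and the membrane
#' resets. Spike times are computed in closed form, so LIF rheobase and
#' inter-spike intervals are analytically known. Gaussian noise of `noise_sd`
#' is added to the voltage only; the current trace records the commanded
#' stimulus exactly.
#'
#' @param truth An [ephys_truth()].
#' @param protocol data.frame with `amplitude_pa` and `duration_s` columns;
#'   must be non-empty.
#' @param sampling_rate Hz, must be > 0 (>= 10 kHz recommended).
#' @param noise_sd Gaussian voltage noise (mV).
#' @param pre_s,post_s Pre-/post-stimulus padding (s). The pre window must be
#'   >= 0.5 s for the long-window RMS quality-control measurement.
#' @param tau_slow_s Slow sag time constant (s).
#' @param bridge_balance,bias_current Amplifier metadata stored on each sweep.
#' @param seed RNG seed; defaults to `truth$seed`.
#' @return List of [new_sweep()] objects, one per protocol row, with the truth
#'   attached as attribute `"truth"`.
#' @export
simulate_sweep_set <- function(truth, protocol = default_protocol(truth),
                               sampling_rate = 25000, noise_sd = 0,
                               pre_s = 0.6, post_s = 0.2, tau_slow_s = 0.1,
                               bridge_balance = 10, bias_current = 0,
                               seed = truth$seed) {
  stopifnot(inherits(truth, "ephys_truth"))
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (is.null(protocol) || nrow(protocol) == 0) stop("empty protocol")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nrow(protocol)), function(i) {
    .simulate_one_sweep(truth, protocol$amplitude_pa[i], protocol$duration_s[i],
                        sampling_rate, noise_sd, pre_s, post_s, tau_slow_s,
                        bridge_balance, bias_current)
  }) -> sweeps
  attr(sweeps, "truth") <- truth
  sweeps
}

.simulate_one_sweep <- function(truth, amp, dur, fs, noise_sd, pre_s, post_s,
                                tau_slow_s, bridge, bias) {
  n_pre  <- round(pre_s * fs)
  n_stim <- round(dur * fs)
  n_post <- round(post_s * fs)
  n <- n_pre + n_stim + n_post
  dt <- 1 / fs
  # time within the stimulus, seconds, for the stimulated samples
  ts <- (seq_len(n_stim) - 1) * dt
  tau_s <- truth$tau / 1000
  defl_ss <- amp * truth$r_input * 1e-3      # Ohmic steady-state deflection, mV
  v <- rep(truth$rmp, n)
  sag <- truth$sag_fraction

  if (amp < 0 && sag > 0) {
    # overshoot charge + delayed slow rebound (see simulate_sweep_set docs)
    c_over <- sag / (1 - sag)
    t_on <- 7 * tau_s
    rebound <- ifelse(ts <= t_on, 1, exp(-(ts - t_on) / tau_slow_s))
    defl <- defl_ss * (1 - exp(-ts / tau_s)) * (1 + c_over * rebound)
    v[n_pre + seq_len(n_stim)] <- truth$rmp + defl
    v_end <- truth$rmp + defl[n_stim]
  } else {
    v_inf <- truth$rmp + defl_ss
    if (v_inf <= truth$v_threshold) {
      defl <- defl_ss * (1 - exp(-ts / tau_s))
      v[n_pre + seq_len(n_stim)] <- truth$rmp + defl
      v_end <- truth$rmp + defl[n_stim]
    } else {
      # suprathreshold: closed-form spike times with spliced AP waveforms
      seg <- .lif_spiking_trace(truth, amp, dur, fs)
      v[n_pre + seq_len(n_stim)] <- seg
      v_end <- seg[n_stim]
    }
  }
  # post-stimulus relaxation back to rest
  if (n_post > 0) {
    tp <- (seq_len(n_post)) * dt
    v[n_pre + n_stim + seq_len(n_post)] <-
      truth$rmp + (v_end - truth$rmp) * exp(-tp / tau_s)
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  cur <- rep(0, n)
  cur[n_pre + seq_len(n_stim)] <- amp
  new_sweep(v, cur, fs, stim_start = n_pre / fs, stim_end = (n_pre + n_stim) / fs,
        stim_amplitude = amp, bridge_balance = bridge, bias_current = bias)
}

# Voltage trace (stimulus window only) for a suprathreshold LIF step,
# built piecewise from closed-form charging segments and spliced APs.
.lif_spiking_trace <- function(truth, amp, dur, fs) {
  n_stim <- round(dur * fs)
  dt <- 1 / fs
  tau_s <- truth$tau / 1000
  v_inf <- truth$rmp + amp * truth$r_input * 1e-3
  v_th <- truth$v_threshold
  v_reset <- v_th - .ap_shape$ahp_mv
  rise_s <- .ap_shape$rise_ms / 1000
  fall_s <- .ap_shape$fall_ms / 1000
  out <- numeric(n_stim)
  t0 <- 0            # segment start time (s into stimulus)
  v0 <- truth$rmp
  ts_all <- (seq_len(n_stim) - 1) * dt
  repeat {
    # closed-form threshold crossing from (t0, v0)
    dt_cross <- -tau_s * log((v_inf - v_th) / (v_inf - v0))
    t_cross <- t0 + dt_cross
    idx <- which(ts_all >= t0 & ts_all < min(t_cross, dur))
    if (length(idx))
      out[idx] <- v_inf + (v0 - v_inf) * exp(-(ts_all[idx] - t0) / tau_s)
    if (t_cross >= dur) break
    # splice AP: linear rise then linear fall
    i_r <- which(ts_all >= t_cross & ts_all < t_cross + rise_s)
    if (length(i_r))
      out[i_r] <- v_th + (.ap_shape$peak_mv - v_th) *
        (ts_all[i_r] - t_cross) / rise_s
    i_f <- which(ts_all >= t_cross + rise_s & ts_all < t_cross + rise_s + fall_s)
    if (length(i_f))
      out[i_f] <- .ap_shape$peak_mv + (v_reset - .ap_shape$peak_mv) *
        (ts_all[i_f] - t_cross - rise_s) / fall_s
    t0 <- t_cross + rise_s + fall_s
    v0 <- v_reset
    if (t0 >= dur) break
  }
  out
}

#' Analytic LIF spike times for a constant step
#'
#' Closed-form spike (threshold-crossing) times for the simulator's LIF
#' dynamics, used as an independent oracle in tests.
#'
#' @inheritParams simulate_sweep_set
#' @param amp Step amplitude (pA).
#' @param dur Step duration (s).
#' @return Numeric vector of threshold-crossing times (s into the stimulus).
#' @export
lif_spike_times <- function(truth, amp, dur) {
  tau_s <- truth$tau / 1000
  v_inf <- truth$rmp + amp * truth$r_input * 1e-3
  if (v_inf <= truth$v_threshold) return(numeric(0))
  v_reset <- truth$v_threshold - .ap_shape$ahp_mv
  ap_s <- (.ap_shape$rise_ms + .ap_shape$fall_ms) / 1000
  times <- numeric(0)
  t0 <- 0; v0 <- truth$rmp
  repeat {
    t_cross <- t0 - tau_s * log((v_inf - truth$v_threshold) / (v_inf - v0))
    if (t_cross >= dur) break
    times <- c(times, t_cross)
    t0 <- t_cross + ap_s
    v0 <- v_reset
    if (t0 >= dur) break
  }
  times
}
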