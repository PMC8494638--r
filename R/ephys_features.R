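#' @title Intrinsic electrophysiology feature extraction
#' @description Spike detection, per-spike waveform features, sweep quality
#'   control and per-cell subthreshold/suprathreshold features from
#'   current-clamp sweep sets.
#' @name ephys_features
NULL

# moving-average (linear-phase) smoother, window of w samples centred at
# each position (floor((w-1)/2) back, the rest forward), truncated at the
# series edges; cumsum implementation, O(n)
.smooth_ma <- function(x, w) {
  w <- max(2L, as.integer(w))
  n <- length(x)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# dV/dt in mV/ms (forward difference, last value replicated)
.dvdt <- function(v, fs) {
  d <- diff(v) * fs / 1000
  c(d, d[length(d)])
}

#' Detect action potentials in a sweep
#'
#' Candidate spike onsets are upward crossings of the smoothed dV/dt
#' threshold (default 20 mV/ms). Candidates are refined: the threshold-to-peak
#' height must reach `min_height_mv`, the peak must occur within
#' `max_interval_ms` of the onset, and the absolute peak voltage must reach
#' `min_peak_mv`. Troughs are the voltage minima between consecutive retained
#' peaks (peak to stimulus-window end for the last spike). Detection is
#' restricted to the stimulus window.
#'
#' @param sw A [new_sweep()].
#' @param dvdt_threshold Onset threshold on smoothed dV/dt (mV/ms), > 0.
#' @param smoothing_window_ms Width of the linear-phase (moving-average)
#'   smoother applied to dV/dt (ms); must span at least 2 samples.
#' @param min_height_mv,max_interval_ms,min_peak_mv Refinement constants.
#' @return data.frame with integer sample indices `onset`, `peak`, `trough`
#'   (ordered, non-overlapping); zero rows when no spike is found.
#' @export
detect_spikes <- function(sw, dvdt_threshold = 20, smoothing_window_ms = 0.5,
                          min_height_mv = 2, max_interval_ms = 5,
                          min_peak_mv = -30) {
  stopifnot(inherits(sw, "sweep"))
  if (dvdt_threshold <= 0) stop("dvdt_threshold must be > 0")
  fs <- sw$sampling_rate
  w <- round(smoothing_window_ms * fs / 1000)
  if (w < 2) stop("smoothing window shorter than 2 samples")
  i0 <- floor(sw$stim_start * fs) + 1L
  i1 <- ceiling(sw$stim_end * fs)
  i1 <- min(i1, length(sw$voltage))
  if (i1 <= i0) stop("stimulus window is empty")
  v <- sw$voltage
  d <- .smooth_ma(.dvdt(v, fs), w)
  seg <- i0:i1
  up <- seg[-1][d[seg[-1]] >= dvdt_threshold &
                d[seg[-length(seg)]] < dvdt_threshold]
  if (!length(up)) return(.empty_spikes())
  max_int <- round(max_interval_ms * fs / 1000)
  onsets <- integer(0); peaks <- integer(0)
  for (on in up) {
    lim <- min(on + max_int, i1)
    if (lim <= on) next
    rel <- v[on:lim]
    pk <- on + which.max(rel) - 1L
    if (v[pk] - v[on] < min_height_mv) next
    if (v[pk] < min_peak_mv) next
    if (length(peaks) && pk == peaks[length(peaks)]) next  # same AP, keep first
    if (length(peaks) && on <= peaks[length(peaks)]) next  # overlapping
    onsets <- c(onsets, on); peaks <- c(peaks, pk)
  }
  if (!length(onsets)) return(.empty_spikes())
  troughs <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    to <- if (k < length(peaks)) onsets[k + 1L] else i1
    sp <- peaks[k]:to
    troughs[k] <- sp[which.min(v[sp])]
  }
  data.frame(onset = onsets, peak = peaks, trough = troughs)
}

.empty_spikes <- function()
  data.frame(onset = integer(0), peak = integer(0), trough = integer(0))

#' Per-spike waveform features
#'
#' For each detected spike, the threshold is re-localized as the first point
#' at which dV/dt reaches `threshold_frac` (default 5%) of that spike's
#' maximal upstroke. Width is measured at half of (peak - threshold) with
#' linear interpolation of the flank crossing times. The fast AHP is the
#' voltage minimum within 5 ms after the end of the downstroke, and the trough
#' the inter-spike minimum; both are reported relative to threshold.
#'
#' @param sw A [new_sweep()].
#' @param spikes data.frame from [detect_spikes()].
#' @param threshold_frac Fraction of maximal upstroke defining threshold.
#' @return data.frame, one row per spike: `threshold_v`, `threshold_t`,
#'   `peak_v`, `height`, `width_half_height` (ms), `fast_ahp`, `trough` (mV,
#'   relative to threshold), `upstroke`, `downstroke` (mV/ms), `updown_ratio`.
#' @export
extract_spike_features <- function(sw, spikes, threshold_frac = 0.05) {
  stopifnot(inherits(sw, "sweep"))
  if (!nrow(spikes)) return(.empty_spike_features())
  if (is.unsorted(spikes$onset, strictly = TRUE) ||
      any(spikes$peak < spikes$onset) ||
      any(c(spikes$onset, spikes$peak, spikes$trough) < 1) ||
      any(c(spikes$onset, spikes$peak, spikes$trough) > length(sw$voltage)))
    stop("spike indices out of order or out of range")
  fs <- sw$sampling_rate
  v <- sw$voltage
  d <- .dvdt(v, fs)
  n <- nrow(spikes)
  out <- .empty_spike_features(n)
  i_end <- min(ceiling(sw$stim_end * fs), length(v))
  for (k in seq_len(n)) {
    on <- spikes$onset[k]; pk <- spikes$peak[k]; tr <- spikes$trough[k]
    lo <- if (k > 1) spikes$trough[k - 1L] else max(1L, on - round(0.005 * fs))
    up_seg <- lo:pk
    upstroke <- max(d[up_seg])
    th_candidates <- up_seg[d[up_seg] >= threshold_frac * upstroke]
    th_i <- th_candidates[1]
    th_v <- v[th_i]
    height <- v[pk] - th_v
    half <- th_v + height / 2
    # rising flank crossing (linear interpolation)
    ris <- th_i:pk
    ri <- ris[which(v[ris] >= half)[1]]
    t_rise <- if (ri == th_i) ri else
      ri - 1 + (half - v[ri - 1]) / (v[ri] - v[ri - 1])
    # falling flank crossing
    fal <- pk:tr
    fi <- fal[which(v[fal] <= half)[1]]
    t_fall <- if (is.na(fi) || fi == pk) NA_real_ else
      fi - 1 + (half - v[fi - 1]) / (v[fi] - v[fi - 1])
    width <- (t_fall - t_rise) / fs * 1000
    down_seg <- pk:tr
    downstroke <- min(d[down_seg])
    # downstroke end: first sample after the falling phase stops (dV/dt >= 0)
    after_pk <- pk:min(tr + 1L, length(v))
    de <- after_pk[which(d[after_pk] >= 0 & after_pk > pk)[1]]
    if (is.na(de)) de <- tr
    ahp_lim <- min(de + round(0.005 * fs), i_end)
    fast_ahp <- min(v[de:ahp_lim]) - th_v
    out$threshold_v[k] <- th_v
    out$threshold_t[k] <- (th_i - 1) / fs
    out$peak_v[k] <- v[pk]
    out$height[k] <- height
    out$width_half_height[k] <- width
    out$fast_ahp[k] <- fast_ahp
    out$trough[k] <- v[tr] - th_v
    out$upstroke[k] <- upstroke
    out$downstroke[k] <- downstroke
    out$updown_ratio[k] <- upstroke / abs(downstroke)
  }
  out
}

.empty_spike_features <- function(n = 0) {
  cols <- c("threshold_v", "threshold_t", "peak_v", "height",
            "width_half_height", "fast_ahp", "trough", "upstroke",
            "downstroke", "updown_ratio")
  as.data.frame(stats::setNames(rep(list(rep(NA_real_, n)), length(cols)),
                                cols))
}

#' Sweep quality control
#'
#' Applies the per-sweep inclusion criteria: bridge balance < 20 MOhm and
#' < 15% of the input resistance, bias current within 0 +/- 100 pA, and
#' baseline root-mean-square noise below 0.07 mV in a short (1.5 ms) window
#' and 0.5 mV in a long (500 ms) window. RMS is measured on the final 500 ms
#' of the pre-stimulus baseline after linear detrending; the short-window
#' value is the maximum over sliding 1.5 ms windows.
#'
#' @param sw A [new_sweep()].
#' @param r_input Cell input resistance (MOhm), > 0.
#' @param bridge_max,bridge_frac,bias_max,rms_short_max,rms_long_max
#'   Criterion thresholds.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   fail codes among `bridge_abs`, `bridge_rel`, `bias`, `rms_short`,
#'   `rms_long`, `missing_metadata`).
#' @export
sweep_qc <- function(sw, r_input, bridge_max = 20, bridge_frac = 0.15,
                     bias_max = 100, rms_short_max = 0.07,
                     rms_long_max = 0.5) {
  stopifnot(inherits(sw, "sweep"))
  if (r_input <= 0) stop("r_input must be > 0")
  reasons <- character(0)
  if (is.null(sw$bridge_balance) || is.na(sw$bridge_balance) ||
      is.null(sw$bias_current) || is.na(sw$bias_current)) {
    reasons <- c(reasons, "missing_metadata")
  } else {
    if (sw$bridge_balance >= bridge_max) reasons <- c(reasons, "bridge_abs")
    if (sw$bridge_balance >= bridge_frac * r_input)
      reasons <- c(reasons, "bridge_rel")
    if (abs(sw$bias_current) > bias_max) reasons <- c(reasons, "bias")
  }
  fs <- sw$sampling_rate
  n_base <- round(0.5 * fs)
  i1 <- floor(sw$stim_start * fs)
  i0 <- max(1L, i1 - n_base + 1L)
  base <- sw$voltage[i0:i1]
  t <- seq_along(base)
  base <- stats::residuals(stats::lm.fit(cbind(1, t), base))
  rms_long <- sqrt(mean(base^2))
  if (rms_long >= rms_long_max) reasons <- c(reasons, "rms_long")
  wshort <- max(2L, round(0.0015 * fs))
  cs <- cumsum(c(0, base^2))
  nb <- length(base)
  if (nb >= wshort) {
    win_ms <- (cs[(wshort + 1):(nb + 1)] - cs[1:(nb - wshort + 1)]) / wshort
    if (sqrt(max(win_ms)) >= rms_short_max) reasons <- c(reasons, "rms_short")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

# mean pre-stimulus voltage
.baseline <- function(sw) {
  fs <- sw$sampling_rate
  mean(sw$voltage[seq_len(max(1L, floor(sw$stim_start * fs)))])
}

#' Subthreshold features from hyperpolarizing steps
#'
#' Resting membrane potential is the mean pre-stimulus voltage across sweeps.
#' Input resistance is the least-squares slope of steady-state deflection
#' versus step amplitude (not forced through the origin). The membrane time
#' constant is fitted (log-linear) to the onset transient between 10% and 90%
#' of the peak deflection, averaged over sweeps. Sag is
#' `(V_min - V_ss) / (V_min - baseline)` on the sweep nearest -100 pA (within
#' `sag_tol_pa`); the voltage is lightly smoothed (5 ms) before the sag
#' extrema are read so the minimum is not a pure noise excursion.
#'
#' @param sweeps List of hyperpolarizing [new_sweep()]s, >= 2 distinct amplitudes.
#' @param sag_target_pa,sag_tol_pa Amplitude targeted for the sag sweep and
#'   its tolerance; no sweep within tolerance gives a missing (`NA`) sag.
#' @return List: `rmp` (mV), `r_input` (MOhm), `tau` (ms), `sag`.
#' @export
subthreshold_features <- function(sweeps, sag_target_pa = -100,
                                  sag_tol_pa = 20) {
  amps <- vapply(sweeps, function(s) s$stim_amplitude, 0)
  if (length(unique(amps)) < 2)
    stop("need >= 2 distinct hyperpolarizing amplitudes")
  rmp <- mean(vapply(sweeps, .baseline, 0))
  defl <- numeric(length(sweeps))
  taus <- numeric(length(sweeps))
  for (i in seq_along(sweeps)) {
    sw <- sweeps[[i]]
    fs <- sw$sampling_rate
    i0 <- floor(sw$stim_start * fs) + 1L
    i1 <- min(ceiling(sw$stim_end * fs), length(sw$voltage))
    b <- .baseline(sw)
    seg <- sw$voltage[i0:i1]
    # steady state: mean over the last 10% of the step
    ss <- mean(seg[max(1, floor(0.9 * length(seg))):length(seg)])
    defl[i] <- ss - b
    taus[i] <- .fit_tau(seg, fs, b)
  }
  fit <- stats::lm.fit(cbind(1, amps), defl)
  r_input <- fit$coefficients[2] * 1e3   # mV/pA -> MOhm
  sag <- NA_real_
  di <- abs(amps - sag_target_pa)
  if (min(di) <= sag_tol_pa) {
    sw <- sweeps[[which.min(di)]]
    fs <- sw$sampling_rate
    vs <- .smooth_ma(sw$voltage, round(0.005 * fs))
    i0 <- floor(sw$stim_start * fs) + 1L
    i1 <- min(ceiling(sw$stim_end * fs), length(vs))
    b <- mean(vs[seq_len(floor(sw$stim_start * fs))])
    seg <- vs[i0:i1]
    v_min <- min(seg)
    v_ss <- mean(seg[max(1, floor(0.9 * length(seg))):length(seg)])
    sag <- (v_min - v_ss) / (v_min - b)
  }
  list(rmp = rmp, r_input = unname(r_input),
       tau = mean(taus, na.rm = TRUE), sag = sag)
}

# single-exponential fit to the onset transient: a log-linear fit between
# 10% and 90% of the peak deflection seeds a nonlinear least-squares
# refinement (unbiased under additive noise); returns the time constant in ms
.fit_tau <- function(seg, fs, baseline) {
  w <- max(2L, round(0.0005 * fs))
  s <- .smooth_ma(seg, w)
  i_ext <- which.max(abs(s - baseline))
  d_ext <- s[i_ext] - baseline
  if (abs(d_ext) < 1e-9) return(NA_real_)
  frac <- (s[seq_len(i_ext)] - baseline) / d_ext
  idx <- which(frac >= 0.1 & frac <= 0.9)
  if (length(idx) < 3) return(NA_real_)
  resid <- 1 - frac[idx]
  ok <- resid > 0
  if (sum(ok) < 3) return(NA_real_)
  t_ms <- (idx[ok] - 1) / fs * 1000
  fit <- stats::lm.fit(cbind(1, t_ms), log(resid[ok]))
  tau0 <- -1 / fit$coefficients[2]
  if (!is.finite(tau0) || tau0 <= 0) return(NA_real_)
  # refine on the raw (unsmoothed) transient up to 95% of peak deflection
  i95 <- which(frac >= 0.95)[1]
  if (is.na(i95)) i95 <- i_ext
  df <- data.frame(t = (seq_len(i95) - 1) / fs * 1000, v = seg[seq_len(i95)])
  fit2 <- tryCatch(
    suppressWarnings(
      stats::nls(v ~ b + D * (1 - exp(-t / tau)), data = df,
                 start = list(b = baseline, D = d_ext, tau = tau0),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit2)) return(tau0)
  tau_hat <- stats::coef(fit2)[["tau"]]
  if (is.finite(tau_hat) && tau_hat > 0) tau_hat else tau0
}

#' Suprathreshold features from a depolarizing step series
#'
#' Rheobase is the smallest amplitude eliciting at least one spike. Latency
#' and initial firing rate (inverse first inter-spike interval) are measured
#' at rheobase; the f-I slope is the least-squares slope of mean firing rate
#' versus amplitude over spiking sweeps; mean rate and the spike-frequency
#' adaptation index, `mean((ISI[k+1] - ISI[k]) / (ISI[k+1] + ISI[k]))`, are
#' measured on the sweep nearest rheobase + 50 pA.
#'
#' @param sweeps List of depolarizing long-step [new_sweep()]s.
#' @param ... Passed to [detect_spikes()].
#' @return List: `rheobase` (pA), `fi_slope` (Hz/pA), `latency` (s),
#'   `initial_rate` (Hz), `mean_rate` (Hz), `adaptation`; all `NA` when no
#'   sweep spikes. Spike tables are attached as attribute `"spikes"`.
#' @export
suprathreshold_features <- function(sweeps, ...) {
  amps <- vapply(sweeps, function(s) s$stim_amplitude, 0)
  ord <- order(amps)
  sweeps <- sweeps[ord]; amps <- amps[ord]
  spk <- lapply(sweeps, detect_spikes, ...)
  nsp <- vapply(spk, nrow, 0L)
  miss <- list(rheobase = NA_real_, fi_slope = NA_real_, latency = NA_real_,
               initial_rate = NA_real_, mean_rate = NA_real_,
               adaptation = NA_real_)
  if (!any(nsp > 0)) return(miss)
  i_rheo <- which(nsp > 0)[1]
  rheobase <- amps[i_rheo]
  sw <- sweeps[[i_rheo]]
  fs <- sw$sampling_rate
  feats_rheo <- extract_spike_features(sw, spk[[i_rheo]])
  latency <- feats_rheo$threshold_t[1] - sw$stim_start
  isi <- diff(feats_rheo$threshold_t)
  initial_rate <- if (length(isi) >= 1) 1 / isi[1] else NA_real_
  dur <- vapply(sweeps, function(s) s$stim_end - s$stim_start, 0)
  rates <- nsp / dur
  sp_idx <- which(nsp > 0)
  fi_slope <- if (length(sp_idx) >= 2)
    unname(stats::lm.fit(cbind(1, amps[sp_idx]),
                         rates[sp_idx])$coefficients[2]) else NA_real_
  i50 <- which.min(abs(amps - (rheobase + 50)))
  mean_rate <- rates[i50]
  adaptation <- NA_real_
  if (nsp[i50] >= 3) {
    f50 <- extract_spike_features(sweeps[[i50]], spk[[i50]])
    isis <- diff(f50$threshold_t)
    adaptation <- mean((isis[-1] - isis[-length(isis)]) /
                       (isis[-1] + isis[-length(isis)]))
  }
  out <- list(rheobase = rheobase, fi_slope = fi_slope, latency = latency,
              initial_rate = initial_rate, mean_rate = mean_rate,
              adaptation = adaptation)
  attr(out, "spikes") <- spk
  attr(out, "rheo_spike_features") <- feats_rheo
  out
}

#' The 18 per-cell intrinsic electrophysiology features
#'
#' Aggregates sweep-level measurements into the standard per-cell feature set:
#' passive/subthreshold (RMP, input resistance, tau, sag), firing
#' (rheobase, f-I slope, latency, initial and mean rate, adaptation) and
#' action-potential shape features taken from the first spike of the rheobase
#' sweep (threshold, height, width, fast AHP, trough, upstroke, downstroke,
#' upstroke/downstroke ratio). Voltages are reported uncorrected for the
#' liquid junction potential; the measured -14 mV offset is recorded as the
#' `junction_potential_mv` attribute.
#'
#' @param sweeps List of [new_sweep()]s covering hyper- and depolarizing steps.
#' @param qc Apply [sweep_qc()] and drop failing sweeps first. The default QC
#'   noise thresholds assume filtered recordings; disable for white-noise
#'   synthetic data.
#' @param ... Passed to [detect_spikes()].
#' @return Named list of the 18 features (each numeric or `NA`), with
#'   attributes `junction_potential_mv` (-14) and `qc` (per-sweep results
#'   when `qc = TRUE`).
#' @export
cell_features <- function(sweeps, qc = TRUE, ...) {
  if (!length(sweeps)) stop("empty sweep set")
  amps <- vapply(sweeps, function(s) s$stim_amplitude, 0)
  qc_res <- NULL
  if (qc) {
    hyp0 <- sweeps[amps < 0]
    if (length(hyp0) >= 2) {
      r0 <- subthreshold_features(hyp0)$r_input
    } else r0 <- 100
    qc_res <- lapply(sweeps, sweep_qc, r_input = r0)
    keep <- vapply(qc_res, `[[`, TRUE, "pass")
    sweeps <- sweeps[keep]; amps <- amps[keep]
    if (!length(sweeps)) stop("no sweep passed QC")
  }
  hyp <- sweeps[amps < 0]
  dep <- sweeps[amps > 0]
  sub <- if (length(hyp) >= 2 && length(unique(amps[amps < 0])) >= 2)
    subthreshold_features(hyp)
  else list(rmp = if (length(sweeps)) mean(vapply(sweeps, .baseline, 0))
            else NA_real_, r_input = NA_real_, tau = NA_real_, sag = NA_real_)
  sup <- if (length(dep)) suprathreshold_features(dep, ...) else
    list(rheobase = NA_real_, fi_slope = NA_real_, latency = NA_real_,
         initial_rate = NA_real_, mean_rate = NA_real_, adaptation = NA_real_)
  ap <- attr(sup, "rheo_spike_features")
  ap1 <- if (!is.null(ap) && nrow(ap)) ap[1, ] else .empty_spike_features(1)
  out <- list(
    rmp = sub$rmp, r_input = sub$r_input, tau = sub$tau, sag = sub$sag,
    rheobase = sup$rheobase, fi_slope = sup$fi_slope, latency = sup$latency,
    initial_rate = sup$initial_rate, mean_rate = sup$mean_rate,
    adaptation = sup$adaptation,
    ap_threshold = ap1$threshold_v, ap_height = ap1$height,
    ap_width = ap1$width_half_height, ap_fast_ahp = ap1$fast_ahp,
    ap_trough = ap1$trough, ap_upstroke = ap1$upstroke,
    ap_downstroke = ap1$downstroke, ap_updown_ratio = ap1$updown_ratio)
  attr(out, "junction_potential_mv") <- -14
  attr(out, "qc") <- qc_res
  out
}

#' Names of the 18 per-cell electrophysiology features
#' @return Character vector of length 18.
#' @export
ephys_feature_names <- function() {
  c("rmp", "r_input", "tau", "sag", "rheobase", "fi_slope", "latency",
    "initial_rate", "mean_rate", "adaptation", "ap_threshold", "ap_height",
    "ap_width", "ap_fast_ahp", "ap_trough", "ap_upstroke", "ap_downstroke",
    "ap_updown_ratio")
}
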