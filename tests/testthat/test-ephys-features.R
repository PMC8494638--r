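test_that("detect_spikes finds nothing on flat or subthreshold traces", {
  fs <- 20000
  flat <- new_sweep(rep(-70, fs), rep(c(0, 100, 0), c(fs * 0.3, fs * 0.5,
                                                      fs * 0.2)),
                    fs, 0.3, 0.8, 100)
  expect_identical(nrow(detect_spikes(flat)), 0L)
  # 1 mV EPSP-like bump, dV/dt max ~5 mV/ms: below the 20 mV/ms threshold
  t <- seq_len(fs) / fs
  bump <- -70 + pmax(0, 1 - abs(t - 0.5) / 2e-4) * 1
  sw <- new_sweep(bump, rep(c(0, 100, 0), c(fs * 0.3, fs * 0.5, fs * 0.2)),
                  fs, 0.3, 0.8, 100)
  expect_identical(nrow(detect_spikes(sw)), 0L)
})

test_that("a single spliced AP is found at the closed-form spike time", {
  tr <- ephys_truth(rmp = -70, r_input = 100, tau = 20, sag_fraction = 0,
                    v_threshold = -50)
  # one threshold crossing within a short step
  st <- lif_spike_times(tr, 210, 0.07)
  expect_identical(length(st), 1L)
  sws <- simulate_sweep_set(
    tr, protocol = data.frame(amplitude_pa = 210, duration_s = 0.07),
    noise_sd = 0, sampling_rate = 20000)
  sp <- detect_spikes(sws[[1]])
  expect_identical(nrow(sp), 1L)
  peak_t <- sp$peak / 20000 - sws[[1]]$stim_start
  expect_lt(abs(peak_t - (st + 1e-3)), 5e-4)  # peak = crossing + 1 ms rise
})

test_that("detect_spikes validates its arguments", {
  sw <- make_triangle_sweep(0.5)
  expect_error(detect_spikes(sw, dvdt_threshold = 0), "dvdt_threshold")
  expect_error(detect_spikes(sw, smoothing_window_ms = 0.01),
               "smoothing window")
})

test_that("detection equals the brute-force oracle on random sweeps", {
  for (s in 1:10) {
    tr <- random_truth(s)
    amp <- sample(c(tr$rheobase_true * 1.1, tr$rheobase_true * 1.5, 50), 1)
    sws <- simulate_sweep_set(
      tr, protocol = data.frame(amplitude_pa = amp, duration_s = 0.5),
      noise_sd = 0.2, sampling_rate = 10000, pre_s = 0.55)
    got <- detect_spikes(sws[[1]])
    want <- oracle_detect_spikes(sws[[1]])
    expect_identical(got$onset, want$onset)
    expect_identical(got$peak, want$peak)
    expect_identical(got$trough, want$trough)
  }
})

test_that("triangle-pulse geometry: height 80 mV, width 1 ms, symmetric
          up/down ratio 1", {
  sw <- make_triangle_sweep(0.25)
  sp <- detect_spikes(sw)
  expect_identical(nrow(sp), 1L)
  f <- extract_spike_features(sw, sp)
  expect_equal(f$height, 80, tolerance = 1e-6)
  expect_equal(f$width_half_height, 1, tolerance = 0.01)
  expect_equal(f$updown_ratio, 1, tolerance = 1e-6)
  expect_equal(f$threshold_v, -50, tolerance = 1e-6)
})

test_that("stereotyped simulator AP: fast AHP and trough 5 mV below
          threshold", {
  tr <- ephys_truth(rmp = -70, r_input = 100, tau = 20, sag_fraction = 0,
                    v_threshold = -50)
  sws <- simulate_sweep_set(
    tr, protocol = data.frame(amplitude_pa = 250, duration_s = 1),
    noise_sd = 0, sampling_rate = 50000)
  f <- extract_spike_features(sws[[1]], detect_spikes(sws[[1]]))
  expect_equal(f$fast_ahp[1], -5, tolerance = 0.05)
  expect_equal(f$trough[1], -5, tolerance = 0.05)
  expect_equal(f$threshold_v[1], -50, tolerance = 0.1)
})

test_that("updown_ratio is invariant under time-base resampling", {
  f1 <- local({
    sw <- make_triangle_sweep(0.25, fs = 10000)
    extract_spike_features(sw, detect_spikes(sw))
  })
  f2 <- local({
    sw <- make_triangle_sweep(0.25, fs = 40000)
    extract_spike_features(sw, detect_spikes(sw))
  })
  expect_equal(f1$updown_ratio, f2$updown_ratio, tolerance = 1e-6)
})

test_that("extract_spike_features rejects malformed spike tables", {
  sw <- make_triangle_sweep(0.25)
  sp <- detect_spikes(sw)
  bad <- sp[c(1, 1), ]
  expect_error(extract_spike_features(sw, bad), "out of order")
  sp2 <- sp; sp2$peak <- length(sw$voltage) + 10L
  expect_error(extract_spike_features(sw, sp2), "out of range")
})

test_that("sweep_qc applies each criterion with its own fail code", {
  quiet <- make_triangle_sweep(numeric(0))
  qc <- function(sw, ...) sweep_qc(sw, ...)
  sw <- quiet; sw$bridge_balance <- 25
  expect_true("bridge_abs" %in% qc(sw, r_input = 200)$reasons)
  sw$bridge_balance <- 18
  r <- qc(sw, r_input = 100)
  expect_true("bridge_rel" %in% r$reasons)    # 18 >= 15% of 100
  expect_false("bridge_abs" %in% r$reasons)
  sw <- quiet; sw$bias_current <- -50
  expect_true(qc(sw, r_input = 200)$pass)
  sw$bias_current <- -150
  expect_true("bias" %in% qc(sw, r_input = 200)$reasons)
  sw <- quiet; sw$bridge_balance <- NA
  r <- qc(sw, r_input = 200)
  expect_false(r$pass)
  expect_identical(r$reasons, "missing_metadata")
  expect_error(qc(quiet, r_input = 0), "r_input")
})

test_that("sweep_qc flags baseline noise in the correct window", {
  tr <- ephys_truth(seed = 3)
  mk <- function(noise) simulate_sweep_set(
    tr, protocol = data.frame(amplitude_pa = -70, duration_s = 0.5),
    noise_sd = noise, sampling_rate = 20000)[[1]]
  expect_true(sweep_qc(mk(0.01), r_input = 100)$pass)
  r <- sweep_qc(mk(0.2), r_input = 100)
  expect_true("rms_short" %in% r$reasons)   # white 0.2 mV trips 0.07 mV
  expect_false("rms_long" %in% r$reasons)   # but not the 0.5 mV long window
  expect_true("rms_long" %in% sweep_qc(mk(0.8), r_input = 100)$reasons)
})

test_that("two-point subthreshold slope is exact on exact linear data", {
  tr <- ephys_truth(rmp = -70, r_input = 150, tau = 15, sag_fraction = 0,
                    v_threshold = -50)
  sws <- simulate_sweep_set(
    tr, protocol = data.frame(amplitude_pa = c(-100, -50), duration_s = 1),
    noise_sd = 0, sampling_rate = 20000)
  sub <- subthreshold_features(sws)
  expect_equal(sub$r_input, 150, tolerance = 1e-4)
  expect_equal(sub$sag, 0, tolerance = 1e-3)  # no slow component
  expect_error(subthreshold_features(sws[1]), "distinct")
})

test_that("sag is missing without a step near -100 pA", {
  tr <- ephys_truth(sag_fraction = 0.2)
  sws <- simulate_sweep_set(
    tr, protocol = data.frame(amplitude_pa = c(-60, -30), duration_s = 1),
    noise_sd = 0, sampling_rate = 10000)
  expect_true(is.na(subthreshold_features(sws)$sag))
})

test_that("suprathreshold features: exact f-I line and zero adaptation for
          regular trains", {
  # constructed trains: 10/20/30 spikes in 1 s at 200/250/300 pA
  sws <- list(
    make_triangle_sweep(seq(0.05, 0.95, length.out = 10), amp_pa = 200),
    make_triangle_sweep(seq(0.05, 0.95, length.out = 20), amp_pa = 250),
    make_triangle_sweep(seq(0.05, 0.95, length.out = 30), amp_pa = 300))
  sup <- suprathreshold_features(sws)
  expect_equal(sup$rheobase, 200)
  expect_equal(sup$fi_slope, 0.2, tolerance = 1e-9)
  expect_equal(sup$adaptation, 0, tolerance = 1e-9)  # all ISIs equal
  expect_equal(sup$latency, 0.05, tolerance = 1e-3)
  expect_equal(sup$initial_rate, 1 / 0.1, tolerance = 0.01)
  expect_equal(sup$mean_rate, 20, tolerance = 1e-9)  # nearest rheo + 50
})

test_that("no spiking sweep yields all-missing suprathreshold features", {
  tr <- ephys_truth()
  sws <- simulate_sweep_set(
    tr, protocol = data.frame(amplitude_pa = c(10, 20), duration_s = 0.5),
    noise_sd = 0, sampling_rate = 10000)
  sup <- suprathreshold_features(sws)
  expect_true(all(is.na(unlist(sup))))
})

test_that("cell_features populates all 18 features and records the junction
          potential", {
  tr <- ephys_truth(rmp = -70, r_input = 100, tau = 20, sag_fraction = 0.1,
                    v_threshold = -50, seed = 2)
  sws <- simulate_sweep_set(tr, noise_sd = 0, sampling_rate = 20000)
  cf <- cell_features(sws, qc = FALSE)
  expect_identical(names(cf), ephys_feature_names())
  expect_identical(sum(is.na(unlist(cf))), 0L)
  expect_identical(attr(cf, "junction_potential_mv"), -14)
  # voltages are reported uncorrected
  expect_equal(cf$rmp, -70, tolerance = 1e-6)
})

test_that("protocol without a -100 pA step leaves only sag missing", {
  tr <- ephys_truth(seed = 4)
  proto <- default_protocol(tr)
  proto <- proto[proto$amplitude_pa != -100, ]
  sws <- simulate_sweep_set(tr, proto, noise_sd = 0, sampling_rate = 20000)
  cf <- cell_features(sws, qc = FALSE)
  expect_true(is.na(cf$sag))
  expect_identical(sum(is.na(unlist(cf))), 1L)
  expect_error(cell_features(list()), "empty")
})
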