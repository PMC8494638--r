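# Independent brute-force oracles. Each re-derives a quantity from its
# plainest possible definition (sample-by-sample loops, exhaustive pair
# enumeration) so the vectorized implementations can be checked against
# them exactly.

# literal per-sample re-implementation of the spike-detection contract
oracle_detect_spikes <- function(sw, dvdt_threshold = 20,
                                 smoothing_window_ms = 0.5,
                                 min_height_mv = 2, max_interval_ms = 5,
                                 min_peak_mv = -30) {
  fs <- sw$sampling_rate
  v <- sw$voltage
  n <- length(v)
  d <- numeric(n)
  for (i in seq_len(n - 1)) d[i] <- (v[i + 1] - v[i]) * fs / 1000
  d[n] <- d[n - 1]
  w <- max(2L, as.integer(round(smoothing_window_ms * fs / 1000)))
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  ds <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (j in max(1L, i - hl):min(n, i + hr)) {
      acc <- acc + d[j]; cnt <- cnt + 1
    }
    ds[i] <- acc / cnt
  }
  i0 <- floor(sw$stim_start * fs) + 1L
  i1 <- min(ceiling(sw$stim_end * fs), n)
  cand <- integer(0)
  for (i in (i0 + 1L):i1)
    if (ds[i] >= dvdt_threshold && ds[i - 1L] < dvdt_threshold)
      cand <- c(cand, i)
  max_int <- round(max_interval_ms * fs / 1000)
  onsets <- integer(0); peaks <- integer(0)
  for (on in cand) {
    lim <- min(on + max_int, i1)
    if (lim <= on) next
    pk <- on; best <- v[on]
    for (j in on:lim) if (v[j] > best) { best <- v[j]; pk <- j }
    if (v[pk] - v[on] < min_height_mv) next
    if (v[pk] < min_peak_mv) next
    if (length(peaks) && pk == peaks[length(peaks)]) next
    if (length(peaks) && on <= peaks[length(peaks)]) next
    onsets <- c(onsets, on); peaks <- c(peaks, pk)
  }
  troughs <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    to <- if (k < length(peaks)) onsets[k + 1L] else i1
    tr <- peaks[k]; best <- v[peaks[k]]
    for (j in peaks[k]:to) if (v[j] < best) { best <- v[j]; tr <- j }
    troughs[k] <- tr
  }
  data.frame(onset = onsets, peak = peaks, trough = troughs)
}

# exhaustive pairwise beta-score evaluation for one proportion vector
oracle_beta <- function(p, eps = 1e-6) {
  num <- 0; den <- 0
  k <- length(p)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    num <- num + (p[i] - p[j])^2
    den <- den + abs(p[i] - p[j])
  }
  num / (den + eps)
}

# Mann-Whitney U by exhaustive pair counting
oracle_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# Benjamini-Hochberg step-up by direct definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# laminar histogram by fine subdivision: split each segment into ~1 um
# pieces, bin the piece midpoints
oracle_hist_fine <- function(m, compartment, ctx, bin_um = 50,
                             piece_um = 1) {
  ch <- m[m$type == compartment & m$parent != -1, ]
  pi_ <- match(ch$parent, m$id)
  max_d <- ctx$boundaries[["wm"]]
  edges <- seq(0, bin_um * ceiling(max_d / bin_um), by = bin_um)
  counts <- numeric(length(edges) - 1)
  for (i in seq_len(nrow(ch))) {
    p1 <- c(m$x[pi_[i]], m$y[pi_[i]], m$z[pi_[i]])
    p2 <- c(ch$x[i], ch$y[i], ch$z[i])
    len <- sqrt(sum((p2 - p1)^2))
    if (len == 0) next
    nseg <- max(1L, ceiling(len / piece_um))
    for (s in seq_len(nseg)) {
      mid <- p1 + (p2 - p1) * (s - 0.5) / nseg
      dmid <- -mid[2]
      k <- findInterval(dmid, edges, left.open = TRUE,
                        rightmost.closed = TRUE)
      k <- min(max(k, 1L), length(counts))
      counts[k] <- counts[k] + len / nseg
    }
  }
  counts
}

# maximum Euclidean basal node-to-soma distance by exhaustive scan
oracle_basal_max <- function(m) {
  soma <- m[m$type == "soma" & m$parent == -1, ]
  best <- -Inf
  for (i in which(m$type == "basal")) {
    d <- sqrt((m$x[i] - soma$x)^2 + (m$y[i] - soma$y)^2 +
                (m$z[i] - soma$z)^2)
    if (d > best) best <- d
  }
  best
}

# total compartment length by exhaustive node scan
oracle_total_length <- function(m, compartments = c("basal", "apical")) {
  tot <- 0
  for (i in which(m$type %in% compartments)) {
    p <- m$parent[i]
    if (p == -1) next
    j <- match(p, m$id)
    tot <- tot + sqrt((m$x[i] - m$x[j])^2 + (m$y[i] - m$y[j])^2 +
                        (m$z[i] - m$z[j])^2)
  }
  tot
}

# random truth for ephys property tests
random_truth <- function(seed) {
  set.seed(seed)
  ephys_truth(rmp = runif(1, -75, -65), r_input = runif(1, 80, 250),
              tau = runif(1, 12, 30), sag_fraction = runif(1, 0, 0.3),
              v_threshold = runif(1, -52, -45), seed = seed)
}

# flat sweep with triangular spikes spliced at given times (s); linear
# flanks make every waveform feature hand-computable
make_triangle_sweep <- function(spike_times_s, amp_pa = 100, fs = 20000,
                                dur = 1, pre = 0.6, post = 0.1,
                                base_mv = -50, peak_mv = 30,
                                flank_ms = 1) {
  n <- round((pre + dur + post) * fs)
  v <- rep(base_mv, n)
  half_n <- round(flank_ms / 1000 * fs)
  for (t0 in spike_times_s) {
    i0 <- round((pre + t0) * fs)
    up <- seq(0, 1, length.out = half_n + 1)
    v[i0 + 0:half_n] <- base_mv + (peak_mv - base_mv) * up
    v[i0 + half_n + seq_len(half_n)] <-
      peak_mv - (peak_mv - base_mv) * up[-1]
  }
  cur <- rep(0, n)
  cur[round(pre * fs) + seq_len(round(dur * fs))] <- amp_pa
  new_sweep(v, cur, fs, pre, pre + dur, amp_pa)
}
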