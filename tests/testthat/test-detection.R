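real <- whisker_preset("real")

make_tone <- function(f, fs = 20000, dur = 0.5, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  torque_trace(t, amp * sin(2 * pi * f * t))
}

test_that("band-pass filter: DC rejection and gains against the analytic cascade", {
  fs <- 20000
  t <- seq(0, 0.5, by = 1 / fs)
  dc <- bandpass_first_order(torque_trace(t, rep(1, length(t))))
  expect_lt(max(abs(dc$M[t > 0.2])), 1e-3)
  # steady-state tone gains vs the continuous-time first-order cascade
  for (f in c(15, 100, 300, 800)) {
    out <- bandpass_first_order(make_tone(f, fs))
    gain <- max(abs(out$M[t > 0.3])) / 1
    expect_equal(gain, bandpass_gain(f), tolerance = 0.02)
  }
  # 15 Hz whisking is attenuated by >= 14 dB; 300 Hz passes within 3 dB
  g15 <- max(abs(bandpass_first_order(make_tone(15, fs))$M[t > 0.3]))
  expect_lt(20 * log10(g15), -14)
  g300 <- max(abs(bandpass_first_order(make_tone(300, fs))$M[t > 0.3]))
  expect_gt(20 * log10(g300), -3)
  expect_error(bandpass_first_order(make_tone(100), f_lo = 500, f_hi = 100),
               "below")
  expect_error(bandpass_first_order(make_tone(100, fs = 1500)), "twice")
})

test_that("filter is causal: output ignores future inputs", {
  fs <- 20000
  t <- seq(0, 0.1, by = 1 / fs)
  x1 <- rnorm(length(t))
  x2 <- x1
  cut <- which(t > 0.05)[1]
  x2[cut:length(x2)] <- x2[cut:length(x2)] + 10
  y1 <- bandpass_first_order(torque_trace(t, x1))$M
  y2 <- bandpass_first_order(torque_trace(t, x2))$M
  expect_equal(y1[1:(cut - 1)], y2[1:(cut - 1)], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(y1[cut:length(y1)], y2[cut:length(y1)])))
})

test_that("noise floor is the sinusoid amplitude and zero for silence", {
  tone <- make_tone(15, dur = 0.4, amp = 3.7e-7)
  expect_equal(noise_floor(tone, period = 1 / 15), 3.7e-7, tolerance = 0.01)
  flat <- torque_trace(seq(0, 0.3, by = 5e-5), rep(0, 6001))
  expect_equal(noise_floor(flat), 0)
  short <- torque_trace(seq(0, 0.05, by = 5e-5), rnorm(1001))
  expect_error(noise_floor(short, period = 1 / 15), "two whisking periods")
})

test_that("simulated free whisking sits at the printed noise-floor order", {
  t <- seq(0, 4 / 15, by = 1 / 20000)
  fw <- free_whisking_response(real, 15, 10 * pi / 180, t, steady_state = TRUE)
  sigma <- noise_floor(torque_trace(t, fw$M), period = 1 / 15)
  expect_gt(sigma, 3e-8)
  expect_lt(sigma, 3e-7)
})

test_that("threshold detection: misses, instant hits, monotone in threshold", {
  fs <- 10000
  t <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 15 * t)          # amplitude = sigma = 1
  below <- detect_contact(torque_trace(t, x), 1, 0.5)
  expect_false(below$detected)
  expect_true(is.na(below$tau))
  x2 <- x; x2[t > 0.5] <- x2[t > 0.5] + 10
  hit <- detect_contact(torque_trace(t, x2), 1, 0.5)
  expect_true(hit$detected)
  expect_equal(hit$tau, 1 / fs, tolerance = 1e-9)
  # raising the threshold never shortens tau nor gains detections
  x3 <- x + pmax(0, (t - 0.5)) * 12  # slow ramp after onset
  taus <- sapply(c(2, 3, 5), function(th)
    detect_contact(torque_trace(t, x3), 1, 0.5, threshold = th)$tau)
  expect_true(all(diff(taus) >= 0))
  expect_false(detect_contact(torque_trace(t, x3), 1, 0.5,
                              threshold = 15)$detected)
  expect_error(detect_contact(torque_trace(t, x), 1, 2), "outside")
})

test_that("PSD: dominant bin, Parseval, white-noise flatness", {
  fs <- 20000
  t <- seq(0, 0.5, by = 1 / fs)
  tone <- torque_trace(t, sin(2 * pi * 300 * t))
  p <- psd_window(tone, 0.1, duration = 0.05)
  expect_equal(p$f[which.max(p$psd)], 300, tolerance = 0.05)
  # Parseval: integral of the one-sided PSD equals the window-normalised power
  n <- round(0.05 * fs)
  i0 <- which.min(abs(t - 0.1))
  x <- tone$M[i0:(i0 + n - 1)]
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  expect_equal(sum(p$psd) * (fs / n), sum((w * x)^2) / sum(w^2),
               tolerance = 0.01)
  # white noise: flat to within chi-square scatter when averaged over windows
  set.seed(11)
  wn <- torque_trace(t, rnorm(length(t)))
  ps <- sapply(seq(0, 0.4, by = 0.05), function(t0)
    psd_window(wn, t0, duration = 0.05)$psd)
  avg <- rowMeans(ps)[-1]
  expect_lt(max(avg) / median(avg), 2.5)
  expect_gt(min(avg) / median(avg), 0.3)
})

test_that("spectrogram: stationary ridge, contact bursts aligned with events", {
  fs <- 20000
  t <- seq(0, 0.5, by = 1 / fs)
  tone <- torque_trace(t, sin(2 * pi * 300 * t))
  sg <- spectrogram_trace(tone, window = 0.0147)
  ridge <- sg$f[apply(sg$S, 2, which.max)]
  expect_true(all(abs(ridge - 300) < 75))
  # whisking-with-contact trace: high-frequency energy rises at contacts
  tr <- whisking_contact_sim(real, 15, 10 * pi / 180,
                             object = list(epsilon = 0.5, phi_c = 0),
                             n_cycles = 3, fs = fs)
  sg2 <- spectrogram_trace(tr, window = 0.0147, overlap = 0.5)
  hi <- sg2$f > 150 & sg2$f < 1000
  hi_energy <- colSums(sg2$S[hi, , drop = FALSE])
  onsets <- tr$events$time[tr$events$label == "contact"]
  at_contact <- sapply(sg2$t, function(tc)
    any(tc >= onsets & tc <= onsets + 0.02))
  in_air <- sg2$t < onsets[1] - 0.0147  # before anything has rung
  expect_gt(min(hi_energy[at_contact]), 10 * max(hi_energy[in_air]))
  # silence stays at the numerical floor
  sg0 <- spectrogram_trace(torque_trace(t, rep(0, length(t))), window = 0.0147)
  expect_lt(max(sg0$S), 1e-20)
})

test_that("contact windows show a vibration peak well above the whisking line", {
  fs <- 20000
  tr <- whisking_contact_sim(real, 15, 10 * pi / 180,
                             object = list(epsilon = 0.5, phi_c = 0),
                             n_cycles = 3, fs = fs)
  onset <- tr$events$time[tr$events$label == "contact"][1]
  p <- psd_window(tr, onset, duration = 0.0147)
  # second spectral peak f0 far above f_w, in the band the filter passes
  f0 <- p$f[p$f > 100][which.max(p$psd[p$f > 100])]
  expect_gt(f0, 100)
  expect_lt(f0, 1000)
  # the first pinned-mode frequency at mid-shaft lies in the pass band while
  # f_w = 15 Hz lies below it: the frequency decoupling behind the method
  f1 <- solve_modes_pinned(real, 0.5, 1)$omega[1] / (2 * pi)
  expect_gt(f1, 80); expect_lt(f1, 1000)
  expect_lt(15, 80)
})

test_that("detection maps: counts, corner behaviour, reproducibility", {
  eg <- seq(0.15, 0.85, length.out = 6)
  pg <- seq(-0.9, 0.9, length.out = 6)
  maps <- detection_map(real, epsilon_grid = eg, phic_grid = pg,
                        fs = 20000, n_cycles = 3)
  tot <- maps$total; fil <- maps$filtered
  expect_s3_class(tot, "detection_map")
  # the band-passed channel misses strictly fewer contacts
  expect_gt(sum(!tot$detected, na.rm = TRUE),
            sum(!fil$detected, na.rm = TRUE))
  # near-tip contacts at the end of protraction are lost on the total channel
  expect_false(tot$detected[1, 6])
  # undetected cells carry no tau
  expect_true(all(is.na(tot$tau_ms[!tot$detected])))
  # cell-wise, filtered detection is never slower where both channels detect
  both <- tot$detected & fil$detected
  expect_true(all(fil$tau_ms[both] <= tot$tau_ms[both] + 0.051))
  # identical inputs give bit-identical maps
  maps2 <- detection_map(real, epsilon_grid = eg, phic_grid = pg,
                         fs = 20000, n_cycles = 3)
  expect_identical(maps$total$tau_ms, maps2$total$tau_ms)
  expect_identical(maps$filtered$tau_ms, maps2$filtered$tau_ms)
  # long-format CSV round trip
  f <- tempfile(fileext = ".csv")
  write_detection_map(tot, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 36)
  expect_named(back, c("epsilon", "phic_over_phi0", "tau_ms", "detected"))
})

test_that("map grids are validated", {
  expect_error(detection_map(real, epsilon_grid = c(0.5, 0.4)),
               "strictly increasing")
  expect_error(detection_map(real, epsilon_grid = c(0.01, 0.5)),
               "s_tip")
  expect_error(detection_map(real, phic_grid = c(-1.2, 0)), "phi_c")
})
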