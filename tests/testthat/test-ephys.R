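flat_sweeps <- function(v = -70, currents = c(-10, 0, 10), fs = 20000,
                        onset = 0.1, dur = 0.8) {
  n <- round((onset + dur + 0.1) * fs)
  sweep_set(matrix(v, n, length(currents)), currents, fs, onset, dur)
}

test_that("resting membrane potential averages the pre-stimulus baseline", {
  expect_equal(resting_membrane_potential(flat_sweeps(-70)), -70)
  expect_error(resting_membrane_potential(flat_sweeps(currents = c(10, 20))),
               "zero-current")
  # noisy baseline: CLT bound at 50 ms x 20 kHz = 1000 samples, sd 0.5
  set.seed(1)
  ss <- flat_sweeps(-70)
  ss$traces <- ss$traces + rnorm(length(ss$traces), 0, 0.5)
  expect_lt(abs(resting_membrane_potential(ss) + 70), 0.2)
  # linear drift: mean of the window is its midpoint value
  ss2 <- flat_sweeps(-70, fs = 20000)
  drift <- seq(0, 2, length.out = nrow(ss2$traces))
  ss2$traces <- ss2$traces + drift
  w <- (round(0.05 * 20000) + 1):round(0.1 * 20000)
  expect_equal(resting_membrane_potential(ss2), mean(-70 + drift[w]))
})

test_that("input resistance recovers the programmed RC cell", {
  spec <- ephys_template_spec("FS", rin = 100, noise_sd = 0)
  cell <- gen_ephys_cell(spec, seed = 2)
  expect_lt(abs(input_resistance(cell$sweeps) - 100), 0.5)
  # zero-response traces give zero resistance
  expect_equal(input_resistance(flat_sweeps(-70, c(-30, -20, -10, 0, 10))), 0)
  # noisy RC cells stay within 5% of truth
  for (s in 1:5) {
    spec <- ephys_template_spec("RS", rin = 150, noise_sd = 0.3)
    cell <- gen_ephys_cell(spec, seed = 10 + s)
    expect_lt(abs(input_resistance(cell$sweeps) - 150) / 150, 0.05)
  }
})

test_that("spike detection finds template spikes and honors the refractory rule", {
  expect_length(detect_spikes(rep(-70, 1000), 20000), 0)
  # five rendered spikes are found at their peaks (within one sample)
  cell <- gen_ephys_cell(ephys_template_spec("RS", noise_sd = 0), seed = 3)
  fir <- firing_analysis(cell$sweeps)
  i <- which(fir$counts == 5)[1]
  expect_false(is.na(i))
  sched <- prescout:::spike_schedule(
    ephys_template_spec("RS"), cell$sweeps$currents[i], 0.1, 0.8)
  expect_equal(fir$spike_times[[i]], sched,
               tolerance = 1.5 / cell$sweeps$sampling_rate)
  # a doublet within 0.5 ms collapses to one detection
  fs <- 50000
  v <- rep(-70, 500)
  v[100:101] <- c(-15, 30)
  v[115:116] <- c(-15, 30)   # 0.3 ms later
  expect_length(detect_spikes(v, fs), 1)
})

test_that("firing analysis reports counts, frequencies and rheobase", {
  cell <- gen_ephys_cell(ephys_template_spec("FS"), seed = 4)
  fir <- firing_analysis(cell$sweeps)
  expect_equal(unname(fir$counts[match(names(cell$truth$counts),
                                       fir$currents)]),
               unname(cell$truth$counts))
  expect_equal(fir$rheobase, cell$truth$rheobase)
  expect_equal(fir$max_firing_frequency, cell$truth$max_firing_frequency)
  # 40 spikes in 800 ms is 50 Hz
  i40 <- which(fir$counts == 40)
  if (length(i40)) expect_equal(fir$frequencies[i40[1]], 50)
  # a silent cell has undefined rheobase
  silent <- firing_analysis(flat_sweeps(-70))
  expect_true(is.na(silent$rheobase))
  expect_error(ap_features(flat_sweeps(-70), silent$rheobase), "rheobase")
})

test_that("AP features recover the programmed template values", {
  for (cls in c("FS", "RS")) {
    cell <- gen_ephys_cell(ephys_template_spec(cls), seed = 5)
    fir <- firing_analysis(cell$sweeps)
    ap <- ap_features(cell$sweeps, fir$rheobase)
    expect_equal(ap$analyzed_current, fir$rheobase + 50)
    expect_lt(abs(ap$threshold - cell$truth$threshold), 1)
    expect_lt(abs(ap$amplitude - cell$truth$amplitude), 2)
    expect_lt(abs(ap$half_width - cell$truth$half_width), 0.05)
    expect_lt(abs(ap$fahp - cell$truth$fahp), 2)
    expect_gt(ap$max_dvdt, 100)  # steep template rise
  }
})

test_that("half-width of a symmetric-rise triangle matches the closed form", {
  fs <- 50000
  v <- triangle_spike(fs, base = -60, peak = 20, rise_ms = 0.4, fall_ms = 0.6)
  n <- length(v)
  ss <- sweep_set(cbind(rep(-60, n), v), c(0, 100), fs,
                  stim_onset = 0.005, stim_duration = 0.03)
  ap <- ap_features(ss, rheobase = 50)
  # the third-derivative threshold sits near the triangle base; analytic
  # width at half amplitude is (rise + fall) / 2 for a triangle
  expect_lt(abs(ap$half_width - 0.5), 0.06)
})

test_that("the fAHP window truncates at the second spike's onset", {
  # first spike has a shallow fAHP (6 mV), a second spike 4 ms later has a
  # deep one (20 mV); without truncation at the second spike's onset the
  # 10 ms window would pick up the deeper trough
  fs <- 50000
  seg <- function(from, to, ms) {
    seq(from, to, length.out = round(ms / 1000 * fs) + 1)[-1]
  }
  v <- c(rep(-55, 1000),
         seg(-55, -40, 2),    # slow approach to threshold
         seg(-40, 40, 0.3),   # spike 1 rise
         seg(40, -50, 0.4),   # spike 1 fall: trough -50 (fAHP 10)
         seg(-50, -45, 1),    # partial recovery
         rep(-45, round(0.0025 * fs)),
         seg(-45, 40, 0.3),   # spike 2, 4 ms after spike 1
         seg(40, -65, 0.4),   # much deeper trough (would read as fAHP 25)
         seg(-65, -45, 2),
         rep(-55, 1000))
  n <- length(v)
  ss <- sweep_set(cbind(rep(-70, n), v), c(0, 100), fs,
                  stim_onset = 0.002, stim_duration = n / fs - 0.004)
  ap <- ap_features(ss, rheobase = 50)
  expect_lt(abs(ap$fahp - 10), 2)
})

test_that("SFA follows its definition and is invariant to time rescaling", {
  expect_equal(spike_frequency_accommodation(c(0, 100, 250, 450) / 1000), 2)
  expect_equal(spike_frequency_accommodation(c(0.1, 0.2, 0.3, 0.4)), 1)
  expect_true(is.na(spike_frequency_accommodation(c(0.1, 0.2))))
  set.seed(6)
  tt <- cumsum(runif(8, 0.01, 0.1))
  expect_equal(spike_frequency_accommodation(tt * 3.7),
               spike_frequency_accommodation(tt))
  isi <- diff(tt)
  expect_equal(spike_frequency_accommodation(tt),
               isi[length(isi)] / isi[1])
})

test_that("the FS/RS rule reproduces the three worked feature vectors", {
  r1 <- classify_fs_rs(0.30, 120, 20, 1.2)
  expect_equal(r1$class, "FS")
  expect_equal(sum(r1$criteria_met), 4)
  r2 <- classify_fs_rs(0.70, 30, 10, 3.5)
  expect_equal(r2$class, "RS")
  expect_equal(sum(r2$criteria_met), 0)
  r3 <- classify_fs_rs(0.40, 60, 10, 3.0)
  expect_equal(r3$class, "RS")
  expect_equal(sum(r3$criteria_met), 2)
  # boundary values fail their strict inequalities
  expect_equal(sum(classify_fs_rs(0.5, 50, 15, 2)$criteria_met), 0)
  # undefined SFA: all three remaining criteria required
  expect_equal(classify_fs_rs(0.30, 120, 20, NA)$class, "FS")
  expect_equal(classify_fs_rs(0.30, 120, 10, NA)$class, "RS")
})

test_that("features are invariant to time shifts and track voltage offsets", {
  cell <- gen_ephys_cell(ephys_template_spec("FS"), seed = 7)
  ss <- cell$sweeps
  fir <- firing_analysis(ss)
  ap <- ap_features(ss, fir$rheobase)
  # voltage offset: threshold shifts, amplitude/half-width/fAHP do not
  ss_off <- ss
  ss_off$traces <- ss$traces + 7
  ap_off <- ap_features(ss_off, fir$rheobase)
  expect_equal(ap_off$threshold, ap$threshold + 7, tolerance = 1e-6)
  expect_equal(ap_off$amplitude, ap$amplitude, tolerance = 1e-6)
  expect_equal(ap_off$half_width, ap$half_width, tolerance = 1e-6)
  expect_equal(ap_off$fahp, ap$fahp, tolerance = 1e-6)
  # prepending quiet baseline shifts spike times but not ISIs or features
  fs <- ss$sampling_rate
  pad <- matrix(ss$traces[1, ], round(0.05 * fs), ncol(ss$traces),
                byrow = TRUE)
  ss_pad <- sweep_set(rbind(pad, ss$traces), ss$currents, fs,
                      ss$stim_onset + 0.05, ss$stim_duration)
  fir_pad <- firing_analysis(ss_pad)
  expect_equal(fir_pad$counts, fir$counts)
  best <- which.max(fir$counts)
  expect_equal(spike_frequency_accommodation(fir_pad$spike_times[[best]]),
               spike_frequency_accommodation(fir$spike_times[[best]]),
               tolerance = 1e-6)
})

test_that("sweep sets round-trip through the long CSV format", {
  cell <- gen_ephys_cell(
    ephys_template_spec("RS"),
    ephys_protocol(sampling_rate = 10000,
                   firing_currents = seq(100, 200, by = 50)),
    seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweeps_csv(cell$sweeps, path)
  back <- read_sweeps_csv(path)
  expect_equal(back$currents, cell$sweeps$currents)
  expect_equal(back$sampling_rate, cell$sweeps$sampling_rate)
  expect_equal(back$traces, cell$sweeps$traces, tolerance = 1e-6,
               ignore_attr = TRUE)
})
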