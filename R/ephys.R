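#' Current-clamp sweep sets
#'
#' A `SweepSet` holds the voltage responses of one cell to a family of
#' square current injections: a samples-by-sweeps voltage matrix (mV), the
#' injected current per sweep (pA, strictly increasing), the sampling rate
#' (Hz) and the stimulus onset/duration (s).  Time starts at 0 at the first
#' sample.
#'
#' @param traces Numeric matrix, one column per sweep (mV).
#' @param currents Injected current per sweep (pA), strictly increasing.
#' @param sampling_rate Sampling rate in Hz.
#' @param stim_onset,stim_duration Stimulus timing in seconds (the standard
#'   firing protocol uses 0.8 s steps).
#' @return A list of class `SweepSet`.
#' @export
sweep_set <- function(traces, currents, sampling_rate,
                      stim_onset = 0.1, stim_duration = 0.8) {
  traces <- as.matrix(traces)
  stopifnot(ncol(traces) == length(currents),
            all(diff(currents) > 0),
            sampling_rate > 0, stim_onset >= 0, stim_duration > 0)
  structure(
    list(traces = traces, currents = as.numeric(currents),
         sampling_rate = as.numeric(sampling_rate),
         stim_onset = stim_onset, stim_duration = stim_duration),
    class = "SweepSet"
  )
}

#' @export
print.SweepSet <- function(x, ...) {
  cat(sprintf(
    "SweepSet: %d sweeps (%g..%g pA), %.0f kHz, %g s step at t=%g s\n",
    ncol(x$traces), min(x$currents), max(x$currents),
    x$sampling_rate / 1000, x$stim_duration, x$stim_onset
  ))
  invisible(x)
}

#' Read / write sweep sets as long-format CSV
#'
#' Columns: `sweep` (integer id), `current_pA`, `time_s`, `voltage_mV`.
#'
#' @param path File path.
#' @param stim_onset,stim_duration Stimulus timing (stored outside the CSV).
#' @return A `SweepSet` (read) or `path` invisibly (write).
#' @export
read_sweeps_csv <- function(path, stim_onset = 0.1, stim_duration = 0.8) {
  df <- read.table(path, sep = ",", header = TRUE)
  stopifnot(all(c("sweep", "current_pA", "time_s", "voltage_mV") %in%
                  names(df)))
  sweeps <- sort(unique(df$sweep))
  cols <- lapply(sweeps, function(s) {
    d <- df[df$sweep == s, ]
    d$voltage_mV[order(d$time_s)]
  })
  currents <- vapply(sweeps, function(s) df$current_pA[df$sweep == s][1], 0)
  t <- sort(unique(df$time_s[df$sweep == sweeps[1]]))
  fs <- round(1 / median(diff(t)))
  sweep_set(do.call(cbind, cols), currents, fs, stim_onset, stim_duration)
}

#' @rdname read_sweeps_csv
#' @param ss A `SweepSet` to serialize.
#' @export
write_sweeps_csv <- function(ss, path) {
  stopifnot(is(ss, "SweepSet"))
  n <- nrow(ss$traces)
  t <- (seq_len(n) - 1L) / ss$sampling_rate
  df <- data.frame(
    sweep = rep(seq_len(ncol(ss$traces)), each = n),
    current_pA = rep(ss$currents, each = n),
    time_s = rep(t, ncol(ss$traces)),
    voltage_mV = as.vector(ss$traces)
  )
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resting membrane potential
#'
#' Mean voltage over the 50 ms pre-stimulus baseline window of the
#' zero-current sweep.
#'
#' @param ss A `SweepSet` containing a 0 pA sweep.
#' @return RMP in mV.
#' @export
resting_membrane_potential <- function(ss) {
  stopifnot(is(ss, "SweepSet"))
  i <- which(ss$currents == 0)
  if (length(i) == 0) stop("no zero-current sweep in this sweep set")
  fs <- ss$sampling_rate
  w <- seq(max(1L, round((ss$stim_onset - 0.05) * fs) + 1L),
           max(1L, round(ss$stim_onset * fs)))
  mean(ss$traces[w, i[1]])
}

#' Input resistance from subthreshold current steps
#'
#' Ordinary least-squares slope of the steady-state voltage deflection
#' (last 100 ms of the step, relative to the 50 ms pre-stimulus baseline)
#' against injected current, over spike-free sweeps in the -50..+20 pA
#' range.  With voltage in mV and current in nA the slope is in megaohms.
#'
#' @param ss A `SweepSet`.
#' @param current_range Currents (pA) considered subthreshold.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(ss, current_range = c(-50, 20)) {
  stopifnot(is(ss, "SweepSet"))
  fs <- ss$sampling_rate
  sel <- which(ss$currents >= current_range[1] &
                 ss$currents <= current_range[2])
  sel <- sel[vapply(sel, function(i) {
    length(detect_spikes(ss$traces[, i], fs)) == 0L
  }, TRUE)]
  if (length(sel) < 3) stop("need at least 3 spike-free subthreshold sweeps")
  base_w <- seq(max(1L, round((ss$stim_onset - 0.05) * fs) + 1L),
                max(1L, round(ss$stim_onset * fs)))
  end_t <- ss$stim_onset + ss$stim_duration
  ss_w <- seq(round((end_t - 0.1) * fs) + 1L, round(end_t * fs))
  dv <- vapply(sel, function(i) {
    mean(ss$traces[ss_w, i]) - mean(ss$traces[base_w, i])
  }, 0)
  i_na <- ss$currents[sel] / 1000
  unname(coef(lm(dv ~ i_na))[2])
}

#' Detect action potential peaks in a voltage trace
#'
#' A spike is an upward crossing of `v_cross` (default -20 mV) with
#' depolarization rate at least `dvdt_min` (default 10 mV/ms), followed by a
#' local maximum above `peak_min` (default 0 mV).  Peaks closer than
#' `refractory_ms` (default 1 ms) to the previous accepted peak are
#' discarded.
#'
#' @param trace Voltage vector (mV).
#' @param sampling_rate Sampling rate (Hz).
#' @param v_cross,dvdt_min,peak_min,refractory_ms Detection parameters.
#' @return Integer vector of spike peak sample indices; the matching
#'   threshold-crossing indices are attached as `attr(, "onsets")`.
#' @export
detect_spikes <- function(trace, sampling_rate, v_cross = -20,
                          dvdt_min = 10, peak_min = 0, refractory_ms = 1) {
  n <- length(trace)
  if (n < 3) return(integer(0))
  dvdt <- c(diff(trace), 0) * sampling_rate / 1000   # mV/ms
  cross <- which(trace[-n] < v_cross & trace[-1] >= v_cross &
                   dvdt[-n] >= dvdt_min)
  if (length(cross) == 0) return(integer(0))
  win <- max(1L, round(0.002 * sampling_rate))   # peak search: 2 ms
  peaks <- integer(0)
  onsets <- integer(0)
  last <- -Inf
  for (cx in cross) {
    hi <- min(n, cx + win)
    pk <- cx + which.max(trace[cx:hi]) - 1L
    if (trace[pk] <= peak_min) next
    if ((pk - last) / sampling_rate * 1000 < refractory_ms) next
    if (length(peaks) && pk == peaks[length(peaks)]) next
    peaks <- c(peaks, pk)
    onsets <- c(onsets, cx)
    last <- pk
  }
  structure(peaks, onsets = onsets)
}

#' Firing output across a family of current steps
#'
#' Counts spikes within the stimulus window of each sweep; firing frequency
#' is the count divided by the step duration.  Rheobase is the smallest
#' current eliciting at least one spike (`NA` when the cell never fires --
#' downstream AP analysis then refuses to run).
#'
#' @param ss A `SweepSet`.
#' @return A list: `counts`, `frequencies` (Hz), `currents` (pA),
#'   `rheobase` (pA or `NA`), `max_firing_frequency` (Hz),
#'   `spike_times` (list of spike peak times in s per sweep).
#' @export
firing_analysis <- function(ss) {
  stopifnot(is(ss, "SweepSet"))
  fs <- ss$sampling_rate
  t0 <- ss$stim_onset
  t1 <- ss$stim_onset + ss$stim_duration
  spike_times <- lapply(seq_len(ncol(ss$traces)), function(i) {
    pk <- detect_spikes(ss$traces[, i], fs)
    tt <- (pk - 1) / fs
    tt[tt >= t0 & tt <= t1]
  })
  counts <- lengths(spike_times)
  freqs <- counts / ss$stim_duration
  fired <- which(counts > 0)
  list(
    counts = counts, frequencies = freqs, currents = ss$currents,
    rheobase = if (length(fired)) min(ss$currents[fired]) else NA_real_,
    max_firing_frequency = if (length(fired)) max(freqs) else 0,
    spike_times = spike_times
  )
}

#' Single action-potential features
#'
#' Analyzes the first AP of the sweep at 50 pA above rheobase (or the
#' nearest larger current when that exact step is absent).  The voltage is
#' smoothed with a Savitzky-Golay local polynomial before derivative
#' estimation.  Threshold is the voltage at the maximum of the third
#' derivative within the 2 ms preceding the AP peak; amplitude is peak minus
#' threshold; half-width is the time between linearly interpolated crossings
#' of threshold plus half the amplitude; fAHP is threshold minus the voltage
#' trough between the peak and the next spike onset (or 10 ms, whichever
#' comes first); max dV/dt is taken on the rising phase.
#'
#' @param ss A `SweepSet` sampled at 10 kHz or faster.
#' @param rheobase Rheobase in pA (from [firing_analysis()]).
#' @param sg_window_ms Smoothing window for the Savitzky-Golay filter (ms).
#' @param d3_window_ms Wider window used for the third-derivative filter
#'   (ms); derivative estimation from noisy traces needs more support than
#'   value smoothing.
#' @param sg_order Polynomial order of the filters.
#' @return A list of class `APFeatures`: `threshold`, `max_dvdt`,
#'   `amplitude`, `half_width`, `fahp`, and `analyzed_current` (pA).
#' @export
ap_features <- function(ss, rheobase, sg_window_ms = 0.5,
                        d3_window_ms = 1.0, sg_order = 4L) {
  stopifnot(is(ss, "SweepSet"))
  if (is.na(rheobase)) stop("rheobase is undefined: the cell never fired")
  if (ss$sampling_rate < 10000) {
    stop("AP analysis requires a sampling rate of at least 10 kHz")
  }
  target <- rheobase + 50
  cand <- which(ss$currents >= target)
  if (length(cand) == 0) {
    stop("no sweep at or above rheobase + 50 pA (", target, " pA)")
  }
  i <- cand[1]
  v <- ss$traces[, i]
  fs <- ss$sampling_rate
  dtms <- 1000 / fs
  pk_all <- detect_spikes(v, fs)
  if (length(pk_all) == 0) {
    stop("no spike on the sweep selected for AP analysis (",
         ss$currents[i], " pA)")
  }
  run_max <- max(v)
  if (sum(v == run_max) >= 3 &&
      any(rle(v == run_max)$lengths[rle(v == run_max)$values] >= 3)) {
    stop("trace appears clipped/saturated at ", signif(run_max, 4), " mV")
  }
  pk <- pk_all[1]
  onsets <- attr(pk_all, "onsets")
  n_sm <- max(5L, 2L * floor(sg_window_ms / dtms / 2) + 1L)
  n_d3 <- max(n_sm, 2L * floor(d3_window_ms / dtms / 2) + 1L)
  sm <- signal::sgolayfilt(v, p = sg_order, n = n_sm)
  d1 <- signal::sgolayfilt(v, p = sg_order, n = n_sm, m = 1, ts = dtms)
  d3 <- signal::sgolayfilt(v, p = sg_order, n = n_d3, m = 3, ts = dtms)
  w0 <- max(1L, pk - round(2 / dtms))
  thr_idx <- w0 - 1L + which.max(d3[w0:pk])
  threshold <- sm[thr_idx]
  max_dvdt <- max(d1[thr_idx:pk])
  amplitude <- v[pk] - threshold
  if (amplitude <= 0) stop("non-positive AP amplitude; check the trace")
  half <- threshold + amplitude / 2
  ir <- thr_idx:(pk - 1L)
  up <- ir[v[ir] < half & v[ir + 1L] >= half]
  up <- up[length(up)]
  t_up <- up + (half - v[up]) / (v[up + 1L] - v[up])
  idn <- pk:min(length(v) - 1L, pk + round(5 / dtms))
  dn <- idn[v[idn] >= half & v[idn + 1L] < half][1]
  if (length(up) == 0 || is.na(dn)) {
    stop("could not locate half-amplitude crossings")
  }
  t_dn <- dn + (v[dn] - half) / (v[dn] - v[dn + 1L])
  half_width <- (t_dn - t_up) * dtms
  w_end <- pk + round(10 / dtms)
  if (length(pk_all) >= 2) {
    w_end <- min(w_end, onsets[2] - 1L)
  }
  w_end <- min(w_end, length(v))
  fahp <- threshold - min(sm[pk:w_end])
  structure(
    list(threshold = threshold, max_dvdt = max_dvdt, amplitude = amplitude,
         half_width = half_width, fahp = fahp,
         analyzed_current = ss$currents[i]),
    class = "APFeatures"
  )
}

#' Spike-frequency accommodation
#'
#' Ratio of the last to the first inter-spike interval of a train; requires
#' at least three spikes, otherwise `NA` is returned (the FS/RS classifier
#' then falls back to the remaining criteria).
#'
#' @param spike_times Spike times in seconds (or any common unit).
#' @return The SFA ratio, or `NA_real_` for trains of fewer than 3 spikes.
#' @export
spike_frequency_accommodation <- function(spike_times) {
  if (length(spike_times) < 3) return(NA_real_)
  isi <- diff(sort(spike_times))
  isi[length(isi)] / isi[1]
}

#' Rule-based fast-spiking / regular-spiking classification
#'
#' A cell is fast spiking when it satisfies at least three of the four
#' criteria: AP half-width < 0.5 ms, maximum firing frequency > 50 Hz, fAHP
#' amplitude > 15 mV, SFA < 2 (all strict inequalities).  When SFA is
#' unavailable (too few spikes) the cell is classified on the remaining
#' three criteria and must satisfy all three.
#'
#' @param half_width_ms AP half-width (ms).
#' @param max_firing_hz Maximum firing frequency (Hz).
#' @param fahp_mv fAHP amplitude (mV).
#' @param sfa SFA ratio, possibly `NA`.
#' @return A list: `class` (`"FS"` or `"RS"`) and `criteria_met` (named
#'   logical vector of length 4; the SFA entry is `NA` when SFA was
#'   unavailable).
#' @export
classify_fs_rs <- function(half_width_ms, max_firing_hz, fahp_mv, sfa) {
  crit <- c(half_width = half_width_ms < 0.5,
            max_firing = max_firing_hz > 50,
            fahp = fahp_mv > 15,
            sfa = if (is.na(sfa)) NA else sfa < 2)
  if (any(is.na(crit[1:3]))) stop("half-width, firing and fAHP are required")
  need <- if (is.na(crit["sfa"])) 3L else 3L
  fs <- sum(crit, na.rm = TRUE) >= need
  list(class = if (fs) "FS" else "RS", criteria_met = crit)
}

#' Full passive, firing and AP characterization of one cell
#'
#' Convenience wrapper running [resting_membrane_potential()] (when a 0 pA
#' sweep exists), [input_resistance()] (when enough subthreshold sweeps
#' exist), [firing_analysis()], [ap_features()],
#' [spike_frequency_accommodation()] on the maximum-firing sweep, and
#' [classify_fs_rs()].
#'
#' @param ss A `SweepSet` covering subthreshold and suprathreshold steps.
#' @return A list of class `CellPhysiology` with components `rmp`, `rin`,
#'   `firing`, `ap`, `sfa`, `classification` and `criteria_met`.
#' @export
analyze_cell <- function(ss) {
  stopifnot(is(ss, "SweepSet"))
  rmp <- tryCatch(resting_membrane_potential(ss), error = function(e) NA_real_)
  rin <- tryCatch(input_resistance(ss), error = function(e) NA_real_)
  fir <- firing_analysis(ss)
  if (is.na(fir$rheobase)) stop("cell never fired; cannot characterize APs")
  ap <- ap_features(ss, fir$rheobase)
  best <- which.max(fir$counts)
  sfa <- spike_frequency_accommodation(fir$spike_times[[best]])
  cls <- classify_fs_rs(ap$half_width, fir$max_firing_frequency, ap$fahp, sfa)
  structure(
    list(rmp = rmp, rin = rin, firing = fir, ap = ap, sfa = sfa,
         classification = cls$class, criteria_met = cls$criteria_met),
    class = "CellPhysiology"
  )
}

#' @export
print.CellPhysiology <- function(x, ...) {
  cat(sprintf(
    paste0("CellPhysiology: %s | RMP %.1f mV, Rin %.0f MOhm, rheobase %g pA,",
           " max %.0f Hz\n  AP: thr %.1f mV, amp %.1f mV, hw %.2f ms,",
           " fAHP %.1f mV, SFA %s\n"),
    x$classification, x$rmp, x$rin, x$firing$rheobase,
    x$firing$max_firing_frequency, x$ap$threshold, x$ap$amplitude,
    x$ap$half_width, x$ap$fahp,
    if (is.na(x$sfa)) "NA" else sprintf("%.2f", x$sfa)
  ))
  invisible(x)
}
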