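#' Synthetic data generators
#'
#' Every generator is a pure function of its specification and a seed: the
#' RNG state is saved and restored around each call, the seed is recorded in
#' the output, and the same inputs always reproduce the same data.  Outputs
#' use the same containers the analysis functions consume, and each carries
#' an exact ground-truth record so recovery can be scored.
#'
#' @name synthetic
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Two-condition, two-replicate coverage simulation design
#'
#' Describes a toy genome with planted enriched regions: some specific to
#' condition 1, some to condition 2, some shared.  Backgrounds are Poisson
#' fragment counts per bin; planted regions multiply the fragment rate by
#' `fold` in the matching condition(s).  Region positions are drawn once
#' from the seed, non-overlapping with at least 2 kb clearance.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp.
#' @param background_rate Background fragment starts per bin.
#' @param n_cond1,n_cond2,n_shared Numbers of planted regions per class.
#' @param region_width Width of each planted region (bp).
#' @param fold Enrichment fold of planted regions (> 1).
#' @param depth_factors Per-replicate library depth multipliers.
#' @param fragment_extension Fragment length laid down on the genome (bp).
#' @param seed Seed for region placement (recorded; coverage generation
#'   takes its own seed).
#' @return A list of class `SimulationDesign` with a `truth` `GRanges`
#'   carrying a `class` column (`cond1`, `cond2`, `shared`).
#' @export
sim_design <- function(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                       bin_size = 50L, background_rate = 5,
                       n_cond1 = 20L, n_cond2 = 20L, n_shared = 40L,
                       region_width = 1500L, fold = 10,
                       depth_factors = c(1, 0.8),
                       fragment_extension = 200L, seed = 1L) {
  stopifnot(fold > 1, background_rate > 0, all(chrom_lengths > 0),
            region_width >= bin_size)
  n_total <- n_cond1 + n_cond2 + n_shared
  truth <- with_seed(seed, {
    # lay regions on a jittered grid with >= 2 kb clearance
    slot_w <- region_width + 2000L
    slots <- do.call(rbind, lapply(names(chrom_lengths), function(chrom) {
      n_slots <- floor((chrom_lengths[[chrom]] - 2000) / slot_w)
      data.frame(chrom = chrom, slot = seq_len(n_slots))
    }))
    if (nrow(slots) < n_total) stop("genome too small for requested regions")
    pick <- slots[sample.int(nrow(slots), n_total), ]
    start <- (pick$slot - 1L) * slot_w + 1000L +
      sample.int(500L, n_total, replace = TRUE)
    cls <- sample(rep(c("cond1", "cond2", "shared"),
                      c(n_cond1, n_cond2, n_shared)))
    gr <- GenomicRanges::GRanges(pick$chrom,
                                 IRanges::IRanges(start,
                                                  width = region_width))
    gr$class <- cls
    GenomicRanges::sort(gr)
  })
  structure(
    list(chrom_lengths = chrom_lengths, bin_size = as.integer(bin_size),
         background_rate = background_rate, truth = truth, fold = fold,
         depth_factors = depth_factors,
         fragment_extension = as.integer(fragment_extension), seed = seed),
    class = "SimulationDesign"
  )
}

# Fragment-start rates per bin for one condition of a design (internal).
design_rates <- function(design, condition) {
  rates <- lapply(names(design$chrom_lengths), function(chrom) {
    n <- ceiling(design$chrom_lengths[[chrom]] / design$bin_size)
    r <- rep(design$background_rate, n)
    tr <- design$truth[GenomicRanges::seqnames(design$truth) == chrom]
    if (!is.null(condition)) {
      tr <- tr[tr$class %in% c(condition, "shared")]
      for (j in seq_along(tr)) {
        b0 <- (GenomicRanges::start(tr)[j] - 1L) %/% design$bin_size + 1L
        b1 <- min(n, (GenomicRanges::end(tr)[j] - 1L) %/% design$bin_size + 1L)
        r[b0:b1] <- r[b0:b1] * design$fold
      }
    }
    r
  })
  names(rates) <- names(design$chrom_lengths)
  rates
}

#' Simulate per-replicate, per-condition coverage tracks
#'
#' Fragment starts are Poisson-sampled per bin at the design rate (times the
#' replicate depth factor), and each fragment is extended by
#' `fragment_extension` bp so that coverage is the running sum over the
#' extension window -- the caller therefore sees extended coverage, as in
#' real pipelines.  Input tracks are generated at the background rate.
#'
#' @param design A [sim_design()].
#' @param seed Seed for the Poisson sampling.
#' @return A list of class `SimulatedCoverage`: `tracks` (nested list
#'   `cond1`/`cond2`/`input`, each with one `CoverageTrack` per replicate),
#'   `truth` (the design's planted regions) and `seed`.
#' @export
gen_coverage <- function(design, seed = design$seed) {
  stopifnot(is(design, "SimulationDesign"))
  ext_bins <- max(1L, ceiling(design$fragment_extension / design$bin_size))
  sample_track <- function(rates, depth) {
    starts <- lapply(rates, function(r) rpois(length(r), r * depth))
    bins <- lapply(starts, function(s) {
      if (ext_bins == 1L) return(as.numeric(s))
      cs <- cumsum(s)
      n <- length(s)
      lo <- pmax(seq_len(n) - ext_bins, 0L)
      cs[seq_len(n)] - c(0, cs)[lo + 1L]
    })
    coverage_track(bins, design$bin_size,
                   total_fragments = sum(unlist(starts)))
  }
  out <- with_seed(seed, {
    conds <- list(cond1 = design_rates(design, "cond1"),
                  cond2 = design_rates(design, "cond2"),
                  input = design_rates(design, NULL))
    lapply(conds, function(rates) {
      lapply(seq_along(design$depth_factors), function(r) {
        sample_track(rates, design$depth_factors[r])
      })
    })
  })
  structure(list(tracks = out, truth = design$truth, seed = seed),
            class = "SimulatedCoverage")
}

#' Simulate replicate score pairs from the IDR copula mixture
#'
#' With probability `pi` a pair is drawn from the reproducible bivariate
#' normal component (mean `mu`, SD `sigma`, correlation `rho`), otherwise
#' from the independent standard bivariate normal.  Scores are on the log10
#' fold-change scale typical of peak callers.
#'
#' @param n Number of pairs.
#' @param pi,rho,mu,sigma Mixture parameters (see [idr_params()]).
#' @param seed Seed.
#' @return A list: `pairs` (data.frame `score1`, `score2`),
#'   `labels` (`"reproducible"` / `"irreproducible"`), `seed`.
#' @export
gen_idr_pairs <- function(n = 2000L, pi = 0.7, rho = 0.8, mu = 2.6,
                          sigma = 1.3, seed = 1L) {
  stopifnot(n > 0, pi >= 0, pi <= 1, rho > -1, rho < 1, sigma > 0)
  with_seed(seed, {
    lab <- rbinom(n, 1, pi) == 1
    k <- sum(lab)
    s1 <- numeric(n); s2 <- numeric(n)
    a <- rnorm(k); b <- rnorm(k)
    s1[lab] <- mu + sigma * a
    s2[lab] <- mu + sigma * (rho * a + sqrt(1 - rho^2) * b)
    s1[!lab] <- rnorm(n - k)
    s2[!lab] <- rnorm(n - k)
    list(pairs = data.frame(score1 = s1, score2 = s2),
         labels = ifelse(lab, "reproducible", "irreproducible"),
         seed = seed)
  })
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

iupac_instantiate <- function(consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(toupper(consensus), "")[[1]],
               function(ch) sample(sets[[ch]], 1), ""), collapse = "")
}

#' Simulate target and background sequences with planted motifs
#'
#' Generates uniform-random DNA and plants one motif instance (a random
#' realisation of the IUPAC consensus) at a random position in each selected
#' sequence; targets and backgrounds are planted at independent rates.
#'
#' @param n_target,n_background Sequence counts.
#' @param m A [motif()] with a consensus (PWM motifs are planted via their
#'   per-column argmax base).
#' @param target_rate,background_rate Planting probabilities.
#' @param length Sequence length (bp); the typical scan window is 200.
#' @param seed Seed.
#' @return A list: `targets`, `background` ([Biostrings::DNAStringSet]),
#'   `truth` (logical planting flags per set), `seed`.
#' @export
gen_motif_sequences <- function(n_target = 500L, n_background = 500L, m,
                                target_rate = 0.4, background_rate = 0.05,
                                length = 200L, seed = 1L) {
  stopifnot(is(m, "Motif"), length >= 10)
  cons <- if (!is.null(m$consensus)) m$consensus else {
    paste(c("A", "C", "G", "T")[apply(m$pwm, 2, which.max)], collapse = "")
  }
  with_seed(seed, {
    plant <- function(n, rate) {
      seqs <- random_dna(n, length)
      planted <- runif(n) < rate
      w <- nchar(cons)
      for (i in which(planted)) {
        inst <- iupac_instantiate(cons)
        pos <- sample.int(length - w + 1L, 1)
        substr(seqs[i], pos, pos + w - 1L) <- inst
      }
      list(seqs = seqs, planted = planted)
    }
    tg <- plant(n_target, target_rate)
    bg <- plant(n_background, background_rate)
    list(
      targets = Biostrings::DNAStringSet(
        setNames(tg$seqs, paste0("target_", seq_len(n_target)))),
      background = Biostrings::DNAStringSet(
        setNames(bg$seqs, paste0("background_", seq_len(n_background)))),
      truth = list(target_planted = tg$planted,
                   background_planted = bg$planted),
      seed = seed
    )
  })
}

#' Electrophysiology cell template specification
#'
#' Programmed single-AP and firing parameters of a synthetic cell.  The
#' `"FS"` preset satisfies all four fast-spiking criteria with margin
#' (narrow AP, high maximal rate, deep fAHP, no accommodation); the `"RS"`
#' preset satisfies none (broad AP, low rate, shallow fAHP, strong
#' accommodation).  `jitter = TRUE` perturbs the programmed values cell to
#' cell without crossing any criterion boundary.
#'
#' @param class `"FS"` or `"RS"`.
#' @param threshold,amplitude,half_width,fahp Programmed AP parameters
#'   (mV, mV, ms, mV); defaults come from the class preset.
#' @param rheobase Programmed rheobase (pA).
#' @param gain Suprathreshold f-I gain (Hz/pA).
#' @param adaptation Multiplicative stretch applied to each successive ISI
#'   (1 = no accommodation).
#' @param rin,tau Passive input resistance (MOhm) and membrane time constant
#'   (s).
#' @param rmp Resting potential (mV).
#' @param noise_sd Gaussian voltage noise SD (mV).
#' @param jitter Randomize programmed values within class-safe bounds (uses
#'   the generator seed).
#' @return A list of class `EphysTemplateSpec`.
#' @export
ephys_template_spec <- function(class = c("FS", "RS"), threshold = NULL,
                                amplitude = NULL, half_width = NULL,
                                fahp = NULL, rheobase = NULL, gain = NULL,
                                adaptation = NULL, rin = NULL, tau = 0.01,
                                rmp = -70, noise_sd = 0.2, jitter = FALSE) {
  class <- match.arg(class)
  preset <- if (class == "FS") {
    list(threshold = -40, amplitude = 80, half_width = 0.30, fahp = 20,
         rheobase = 150, gain = 0.35, adaptation = 1.0, rin = 100)
  } else {
    list(threshold = -42, amplitude = 75, half_width = 0.80, fahp = 8,
         rheobase = 100, gain = 0.10, adaptation = 1.04, rin = 150)
  }
  take <- function(x, d) if (is.null(x)) d else x
  structure(
    list(class = class,
         threshold = take(threshold, preset$threshold),
         amplitude = take(amplitude, preset$amplitude),
         half_width = take(half_width, preset$half_width),
         fahp = take(fahp, preset$fahp),
         rheobase = take(rheobase, preset$rheobase),
         gain = take(gain, preset$gain),
         adaptation = take(adaptation, preset$adaptation),
         rin = take(rin, preset$rin), tau = tau, rmp = rmp,
         noise_sd = noise_sd, jitter = isTRUE(jitter)),
    class = "EphysTemplateSpec"
  )
}

#' Current-clamp protocol description
#'
#' @param sampling_rate Sampling rate (Hz; at least 10 kHz for AP work).
#' @param stim_onset,stim_duration Step timing (s).
#' @param sub_currents Subthreshold steps (pA), including 0.
#' @param firing_currents Suprathreshold steps (pA).
#' @return A list of class `EphysProtocol`.
#' @export
ephys_protocol <- function(sampling_rate = 50000,
                           stim_onset = 0.1, stim_duration = 0.8,
                           sub_currents = seq(-50, 20, by = 10),
                           firing_currents = seq(25, 500, by = 25)) {
  structure(list(sampling_rate = sampling_rate, stim_onset = stim_onset,
                 stim_duration = stim_duration,
                 sub_currents = sub_currents,
                 firing_currents = firing_currents),
            class = "EphysProtocol")
}

# Render one AP (piecewise template) into the trace vector `v` at peak time
# `t_peak` (s); only the local window of the trace is touched (internal).
render_spike <- function(v, fs, t_peak, theta, A, hw, fahp, ramp_s = 0.006) {
  r <- hw / 1000
  d <- (hw * (A + fahp) / A) / 1000
  vb_post <- theta - 5
  t0 <- t_peak - r
  lo <- max(1L, floor((t0 - ramp_s) * fs) + 1L)
  hi <- min(length(v), ceiling((t_peak + d + 0.04) * fs) + 1L)
  idx <- lo:hi
  tt <- (idx - 1) / fs
  w <- v[idx]
  seg <- tt >= (t0 - ramp_s) & tt < t0
  w[seg] <- theta - 12 + 12 * (tt[seg] - (t0 - ramp_s)) / ramp_s
  seg <- tt >= t0 & tt < t_peak
  w[seg] <- theta + A * (tt[seg] - t0) / r
  seg <- tt >= t_peak & tt < t_peak + d
  w[seg] <- theta + A - (A + fahp) * (tt[seg] - t_peak) / d
  seg <- tt >= t_peak + d
  w[seg] <- vb_post + (theta - fahp - vb_post) *
    exp(-(tt[seg] - t_peak - d) / 0.008)
  v[idx] <- w
  v
}

# Deterministic spike peak times for one suprathreshold sweep (internal).
spike_schedule <- function(spec, current, onset, duration) {
  if (current < spec$rheobase) return(numeric(0))
  n <- 1L + floor(duration * spec$gain * (current - spec$rheobase))
  first <- onset + 0.02
  if (n == 1L) return(first)
  avail <- duration - 0.02 - 0.015
  a <- spec$adaptation
  w <- a^(0:(n - 2L))
  isi <- w * (avail / sum(w))
  first + c(0, cumsum(isi))
}

#' Synthesize a cell's current-clamp sweep set with exact ground truth
#'
#' Subthreshold sweeps follow the RC step response
#' `V = RMP + I R (1 - exp(-t/tau))`; suprathreshold sweeps depolarize to a
#' plateau below threshold and render template APs at deterministic,
#' accommodating spike times (each successive inter-spike interval is
#' stretched by the spec's adaptation factor, so SFA is programmable).
#' Gaussian noise is added throughout.  The truth record carries every
#' programmed value plus the derived rheobase, maximum firing rate and SFA
#' of the maximum-firing sweep.
#'
#' @param spec An [ephys_template_spec()].
#' @param protocol An [ephys_protocol()].
#' @param seed Seed (drives noise, and parameter jitter when the spec asks
#'   for it).
#' @return A list: `sweeps` (a [sweep_set()]), `truth` (programmed values),
#'   `seed`.
#' @export
gen_ephys_cell <- function(spec, protocol = ephys_protocol(), seed = 1L) {
  stopifnot(is(spec, "EphysTemplateSpec"), is(protocol, "EphysProtocol"))
  with_seed(seed, {
    if (spec$jitter) {
      jit <- function(x, sdv) x + rnorm(1, 0, sdv)
      if (spec$class == "FS") {
        spec$threshold <- jit(spec$threshold, 1.5)
        spec$amplitude <- jit(spec$amplitude, 3)
        spec$half_width <- min(max(jit(spec$half_width, 0.03), 0.2), 0.42)
        spec$fahp <- min(max(jit(spec$fahp, 1.5), 17), 25)
        spec$rheobase <- jit(spec$rheobase, 20)
        spec$gain <- max(jit(spec$gain, 0.03), 0.25)
      } else {
        spec$threshold <- jit(spec$threshold, 1.5)
        spec$amplitude <- jit(spec$amplitude, 3)
        spec$half_width <- max(jit(spec$half_width, 0.06), 0.62)
        spec$fahp <- min(max(jit(spec$fahp, 1), 6), 12)
        spec$rheobase <- jit(spec$rheobase, 15)
        spec$gain <- min(max(jit(spec$gain, 0.01), 0.06), 0.12)
      }
    }
    fs <- protocol$sampling_rate
    onset <- protocol$stim_onset
    dur <- protocol$stim_duration
    n <- round((onset + dur + 0.1) * fs)
    t <- (seq_len(n) - 1) / fs
    in_step <- t >= onset & t < onset + dur
    rc <- 1 - exp(-(t - onset) / spec$tau)
    rc_off <- exp(-(t - onset - dur) / spec$tau)

    currents <- sort(unique(c(protocol$sub_currents,
                              protocol$firing_currents)))
    plateau <- spec$threshold - 12
    traces <- vapply(currents, function(I) {
      v <- rep(spec$rmp, n)
      if (I < spec$rheobase || I < min(protocol$firing_currents)) {
        dv <- (I / 1000) * spec$rin
        v[in_step] <- spec$rmp + dv * rc[in_step]
        after <- t >= onset + dur
        v[after] <- spec$rmp + dv * (1 - exp(-dur / spec$tau)) * rc_off[after]
      } else {
        v[in_step] <- spec$rmp + (plateau - spec$rmp) * rc[in_step]
        after <- t >= onset + dur
        v[after] <- spec$rmp +
          (plateau - spec$rmp) * (1 - exp(-dur / spec$tau)) * rc_off[after]
        for (tp in spike_schedule(spec, I, onset, dur)) {
          v <- render_spike(v, fs, tp, spec$threshold, spec$amplitude,
                            spec$half_width, spec$fahp)
        }
      }
      v + rnorm(n, 0, spec$noise_sd)
    }, numeric(n))

    counts <- vapply(currents, function(I) {
      length(spike_schedule(spec, I, onset, dur))
    }, 0L)
    fired <- which(counts > 0)
    best <- fired[which.max(counts[fired])]
    sched <- spike_schedule(spec, currents[best], onset, dur)
    truth <- list(
      class = spec$class, threshold = spec$threshold,
      amplitude = spec$amplitude, half_width = spec$half_width,
      fahp = spec$fahp, rin = spec$rin, rmp = spec$rmp,
      rheobase = min(currents[fired]),
      max_firing_frequency = max(counts) / dur,
      sfa = spike_frequency_accommodation(sched),
      counts = setNames(counts, currents)
    )
    list(sweeps = sweep_set(traces, currents, fs, onset, dur),
         truth = truth, seed = seed)
  })
}

#' Simulate ChIP-qPCR Ct tables with known enrichment
#'
#' Builds paired CIN / non-CIN measurements whose true log2 fold change of
#' ChIP enrichment (CIN over non-CIN) is specified per target; Gaussian
#' cycle noise is added to every Ct.
#'
#' @param true_log2_ratios Named numeric vector of true log2 fold changes.
#' @param ct_noise_sd Ct noise SD in cycles.
#' @param n_replicates Independent measurement replicates per target.
#' @param seed Seed.
#' @param base_ct Baseline Ct of the control region.
#' @return A list: `measurements` (data.frame: target, replicate, then the
#'   eight Ct columns of the CIN and non-CIN [qpcr_measurement()]s),
#'   `truth`, `seed`.
#' @export
gen_qpcr <- function(true_log2_ratios, ct_noise_sd = 0, n_replicates = 1L,
                     seed = 1L, base_ct = 25) {
  stopifnot(!is.null(names(true_log2_ratios)))
  with_seed(seed, {
    rows <- expand.grid(target = names(true_log2_ratios),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    nz <- function() rnorm(nrow(rows), 0, ct_noise_sd)
    truth_dd <- -true_log2_ratios[rows$target]  # ddCt of the CIN sample
    df <- data.frame(
      rows,
      cin_ct_chip_target = base_ct + truth_dd + nz(),
      cin_ct_chip_control = base_ct + nz(),
      cin_ct_input_target = base_ct + nz(),
      cin_ct_input_control = base_ct + nz(),
      noncin_ct_chip_target = base_ct + nz(),
      noncin_ct_chip_control = base_ct + nz(),
      noncin_ct_input_target = base_ct + nz(),
      noncin_ct_input_control = base_ct + nz()
    )
    list(measurements = df, truth = true_log2_ratios, seed = seed)
  })
}

#' Recover per-target log2 fold changes from a simulated Ct table
#'
#' Averages Ct values across replicates per target (as triplicate wells are
#' averaged in practice), then applies [ddct_log2_ratio()].
#'
#' @param measurements The `measurements` data.frame from [gen_qpcr()].
#' @return Named numeric vector of estimated log2 fold changes.
#' @export
ddct_from_table <- function(measurements) {
  targets <- unique(measurements$target)
  vapply(setNames(targets, targets), function(tg) {
    d <- measurements[measurements$target == tg, ]
    cm <- colMeans(d[, grep("_ct_", names(d))])
    cin <- qpcr_measurement(cm[["cin_ct_chip_target"]],
                            cm[["cin_ct_chip_control"]],
                            cm[["cin_ct_input_target"]],
                            cm[["cin_ct_input_control"]])
    noncin <- qpcr_measurement(cm[["noncin_ct_chip_target"]],
                               cm[["noncin_ct_chip_control"]],
                               cm[["noncin_ct_input_target"]],
                               cm[["noncin_ct_input_control"]])
    ddct_log2_ratio(cin, noncin)
  }, 0)
}
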