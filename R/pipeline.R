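#' Pipeline run configuration
#'
#' Bundles every knob of the simulate - call - IDR - differential - HC -
#' integrate - report pipeline; a run is fully determined by its config and
#' seed.  Defaults mirror the standard workflow parameters (FDR 0.01 peak
#' calling, 150 bp minimum differential length, 500 bp merge gap, IDR
#' starting values (2.6, 1.3, 0.8, 0.7)).
#'
#' @param outdir Output directory for the run.
#' @param seed Master seed.
#' @param design A [sim_design()] describing the synthetic experiment.
#' @param peak_cfg A [peak_call_config()].
#' @param idr_init An [idr_params()].
#' @param merge_gap Merge gap (bp) for high-confidence set construction.
#' @param tf_names Names of the simulated TF evidence sets.
#' @param tf_hit_rate Probability that a planted condition-1 region carries
#'   a given TF binding site in the simulated evidence.
#' @param conserved_rate Probability that a planted region overlaps a
#'   simulated conserved element.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(outdir, seed = 1L, design = sim_design(seed = seed),
                       peak_cfg = peak_call_config(),
                       idr_init = idr_params(), merge_gap = 500L,
                       tf_names = c("DLX2", "LHX6", "NKX2-1"),
                       tf_hit_rate = 0.4, conserved_rate = 0.7) {
  stopifnot(is.character(outdir), length(outdir) == 1L)
  structure(
    list(outdir = outdir, seed = as.integer(seed), design = design,
         peak_cfg = peak_cfg, idr_init = idr_init,
         merge_gap = as.integer(merge_gap), tf_names = tf_names,
         tf_hit_rate = tf_hit_rate, conserved_rate = conserved_rate),
    class = "RunConfig"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `outdir`, `seed`, `merge_gap`, `tf_hit_rate`,
#' `conserved_rate`, and nested `design` (fields of [sim_design()]),
#' `peak_cfg` (fields of [peak_call_config()]) and `idr_init` (fields of
#' [idr_params()]).  Unknown keys abort with a message naming them.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("outdir", "seed", "merge_gap", "tf_hit_rate", "conserved_rate",
             "design", "peak_cfg", "idr_init", "tf_names")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(y$outdir)) stop("config is missing required field 'outdir'")
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  design_args <- y$design
  if (!is.null(design_args$chrom_lengths)) {
    design_args$chrom_lengths <- unlist(design_args$chrom_lengths)
  }
  if (is.null(design_args$seed)) design_args$seed <- seed
  run_config(
    outdir = y$outdir, seed = seed,
    design = do.call(sim_design, as.list(design_args)),
    peak_cfg = do.call(peak_call_config, as.list(y$peak_cfg)),
    idr_init = do.call(idr_params, as.list(y$idr_init)),
    merge_gap = if (is.null(y$merge_gap)) 500L else as.integer(y$merge_gap),
    tf_names = if (is.null(y$tf_names)) c("DLX2", "LHX6", "NKX2-1")
               else unlist(y$tf_names),
    tf_hit_rate = if (is.null(y$tf_hit_rate)) 0.4 else y$tf_hit_rate,
    conserved_rate = if (is.null(y$conserved_rate)) 0.7
                     else y$conserved_rate
  )
}

# Simulated evidence sets derived from the design truth (internal): each TF
# set covers a random subset of planted condition-1 regions (trimmed to the
# central portion) plus random background intervals; conserved elements
# cover a random subset of all planted regions.
simulate_evidence <- function(config) {
  truth <- config$design$truth
  chrom_lengths <- config$design$chrom_lengths
  shrink <- function(gr, frac = 0.5) {
    w <- pmax(50L, round(GenomicRanges::width(gr) * frac))
    mid <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                           IRanges::IRanges(pmax(1, mid - w %/% 2),
                                            width = w))
  }
  rand_intervals <- function(n, w = 300L) {
    chrom <- sample(names(chrom_lengths), n, replace = TRUE)
    start <- vapply(chrom, function(ch) {
      sample.int(chrom_lengths[[ch]] - w, 1)
    }, 0)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = w))
  }
  cond1 <- truth[truth$class == "cond1"]
  tf_sets <- lapply(setNames(config$tf_names, config$tf_names), function(tf) {
    hit <- runif(length(cond1)) < config$tf_hit_rate
    GenomicRanges::sort(c(shrink(cond1[hit]), rand_intervals(30)))
  })
  conserved <- GenomicRanges::sort(c(
    shrink(truth[runif(length(truth)) < config$conserved_rate], 0.3),
    rand_intervals(100, 150L)
  ))
  list(tf_sets = tf_sets, conserved = conserved)
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full pRE discovery pipeline on a synthetic design
#'
#' Simulates coverage, calls peaks per condition and replicate against the
#' matched input, assesses replicate consistency by IDR, classifies
#' differential regions per replicate, builds high-confidence sets,
#' annotates and ranks candidates against simulated TF and conservation
#' evidence, scores recovery against the planted truth, and writes every
#' stage artifact (BED/TSV/JSON plus a log) into the run directory.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly; artifacts land in `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$outdir, "run.log"), "w")
  on.exit(close(logf))
  cfg_hash <- substr(paste(
    as.hexmode(utf8ToInt(substr(paste(deparse(config), collapse = ""),
                                1, 2000))), collapse = ""), 1, 12)
  log_line(logf, "prescout ", as.character(utils::packageVersion("prescout")),
           " | seed ", config$seed, " | config hash ", cfg_hash)

  sim <- gen_coverage(config$design, seed = config$seed)
  write_bed(sim$truth, file.path(config$outdir, "truth.bed"))
  log_line(logf, "simulated coverage: ",
           length(sim$truth), " planted regions")

  n_rep <- length(config$design$depth_factors)
  peaks <- list()
  for (cond in c("cond1", "cond2")) {
    for (r in seq_len(n_rep)) {
      p <- call_peaks(sim$tracks[[cond]][[r]], sim$tracks$input[[r]],
                      config$peak_cfg)
      peaks[[paste0(cond, "_rep", r)]] <- p
      write_bed(p, file.path(config$outdir,
                             paste0("peaks_", cond, "_rep", r, ".bed")))
      log_line(logf, cond, " rep", r, ": ", length(p), " peaks")
    }
  }

  idr_fits <- lapply(c(cond1 = "cond1", cond2 = "cond2"), function(cond) {
    pairs <- match_replicate_peaks(peaks[[paste0(cond, "_rep1")]],
                                   peaks[[paste0(cond, "_rep2")]])
    fit <- tryCatch(
      fit_idr(pairs, init = config$idr_init),
      error = function(e) {
        log_line(logf, "IDR skipped for ", cond, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) {
      write_idr_pairs(fit, file.path(config$outdir,
                                     paste0("idr_", cond, ".tsv")))
      log_line(logf, "IDR ", cond, sprintf(
        ": pi=%.3f rho=%.3f over %d pairs", fit$params$pi,
        fit$params$rho, length(fit$local_idr)))
    }
    fit
  })

  diffs <- lapply(seq_len(n_rep), function(r) {
    classify_differential(sim$tracks$cond1[[r]], sim$tracks$cond2[[r]],
                          config$peak_cfg, input = sim$tracks$input[[r]])
  })
  hc <- build_hc_differential(diffs[[1]], diffs[[2]], config$merge_gap)
  for (nm in names(hc)) {
    write_bed(hc[[nm]], file.path(config$outdir, paste0("hc_", nm, ".bed")))
  }
  log_line(logf, "HC sets: ", length(hc$enriched_in_1), " / ",
           length(hc$enriched_in_2), " / ", length(hc$common))

  evidence <- with_seed(config$seed + 1L, simulate_evidence(config))
  scores <- vapply(seq_along(hc$enriched_in_1), function(i) {
    ov <- overlaps_any(peaks$cond1_rep1, hc$enriched_in_1[i])
    if (any(ov)) max(peaks$cond1_rep1$score[ov]) else 0
  }, 0)
  hc1 <- hc$enriched_in_1
  hc1$score <- scores
  cands <- annotate_candidates(hc1, tf_sets = evidence$tf_sets,
                               conserved = evidence$conserved)
  cands <- rank_candidates(cands)
  write.table(cands, file.path(config$outdir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  truth1 <- sim$truth[sim$truth$class == "cond1"]
  recov <- recovery_stats(hc$enriched_in_1, truth1)
  log_line(logf, sprintf("cond1 HC recovery: sensitivity %.3f precision %.3f",
                         recov$sensitivity, recov$precision))

  summary <- list(
    seed = config$seed, config_hash = cfg_hash,
    n_planted = as.list(table(sim$truth$class)),
    peaks_per_set = lapply(peaks, length),
    idr = lapply(idr_fits, function(f) {
      if (is.null(f)) NULL else f$params[c("pi", "rho", "mu", "sigma")]
    }),
    hc = summarize_counts(hc, cands),
    recovery_cond1 = recov
  )
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(logf, "run complete")
  invisible(summary)
}

#' Sensitivity and precision of a called set against planted truth
#'
#' Base-level: sensitivity is the fraction of planted bases covered by
#' calls, precision the fraction of called bases inside planted regions.
#'
#' @param called,truth `GRanges`.
#' @return A list: `sensitivity`, `precision`, `called_bases`,
#'   `truth_bases`.
#' @export
recovery_stats <- function(called, truth) {
  called <- GenomicRanges::reduce(as_granges(called), ignore.strand = TRUE)
  truth <- GenomicRanges::reduce(as_granges(truth), ignore.strand = TRUE)
  inter <- sum(GenomicRanges::width(
    GenomicRanges::intersect(called, truth, ignore.strand = TRUE)))
  cb <- sum(GenomicRanges::width(called))
  tb <- sum(GenomicRanges::width(truth))
  list(sensitivity = if (tb > 0) inter / tb else NA_real_,
       precision = if (cb > 0) inter / cb else NA_real_,
       called_bases = cb, truth_bases = tb)
}

#' Human-readable pipeline run report
#'
#' Reads `summary.json` from a run directory and formats the headline
#' numbers; the same lines are returned invisibly.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return Character vector of report lines, invisibly.
#' @export
pipeline_report <- function(run_dir) {
  path <- file.path(run_dir, "summary.json")
  if (!file.exists(path)) stop("no summary.json in ", run_dir)
  s <- jsonlite::read_json(path)
  fmt_pct <- function(x) {
    if (is.null(x) || is.na(x)) "n/a" else sprintf("%.1f%%", x)
  }
  lines <- c(
    sprintf("prescout run (seed %s)", s$seed),
    sprintf("planted regions: %s cond1 / %s cond2 / %s shared",
            s$n_planted$cond1, s$n_planted$cond2, s$n_planted$shared),
    sprintf("HC sets: %s enriched-in-1, %s enriched-in-2, %s common",
            s$hc$counts$enriched_in_1, s$hc$counts$enriched_in_2,
            s$hc$counts$common),
    sprintf("candidates: %s (TF union %s, TF intersect %s, conserved %s)",
            s$hc$evidence_pct$n_candidates,
            fmt_pct(s$hc$evidence_pct$pct_tf_union),
            fmt_pct(s$hc$evidence_pct$pct_tf_intersect),
            fmt_pct(s$hc$evidence_pct$pct_conserved)),
    sprintf("cond1 recovery: sensitivity %.3f, precision %.3f",
            s$recovery_cond1$sensitivity, s$recovery_cond1$precision)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
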