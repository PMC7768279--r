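#' Peak-calling configuration
#'
#' Collects the tunable parameters of the simplified broad peak caller and the
#' Poisson likelihood-ratio differential classifier.  Defaults mirror the
#' standard broad-mark workflow: peak cores at genome-wide FDR 0.01, linked
#' through bins at FDR 0.01, fragments extended to 200 bp, differential
#' regions at least 150 bp long at a log10 likelihood-ratio of 3.
#'
#' @param q_cutoff FDR threshold for peak core bins.
#' @param broad_cutoff Linking FDR threshold for broad peak extension; must be
#'   at least `q_cutoff`.
#' @param fragment_extension Fragment extension length in bp (used by the
#'   simulator when laying fragments; the caller sees extended coverage).
#' @param min_diff_length Minimum differential region length in bp.
#' @param diff_llr10_cutoff Signed log10 likelihood-ratio threshold for
#'   differential bins.
#' @return A list of class `PeakCallConfig`.
#' @export
peak_call_config <- function(q_cutoff = 0.01, broad_cutoff = 0.01,
                             fragment_extension = 200L,
                             min_diff_length = 150L,
                             diff_llr10_cutoff = 3.0) {
  stopifnot(q_cutoff > 0, q_cutoff <= broad_cutoff, broad_cutoff <= 1,
            fragment_extension > 0, min_diff_length > 0,
            diff_llr10_cutoff > 0)
  structure(
    list(q_cutoff = q_cutoff, broad_cutoff = broad_cutoff,
         fragment_extension = as.integer(fragment_extension),
         min_diff_length = as.integer(min_diff_length),
         diff_llr10_cutoff = diff_llr10_cutoff),
    class = "PeakCallConfig"
  )
}

# Centered running mean over a window of `w` bins (internal); shrinks at the
# chromosome edges.
running_mean <- function(x, w) {
  if (w <= 1L || length(x) <= 1L) return(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Deconvolve the forward fragment extension: a fragment starting at x
# elevates coverage over [x, x + ext), so an enriched coverage run [a, b]
# implies fragment starts over [a, b - ext].  Trim the trailing edge, never
# below one bin (internal).
trim_extension <- function(gr, ext, bin_size) {
  if (length(gr) == 0 || ext <= 0) return(gr)
  new_end <- pmax(GenomicRanges::end(gr) - ext,
                  GenomicRanges::start(gr) + bin_size - 1L)
  GenomicRanges::end(gr) <- new_end
  gr
}

# Collapse runs of flagged bins into a GRanges; `score` per bin is reduced by
# max over each run (internal).
bins_to_regions <- function(flags, scores, chrom, bin_size, min_len = 0L) {
  r <- rle(flags)
  end_bin <- cumsum(r$lengths)
  start_bin <- end_bin - r$lengths + 1L
  keep <- r$values & (r$lengths * bin_size >= min_len)
  if (!any(keep)) return(GenomicRanges::GRanges())
  starts <- (start_bin[keep] - 1L) * bin_size + 1L
  ends <- end_bin[keep] * bin_size
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  if (!is.null(scores)) {
    gr$score <- mapply(function(s, e) max(scores[s:e]),
                       start_bin[keep], end_bin[keep])
  }
  gr
}

#' Call enrichment peaks against a matched input control
#'
#' A simplified broad-mark peak caller.  For every bin the expected count is a
#' depth-scaled local control mean -- the maximum of the control bin itself, a
#' 1 kb centered window mean, and the genome-wide control mean (the floor,
#' a local-bias correction in the spirit of the standard callers).  The
#' per-bin p-value is the upper-tail Poisson probability `P(X >= k)`,
#' converted to q-values by Benjamini-Hochberg over all genome bins.  Core
#' bins satisfy `q <= q_cutoff`; with `broad = TRUE` cores are extended
#' through contiguous bins with `q <= broad_cutoff` and merged.  Because the
#' coverage model lays fragments forward from their start over
#' `fragment_extension` bp, an enriched coverage run overhangs the
#' underlying fragment-start region at its trailing edge by exactly the
#' extension; emitted regions are therefore trimmed by `fragment_extension`
#' at the 3' edge (never below one bin).  [classify_differential()] applies
#' the same deconvolution.
#'
#' @param treatment,control Raw `CoverageTrack`s on the same binning.
#' @param cfg A [peak_call_config()].
#' @param broad Extend peak cores through broad-cutoff bins (default).
#' @return A `GRanges` of peaks with a `score` column holding the best bin's
#'   `-log10(q)`, and `name` column `peak_1, peak_2, ...`.
#' @export
call_peaks <- function(treatment, control, cfg = peak_call_config(),
                       broad = TRUE) {
  stopifnot(is(treatment, "CoverageTrack"), is(control, "CoverageTrack"),
            is(cfg, "PeakCallConfig"))
  check_same_binning(treatment, control)
  if (control$total_fragments <= 0) stop("control track has no fragments")
  window_bins <- max(1L, as.integer(round(1000 / treatment$bin_size)))
  scale <- treatment$total_fragments / control$total_fragments
  ctrl_all <- unlist(control$bins, use.names = FALSE)
  genome_mean <- mean(ctrl_all)

  pvals <- lapply(names(treatment$bins), function(chrom) {
    k <- treatment$bins[[chrom]]
    cb <- control$bins[[chrom]]
    lambda <- scale * pmax(cb, running_mean(cb, window_bins), genome_mean)
    ppois(k - 1, lambda, lower.tail = FALSE)
  })
  q <- p.adjust(unlist(pvals, use.names = FALSE), method = "BH")
  qs <- split(q, rep(names(treatment$bins), lengths(treatment$bins)))
  qs <- qs[names(treatment$bins)]

  peaks <- lapply(names(treatment$bins), function(chrom) {
    qc <- qs[[chrom]]
    core <- qc <= cfg$q_cutoff
    if (broad) {
      linked <- qc <= cfg$broad_cutoff
      # keep linked runs that contain at least one core bin
      r <- rle(linked)
      end_bin <- cumsum(r$lengths)
      start_bin <- end_bin - r$lengths + 1L
      has_core <- mapply(function(s, e, v) v && any(core[s:e]),
                         start_bin, end_bin, r$values)
      flags <- inverse.rle(list(lengths = r$lengths, values = has_core))
    } else {
      flags <- core
    }
    trim_extension(
      bins_to_regions(flags, -log10(pmax(qc, 1e-300)), chrom,
                      treatment$bin_size),
      cfg$fragment_extension, treatment$bin_size)
  })
  out <- suppressWarnings(do.call(c, peaks))
  if (length(out)) out$name <- paste0("peak_", seq_along(out))
  out
}

log_pois <- function(k, lambda) {
  # Poisson log-density valid for real-valued k (depth-scaled counts)
  ifelse(lambda <= 0, ifelse(k == 0, 0, -Inf),
         k * log(lambda) - lambda - lgamma(k + 1))
}

#' Classify bins as condition-enriched or common between two conditions
#'
#' A Poisson likelihood-ratio differential classifier.  Counts are
#' depth-scaled to the smaller library; per bin the signed log10 likelihood
#' ratio compares the model in which each condition has its own rate (floored
#' at a pseudocount of 1) against the common-rate model `m = (k1 + k2) / 2`:
#' `LLR10 = log10[Pois(k1; k1+) Pois(k2; k2+) / (Pois(k1; m) Pois(k2; m))]`,
#' with the sign taken from `k1 - k2`.  Contiguous same-sign runs with
#' `|LLR10| >= diff_llr10_cutoff` and total length at least `min_diff_length`
#' become `enriched_in_1` / `enriched_in_2` regions.  Bins that are enriched
#' against a shared input in both conditions but fall below the differential
#' cutoff form the `common` regions.
#'
#' @param cond1,cond2 Raw `CoverageTrack`s on the same binning.
#' @param cfg A [peak_call_config()].
#' @param input Optional shared input `CoverageTrack` used to delimit common
#'   peaks.  When `NULL`, a flat pseudo-input at the genome-wide median bin
#'   rate of the depth-scaled conditions is used.
#' @return A list of class `DifferentialResult` with mutually disjoint
#'   `GRanges` components `enriched_in_1`, `enriched_in_2` and `common`.
#' @export
classify_differential <- function(cond1, cond2, cfg = peak_call_config(),
                                  input = NULL) {
  stopifnot(is(cond1, "CoverageTrack"), is(cond2, "CoverageTrack"),
            is(cfg, "PeakCallConfig"))
  check_same_binning(cond1, cond2)
  if (sum(lengths(cond1$bins)) == 0L) stop("zero-length coverage tracks")
  depth <- min(cond1$total_fragments, cond2$total_fragments)
  s1 <- depth / cond1$total_fragments
  s2 <- depth / cond2$total_fragments
  bin_size <- cond1$bin_size

  enriched <- list(`1` = list(), `2` = list())
  llr_by_chrom <- list()
  for (chrom in names(cond1$bins)) {
    k1 <- cond1$bins[[chrom]] * s1
    k2 <- cond2$bins[[chrom]] * s2
    m <- pmax((k1 + k2) / 2, 1)
    llr <- (log_pois(k1, pmax(k1, 1)) + log_pois(k2, pmax(k2, 1)) -
              log_pois(k1, m) - log_pois(k2, m)) / log(10)
    sgn <- sign(k1 - k2)
    sllr <- llr * sgn
    llr_by_chrom[[chrom]] <- sllr
    enriched[["1"]][[chrom]] <- trim_extension(
      bins_to_regions(sllr >= cfg$diff_llr10_cutoff, sllr, chrom, bin_size,
                      cfg$min_diff_length),
      cfg$fragment_extension, bin_size)
    enriched[["2"]][[chrom]] <- trim_extension(
      bins_to_regions(sllr <= -cfg$diff_llr10_cutoff, -sllr, chrom, bin_size,
                      cfg$min_diff_length),
      cfg$fragment_extension, bin_size)
  }
  enr1 <- suppressWarnings(do.call(c, unname(enriched[["1"]])))
  enr2 <- suppressWarnings(do.call(c, unname(enriched[["2"]])))

  if (is.null(input)) {
    med <- median(c(unlist(lapply(cond1$bins, function(b) b * s1)),
                    unlist(lapply(cond2$bins, function(b) b * s2))))
    input <- coverage_track(
      lapply(cond1$bins, function(b) rep(max(med, 0.5), length(b))),
      bin_size, total_fragments = depth
    )
  }
  scaled1 <- coverage_track(lapply(cond1$bins, function(b) b * s1), bin_size,
                            total_fragments = depth)
  scaled2 <- coverage_track(lapply(cond2$bins, function(b) b * s2), bin_size,
                            total_fragments = depth)
  p1 <- call_peaks(scaled1, input, cfg)
  p2 <- call_peaks(scaled2, input, cfg)
  common <- interval_intersect(p1, p2)
  common <- suppressWarnings(
    GenomicRanges::setdiff(common, interval_union(list(enr1, enr2)),
                           ignore.strand = TRUE))
  common <- common[GenomicRanges::width(common) >= cfg$min_diff_length]

  structure(
    list(enriched_in_1 = GenomicRanges::sort(enr1),
         enriched_in_2 = GenomicRanges::sort(enr2),
         common = GenomicRanges::sort(common)),
    class = "DifferentialResult"
  )
}

#' @export
print.DifferentialResult <- function(x, ...) {
  cat(sprintf(
    "DifferentialResult: %d enriched-in-1, %d enriched-in-2, %d common regions\n",
    length(x$enriched_in_1), length(x$enriched_in_2), length(x$common)
  ))
  invisible(x)
}
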