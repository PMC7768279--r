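#' High-confidence peaks from two replicates
#'
#' Merges peaks separated by at most `merge_gap` within each replicate, then
#' takes the base-level intersection of the two replicates.  The order is
#' fixed -- merge first, intersect second -- because merging within a
#' replicate can create intersection that would otherwise be missed across
#' the ragged boundaries typical of broad histone-modification peaks.
#'
#' @param rep1,rep2 Peak `GRanges` for the two biological replicates of the
#'   same class.
#' @param merge_gap Merge gap in bp applied within each replicate first.
#' @return A merged `GRanges` of high-confidence spans.
#' @export
hc_peaks <- function(rep1, rep2, merge_gap = 500L) {
  interval_intersect(merge_within(rep1, merge_gap),
                     merge_within(rep2, merge_gap))
}

#' High-confidence differential peak sets from two replicates
#'
#' Applies [hc_peaks()] to each differential class (enriched in condition 1,
#' enriched in condition 2, common), then restores mutual disjointness:
#' merging within a class can re-create overlap across classes, which is
#' trimmed with priority to the enriched classes over common (overlap between
#' the two enriched classes, which can only arise through merging, is dropped
#' from both).
#'
#' @param diff_rep1,diff_rep2 `DifferentialResult`s from
#'   [classify_differential()], one per replicate.
#' @param merge_gap Merge gap in bp.
#' @return A `DifferentialResult` of high-confidence sets.
#' @export
build_hc_differential <- function(diff_rep1, diff_rep2, merge_gap = 500L) {
  stopifnot(is(diff_rep1, "DifferentialResult"),
            is(diff_rep2, "DifferentialResult"))
  enr1 <- hc_peaks(diff_rep1$enriched_in_1, diff_rep2$enriched_in_1, merge_gap)
  enr2 <- hc_peaks(diff_rep1$enriched_in_2, diff_rep2$enriched_in_2, merge_gap)
  common <- hc_peaks(diff_rep1$common, diff_rep2$common, merge_gap)
  both <- interval_intersect(enr1, enr2)
  if (length(both)) {
    enr1 <- suppressWarnings(
      GenomicRanges::setdiff(enr1, both, ignore.strand = TRUE))
    enr2 <- suppressWarnings(
      GenomicRanges::setdiff(enr2, both, ignore.strand = TRUE))
  }
  common <- suppressWarnings(
    GenomicRanges::setdiff(common, interval_union(list(enr1, enr2)),
                           ignore.strand = TRUE))
  structure(
    list(enriched_in_1 = GenomicRanges::sort(enr1),
         enriched_in_2 = GenomicRanges::sort(enr2),
         common = GenomicRanges::sort(common)),
    class = "DifferentialResult"
  )
}

#' Annotate candidate regulatory elements with overlap evidence
#'
#' Flags each high-confidence enriched peak for overlap with each
#' transcription-factor binding set (plus union/intersection summaries),
#' conserved elements, and per-cell-type accessibility sets, and records the
#' nearest gene by TSS distance (ties broken alphabetically).
#'
#' @param hc_enriched `GRanges` of high-confidence enriched peaks (an
#'   optional `score` column is carried into the table).
#' @param tf_sets Named list of TF-binding `GRanges`.
#' @param conserved Optional `GRanges` of conserved elements.
#' @param accessibility Optional named list of accessibility `GRanges` (one
#'   per cell type).
#' @param tss_table Optional data.frame with columns `gene`, `chrom`, `pos`
#'   (1-based TSS position) and optionally `strand`.
#' @param diff_class Label stored in the `diff_class` column.
#' @return A data.frame of candidates (class `CandidateRE`), one row per
#'   peak, with BED-convention coordinates, per-evidence logical flags,
#'   `tf_union`, `tf_intersect`, `n_tf`, `n_acc`, `nearest_gene` and
#'   `tss_distance` columns.
#' @export
annotate_candidates <- function(hc_enriched, tf_sets = list(),
                                conserved = NULL, accessibility = list(),
                                tss_table = NULL,
                                diff_class = "cond1_enriched") {
  gr <- as_granges(hc_enriched)
  n <- length(gr)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name)
           else paste0("cand_", seq_len(n)),
    score = if (!is.null(gr$score)) gr$score else 0,
    diff_class = rep(diff_class, n),
    stringsAsFactors = FALSE
  )
  stopifnot(is.list(tf_sets), is.list(accessibility))
  tf_flags <- matrix(FALSE, n, length(tf_sets))
  for (i in seq_along(tf_sets)) {
    tf_flags[, i] <- overlaps_any(gr, tf_sets[[i]])
    out[[paste0("tf_", names(tf_sets)[i])]] <- tf_flags[, i]
  }
  out$n_tf <- if (length(tf_sets)) rowSums(tf_flags) else rep(0L, n)
  out$tf_union <- out$n_tf > 0L
  out$tf_intersect <- length(tf_sets) > 0L & out$n_tf == length(tf_sets)
  out$conserved <- if (!is.null(conserved)) overlaps_any(gr, conserved)
                   else rep(FALSE, n)
  acc_flags <- matrix(FALSE, n, length(accessibility))
  for (i in seq_along(accessibility)) {
    acc_flags[, i] <- overlaps_any(gr, accessibility[[i]])
    out[[paste0("acc_", names(accessibility)[i])]] <- acc_flags[, i]
  }
  out$n_acc <- if (length(accessibility)) rowSums(acc_flags) else rep(0L, n)
  out$nearest_gene <- NA_character_
  out$tss_distance <- NA_real_
  if (!is.null(tss_table) && nrow(tss_table) > 0 && n > 0) {
    tss <- GenomicRanges::GRanges(tss_table$chrom,
                                  IRanges::IRanges(tss_table$pos, width = 1L))
    # distance to every TSS on the same chromosome; nearest wins, ties by
    # alphabetical gene name
    d <- suppressWarnings(
      GenomicRanges::distance(rep(gr, each = nrow(tss_table)),
                              rep(tss, n), ignore.strand = TRUE))
    dm <- matrix(d, nrow = nrow(tss_table))
    for (j in seq_len(n)) {
      dj <- dm[, j]
      if (all(is.na(dj))) next
      best <- which(dj == min(dj, na.rm = TRUE))
      best <- best[order(tss_table$gene[best])][1]
      out$nearest_gene[j] <- tss_table$gene[best]
      out$tss_distance[j] <- dj[best]
    }
  }
  class(out) <- c("CandidateRE", "data.frame")
  out
}

#' Rank candidate regulatory elements
#'
#' Orders candidates lexicographically (descending) on: overlap with all TF
#' sets, number of TF sets hit, conservation, number of selective
#' accessibility hits, then peak score; remaining ties are broken
#' deterministically by coordinate.
#'
#' @param candidates A `CandidateRE` data.frame from [annotate_candidates()].
#' @return The candidates reordered, with a `rank` column prepended.
#' @export
rank_candidates <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  ord <- order(-candidates$tf_intersect, -candidates$n_tf,
               -candidates$conserved, -candidates$n_acc, -candidates$score,
               candidates$chrom, candidates$start, candidates$end)
  out <- candidates[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("CandidateRE", "data.frame")
  out
}

#' Summarize high-confidence sets and candidate evidence
#'
#' Bookkeeping report: interval counts and total bases per differential
#' class, and the percentage of candidates carrying TF-union, TF-intersect
#' and conservation evidence.
#'
#' @param hc A `DifferentialResult` of high-confidence sets.
#' @param candidates A `CandidateRE` data.frame (may be empty).
#' @return A list with components `counts`, `bases` and `evidence_pct`,
#'   suitable for JSON serialization.
#' @export
summarize_counts <- function(hc, candidates = NULL) {
  stopifnot(is(hc, "DifferentialResult"))
  counts <- vapply(hc, length, 0L)
  bases <- vapply(hc, function(g) sum(GenomicRanges::width(g)), 0)
  ev <- list(pct_tf_union = NA_real_, pct_tf_intersect = NA_real_,
             pct_conserved = NA_real_, n_candidates = 0L)
  if (!is.null(candidates) && nrow(candidates) > 0) {
    ev$n_candidates <- nrow(candidates)
    ev$pct_tf_union <- 100 * mean(candidates$tf_union)
    ev$pct_tf_intersect <- 100 * mean(candidates$tf_intersect)
    ev$pct_conserved <- 100 * mean(candidates$conserved)
  }
  list(counts = as.list(counts), bases = as.list(bases), evidence_pct = ev)
}
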