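#' Genomic interval utilities
#'
#' All peak post-processing in prescout runs on [GenomicRanges::GRanges]
#' objects.  In memory, coordinates follow the usual GRanges convention
#' (1-based, closed); on disk the package reads and writes BED (0-based,
#' half-open), and [read_bed()]/[write_bed()] perform the conversion.  Strand
#' is ignored throughout: histone-modification peaks are unstranded.
#'
#' @name intervals
NULL

# Coerce a peak-like object (GRanges or data.frame with chrom/start/end in
# BED convention) to an unstranded GRanges.  Internal currency converter.
as_granges <- function(x) {
  if (is(x, "GRanges")) {
    return(x)
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    gr <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
    )
    extra <- setdiff(names(x), c("chrom", "start", "end"))
    if (length(extra)) S4Vectors::mcols(gr) <- x[extra]
    return(gr)
  }
  stop("cannot interpret object of class '", class(x)[1], "' as intervals")
}

# Canonical form: sorted seqlevels, sorted ranges (internal).
tidy_intervals <- function(gr) {
  GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr), ignore.strand = TRUE)
}

validate_intervals <- function(gr, what = "interval set") {
  # GRanges already guarantees end >= start (width >= 1) and start >= 1;
  # guard against zero-width and empty seqnames that can arise from coercion.
  if (any(GenomicRanges::width(gr) < 1)) {
    bad <- which(GenomicRanges::width(gr) < 1)[1]
    stop(what, ": record ", bad, " has end <= start")
  }
  invisible(gr)
}

#' Merge intervals separated by at most a given gap
#'
#' Coalesces intervals on the same chromosome whose separation (bases strictly
#' between them) is less than or equal to `max_gap`.  Merging is transitive:
#' the operation is run to fixpoint.  Overlapping and abutting intervals are
#' always merged (they have gap <= 0).  This reproduces the common
#' `bedtools merge -d` post-processing used to stabilise broad
#' histone-modification peak boundaries (a 500 bp gap by default downstream).
#'
#' @param x A `GRanges` (or BED-style data.frame) of intervals.
#' @param max_gap Non-negative integer gap in bp; intervals separated by
#'   `max_gap` or fewer bases are merged.
#' @return A sorted, merged `GRanges` with no metadata columns.  The result
#'   carries `metadata(x)$merged = TRUE`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 351), c(100, 400)))
#' merge_within(gr, 500)
#' @export
merge_within <- function(x, max_gap = 0L) {
  stopifnot(is.numeric(max_gap), length(max_gap) == 1L, max_gap >= 0)
  gr <- validate_intervals(as_granges(x))
  out <- tidy_intervals(GenomicRanges::reduce(
    GenomicRanges::sort(gr),
    min.gapwidth = as.integer(max_gap) + 1L,
    ignore.strand = TRUE
  ))
  S4Vectors::metadata(out)$merged <- TRUE
  out
}

#' Base-level intersection of two interval sets
#'
#' Returns the maximal spans covered by both inputs.  Used to build
#' high-confidence peak sets from two biological replicates.
#'
#' @param a,b `GRanges` interval sets.
#' @return A merged `GRanges` of the bases present in both `a` and `b`.
#' @export
interval_intersect <- function(a, b) {
  a <- GenomicRanges::reduce(as_granges(a), ignore.strand = TRUE)
  b <- GenomicRanges::reduce(as_granges(b), ignore.strand = TRUE)
  # sets may legitimately live on disjoint chromosomes; silence the
  # no-common-seqlevels warning
  out <- tidy_intervals(
    suppressWarnings(GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
  S4Vectors::metadata(out)$merged <- TRUE
  out
}

#' Base-level union of interval sets
#'
#' @param sets A list of `GRanges` interval sets (possibly empty).
#' @return A merged `GRanges` covering every base present in any input set.
#' @export
interval_union <- function(sets) {
  stopifnot(is.list(sets))
  if (length(sets) == 0L) {
    out <- GenomicRanges::GRanges()
  } else {
    grl <- lapply(sets, function(s) {
      g <- as_granges(s)
      S4Vectors::mcols(g) <- NULL
      g
    })
    out <- tidy_intervals(GenomicRanges::reduce(
      suppressWarnings(do.call(c, unname(grl))),
      ignore.strand = TRUE
    ))
  }
  S4Vectors::metadata(out)$merged <- TRUE
  out
}

#' Flag query intervals that overlap any evidence interval
#'
#' An interval counts as overlapping when it shares at least one base with an
#' evidence interval; intervals that merely touch (half-open BED coordinates)
#' do not overlap.
#'
#' @param query,evidence `GRanges` interval sets.
#' @return A logical vector, one flag per query interval.
#' @export
overlaps_any <- function(query, evidence) {
  suppressWarnings(
    IRanges::overlapsAny(as_granges(query), as_granges(evidence),
                         ignore.strand = TRUE)
  )
}

#' Read a BED3/BED6 file
#'
#' Parses tab-separated BED with 3-6 columns (chrom, start, end, then optional
#' name, score, strand).  `track`, `browser` and `#` comment lines are skipped
#' with a warning.  Malformed lines (fewer than three fields, non-numeric or
#' inverted coordinates) abort with the offending line number.
#'
#' @param path Path to a BED file.
#' @return A `GRanges`; `name` and `score` columns are preserved as metadata
#'   columns when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (any(!keep & nzchar(trimws(lines)))) {
    warning("skipped ", sum(!keep & nzchar(trimws(lines))),
            " header/track line(s) in ", path)
  }
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", lineno[which(nf < 3L)[1]], " in ", path,
         ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) | end <= start | start < 0)
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         ": invalid coordinates")
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1, end = end))
  if (all(nf >= 4L)) gr$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) {
    gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  gr
}

#' Write intervals as BED
#'
#' Writes BED3, or BED6 (with `.` strand) when `name` or `score` metadata
#' columns are present.  Coordinates are converted to the 0-based half-open
#' BED convention.  `write_bed(read_bed(path), path)` is the identity on
#' canonical records.
#'
#' @param x A `GRanges` (or BED-style data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  gr <- as_granges(x)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if (any(c("name", "score") %in% names(mc))) {
    df$name <- if ("name" %in% names(mc)) as.character(mc$name) else "."
    df$score <- if ("score" %in% names(mc)) mc$score else 0
    df$strand <- "."
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom-sizes file
#'
#' @param path Two-column tab-separated file: chromosome name, length.
#' @return A named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df$length), df$chrom)
}
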