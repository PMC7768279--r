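#' Binned genome coverage tracks
#'
#' A `CoverageTrack` holds fixed-width per-chromosome bin values (raw fragment
#' counts or RPKM), the bin size, and the total fragment count of the library
#' it came from.  It is the input to [call_peaks()] and
#' [classify_differential()].
#'
#' @param bins Named list of non-negative numeric vectors, one per chromosome;
#'   element `i` covers bases `[(i-1)*bin_size, i*bin_size)`.
#' @param bin_size Bin width in bp.
#' @param total_fragments Total number of fragments in the library; defaults
#'   to the sum of all bin values (exact for raw count tracks built from
#'   non-extended fragments, an approximation otherwise).
#' @param normalized Logical; `TRUE` for RPKM tracks.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(bins, bin_size, total_fragments = NULL,
                           normalized = FALSE) {
  stopifnot(is.list(bins), length(bins) > 0, !is.null(names(bins)),
            bin_size >= 1)
  if (any(vapply(bins, function(b) any(b < 0) || any(!is.finite(b)), TRUE))) {
    stop("coverage bins must be finite and non-negative")
  }
  if (is.null(total_fragments)) total_fragments <- sum(unlist(bins))
  structure(
    list(bins = lapply(bins, as.numeric), bin_size = as.integer(bin_size),
         total_fragments = as.numeric(total_fragments),
         normalized = isTRUE(normalized)),
    class = "CoverageTrack"
  )
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf(
    "CoverageTrack: %d chromosome(s), bin %d bp, %d bins, %.3g fragments%s\n",
    length(x$bins), x$bin_size, sum(lengths(x$bins)), x$total_fragments,
    if (x$normalized) " (RPKM)" else ""
  ))
  invisible(x)
}

check_same_binning <- function(a, b) {
  if (a$bin_size != b$bin_size) {
    stop("tracks have different bin sizes (", a$bin_size, " vs ", b$bin_size, ")")
  }
  if (!identical(names(a$bins), names(b$bins)) ||
      !identical(lengths(a$bins), lengths(b$bins))) {
    stop("tracks cover different chromosomes or lengths")
  }
  invisible(TRUE)
}

#' RPKM-normalize a coverage track
#'
#' Each bin value becomes `count / (bin_kb * million_fragments)`, i.e. reads
#' per kilobase per million mapped fragments.
#'
#' @param track A raw `CoverageTrack` with `total_fragments > 0`.
#' @return A `CoverageTrack` with `normalized = TRUE`.
#' @export
normalize_rpkm <- function(track) {
  stopifnot(is(track, "CoverageTrack"))
  if (track$normalized) stop("track is already RPKM-normalized")
  if (track$total_fragments <= 0) stop("total_fragments must be > 0")
  denom <- (track$bin_size / 1e3) * (track$total_fragments / 1e6)
  out <- track
  out$bins <- lapply(track$bins, function(b) b / denom)
  out$normalized <- TRUE
  out
}

#' Read / write bedGraph coverage
#'
#' `read_bedgraph()` parses a fixed-step bedGraph (chrom, start, end, value;
#' 0-based half-open) into a `CoverageTrack`; runs of equal values are
#' expanded, and every record must align to the bin grid.  `write_bedgraph()`
#' writes the complement, run-length compressing equal adjacent bins.
#'
#' @param path File path.
#' @param bin_size Bin width in bp of the track on disk.
#' @param total_fragments,normalized Passed to [coverage_track()].
#' @return A `CoverageTrack` (read) or `path` invisibly (write).
#' @export
read_bedgraph <- function(path, bin_size, total_fragments = NULL,
                          normalized = FALSE) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  if (any((df$start %% bin_size) != 0 | (df$end %% bin_size) != 0)) {
    stop("bedGraph records do not align to a ", bin_size, " bp grid")
  }
  bins <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), ]
    n <- max(d$end) / bin_size
    v <- numeric(n)
    idx <- sequence((d$end - d$start) / bin_size, from = d$start / bin_size + 1)
    v[idx] <- rep(d$value, (d$end - d$start) / bin_size)
    v
  })
  coverage_track(bins, bin_size, total_fragments, normalized)
}

#' @rdname read_bedgraph
#' @param track A `CoverageTrack` to serialize.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(is(track, "CoverageTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$bins)) {
    r <- rle(track$bins[[chrom]])
    end <- cumsum(r$lengths) * track$bin_size
    start <- end - r$lengths * track$bin_size
    writeLines(sprintf("%s\t%d\t%d\t%g", chrom, start, end, r$values), con)
  }
  invisible(path)
}

# GRanges of all bins of a track, in storage order (internal).
track_bins_gr <- function(track) {
  per <- lapply(names(track$bins), function(chrom) {
    n <- length(track$bins[[chrom]])
    GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(start = (seq_len(n) - 1L) * track$bin_size + 1L,
                       width = track$bin_size)
    )
  })
  suppressWarnings(do.call(c, per))
}
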