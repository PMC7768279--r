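#' Define a sequence motif
#'
#' A motif is either an IUPAC consensus string or a position weight matrix
#' (4 x width, rows A/C/G/T, columns summing to one).  PWM matches are scored
#' by log2 odds against a uniform background; a window is a hit when its
#' score reaches `match_threshold` times the maximum achievable score.
#'
#' @param id Motif identifier.
#' @param consensus IUPAC consensus string (e.g. `"TAATTA"`, `"TGASTCA"`).
#' @param pwm Numeric 4 x width matrix with rownames A, C, G, T.
#' @param match_threshold Fraction of the maximum log-odds score required for
#'   a PWM hit (default 0.8).
#' @return A list of class `Motif`.
#' @export
motif <- function(id, consensus = NULL, pwm = NULL, match_threshold = 0.8) {
  if (is.null(consensus) == is.null(pwm)) {
    stop("supply exactly one of 'consensus' or 'pwm'")
  }
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    valid <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
    if (!all(strsplit(consensus, "")[[1]] %in% valid)) {
      stop("consensus contains non-IUPAC letters")
    }
  }
  if (!is.null(pwm)) {
    pwm <- as.matrix(pwm)
    stopifnot(nrow(pwm) == 4)
    if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
    stopifnot(identical(rownames(pwm), c("A", "C", "G", "T")))
    if (any(abs(colSums(pwm) - 1) > 1e-6)) {
      stop("PWM columns must sum to 1")
    }
    stopifnot(match_threshold > 0, match_threshold <= 1)
  }
  structure(list(id = id, consensus = consensus, pwm = pwm,
                 match_threshold = match_threshold),
            class = "Motif")
}

# log2-odds PWM scan of one strand of character sequences; N scores -Inf.
# Returns per-sequence max score and count above `cut` (internal).
pwm_scan_counts <- function(seqs, lodds, cut) {
  w <- ncol(lodds)
  idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    if (n < w) return(0L)
    code <- unname(idx[ch])            # NA for N and anything else
    sc <- numeric(n - w + 1L)
    for (j in seq_len(w)) {
      col <- lodds[, j][code[j:(j + n - w)]]
      col[is.na(col)] <- -Inf
      sc <- sc + col
    }
    sum(sc >= cut)
  }, 0L)
}

#' Scan sequences for motif occurrences
#'
#' Both strands are scanned; positions containing N never match.  Consensus
#' motifs match any window compatible with the IUPAC codes; PWM motifs match
#' windows whose log2-odds score (uniform background) reaches
#' `match_threshold` of the maximum achievable.
#'
#' @param seqs A [Biostrings::DNAStringSet] or character vector of sequences
#'   over A/C/G/T/N.
#' @param m A [motif()].
#' @return A data.frame with one row per sequence: `seq` (name), `count`
#'   (occurrences over both strands) and `hit` (logical).
#' @export
scan_motif <- function(seqs, m) {
  stopifnot(is(m, "Motif"))
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  stopifnot(is(seqs, "DNAStringSet"))
  nm <- if (!is.null(names(seqs))) names(seqs)
        else paste0("seq_", seq_along(seqs))
  if (!is.null(m$consensus)) {
    # fixed = pattern FALSE / subject TRUE: IUPAC codes in the pattern match
    # their base sets, while N in the subject matches nothing
    fwd <- Biostrings::vcountPattern(m$consensus, seqs,
                                     fixed = c(pattern = FALSE, subject = TRUE))
    rev <- Biostrings::vcountPattern(
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(m$consensus))),
      seqs, fixed = c(pattern = FALSE, subject = TRUE))
    count <- fwd + rev
  } else {
    lodds <- log2(pmax(m$pwm, 1e-4) / 0.25)
    cut <- m$match_threshold * sum(apply(lodds, 2, max))
    chr <- as.character(seqs)
    rc <- as.character(Biostrings::reverseComplement(seqs))
    count <- pwm_scan_counts(chr, lodds, cut) + pwm_scan_counts(rc, lodds, cut)
  }
  data.frame(seq = nm, count = as.integer(count), hit = count > 0L,
             stringsAsFactors = FALSE)
}

#' Motif fold enrichment in target versus background sequences
#'
#' Fold enrichment is the percentage of target sequences containing the motif
#' divided by the percentage of background sequences containing it.  The
#' p-value is the upper-tail binomial probability of observing at least the
#' target hit count at the background hit rate.  When the background has zero
#' hits the fold is reported as `Inf` and the binomial rate is floored at
#' `0.5 / n_background`.
#'
#' @param targets,background Sequence sets accepted by [scan_motif()].
#' @param m A [motif()].
#' @return A list: `fold`, `p`, `pct_targets`, `pct_background`, and the hit
#'   counts `k_target`, `n_target`, `k_background`, `n_background`.
#' @export
motif_fold_enrichment <- function(targets, background, m) {
  st <- scan_motif(targets, m)
  sb <- scan_motif(background, m)
  nt <- nrow(st); nb <- nrow(sb)
  if (nt == 0 || nb == 0) stop("target and background sets must be non-empty")
  kt <- sum(st$hit); kb <- sum(sb$hit)
  pt <- kt / nt; pb <- kb / nb
  fold <- if (pb > 0) pt / pb else if (pt > 0) Inf else NaN
  rate <- max(pb, 0.5 / nb)
  p <- pbinom(kt - 1, nt, rate, lower.tail = FALSE)
  list(fold = fold, p = p, pct_targets = 100 * pt, pct_background = 100 * pb,
       k_target = kt, n_target = nt, k_background = kb, n_background = nb)
}
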