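# Independent brute-force oracles used across the test files.  These stay
# deliberately naive (per-base bitmaps, O(n^2) fixpoints, sliding windows,
# full enumerations) so they share no code path with the implementation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

TOY_GENOME <- c(chrA = 10000L, chrB = 10000L)

# --- per-base bitmap oracle ------------------------------------------------

# GRanges -> list of per-chromosome logical vectors over the toy genome
bitmap_of <- function(gr, genome = TOY_GENOME) {
  bm <- lapply(genome, function(len) logical(len))
  for (i in seq_along(gr)) {
    ch <- as.character(seqnames(gr))[i]
    bm[[ch]][start(gr)[i]:min(end(gr)[i], genome[[ch]])] <- TRUE
  }
  bm
}

bitmap_to_gr <- function(bm) {
  pieces <- lapply(names(bm), function(ch) {
    r <- rle(bm[[ch]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(GRanges())
    GRanges(ch, IRanges(s[keep], e[keep]))
  })
  suppressWarnings(do.call(c, pieces))
}

gr_identical_bases <- function(a, b, genome = TOY_GENOME) {
  identical(bitmap_of(a, genome), bitmap_of(b, genome))
}

random_interval_set <- function(n, genome = TOY_GENOME, max_w = 400L) {
  ch <- sample(names(genome), n, replace = TRUE)
  s <- vapply(ch, function(c) sample.int(genome[[c]] - max_w, 1L), 0L)
  w <- sample.int(max_w, n, replace = TRUE)
  GRanges(ch, IRanges(s, width = w))
}

# --- O(n^2) pairwise-coalescence merge oracle ------------------------------

merge_oracle <- function(gr, max_gap) {
  iv <- data.frame(ch = as.character(seqnames(gr)), s = start(gr),
                   e = end(gr), stringsAsFactors = FALSE)
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i <= nrow(iv)) {
      j <- i + 1L
      while (j <= nrow(iv)) {
        if (iv$ch[i] == iv$ch[j]) {
          gap <- max(iv$s[i], iv$s[j]) - min(iv$e[i], iv$e[j]) - 1L
          if (gap <= max_gap) {
            iv$s[i] <- min(iv$s[i], iv$s[j])
            iv$e[i] <- max(iv$e[i], iv$e[j])
            iv <- iv[-j, , drop = FALSE]
            merged_any <- TRUE
            next
          }
        }
        j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  iv <- iv[order(iv$ch, iv$s), ]
  GRanges(iv$ch, IRanges(iv$s, iv$e))
}

# --- sliding-window motif oracle -------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                   Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                   K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                   D = c("A", "G", "T"), H = c("A", "C", "T"),
                   V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

consensus_count_oracle <- function(seq, consensus) {
  count_one_strand <- function(s, pat) {
    p <- strsplit(pat, "")[[1]]
    ch <- strsplit(s, "")[[1]]
    w <- length(p)
    n <- length(ch)
    if (n < w) return(0L)
    hits <- 0L
    for (i in 1:(n - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!(ch[i + j - 1L] %in% IUPAC_SETS[[p[j]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- hits + 1L
    }
    hits
  }
  count_one_strand(seq, consensus) + count_one_strand(revcomp_chr(seq),
                                                      consensus)
}

pwm_count_oracle <- function(seq, pwm, threshold) {
  lodds <- log2(pmax(pwm, 1e-4) / 0.25)
  cut <- threshold * sum(apply(lodds, 2, max))
  count_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    w <- ncol(lodds)
    n <- length(ch)
    if (n < w) return(0L)
    hits <- 0L
    for (i in 1:(n - w + 1L)) {
      sc <- 0
      for (j in seq_len(w)) {
        row <- match(ch[i + j - 1L], c("A", "C", "G", "T"))
        sc <- sc + if (is.na(row)) -Inf else lodds[row, j]
      }
      if (sc >= cut) hits <- hits + 1L
    }
    hits
  }
  count_one(seq) + count_one(revcomp_chr(seq))
}

# --- exact 2x2 enumeration oracle ------------------------------------------

fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  lprob <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(-Inf)
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
      lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(c) -
      lfactorial(d)
  }
  lp_obs <- lprob(tab[1, 1])
  total <- 0
  for (a in 0:min(r1, c1)) {
    lp <- lprob(a)
    if (is.finite(lp) && lp <= lp_obs + log(1 + 1e-7)) total <- total + exp(lp)
  }
  min(total, 1)
}

# --- simple triangular pseudo-spike builder (closed-form half-width) -------

triangle_spike <- function(fs, base = -60, peak = 20, rise_ms = 0.4,
                           fall_ms = 0.6, pad_ms = 20) {
  up <- seq(base, peak, length.out = round(rise_ms / 1000 * fs) + 1L)
  dn <- seq(peak, base, length.out = round(fall_ms / 1000 * fs) + 1L)[-1]
  c(rep(base, round(pad_ms / 1000 * fs)), up, dn,
    rep(base, round(pad_ms / 1000 * fs)))
}
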