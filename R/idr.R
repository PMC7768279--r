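#' IDR copula-mixture parameters
#'
#' Starting values for the two-component Gaussian copula mixture behind the
#' irreproducible discovery rate.  The reproducible component is bivariate
#' normal with common mean `mu`, standard deviation `sigma` and correlation
#' `rho`, mixed with weight `pi`; the irreproducible component is standard
#' bivariate normal with zero correlation.  The defaults are the convention
#' for replicate peak scores on a log10 fold-change scale.
#'
#' @param mu Reproducible-component mean.
#' @param sigma Reproducible-component standard deviation (> 0).
#' @param rho Reproducible-component correlation (between -1 and 1).
#' @param pi Reproducible mixing proportion (between 0 and 1).
#' @return A list of class `IDRParams`.
#' @export
idr_params <- function(mu = 2.6, sigma = 1.3, rho = 0.8, pi = 0.7) {
  stopifnot(sigma > 0, rho > -1, rho < 1, pi > 0, pi < 1)
  structure(list(mu = mu, sigma = sigma, rho = rho, pi = pi),
            class = "IDRParams")
}

#' Pair peaks across two replicates by overlap
#'
#' Forms one score pair per overlapping peak pair; each peak contributes to at
#' most one pair.  Candidate pairs are ranked by overlap width (largest
#' first), ties broken by leftmost coordinate, and assigned greedily.
#'
#' @param peaks1,peaks2 Scored `GRanges` peak sets (a `score` metadata column
#'   is required, e.g. from [call_peaks()]).
#' @return A `GRanges` of the replicate-1 peak intervals of each pair with
#'   metadata columns `score1` and `score2`.
#' @export
match_replicate_peaks <- function(peaks1, peaks2) {
  p1 <- as_granges(peaks1)
  p2 <- as_granges(peaks2)
  if (is.null(p1$score) || is.null(p2$score)) {
    stop("both peak sets must carry a 'score' metadata column")
  }
  hits <- GenomicRanges::findOverlaps(p1, p2, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    out <- p1[0]
    out$score1 <- numeric(0)
    out$score2 <- numeric(0)
    S4Vectors::mcols(out) <- S4Vectors::mcols(out)[c("score1", "score2")]
    return(out)
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(p1)[qh], GenomicRanges::ranges(p2)[sh]))
  ord <- order(-ov, GenomicRanges::start(p1)[qh], GenomicRanges::start(p2)[sh])
  used1 <- logical(length(p1))
  used2 <- logical(length(p2))
  keep <- logical(length(ord))
  for (i in ord) {
    if (!used1[qh[i]] && !used2[sh[i]]) {
      keep[i] <- TRUE
      used1[qh[i]] <- TRUE
      used2[sh[i]] <- TRUE
    }
  }
  sel <- which(keep)
  out <- p1[qh[sel]]
  out$score1 <- p1$score[qh[sel]]
  out$score2 <- p2$score[sh[sel]]
  S4Vectors::mcols(out) <-
    S4Vectors::mcols(out)[c("score1", "score2")]
  GenomicRanges::sort(out)
}

# log-density of a bivariate normal with common mean/sd (internal)
ldbvnorm <- function(x, y, mu, sigma, rho) {
  q <- ((x - mu)^2 - 2 * rho * (x - mu) * (y - mu) + (y - mu)^2) /
    (sigma^2 * (1 - rho^2))
  -log(2 * pi * sigma^2 * sqrt(1 - rho^2)) - q / 2
}

# Invert the mixture-implied marginal CDF
# G(z) = pi * pnorm(z, mu, sigma) + (1 - pi) * pnorm(z) by bisection,
# vectorized over u (internal).
mixture_quantile <- function(u, p, mu, sigma) {
  lo <- rep(min(mu - 8 * sigma, -8), length(u))
  hi <- rep(max(mu + 8 * sigma, 8), length(u))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- (p * pnorm(mid, mu, sigma) + (1 - p) * pnorm(mid)) < u
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

extract_scores <- function(pairs) {
  if (is(pairs, "GRanges")) {
    mc <- S4Vectors::mcols(pairs)
    stopifnot(all(c("score1", "score2") %in% names(mc)))
    return(cbind(score1 = mc$score1, score2 = mc$score2))
  }
  if (is.data.frame(pairs) || is.matrix(pairs)) {
    pairs <- as.data.frame(pairs)
    stopifnot(all(c("score1", "score2") %in% names(pairs)))
    return(cbind(score1 = pairs$score1, score2 = pairs$score2))
  }
  stop("pairs must be a GRanges or data.frame with score1/score2")
}

#' Fit the IDR copula mixture to replicate peak scores
#'
#' Estimates the two-component Gaussian copula mixture by expectation
#' conditional maximisation.  Scores enter only through their ranks: the
#' empirical quantiles `(rank - 0.5)/n` are mapped to pseudo-values by
#' inverting the mixture-implied marginal CDF under the current parameters,
#' and the pseudo-values are refreshed after every few EM passes, so the fit
#' is invariant to any strictly monotone transform of the scores.  The local
#' idr of a pair is the posterior probability of the irreproducible
#' component; the global IDR is the running mean of local idr over pairs
#' sorted by increasing local idr (the expected irreproducible rate among
#' all pairs at least as reproducible).
#'
#' @param pairs A `GRanges` from [match_replicate_peaks()], or any
#'   data.frame/matrix with `score1` and `score2` columns.  At least 50 pairs
#'   are required.
#' @param init An [idr_params()] of starting values.
#' @param max_iter Maximum total EM iterations.
#' @param tol Relative log-likelihood convergence tolerance, assessed each
#'   time the pseudo-values are refreshed.
#' @param em_per_update EM passes between pseudo-value refreshes.
#' @return A list of class `IDRFit`: `params` (fitted [idr_params()]),
#'   `local_idr`, `global_idr`, `loglik` (trace, one entry per EM pass),
#'   `converged`, `n_iter`, and the input `pairs`.
#' @export
fit_idr <- function(pairs, init = idr_params(), max_iter = 500L,
                    tol = 1e-6, em_per_update = 5L) {
  sc <- extract_scores(pairs)
  if (any(!is.finite(sc))) stop("scores must be finite")
  n <- nrow(sc)
  if (n < 50L) {
    stop("fit_idr needs at least 50 peak pairs (got ", n,
         "); supply more data")
  }
  stopifnot(is(init, "IDRParams"))
  u1 <- (rank(sc[, 1], ties.method = "average") - 0.5) / n
  u2 <- (rank(sc[, 2], ties.method = "average") - 0.5) / n
  mu <- init$mu; sigma <- init$sigma; rho <- init$rho; p <- init$pi
  loglik <- numeric(0)
  ll_at_update <- -Inf
  converged <- FALSE
  it <- 0L
  g <- rep(p, n)
  while (it < max_iter) {
    z1 <- mixture_quantile(u1, p, mu, sigma)
    z2 <- mixture_quantile(u2, p, mu, sigma)
    for (pass in seq_len(em_per_update)) {
      it <- it + 1L
      l1 <- ldbvnorm(z1, z2, mu, sigma, rho) + log(p)
      l0 <- ldbvnorm(z1, z2, 0, 1, 0) + log(1 - p)
      mx <- pmax(l1, l0)
      lden <- mx + log(exp(l1 - mx) + exp(l0 - mx))
      g <- exp(l1 - lden)
      loglik <- c(loglik, sum(lden))
      p <- min(max(mean(g), 1e-4), 1 - 1e-4)
      sw <- sum(g)
      mu <- sum(g * (z1 + z2)) / (2 * sw)
      sigma <- max(sqrt(sum(g * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * sw)),
                   1e-4)
      rho <- min(max(sum(g * (z1 - mu) * (z2 - mu)) / (sw * sigma^2),
                     -0.999), 0.999)
      if (it >= max_iter) break
    }
    ll <- loglik[length(loglik)]
    if (is.finite(ll_at_update) &&
        abs(ll - ll_at_update) / abs(ll) < tol) {
      converged <- TRUE
      break
    }
    ll_at_update <- ll
  }
  if (!converged) {
    warning("IDR EM did not converge in ", max_iter,
            " iterations; returning best parameters")
  }
  local_idr <- 1 - g
  ord <- order(local_idr)
  global_idr <- numeric(n)
  global_idr[ord] <- cumsum(local_idr[ord]) / seq_len(n)
  structure(
    list(params = idr_params(mu = mu, sigma = sigma, rho = rho, pi = p),
         local_idr = local_idr, global_idr = global_idr,
         loglik = loglik, converged = converged, n_iter = it,
         pairs = pairs),
    class = "IDRFit"
  )
}

#' @export
print.IDRFit <- function(x, ...) {
  cat(sprintf(
    paste0("IDRFit: %d pairs, pi=%.3f mu=%.2f sigma=%.2f rho=%.3f",
           " (%s in %d iterations)\n"),
    length(x$local_idr), x$params$pi, x$params$mu, x$params$sigma,
    x$params$rho, if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  invisible(x)
}

#' Select peak pairs passing a global IDR threshold
#'
#' @param fit An `IDRFit` from [fit_idr()].
#' @param alpha Global IDR threshold (pairs with `global_idr <= alpha` pass).
#' @return The subset of `fit$pairs` passing the threshold (same class as the
#'   pairs supplied to [fit_idr()]).
#' @export
idr_threshold <- function(fit, alpha) {
  stopifnot(is(fit, "IDRFit"), alpha >= 0, alpha <= 1)
  pass <- fit$global_idr <= alpha
  if (is(fit$pairs, "GRanges")) fit$pairs[pass] else fit$pairs[pass, ]
}

#' Write IDR pairs and scores as TSV
#'
#' Emits chrom, start, end (BED convention), score1, score2, local_idr and
#' global_IDR, one row per pair.
#'
#' @param fit An `IDRFit` whose pairs are a `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idr_pairs <- function(fit, path) {
  stopifnot(is(fit, "IDRFit"), is(fit$pairs, "GRanges"))
  gr <- fit$pairs
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score1 = gr$score1, score2 = gr$score2,
    local_idr = fit$local_idr, global_IDR = fit$global_idr
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
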