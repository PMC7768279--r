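#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Enumerates all tables with the observed margins and sums the
#' hypergeometric point probabilities of those no more probable than the
#' observed table (the point-probability two-sided convention, the one used
#' by mainstream statistics packages).  Probability comparisons use a
#' relative tolerance of 1e-7 to avoid floating-point ties.
#'
#' @param tab A 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcomes), or the counts `a, b, c, d` in row-major order.
#' @param b,c,d Remaining cells when `tab` is given as the scalar `a`.
#' @return A list: `p` (two-sided p-value), `odds_ratio` (sample odds
#'   ratio), and `table`.
#' @examples
#' fisher_exact_2x2(matrix(c(11, 5, 2, 7), 2))$p  # 0.0414
#' @export
fisher_exact_2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) tab <- matrix(c(tab, c, b, d), 2)
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (sum(tab) == 0) stop("table total must be positive")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p = min(p, 1), odds_ratio = or, table = tab)
}

#' One-sample t test
#'
#' Two-sided t test of the mean against `mu0`.  Zero-variance input is
#' flagged as degenerate: a constant vector equal to `mu0` yields `t = 0`,
#' `p = 1`; a constant vector elsewhere yields undefined `t`/`p`.
#'
#' @param x Numeric vector (n >= 2).
#' @param mu0 Null mean.
#' @return A list: `t`, `df`, `p`, `mean`, `degenerate`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  stopifnot(length(x) >= 2, all(is.finite(x)))
  if (sd(x) == 0) {
    same <- x[1] == mu0
    return(list(t = if (same) 0 else NA_real_, df = length(x) - 1L,
                p = if (same) 1 else NA_real_, mean = x[1],
                degenerate = TRUE))
  }
  ht <- t.test(x, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(x), degenerate = FALSE)
}

#' Paired t test
#'
#' Two-tailed paired t test; identical vectors (zero-variance differences)
#' are flagged as degenerate.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return A list: `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  res <- one_sample_t(x - y, 0)
  names(res)[names(res) == "mean"] <- "mean_diff"
  res
}

#' One-way ANOVA with Tukey's HSD
#'
#' Omnibus F test across groups followed by Tukey-adjusted pairwise
#' comparisons (Tukey-Kramer for unequal group sizes, via the studentized
#' range distribution).  When all group means are identical the F statistic
#' is reported as 0 with p = 1.
#'
#' @param groups Named list of numeric vectors.
#' @return A list: `F`, `df`, `p`, and `tukey` (data.frame of pairwise
#'   comparisons with mean difference and adjusted p).
#' @export
anova_oneway_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  )
  fit <- aov(value ~ group, data = df)
  sm <- summary(fit)[[1]]
  ss_between <- sm["group", "Sum Sq"]
  total_ss <- sum((df$value - mean(df$value))^2)
  if (total_ss == 0 || ss_between <= 1e-12 * total_ss) {
    comparisons <- utils::combn(names(groups), 2)
    tk <- data.frame(comparison = apply(comparisons, 2, paste, collapse = "-"),
                     diff = 0, p_adj = 1)
    return(list(F = 0, df = unname(sm[, "Df"]), p = 1, tukey = tk))
  }
  th <- TukeyHSD(fit)$group
  tk <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                   p_adj = th[, "p adj"], row.names = NULL)
  list(F = sm["group", "F value"], df = unname(sm[, "Df"]),
       p = sm["group", "Pr(>F)"], tukey = tk)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param pvals Numeric vector of p-values.
#' @return Step-up adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  p.adjust(pvals, method = "BH")
}

#' A single ChIP-qPCR measurement
#'
#' Averaged Ct values for one sample at one target locus: ChIP and input
#' fractions, each with the target and the control-region Ct.
#'
#' @param ct_chip_target,ct_chip_control Ct of target/control region in the
#'   ChIP fraction (cycles).
#' @param ct_input_target,ct_input_control Same for the input fraction.
#' @return A list of class `QPCRMeasurement`.
#' @export
qpcr_measurement <- function(ct_chip_target, ct_chip_control,
                             ct_input_target, ct_input_control) {
  vals <- c(ct_chip_target, ct_chip_control, ct_input_target,
            ct_input_control)
  stopifnot(all(is.finite(vals)))
  structure(list(ct_chip_target = ct_chip_target,
                 ct_chip_control = ct_chip_control,
                 ct_input_target = ct_input_target,
                 ct_input_control = ct_input_control),
            class = "QPCRMeasurement")
}

ddct_of <- function(m) {
  stopifnot(is(m, "QPCRMeasurement"))
  d_chip <- m$ct_chip_target - m$ct_chip_control
  d_input <- m$ct_input_target - m$ct_input_control
  d_chip - d_input
}

#' Log2 fold change of ChIP enrichment between two samples (delta-delta-Ct)
#'
#' Per sample, `dCt = Ct(target) - Ct(control region)` within each fraction
#' and `ddCt = dCt(ChIP) - dCt(input)`; fold enrichment over input is
#' `2^(-ddCt)`.  The reported value is the log2 ratio of the first sample's
#' fold enrichment over the second's, i.e. `ddCt(sample2) - ddCt(sample1)`:
#' positive values mean stronger enrichment in the first (e.g. CIN) sample.
#'
#' @param cin,noncin [qpcr_measurement()]s for the two samples.
#' @return Log2 fold change (first over second sample).
#' @export
ddct_log2_ratio <- function(cin, noncin) {
  ddct_of(noncin) - ddct_of(cin)
}

#' Colocalization ratio normalized to a reference population
#'
#' `(marker+ labeled / total labeled) / (marker+ reference / total
#' reference)`; 1 means the marker is represented among labeled cells
#' exactly as in the reference population.
#'
#' @param eyfp_marker,eyfp_total Marker-positive and total counts among
#'   labeled (e.g. EYFP+) cells.
#' @param tdt_marker,tdt_total Same among the reference (e.g. tdTomato+)
#'   population.
#' @return The normalized ratio.
#' @export
normalized_colocalization <- function(eyfp_marker, eyfp_total,
                                      tdt_marker, tdt_total) {
  stopifnot(eyfp_total > 0, tdt_total > 0, tdt_marker > 0)
  (eyfp_marker / eyfp_total) / (tdt_marker / tdt_total)
}
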