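test_that("consensus scanning finds forced hits and never matches N", {
  m <- motif("t1", consensus = "TAAT")
  hit <- scan_motif(c(s1 = "GGTAATGG"), m)
  expect_true(hit$hit)
  expect_equal(hit$count, 1L)
  # a palindromic consensus is counted once per strand
  expect_equal(scan_motif(c(s = "GGTTAACC"), motif("p", consensus = "TTAA"))$count, 2L)
  expect_false(scan_motif(c(s = strrep("N", 50)), m)$hit)
  expect_false(scan_motif(c(s = "GGTANTGG"), m)$hit)
})

test_that("consensus and PWM scans match a sliding-window oracle", {
  set.seed(1)
  seqs <- vapply(1:40, function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  }, "")
  m1 <- motif("amb", consensus = "TAAYTR")
  got <- scan_motif(seqs, m1)
  want <- vapply(seqs, consensus_count_oracle, 0L, consensus = m1$consensus)
  expect_equal(got$count, unname(want))

  pwm <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.05, 0.05, 0.05, 0.85,
                  0.25, 0.25, 0.25, 0.25,
                  0.1, 0.4, 0.4, 0.1), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  m2 <- motif("pwm", pwm = pwm, match_threshold = 0.7)
  got2 <- scan_motif(seqs, m2)
  want2 <- vapply(seqs, pwm_count_oracle, 0L, pwm = pwm, threshold = 0.7)
  expect_equal(got2$count, unname(want2))
})

test_that("hit flags are invariant under reverse complement", {
  set.seed(2)
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  }, "")
  rc <- vapply(seqs, revcomp_chr, "")
  m <- motif("x", consensus = "TGACGT")
  expect_equal(scan_motif(seqs, m)$hit, scan_motif(unname(rc), m)$hit)
})

test_that("fold enrichment is exactly %targets over %background", {
  set.seed(3)
  m <- motif("t", consensus = "TTAACC")
  raw <- vapply(1:40, function(i) {
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  }, "")
  seqs <- Biostrings::DNAStringSet(setNames(raw, paste0("s", 1:40)))
  same <- motif_fold_enrichment(seqs, seqs, m)
  if (same$k_target > 0) expect_equal(same$fold, 1.0)

  # forced 50% / 5%: 10/20 targets, 1/20 background
  with_motif <- paste0(strrep("A", 30), "TTAACC", strrep("G", 30))
  without <- strrep("AG", 33)
  tg <- c(rep(with_motif, 10), rep(without, 10))
  bg <- c(with_motif, rep(without, 19))
  fe <- motif_fold_enrichment(tg, bg, m)
  expect_equal(fe$fold, 10.0)
  expect_equal(fe$pct_targets, 50)
  expect_equal(fe$pct_background, 5)
  expect_equal(fe$p, sum(dbinom(10:20, 20, 0.05)), tolerance = 1e-12)

  # zero background hits: infinite fold, floored rate
  fe0 <- motif_fold_enrichment(tg, rep(without, 20), m)
  expect_true(is.infinite(fe0$fold))
  expect_equal(fe0$p, sum(dbinom(10:20, 20, 0.5 / 20)), tolerance = 1e-12)
})

test_that("planted-motif simulation reproduces rates and the exact binomial p", {
  m <- motif("dlx", consensus = "TAATTA")
  sim <- gen_motif_sequences(500, 500, m, target_rate = 0.4,
                             background_rate = 0.05, seed = 11)
  fe <- motif_fold_enrichment(sim$targets, sim$background, m)
  st <- scan_motif(sim$targets, m)
  sb <- scan_motif(sim$background, m)
  expect_equal(fe$fold, (mean(st$hit)) / (mean(sb$hit)))
  rate <- max(mean(sb$hit), 0.5 / 500)
  oracle_p <- sum(dbinom(sum(st$hit):500, 500, rate))
  expect_equal(fe$p, oracle_p, tolerance = 1e-10)
  # every planted sequence must scan positive
  expect_true(all(st$hit[sim$truth$target_planted]))
})

toy_models <- function() {
  gene_models(
    data.frame(gene = c("g1", "g2", "g3"),
               chrom = "chr1", strand = c("+", "-", "+"),
               start = c(10000, 30000, 31000), end = c(20000, 30900, 40000)),
    exons = data.frame(chrom = "chr1",
                       start = c(10000, 19000), end = c(10500, 20000)),
    utr5 = data.frame(chrom = "chr1", start = 10000, end = 10200)
  )
}

test_that("genomic context respects the precedence chain", {
  gm <- toy_models()
  peak_at <- function(mid) GRanges("chr1", IRanges(mid - 50, mid + 50))
  ctx <- function(gr) as.character(
    annotate_genomic_context(gr, gm)$categories)
  expect_equal(ctx(peak_at(10000)), "promoter-TSS")   # at g1 TSS
  expect_equal(ctx(peak_at(9200)), "promoter-TSS")    # 800 bp upstream
  expect_equal(ctx(peak_at(10150)), "5UTR")           # UTR beats exon
  expect_equal(ctx(peak_at(19500)), "exon")
  expect_equal(ctx(peak_at(15000)), "intron")
  expect_equal(ctx(peak_at(20500)), "TTS")            # past g1 end
  expect_equal(ctx(peak_at(99000)), "intergenic")
  expect_equal(ctx(GRanges("chrEmpty", IRanges(5000, 5100))), "intergenic")
  # proportions sum to one over peaks
  pk <- GRanges("chr1", IRanges(seq(1000, 90000, by = 3000), width = 100))
  out <- annotate_genomic_context(pk, gm)
  expect_equal(sum(out$proportions), 1)
})

test_that("midpoint categories match a per-base precedence oracle", {
  gm <- toy_models()
  set.seed(4)
  mids <- sample.int(95000, 150) + 1000
  pk <- GRanges("chr1", IRanges(mids - 20, mids + 20))
  got <- as.character(annotate_genomic_context(pk, gm)$categories)
  # hand-derived windows: promoters [9000,10100] (g1,+), [30800,31900]
  # (g2,-), [30000,31100] (g3,+); TTS windows [19900,21000], [29000,30100],
  # [39900,41000]; gene bodies give introns where no exon/UTR applies
  oracle <- vapply(mids, function(x) {
    if ((x >= 9000 && x <= 10100) || (x >= 30800 && x <= 31900) ||
        (x >= 30000 && x <= 31100)) return("promoter-TSS")
    if (x >= 10000 && x <= 10200) return("5UTR")
    if ((x >= 10000 && x <= 10500) || (x >= 19000 && x <= 20000)) {
      return("exon")
    }
    if ((x >= 10000 && x <= 20000) || (x >= 30000 && x <= 30900) ||
        (x >= 31000 && x <= 40000)) return("intron")
    if ((x >= 19900 && x <= 21000) || (x >= 29000 && x <= 30100) ||
        (x >= 39900 && x <= 41000)) return("TTS")
    "intergenic"
  }, "")
  expect_equal(got, oracle)
})

test_that("basal-plus-extension domains match hand-computed values", {
  gm <- toy_models()
  # hand-derived basal domains: g1 TSS 10000 (+): [5000, 11000]; g2 TSS
  # 30900 (-): [29900, 35900]; g3 TSS 31000 (+): [26000, 32000].
  # g1 extends left to max(1, 10000 - 1e6) = 1 and right to the nearest
  # following basal edge, min(29900, 26000) = 26000; g2's rightward
  # obstruction (26000) lies inside its own basal domain, which is never
  # truncated, so its end stays 35900.
  assoc <- associate_regions_to_genes(GRanges("chr1", IRanges(1, 2)), gm,
                                      max_extension = 1e6)
  d <- assoc$domains
  expect_equal(unname(start(d["g1"])), 1)
  expect_equal(unname(end(d["g1"])), 26000)
  expect_equal(unname(end(d["g2"])), 35900)
  # a region inside a basal domain associates with that gene
  hit <- associate_regions_to_genes(GRanges("chr1", IRanges(6000, 6100)), gm)
  expect_true("g1" %in% hit$assoc$gene)
  # beyond max_extension from every gene: no association
  far <- GRanges("chr1", IRanges(900000, 900100))
  out <- associate_regions_to_genes(far, gm, max_extension = 10000)
  expect_equal(nrow(out$assoc), 0)
})

test_that("region-gene association grows monotonically with max_extension", {
  gm <- toy_models()
  set.seed(5)
  regions <- GRanges("chr1", IRanges(sample.int(200000, 50), width = 200))
  prev <- NULL
  for (ext in c(1000, 10000, 100000, 1e6)) {
    a <- associate_regions_to_genes(regions, gm, max_extension = ext)
    pairs <- paste(a$assoc$region, a$assoc$gene)
    if (!is.null(prev)) expect_true(all(prev %in% pairs))
    prev <- pairs
  }
})

test_that("term enrichment flags a planted dense term and not the genome-wide term", {
  set.seed(6)
  genes <- data.frame(
    gene = sprintf("g%02d", 1:60), chrom = "chr1", strand = "+",
    start = round(seq(10000, 980000, length.out = 60)),
    end = round(seq(10000, 980000, length.out = 60)) + 2000
  )
  gm <- gene_models(genes)
  term_map <- data.frame(
    term = c(rep("planted", 6), rep("whole", 60), rep("empty", 3)),
    gene = c(genes$gene[1:6], genes$gene, paste0("x", 1:3))
  )
  # plant regions densely in the first six genes' basal domains; a light
  # sprinkle of random regions elsewhere leaves many genes without hits
  tss <- genes$start
  dense <- unlist(lapply(tss[1:6], function(p) p + sample(-4000:800, 20)))
  sparse <- sample.int(1e6, 20)
  regions <- GRanges("chr1", IRanges(sort(c(dense, sparse)), width = 50))
  assoc <- associate_regions_to_genes(regions, gm, max_extension = 20000)
  res <- term_enrichment(assoc, term_map, genome_length = 1e6)
  planted <- res[res$term == "planted", ]
  expect_true(planted$significant)
  expect_gt(planted$fold, 2)
  # exact binomial oracle for the planted term's p-value
  dom <- GenomicRanges::reduce(assoc$domains[sprintf("g%02d", 1:6)])
  p_cov <- sum(width(dom)) / 1e6
  k <- sum(overlaps_any(regions, dom))
  expect_equal(planted$p_binom, sum(dbinom(k:length(regions),
                                           length(regions), p_cov)),
               tolerance = 1e-12)
  # a term containing every gene has fold near 1... and cannot be enriched
  whole <- res[res$term == "whole", ]
  expect_false(whole$significant)
  # a term with no matching genes has zero hits and fold 0
  empty <- res[res$term == "empty", ]
  expect_equal(empty$fold, 0)
  expect_false(empty$significant)
})
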