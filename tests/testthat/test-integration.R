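test_that("hc_peaks of identical replicates is the merged set, and is commutative", {
  gr <- GRanges("chr1", IRanges(c(1, 301, 5001), c(100, 400, 5100)))
  out <- hc_peaks(gr, gr)
  expect_identical(granges(out), granges(merge_within(gr, 500)))
  expect_length(hc_peaks(gr, GRanges("chr2", IRanges(1, 100))), 0)
  set.seed(1)
  a <- random_interval_set(30)
  b <- random_interval_set(30)
  expect_identical(granges(hc_peaks(a, b)), granges(hc_peaks(b, a)))
})

test_that("merging before intersecting can create intersection absent otherwise", {
  # rep1 has two peaks with a 200 bp gap; rep2 covers exactly that gap
  rep1 <- GRanges("chrA", IRanges(c(1001, 1701), c(1500, 2200)))
  rep2 <- GRanges("chrA", IRanges(1501, 1700))
  expect_length(interval_intersect(rep1, rep2), 0)
  out <- hc_peaks(rep1, rep2, 500)
  want <- bitmap_to_gr(mapply(`&`,
                              bitmap_of(merge_oracle(rep1, 500)),
                              bitmap_of(merge_within(rep2, 500)),
                              SIMPLIFY = FALSE))
  expect_true(gr_identical_bases(out, want))
  expect_equal(sum(width(out)), 200)
})

test_that("HC output is contained in both merged replicates base-wise", {
  set.seed(2)
  for (i in 1:10) {
    a <- random_interval_set(40)
    b <- random_interval_set(40)
    hc <- hc_peaks(a, b)
    bm <- bitmap_of(hc)
    for (m in list(merge_within(a, 500), merge_within(b, 500))) {
      mb <- bitmap_of(m)
      expect_true(all(mapply(function(x, y) all(!x | y), bm, mb)))
    }
  }
})

fake_diff <- function(e1, e2, cm) {
  structure(list(enriched_in_1 = e1, enriched_in_2 = e2, common = cm),
            class = "DifferentialResult")
}

test_that("build_hc_differential keeps classes disjoint with enriched priority", {
  e1 <- GRanges("chr1", IRanges(c(1001, 1801), c(1500, 2300)))
  e2 <- GRanges("chr1", IRanges(9001, 9400))
  cm <- GRanges("chr1", IRanges(1501, 1800))  # bridges the e1 gap after merge
  d <- fake_diff(e1, e2, cm)
  hc <- build_hc_differential(d, d)
  # e1 merges across the gap and swallows the common bases: common loses them
  expect_equal(sum(width(hc$enriched_in_1)), 1300)
  expect_length(hc$common, 0)
  expect_length(GenomicRanges::intersect(hc$enriched_in_1, hc$enriched_in_2), 0)

  empty <- fake_diff(GRanges(), GRanges(), GRanges())
  hc2 <- build_hc_differential(d, empty)
  expect_length(hc2$enriched_in_1, 0)
  expect_length(hc2$common, 0)
})

test_that("candidate annotation flags match a bitmap oracle on a planted design", {
  set.seed(3)
  cands <- random_interval_set(60)
  tfs <- list(tf1 = random_interval_set(25), tf2 = random_interval_set(25),
              tf3 = random_interval_set(25))
  cons <- random_interval_set(40)
  df <- annotate_candidates(cands, tf_sets = tfs, conserved = cons)
  for (nm in names(tfs)) {
    bm <- bitmap_of(tfs[[nm]])
    want <- vapply(seq_along(cands), function(i) {
      ch <- as.character(seqnames(cands))[i]
      any(bm[[ch]][start(cands)[i]:end(cands)[i]])
    }, TRUE)
    expect_identical(df[[paste0("tf_", nm)]], want)
  }
  expect_identical(df$tf_union, df$tf_tf1 | df$tf_tf2 | df$tf_tf3)
  expect_identical(df$tf_intersect, df$tf_tf1 & df$tf_tf2 & df$tf_tf3)
  expect_identical(df$n_tf, rowSums(cbind(df$tf_tf1, df$tf_tf2, df$tf_tf3)))
})

test_that("candidates inside all or none of the evidence get the forced flags", {
  cand <- GRanges("chrA", IRanges(1000, 1200))
  everywhere <- GRanges("chrA", IRanges(1, 5000))
  df <- annotate_candidates(cand,
                            tf_sets = list(a = everywhere, b = everywhere,
                                           c = everywhere),
                            conserved = everywhere)
  expect_true(df$tf_union && df$tf_intersect && df$conserved)
  df0 <- annotate_candidates(cand, tf_sets = list(a = GRanges()),
                             conserved = GRanges())
  expect_false(df0$tf_union || df0$tf_intersect || df0$conserved)
})

test_that("nearest gene is by TSS distance with alphabetical ties", {
  tss <- data.frame(gene = c("zeb", "abc", "mid"),
                    chrom = c("chr1", "chr1", "chr1"),
                    pos = c(5000, 5000, 1150))
  df <- annotate_candidates(GRanges("chr1", IRanges(1100, 1200)),
                            tss_table = tss)
  expect_equal(df$nearest_gene, "mid")
  expect_equal(df$tss_distance, 0)
  df2 <- annotate_candidates(GRanges("chr1", IRanges(4000, 4100)),
                             tss_table = tss[1:2, ])
  expect_equal(df2$nearest_gene, "abc")  # tie -> alphabetical
})

test_that("ranking is lexicographic on evidence then score, ties by coordinate", {
  df <- annotate_candidates(
    GRanges("chr1", IRanges(c(100, 200, 300, 400), width = 50)),
    tf_sets = list(a = GRanges(), b = GRanges(), c = GRanges())
  )
  df$n_tf <- c(1L, 3L, 3L, 0L)
  df$tf_intersect <- c(FALSE, TRUE, FALSE, FALSE)
  df$conserved <- c(TRUE, FALSE, FALSE, TRUE)
  df$score <- c(9, 1, 2, 9)
  r <- rank_candidates(df)
  expect_equal(r$start, c(200, 300, 100, 400) - 1L)
  # random tables against an independent sort oracle
  set.seed(4)
  n <- 100
  rnd <- annotate_candidates(random_interval_set(n))
  rnd$n_tf <- sample(0:3, n, TRUE)
  rnd$tf_intersect <- rnd$n_tf == 3
  rnd$conserved <- sample(c(TRUE, FALSE), n, TRUE)
  rnd$n_acc <- sample(0:2, n, TRUE)
  rnd$score <- round(runif(n), 3)
  got <- rank_candidates(rnd)
  key <- with(rnd, paste(9 - tf_intersect, 9 - n_tf, 9 - conserved,
                         9 - n_acc, sprintf("%08.3f", 1000 - score),
                         chrom, sprintf("%09d", start)))
  expect_equal(got$name, rnd$name[order(key)])
})

test_that("summaries do the bookkeeping and respect union >= per-TF percentages", {
  empty <- fake_diff(GRanges(), GRanges(), GRanges())
  s0 <- summarize_counts(empty)
  expect_equal(unlist(s0$counts), c(enriched_in_1 = 0, enriched_in_2 = 0,
                                    common = 0))
  set.seed(5)
  e1 <- random_interval_set(20)
  hc <- fake_diff(merge_within(e1, 0), GRanges(), GRanges())
  tfs <- list(x = random_interval_set(30), y = random_interval_set(30))
  cands <- annotate_candidates(hc$enriched_in_1, tf_sets = tfs)
  s <- summarize_counts(hc, cands)
  expect_equal(s$evidence_pct$n_candidates, nrow(cands))
  expect_equal(s$evidence_pct$pct_tf_union, 100 * mean(cands$tf_union))
  expect_gte(s$evidence_pct$pct_tf_union, 100 * mean(cands$tf_x))
  expect_gte(s$evidence_pct$pct_tf_union, 100 * mean(cands$tf_y))
})
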