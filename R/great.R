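#' Gene models for annotation and region-gene association
#'
#' A light container for gene bodies with strand-aware TSS/TTS, plus
#' optional exon and 5'-UTR spans used by [annotate_genomic_context()].
#'
#' @param genes data.frame with columns `gene`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end` (1-based inclusive transcript span).
#' @param exons,utr5 Optional data.frames with columns `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @return A list of class `GeneModels` with `genes` and `GRanges` components
#'   `tss` (width-1, one per gene), `exons`, `utr5`.
#' @export
gene_models <- function(genes, exons = NULL, utr5 = NULL) {
  stopifnot(all(c("gene", "chrom", "strand", "start", "end") %in% names(genes)),
            all(genes$strand %in% c("+", "-")),
            all(genes$end >= genes$start))
  tss_pos <- ifelse(genes$strand == "+", genes$start, genes$end)
  tts_pos <- ifelse(genes$strand == "+", genes$end, genes$start)
  to_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  }
  structure(
    list(genes = genes,
         tss = GenomicRanges::GRanges(genes$chrom,
                                      IRanges::IRanges(tss_pos, width = 1L),
                                      strand = genes$strand),
         tts = GenomicRanges::GRanges(genes$chrom,
                                      IRanges::IRanges(tts_pos, width = 1L),
                                      strand = genes$strand),
         body = GenomicRanges::GRanges(genes$chrom,
                                       IRanges::IRanges(genes$start,
                                                        genes$end)),
         exons = to_gr(exons), utr5 = to_gr(utr5)),
    class = "GeneModels"
  )
}

# Strand-aware window around anchor points: `up` bp upstream through `down`
# bp downstream (internal).
anchored_window <- function(anchor, up, down) {
  pos <- GenomicRanges::start(anchor)
  plus <- as.character(GenomicRanges::strand(anchor)) != "-"
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(anchor),
    IRanges::IRanges(start = pmax(1, ifelse(plus, pos - up, pos - down)),
                     end = ifelse(plus, pos + down, pos + up))
  )
}

#' Assign a genomic context category to each peak
#'
#' Categorizes the peak midpoint with the fixed precedence promoter-TSS >
#' 5'UTR > exon > intron > TTS > intergenic.  The promoter-TSS window is
#' `promoter_up` bp upstream through `promoter_down` bp downstream of a TSS
#' (strand-aware); the TTS window is symmetric around the transcript end.
#' Gene-body bases not covered by an exon count as intron (the whole body,
#' when no exon table was supplied).
#'
#' @param peaks A `GRanges` of peaks.
#' @param models A [gene_models()].
#' @param promoter_up,promoter_down Promoter window (bp; defaults 1000/100).
#' @param tts_up,tts_down TTS window (bp; defaults 100/1000).
#' @return A list: `categories` (factor, one level per category, one entry
#'   per peak) and `proportions` (named numeric summing to one when peaks
#'   are present).
#' @export
annotate_genomic_context <- function(peaks, models,
                                     promoter_up = 1000L,
                                     promoter_down = 100L,
                                     tts_up = 100L, tts_down = 1000L) {
  stopifnot(is(models, "GeneModels"))
  gr <- as_granges(peaks)
  mid <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(floor((GenomicRanges::start(gr) +
                              GenomicRanges::end(gr)) / 2), width = 1L)
  )
  lv <- c("promoter-TSS", "5UTR", "exon", "intron", "TTS", "intergenic")
  cat_of <- rep("intergenic", length(gr))
  in_tts <- overlaps_any(mid, anchored_window(models$tts, tts_up, tts_down))
  cat_of[in_tts] <- "TTS"
  in_body <- overlaps_any(mid, models$body)
  in_exon <- overlaps_any(mid, models$exons)
  cat_of[in_body & !in_exon] <- "intron"
  cat_of[in_exon] <- "exon"
  cat_of[overlaps_any(mid, models$utr5)] <- "5UTR"
  in_prom <- overlaps_any(mid, anchored_window(models$tss, promoter_up,
                                               promoter_down))
  cat_of[in_prom] <- "promoter-TSS"
  categories <- factor(cat_of, levels = lv)
  props <- if (length(gr)) table(categories) / length(gr) else
    setNames(rep(0, length(lv)), lv)
  list(categories = categories,
       proportions = setNames(as.numeric(props), lv))
}

#' Basal-plus-extension regulatory domains and region-gene association
#'
#' Each gene receives a basal regulatory domain (`basal_up` bp upstream and
#' `basal_down` bp downstream of its TSS, strand-aware) which is then
#' extended on each side to the nearest neighboring gene's basal domain edge,
#' up to `max_extension` bp from the TSS; a gene's own basal domain is never
#' truncated.  A region associates with every gene whose regulatory domain it
#' overlaps.
#'
#' @param regions A `GRanges` of regions.
#' @param models A [gene_models()].
#' @param basal_up,basal_down Basal domain extents in bp (defaults 5000/1000).
#' @param max_extension Maximum extension from the TSS in bp (default 1e6).
#' @param chrom_lengths Optional named vector clamping domains to chromosome
#'   ends.
#' @return A list of class `RegGeneAssoc`: `assoc` (data.frame with columns
#'   `region` (index), `gene`), `domains` (`GRanges` named by gene),
#'   `regions`, and `genes` (the gene table).
#' @export
associate_regions_to_genes <- function(regions, models, basal_up = 5000L,
                                       basal_down = 1000L,
                                       max_extension = 1e6,
                                       chrom_lengths = NULL) {
  stopifnot(is(models, "GeneModels"))
  regions <- as_granges(regions)
  g <- models$genes
  basal <- anchored_window(models$tss, basal_up, basal_down)
  tss_pos <- GenomicRanges::start(models$tss)
  dom_start <- numeric(nrow(g))
  dom_end <- numeric(nrow(g))
  for (chrom in unique(g$chrom)) {
    i <- which(g$chrom == chrom)
    i <- i[order(tss_pos[i])]
    bs <- GenomicRanges::start(basal)[i]
    be <- GenomicRanges::end(basal)[i]
    ts <- tss_pos[i]
    n <- length(i)
    # nearest obstructing basal edge over all preceding/following genes
    # (basal domains need not be monotone when TSSs are close)
    prev_edge <- cummax(c(-Inf, be[-n]))
    next_edge <- rev(cummin(rev(c(bs[-1], Inf))))
    dom_start[i] <- pmin(bs, pmax(ts - max_extension, prev_edge, 1))
    dom_end[i] <- pmax(be, pmin(ts + max_extension, next_edge))
  }
  dom_start <- pmax(dom_start, 1)
  if (!is.null(chrom_lengths)) {
    dom_end <- pmin(dom_end, chrom_lengths[g$chrom])
  }
  domains <- GenomicRanges::GRanges(g$chrom,
                                    IRanges::IRanges(dom_start, dom_end))
  names(domains) <- g$gene
  hits <- GenomicRanges::findOverlaps(regions, domains, ignore.strand = TRUE)
  assoc <- data.frame(region = S4Vectors::queryHits(hits),
                      gene = g$gene[S4Vectors::subjectHits(hits)],
                      stringsAsFactors = FALSE)
  structure(list(assoc = assoc, domains = domains, regions = regions,
                 genes = g),
            class = "RegGeneAssoc")
}

#' Region-based term enrichment with binomial and hypergeometric tests
#'
#' For each term, the binomial test asks whether more regions fall in the
#' union of the term's genes' regulatory domains than expected from the
#' fraction of the genome those domains cover; the hypergeometric test asks
#' whether the term's genes are over-represented among genes with at least
#' one associated region.  Fold is observed over expected region hits.  A
#' term is called significant when both BH-adjusted FDRs are below
#' `fdr_cutoff` and fold exceeds `fold_cutoff` (defaults 0.05 and 2).
#'
#' @param assoc A `RegGeneAssoc` from [associate_regions_to_genes()].
#' @param term_map data.frame with columns `term` and `gene`.
#' @param genome_length Total genome length in bp.
#' @param fdr_cutoff,fold_cutoff Significance thresholds.
#' @return A data.frame, one row per term: region hit count, fold, binomial
#'   and hypergeometric p-values, their BH FDRs, and `significant`.
#' @export
term_enrichment <- function(assoc, term_map, genome_length,
                            fdr_cutoff = 0.05, fold_cutoff = 2) {
  stopifnot(is(assoc, "RegGeneAssoc"),
            all(c("term", "gene") %in% names(term_map)))
  regions <- assoc$regions
  n_regions <- length(regions)
  all_genes <- assoc$genes$gene
  genes_hit <- unique(assoc$assoc$gene)
  terms <- unique(term_map$term)
  rows <- lapply(terms, function(tm) {
    tg <- intersect(unique(term_map$gene[term_map$term == tm]), all_genes)
    if (length(tg) == 0) {
      return(data.frame(term = tm, n_genes = 0L, region_hits = 0L,
                        expected = 0, fold = 0, p_binom = 1, p_hyper = 1))
    }
    dom_union <- GenomicRanges::reduce(
      assoc$domains[names(assoc$domains) %in% tg])
    p_cov <- min(sum(GenomicRanges::width(dom_union)) / genome_length, 1)
    k <- sum(overlaps_any(regions, dom_union))
    expected <- n_regions * p_cov
    fold <- if (expected > 0) k / expected else 0
    p_binom <- if (p_cov > 0) {
      pbinom(k - 1, n_regions, p_cov, lower.tail = FALSE)
    } else 1
    k_h <- length(intersect(tg, genes_hit))
    p_hyper <- phyper(k_h - 1, length(tg), length(all_genes) - length(tg),
                      length(genes_hit), lower.tail = FALSE)
    data.frame(term = tm, n_genes = length(tg), region_hits = k,
               expected = expected, fold = fold, p_binom = p_binom,
               p_hyper = p_hyper)
  })
  out <- do.call(rbind, rows)
  out$fdr_binom <- p.adjust(out$p_binom, method = "BH")
  out$fdr_hyper <- p.adjust(out$p_hyper, method = "BH")
  out$significant <- out$fdr_binom < fdr_cutoff &
    out$fdr_hyper < fdr_cutoff & out$fold > fold_cutoff
  out[order(out$p_binom), , drop = FALSE]
}
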