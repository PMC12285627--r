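#' @name mutation-features
#' @title Mutation feature operators
#' @description Exonic mutation odds ratio, mean functional-impact scores
#'   and the per-gene copy-number summary.
NULL

variants_gr <- function(variants) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  if (all(c("ref", "alt") %in% names(variants))) {
    bad <- nchar(variants$ref) > 1L & nchar(variants$alt) > 1L
    if (any(bad)) {
      stop("only single-nucleotide variants and length-1 indels are allowed",
           call. = FALSE)
    }
  }
  gi_to_granges(variants$chrom, variants$pos, variants$pos + 1L)
}

#' Exonic mutation odds ratio
#'
#' Compares the mutation rate in a gene's merged exons against its
#' background (gene span minus exons, plus the promoter), with Haldane +0.5
#' pseudocounts:
#' `OR = ((m_ex + 0.5) / (L_ex + 0.5)) / ((m_bg + 0.5) / (L_bg + 0.5))`.
#' Genes listed in `genes_with_data` (or all genes when `NULL`) get the
#' pseudocount OR even with zero counts; genes outside it get the
#' missing-data value 0.
#'
#' @param variants data.frame with `chrom`, `pos` (0-based) and optionally
#'   `ref`/`alt` (single-nucleotide or length-1 indel records only).
#' @param region_sets list of `RegionSet` objects.
#' @param genes_with_data optional character vector of gene ids covered by
#'   the variant data.
#' @return named numeric vector over all genes in `region_sets`.
#' @export
mutation_odds_ratio <- function(variants, region_sets,
                                genes_with_data = NULL) {
  vgr <- variants_gr(variants)
  gids <- vapply(region_sets, `[[`, "", "gene_id")
  # per-gene background intervals: (span \ exons) U promoter
  bg_ivs <- lapply(region_sets, function(rs) {
    gap <- complement_within(rs$span_start, rs$span_end, rs$exons_merged)
    union_intervals(rbind(gap, rs$promoter))
  })
  count_hits <- function(st) {
    hits <- GenomicRanges::findOverlaps(vgr, st$gr, ignore.strand = TRUE)
    m <- integer(length(region_sets))
    if (length(hits)) {
      pairs <- unique(data.frame(v = S4Vectors::queryHits(hits),
                                 g = st$gene[S4Vectors::subjectHits(hits)]))
      tab <- table(pairs$g)
      m[as.integer(names(tab))] <- as.integer(tab)
    }
    m
  }
  stack_df <- function(rs, df) {
    if (nrow(df) == 0L) {
      data.frame(chrom = character(), start = integer(), end = integer())
    } else {
      data.frame(chrom = rs$chrom, start = df$start, end = df$end)
    }
  }
  st_ex <- stack_regions(region_sets, function(rs) {
    stack_df(rs, rs$exons_merged)
  })
  st_bg <- stack_regions(seq_along(region_sets), function(i) {
    stack_df(region_sets[[i]], bg_ivs[[i]])
  })
  m_ex <- count_hits(st_ex)
  m_bg <- count_hits(st_bg)
  L_ex <- vapply(region_sets, function(rs) {
    sum(rs$exons_merged$end - rs$exons_merged$start)
  }, 0)
  L_bg <- vapply(bg_ivs, function(iv) sum(iv$end - iv$start), 0)
  or <- ((m_ex + 0.5) / (L_ex + 0.5)) / ((m_bg + 0.5) / (L_bg + 0.5))
  for (g in which(L_ex == 0)) {
    warning(sprintf("gene %s has empty exon region; OR set to 0", gids[g]))
    or[g] <- 0
  }
  if (!is.null(genes_with_data)) or[!gids %in% genes_with_data] <- 0
  setNames(or, gids)
}

#' Mean functional-impact score over a gene's variants
#'
#' Arithmetic mean of a precomputed impact score (e.g. structural or
#' deleteriousness scores) over the variants falling in the gene span; genes
#' with no overlapping variant get 0.
#'
#' @param variants data.frame with `chrom`, `pos` and one numeric column per
#'   scorer.
#' @param region_sets list of `RegionSet` objects.
#' @param scorer name of the score column to average.
#' @return named numeric vector over all genes.
#' @export
functional_impact_mean <- function(variants, region_sets, scorer) {
  if (!scorer %in% names(variants)) {
    stop(sprintf("missing score column '%s' in variant table", scorer),
         call. = FALSE)
  }
  if (anyNA(variants[[scorer]])) {
    stop(sprintf("NA values in score column '%s'", scorer), call. = FALSE)
  }
  vgr <- variants_gr(variants)
  st <- stack_regions(region_sets, function(rs) {
    data.frame(chrom = rs$chrom, start = rs$span_start, end = rs$span_end)
  })
  out <- setNames(numeric(length(region_sets)),
                  vapply(region_sets, `[[`, "", "gene_id"))
  hits <- GenomicRanges::findOverlaps(vgr, st$gr, ignore.strand = TRUE)
  if (length(hits)) {
    m <- tapply(variants[[scorer]][S4Vectors::queryHits(hits)],
                st$gene[S4Vectors::subjectHits(hits)], mean)
    out[as.integer(names(m))] <- as.numeric(m)
  }
  out
}

#' Per-gene copy-number feature
#'
#' Within each sample the gene's value is the overlap-length-weighted median
#' of the copy numbers of all segments intersecting the gene span; the
#' feature is the mean over samples with at least one overlapping segment.
#' Genes no sample covers get 0.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `sample_id`, `copy_number` (>= 0).
#' @param genes gene spans or gene-model list.
#' @return named numeric vector over all genes.
#' @export
cnv_feature <- function(segments, genes) {
  stopifnot(all(segments$start < segments$end), all(segments$copy_number >= 0))
  spans <- spans_from(genes)
  gids <- S4Vectors::mcols(spans)$gene_id
  seg_gr <- gi_to_granges(segments$chrom, segments$start, segments$end)
  hits <- GenomicRanges::findOverlaps(spans, seg_gr, ignore.strand = TRUE)
  out <- setNames(numeric(length(spans)), gids)
  if (length(hits) == 0L) return(out)
  ov_w <- IRanges::width(GenomicRanges::pintersect(
    spans[S4Vectors::queryHits(hits)], seg_gr[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  df <- data.frame(gene = S4Vectors::queryHits(hits),
                   sample = segments$sample_id[S4Vectors::subjectHits(hits)],
                   cn = segments$copy_number[S4Vectors::subjectHits(hits)],
                   w = ov_w)
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, ]
    per_sample <- vapply(split(sub, sub$sample), function(s) {
      weighted_median(s$cn, s$w)
    }, numeric(1L))
    out[g] <- mean(per_sample)
  }
  out
}
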