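#' @name genomic-features
#' @title Genomic feature operators
#' @description Gene length, conservation, GC content, repeat densities,
#'   cancer-driver-TAD membership and the k-mer composition PC1.
NULL

#' Log2 gene length
#'
#' @param genes gene spans or gene-model list.
#' @return named numeric vector of `log2(span length)`.
#' @export
gene_length_log2 <- function(genes) {
  spans <- spans_from(genes)
  setNames(log2(IRanges::width(spans)), S4Vectors::mcols(spans)$gene_id)
}

#' Region "mean0" conservation score
#'
#' Sum of per-base scores over the covered part of the region divided by the
#' *total* region length: bases without a score contribute 0 (the mean0
#' convention of bigWigAverageOverBed).
#'
#' @param scores data.frame of non-overlapping scored intervals `chrom`,
#'   `start`, `end` (0-based half-open), `score` (constant per base within
#'   the interval).
#' @param region_sets list of `RegionSet` objects.
#' @param which `"gene"` (whole span) or `"exon"` (merged exons).
#' @return named numeric vector over all genes.
#' @export
conservation_mean0 <- function(scores, region_sets,
                               which = c("gene", "exon")) {
  which <- match.arg(which)
  sgr <- gi_to_granges(scores$chrom, scores$start, scores$end)
  st <- stack_regions(region_sets, function(rs) {
    if (which == "gene") {
      data.frame(chrom = rs$chrom, start = rs$span_start, end = rs$span_end)
    } else if (nrow(rs$exons_merged)) {
      data.frame(chrom = rs$chrom, start = rs$exons_merged$start,
                 end = rs$exons_merged$end)
    } else {
      data.frame(chrom = character(), start = integer(), end = integer())
    }
  })
  out <- setNames(numeric(length(region_sets)),
                  vapply(region_sets, `[[`, "", "gene_id"))
  if (length(st$gene) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(sgr, st$gr, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::pintersect(sgr[qh], st$gr[sh])
    contrib <- tapply(IRanges::width(ov) * scores$score[qh], st$gene[sh], sum)
    out[as.integer(names(contrib))] <- as.numeric(contrib)
  }
  len <- tapply(IRanges::width(st$gr), st$gene, sum)
  idx <- as.integer(names(len))
  out[idx] <- out[idx] / as.numeric(len)
  out
}

#' GC content of gene or exon regions
#'
#' `(#G + #C) / region length`, case-insensitive; ambiguous bases are
#' excluded from the numerator but stay in the denominator.
#'
#' @param genome named `DNAStringSet` of chromosome sequences.
#' @param region_sets list of `RegionSet` objects.
#' @param which `"gene"` or `"exon"`.
#' @return named numeric vector in `[0, 1]`.
#' @export
gc_content <- function(genome, region_sets, which = c("gene", "exon")) {
  which <- match.arg(which)
  clen <- setNames(Biostrings::width(genome), names(genome))
  rows <- lapply(region_sets, function(rs) {
    if (!rs$chrom %in% names(genome)) {
      stop(sprintf("chromosome %s missing from genome", rs$chrom),
           call. = FALSE)
    }
    iv <- if (which == "gene") {
      data.frame(start = rs$span_start, end = rs$span_end)
    } else {
      rs$exons_merged
    }
    if (nrow(iv) == 0L) return(NULL)
    if (any(iv$start < 0) || any(iv$end > clen[[rs$chrom]])) {
      stop(sprintf("region outside sequence bounds for gene %s", rs$gene_id),
           call. = FALSE)
    }
    data.frame(chrom = rs$chrom, start = iv$start, end = iv$end)
  })
  n_iv <- vapply(rows, function(r) if (is.null(r)) 0L else nrow(r), 0L)
  out <- setNames(numeric(length(region_sets)),
                  vapply(region_sets, `[[`, "", "gene_id"))
  if (sum(n_iv) == 0L) return(out)
  df <- do.call(rbind, rows)
  gene <- rep(seq_along(region_sets), n_iv)
  gc <- len <- numeric(length(region_sets))
  for (ch in unique(df$chrom)) {
    sel <- df$chrom == ch
    segs <- Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(df$start[sel] + 1L, df$end[sel]))
    g <- tapply(as.numeric(Biostrings::letterFrequency(segs, "GC")),
                gene[sel], sum)
    l <- tapply(Biostrings::width(segs), gene[sel], sum)
    gc[as.integer(names(g))] <- gc[as.integer(names(g))] + as.numeric(g)
    len[as.integer(names(l))] <- len[as.integer(names(l))] + as.numeric(l)
  }
  has <- len > 0
  out[has] <- gc[has] / len[has]
  out
}

#' Repeat-element densities
#'
#' Number of repeat elements of each class overlapping the gene span, per kb
#' of gene length.
#'
#' @param repeats data.frame with `chrom`, `start`, `end`, `class`
#'   (values among SINE, LINE, LTR, Satellite; case-insensitive).
#' @param genes gene spans or gene-model list.
#' @return matrix genes x 4 with columns `sine_density`, `line_density`,
#'   `ltr_density`, `satellite_density`.
#' @export
repeat_density <- function(repeats, genes) {
  spans <- spans_from(genes)
  gids <- S4Vectors::mcols(spans)$gene_id
  kb <- IRanges::width(spans) / 1000
  classes <- c(sine_density = "sine", line_density = "line",
               ltr_density = "ltr", satellite_density = "satellite")
  out <- sapply(classes, function(cl) {
    sub <- repeats[tolower(repeats$class) == cl, , drop = FALSE]
    if (nrow(sub) == 0L) return(numeric(length(spans)))
    rgr <- gi_to_granges(sub$chrom, sub$start, sub$end)
    GenomicRanges::countOverlaps(spans, rgr, ignore.strand = TRUE) / kb
  })
  rownames(out) <- gids
  out
}

#' Cancer-driver-TAD indicator
#'
#' 1 when the gene span overlaps any cancer driver topologically associated
#' domain (any-overlap convention), else 0.
#'
#' @param cdt_regions CDT intervals (data.frame or GRanges); blood and solid
#'   tumor domains may simply be concatenated.
#' @param genes gene spans or gene-model list.
#' @return named 0/1 vector.
#' @export
cdt_indicator <- function(cdt_regions, genes) {
  spans <- spans_from(genes)
  cgr <- as_intervals_gr(cdt_regions)
  setNames(
    as.numeric(GenomicRanges::countOverlaps(spans, cgr,
                                            ignore.strand = TRUE) > 0L),
    S4Vectors::mcols(spans)$gene_id)
}

# First principal component score with a deterministic sign: features are
# centered (not scaled) and the sign is fixed so the largest-magnitude
# loading is positive.
pc1_scores <- function(x) {
  x <- as.matrix(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  keep <- which(apply(xc, 2L, function(v) any(v != 0)))
  if (length(keep) == 0L) return(setNames(numeric(nrow(x)), rownames(x)))
  sv <- svd(xc[, keep, drop = FALSE], nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  if (v[which.max(abs(v))] < 0) v <- -v
  setNames(as.numeric(xc[, keep, drop = FALSE] %*% v), rownames(x))
}

#' K-mer composition PC1
#'
#' Per transcript, the 4^k k-mer counts divided by transcript length; per
#' gene, the mean over its transcripts; the feature is each gene's score on
#' the first principal component of the centered gene x 4^k matrix, with the
#' sign fixed so the largest-magnitude loading is positive.
#'
#' @param transcript_seqs named `DNAStringSet` of transcript sequences.
#' @param tx2gene data.frame with `transcript_id`, `gene_id`.
#' @param k k-mer length (default 6).
#' @return named numeric vector of PC1 scores (one per gene with >= 1
#'   transcript).
#' @export
kmer_pc1 <- function(transcript_seqs, tx2gene, k = 6) {
  stopifnot(!is.null(names(transcript_seqs)))
  tx2gene <- tx2gene[tx2gene$transcript_id %in% names(transcript_seqs), ]
  short <- Biostrings::width(transcript_seqs) < k
  if (any(short)) {
    warning(sprintf("%d transcript(s) shorter than k=%d: zero k-mer vector",
                    sum(short), k))
  }
  freq <- Biostrings::oligonucleotideFrequency(transcript_seqs, width = k)
  rownames(freq) <- names(transcript_seqs)
  freq <- freq / pmax(Biostrings::width(transcript_seqs), 1L)
  freq[short, ] <- 0
  gene_of <- setNames(tx2gene$gene_id, tx2gene$transcript_id)
  gmat <- rowsum(freq[tx2gene$transcript_id, , drop = FALSE],
                 gene_of[tx2gene$transcript_id])
  ntx <- table(gene_of[tx2gene$transcript_id])
  gmat <- gmat / as.numeric(ntx[rownames(gmat)])
  if (nrow(gmat) < 2L) stop("k-mer PC1 needs at least 2 genes", call. = FALSE)
  pc1_scores(gmat)
}
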