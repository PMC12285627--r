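#' @name epigenomic-features
#' @title Epigenomic feature operators
#' @description Histone-mark peak widths, super-enhancer percentage,
#'   differential methylation and replication-timing S50. All interval inputs
#'   use 0-based half-open coordinates (`chrom`, `start`, `end` data.frames)
#'   or `GRanges`.
NULL

as_intervals_gr <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  gr <- gi_to_granges(x$chrom, x$start, x$end)
  extra <- setdiff(names(x), c("chrom", "start", "end", "strand"))
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- x[[nm]]
  gr
}

spans_from <- function(genes) {
  if (inherits(genes, "GRanges")) {
    stopifnot(!is.null(S4Vectors::mcols(genes)$gene_id))
    return(genes)
  }
  gene_spans(genes)
}

#' Mean per-sample summed peak width over a gene
#'
#' For one histone mark: in every sample, a gene's value is the summed full
#' length of all peaks overlapping its span; the feature is the mean of these
#' per-sample sums. Genes no sample has a peak for get 0.
#'
#' @param peaks_by_sample named list (one element per sample) of peak interval
#'   sets (data.frame or GRanges).
#' @param genes gene spans (`GRanges` with `gene_id`) or gene-model list.
#' @return named numeric vector over all genes.
#' @export
peak_width_feature <- function(peaks_by_sample, genes) {
  if (length(peaks_by_sample) == 0L) {
    stop("empty sample set: cannot average peak widths", call. = FALSE)
  }
  spans <- spans_from(genes)
  gids <- S4Vectors::mcols(spans)$gene_id
  per_sample <- vapply(peaks_by_sample, function(p) {
    p <- as_intervals_gr(p)
    out <- numeric(length(spans))
    hits <- GenomicRanges::findOverlaps(spans, p, ignore.strand = TRUE)
    if (length(hits)) {
      s <- tapply(IRanges::width(p)[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
      out[as.integer(names(s))] <- as.numeric(s)
    }
    out
  }, numeric(length(spans)))
  setNames(rowMeans(as.matrix(per_sample)), gids)
}

#' Super-enhancer percentage in the upstream window
#'
#' Fraction of cell/tissue types in which at least one super enhancer
#' overlaps the strand-aware upstream window of the gene.
#'
#' @param se_by_celltype named list (one element per cell type) of
#'   super-enhancer interval sets.
#' @param genes gene spans or gene-model list.
#' @param window upstream window length in bases (default 50000).
#' @return named numeric vector in `[0, 1]`.
#' @export
super_enhancer_pct <- function(se_by_celltype, genes, window = 50000) {
  if (length(se_by_celltype) == 0L) {
    stop("empty cell-type set", call. = FALSE)
  }
  spans <- spans_from(genes)
  upstream <- GenomicRanges::flank(spans, width = window, start = TRUE)
  upstream <- GenomicRanges::restrict(upstream, start = 1L)
  hit_count <- Reduce(`+`, lapply(se_by_celltype, function(se) {
    se <- as_intervals_gr(se)
    as.integer(GenomicRanges::countOverlaps(upstream, se,
                                            ignore.strand = TRUE) > 0L)
  }))
  setNames(hit_count / length(se_by_celltype),
           S4Vectors::mcols(spans)$gene_id)
}

#' Differential methylation over promoter or gene body
#'
#' Median cancer-minus-normal beta difference over the methylation sites
#' falling in the chosen region; genes with no overlapping site get 0.
#'
#' @param meth_sites data.frame with `chrom`, `pos` (0-based), `beta_cancer`,
#'   `beta_normal` (each in `[0, 1]`), or precomputed `beta_diff`.
#' @param region_sets list of `RegionSet` objects.
#' @param which `"promoter"` or `"gene_body"`.
#' @return named numeric vector over all genes in `region_sets`.
#' @export
diff_methylation <- function(meth_sites, region_sets,
                             which = c("promoter", "gene_body")) {
  which <- match.arg(which)
  if (is.null(meth_sites$beta_diff)) {
    stopifnot(all(c("beta_cancer", "beta_normal") %in% names(meth_sites)))
    betas <- c(meth_sites$beta_cancer, meth_sites$beta_normal)
    if (any(betas < 0 | betas > 1)) {
      stop("beta values must lie in [0, 1]", call. = FALSE)
    }
    meth_sites$beta_diff <- meth_sites$beta_cancer - meth_sites$beta_normal
  }
  sites <- gi_to_granges(meth_sites$chrom, meth_sites$pos, meth_sites$pos + 1L)
  st <- stack_regions(region_sets, function(rs) {
    df <- rs[[which]]
    if (nrow(df) == 0L) {
      data.frame(chrom = character(), start = integer(), end = integer())
    } else {
      data.frame(chrom = rs$chrom, start = df$start, end = df$end)
    }
  })
  out <- setNames(numeric(length(region_sets)),
                  vapply(region_sets, `[[`, "", "gene_id"))
  if (length(st$gene) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(sites, st$gr, ignore.strand = TRUE)
  if (length(hits)) {
    pairs <- unique(data.frame(site = S4Vectors::queryHits(hits),
                               gene = st$gene[S4Vectors::subjectHits(hits)]))
    med <- tapply(meth_sites$beta_diff[pairs$site], pairs$gene, median)
    out[as.integer(names(med))] <- as.numeric(med)
  }
  out
}

#' Replication-timing S50 score
#'
#' Counts over ordered S-phase fractions (earliest to latest) are normalized
#' to proportions; S50 is the position in `[0, 1]` at which the piecewise
#' linear cumulative signal first reaches one half. All-zero count vectors
#' give the mid-S value 0.5.
#'
#' @param counts numeric matrix or data.frame, one row per gene (rownames =
#'   gene ids), K >= 2 ordered fraction columns.
#' @return named numeric vector of S50 scores in `[0, 1]`.
#' @export
s50_feature <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) < 2L) stop("need at least 2 S-phase fractions", call. = FALSE)
  K <- ncol(m)
  out <- apply(m, 1L, function(x) {
    tot <- sum(x)
    if (tot <= 0) return(0.5)
    cum <- cumsum(x / tot)
    i <- which(cum >= 0.5)[1L]
    prev <- if (i == 1L) 0 else cum[i - 1L]
    # linear interpolation of the cumulative curve within fraction i
    (i - 1L) / K + (0.5 - prev) / (cum[i] - prev) / K
  })
  setNames(as.numeric(out), rownames(m))
}
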