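#' @name annotation
#' @title Gene models, regions and training labels
#'
#' @description
#' Gene models are parsed from GTF into an internal 0-based half-open
#' coordinate representation. For every gene three region sets drive the
#' feature layer: the merged promoter (a fixed window upstream of every
#' transcript start site, strand-aware), the gene body (the gene span minus
#' the merged promoter) and the merged exons. Training labels are assembled
#' from user-supplied positive and exclusion gene lists over the parsed gene
#' universe.
NULL

new_gene_model <- function(gene_id, gene_name, chrom, strand, span_start,
                           span_end, transcripts) {
  structure(
    list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
         strand = strand, span_start = span_start, span_end = span_end,
         transcripts = transcripts),
    class = "GeneModel"
  )
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("<GeneModel> %s (%s) %s:%d-%d (%s), %d transcript(s)\n",
              x$gene_id, x$gene_name, x$chrom, x$span_start, x$span_end,
              x$strand, length(x$transcripts)))
  invisible(x)
}

validate_gene_model <- function(gm) {
  for (tx_id in names(gm$transcripts)) {
    ex <- gm$transcripts[[tx_id]]
    if (any(ex$start < gm$span_start) || any(ex$end > gm$span_end)) {
      stop(sprintf("gene %s: exon of transcript %s outside gene span",
                   gm$gene_id, tx_id), call. = FALSE)
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop(sprintf("gene %s: overlapping exons in transcript %s",
                   gm$gene_id, tx_id), call. = FALSE)
    }
  }
  invisible(gm)
}

check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L || is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L])))) {
      stop(sprintf("malformed GTF record at line %d of %s", i, path),
           call. = FALSE)
    }
  }
  invisible(path)
}

#' Parse gene models from GTF
#'
#' Reads gene/transcript/exon records and assembles one [GeneModel] per gene.
#' GTF 1-based closed coordinates are converted to the package's 0-based
#' half-open convention. When a protein-coding annotation is supplied, lncRNA
#' genes whose span overlaps any protein-coding gene span are dropped, keeping
#' only intergenic genes.
#'
#' @param gtf_source path to a GTF file with `gene_id`, `transcript_id` and
#'   optionally `gene_name` attributes.
#' @param pcg_gtf optional path to a protein-coding gene GTF; any overlap of
#'   gene spans excludes the lncRNA gene.
#' @return named list of `GeneModel` objects, keyed by `gene_id`.
#' @export
parse_gene_models <- function(gtf_source, pcg_gtf = NULL) {
  check_gtf_lines(gtf_source)
  gr <- rtracklayer::import(gtf_source, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$type)) {
    stop("GTF must carry 'type' and 'gene_id' attributes", call. = FALSE)
  }
  ex <- gr[md$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon records", call. = FALSE)
  exd <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    gene_name = if (!is.null(S4Vectors::mcols(ex)$gene_name)) {
      S4Vectors::mcols(ex)$gene_name
    } else {
      S4Vectors::mcols(ex)$gene_id
    },
    stringsAsFactors = FALSE
  )
  if (anyNA(exd$transcript_id)) {
    stop("exon record without transcript_id", call. = FALSE)
  }

  gene_rec <- gr[md$type == "gene"]
  gene_span <- if (length(gene_rec)) {
    data.frame(gene_id = S4Vectors::mcols(gene_rec)$gene_id,
               start = GenomicRanges::start(gene_rec) - 1L,
               end = GenomicRanges::end(gene_rec),
               stringsAsFactors = FALSE)
  } else {
    NULL
  }

  models <- lapply(split(exd, exd$gene_id), function(g) {
    gid <- g$gene_id[1L]
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L) {
      stop(sprintf("gene %s: exons on multiple chromosomes or strands", gid),
           call. = FALSE)
    }
    span <- if (!is.null(gene_span) && gid %in% gene_span$gene_id) {
      s <- gene_span[gene_span$gene_id == gid, ]
      c(s$start[1L], s$end[1L])
    } else {
      c(min(g$start), max(g$end))
    }
    txs <- lapply(split(g, g$transcript_id), function(t) {
      t <- t[order(t$start), ]
      data.frame(start = t$start, end = t$end)
    })
    validate_gene_model(new_gene_model(
      gid, g$gene_name[1L], g$chrom[1L], g$strand[1L], span[1L], span[2L], txs
    ))
  })

  if (!is.null(pcg_gtf)) {
    pcg <- rtracklayer::import(pcg_gtf, format = "gtf")
    pcg <- pcg[S4Vectors::mcols(pcg)$type %in% c("gene", "transcript", "exon")]
    pcg_spans <- GenomicRanges::reduce(pcg, ignore.strand = TRUE)
    spans <- gene_spans(models)
    hit <- GenomicRanges::findOverlaps(spans, pcg_spans, ignore.strand = TRUE)
    drop <- unique(S4Vectors::mcols(spans)$gene_id[S4Vectors::queryHits(hit)])
    models <- models[!names(models) %in% drop]
  }
  models
}

#' Gene spans of a gene-model list as GRanges
#'
#' @param models list of `GeneModel` objects.
#' @return a `GRanges` with a `gene_id` metadata column (1-based closed, as
#'   usual for GRanges).
#' @export
gene_spans <- function(models) {
  gr <- gi_to_granges(
    vapply(models, `[[`, "", "chrom"),
    vapply(models, `[[`, 0, "span_start"),
    vapply(models, `[[`, 0, "span_end"),
    vapply(models, `[[`, "", "strand")
  )
  S4Vectors::mcols(gr)$gene_id <- vapply(models, `[[`, "", "gene_id")
  names(gr) <- S4Vectors::mcols(gr)$gene_id
  gr
}

#' Write gene models to GTF
#'
#' Emits gene, transcript and exon records, converting back to 1-based
#' closed coordinates. Round-tripping through [parse_gene_models()] recovers
#' identical region sets.
#'
#' @param models list of `GeneModel` objects.
#' @param path output GTF path.
#' @export
write_gtf <- function(models, path) {
  rows <- lapply(models, function(gm) {
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";', gm$gene_id,
                      gm$gene_name)
    out <- list(sprintf("%s\tlncforge\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        gm$chrom, gm$span_start + 1L, gm$span_end,
                        gm$strand, attr_g))
    for (tx_id in names(gm$transcripts)) {
      ex <- gm$transcripts[[tx_id]]
      attr_t <- sprintf('%s transcript_id "%s";', attr_g, tx_id)
      out[[length(out) + 1L]] <- sprintf(
        "%s\tlncforge\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        gm$chrom, min(ex$start) + 1L, max(ex$end), gm$strand, attr_t)
      for (i in seq_len(nrow(ex))) {
        out[[length(out) + 1L]] <- sprintf(
          "%s\tlncforge\texon\t%d\t%d\t.\t%s\t.\t%s",
          gm$chrom, ex$start[i] + 1L, ex$end[i], gm$strand, attr_t)
      }
    }
    unlist(out)
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Derive promoter, gene-body and merged-exon regions for a gene
#'
#' The promoter of each transcript is `promoter_len` bases immediately
#' upstream of its strand-aware transcript start site; per-gene promoters are
#' merged. The gene body is the gene span minus the merged promoter, and the
#' exon region is the union of all transcript exons. Unstranded genes are
#' treated as plus strand with a warning. Promoters running past coordinate 0
#' are truncated at 0.
#'
#' @param gene a `GeneModel`.
#' @param promoter_len promoter window length in bases (default 1000).
#' @return a `RegionSet`: list with `gene_id`, `chrom`, `strand` and
#'   data.frames `promoter`, `gene_body`, `exons_merged` of 0-based half-open
#'   `start`/`end` intervals, each sorted by start.
#' @export
derive_regions <- function(gene, promoter_len = 1000) {
  stopifnot(inherits(gene, "GeneModel"), promoter_len >= 1)
  if (length(gene$transcripts) == 0L) {
    stop(sprintf("gene %s has no transcripts", gene$gene_id), call. = FALSE)
  }
  strand <- gene$strand
  if (!strand %in% c("+", "-")) {
    warning(sprintf("gene %s is unstranded; treating as plus strand",
                    gene$gene_id))
    strand <- "+"
  }
  prom <- lapply(gene$transcripts, function(ex) {
    if (strand == "+") {
      tss <- min(ex$start)
      c(max(0, tss - promoter_len), tss)
    } else {
      tss <- max(ex$end)
      c(tss, tss + promoter_len)
    }
  })
  prom <- do.call(rbind, prom)
  prom <- prom[prom[, 1L] < prom[, 2L], , drop = FALSE]
  promoter <- if (nrow(prom)) {
    union_intervals(data.frame(start = prom[, 1L], end = prom[, 2L]))
  } else {
    data.frame(start = integer(), end = integer())
  }
  gene_body <- complement_within(gene$span_start, gene$span_end, promoter)
  ex_all <- do.call(rbind, gene$transcripts)
  exons_merged <- union_intervals(ex_all[, c("start", "end")])

  structure(
    list(gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
         span_start = gene$span_start, span_end = gene$span_end,
         promoter = promoter, gene_body = gene_body,
         exons_merged = exons_merged),
    class = "RegionSet"
  )
}

region_granges <- function(rs, which = c("promoter", "gene_body",
                                         "exons_merged")) {
  which <- match.arg(which)
  df <- rs[[which]]
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  gi_to_granges(rep(rs$chrom, nrow(df)), df$start, df$end)
}

#' Assemble training labels from gene lists
#'
#' Positives are the supplied positive ids intersected with the gene
#' universe; negatives are the remaining universe after removing positives
#' and all exclusion-list genes. With `name_filter = TRUE`, genes whose
#' *name* contains the accession pattern "ENSG" (unstudied genes named by
#' their accession) are dropped from both classes.
#'
#' @param universe character vector of gene ids (the parsed gene universe),
#'   or a list of `GeneModel` objects.
#' @param positive_lists list of character vectors of positive gene ids.
#' @param exclusion_lists list of character vectors of ids excluded from the
#'   negative class (e.g. cancer-associated but not confirmed).
#' @param name_filter drop accession-named genes (default TRUE).
#' @param gene_names optional named character vector mapping gene_id to
#'   gene_name; derived automatically when `universe` is a gene-model list.
#' @param subclass optional named character vector mapping gene_id to a
#'   subclass tag (e.g. onco/ts/dual).
#' @return a `LabelSet`: list with character vectors `positives`,
#'   `negatives` and the `subclass` map (neutral for negatives).
#' @export
assemble_labels <- function(universe, positive_lists, exclusion_lists = list(),
                            name_filter = TRUE, gene_names = NULL,
                            subclass = NULL) {
  if (is.list(universe) && all(vapply(universe, inherits, TRUE, "GeneModel"))) {
    gene_names <- vapply(universe, `[[`, "", "gene_name")
    names(gene_names) <- vapply(universe, `[[`, "", "gene_id")
    universe <- names(gene_names)
  }
  stopifnot(is.character(universe))
  if (!is.list(positive_lists)) positive_lists <- list(positive_lists)
  if (!is.list(exclusion_lists)) exclusion_lists <- list(exclusion_lists)

  if (name_filter && !is.null(gene_names)) {
    accession <- names(gene_names)[grepl("ENSG", gene_names, fixed = TRUE)]
    universe <- setdiff(universe, accession)
  }
  pos_all <- unique(unlist(positive_lists))
  missing <- setdiff(pos_all, universe)
  if (length(missing)) {
    warning(sprintf("%d positive id(s) absent from universe; skipped",
                    length(missing)))
  }
  positives <- intersect(pos_all, universe)
  excluded <- unique(unlist(exclusion_lists))
  negatives <- setdiff(universe, union(pos_all, excluded))

  sub <- setNames(rep("neutral", length(negatives)), negatives)
  if (!is.null(subclass)) {
    keep <- intersect(names(subclass), positives)
    sub <- c(setNames(subclass[keep], keep), sub)
  }
  structure(list(positives = positives, negatives = negatives,
                 subclass = sub),
            class = "LabelSet")
}

#' @export
print.LabelSet <- function(x, ...) {
  cat(sprintf("<LabelSet> %d positives, %d negatives\n",
              length(x$positives), length(x$negatives)))
  invisible(x)
}

#' Export region sets to BED6
#'
#' @param region_sets list of `RegionSet` objects.
#' @param which one of "promoter", "gene_body", "exons_merged".
#' @param path output BED path (0-based half-open, as BED requires).
#' @export
write_regions_bed <- function(region_sets, which, path) {
  rows <- lapply(region_sets, function(rs) {
    df <- rs[[which]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(chrom = rs$chrom, start = df$start, end = df$end,
               name = rs$gene_id, score = 0L, strand = rs$strand)
  })
  out <- do.call(rbind, rows)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
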