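#' @name feature-table
#' @title Assembling the 44-feature table
#' @description Runs every feature operator over a bundle of parsed inputs
#'   and assembles the genes x 44 matrix in registry order, filling the
#'   per-feature missing-value defaults for absent inputs or uncovered genes.
NULL

new_feature_table <- function(values, specs = feature_specs()) {
  values <- as.matrix(values)
  stopifnot(identical(colnames(values), specs$name),
            !is.null(rownames(values)), !anyNA(values))
  structure(list(gene_ids = rownames(values), values = values, specs = specs),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("<FeatureTable> %d genes x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Subset a feature table by genes and/or features
#'
#' @param ft a `FeatureTable`.
#' @param genes optional gene ids to keep (in the given order).
#' @param features optional feature names to keep.
#' @return a `FeatureTable` (specs subset accordingly).
#' @export
subset_features <- function(ft, genes = NULL, features = NULL) {
  v <- ft$values
  specs <- ft$specs
  if (!is.null(genes)) {
    stopifnot(all(genes %in% rownames(v)))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(features)) {
    stopifnot(all(features %in% colnames(v)))
    v <- v[, features, drop = FALSE]
    specs <- specs[match(features, specs$name), ]
  }
  structure(list(gene_ids = rownames(v), values = v, specs = specs),
            class = "FeatureTable")
}

fill_feature <- function(tbl, name, values) {
  if (is.null(values) || length(values) == 0L) return(tbl)
  ids <- names(values)
  unknown <- setdiff(ids, rownames(tbl))
  if (length(unknown)) {
    warning(sprintf("feature %s: %d unknown gene id(s) skipped", name,
                    length(unknown)))
    values <- values[ids %in% rownames(tbl)]
    ids <- names(values)
  }
  tbl[ids, name] <- as.numeric(values)
  tbl
}

#' Build the 44-feature table from an input bundle
#'
#' Every recognised element of `inputs` feeds its feature operator; features
#' whose inputs are absent keep their registry missing-value default (0
#' everywhere, 0.5 for the replication S50). Gene ids in the inputs that are
#' not in the gene universe are skipped with a warning.
#'
#' @param inputs named list; recognised elements (all optional):
#'   `peaks` (list mark -> list sample -> intervals),
#'   `super_enhancers` (list cell type -> intervals),
#'   `methylation` (site table), `repliseq` (gene x fraction counts with
#'   gene ids in the first column), `conservation` (list with `phylop` and/or
#'   `phastcons` scored-interval tables), `genome` (DNAStringSet),
#'   `transcript_seqs` (DNAStringSet) + `tx2gene`, `repeats`, `cdt`,
#'   `expression` (`ExpressionMatrix`), `structures`,
#'   `screen`, `smprot`, `coexpression` (list with `expr` ExpressionMatrix
#'   and `important_genes`), `mirna` (list with `targets`, `cancer_mirnas`),
#'   `protein` (list with `clusters`, `important_proteins`),
#'   `variants` (with `rnasnp`/`cadd` columns), `cnv` (segment table).
#' @param models named list of `GeneModel` objects (the gene universe).
#' @param promoter_len promoter window for derived regions (default 1000).
#' @return a `FeatureTable` over all genes in `models`.
#' @export
build_feature_table <- function(inputs, models, promoter_len = 1000) {
  if (anyDuplicated(names(models))) {
    stop("duplicated gene_id in gene models", call. = FALSE)
  }
  specs <- feature_specs()
  gids <- names(models)
  tbl <- matrix(rep(specs$missing_default, each = length(gids)),
                nrow = length(gids),
                dimnames = list(gids, specs$name))
  spans <- gene_spans(models)
  regions <- lapply(models, derive_regions, promoter_len = promoter_len)

  if (!is.null(inputs$peaks)) {
    for (mark in names(inputs$peaks)) {
      col <- paste0(tolower(mark), "_peak_width")
      if (!col %in% specs$name) {
        warning(sprintf("unknown histone mark '%s' skipped", mark))
        next
      }
      tbl <- fill_feature(tbl, col,
                          peak_width_feature(inputs$peaks[[mark]], spans))
    }
  }
  if (!is.null(inputs$super_enhancers)) {
    tbl <- fill_feature(tbl, "super_enhancer_pct",
                        super_enhancer_pct(inputs$super_enhancers, spans))
  }
  if (!is.null(inputs$methylation)) {
    tbl <- fill_feature(tbl, "promoter_methylation_diff",
                        diff_methylation(inputs$methylation, regions,
                                         "promoter"))
    tbl <- fill_feature(tbl, "gene_body_methylation_diff",
                        diff_methylation(inputs$methylation, regions,
                                         "gene_body"))
  }
  if (!is.null(inputs$repliseq)) {
    rs <- as.data.frame(inputs$repliseq)
    counts <- as.matrix(rs[, -1L, drop = FALSE])
    rownames(counts) <- rs[[1L]]
    tbl <- fill_feature(tbl, "replication_s50", s50_feature(counts))
  }

  tbl <- fill_feature(tbl, "gene_length_log2", gene_length_log2(spans))
  if (!is.null(inputs$conservation)) {
    for (sc in intersect(names(inputs$conservation),
                         c("phylop", "phastcons"))) {
      for (w in c("gene", "exon")) {
        tbl <- fill_feature(tbl, paste0(sc, "_", w),
                            conservation_mean0(inputs$conservation[[sc]],
                                               regions, w))
      }
    }
  }
  if (!is.null(inputs$genome)) {
    tbl <- fill_feature(tbl, "gc_content_gene",
                        gc_content(inputs$genome, regions, "gene"))
    tbl <- fill_feature(tbl, "gc_content_exon",
                        gc_content(inputs$genome, regions, "exon"))
  }
  if (!is.null(inputs$repeats)) {
    rd <- repeat_density(inputs$repeats, spans)
    for (col in colnames(rd)) tbl <- fill_feature(tbl, col, rd[, col])
  }
  if (!is.null(inputs$cdt)) {
    tbl <- fill_feature(tbl, "cdt", cdt_indicator(inputs$cdt, spans))
  }
  if (!is.null(inputs$transcript_seqs) && !is.null(inputs$tx2gene)) {
    tbl <- fill_feature(tbl, "kmer_pc1",
                        kmer_pc1(inputs$transcript_seqs, inputs$tx2gene))
  }

  if (!is.null(inputs$expression)) {
    tbl <- fill_feature(tbl, "gene_expression_logfc",
                        expression_logfc(inputs$expression))
    tbl <- fill_feature(tbl, "tissue_specificity", tau(inputs$expression))
  }
  if (!is.null(inputs$structures) && !is.null(inputs$tx2gene)) {
    sf <- structure_features(inputs$structures, inputs$tx2gene)
    for (col in setdiff(names(sf), "gene_id")) {
      tbl <- fill_feature(tbl, col, setNames(sf[[col]], sf$gene_id))
    }
  }

  if (!is.null(inputs$screen)) {
    tbl <- fill_feature(tbl, "crispri_screen_score",
                        crispri_phenotype(inputs$screen))
  }
  if (!is.null(inputs$smprot)) {
    sp <- small_protein_features(inputs$smprot, spans)
    for (col in colnames(sp)) tbl <- fill_feature(tbl, col, sp[, col])
  }

  if (!is.null(inputs$coexpression)) {
    tbl <- fill_feature(tbl, "mrna_centrality",
                        mrna_degree(inputs$coexpression$expr,
                                    inputs$coexpression$important_genes,
                                    beta = inputs$coexpression$beta))
  }
  if (!is.null(inputs$mirna)) {
    tbl <- fill_feature(tbl, "mirna_centrality",
                        mirna_degree(inputs$mirna$targets,
                                     inputs$mirna$cancer_mirnas,
                                     inputs$tx2gene))
  }
  if (!is.null(inputs$protein)) {
    tbl <- fill_feature(tbl, "protein_centrality",
                        protein_degree(inputs$protein$clusters,
                                       inputs$protein$important_proteins))
  }

  if (!is.null(inputs$variants)) {
    vgr <- variants_gr(inputs$variants)
    st <- stack_regions(regions, function(rs) {
      df <- rbind(data.frame(start = rs$span_start, end = rs$span_end),
                  rs$promoter)
      data.frame(chrom = rs$chrom, start = df$start, end = df$end)
    })
    hit <- GenomicRanges::findOverlaps(st$gr, vgr, ignore.strand = TRUE)
    touched <- names(regions)[unique(st$gene[S4Vectors::queryHits(hit)])]
    tbl <- fill_feature(tbl, "exon_mutation_or",
                        mutation_odds_ratio(inputs$variants, regions,
                                            genes_with_data = touched))
    for (sc in intersect(c("rnasnp", "cadd"), names(inputs$variants))) {
      tbl <- fill_feature(tbl, paste0(sc, "_impact"),
                          functional_impact_mean(inputs$variants, regions,
                                                 sc))
    }
  }
  if (!is.null(inputs$cnv)) {
    tbl <- fill_feature(tbl, "cnv", cnv_feature(inputs$cnv, spans))
  }

  new_feature_table(tbl, specs)
}

#' Write a feature table to TSV
#'
#' @param ft a `FeatureTable`.
#' @param path output path; first column `gene_id`, then the 44 features in
#'   registry order.
#' @export
write_feature_table <- function(ft, path) {
  out <- data.table::data.table(gene_id = ft$gene_ids)
  out <- cbind(out, data.table::as.data.table(ft$values))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return a `FeatureTable`.
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  v <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(v) <- dt[[1L]]
  new_feature_table(v)
}
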