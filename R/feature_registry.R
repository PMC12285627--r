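#' The 44-feature registry
#'
#' Central registry of the 44 candidate features used to score cancer
#' potential of intergenic lncRNA genes. Features are grouped into six
#' categories (15 epigenomic, 13 genomic, 6 transcriptomic, 3 phenotype,
#' 3 network, 4 mutation). Each feature carries the default used when the
#' corresponding input carries no data for a gene: 0 for everything except
#' the replication-timing S50 score, whose all-zero-signal convention is the
#' mid-S-phase value 0.5.
#'
#' @return a data.frame with columns `index`, `name` (machine-readable column
#'   id), `label` (human-readable name), `category` and `missing_default`.
#' @export
feature_specs <- function() {
  marks <- c("H3K4me3", "H3K4me2", "H3K4me1", "H3K27ac", "H3K36me3",
             "H3K9ac", "H3K27me3", "H3K9me2", "H3K9me3", "H3K79me2",
             "H4K20me1")
  specs <- rbind(
    data.frame(name = paste0(tolower(marks), "_peak_width"),
               label = paste(marks, "peak width"),
               category = "Epigenomics", missing_default = 0),
    data.frame(name = c("super_enhancer_pct", "promoter_methylation_diff",
                        "gene_body_methylation_diff", "replication_s50"),
               label = c("Super enhancer percentage",
                         "Promoter methylation difference",
                         "Gene body methylation difference",
                         "Replication time S50"),
               category = "Epigenomics",
               missing_default = c(0, 0, 0, 0.5)),
    data.frame(name = c("gene_length_log2",
                        "phylop_gene", "phylop_exon",
                        "phastcons_gene", "phastcons_exon",
                        "gc_content_gene", "gc_content_exon",
                        "sine_density", "line_density", "ltr_density",
                        "satellite_density", "cdt", "kmer_pc1"),
               label = c("Gene length (log2)",
                         "PhyloP conservation (gene)",
                         "PhyloP conservation (exon)",
                         "PhastCons conservation (gene)",
                         "PhastCons conservation (exon)",
                         "GC content (gene)", "GC content (exon)",
                         "SINE density", "LINE density", "LTR density",
                         "Satellite density", "Cancer driver TAD",
                         "K-mer PC1"),
               category = "Genomics", missing_default = 0),
    data.frame(name = c("gene_expression_logfc", "tissue_specificity",
                        "secondary_structure_mfe", "paired_proportion",
                        "paired_gc_proportion", "secondary_structure_pc1"),
               label = c("Gene expression logFC", "Tissue specificity",
                         "Secondary structure MFE", "Paired proportion",
                         "Paired GC proportion", "Secondary structure PC1"),
               category = "Transcriptomics", missing_default = 0),
    data.frame(name = c("crispri_screen_score", "small_protein_density",
                        "small_protein_coverage"),
               label = c("CRISPRi screen score", "Small protein density",
                         "Small protein coverage"),
               category = "Phenotype", missing_default = 0),
    data.frame(name = c("mrna_centrality", "mirna_centrality",
                        "protein_centrality"),
               label = c("mRNA centrality", "miRNA centrality",
                         "Protein centrality"),
               category = "Network", missing_default = 0),
    data.frame(name = c("exon_mutation_or", "rnasnp_impact", "cadd_impact",
                        "cnv"),
               label = c("Exon mutation odds ratio", "RNAsnp impact",
                         "CADD impact", "CNV"),
               category = "Mutation", missing_default = 0)
  )
  specs$index <- seq_len(nrow(specs))
  specs[, c("index", "name", "label", "category", "missing_default")]
}

# Features shifted by each named effect-size family in the synthetic
# generator. Families follow the natural membership of the registry:
# every histone-mark width for "peak_width", the three network centralities
# for "degrees", and the single MFE / logFC columns. Any registry column name
# can also be used directly as an effect-size key.
effect_family_members <- function(family) {
  specs <- feature_specs()
  switch(family,
    peak_width = grep("_peak_width$", specs$name, value = TRUE),
    degrees = c("mrna_centrality", "mirna_centrality", "protein_centrality"),
    mfe = "secondary_structure_mfe",
    abs_logfc = "gene_expression_logfc",
    if (family %in% specs$name) family
    else stop(sprintf("unknown effect-size family or feature: '%s'", family),
              call. = FALSE)
  )
}
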