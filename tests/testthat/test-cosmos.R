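# Standardized class shift of one feature column: positives vs negatives.
std_shift <- function(values, labels, feature, transform = identity) {
  v <- transform(values[, feature])
  (mean(v[labels == 1]) - mean(v[labels == 0])) / sd(v[labels == 0])
}

test_that("generate_feature_table has the right shape, labels and truth", {
  cfg <- cosmos_config(n_genes = 120, n_pos = 20, seed = 2)
  cz <- generate_feature_table(cfg)
  expect_equal(dim(cz$features$values), c(120, 44))
  expect_equal(colnames(cz$features$values), feature_specs()$name)
  expect_equal(sum(cz$labels), 20)
  expect_setequal(names(which(cz$labels == 1)), cz$truth$positives)
  # informative set = union of the four default effect families (16 features)
  expect_length(cz$truth$informative, 16)
  expect_true("secondary_structure_mfe" %in% cz$truth$informative)
  expect_true(all(grep("_peak_width$", colnames(cz$features$values),
                       value = TRUE) %in% cz$truth$informative))
})

test_that("generate_feature_table is seed-deterministic", {
  a <- generate_feature_table(cosmos_config(n_genes = 60, n_pos = 10,
                                            seed = 5))
  b <- generate_feature_table(cosmos_config(n_genes = 60, n_pos = 10,
                                            seed = 5))
  d <- generate_feature_table(cosmos_config(n_genes = 60, n_pos = 10,
                                            seed = 6))
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$truth$positives, b$truth$positives)
  expect_false(identical(a$features$values, d$features$values))
})

test_that("direct feature table plants the configured standardized shifts", {
  cfg <- cosmos_config(n_genes = 900, n_pos = 150, seed = 11)
  cz <- generate_feature_table(cfg)
  se3 <- 3 * sqrt(1 / 150 + 1 / 750)
  expect_lt(abs(std_shift(cz$features$values, cz$labels,
                          "secondary_structure_mfe") - (-1)), se3)
  expect_lt(abs(std_shift(cz$features$values, cz$labels,
                          "h3k4me3_peak_width") - 0.8), se3)
  expect_lt(abs(std_shift(cz$features$values, cz$labels,
                          "mirna_centrality") - 1), se3)
  # abs_logfc shifts the magnitude: mean(|pos|) - mean(|neg|) = 1.2 exactly
  # in expectation (the SE scales with the sd of the folded values)
  av <- abs(cz$features$values[, "gene_expression_logfc"])
  dmean <- mean(av[cz$labels == 1]) - mean(av[cz$labels == 0])
  expect_lt(abs(dmean - 1.2),
            3 * sd(av[cz$labels == 0]) * sqrt(1 / 150 + 1 / 750))
  # a neutral feature stays unshifted
  expect_lt(abs(std_shift(cz$features$values, cz$labels, "cnv")), se3)
})

test_that("shifting only the MFE puts it at rank 1 of the global ranking", {
  cfg <- cosmos_config(n_genes = 400, n_pos = 60,
                       effect_sizes = list(mfe = -2), seed = 3)
  cz <- generate_feature_table(cfg)
  model <- train_model(cz$features, cz$labels, train_config(seed = 3))
  imp <- feature_importance(shap_values(model, cz$features))
  expect_equal(imp$feature[1], "secondary_structure_mfe")
})

test_that("cosmos_config validates counts and effect keys", {
  expect_error(cosmos_config(n_genes = 10, n_pos = 10))
  expect_error(cosmos_config(n_genes = 10, n_pos = 2, n_tumor = 1))
  expect_error(cosmos_config(effect_sizes = list(nope = 1)), "unknown")
  expect_error(cosmos_config(noise_sd = 0))
})

test_that("generate_cosmos is byte-identical across runs of one seed", {
  cfg <- cosmos_config(n_genes = 25, n_pos = 6, n_tumor = 4, n_normal = 3,
                       n_tissues = 2, seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cosmos(cfg, d1)
  generate_cosmos(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  expect_true(length(f1) >= 15)  # annotation + all omics layers + labels
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # refuses to overwrite an existing cosmos
  expect_error(generate_cosmos(cfg, d1), "already")
})

test_that("every generated file parses back with zero warnings", {
  cfg <- cosmos_config(n_genes = 30, n_pos = 8, n_tumor = 4, n_normal = 3,
                       n_tissues = 2, seed = 9)
  dir <- withr::local_tempdir()
  generate_cosmos(cfg, dir)
  expect_no_warning(cz <- read_cosmos(dir))
  expect_length(cz$models, 30)
  expect_setequal(cz$labels$positives, cz$truth$positives)
  expect_no_warning(build_feature_table(cz$inputs, cz$models))
})

test_that("file-derived features carry the planted family shifts (3 SE)", {
  cfg <- cosmos_config(n_genes = 500, n_pos = 75, n_tumor = 8, n_normal = 5,
                       n_tissues = 3, seed = 4)
  dir <- withr::local_tempdir()
  generate_cosmos(cfg, dir)
  cz <- read_cosmos(dir)
  ft <- build_feature_table(cz$inputs, cz$models)
  y <- lncforge:::labels_vector(cz$labels, ft$gene_ids)[ft$gene_ids]
  se3 <- 3 * sqrt(1 / 75 + 1 / 425)
  expect_lt(abs(std_shift(ft$values, y, "secondary_structure_mfe") - (-1)),
            se3)
  expect_lt(abs(std_shift(ft$values, y, "h3k4me3_peak_width") - 0.8), se3)
  expect_lt(abs(std_shift(ft$values, y, "mirna_centrality") - 1), se3)
  expect_lt(abs(std_shift(ft$values, y, "protein_centrality") - 1), se3)
  # the logFC magnitude shift is compared against the direct-table
  # generator under the same configuration (standardized scales match
  # within combined sampling error)
  direct <- generate_feature_table(cfg)
  expect_lt(abs(std_shift(ft$values, y, "gene_expression_logfc", abs) -
                  std_shift(direct$features$values, direct$labels,
                            "gene_expression_logfc", abs)),
            sqrt(2) * se3)
  # degree family via co-expression is directional only (heavy-tailed scale)
  expect_gt(std_shift(ft$values, y, "mrna_centrality"), 0)
  # neutral layers stay unshifted
  expect_lt(abs(std_shift(ft$values, y, "cnv")), se3)
  expect_lt(abs(std_shift(ft$values, y, "sine_density")), se3)
  expect_lt(abs(std_shift(ft$values, y, "phylop_gene")), se3)
})

test_that("feature table TSV round trip is lossless", {
  cz <- generate_feature_table(cosmos_config(n_genes = 40, n_pos = 8,
                                             seed = 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(cz$features, path)
  back <- read_feature_table(path)
  expect_equal(back$gene_ids, cz$features$gene_ids)
  expect_equal(back$values, cz$features$values, tolerance = 1e-12)
  sub <- subset_features(back, genes = back$gene_ids[1:5],
                         features = c("cnv", "kmer_pc1"))
  expect_equal(dim(sub$values), c(5, 2))
  expect_equal(sub$specs$name, c("cnv", "kmer_pc1"))
})

test_that("absent inputs fall back to registry defaults", {
  models <- tiny_models()
  ft <- build_feature_table(list(), models)
  expect_equal(unname(ft$values[, "replication_s50"]), c(0.5, 0.5))
  expect_equal(unname(ft$values[, "cnv"]), c(0, 0))
  # gene length is derivable from the models alone
  expect_equal(unname(ft$values["gA", "gene_length_log2"]), log2(3000))
})
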