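#' @name transcriptomic-features
#' @title Transcriptomic feature operators
#' @description Expression log fold change, the tissue-specificity tau score
#'   and RNA secondary-structure summaries.
NULL

#' Construct an expression matrix with sample metadata
#'
#' @param values nonnegative numeric matrix (genes x samples; FPKM-like
#'   units), with gene rownames and sample colnames.
#' @param sample_meta data.frame with `sample_id`, `condition`
#'   (`tumor`/`normal`) and `tissue`.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, sample_meta) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)),
            all(values >= 0),
            all(c("sample_id", "condition", "tissue") %in% names(sample_meta)),
            all(colnames(values) %in% sample_meta$sample_id),
            all(sample_meta$condition %in% c("tumor", "normal")))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  structure(list(values = values, sample_meta = sample_meta),
            class = "ExpressionMatrix")
}

#' Tumor-versus-normal expression log fold change
#'
#' `log2((mean tumor + eps) / (mean normal + eps))` per gene; the pseudocount
#' keeps zero-expression genes finite on FPKM-like scales.
#'
#' @param expr an `ExpressionMatrix`.
#' @param eps pseudocount (default 0.01).
#' @return named numeric vector over the matrix's genes.
#' @export
expression_logfc <- function(expr, eps = 0.01) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  tum <- expr$sample_meta$condition == "tumor"
  if (!any(tum) || all(tum)) {
    stop("need at least one tumor and one normal sample", call. = FALSE)
  }
  mt <- rowMeans(expr$values[, tum, drop = FALSE])
  mn <- rowMeans(expr$values[, !tum, drop = FALSE])
  log2((mt + eps) / (mn + eps))
}

#' Tissue-specificity tau score for one gene
#'
#' `tau = (n - sum_i x_i / max(x)) / (n - 1)` over `n >= 2` nonnegative
#' per-tissue mean expression values: 0 for uniform expression, 1 for
#' single-tissue expression. All-zero input returns 0 (the no-expression
#' convention).
#'
#' @param tissue_means nonnegative numeric vector of per-tissue means.
#' @return tau in `[0, 1]`.
#' @export
tau_score <- function(tissue_means) {
  stopifnot(all(tissue_means >= 0))
  n <- length(tissue_means)
  if (n < 2L) stop("tau needs at least 2 tissues", call. = FALSE)
  mx <- max(tissue_means)
  if (mx == 0) return(0)
  (n - sum(tissue_means / mx)) / (n - 1)
}

#' Tissue-specificity tau over an expression matrix
#'
#' Mean expression is computed per tumor tissue, then [tau_score()] is
#' applied per gene.
#'
#' @param expr an `ExpressionMatrix`; tumor samples define the tissues.
#' @return named numeric vector of tau scores in `[0, 1]`.
#' @export
tau <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  tum <- expr$sample_meta$condition == "tumor"
  tissues <- expr$sample_meta$tissue[tum]
  if (length(unique(tissues)) < 2L) {
    stop("tau needs at least 2 tumor tissues", call. = FALSE)
  }
  v <- expr$values[, tum, drop = FALSE]
  means <- t(rowsum(t(v), tissues) / as.numeric(table(tissues)))
  apply(means, 1L, tau_score)
}

validate_dot_bracket <- function(db, seq) {
  if (nchar(db) != nchar(seq)) {
    stop("dot-bracket length differs from sequence length", call. = FALSE)
  }
  depth <- cumsum((strsplit(db, "")[[1L]] == "(") -
                    (strsplit(db, "")[[1L]] == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    stop("unbalanced dot-bracket structure", call. = FALSE)
  }
  invisible(db)
}

# 512-dimensional structural profile of one transcript: sliding 3-nt windows
# indexed by (trinucleotide, per-position paired pattern): 4^3 * 2^3 = 512
# combinations, counts normalized by transcript length.
structure_profile_512 <- function(seq, db) {
  chars <- strsplit(toupper(chartr("T", "U", seq)), "")[[1L]]
  base_idx <- match(chars, c("A", "C", "G", "U"))
  paired <- strsplit(db, "")[[1L]] %in% c("(", ")")
  n <- length(chars)
  out <- numeric(512L)
  if (n >= 3L) {
    i <- seq_len(n - 2L)
    b1 <- base_idx[i]
    b2 <- base_idx[i + 1L]
    b3 <- base_idx[i + 2L]
    tri <- (b1 - 1L) * 16L + (b2 - 1L) * 4L + (b3 - 1L)
    pat <- paired[i] * 4L + paired[i + 1L] * 2L + paired[i + 2L]
    idx <- tri * 8L + pat + 1L
    counts <- tabulate(idx[!is.na(idx)], nbins = 512L)
    out <- as.numeric(counts)
  }
  out / n
}

#' Secondary-structure features from dot-bracket records
#'
#' Per gene (mean over its transcripts): minimum free energy, the fraction
#' of paired positions, the G/C fraction among paired positions, and the PC1
#' score of the 512-dimensional (trinucleotide x paired-pattern) windowed
#' profile.
#'
#' @param structures data.frame with `transcript_id`, `sequence` (RNA or DNA
#'   alphabet), `dot_bracket` and `mfe` (kcal/mol).
#' @param tx2gene data.frame with `transcript_id`, `gene_id`.
#' @return data.frame with `gene_id`, `secondary_structure_mfe`,
#'   `paired_proportion`, `paired_gc_proportion`, `secondary_structure_pc1`.
#' @export
structure_features <- function(structures, tx2gene) {
  structures <- merge(structures, tx2gene, by = "transcript_id")
  if (nrow(structures) == 0L) {
    stop("no structure record maps to a gene", call. = FALSE)
  }
  per_tx <- lapply(seq_len(nrow(structures)), function(i) {
    seq <- structures$sequence[i]
    db <- structures$dot_bracket[i]
    validate_dot_bracket(db, seq)
    chars <- strsplit(toupper(chartr("T", "U", seq)), "")[[1L]]
    paired <- strsplit(db, "")[[1L]] %in% c("(", ")")
    list(
      mfe = structures$mfe[i],
      paired_prop = mean(paired),
      paired_gc = if (any(paired)) {
        mean(chars[paired] %in% c("G", "C"))
      } else {
        0
      },
      profile = structure_profile_512(seq, db)
    )
  })
  by_gene <- split(per_tx, structures$gene_id)
  prof <- t(vapply(by_gene, function(txs) {
    rowMeans(vapply(txs, `[[`, numeric(512L), "profile"))
  }, numeric(512L)))
  pc1 <- if (nrow(prof) >= 2L) {
    pc1_scores(prof)
  } else {
    setNames(0, rownames(prof))
  }
  data.frame(
    gene_id = names(by_gene),
    secondary_structure_mfe = vapply(by_gene, function(t) {
      mean(vapply(t, `[[`, 0, "mfe"))
    }, 0),
    paired_proportion = vapply(by_gene, function(t) {
      mean(vapply(t, `[[`, 0, "paired_prop"))
    }, 0),
    paired_gc_proportion = vapply(by_gene, function(t) {
      mean(vapply(t, `[[`, 0, "paired_gc"))
    }, 0),
    secondary_structure_pc1 = as.numeric(pc1[names(by_gene)]),
    row.names = NULL
  )
}
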