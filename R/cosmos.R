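#' @name synthetic-cosmos
#' @title Synthetic multi-omics cosmos generator
#' @description Generates a fully synthetic "cosmos" with known ground truth:
#'   either a feature table directly (Gaussian features with standardized
#'   class shifts planted into the configured effect families) or a directory
#'   of raw annotation/omics files that the ingestion and feature layers can
#'   consume end to end. All output is a deterministic function of the
#'   configuration seed.
NULL

#' Configuration of the synthetic cosmos
#'
#' @param n_genes number of lncRNA genes (default 1946).
#' @param n_pos number of planted positive (cancer) genes (default 285).
#' @param n_tissues number of tumor tissues (default 8).
#' @param n_tumor,n_normal tumor / normal sample counts (defaults 30 / 15).
#' @param effect_sizes named list of standardized class shifts, keyed by
#'   effect family (`peak_width`, `mfe`, `abs_logfc`, `degrees`) or by any
#'   single registry feature name; every member feature of a family receives
#'   the full family shift. `abs_logfc` shifts the *magnitude* of the log
#'   fold change with a random sign. Defaults:
#'   `mfe = -1`, `abs_logfc = 1.2`, `degrees = 1`, `peak_width = 0.8`.
#' @param noise_sd baseline feature standard deviation (default 1).
#' @param seed master seed (default 1).
#' @return a `CosmosConfig` object.
#' @export
cosmos_config <- function(n_genes = 1946, n_pos = 285, n_tissues = 8,
                          n_tumor = 30, n_normal = 15,
                          effect_sizes = list(mfe = -1, abs_logfc = 1.2,
                                              degrees = 1, peak_width = 0.8),
                          noise_sd = 1, seed = 1) {
  stopifnot(n_genes >= 4, n_pos >= 2, n_pos < n_genes, n_tissues >= 2,
            n_tumor >= 2, n_normal >= 2, noise_sd > 0,
            length(effect_sizes) == 0L || !is.null(names(effect_sizes)))
  for (fam in names(effect_sizes)) effect_family_members(fam)  # validate keys
  structure(list(n_genes = as.integer(n_genes), n_pos = as.integer(n_pos),
                 n_tissues = as.integer(n_tissues),
                 n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 seed = seed),
            class = "CosmosConfig")
}

#' @export
print.CosmosConfig <- function(x, ...) {
  cat(sprintf(
    "<CosmosConfig> %d genes (%d positives), %d tissues, seed %s\n",
    x$n_genes, x$n_pos, x$n_tissues, format(x$seed)))
  cat("  effects:", paste(sprintf("%s=%g", names(x$effect_sizes),
                                  unlist(x$effect_sizes)), collapse = ", "),
      "\n")
  invisible(x)
}

cosmos_gene_ids <- function(cfg) sprintf("LNC%05d", seq_len(cfg$n_genes))

cosmos_positives <- function(cfg, ids = cosmos_gene_ids(cfg)) {
  sort(with_seed(derive_seed(cfg$seed, "labels"), sample(ids, cfg$n_pos)))
}

cosmos_informative <- function(cfg) {
  fams <- names(cfg$effect_sizes)[unlist(cfg$effect_sizes) != 0]
  sort(unique(unlist(lapply(fams, effect_family_members))))
}

#' Generate a synthetic feature table with planted class shifts
#'
#' Draws every feature i.i.d. Gaussian with standard deviation `noise_sd`
#' and shifts the positive class in each configured effect family by
#' `effect * noise_sd` (for `abs_logfc`, the magnitude is shifted and a
#' random sign applied). This is the fast path for exercising the learning,
#' threshold and attribution layers against known truth.
#'
#' @param cfg a `CosmosConfig`.
#' @return list with `features` (a `FeatureTable`), `labels` (named 0/1
#'   vector) and `truth` (a `PlantedTruth`: positives, informative feature
#'   names, effect sizes, config).
#' @export
generate_feature_table <- function(cfg = cosmos_config()) {
  stopifnot(inherits(cfg, "CosmosConfig"))
  specs <- feature_specs()
  ids <- cosmos_gene_ids(cfg)
  positives <- cosmos_positives(cfg, ids)
  is_pos <- ids %in% positives
  x <- with_seed(derive_seed(cfg$seed, "features"), {
    m <- matrix(stats::rnorm(cfg$n_genes * nrow(specs), sd = cfg$noise_sd),
                nrow = cfg$n_genes,
                dimnames = list(ids, specs$name))
    for (fam in names(cfg$effect_sizes)) {
      eff <- cfg$effect_sizes[[fam]]
      if (eff == 0) next
      for (col in effect_family_members(fam)) {
        if (fam == "abs_logfc") {
          sgn <- sample(c(-1, 1), sum(is_pos), replace = TRUE)
          m[is_pos, col] <- sgn * (abs(m[is_pos, col]) + eff * cfg$noise_sd)
        } else {
          m[is_pos, col] <- m[is_pos, col] + eff * cfg$noise_sd
        }
      }
    }
    m
  })
  labels <- setNames(as.numeric(is_pos), ids)
  truth <- structure(list(positives = positives,
                          informative = cosmos_informative(cfg),
                          effect_sizes = cfg$effect_sizes, config = cfg),
                     class = "PlantedTruth")
  list(features = new_feature_table(x, specs), labels = labels, truth = truth)
}

## Raw-file cosmos -------------------------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

cosmos_gene_models <- function(cfg) {
  ids <- cosmos_gene_ids(cfg)
  with_seed(derive_seed(cfg$seed, "genes"), {
    chroms <- paste0("chr", 1:3)
    per_chrom <- split(seq_len(cfg$n_genes),
                       rep_len(seq_along(chroms), cfg$n_genes))
    models <- vector("list", cfg$n_genes)
    for (ci in seq_along(chroms)) {
      offset <- 5000L
      for (gi in per_chrom[[ci]]) {
        len <- as.integer(round(stats::runif(1, 2000, 6000)))
        span <- c(offset, offset + len)
        strand <- sample(c("+", "-"), 1L)
        n_tx <- sample(1:2, 1L)
        txs <- list()
        for (t in seq_len(n_tx)) {
          n_ex <- sample(2:3, 1L)
          # cut the span into alternating exon/intron segments; the first
          # exon starts at span start and the last ends at span end so every
          # transcript shares the gene TSS window
          cuts <- sort(sample(seq(span[1] + 100L, span[2] - 100L, by = 50L),
                              2L * (n_ex - 1L)))
          bounds <- c(span[1], cuts, span[2])
          starts <- bounds[seq(1L, length(bounds), by = 2L)]
          ends <- bounds[seq(2L, length(bounds), by = 2L)]
          txs[[sprintf("%s.t%d", ids[gi], t)]] <-
            data.frame(start = starts, end = ends)
        }
        models[[gi]] <- new_gene_model(ids[gi], ids[gi], chroms[ci], strand,
                                       span[1], span[2], txs)
        offset <- span[2] + 8000L
      }
    }
    names(models) <- ids
    models
  })
}

cosmos_write_tsv <- function(df, dir, name) {
  data.table::fwrite(df, file.path(dir, name), sep = "\t")
}

#' Generate a raw-file synthetic cosmos
#'
#' Writes a complete synthetic input bundle -- gene annotation (GTF), genome
#' (FASTA), per-mark histone peaks, super enhancers, methylation sites,
#' replication-timing counts, conservation tracks, repeats, cancer-driver
#' TADs, expression and co-expression matrices, secondary structures, CRISPRi
#' screen, small proteins, miRNA targets, protein binding clusters, variants,
#' CNV segments, label lists and a `truth.json` -- such that running the
#' ingestion and feature layers over the directory yields features whose
#' positive-class standardized shifts match the configured effect sizes
#' (the co-expression centrality shift is planted directionally through a
#' shared latent factor). Output is byte-identical for a fixed config.
#'
#' @param cfg a `CosmosConfig`.
#' @param out_dir output directory (created; must not already contain a
#'   `truth.json`).
#' @return `out_dir`, invisibly.
#' @export
generate_cosmos <- function(cfg = cosmos_config(), out_dir) {
  stopifnot(inherits(cfg, "CosmosConfig"))
  if (file.exists(file.path(out_dir, "truth.json"))) {
    stop("output directory already holds a cosmos", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cosmos_gene_ids(cfg)
  positives <- cosmos_positives(cfg, ids)
  is_pos <- setNames(ids %in% positives, ids)
  models <- cosmos_gene_models(cfg)
  write_gtf(models, file.path(out_dir, "genes.gtf"))

  chroms <- unique(vapply(models, `[[`, "", "chrom"))
  chrom_len <- vapply(chroms, function(ch) {
    max(vapply(models[vapply(models, `[[`, "", "chrom") == ch], `[[`, 0,
               "span_end")) + 10000L
  }, 0)
  genome <- with_seed(derive_seed(cfg$seed, "genome"), {
    Biostrings::DNAStringSet(setNames(
      vapply(chrom_len, random_dna, ""), chroms))
  })
  Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))

  spans <- lapply(models, function(m) c(m$span_start, m$span_end))
  chrom_of <- unname(vapply(models, `[[`, "", "chrom"))

  # --- histone peaks: gene-level latent width shared across samples --------
  eff <- function(fam) cfg$effect_sizes[[fam]] %||% 0
  marks <- sub("_peak_width$", "",
               grep("_peak_width$", feature_specs()$name, value = TRUE))
  n_peak_samples <- 3L
  peaks <- with_seed(derive_seed(cfg$seed, "peaks"), {
    rows <- list()
    for (mark in marks) {
      w_g <- 2000 + 400 * stats::rnorm(cfg$n_genes) +
        400 * eff("peak_width") * is_pos
      w_g <- pmax(50, w_g)
      for (s in seq_len(n_peak_samples)) {
        w <- pmin(pmax(50, round(w_g + 40 * stats::rnorm(cfg$n_genes))),
                  vapply(spans, diff, 0))
        start <- vapply(seq_len(cfg$n_genes), function(g) {
          spans[[g]][1] + sample.int(spans[[g]][2] - spans[[g]][1] -
                                       w[g] + 1L, 1L) - 1L
        }, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          mark = mark, sample = sprintf("s%d", s), chrom = chrom_of,
          start = as.integer(start), end = as.integer(start + w))
      }
    }
    do.call(rbind, rows)
  })
  cosmos_write_tsv(peaks, out_dir, "peaks.tsv")

  # --- expression: per-gene true logFC, lognormal sample noise --------------
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(cfg$n_tumor + cfg$n_normal)),
    condition = rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)),
    tissue = c(rep_len(sprintf("tissue%d", seq_len(cfg$n_tissues)),
                       cfg$n_tumor),
               rep("normal_tissue", cfg$n_normal)))
  expr <- with_seed(derive_seed(cfg$seed, "expression"), {
    lfc <- 0.5 * stats::rnorm(cfg$n_genes)
    if (eff("abs_logfc") != 0) {
      np <- sum(is_pos)
      lfc[is_pos] <- sample(c(-1, 1), np, replace = TRUE) *
        (abs(lfc[is_pos]) + 0.5 * eff("abs_logfc"))
    }
    base <- exp(stats::rnorm(cfg$n_genes, log(5), 0.5))
    tum <- samples$condition == "tumor"
    v <- matrix(0, cfg$n_genes, nrow(samples),
                dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- base * if (tum[j]) 2^lfc else 1
      v[, j] <- mu * exp(stats::rnorm(cfg$n_genes, 0, 0.15))
    }
    v
  })
  cosmos_write_tsv(cbind(data.frame(gene_id = ids), as.data.frame(expr)),
                   out_dir, "expression.tsv")
  cosmos_write_tsv(samples, out_dir, "samples.tsv")

  # --- secondary structures: gene-level latent MFE --------------------------
  structures <- with_seed(derive_seed(cfg$seed, "structures"), {
    m_g <- stats::rnorm(cfg$n_genes, -30, 5) + 5 * eff("mfe") * is_pos
    rows <- list()
    for (g in seq_len(cfg$n_genes)) {
      gm <- models[[g]]
      chrom_seq <- genome[[gm$chrom]]
      for (tx_id in names(gm$transcripts)) {
        ex <- gm$transcripts[[tx_id]]
        seq <- paste(vapply(seq_len(nrow(ex)), function(i) {
          as.character(Biostrings::subseq(chrom_seq, ex$start[i] + 1L,
                                          ex$end[i]))
        }, ""), collapse = "")
        n <- nchar(seq)
        npair <- round(stats::runif(1, 0.2, 0.3) * n)
        db <- paste0(strrep("(", npair), strrep(".", n - 2L * npair),
                     strrep(")", npair))
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tx_id, sequence = seq, dot_bracket = db,
          mfe = m_g[g] + 0.5 * stats::rnorm(1))
      }
    }
    do.call(rbind, rows)
  })
  cosmos_write_tsv(structures, out_dir, "structures.tsv")

  # --- network degrees: Poisson counts shifted by effect * sqrt(lambda) ----
  deg <- eff("degrees")
  mirnas <- sprintf("miR-%03d", 1:80)
  cancer_mirnas <- mirnas[1:50]
  mirna_targets <- with_seed(derive_seed(cfg$seed, "mirna"), {
    n_mir <- stats::rpois(cfg$n_genes, 3 + deg * sqrt(3) * is_pos)
    rows <- lapply(which(n_mir > 0), function(g) {
      data.frame(
        transcript_id = names(models[[g]]$transcripts)[1L],
        mirna = sample(cancer_mirnas, min(n_mir[g], length(cancer_mirnas))))
    })
    do.call(rbind, c(rows, list(data.frame(transcript_id = character(),
                                           mirna = character()))))
  })
  cosmos_write_tsv(mirna_targets, out_dir, "mirna_targets.tsv")
  writeLines(cancer_mirnas, file.path(out_dir, "cancer_mirnas.txt"))

  proteins <- sprintf("RBP%02d", 1:25)
  important_proteins <- proteins[1:15]
  clusters <- with_seed(derive_seed(cfg$seed, "protein"), {
    n_cl <- stats::rpois(cfg$n_genes, 4 + deg * 2 * is_pos)
    rows <- lapply(which(n_cl > 0), function(g) {
      data.frame(gene_id = ids[g],
                 protein = sample(important_proteins, n_cl[g],
                                  replace = TRUE),
                 cluster_id = sprintf("%s_c%03d", ids[g], seq_len(n_cl[g])))
    })
    do.call(rbind, c(rows, list(data.frame(gene_id = character(),
                                           protein = character(),
                                           cluster_id = character()))))
  })
  cosmos_write_tsv(clusters, out_dir, "protein_clusters.tsv")
  writeLines(important_proteins, file.path(out_dir, "important_proteins.txt"))

  # co-expression with important protein-coding genes: positives load on the
  # same latent factor as the important genes (directional planting)
  pcg_ids <- sprintf("PCG%03d", 1:30)
  coexpr <- with_seed(derive_seed(cfg$seed, "coexpr"), {
    n_s <- 20L
    f <- stats::rnorm(n_s)
    lnc <- matrix(stats::rnorm(cfg$n_genes * n_s), cfg$n_genes, n_s) +
      outer(0.8 * sign(deg) * is_pos, f)
    pcg <- matrix(0.6 * stats::rnorm(30 * n_s), 30, n_s) + outer(rep(0.8, 30), f)
    v <- exp(rbind(lnc, pcg) * 0.5 + log(5))
    dimnames(v) <- list(c(ids, pcg_ids), sprintf("cx%02d", seq_len(n_s)))
    v
  })
  cosmos_write_tsv(cbind(data.frame(gene_id = rownames(coexpr)),
                         as.data.frame(coexpr)), out_dir, "coexpression.tsv")
  writeLines(pcg_ids, file.path(out_dir, "important_genes.txt"))

  # --- class-neutral layers (exercise parsing and operators) ----------------
  with_seed(derive_seed(cfg$seed, "neutral"), {
    se_rows <- do.call(rbind, lapply(sprintf("cell%d", 1:6), function(ct) {
      g <- sample(cfg$n_genes, max(2L, round(cfg$n_genes * 0.2)))
      data.frame(cell_type = ct, chrom = chrom_of[g],
                 start = vapply(spans[g], function(s) {
                   max(0L, as.integer(s[1] - sample(500:20000, 1L)))
                 }, 0L))
    }))
    se_rows$end <- se_rows$start + sample(500:3000, nrow(se_rows),
                                          replace = TRUE)
    cosmos_write_tsv(se_rows, out_dir, "super_enhancers.tsv")

    meth_g <- sample(cfg$n_genes, round(cfg$n_genes * 0.8))
    meth <- do.call(rbind, lapply(meth_g, function(g) {
      n_site <- sample(2:6, 1L)
      data.frame(chrom = chrom_of[g],
                 pos = as.integer(spans[[g]][1] +
                                    sample(seq(-900L, 900L), n_site)),
                 beta_cancer = stats::runif(n_site),
                 beta_normal = stats::runif(n_site))
    }))
    cosmos_write_tsv(meth, out_dir, "methylation.tsv")

    repliseq <- data.frame(gene_id = ids,
                           matrix(stats::rpois(cfg$n_genes * 6L, 20),
                                  cfg$n_genes, 6L,
                                  dimnames = list(NULL, paste0("S", 1:6))))
    cosmos_write_tsv(repliseq, out_dir, "repliseq.tsv")

    cons <- function() {
      data.frame(chrom = chrom_of,
                 start = vapply(spans, `[`, 0, 1L),
                 end = vapply(spans, `[`, 0, 2L),
                 score = round(stats::runif(cfg$n_genes, 0, 0.6), 4))
    }
    cosmos_write_tsv(cons(), out_dir, "conservation_phylop.tsv")
    cosmos_write_tsv(cons(), out_dir, "conservation_phastcons.tsv")

    n_rep <- cfg$n_genes * 2L
    rep_g <- sample(cfg$n_genes, n_rep, replace = TRUE)
    rep_start <- vapply(rep_g, function(g) {
      as.integer(spans[[g]][1] + sample.int(1500L, 1L))
    }, 0L)
    cosmos_write_tsv(
      data.frame(chrom = chrom_of[rep_g], start = rep_start,
                 end = rep_start + sample(100:400, n_rep, replace = TRUE),
                 class = sample(c("SINE", "LINE", "LTR", "Satellite"),
                                n_rep, replace = TRUE)),
      out_dir, "repeats.tsv")

    cdt_g <- sample(cfg$n_genes, round(cfg$n_genes * 0.3))
    cosmos_write_tsv(
      data.frame(chrom = chrom_of[cdt_g],
                 start = vapply(spans[cdt_g], `[`, 0, 1L) - 1000L,
                 end = vapply(spans[cdt_g], `[`, 0, 2L) + 1000L),
      out_dir, "cdt.tsv")

    screen <- do.call(rbind, lapply(sprintf("line%d", 1:4), function(cl) {
      data.frame(gene_id = rep(ids, 2L), cell_line = cl,
                 score = stats::rnorm(2L * cfg$n_genes, 0, 0.5))
    }))
    cosmos_write_tsv(screen, out_dir, "screen.tsv")

    sm_g <- sample(cfg$n_genes, round(cfg$n_genes * 0.4))
    sm_start <- vapply(sm_g, function(g) {
      as.integer(spans[[g]][1] + sample.int(1000L, 1L))
    }, 0L)
    cosmos_write_tsv(
      data.frame(chrom = chrom_of[sm_g], start = sm_start,
                 end = sm_start + sample(60:300, length(sm_g),
                                         replace = TRUE)),
      out_dir, "smprot.tsv")

    var_g <- sample(cfg$n_genes, cfg$n_genes * 3L, replace = TRUE)
    var_pos <- vapply(var_g, function(g) {
      as.integer(spans[[g]][1] +
                   sample.int(spans[[g]][2] - spans[[g]][1], 1L) - 1L)
    }, 0L)
    cosmos_write_tsv(
      data.frame(chrom = chrom_of[var_g], pos = var_pos,
                 ref = sample(c("A", "C", "G", "T"), length(var_g),
                              replace = TRUE),
                 alt = sample(c("A", "C", "G", "T"), length(var_g),
                              replace = TRUE),
                 rnasnp = round(stats::runif(length(var_g)), 4),
                 cadd = round(stats::rexp(length(var_g), 1 / 3), 4)),
      out_dir, "variants.tsv")

    cnv <- do.call(rbind, lapply(sprintf("cn%d", 1:5), function(sm) {
      do.call(rbind, lapply(chroms, function(ch) {
        L <- chrom_len[[ch]]
        bk <- unique(c(0L, sort(sample.int(L - 1L, 9L)), L))
        data.frame(chrom = ch, start = bk[-length(bk)], end = bk[-1L],
                   sample_id = sm,
                   copy_number = pmax(0, round(
                     2 + stats::rnorm(length(bk) - 1L, 0, 0.4), 3)))
      }))
    }))
    cosmos_write_tsv(cnv, out_dir, "cnv.tsv")
  })

  writeLines(positives, file.path(out_dir, "positives.txt"))
  truth <- list(positives = positives,
                informative = cosmos_informative(cfg),
                effect_sizes = cfg$effect_sizes,
                config = unclass(cfg))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a cosmos directory back into an input bundle
#'
#' @param dir a directory written by [generate_cosmos()].
#' @return list with `models` (gene models parsed from the GTF), `inputs`
#'   (ready for [build_feature_table()]), `labels` (a `LabelSet`) and
#'   `truth` (the planted ground truth).
#' @export
read_cosmos <- function(dir) {
  tsv <- function(name) {
    data.table::fread(file.path(dir, name), sep = "\t", data.table = FALSE)
  }
  models <- parse_gene_models(file.path(dir, "genes.gtf"))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))

  peaks_df <- tsv("peaks.tsv")
  peaks <- lapply(split(peaks_df, peaks_df$mark), function(m) {
    lapply(split(m, m$sample), function(s) {
      s[, c("chrom", "start", "end")]
    })
  })
  se_df <- tsv("super_enhancers.tsv")
  super_enhancers <- lapply(split(se_df, se_df$cell_type), function(s) {
    s[, c("chrom", "start", "end")]
  })

  expr_df <- tsv("expression.tsv")
  ev <- as.matrix(expr_df[, -1L])
  rownames(ev) <- expr_df$gene_id
  expression <- expression_matrix(ev, tsv("samples.tsv"))

  tx2gene <- do.call(rbind, lapply(models, function(m) {
    data.frame(transcript_id = names(m$transcripts), gene_id = m$gene_id)
  }))
  rownames(tx2gene) <- NULL

  structures <- tsv("structures.tsv")
  transcript_seqs <- Biostrings::DNAStringSet(
    setNames(structures$sequence, structures$transcript_id))

  cx_df <- tsv("coexpression.tsv")
  cxv <- as.matrix(cx_df[, -1L])
  rownames(cxv) <- cx_df$gene_id
  coexpr <- expression_matrix(
    cxv, data.frame(sample_id = colnames(cxv), condition = "tumor",
                    tissue = "cx"))

  inputs <- list(
    peaks = peaks,
    super_enhancers = super_enhancers,
    methylation = tsv("methylation.tsv"),
    repliseq = tsv("repliseq.tsv"),
    conservation = list(phylop = tsv("conservation_phylop.tsv"),
                        phastcons = tsv("conservation_phastcons.tsv")),
    genome = genome,
    transcript_seqs = transcript_seqs,
    tx2gene = tx2gene,
    repeats = tsv("repeats.tsv"),
    cdt = tsv("cdt.tsv"),
    expression = expression,
    structures = structures,
    screen = tsv("screen.tsv"),
    smprot = tsv("smprot.tsv"),
    coexpression = list(expr = coexpr,
                        important_genes = readLines(
                          file.path(dir, "important_genes.txt")),
                        beta = 6),
    mirna = list(targets = tsv("mirna_targets.tsv"),
                 cancer_mirnas = readLines(
                   file.path(dir, "cancer_mirnas.txt"))),
    protein = list(clusters = tsv("protein_clusters.tsv"),
                   important_proteins = readLines(
                     file.path(dir, "important_proteins.txt"))),
    variants = tsv("variants.tsv"),
    cnv = tsv("cnv.tsv")
  )
  labels <- assemble_labels(names(models),
                            list(readLines(file.path(dir, "positives.txt"))),
                            name_filter = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(models = models, inputs = inputs, labels = labels, truth = truth)
}
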