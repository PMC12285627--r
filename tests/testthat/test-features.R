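# Brute-force oracles for the feature operators on small fixtures.

test_that("peak_width_feature averages summed full peak widths per sample", {
  models <- tiny_models()
  # gA span [1000,4000), gB span [6000,9000)
  s1 <- data.frame(chrom = "chr1", start = c(900, 3900, 7000),
                   end = c(1100, 4100, 7500))
  s2 <- data.frame(chrom = "chr1", start = 5000, end = 5500)  # hits nothing
  pw <- peak_width_feature(list(a = s1, b = s2), models)
  # full widths count, even for partial overlap: gA = (200 + 200)/2 samples
  expect_equal(pw[["gA"]], (200 + 200 + 0) / 2)
  expect_equal(pw[["gB"]], 500 / 2)
  expect_error(peak_width_feature(list(), models), "empty sample")
})

test_that("super_enhancer_pct is the fraction of hit cell types", {
  models <- tiny_models()
  # gA upstream window [1,1000] (1-based); gB (minus) upstream [9001,...]
  ct1 <- data.frame(chrom = "chr1", start = 100, end = 300)    # hits gA
  ct2 <- data.frame(chrom = "chr1", start = 9100, end = 9200)  # hits gB
  ct3 <- data.frame(chrom = "chr1", start = 70000, end = 71000)
  pct <- super_enhancer_pct(list(ct1, ct2, ct3), models)
  expect_equal(unname(pct), c(1 / 3, 1 / 3))
})

test_that("diff_methylation is the median cancer-normal delta over sites", {
  rs <- tiny_regions()
  sites <- data.frame(chrom = "chr1", pos = c(100, 500, 1500, 9500),
                      beta_cancer = c(0.9, 0.2, 0.8, 0.5),
                      beta_normal = c(0.1, 0.4, 0.3, 0.5))
  prom <- diff_methylation(sites, rs, "promoter")
  expect_equal(prom[["gA"]], median(c(0.8, -0.2)))  # sites 100, 500
  expect_equal(prom[["gB"]], 0)                     # site 9500 in promoter
  body <- diff_methylation(sites, rs, "gene_body")
  expect_equal(body[["gA"]], 0.5)                   # site 1500 only
  bad <- transform(sites, beta_cancer = beta_cancer * 2)
  expect_error(diff_methylation(bad, rs, "promoter"), "\\[0, 1\\]")
})

test_that("s50 matches piecewise-linear hand computation and conventions", {
  m <- rbind(allearly = c(10, 0, 0, 0),
             uniform = c(1, 1, 1, 1),
             zero = c(0, 0, 0, 0))
  s <- s50_feature(m)
  # all signal in fraction 1: cumulative reaches 0.5 halfway through bin 1
  expect_equal(s[["allearly"]], 0.5 / 4)
  expect_equal(s[["uniform"]], 0.5)
  expect_equal(s[["zero"]], 0.5)
  expect_error(s50_feature(m[, 1, drop = FALSE]), "at least 2")
})

test_that("s50 reversal symmetry: S50(rev(x)) == 1 - S50(x)", {
  set.seed(4)
  for (i in 1:20) {
    x <- rpois(6, 5)
    if (sum(x) == 0) next
    s <- s50_feature(rbind(x))
    sr <- s50_feature(rbind(rev(x)))
    expect_equal(unname(sr), 1 - unname(s))
  }
})

test_that("gc_content matches per-base counting, ambiguous in denominator", {
  models <- tiny_models()
  rs <- lapply(models, derive_regions)
  set.seed(11)
  chr <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.25, 0.05)), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  bases <- strsplit(chr, "")[[1]]
  gc_or <- function(iv) {
    picked <- unlist(lapply(seq_len(nrow(iv)), function(i) {
      bases[(iv$start[i] + 1):iv$end[i]]
    }))
    sum(picked %in% c("G", "C")) / length(picked)
  }
  got <- gc_content(genome, rs, "gene")
  expect_equal(got[["gA"]], gc_or(data.frame(start = 1000, end = 4000)))
  got_ex <- gc_content(genome, rs, "exon")
  expect_equal(got_ex[["gA"]], gc_or(rs$gA$exons_merged))
  expect_error(gc_content(Biostrings::DNAStringSet(c(chrX = "ACGT")), rs),
               "missing")
})

test_that("conservation_mean0 matches the per-base oracle", {
  rs <- tiny_regions()
  scores <- data.frame(chrom = "chr1",
                       start = c(900, 2000, 3500),
                       end = c(1500, 2600, 4200),
                       score = c(2, -1, 0.5))
  # per-base oracle over gA span [1000, 4000)
  per_base <- numeric(10000)
  for (i in seq_len(nrow(scores))) {
    per_base[(scores$start[i] + 1):scores$end[i]] <- scores$score[i]
  }
  want_gene <- sum(per_base[1001:4000]) / 3000
  got <- conservation_mean0(scores, rs, "gene")
  expect_equal(got[["gA"]], want_gene)
  ex <- rs$gA$exons_merged
  covered <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    (ex$start[i] + 1):ex$end[i]
  }))
  expect_equal(conservation_mean0(scores, rs, "exon")[["gA"]],
               sum(per_base[covered]) / length(covered))
  expect_equal(got[["gB"]], 0)  # uncovered gene stays 0
})

test_that("repeat densities count overlapping elements per kb", {
  models <- tiny_models()
  reps <- data.frame(chrom = "chr1",
                     start = c(1100, 1200, 3900, 6500, 5000),
                     end = c(1150, 1300, 4100, 6600, 5100),
                     class = c("SINE", "sine", "LINE", "LTR", "SINE"))
  rd <- repeat_density(reps, models)
  expect_equal(rd["gA", "sine_density"], 2 / 3)   # 2 SINEs / 3 kb
  expect_equal(rd["gA", "line_density"], 1 / 3)   # partial overlap counts
  expect_equal(rd["gB", "ltr_density"], 1 / 3)
  expect_equal(rd["gA", "satellite_density"], 0)
})

test_that("cdt indicator uses the any-overlap convention", {
  models <- tiny_models()
  cdt <- data.frame(chrom = "chr1", start = 3999, end = 6001)
  got <- cdt_indicator(cdt, models)
  expect_equal(unname(got), c(1, 1))  # 1-base overlaps on both ends
  cdt2 <- data.frame(chrom = "chr1", start = 4000, end = 6000)
  expect_equal(unname(cdt_indicator(cdt2, models)), c(0, 0))
})

test_that("tau matches Eq-style hand computation and conventions", {
  expect_equal(tau_score(c(8, 0, 0, 0)), 1)
  expect_equal(tau_score(c(5, 5, 5)), 0)
  expect_equal(tau_score(c(0, 0)), 0)       # all-zero convention
  x <- c(4, 2, 1)
  expect_equal(tau_score(x), (3 - sum(x / 4)) / 2)
  expect_error(tau_score(5), "at least 2")
  expect_error(tau_score(c(-1, 2)))
})

test_that("expression logfc and tau work through ExpressionMatrix", {
  v <- rbind(g1 = c(10, 12, 1, 1), g2 = c(0, 0, 0, 0))
  colnames(v) <- paste0("s", 1:4)
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     condition = c("tumor", "tumor", "normal", "normal"),
                     tissue = c("liver", "lung", "liver", "lung"))
  em <- expression_matrix(v, meta)
  lfc <- expression_logfc(em)
  expect_equal(lfc[["g1"]], log2(11.01 / 1.01))
  expect_equal(lfc[["g2"]], 0)  # eps keeps zero-expression finite at 0
  tt <- tau(em)
  expect_equal(tt[["g1"]], tau_score(c(10, 12)))
  expect_equal(tt[["g2"]], 0)
})

test_that("structure features: validation, proportions and per-gene means", {
  tx2gene <- data.frame(transcript_id = c("t1", "t2", "t3"),
                        gene_id = c("g1", "g1", "g2"))
  st <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    sequence = c("GGGCAAAAGCCC", "ACGUACGU", "AAAAAAAA"),
    dot_bracket = c("((((....))))", "........", "........"),
    mfe = c(-20, -10, -2))
  sf <- structure_features(st, tx2gene)
  g1 <- sf[sf$gene_id == "g1", ]
  expect_equal(g1$secondary_structure_mfe, -15)
  expect_equal(g1$paired_proportion, mean(c(8 / 12, 0)))
  expect_equal(g1$paired_gc_proportion, mean(c(8 / 8, 0)))
  bad <- st
  bad$dot_bracket[1] <- "))((....(((("
  expect_error(structure_features(bad, tx2gene), "unbalanced")
  bad2 <- st
  bad2$dot_bracket[1] <- "(...)"
  expect_error(structure_features(bad2, tx2gene), "length")
})

test_that("512-profile counts windows normalized by length", {
  p <- lncforge:::structure_profile_512("ACGU", "(..)")
  expect_equal(sum(p), 2 / 4)  # two windows / length 4
  # window 1: ACG paired pattern (1,0,0) -> tri=0*16+1*4+2=6, pat=4
  expect_equal(p[6 * 8 + 4 + 1], 1 / 4)
  # N bases give NA windows that are dropped
  pn <- lncforge:::structure_profile_512("ANGU", "....")
  expect_equal(sum(pn), 0)
})

test_that("kmer_pc1 is deterministic with a positive max-|loading| sign", {
  set.seed(7)
  seqs <- Biostrings::DNAStringSet(setNames(vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  }, ""), paste0("t", 1:6)))
  tx2gene <- data.frame(transcript_id = paste0("t", 1:6),
                        gene_id = rep(paste0("g", 1:3), each = 2))
  p1 <- kmer_pc1(seqs, tx2gene)
  p2 <- kmer_pc1(seqs, tx2gene)
  expect_identical(p1, p2)
  expect_equal(sort(names(p1)), paste0("g", 1:3))
  expect_equal(sum(p1), 0, tolerance = 1e-10)  # centered scores
  expect_warning(
    kmer_pc1(Biostrings::DNAStringSet(c(t1 = "ACG", t2 = "ACGTACGTACGT")),
             data.frame(transcript_id = c("t1", "t2"),
                        gene_id = c("g1", "g2"))),
    "shorter")
})

test_that("pc1_scores flips sign so the largest-magnitude loading is +", {
  set.seed(2)
  x <- matrix(rnorm(40), 10, 4)
  x[, 2] <- x[, 2] * 10  # dominant column
  s <- lncforge:::pc1_scores(x)
  expect_gt(cor(s, x[, 2]), 0.9)  # aligned with the dominant column, + sign
  expect_equal(unname(lncforge:::pc1_scores(matrix(1, 5, 3))), rep(0, 5))
})

test_that("crispri phenotype is max over cell lines of replicate means", {
  sc <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                   cell_line = c("A", "A", "B", "A"),
                   score = c(1, 3, -1, 0.5))
  got <- crispri_phenotype(sc)
  expect_equal(got[["g1"]], max(mean(c(1, 3)), -1))
  expect_equal(got[["g2"]], 0.5)
})

test_that("small protein density/coverage: only fully-contained intervals", {
  models <- tiny_models()
  sp <- data.frame(chrom = "chr1",
                   start = c(1100, 1150, 3900, 8000),
                   end = c(1200, 1250, 4100, 8300))
  out <- small_protein_features(sp, models)
  # gA: two contained (overlapping), one straddling the end is excluded
  expect_equal(out["gA", "small_protein_density"], 2 / 3)
  expect_equal(out["gA", "small_protein_coverage"], 150 / 3000)  # union
  expect_equal(out["gB", "small_protein_density"], 1 / 3)
})

test_that("mirna/protein degrees count unique partners", {
  tx2gene <- data.frame(transcript_id = c("t1", "t2"),
                        gene_id = c("g1", "g1"))
  targets <- data.frame(transcript_id = c("t1", "t2", "t1", "t1"),
                        mirna = c("m1", "m1", "m2", "m9"))
  got <- mirna_degree(targets, cancer_mirnas = c("m1", "m2"), tx2gene)
  expect_equal(got[["g1"]], 2)  # m1 via both transcripts counts once
  cl <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                   protein = c("p1", "p1", "p9", "p2"),
                   cluster_id = c("c1", "c1", "c2", "c3"))
  pd <- protein_degree(cl, important_proteins = c("p1", "p2"))
  expect_equal(pd[["g1"]], 1)  # duplicate c1 row once; c2 not important
  expect_equal(pd[["g2"]], 1)
})

test_that("mrna_degree sums |cor|^beta against important genes", {
  set.seed(5)
  v <- matrix(abs(rnorm(5 * 10)), 5, 10,
              dimnames = list(c("l1", "l2", "imp1", "imp2", "imp3"),
                              paste0("s", 1:10)))
  em <- expression_matrix(v, data.frame(sample_id = paste0("s", 1:10),
                                        condition = "tumor", tissue = "t"))
  got <- mrna_degree(em, c("imp1", "imp2", "imp3"), beta = 6)
  want <- vapply(c("l1", "l2"), function(l) {
    sum(vapply(c("imp1", "imp2", "imp3"), function(im) {
      abs(cor(v[l, ], v[im, ]))^6
    }, 0))
  }, 0)
  expect_equal(got, want, ignore_attr = TRUE)
  expect_equal(attr(got, "beta"), 6)
})

test_that("pick_soft_threshold returns the fallback when nothing fits", {
  set.seed(9)
  v <- matrix(rnorm(8 * 6), 8, 6)  # tiny noise matrix: no scale-free fit
  res <- pick_soft_threshold(v, betas = 1:3, target_r2 = 0.999)
  expect_equal(res$beta, 6L)
  expect_equal(nrow(res$fit), 3)
})

test_that("mutation OR matches the pseudocount oracle", {
  rs <- tiny_regions()
  # gA: exons [1000,1800)+[2500,3200)+[3400,4000) = 1900 bp
  #     background = gaps [1800,2500)+[3200,3400) = 900 bp + promoter 1000 bp
  variants <- data.frame(chrom = "chr1",
                         pos = c(1100, 2550, 1900, 500, 8999))
  got <- mutation_odds_ratio(variants, rs)
  m_ex <- 2  # 1100, 2550
  m_bg <- 2  # 1900 (gap), 500 (promoter)
  # L_ex = 800 + 700 + 600 = 2100; L_bg = gaps 700 + 200 + promoter 1000
  want <- ((m_ex + 0.5) / (2100 + 0.5)) / ((m_bg + 0.5) / (1900 + 0.5))
  expect_equal(got[["gA"]], want)
  # gB exons [6000,7000)+[8000,9000), background gap [7000,8000) + promoter
  wantB <- ((1 + 0.5) / (2000 + 0.5)) / ((0 + 0.5) / (2000 + 0.5))
  expect_equal(got[["gB"]], wantB)
  # genes_with_data masks uncovered genes to 0
  masked <- mutation_odds_ratio(variants, rs, genes_with_data = "gA")
  expect_equal(masked[["gB"]], 0)
  expect_error(lncforge:::variants_gr(
    data.frame(chrom = "chr1", pos = 1, ref = "AT", alt = "GC")),
    "single-nucleotide")
})

test_that("functional impact mean averages span-overlapping variants", {
  rs <- tiny_regions()
  variants <- data.frame(chrom = "chr1", pos = c(1500, 3999, 4000, 6500),
                         cadd = c(1, 3, 100, 7))
  got <- functional_impact_mean(variants, rs, "cadd")
  expect_equal(got[["gA"]], mean(c(1, 3)))  # 4000 is outside [1000,4000)
  expect_equal(got[["gB"]], 7)
  expect_error(functional_impact_mean(variants, rs, "nope"), "missing score")
  variants$cadd[1] <- NA
  expect_error(functional_impact_mean(variants, rs, "cadd"), "NA")
})

test_that("cnv matches the overlap-weighted-median-then-mean oracle", {
  models <- tiny_models()
  segs <- data.frame(
    chrom = "chr1",
    start = c(0, 2000, 0, 8000),
    end = c(2000, 5000, 10000, 9000),
    sample_id = c("s1", "s1", "s2", "s3"),
    copy_number = c(1, 4, 2, 6))
  got <- cnv_feature(segs, models)
  # gA/s1: overlaps 1000bp of cn=1 and 2000bp of cn=4 -> weighted median 4
  # gA/s2: cn 2; mean over s1, s2 (s3 does not cover gA)
  expect_equal(got[["gA"]], mean(c(weighted_median(c(1, 4), c(1000, 2000)),
                                   2)))
  expect_equal(got[["gB"]], mean(c(2, 6)))
})

test_that("weighted_median follows the cumulative-weight rule", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_median(c(5, 1), c(10, 1)), 5)
  expect_equal(weighted_median(c(1, 2), c(1, 1)), 1)  # first to reach 0.5
})
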