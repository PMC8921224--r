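test_that("FPKM follows the unit definition", {
  counts <- matrix(c(10L, 0L, 25L), 3, 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  fpkm <- compute_fpkm(counts, lengths = c(1000, 500, 2500),
                       library_sizes = c(s1 = 1e6))
  expect_equal(unname(fpkm[, 1]), c(10, 0, 10))
  fpkm2 <- compute_fpkm(counts["c", , drop = FALSE], lengths = 2500,
                        library_sizes = c(s1 = 5e6))
  expect_equal(unname(fpkm2[1, 1]), 2)
  expect_error(compute_fpkm(counts, lengths = c(0, 1, 1)), "length")
})

test_that("expression filter keeps genes detectable in at least one genotype", {
  design <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                       genotype = c("A", "A", "B", "B"))
  fpkm <- rbind(low = c(0.1, 0.3, 0.2, 0.4),      # genotype means 0.2, 0.3
                one = c(0.1, 0.1, 0.8, 1.0),      # B mean 0.9
                edge = c(0.5, 0.5, 0.5, 0.5))     # exactly at threshold
  colnames(fpkm) <- design$sample
  kept <- filter_expressed(fpkm, design, threshold = 0.5)
  expect_identical(sort(kept), c("edge", "one"))
})

test_that("size factors recover planted depth differences", {
  set.seed(51)
  mu <- rexp(500, 1 / 300)
  depth <- c(1, 2, 0.5)
  counts <- sapply(depth, function(d) rpois(500, mu * d))
  rownames(counts) <- sprintf("f%03d", 1:500)
  colnames(counts) <- c("s1", "s2", "s3")
  sf <- estimate_size_factors(counts)
  expect_equal(unname(sf / sf[1]), depth, tolerance = 0.05)
})

test_that("null features give near-zero fold change and uniform p-values", {
  set.seed(52)
  design <- data.frame(sample = paste0(rep(c("WT", "mut"), each = 3), 1:3),
                       genotype = rep(c("WT", "mut"), each = 3))
  counts <- matrix(rnbinom(1000 * 6, mu = 200, size = 10), 1000, 6,
                   dimnames = list(sprintf("f%04d", 1:1000), design$sample))
  res <- de_test(counts, design, c("mut", "WT"))
  expect_lt(abs(median(res$log2fc)), 0.1)
  expect_gt(mean(res$p_value > 0.5), 0.4)
  # identical counts in both groups: log2fc 0, p 1
  flat <- matrix(rep(c(100L, 120L, 90L), 2), 1, 6,
                 dimnames = list("x", design$sample))
  r1 <- de_test(rbind(flat, counts[1:50, ]), design, c("mut", "WT"),
                size_factors = setNames(rep(1, 6), design$sample))[1, ]
  expect_equal(r1$log2fc, 0, tolerance = 1e-9)
  expect_equal(r1$p_value, 1, tolerance = 1e-9)
  # all-zero features are excluded from testing
  zero <- matrix(0L, 1, 6, dimnames = list("z", design$sample))
  rz <- de_test(rbind(zero, counts[1:50, ]), design, c("mut", "WT"))
  expect_true(is.na(rz$p_value[1]) && is.na(rz$padj[1]))
  expect_error(de_test(counts[, c(1, 4)],
                       design[c(1, 4), ], c("mut", "WT")), "replicates")
})

test_that("a planted four-fold change is recovered with confident calls", {
  set.seed(53)
  design <- data.frame(sample = paste0(rep(c("WT", "mut"), each = 3), 1:3),
                       genotype = rep(c("WT", "mut"), each = 3))
  nf <- 400
  counts <- matrix(rnbinom(nf * 6, mu = 200, size = 20), nf, 6,
                   dimnames = list(sprintf("f%04d", 1:nf), design$sample))
  planted <- 1:20
  counts[planted, 4:6] <- rnbinom(length(planted) * 3, mu = 800, size = 20)
  res <- de_test(counts, design, c("mut", "WT"))
  expect_lt(abs(median(res$log2fc[planted]) - 2), 0.5)
  expect_true(all(res$padj[planted] < 0.01))
})

test_that("DE status applies class-specific fold-change thresholds", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    log2fc = c(1.1, 0.9, 1.5),
                    padj = c(0.005, 1e-6, 0.001))
  g <- call_de_features(res, "gene")
  expect_equal(g$status, c("up", "ns", "up"))
  a <- call_de_features(res, "antisense")
  expect_equal(a$status, c("ns", "ns", "ns"))   # FC 2.83 < 4
  a2 <- call_de_features(data.frame(feature_id = "d", log2fc = 2.2,
                                    padj = 1e-4), "antisense")
  expect_equal(a2$status, "up")
  dn <- call_de_features(data.frame(feature_id = "e", log2fc = -1.6,
                                    padj = 1e-4), "gene")
  expect_equal(dn$status, "down")
  # up and down sets are disjoint by construction
  set.seed(54)
  r <- data.frame(feature_id = sprintf("f%03d", 1:200),
                  log2fc = rnorm(200, 0, 2), padj = runif(200))
  cc <- call_de_features(r, "gene")
  expect_equal(sum(cc$status == "up" & cc$status == "down"), 0L)
})

make_de <- function(ids, lfc, status) {
  data.frame(feature_id = ids, log2fc = lfc, padj = 0.001, status = status,
             stringsAsFactors = FALSE)
}

test_that("regulation patterns follow the decision rules on designed cases", {
  ids <- sprintf("g%02d", 1:8)
  # columns: ddcc, met1, mddcc (lfc, status)
  ddcc <- make_de(ids, c(0.1, 0.2, 1.5, 0.1, 1.2, 0.1, 2.9, 0.2),
                  c("ns", "ns", "up", "ns", "up", "ns", "up", "ns"))
  met1 <- make_de(ids, c(0.2, 1.5, 0.2, 2.9, 1.2, 3.0, 0.2, 1.4),
                  c("ns", "up", "ns", "up", "up", "up", "ns", "up"))
  mddcc <- make_de(ids, c(3.0, 3.2, 3.2, 3.0, 3.0, 3.1, 3.0, -2),
                   c("up", "up", "up", "up", "up", "up", "up", "ns"))
  pat <- classify_regulation_pattern(ddcc, met1, mddcc)
  expect_equal(pat$pattern[match(c("g01", "g02", "g03", "g04", "g05",
                                   "g06", "g07"), pat$feature_id)],
               c("Redundancy",   # ns/ns
                 "DosageI",      # met1 1.5 up, gap 1.7
                 "DosageII",     # ddcc 1.5 up, gap 1.7
                 "mCG",          # met1 2.9 up, gap 0.1 < delta
                 "DosageIII",    # both up, both gaps 1.8
                 "mCG",          # met1 3.0, gap 0.1 takes precedence
                 "non_mCG"))     # ddcc 2.9, gap 0.1
  # g08 is ns in mddcc: not classified
  expect_false("g08" %in% pat$feature_id)
})

test_that("the down direction mirrors the up rules", {
  ids <- c("d1", "d2")
  ddcc <- make_de(ids, c(-0.1, -0.2), c("ns", "ns"))
  met1 <- make_de(ids, c(-0.2, -1.5), c("ns", "down"))
  mddcc <- make_de(ids, c(-3.0, -3.2), c("down", "down"))
  pat <- classify_regulation_pattern(ddcc, met1, mddcc)
  expect_equal(pat$direction, c("down", "down"))
  expect_equal(pat$pattern, c("Redundancy", "DosageI"))
})

test_that("planted regulation patterns are recovered from simulated counts", {
  cfg <- sim_config(seed = 55, n_de_features = 300, n_null_features = 300)
  sc <- simulate_counts(cfg)
  de <- lapply(c("ddcc", "met1", "mddcc"), function(g)
    call_de_features(de_test(sc$counts, sc$design, c(g, "WT")), "gene"))
  names(de) <- c("ddcc", "met1", "mddcc")
  pat <- classify_regulation_pattern(de$ddcc, de$met1, de$mddcc)
  tr <- merge(pat, sc$truth, by = "feature_id")
  planted <- tr[tr$pattern.y != "null"]
  expect_gt(nrow(planted) / 300, 0.9)     # nearly all planted features are DE
  expect_gt(mean(planted$pattern.x == planted$pattern.y), 0.9)
})

test_that("the split intron is the one with maximal non-CG methylation", {
  g <- genome_from_strings(c(c1 = random_genome_string(5000, 56)))
  ann <- make_annotation(
    data.frame(gene_id = "gS", chrom = "c1", strand = "+",
               start = 1001L, end = 3000L, stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "gS",
                       start = c(1001L, 1501L, 2501L),
                       end = c(1400L, 2400L, 3000L)))
  # introns: 1401-1500 and 2401-2500; make the second one hot in CHH
  tab <- make_methylome("c1", c(1450, 2450, 2460), "+",
                        c("CHH", "CHH", "CHG"), c(1, 8, 9), c(10, 10, 10))
  sel <- select_split_intron(ann, tab, "gS")
  expect_equal(sel$intron, c(2401L, 2500L))
  expect_equal(sel$level, 17 / 20)
  expect_null(select_split_intron(make_annotation(
    data.frame(gene_id = "g0", chrom = "c1", strand = "+", start = 10L,
               end = 100L, stringsAsFactors = FALSE)), tab, "g0"))
})

test_that("the 3'/5' ratio statistic matches hand arithmetic and flags depletion", {
  sc <- data.frame(gene_id = rep(c("gA", "gB", "gC"), each = 2),
                   genotype = rep(c("WT", "mddcc"), 3),
                   n5 = c(100, 100, 9, 50, 80, 80),
                   n3 = c(100, 20, 500, 500, 40, 40))
  res <- intron_tem_3prime_test(sc)
  a <- res[res$gene_id == "gA"]
  expect_equal(a$log2_ratio_change, log2(0.2), tolerance = 1e-12)
  expect_true(a$flagged)
  b <- res[res$gene_id == "gB"]                 # WT 5' = 9 < 10: excluded
  expect_false(b$retained)
  expect_true(is.na(b$log2_ratio_change))
  cc <- res[res$gene_id == "gC"]                # identical ratios
  expect_equal(cc$log2_ratio_change, 0)
  expect_false(cc$flagged)
})

test_that("the ratio statistic is invariant to scaling one genotype", {
  sc <- data.frame(gene_id = rep("g", 2), genotype = c("WT", "mddcc"),
                   n5 = c(40, 200), n3 = c(60, 90))
  base <- intron_tem_3prime_test(sc)$log2_ratio_change
  sc2 <- sc; sc2[sc2$genotype == "mddcc", c("n5", "n3")] <-
    sc[sc$genotype == "mddcc", c("n5", "n3")] * 7
  expect_equal(intron_tem_3prime_test(sc2)$log2_ratio_change, base,
               tolerance = 1e-12)
})

test_that("undefined ratios are reported unflagged with a reason", {
  sc <- data.frame(gene_id = rep("g", 2), genotype = c("WT", "mddcc"),
                   n5 = c(40, 0), n3 = c(60, 90))
  res <- intron_tem_3prime_test(sc)
  expect_true(res$retained)
  expect_false(res$flagged)
  expect_equal(res$reason, "mutant_5prime_zero")
})

test_that("the NB Wald engine agrees with an established shrinkage DE framework", {
  set.seed(91)
  design <- data.frame(sample = paste0(rep(c("WT", "mut"), each = 3), 1:3),
                       genotype = rep(c("WT", "mut"), each = 3))
  nf <- 300
  counts <- matrix(rnbinom(nf * 6, mu = 300, size = 15), nf, 6,
                   dimnames = list(sprintf("f%03d", 1:nf), design$sample))
  counts[1:40, 4:6] <- rnbinom(40 * 3, mu = 300 * 2^runif(40, 1, 3), size = 15)
  res <- de_test(counts, design, c("mut", "WT"))

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, data.frame(condition = factor(design$genotype,
                                            levels = c("WT", "mut"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
  })
  ref <- DESeq2::results(dds, contrast = c("condition", "mut", "WT"))
  expect_gt(cor(res$log2fc, ref$log2FoldChange, use = "complete.obs"), 0.99)
  sig_pkg <- which(res$padj < 0.01 & abs(res$log2fc) > 1)
  sig_ref <- which(!is.na(ref$padj) & ref$padj < 0.01 &
                     abs(ref$log2FoldChange) > 1)
  jaccard <- length(intersect(sig_pkg, sig_ref)) /
    length(union(sig_pkg, sig_ref))
  expect_gt(jaccard, 0.8)
})
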