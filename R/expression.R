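#' Fragments per kilobase of exon model per million mapped fragments
#'
#' @param counts Integer matrix, features x samples.
#' @param lengths Per-feature union-exon lengths in bp (> 0).
#' @param library_sizes Per-sample total mapped fragments; defaults to the
#'   column sums of `counts`.
#' @return FPKM matrix of the same shape as `counts`.
#' @export
compute_fpkm <- function(counts, lengths,
                         library_sizes = colSums(counts)) {
  if (any(lengths <= 0)) stop("feature length must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  sweep(sweep(counts, 1, lengths / 1e3, "/"), 2, library_sizes / 1e6, "/")
}

#' Filter to genes with detectable expression
#'
#' A gene is retained when its genotype-level FPKM (mean over replicates)
#' reaches `threshold` in at least one genotype; genes below the threshold
#' in every genotype are excluded.
#'
#' @param fpkm FPKM matrix (features x samples).
#' @param design data.frame with columns sample, genotype; `sample` must
#'   match `colnames(fpkm)`.
#' @param threshold Minimum genotype-mean FPKM (default 0.5).
#' @return Character vector of retained feature IDs.
#' @export
filter_expressed <- function(fpkm, design, threshold = 0.5) {
  stopifnot(all(design$sample %in% colnames(fpkm)))
  geno_means <- sapply(split(design$sample, design$genotype), function(s)
    rowMeans(fpkm[, s, drop = FALSE]))
  rownames(fpkm)[apply(geno_means >= threshold, 1, any)]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across features of the
#' ratio of each sample's count to the feature's geometric mean, computed
#' over features with all-positive counts.
#'
#' @param counts Integer matrix, features x samples.
#' @return Numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no feature with all-positive counts")
  sf <- apply(counts[use, , drop = FALSE], 2, function(x)
    exp(stats::median(log(x) - log_geo[use])))
  sf
}

#' Negative-binomial Wald test for differential expression
#'
#' A documented stand-in for a full shrinkage-based NB engine: counts are
#' normalized by median-of-ratios size factors; per-feature dispersions are
#' estimated by method of moments from within-group variability and shrunk
#' toward a fitted mean-dispersion trend (a0 + a1/mean); the log2
#' fold-change of group means is tested with a Wald statistic referred to
#' the standard normal (the dispersion entering the standard error is
#' pooled across thousands of features, not re-estimated per feature, so
#' no small-sample t correction is applied).  Features with
#' all-zero counts are excluded from testing (NA results).  Downstream
#' logic consumes only (log2fc, padj, status).
#'
#' @param counts Integer matrix, features x samples.
#' @param design data.frame with columns sample, genotype.
#' @param contrast Character vector `c(test_genotype, reference_genotype)`.
#' @param size_factors Optional precomputed size factors (full matrix);
#'   defaults to [estimate_size_factors()] on all samples.
#' @param prior_df Prior weight (pseudo-degrees of freedom) pulling raw
#'   dispersions toward the trend (default 8).
#' @return data.frame with feature_id, base_mean, log2fc, se_log2fc,
#'   dispersion, p_value, padj.
#' @export
de_test <- function(counts, design, contrast,
                    size_factors = NULL, prior_df = 8) {
  stopifnot(length(contrast) == 2)
  test_g <- contrast[1]; ref_g <- contrast[2]
  s_test <- design$sample[design$genotype == test_g]
  s_ref <- design$sample[design$genotype == ref_g]
  if (length(s_test) < 2 || length(s_ref) < 2)
    stop("need at least 2 replicates per group")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  nc <- sweep(counts, 2, size_factors[colnames(counts)], "/")

  A <- nc[, s_ref, drop = FALSE];  B <- nc[, s_test, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  muA <- rowMeans(A); muB <- rowMeans(B)
  mu <- (muA * nA + muB * nB) / (nA + nB)
  tested <- mu > 0

  ssA <- rowSums((A - muA)^2); ssB <- rowSums((B - muB)^2)
  s2 <- (ssA + ssB) / (nA + nB - 2)
  raw_disp <- (s2 - mu) / mu^2
  raw_disp[!is.finite(raw_disp)] <- NA_real_

  # mean-dispersion trend alpha(mu) = a0 + a1/mu fitted on features with a
  # usable positive raw estimate; falls back to the median when the fit is
  # degenerate
  fit_ok <- tested & !is.na(raw_disp) & raw_disp > 0
  if (sum(fit_ok) >= 10) {
    fit <- stats::lm(raw_disp[fit_ok] ~ I(1 / mu[fit_ok]))
    a0 <- max(stats::coef(fit)[1], 1e-4)
    a1 <- max(stats::coef(fit)[2], 0)
  } else {
    a0 <- max(stats::median(raw_disp[fit_ok], na.rm = TRUE), 1e-4)
    if (!is.finite(a0)) a0 <- 0.1
    a1 <- 0
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  df_raw <- nA + nB - 2
  w_raw <- ifelse(is.na(raw_disp), 0, df_raw)
  disp <- (pmax(raw_disp, 0, na.rm = TRUE) * w_raw + trend * prior_df) /
    (w_raw + prior_df)
  disp <- pmax(disp, 1e-8)

  pseudo <- 0.5
  lfc_ln <- log(muB + pseudo) - log(muA + pseudo)
  se_ln <- sqrt((1 / (muA + pseudo) + disp) / nA +
                (1 / (muB + pseudo) + disp) / nB)
  z <- lfc_ln / se_ln
  p <- 2 * stats::pnorm(-abs(z))
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- bh_adjust(p[tested])

  data.frame(feature_id = rownames(counts),
             base_mean = mu,
             log2fc = ifelse(tested, lfc_ln / log(2), NA_real_),
             se_log2fc = ifelse(tested, se_ln / log(2), NA_real_),
             dispersion = disp,
             p_value = p, padj = padj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed features
#'
#' Applies the class-specific fold-change threshold (genes, transposons and
#' non-annotated transcripts: 2; antisense transcripts: 4) and the adjusted
#' p-value cutoff, assigning `up`, `down` or `ns` per feature.
#'
#' @param results Output of [de_test()].
#' @param feature_class One of "gene", "TE", "antisense", "non_annotated".
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param fc Fold-change threshold; defaults to the class-specific value.
#' @return `results` with an added `status` column.
#' @export
call_de_features <- function(results,
                             feature_class = c("gene", "TE", "antisense",
                                               "non_annotated"),
                             alpha = 0.01, fc = NULL) {
  feature_class <- match.arg(feature_class)
  if (is.null(fc))
    fc <- c(gene = 2, TE = 2, antisense = 4, non_annotated = 2)[[feature_class]]
  lfc_min <- log2(fc)
  sig <- !is.na(results$padj) & results$padj < alpha
  status <- rep("ns", nrow(results))
  status[sig & results$log2fc > lfc_min] <- "up"
  status[sig & results$log2fc < -lfc_min] <- "down"
  results$status <- status
  results
}

#' Classify cross-genotype regulation patterns
#'
#' For every feature differentially expressed in the quintuple mutant
#' (mddcc), classifies how CG and non-CG methylation jointly shape its
#' expression, from the per-genotype fold changes and DE statuses.  With
#' `L` the log2 fold change versus wild type and `delta` the gap defining
#' "comparable" versus "further increased", for an up-regulated feature:
#'
#' * **Redundancy** — not DE in either single-pathway mutant.
#' * **mCG** — DE-up in the CG mutant with `|L_mddcc - L_met1| < delta`.
#' * **non_mCG** — DE-up in the non-CG mutant with
#'   `|L_mddcc - L_ddcc| < delta`.
#' * **DosageI** — DE-up in the CG mutant only, with
#'   `L_mddcc - L_met1 >= delta`.
#' * **DosageII** — DE-up in the non-CG mutant only, with
#'   `L_mddcc - L_ddcc >= delta`.
#' * **DosageIII** — DE-up in both, with `L_mddcc` at least `delta` above
#'   both.
#' * **Unclassified** otherwise.
#'
#' The comparable-gap rules take precedence over the dosage rules; the
#' down direction mirrors all inequalities.
#'
#' @param de_ddcc,de_met1,de_mddcc Outputs of [call_de_features()] for the
#'   three mutants versus wild type, with matching feature_id sets.
#' @param delta Log2 fold-change gap (default 1.0).
#' @return `data.table` with feature_id, direction (up/down) and pattern,
#'   one row per feature DE in mddcc.
#' @export
classify_regulation_pattern <- function(de_ddcc, de_met1, de_mddcc,
                                        delta = 1.0) {
  key <- de_mddcc$feature_id
  idx_d <- match(key, de_ddcc$feature_id)
  idx_m <- match(key, de_met1$feature_id)
  if (anyNA(idx_d) || anyNA(idx_m))
    stop("feature sets of the three contrasts do not match")
  de <- de_mddcc$status %in% c("up", "down")
  if (!any(de))
    return(data.table::data.table(feature_id = character(),
                                  direction = character(),
                                  pattern = character()))
  direction <- de_mddcc$status[de]
  sgn <- ifelse(direction == "up", 1, -1)
  Lq <- de_mddcc$log2fc[de] * sgn
  Lm <- de_met1$log2fc[idx_m][de] * sgn
  Ld <- de_ddcc$log2fc[idx_d][de] * sgn
  # after the sign flip, "DE in the same direction" means status equals the
  # mddcc direction
  m_de <- de_met1$status[idx_m][de] == direction
  d_de <- de_ddcc$status[idx_d][de] == direction
  gm <- Lq - Lm
  gd <- Lq - Ld

  pattern <- rep("Unclassified", sum(de))
  pattern[!m_de & !d_de] <- "Redundancy"
  sel <- pattern == "Unclassified" & m_de & abs(gm) < delta
  pattern[sel] <- "mCG"
  sel <- pattern == "Unclassified" & d_de & abs(gd) < delta
  pattern[sel] <- "non_mCG"
  sel <- pattern == "Unclassified" & m_de & !d_de & gm >= delta
  pattern[sel] <- "DosageI"
  sel <- pattern == "Unclassified" & d_de & !m_de & gd >= delta
  pattern[sel] <- "DosageII"
  sel <- pattern == "Unclassified" & m_de & d_de & gm >= delta & gd >= delta
  pattern[sel] <- "DosageIII"

  data.table::data.table(feature_id = de_mddcc$feature_id[de],
                         direction = direction, pattern = pattern)
}

#' Choose the splitting intron of a gene
#'
#' Returns the intron with the maximum pooled non-CG (CHG + CHH) weighted
#' methylation level; the gene is then divided into a 5' part upstream of
#' this intron and a 3' part downstream of it.
#'
#' @param ann An `md_annotation`.
#' @param table An `md_methylome` (wild type).
#' @param gene_id Gene to split.
#' @return list(intron = c(start, end), level); NULL for intron-less genes.
#' @export
select_split_intron <- function(ann, table, gene_id) {
  ir <- ann$introns[ann$introns$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ir)) return(NULL)
  gchrom <- ann$genes$chrom[ann$genes$gene_id == gene_id]
  lv <- vapply(seq_len(nrow(ir)), function(i) {
    keep <- table$chrom == gchrom & table$pos >= ir$start[i] &
      table$pos <= ir$end[i] & table$context %in% c("CHG", "CHH")
    sub <- table[which(keep), ]
    n <- sum(sub$ct_count)
    if (n == 0L) -Inf else sum(sub$c_count) / n
  }, numeric(1))
  best <- which.max(lv)
  list(intron = c(ir$start[best], ir$end[best]),
       level = if (is.finite(lv[best])) lv[best] else NA_real_)
}

#' 3'/5' transcript-ratio test for intron-methylated genes
#'
#' For genes whose body methylation is intron-restricted, intronic
#' methylation can be required for accumulation of the full-length (3')
#' transcript.  The gene is split at its most methylated intron; read
#' counts (summed over replicates) upstream (5') and downstream (3') of the
#' intron are compared between a mutant and wild type via
#' `log2((3'/5' mutant) / (3'/5' WT))`.  Genes with fewer than
#' `min_wt5` wild-type 5' reads are excluded; a statistic below
#' `flag_threshold` flags 3' depletion.
#'
#' @param split_counts data.frame with columns gene_id, genotype, n5, n3
#'   (replicate-summed read counts for the 5' and 3' parts).
#' @param wt Wild-type genotype label (default "WT").
#' @param mutants Mutant genotype labels to test; defaults to every
#'   non-wild-type genotype present.
#' @param min_wt5 Minimum wild-type 5' reads for retention (default 10).
#' @param flag_threshold Log2 ratio-change below which a gene is flagged
#'   (default -1).
#' @return `data.table` with gene_id, genotype, retained, log2_ratio_change,
#'   flagged, reason.
#' @export
intron_tem_3prime_test <- function(split_counts, wt = "WT", mutants = NULL,
                                   min_wt5 = 10, flag_threshold = -1) {
  sc <- data.table::as.data.table(split_counts)
  if (is.null(mutants)) mutants <- setdiff(unique(sc$genotype), wt)
  w <- sc[sc$genotype == wt]
  out <- lapply(mutants, function(g) {
    m <- sc[sc$genotype == g]
    d <- merge(w[, c("gene_id", "n5", "n3"), with = FALSE],
               m[, c("gene_id", "n5", "n3"), with = FALSE],
               by = "gene_id", suffixes = c("_wt", "_mut"))
    d[, retained := n5_wt >= min_wt5]
    d[, log2_ratio_change := NA_real_]
    d[, reason := ifelse(retained, "", sprintf("wt_5prime_below_%d", min_wt5))]
    ok <- d$retained & d$n5_mut > 0 & d$n3_wt > 0
    d[retained & n5_mut == 0, reason := "mutant_5prime_zero"]
    d[retained & n5_mut > 0 & n3_wt == 0, reason := "wt_3prime_zero"]
    d[ok, log2_ratio_change :=
        log2((n3_mut / n5_mut) / (n3_wt / n5_wt))]
    d[, flagged := !is.na(log2_ratio_change) &
        log2_ratio_change < flag_threshold]
    data.table::data.table(gene_id = d$gene_id, genotype = g,
                           retained = d$retained,
                           log2_ratio_change = d$log2_ratio_change,
                           flagged = d$flagged, reason = d$reason)
  })
  data.table::rbindlist(out)
}
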