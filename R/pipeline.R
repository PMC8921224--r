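#' Published category counts for the expressed-gene partition
#'
#' The five-way methylation-category counts reported for the Columbia-0
#' expressed-gene set (17,930 genes with detectable expression), used as
#' printed-table input for partition-arithmetic checks: counts must sum to
#' the expressed-gene total and the printed percentages must reproduce
#' from the counts.
#'
#' @return data.frame with category, n and the printed percentage.
#' @export
reference_category_counts <- function() {
  data.frame(category = c("gbM", "teM", "pM", "dM", "UM"),
             n = c(3463L, 292L, 3773L, 2367L, 8035L),
             printed_pct = c(19.3, 1.6, 21.0, 13.2, 44.8),
             stringsAsFactors = FALSE)
}

#' Run the full synthetic-panel analysis pipeline
#'
#' Executes every stage on data generated from one configuration:
#' methylome simulation and coverage filtering; per-genotype nuclear
#' versus organelle methylation levels and the non-conversion estimate;
#' gene-methylation classification of the expressed-gene set;
#' differential expression per mutant genotype; cross-genotype regulation
#' patterns; the intron-split 3'/5' ratio test; and split-read insertion
#' calling.  Stages run in dependency order; any failure aborts with the
#' stage name.
#'
#' @param config An `md_sim_config`.
#' @param out_dir Optional directory; when given, the report (JSON) and
#'   per-stage tables (TSV) are written there.
#' @param min_cov Coverage filter threshold (default 4).
#' @param q_thresh Classifier q-value threshold (default 0.01).
#' @param alpha,fc_gene,fc_antisense DE thresholds.
#' @param delta Pattern-classification log2 gap (default 1).
#' @param min_wt5 Intron-test retention threshold (default 10).
#' @return A `md_pipeline_report`: a list with elements
#'   `methylation_levels`, `nonconversion`, `categories`, `de_counts`,
#'   `patterns`, `intron_tem`, `insertions`, `thresholds`, `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL, min_cov = 4L,
                         q_thresh = 0.01, alpha = 0.01, fc_gene = 2,
                         fc_antisense = 4, delta = 1, min_wt5 = 10) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- stage("simulate_genome", simulate_genome(config))
  meths <- stage("simulate_methylomes", simulate_methylomes(sim))
  meths <- stage("filter_coverage",
                 lapply(meths, filter_coverage, min_cov = min_cov))

  levels_tab <- stage("methylation_levels", {
    rows <- list()
    for (g in names(meths)) for (ctx in c("CG", "CHG", "CHH")) {
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, context = ctx,
        nuclear = weighted_level(meths[[g]],
                                 chrom = nuclear_chroms(sim$genome),
                                 context = ctx),
        organelle = weighted_level(meths[[g]],
                                   chrom = sim$genome$organelle,
                                   context = ctx))
    }
    do.call(rbind, rows)
  })
  nonconv <- stage("nonconversion",
                   estimate_nonconversion(meths$WT, sim$genome))

  gene_counts <- stage("simulate_counts",
                       simulate_counts(config, feature_prefix = "G"))
  # tie count features to annotated genes where possible
  regions <- stage("derive_regions", derive_gene_regions(sim$ann, sim$genome))
  fpkm <- stage("fpkm", compute_fpkm(gene_counts$counts, gene_counts$lengths))
  expressed_features <- stage("filter_expressed",
                              filter_expressed(fpkm, gene_counts$design))
  expressed_genes <- sim$ann$genes$gene_id
  classification <- stage("classify_genes",
                          classify_genes(expressed_genes, meths$WT, regions,
                                         sim$ann, q_thresh = q_thresh))
  categories <- category_summary(classification, merge_tem = FALSE)

  de <- stage("de_test", {
    out <- list()
    for (g in c("ddcc", "met1", "mddcc")) {
      res <- de_test(gene_counts$counts[expressed_features, , drop = FALSE],
                     gene_counts$design, contrast = c(g, "WT"))
      out[[g]] <- call_de_features(res, "gene", alpha = alpha, fc = fc_gene)
    }
    out
  })
  de_counts <- do.call(rbind, lapply(names(de), function(g) data.frame(
    genotype = g, up = sum(de[[g]]$status == "up"),
    down = sum(de[[g]]$status == "down"))))

  patterns <- stage("patterns",
                    classify_regulation_pattern(de$ddcc, de$met1, de$mddcc,
                                                delta = delta))
  pattern_counts <- as.data.frame(table(patterns$direction, patterns$pattern),
                                  stringsAsFactors = FALSE)
  names(pattern_counts) <- c("direction", "pattern", "n")

  split_sim <- stage("simulate_split_counts", simulate_split_counts(config))
  intron_res <- stage("intron_tem",
                      intron_tem_3prime_test(split_sim$split_counts,
                                             min_wt5 = min_wt5))
  intron_summary <- intron_res[, .(retained = sum(retained),
                                   flagged = sum(flagged)), by = "genotype"]

  ins_sim <- stage("simulate_insertions", simulate_insertion_readset(sim))
  ins <- stage("call_insertions",
               call_te_insertions(ins_sim$sam, sim$genome, sim$ann))

  report <- structure(list(
    seed = config$seed,
    thresholds = list(min_cov = min_cov, q_thresh = q_thresh, alpha = alpha,
                      fc_gene = fc_gene, fc_antisense = fc_antisense,
                      delta = delta, min_wt5 = min_wt5),
    methylation_levels = levels_tab,
    nonconversion = nonconv,
    categories = as.data.frame(categories),
    n_expressed = nrow(classification),
    de_counts = de_counts,
    pattern_counts = pattern_counts,
    intron_tem = as.data.frame(intron_summary),
    insertions = ins$calls), class = "md_pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report[setdiff(names(report), "insertions")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.table(as.data.frame(classification),
                       file.path(out_dir, "gene_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ins$calls, file.path(out_dir, "insertions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(levels_tab,
                       file.path(out_dir, "methylation_levels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.md_pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$seed, ")\n")
  cat("  non-conversion estimate:", signif(x$nonconversion, 3), "\n")
  cat("  expressed genes classified:", x$n_expressed, "\n")
  print(x$categories)
  cat("  DE feature counts:\n")
  print(x$de_counts)
  cat("  insertion calls:", nrow(x$insertions), "\n")
  invisible(x)
}
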