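#' One-tailed binomial enrichment p-value
#'
#' P(X >= k) for X ~ Binomial(n, p_bg): the probability of observing at
#' least the recorded number of methylated calls if the region were
#' methylated at the background rate.  Untestable regions (n = 0) and k = 0
#' return 1.
#'
#' @param k Methylated-call counts (vectorized).
#' @param n Informative-call totals.
#' @param p_bg Background methylation level(s), in (0,1).
#' @return p-values in \[0,1\].
#' @export
binomial_tail_p <- function(k, n, p_bg) {
  if (any(p_bg <= 0 | p_bg >= 1)) stop("p_bg must lie strictly in (0,1)")
  if (any(k < 0 | k > n)) stop("require 0 <= k <= n")
  p <- stats::pbinom(k - 1, n, p_bg, lower.tail = FALSE)
  p[n == 0L | k == 0L] <- 1
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; input order preserved.
#'
#' @param p p-values in \[0,1\].
#' @return q-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Aggregate methylome counts over gene analysis regions
#'
#' For every gene and context (CG, CHG, CHH, plus pooled "C"), sums
#' methylated (k) and informative (n) calls over the gene body, the
#' exon-only and intron-only parts of the body, and every 500-bp promoter
#' and downstream bin.
#'
#' @param table A coverage-filtered `md_methylome` (typically wild type).
#' @param regions Output of [derive_gene_regions()].
#' @param ann The `md_annotation` the regions came from (supplies
#'   exon/intron structure).
#' @return `data.table` with columns gene_id, region_class (`body`,
#'   `body_exon`, `body_intron`, `promoter_bin`, `downstream_bin`), bin,
#'   context, k, n.  Every (gene, region, context) combination present in
#'   the annotation appears, with k = n = 0 where there is no coverage.
#' @export
aggregate_region_counts <- function(table, regions, ann) {
  ctxs <- c("CG", "CHG", "CHH")

  region_tab <- function(df, region_class) {
    if (!nrow(df)) return(NULL)
    data.table::data.table(gene_id = df$gene_id, chrom = df$chrom,
                           region_class = region_class,
                           bin = if (!is.null(df$bin)) df$bin else 0L,
                           start = df$start, end = df$end)
  }
  body <- regions[regions$region_class == "body" & regions$bin == 0L]
  gene_chrom <- stats::setNames(ann$genes$chrom, ann$genes$gene_id)
  ex <- ann$exons;  ex$chrom <- gene_chrom[ex$gene_id]
  ir <- ann$introns; if (nrow(ir)) ir$chrom <- gene_chrom[ir$gene_id]
  pieces <- data.table::rbindlist(list(
    region_tab(body, "body"),
    region_tab(ex, "body_exon"),
    region_tab(ir, "body_intron"),
    region_tab(regions[regions$region_class == "promoter" & regions$bin > 0L],
               "promoter_bin"),
    region_tab(regions[regions$region_class == "downstream" & regions$bin > 0L],
               "downstream_bin")))

  # overlap cytosine records with region pieces
  rec_gr <- GenomicRanges::GRanges(table$chrom,
                                   IRanges::IRanges(table$pos, table$pos))
  reg_gr <- GenomicRanges::GRanges(pieces$chrom,
                                   IRanges::IRanges(pieces$start, pieces$end))
  hits <- GenomicRanges::findOverlaps(rec_gr, reg_gr)
  dt <- data.table::data.table(
    gene_id = pieces$gene_id[S4Vectors::subjectHits(hits)],
    region_class = pieces$region_class[S4Vectors::subjectHits(hits)],
    bin = pieces$bin[S4Vectors::subjectHits(hits)],
    context = table$context[S4Vectors::queryHits(hits)],
    c_count = table$c_count[S4Vectors::queryHits(hits)],
    ct_count = table$ct_count[S4Vectors::queryHits(hits)])
  counts <- dt[, .(k = sum(c_count), n = sum(ct_count)),
               by = c("gene_id", "region_class", "bin", "context")]

  # complete the grid so untestable regions appear with k = n = 0
  # (body_exon rows for a multi-exon gene collapse to one row per gene)
  grid_src <- unique(pieces[, c("gene_id", "region_class", "bin")])
  grid <- grid_src[rep(seq_len(nrow(grid_src)), each = length(ctxs))]
  grid[, context := rep(ctxs, nrow(grid_src))]
  counts <- counts[grid, on = c("gene_id", "region_class", "bin", "context")]
  counts[is.na(k), `:=`(k = 0L, n = 0L)]

  pooled <- counts[, .(context = "C", k = sum(k), n = sum(n)),
                   by = c("gene_id", "region_class", "bin")]
  res <- data.table::rbindlist(list(counts, pooled), use.names = TRUE)
  data.table::setkeyv(res, c("gene_id", "region_class", "bin", "context"))
  res[]
}

#' Per-region-class background methylation levels
#'
#' Pools coverage-filtered counts over all gene bodies, all promoter bins
#' and all downstream bins (nuclear genes) and returns the weighted level
#' per (region class, context), clamped to \[1e-6, 1 - 1e-6\] so tests
#' against a degenerate zero background remain defined.
#'
#' @param region_counts Output of [aggregate_region_counts()].
#' @param clamp Clamping bound (default 1e-6).
#' @return `data.table` with region_class (`body`, `promoter`,
#'   `downstream`), context, p_bg.
#' @export
compute_backgrounds <- function(region_counts, clamp = 1e-6) {
  map <- c(body = "body", promoter_bin = "promoter",
           downstream_bin = "downstream")
  rc <- region_counts[region_counts$region_class %in% names(map)]
  rc <- data.table::copy(rc)[, region_class := map[region_class]]
  bg <- rc[, .(k = sum(k), n = sum(n)), by = c("region_class", "context")]
  if (!nrow(bg)) stop("region class with zero total coverage: no counts")
  if (any(bg$n == 0L))
    stop("region class with zero total coverage: ",
         paste(unique(bg$region_class[bg$n == 0L]), collapse = ", "))
  bg[, p_bg := pmin(pmax(k / n, clamp), 1 - clamp)]
  bg[, c("region_class", "context", "p_bg"), with = FALSE]
}

#' Select the maximally methylated bin of a flank region
#'
#' Among the 500-bp bins of one gene's promoter (or downstream) region,
#' returns the bin with the highest pooled-context weighted level.  Bins
#' without coverage rank lowest; ties are broken in favour of the
#' gene-proximal bin (lowest bin index).  If no bin has coverage, a
#' sentinel with k = n = 0 is returned (which tests at p = 1).
#'
#' @param bins `data.table` of pooled-context ("C") bin counts for one gene
#'   and one region class, with columns bin, k, n.
#' @return One-row `data.table` (bin, k, n).
#' @export
select_max_bin <- function(bins) {
  if (!nrow(bins)) stop("no bins supplied")
  lvl <- ifelse(bins$n > 0L, bins$k / bins$n, -Inf)
  if (all(!is.finite(lvl)))
    return(data.table::data.table(bin = 0L, k = 0L, n = 0L))
  ord <- order(-lvl, bins$bin)
  bins[ord[1], c("bin", "k", "n"), with = FALSE]
}

# per-gene max bin for one region class, vectorized over genes
max_bin_by_gene <- function(region_counts, rclass) {
  keep <- region_counts$region_class == rclass & region_counts$context == "C"
  rc <- region_counts[which(keep), ]
  if (!nrow(rc))
    return(data.table::data.table(gene_id = character(), bin = integer(),
                                  k = integer(), n = integer()))
  rc[, .(sel = list(select_max_bin(.SD))), by = "gene_id",
     .SDcols = c("bin", "k", "n")][
       , .(bin = sel[[1]]$bin, k = sel[[1]]$k, n = sel[[1]]$n),
       by = "gene_id"]
}

#' Classify expressed genes into six methylation categories
#'
#' Implements the one-tailed binomial decision tree over the wild-type
#' methylome.  For every expressed gene, body counts per context, the
#' maximally methylated promoter bin and the maximally methylated
#' downstream bin are tested against the corresponding region-class
#' background; p-values are BH-adjusted separately per (region, context)
#' family across the expressed-gene set.  Categories, in order of
#' precedence:
#'
#' 1. **teM** — body CHG or CHH q < `q_thresh`; split into **Intron-teM**
#'    when the non-CG signal is intron-restricted — the intron-only counts
#'    are significant in CHG or CHH (against the body background) while
#'    the exon-only counts are not — else **Other-teM**.
#' 2. **gbM** — body CG q < `q_thresh` with body CHG and CHH both
#'    non-significant.
#' 3. **pM** — best promoter bin, pooled contexts, q < `q_thresh`.
#' 4. **dM** — best downstream bin q < `q_thresh` with promoter
#'    non-significant.
#' 5. **UM** — everything else.
#'
#' @param expressed_ids Gene IDs passing the expression filter.
#' @param table Coverage-filtered wild-type `md_methylome`.
#' @param regions Output of [derive_gene_regions()].
#' @param ann The matching `md_annotation`.
#' @param q_thresh Significance threshold on q-values (default 0.01).
#' @param intron_rule `"intron_not_exon"` (default): Intron-teM requires a
#'   significant intron test together with a non-significant exon test, so
#'   genes methylated across their whole body remain Other-teM.
#'   `"intron"`: intron significance alone suffices.
#' @param region_counts Optionally, a precomputed
#'   [aggregate_region_counts()] table (saves recomputation).
#' @return `data.table` with gene_id, category and the supporting
#'   q-values (q_body_cg, q_body_chg, q_body_chh, q_intron_chg,
#'   q_intron_chh, q_promoter, q_downstream).
#' @export
classify_genes <- function(expressed_ids, table, regions, ann,
                           q_thresh = 0.01,
                           intron_rule = c("intron_not_exon", "intron"),
                           region_counts = NULL) {
  intron_rule <- match.arg(intron_rule)
  missing_ids <- setdiff(expressed_ids, ann$genes$gene_id)
  if (length(missing_ids))
    stop("expressed gene(s) without annotation/regions: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  if (is.null(region_counts))
    region_counts <- aggregate_region_counts(table, regions, ann)
  rc <- region_counts[region_counts$gene_id %in% expressed_ids]
  bg <- compute_backgrounds(region_counts)
  bg_of <- function(region_class, context)
    bg$p_bg[bg$region_class == region_class & bg$context == context]

  ids <- sort(unique(expressed_ids))
  base <- data.table::data.table(gene_id = ids)

  test_family <- function(counts, p_bg) {
    # counts: gene_id, k, n aligned to ids
    m <- counts[base, on = "gene_id"]
    m[is.na(k), `:=`(k = 0L, n = 0L)]
    p <- binomial_tail_p(m$k, m$n, p_bg)
    data.table::data.table(gene_id = m$gene_id, k = m$k, n = m$n,
                           p = p, q = bh_adjust(p))
  }

  fam_body <- lapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(ctx)
    test_family(rc[region_class == "body" & context == ctx,
                   c("gene_id", "k", "n"), with = FALSE],
                bg_of("body", ctx)))
  fam_intron <- lapply(c(CHG = "CHG", CHH = "CHH"), function(ctx)
    test_family(rc[region_class == "body_intron" & context == ctx,
                   c("gene_id", "k", "n"), with = FALSE],
                bg_of("body", ctx)))
  fam_exon <- lapply(c(CHG = "CHG", CHH = "CHH"), function(ctx)
    test_family(rc[region_class == "body_exon" & context == ctx,
                   c("gene_id", "k", "n"), with = FALSE],
                bg_of("body", ctx)))
  prom_best <- max_bin_by_gene(rc, "promoter_bin")
  down_best <- max_bin_by_gene(rc, "downstream_bin")
  fam_prom <- test_family(prom_best[, c("gene_id", "k", "n"), with = FALSE],
                          bg_of("promoter", "C"))
  fam_down <- test_family(down_best[, c("gene_id", "k", "n"), with = FALSE],
                          bg_of("downstream", "C"))

  q <- data.table::data.table(
    gene_id = ids,
    q_body_cg = fam_body$CG$q, q_body_chg = fam_body$CHG$q,
    q_body_chh = fam_body$CHH$q,
    q_intron_chg = fam_intron$CHG$q, q_intron_chh = fam_intron$CHH$q,
    q_exon_chg = fam_exon$CHG$q, q_exon_chh = fam_exon$CHH$q,
    q_promoter = fam_prom$q, q_downstream = fam_down$q)

  sig <- function(x) !is.na(x) & x < q_thresh
  is_tem <- sig(q$q_body_chg) | sig(q$q_body_chh)
  intron_sig <- sig(q$q_intron_chg) | sig(q$q_intron_chh)
  if (intron_rule == "intron_not_exon")
    intron_sig <- intron_sig & !(sig(q$q_exon_chg) | sig(q$q_exon_chh))
  is_gbm <- sig(q$q_body_cg) & !sig(q$q_body_chg) & !sig(q$q_body_chh)
  is_pm <- sig(q$q_promoter)
  is_dm <- sig(q$q_downstream) & !sig(q$q_promoter)

  category <- rep("UM", length(ids))
  category[is_dm] <- "dM"
  category[is_pm] <- "pM"
  category[is_gbm] <- "gbM"
  category[is_tem & !intron_sig] <- "Other-teM"
  category[is_tem & intron_sig] <- "Intron-teM"
  q[, category := category]
  data.table::setcolorder(q, c("gene_id", "category"))
  q[]
}

#' Summarize gene-category counts and proportions
#'
#' @param classification Output of [classify_genes()].
#' @param merge_tem Merge Intron-teM and Other-teM into a single teM
#'   category (the five-way summary).
#' @return `data.table` with category, n, proportion.
#' @export
category_summary <- function(classification, merge_tem = TRUE) {
  cat <- classification$category
  if (merge_tem) cat[cat %in% c("Intron-teM", "Other-teM")] <- "teM"
  lev <- if (merge_tem) c("gbM", "teM", "pM", "dM", "UM")
         else c("gbM", "Intron-teM", "Other-teM", "pM", "dM", "UM")
  tab <- table(factor(cat, levels = lev))
  data.table::data.table(category = names(tab), n = as.integer(tab),
                         proportion = as.numeric(tab) / length(cat))
}
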