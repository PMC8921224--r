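#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator.  Defaults encode
#' the study conditions the package is designed around: four genotypes
#' (wild type; a non-CG-deficient quadruple mutant "ddcc"; a CG-deficient
#' mutant "met1"; a methylation-free quintuple mutant "mddcc"), planted
#' methylation-category levels, a bisulfite non-conversion floor shared
#' with an unmethylated organelle control chromosome, negative-binomial
#' counts with planted regulation patterns, intron-split transcripts with
#' 3' depletion, and paired-end read sets spanning planted transposon
#' insertions with defined target-site duplications.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_genes Number of genes on the nuclear chromosome.
#' @param category_fractions Named fractions over the six planted
#'   methylation categories.  The default mix is dominated by unmethylated
#'   and promoter/downstream-methylated genes with a small teM class, as
#'   in real plant genomes.
#' @param exon_bp,intron_bp Gene structure: two exons flanking one intron.
#' @param flank_bp Promoter/downstream width (2 kb).
#' @param gene_gap_bp Intergenic gap between consecutive gene footprints.
#' @param n_tes,te_len_bp,te_gap_bp Transposon zone layout.
#' @param margin_bp Plain-sequence margin at each chromosome extremity.
#' @param centromere_n_bp Length of the centromere-analogue N block.
#' @param organelle_len_bp Length of the organelle control chromosome.
#' @param levels Named list of methylation levels: `background` per-context
#'   intergenic baseline, `gbm_cg` (gene-body CG), `tem` (teM body /
#'   intron), `hot_bin` (planted promoter/downstream bin, all contexts),
#'   `te_body` (transposon copies, all contexts).
#' @param nonconversion Bisulfite non-conversion rate (floor everywhere,
#'   including the organelle chromosome).
#' @param coverage_mean Mean per-cytosine coverage (shifted Poisson,
#'   minimum 1, so the coverage filter has bite).
#' @param met1_noncg_factor Residual non-CG scaling in the CG-deficient
#'   mutant (mild genome-wide reduction of CHG/CHH); set to 1 to disable.
#' @param n_rep Replicates per genotype for count simulation.
#' @param base_mean,dispersion Negative-binomial count parameters.
#' @param pattern_fractions Named fractions over regulation patterns for
#'   DE features; dosage patterns II and III are rare and the single-locus
#'   CG-driven dosage pattern is the most common, matching the reported
#'   relative abundances.
#' @param pattern_lfc Named list of per-genotype planted log2 fold
#'   changes for each pattern.
#' @param frac_down Fraction of DE features planted in the down direction.
#' @param n_de_features,n_null_features Count-panel composition.
#' @param split_wt_mean5,split_wt_mean3 Expected 5'/3' part counts in wild
#'   type for intron-split genes.
#' @param split_depletion Fold depletion of the 3' part in affected
#'   genotypes.
#' @param read_len,n_junction_reads,n_background_pairs Insertion read-set
#'   shape.
#' @return A list of class `md_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       category_fractions = c(gbM = 0.15, `Intron-teM` = 0.05,
                                              `Other-teM` = 0.05, pM = 0.175,
                                              dM = 0.125, UM = 0.45),
                       exon_bp = 400L, intron_bp = 400L,
                       flank_bp = 2000L, gene_gap_bp = 300L,
                       n_tes = 6L, te_len_bp = 1000L, te_gap_bp = 800L,
                       margin_bp = 5000L, centromere_n_bp = 2000L,
                       organelle_len_bp = 20000L,
                       levels = list(background = c(CG = 0.05, CHG = 0.02,
                                                    CHH = 0.02),
                                     gbm_cg = 0.3, tem = 0.3, hot_bin = 0.4,
                                     te_body = 0.5),
                       nonconversion = 0.004,
                       coverage_mean = 20,
                       met1_noncg_factor = 0.7,
                       n_rep = 3L, base_mean = 500, dispersion = 0.05,
                       pattern_fractions = c(Redundancy = 0.25, DosageI = 0.35,
                                             DosageII = 0.05, DosageIII = 0.05,
                                             mCG = 0.20, non_mCG = 0.10),
                       pattern_lfc = list(
                         Redundancy = c(ddcc = 0, met1 = 0, mddcc = 3),
                         DosageI = c(ddcc = 0, met1 = 1.5, mddcc = 3),
                         DosageII = c(ddcc = 1.5, met1 = 0, mddcc = 3),
                         DosageIII = c(ddcc = 1.2, met1 = 1.2, mddcc = 3),
                         mCG = c(ddcc = 0, met1 = 3, mddcc = 3),
                         non_mCG = c(ddcc = 3, met1 = 0, mddcc = 3)),
                       frac_down = 0.5,
                       n_de_features = 120L, n_null_features = 400L,
                       split_wt_mean5 = 100, split_wt_mean3 = 100,
                       split_depletion = 5,
                       read_len = 100L, n_junction_reads = 8L,
                       n_background_pairs = 60L) {
  stopifnot(abs(sum(category_fractions) - 1) < 1e-8,
            abs(sum(pattern_fractions) - 1) < 1e-8,
            all(unlist(levels) >= 0), all(unlist(levels) <= 1),
            nonconversion >= 0, nonconversion < 1)
  cfg <- as.list(environment())
  class(cfg) <- "md_sim_config"
  cfg
}

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a genome with annotated genes and transposons
#'
#' Lays out one nuclear chromosome — margin, gene blocks
#' (promoter / exon-intron-exon body / downstream, alternating strand),
#' a transposon zone, a centromere-analogue N block, margin — plus an
#' organelle control chromosome, and assigns each gene a planted
#' methylation category.
#'
#' @param config An `md_sim_config`.
#' @return list with `genome` (`md_genome`), `ann` (`md_annotation`) and
#'   `truth`: a `data.table` (gene_id, category, hot_bin for pM/dM genes).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  ng <- config$n_genes
  body_bp <- 2L * config$exon_bp + config$intron_bp
  block_bp <- 2L * config$flank_bp + body_bp + config$gene_gap_bp
  te_zone_bp <- config$n_tes * (config$te_len_bp + config$te_gap_bp)
  L <- 2L * config$margin_bp + ng * block_bp + te_zone_bp +
    config$centromere_n_bp
  if (L > 5e8) stop("genome layout exceeds supported size")

  seq_nuc <- random_seq(L)
  # carve the centromere N block just before the final margin
  cen_start <- L - config$margin_bp - config$centromere_n_bp + 1L
  cen_end <- L - config$margin_bp
  seq_nuc <- paste0(substring(seq_nuc, 1L, cen_start - 1L),
                    strrep("N", config$centromere_n_bp),
                    substring(seq_nuc, cen_end + 1L, L))

  cats <- sample(rep(names(config$category_fractions),
                     times = round(config$category_fractions * ng))[
                       seq_len(ng)])
  cats[is.na(cats)] <- "UM"
  gene_id <- sprintf("G%04d", seq_len(ng))
  strand <- rep(c("+", "-"), length.out = ng)
  block_start <- config$margin_bp + (seq_len(ng) - 1L) * block_bp + 1L
  body_start <- block_start + config$flank_bp
  body_end <- body_start + body_bp - 1L
  genes <- data.frame(gene_id = gene_id, chrom = "chr1", strand = strand,
                      start = body_start, end = body_end,
                      stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(ng), function(i) data.frame(
    gene_id = gene_id[i],
    start = c(body_start[i], body_start[i] + config$exon_bp + config$intron_bp),
    end = c(body_start[i] + config$exon_bp - 1L, body_end[i]),
    stringsAsFactors = FALSE)))
  introns <- data.frame(gene_id = gene_id,
                        start = body_start + config$exon_bp,
                        end = body_start + config$exon_bp + config$intron_bp - 1L,
                        stringsAsFactors = FALSE)

  te_zone_start <- config$margin_bp + ng * block_bp + 1L
  te_start <- te_zone_start + (seq_len(config$n_tes) - 1L) *
    (config$te_len_bp + config$te_gap_bp)
  fams <- paste0("FAM", rep_len(1:3, config$n_tes))
  tes <- data.frame(te_id = sprintf("TE%03d", seq_len(config$n_tes)),
                    family = fams, chrom = "chr1",
                    strand = rep(c("+", "-"), length.out = config$n_tes),
                    start = te_start, end = te_start + config$te_len_bp - 1L,
                    stringsAsFactors = FALSE)
  if (config$n_tes == 0L)
    tes <- data.frame(te_id = character(), family = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)

  seqs <- c(chr1 = seq_nuc, chrC = random_seq(config$organelle_len_bp))
  genome <- genome_from_strings(seqs, organelle = "chrC")
  ann <- structure(list(genes = genes, exons = exons, introns = introns,
                        tes = tes), class = "md_annotation")

  hot_bin <- ifelse(cats %in% c("pM", "dM"),
                    sample(1:4, ng, replace = TRUE), NA_integer_)
  truth <- data.table::data.table(gene_id = gene_id, category = cats,
                                  hot_bin = hot_bin)
  list(genome = genome, ann = ann, truth = truth, config = config)
}

# planted level intervals: (chrom, start, end, context or "all", level),
# higher priority overrides lower
planted_level_intervals <- function(sim) {
  cfg <- sim$config
  ann <- sim$ann
  truth <- sim$truth
  regions <- derive_gene_regions(ann, sim$genome, flank_bp = cfg$flank_bp)
  iv <- list()
  add <- function(chrom, start, end, context, level, priority)
    iv[[length(iv) + 1L]] <<- data.table::data.table(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      context = context, level = level, priority = priority)

  # gene footprints sit at the floor so planted signal stands out
  foot <- regions[regions$bin == 0L]
  fs <- foot[, .(start = min(start), end = max(end)),
             by = c("gene_id", "chrom")]
  add(fs$chrom, fs$start, fs$end, "all", 0, 1L)

  g <- ann$genes[match(truth$gene_id, ann$genes$gene_id), ]
  for (i in seq_len(nrow(truth))) {
    cat <- truth$category[i]
    if (cat == "UM") next
    gi <- g[i, ]
    if (cat == "gbM") {
      add(gi$chrom, gi$start, gi$end, "CG", cfg$levels$gbm_cg, 2L)
    } else if (cat == "Other-teM") {
      for (ctx in c("CG", "CHG", "CHH"))
        add(gi$chrom, gi$start, gi$end, ctx, cfg$levels$tem, 2L)
    } else if (cat == "Intron-teM") {
      ir <- ann$introns[ann$introns$gene_id == gi$gene_id, ][1, ]
      for (ctx in c("CG", "CHG", "CHH"))
        add(gi$chrom, ir$start, ir$end, ctx, cfg$levels$tem, 2L)
    } else if (cat %in% c("pM", "dM")) {
      rclass <- if (cat == "pM") "promoter" else "downstream"
      b <- regions[regions$gene_id == gi$gene_id &
                   regions$region_class == rclass &
                   regions$bin == truth$hot_bin[i]]
      if (nrow(b))
        add(b$chrom, b$start, b$end, "all", cfg$levels$hot_bin, 2L)
    }
  }
  if (nrow(ann$tes))
    add(ann$tes$chrom, ann$tes$start, ann$tes$end, "all",
        cfg$levels$te_body, 2L)
  data.table::rbindlist(iv)
}

#' Simulate per-cytosine methylomes for the genotype panel
#'
#' For every cytosine of the genome, coverage is drawn from a shifted
#' Poisson and methylated calls from a binomial whose success probability
#' is the planted regional level, modified by the genotype's erasure map
#' (ddcc zeroes non-CG; met1 zeroes CG and mildly reduces non-CG; mddcc
#' zeroes everything) and floored by the non-conversion rate everywhere —
#' including the organelle control chromosome, which is unmethylated in
#' every genotype.
#'
#' @param sim Output of [simulate_genome()].
#' @param genotypes Genotypes to simulate.
#' @return Named list of `md_methylome` tables.
#' @export
simulate_methylomes <- function(sim, genotypes = c("WT", "ddcc", "met1",
                                                   "mddcc")) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  cm <- annotate_contexts(sim$genome)
  base <- cfg$levels$background
  cm[, level := base[context]]
  cm[chrom %in% sim$genome$organelle, level := 0]

  iv <- planted_level_intervals(sim)
  if (nrow(iv)) {
    data.table::setkeyv(iv, c("chrom", "start", "end"))
    pts <- cm[, .(chrom, start = pos, end = pos, idx = seq_len(.N),
                  ctx = context)]
    ov <- data.table::foverlaps(pts, iv, type = "within", nomatch = NULL,
                                by.x = c("chrom", "start", "end"))
    ov <- ov[context == "all" | context == ctx]
    if (nrow(ov)) {
      ov <- ov[order(priority)]
      upd <- ov[, .(level = level[.N]), by = "idx"]
      cm[upd$idx, level := upd$level]
    }
  }

  out <- lapply(genotypes, function(g) {
    lv <- cm$level
    if (g == "ddcc") {
      lv[cm$context != "CG"] <- 0
    } else if (g == "met1") {
      lv[cm$context == "CG"] <- 0
      lv[cm$context != "CG"] <- lv[cm$context != "CG"] * cfg$met1_noncg_factor
    } else if (g == "mddcc") {
      lv[] <- 0
    }
    p <- lv + (1 - lv) * cfg$nonconversion
    cov <- 1L + stats::rpois(nrow(cm), cfg$coverage_mean - 1)
    cc <- stats::rbinom(nrow(cm), cov, p)
    new_methylome(data.table::data.table(
      chrom = cm$chrom, pos = cm$pos, strand = cm$strand,
      context = cm$context, c_count = cc, ct_count = cov),
      sample = g, genotype = g)
  })
  names(out) <- genotypes
  out
}

#' Simulate a count panel with planted regulation patterns
#'
#' Negative-binomial counts for a four-genotype panel: `n_de_features`
#' features carry a planted cross-genotype pattern (per-genotype log2 fold
#' changes from `config$pattern_lfc`, direction up or down) and
#' `n_null_features` are unchanged in every genotype.
#'
#' @param config An `md_sim_config`.
#' @param feature_prefix Prefix for feature IDs.
#' @param seed_offset Offset added to the config seed so distinct panels
#'   drawn from one config are independent.
#' @return list with `counts` (matrix), `design` (sample, genotype),
#'   `lengths` (per-feature bp, for FPKM) and `truth` (feature_id,
#'   pattern, direction).
#' @export
simulate_counts <- function(config, feature_prefix = "F", seed_offset = 2L) {
  set.seed(config$seed + seed_offset)
  genotypes <- c("WT", "ddcc", "met1", "mddcc")
  n_de <- config$n_de_features; n0 <- config$n_null_features
  nf <- n_de + n0
  ids <- sprintf("%s%05d", feature_prefix, seq_len(nf))
  pat <- c(sample(rep(names(config$pattern_fractions),
                      times = round(config$pattern_fractions * n_de))[
                        seq_len(n_de)]),
           rep("null", n0))
  pat[is.na(pat)] <- "Redundancy"
  dir <- ifelse(seq_len(nf) <= n_de &
                  stats::runif(nf) < config$frac_down, "down", "up")
  dir[pat == "null"] <- NA_character_

  design <- data.frame(
    sample = paste0(rep(genotypes, each = config$n_rep), "_r",
                    rep(seq_len(config$n_rep), length(genotypes))),
    genotype = rep(genotypes, each = config$n_rep),
    stringsAsFactors = FALSE)

  lfc <- matrix(0, nf, length(genotypes),
                dimnames = list(ids, genotypes))
  for (i in seq_len(n_de)) {
    eff <- config$pattern_lfc[[pat[i]]]
    sgn <- if (dir[i] == "down") -1 else 1
    lfc[i, names(eff)] <- sgn * eff
  }
  mu <- config$base_mean * 2^lfc[, design$genotype, drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$dispersion),
                   nf, nrow(design),
                   dimnames = list(ids, design$sample))
  list(counts = counts, design = design,
       lengths = stats::setNames(rep(1000L, nf), ids),
       truth = data.table::data.table(feature_id = ids, pattern = pat,
                                      direction = dir))
}

#' Simulate 5'/3' split counts for intron-methylated genes
#'
#' Each gene is split at its methylated intron; 5' and 3' part counts are
#' drawn per genotype (negative binomial, summed over replicates).  In the
#' affected genotypes the 3' mean is divided by `config$split_depletion`,
#' so the expected log2 ratio change is `-log2(split_depletion)`.  A
#' configurable number of genes are planted with shallow wild-type 5'
#' coverage to exercise the retention filter.
#'
#' @param config An `md_sim_config`.
#' @param n_genes Number of intron-split genes.
#' @param n_depleted Genes with planted 3' depletion.
#' @param n_low5 Genes with wild-type 5' counts below the retention
#'   threshold.
#' @param depleted_genotypes Genotypes carrying the depletion (default
#'   "mddcc").
#' @param seed_offset Seed offset.
#' @return list with `split_counts` (gene_id, genotype, n5, n3) and
#'   `truth` (gene_id, depleted, low5).
#' @export
simulate_split_counts <- function(config, n_genes = 40L, n_depleted = 10L,
                                  n_low5 = 5L,
                                  depleted_genotypes = "mddcc",
                                  seed_offset = 3L) {
  set.seed(config$seed + seed_offset)
  genotypes <- c("WT", "ddcc", "met1", "mddcc")
  ids <- sprintf("S%04d", seq_len(n_genes))
  depleted <- seq_len(n_genes) <= n_depleted
  low5 <- seq_len(n_genes) > n_genes - n_low5
  rows <- list()
  for (g in genotypes) {
    m5 <- ifelse(low5, 1, config$split_wt_mean5)
    m3 <- rep(config$split_wt_mean3, n_genes)
    if (g %in% depleted_genotypes)
      m3[depleted] <- m3[depleted] / config$split_depletion
    n5 <- stats::rnbinom(n_genes, mu = m5 * config$n_rep,
                         size = config$n_rep / config$dispersion)
    n3 <- stats::rnbinom(n_genes, mu = m3 * config$n_rep,
                         size = config$n_rep / config$dispersion)
    rows[[g]] <- data.table::data.table(gene_id = ids, genotype = g,
                                        n5 = n5, n3 = n3)
  }
  list(split_counts = data.table::rbindlist(rows),
       truth = data.table::data.table(gene_id = ids, depleted = depleted,
                                      low5 = low5))
}

#' Simulate a paired-end read set spanning planted transposon insertions
#'
#' For each planted insertion the mutant haplotype is the reference up to
#' the end of the duplicated target site, the donor transposon copy, then
#' the reference restarting at the beginning of the target site (yielding
#' the TSD).  Junction-spanning reads are emitted as unmapped records with
#' their sequence retained and a mapped mate nearby, as an aligner would
#' leave them; background concordant pairs are included.  Decoy insertions
#' (boundary TSD sizes, under-supported clusters, masked regions) can be
#' planted to exercise the caller's negative paths.
#'
#' @param sim Output of [simulate_genome()].
#' @param insertions data.frame describing the planted insertions:
#'   columns te_id, chrom, pos (last reference base before the insertion,
#'   = end of the duplicated site), tsd_len, n_reads (per side; default
#'   `config$n_junction_reads`), label (free text recorded in the truth).
#'   When NULL, five insertions with TSDs 4-19 bp are auto-placed in
#'   unmasked territory.
#' @param path Output SAM path (default a tempfile).
#' @param seed_offset Seed offset.
#' @return list with `sam` (path), `truth` (data.frame with the expected
#'   TSD interval per insertion) and `insertions` (as used).
#' @export
simulate_insertion_readset <- function(sim, insertions = NULL,
                                       path = tempfile(fileext = ".sam"),
                                       seed_offset = 4L) {
  cfg <- sim$config
  genome <- sim$genome
  ann <- sim$ann
  set.seed(cfg$seed + seed_offset)
  rl <- cfg$read_len
  chrom <- "chr1"
  ref <- genome$seqs[[chrom]]
  L <- nchar(ref)

  if (is.null(insertions)) {
    mask <- build_chromosome_mask(genome)
    lo <- mask$end_margin + rl + 500L
    hi_zone <- min(c(ann$tes$start, L - mask$end_margin)) - 2000L
    pos <- sort(sample(seq(lo, hi_zone, by = 997L),
                       min(5L, nrow(ann$tes)), replace = FALSE))
    insertions <- data.frame(
      te_id = ann$tes$te_id[seq_along(pos)], chrom = chrom, pos = pos,
      tsd_len = sample(4:19, length(pos), replace = TRUE),
      n_reads = cfg$n_junction_reads, label = "planted",
      stringsAsFactors = FALSE)
  }
  if (is.null(insertions$n_reads)) insertions$n_reads <- cfg$n_junction_reads
  if (is.null(insertions$label)) insertions$label <- "planted"

  recs <- list()
  emit <- function(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
                   seq)
    recs[[length(recs) + 1L]] <<- sprintf(
      "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
      qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq,
      strrep("I", nchar(seq)))

  truth <- list()
  for (i in seq_len(nrow(insertions))) {
    ins <- insertions[i, ]
    te <- ann$tes[ann$tes$te_id == ins$te_id, ]
    te_seq <- substring(genome$seqs[[te$chrom]], te$start, te$end)
    if (te$strand == "-") te_seq <- revcomp(te_seq)
    tl <- nchar(te_seq)
    b <- ins$pos                      # end of duplicated target site
    a <- b - ins$tsd_len + 1L         # start of duplicated target site
    truth[[i]] <- data.frame(te_id = ins$te_id, chrom = ins$chrom,
                             tsd_start = a, tsd_end = b,
                             tsd_len = ins$tsd_len, label = ins$label,
                             stringsAsFactors = FALSE)
    offs <- 30L + ((seq_len(ins$n_reads) - 1L) * 7L) %% (rl - 60L)
    # left junction: genome[..b] | TE 5' start
    for (k in seq_len(ins$n_reads)) {
      o <- offs[k]
      jread <- paste0(substring(ref, b - o + 1L, b),
                      substring(te_seq, 1L, rl - o))
      mstart <- b - o - 150L - rl + 1L
      mseq <- substring(ref, mstart, mstart + rl - 1L)
      q <- sprintf("ins%02d_L%02d", i, k)
      emit(q, 73L, chrom, mstart, 60L, paste0(rl, "M"), "*", 0L, 0L, mseq)
      emit(q, 133L, "*", 0L, 0L, "*", chrom, mstart, 0L, revcomp(jread))
    }
    # right junction: TE 3' end | genome[a..]
    for (k in seq_len(ins$n_reads)) {
      o <- offs[k]
      jread <- paste0(substring(te_seq, tl - o + 1L, tl),
                      substring(ref, a, a + (rl - o) - 1L))
      mstart <- a + (rl - o) + 150L
      mseq <- substring(ref, mstart, mstart + rl - 1L)
      q <- sprintf("ins%02d_R%02d", i, k)
      emit(q, 69L, "*", 0L, 0L, "*", chrom, mstart, 0L, jread)
      emit(q, 153L, chrom, mstart, 60L, paste0(rl, "M"), "*", 0L, 0L, mseq)
    }
  }

  # background concordant pairs
  for (k in seq_len(cfg$n_background_pairs)) {
    p <- sample.int(L - 400L, 1L)
    s1 <- substring(ref, p, p + rl - 1L)
    p2 <- p + 150L + rl
    s2 <- substring(ref, p2, p2 + rl - 1L)
    if (grepl("N", s1, fixed = TRUE) || grepl("N", s2, fixed = TRUE)) next
    q <- sprintf("bg%05d", k)
    emit(q, 99L, chrom, p, 60L, paste0(rl, "M"), "=", p2, p2 + rl - p, s1)
    emit(q, 147L, chrom, p2, 60L, paste0(rl, "M"), "=", p, -(p2 + rl - p), s2)
  }

  con <- file(path, "w")
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(genome$seqs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(genome$seqs[[nm]])), con)
  writeLines(unlist(recs), con)
  close(con)

  list(sam = path, truth = do.call(rbind, truth), insertions = insertions)
}
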