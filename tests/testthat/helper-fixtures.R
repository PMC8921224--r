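# small deterministic fixtures shared across test files

make_annotation <- function(genes, exons = NULL, tes = NULL) {
  if (is.null(exons))
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end, stringsAsFactors = FALSE)
  if (is.null(tes))
    tes <- data.frame(te_id = character(), family = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  introns <- do.call(rbind, lapply(split(exons, exons$gene_id), function(ex) {
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) return(NULL)
    data.frame(gene_id = ex$gene_id[1], start = ex$end[-nrow(ex)] + 1L,
               end = ex$start[-1L] - 1L, stringsAsFactors = FALSE)
  }))
  if (is.null(introns))
    introns <- data.frame(gene_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons, introns = introns, tes = tes),
            class = "md_annotation")
}

make_methylome <- function(chrom, pos, strand, context, c_count, ct_count,
                           genotype = "WT") {
  methdose:::new_methylome(
    data.table::data.table(chrom = chrom, pos = as.integer(pos),
                           strand = strand, context = context,
                           c_count = as.integer(c_count),
                           ct_count = as.integer(ct_count)),
    sample = genotype, genotype = genotype)
}

random_genome_string <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent per-position context oracle used against annotate_contexts
context_oracle <- function(seq_str) {
  b <- strsplit(seq_str, "", fixed = TRUE)[[1]]
  L <- length(b)
  H <- c("A", "C", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rows <- list()
  for (i in seq_len(L)) {
    if (b[i] == "C") {
      b1 <- if (i + 1 <= L) b[i + 1] else "N"
      b2 <- if (i + 2 <= L) b[i + 2] else "N"
      ctx <- if (b1 == "G") "CG"
             else if (b1 %in% H && b2 == "G") "CHG"
             else if (b1 %in% H && b2 %in% H) "CHH" else NA
      if (!is.na(ctx))
        rows[[length(rows) + 1]] <- data.frame(pos = i, strand = "+",
                                               context = ctx)
    }
    if (b[i] == "G") {
      b1 <- if (i - 1 >= 1) comp[[b[i - 1]]] else "N"
      b2 <- if (i - 2 >= 1) comp[[b[i - 2]]] else "N"
      ctx <- if (b1 == "G") "CG"
             else if (b1 %in% H && b2 == "G") "CHG"
             else if (b1 %in% H && b2 %in% H) "CHH" else NA
      if (!is.na(ctx))
        rows[[length(rows) + 1]] <- data.frame(pos = i, strand = "-",
                                               context = ctx)
    }
  }
  do.call(rbind, rows)
}
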