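#' Genome sequence container
#'
#' Builds the in-memory genome object used throughout the package: a set of
#' named chromosome sequences plus a set of chromosome names flagged as
#' unmethylated organelle controls (chloroplast-like).  Sequences are stored
#' uppercase with any non-ACGTN character mapped to N.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param organelle Character vector of chromosome names to flag as
#'   organelle controls.  Must be a subset of `names(seqs)`.
#' @return An object of class `md_genome`: a list with elements `seqs`
#'   (named uppercase character vector) and `organelle`.
#' @export
genome_from_strings <- function(seqs, organelle = character()) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicated chromosome names")
  seqs <- toupper(seqs)
  seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record: ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  if (!all(organelle %in% names(seqs)))
    stop("organelle flags name unknown chromosomes: ",
         paste(setdiff(organelle, names(seqs)), collapse = ", "))
  structure(list(seqs = seqs, organelle = unique(organelle)),
            class = "md_genome")
}

#' Read a genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @param organelle Chromosome names to flag as organelle (chloroplast-like)
#'   controls for non-conversion estimation.
#' @return An `md_genome` object; record order is preserved.
#' @export
read_genome_fasta <- function(path, organelle = character()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dss <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(dss) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- as.character(dss)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(dss))
  genome_from_strings(seqs, organelle = organelle)
}

#' @export
print.md_genome <- function(x, ...) {
  cat("md_genome:", length(x$seqs), "sequence(s),",
      sum(nchar(x$seqs)), "bp total\n")
  for (nm in names(x$seqs))
    cat(sprintf("  %s  %d bp%s\n", nm, nchar(x$seqs[[nm]]),
                if (nm %in% x$organelle) "  [organelle control]" else ""))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome An `md_genome`.
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(nchar(genome$seqs), names(genome$seqs))
}

#' Nuclear (non-organelle) chromosome names
#' @param genome An `md_genome`.
#' @return Character vector of chromosome names.
#' @export
nuclear_chroms <- function(genome) {
  setdiff(names(genome$seqs), genome$organelle)
}

#' Write a genome to FASTA
#'
#' @param genome An `md_genome` object.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seqs)) {
    writeLines(paste0(">", nm), con)
    s <- genome$seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene and transposon annotation from GFF3
#'
#' Assembles gene models (span + exon structure, introns derived as the
#' within-span complement of the exon union) and transposon annotations from
#' a GFF3 file.  Exons are attached to their parent gene through `Parent`
#' attributes (possibly via an mRNA layer); exons of multiple transcripts are
#' unioned per gene.  Coordinates are 1-based inclusive throughout.
#'
#' @param path Path to a GFF3 file containing `gene`, `exon` (optionally
#'   `mRNA`) and `transposable_element` features.
#' @param genome An `md_genome`; features on unknown chromosomes are
#'   rejected.
#' @return An object of class `md_annotation`: list with data frames
#'   `genes` (gene_id, chrom, strand, start, end), `exons` (gene_id, start,
#'   end), `introns` (gene_id, start, end) and `tes` (te_id, family, chrom,
#'   strand, start, end).
#' @export
read_annotation_gff3 <- function(path, genome) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))

  unknown <- setdiff(unique(chrom), names(genome$seqs))
  if (length(unknown))
    stop("annotation features on unknown chromosomes: ",
         paste(unknown, collapse = ", "))

  is_gene <- typ == "gene"
  if (any(is_gene & (is.na(ids) | !nzchar(ids))))
    stop("gene feature without an ID attribute")
  genes <- data.frame(gene_id = ids[is_gene], chrom = chrom[is_gene],
                      strand = strand[is_gene], start = start[is_gene],
                      end = end[is_gene], stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene IDs in annotation")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene with strand outside {+,-}: ",
         paste(genes$gene_id[!genes$strand %in% c("+", "-")], collapse = ", "))

  # map mRNA IDs to their parent gene so exon Parents can be resolved
  parent_of <- character()
  if ("Parent" %in% names(md)) {
    parents <- md$Parent   # CharacterList
    is_mrna <- typ == "mRNA"
    if (any(is_mrna)) {
      mrna_parent <- vapply(parents[is_mrna], function(p)
        if (length(p)) p[[1]] else NA_character_, character(1))
      parent_of <- stats::setNames(mrna_parent, ids[is_mrna])
    }
    is_exon <- typ == "exon"
    ex_parent <- vapply(parents[is_exon], function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    if (anyNA(ex_parent)) stop("exon feature without a Parent attribute")
    ex_gene <- ifelse(ex_parent %in% names(parent_of),
                      unname(parent_of[ex_parent]), ex_parent)
    exons <- data.frame(gene_id = ex_gene, start = start[is_exon],
                        end = end[is_exon], stringsAsFactors = FALSE)
  } else {
    exons <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  }
  exons <- exons[exons$gene_id %in% genes$gene_id, , drop = FALSE]

  # genes without explicit exons are single-exon over their span
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon)) {
    g <- genes[match(no_exon, genes$gene_id), ]
    exons <- rbind(exons, data.frame(gene_id = g$gene_id, start = g$start,
                                     end = g$end, stringsAsFactors = FALSE))
  }

  # validate exons against parent span, merge overlaps, derive introns
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  span <- genes[match(exons$gene_id, genes$gene_id), c("start", "end")]
  bad <- exons$start < span$start | exons$end > span$end | exons$start > exons$end
  if (any(bad))
    stop("exon outside parent gene span for gene(s): ",
         paste(unique(exons$gene_id[bad]), collapse = ", "))
  exons <- merge_intervals_by_gene(exons)
  introns <- derive_introns(genes, exons)

  is_te <- typ %in% c("transposable_element", "transposon")
  fam <- if ("family" %in% names(md)) as.character(md$family)
         else rep(NA_character_, length(gr))
  tes <- data.frame(te_id = ids[is_te], family = fam[is_te],
                    chrom = chrom[is_te], strand = strand[is_te],
                    start = start[is_te], end = end[is_te],
                    stringsAsFactors = FALSE)
  if (nrow(tes)) {
    if (any(is.na(tes$te_id) | !nzchar(tes$te_id)))
      stop("transposable_element feature without an ID attribute")
    tes$family[is.na(tes$family) | !nzchar(tes$family)] <- tes$te_id[is.na(tes$family) | !nzchar(tes$family)]
    cl <- chrom_lengths(genome)
    if (any(tes$start < 1L | tes$end > cl[tes$chrom]))
      stop("transposable_element span outside chromosome")
  }

  cl <- chrom_lengths(genome)
  if (nrow(genes) && any(genes$start < 1L | genes$end > cl[genes$chrom]))
    stop("gene span outside chromosome")

  structure(list(genes = genes, exons = exons, introns = introns, tes = tes),
            class = "md_annotation")
}

# merge overlapping/adjacent intervals within each gene (union over
# transcripts); input sorted by gene then start
merge_intervals_by_gene <- function(df) {
  if (!nrow(df)) return(df)
  out <- lapply(split(df, df$gene_id), function(d) {
    d <- d[order(d$start), ]
    s <- d$start; e <- d$end
    keep_s <- s[1]; keep_e <- e[1]
    rs <- integer(); re <- integer()
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      if (s[i] <= keep_e + 1L) keep_e <- max(keep_e, e[i])
      else { rs <- c(rs, keep_s); re <- c(re, keep_e); keep_s <- s[i]; keep_e <- e[i] }
    }
    rs <- c(rs, keep_s); re <- c(re, keep_e)
    data.frame(gene_id = d$gene_id[1], start = rs, end = re,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$gene_id, unique(df$gene_id)), res$start), ]
}

derive_introns <- function(genes, exons) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) return(NULL)
    data.frame(gene_id = g$gene_id,
               start = ex$end[-nrow(ex)] + 1L,
               end = ex$start[-1L] - 1L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write annotation to GFF3
#'
#' Inverse of [read_annotation_gff3()]; used by the synthetic-data generator
#' and for round-trip testing.
#'
#' @param ann An `md_annotation` object.
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    writeLines(sprintf("%s\tmethdose\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id), con)
    ex <- ann$exons[ann$exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tmethdose\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                         g$chrom, ex$start[j], ex$end[j], g$strand,
                         g$gene_id, j, g$gene_id), con)
  }
  for (i in seq_len(nrow(ann$tes))) {
    t <- ann$tes[i, ]
    writeLines(sprintf("%s\tmethdose\ttransposable_element\t%d\t%d\t.\t%s\t.\tID=%s;family=%s",
                       t$chrom, t$start, t$end, t$strand, t$te_id, t$family),
               con)
  }
  invisible(path)
}

#' Derive analysis regions for every gene
#'
#' For each gene derives its body (the transcribed span), a strand-aware
#' 2-kb promoter upstream of the TSS and a strand-aware 2-kb downstream
#' region past the TES, both clipped silently at chromosome edges, plus
#' 500-bp bins tiling promoter and downstream from the gene-proximal edge
#' outward (at most four bins per region; edge bins may be shorter).
#'
#' @param ann An `md_annotation`.
#' @param genome An `md_genome`.
#' @param flank_bp Width of promoter/downstream regions (default 2000).
#' @param bin_bp Bin width (default 500).
#' @return A `data.table` with columns gene_id, chrom, strand, region_class
#'   (`body`, `promoter`, `downstream`), bin (0 for the whole region, 1..4
#'   counted from the gene-proximal edge for bins), start, end.
#' @export
derive_gene_regions <- function(ann, genome, flank_bp = 2000L, bin_bp = 500L) {
  cl <- chrom_lengths(genome)
  rows <- lapply(seq_len(nrow(ann$genes)), function(i) {
    g <- ann$genes[i, ]
    L <- cl[[g$chrom]]
    if (g$strand == "+") {
      prom <- c(g$start - flank_bp, g$start - 1L)
      down <- c(g$end + 1L, g$end + flank_bp)
    } else {
      prom <- c(g$end + 1L, g$end + flank_bp)
      down <- c(g$start - flank_bp, g$start - 1L)
    }
    clip <- function(iv) c(max(1L, iv[1]), min(L, iv[2]))
    prom <- clip(prom); down <- clip(down)
    # tile from the gene-proximal edge outward; outward is leftward for the
    # promoter of a + gene and the downstream of a - gene
    tile <- function(iv, outward_left) {
      if (iv[1] > iv[2]) return(NULL)
      n <- ceiling((iv[2] - iv[1] + 1L) / bin_bp)
      if (outward_left) {
        ends <- iv[2] - (seq_len(n) - 1L) * bin_bp
        starts <- pmax(iv[1], ends - bin_bp + 1L)
      } else {
        starts <- iv[1] + (seq_len(n) - 1L) * bin_bp
        ends <- pmin(iv[2], starts + bin_bp - 1L)
      }
      data.frame(bin = seq_len(n), start = as.integer(starts),
                 end = as.integer(ends))
    }
    prom_bins <- tile(prom, outward_left = g$strand == "+")
    down_bins <- tile(down, outward_left = g$strand == "-")
    part <- function(region_class, bin, start, end)
      data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                 region_class = region_class, bin = bin,
                 start = as.integer(start), end = as.integer(end),
                 stringsAsFactors = FALSE)
    out <- list(part("body", 0L, g$start, g$end))
    if (prom[1] <= prom[2]) {
      out <- c(out, list(part("promoter", 0L, prom[1], prom[2]),
                         part("promoter", prom_bins$bin, prom_bins$start,
                              prom_bins$end)))
    }
    if (down[1] <= down[2]) {
      out <- c(out, list(part("downstream", 0L, down[1], down[2]),
                         part("downstream", down_bins$bin, down_bins$start,
                              down_bins$end)))
    }
    do.call(rbind, out)
  })
  data.table::as.data.table(do.call(rbind, rows))
}

#' Find runs of Ns in a genome
#'
#' Maximal runs of at least `min_len` consecutive N bases, per chromosome.
#'
#' @param genome An `md_genome`.
#' @param min_len Minimum run length (default 4, i.e. "NNNN").
#' @return data.frame with columns chrom, start, end (1-based inclusive).
#' @export
find_n_runs <- function(genome, min_len = 4L) {
  stopifnot(min_len >= 1L)
  out <- lapply(names(genome$seqs), function(nm) {
    s <- genome$seqs[[nm]]
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == "N")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(NULL)
    data.frame(chrom = nm, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Build the aberrant-region mask used to filter insertion calls
#'
#' Collects centromere spans, N-run spans and chromosome-end margins into
#' one mask object consumed by [filter_insertion_calls()].
#'
#' @param genome An `md_genome`.
#' @param centromeres data.frame (chrom, start, end) of centromeric spans;
#'   by default N-runs of at least `cent_min_n` bp are treated as
#'   centromere analogues.
#' @param n_min_len Minimum N-run length to mask (default 4).
#' @param end_margin Exclusion margin at chromosome extremities (bp).
#' @param cent_margin Exclusion margin around centromere spans (bp).
#' @param n_margin Exclusion margin around N-runs (bp).
#' @param cent_min_n N-run length above which a run is treated as a
#'   centromere analogue when `centromeres` is NULL.
#' @return An object of class `md_mask`.
#' @export
build_chromosome_mask <- function(genome, centromeres = NULL,
                                  n_min_len = 4L, end_margin = 3000L,
                                  cent_margin = 3000L, n_margin = 500L,
                                  cent_min_n = 1000L) {
  n_runs <- find_n_runs(genome, min_len = n_min_len)
  if (is.null(centromeres)) {
    centromeres <- n_runs[n_runs$end - n_runs$start + 1L >= cent_min_n, ,
                          drop = FALSE]
  }
  structure(list(centromeres = centromeres, n_runs = n_runs,
                 end_margin = as.integer(end_margin),
                 cent_margin = as.integer(cent_margin),
                 n_margin = as.integer(n_margin),
                 chrom_lengths = chrom_lengths(genome)),
            class = "md_mask")
}

#' Write intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention at the boundary.
#'
#' @param df data.frame with columns chrom, start, end (1-based inclusive)
#'   and optionally name, score.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  if (!is.null(df$name)) bed$name <- df$name
  if (!is.null(df$score)) bed$score <- df$score
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
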