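#' Assign a sequence context to every genomic cytosine
#'
#' Scans both strands of every chromosome and assigns each cytosine to CG,
#' CHG or CHH (H = A, C or T).  A plus-strand C at position i is CG when
#' base i+1 is G, CHG when base i+1 is H and base i+2 is G, and CHH when
#' both following bases are H; the minus strand mirrors this on the
#' complement.  Cytosines whose context cannot be determined (adjacent N or
#' chromosome end) are excluded.
#'
#' @param genome An `md_genome`.
#' @return `data.table` with columns chrom, pos (1-based), strand, context;
#'   one row per unambiguous genomic cytosine.
#' @export
annotate_contexts <- function(genome) {
  out <- lapply(names(genome$seqs), function(nm) {
    b <- strsplit(genome$seqs[[nm]], "", fixed = TRUE)[[1]]
    L <- length(b)
    pad <- c(b, "N", "N")          # lookahead beyond chromosome end
    lpad <- c("N", "N", b)         # lookbehind
    ctx_plus <- function(i) {
      b1 <- pad[i + 1L]; b2 <- pad[i + 2L]
      ifelse(b1 == "G", "CG",
      ifelse(b1 %in% c("A", "C", "T") & b2 == "G", "CHG",
      ifelse(b1 %in% c("A", "C", "T") & b2 %in% c("A", "C", "T"), "CHH",
             NA_character_)))
    }
    # minus-strand C sits at a plus-strand G; its downstream bases are the
    # complements of plus positions i-1, i-2
    ctx_minus <- function(i) {
      b1 <- lpad[i + 1L]; b2 <- lpad[i]   # lpad[i+1] == b[i-1], lpad[i] == b[i-2]
      ifelse(b1 == "C", "CG",
      ifelse(b1 %in% c("A", "G", "T") & b2 == "C", "CHG",
      ifelse(b1 %in% c("A", "G", "T") & b2 %in% c("A", "G", "T"), "CHH",
             NA_character_)))
    }
    ip <- which(b == "C")
    im <- which(b == "G")
    cp <- if (length(ip)) ctx_plus(ip) else character()
    cm <- if (length(im)) ctx_minus(im) else character()
    keep_p <- !is.na(cp); keep_m <- !is.na(cm)
    data.table::data.table(
      chrom = nm,
      pos = c(ip[keep_p], im[keep_m]),
      strand = c(rep("+", sum(keep_p)), rep("-", sum(keep_m))),
      context = c(cp[keep_p], cm[keep_m]))
  })
  res <- data.table::rbindlist(out)
  data.table::setkeyv(res, c("chrom", "pos", "strand"))
  res[]
}

new_methylome <- function(dt, sample = NA_character_, genotype = NA_character_) {
  data.table::setDT(dt)
  dup <- duplicated(dt, by = c("chrom", "pos", "strand"))
  if (any(dup)) stop("duplicate cytosine records at ", sum(dup), " position(s)")
  data.table::setkeyv(dt, c("chrom", "pos", "strand"))
  data.table::setattr(dt, "sample", sample)
  data.table::setattr(dt, "genotype", genotype)
  data.table::setattr(dt, "class", c("md_methylome", class(dt)))
  dt
}

#' Read a per-cytosine methylation-ratio table
#'
#' Parses the tab-separated per-cytosine output dialect of bisulfite
#' methylation extraction: columns `chrom, pos, strand, context, ratio,
#' eff_CT, C` with a header line.  Records whose stated context disagrees
#' with the genome-derived context map are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @param context_map Optional `data.table` from [annotate_contexts()];
#'   when supplied, records are validated against it.
#' @param sample,genotype Labels attached to the table.
#' @return A methylome table (`md_methylome`, a keyed `data.table` with
#'   columns chrom, pos, strand, context, c_count, ct_count).
#' @export
read_methratio <- function(path, context_map = NULL,
                           sample = basename(path), genotype = NA_character_) {
  if (!file.exists(path)) stop("methylation table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c(1, 3, 4)))
  data.table::setnames(dt, c("chrom", "pos", "strand", "context",
                             "ratio", "ct_count", "c_count")[seq_len(ncol(dt))])
  if (nrow(dt)) {
    if (!is.numeric(dt$pos) || !is.numeric(dt$ct_count) || !is.numeric(dt$c_count)) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt$c_count))) |
                   is.na(suppressWarnings(as.numeric(dt$ct_count))))[1]
      stop("non-numeric count field at line ", bad + 1L, " of ", path)
    }
    over <- which(dt$c_count > dt$ct_count)
    if (length(over))
      stop("methylated-call count exceeds coverage at line ", over[1] + 1L,
           " of ", path)
    neg <- which(dt$c_count < 0 | dt$ct_count < 0)
    if (length(neg)) stop("negative count at line ", neg[1] + 1L, " of ", path)
  }
  dt <- dt[, c("chrom", "pos", "strand", "context", "c_count", "ct_count"),
           with = FALSE]
  dt[, `:=`(pos = as.integer(pos), c_count = as.integer(c_count),
            ct_count = as.integer(ct_count))]
  if (!is.null(context_map) && nrow(dt)) {
    m <- context_map[dt, on = c("chrom", "pos", "strand")]
    mismatch <- is.na(m$context) | m$context != dt$context
    if (any(mismatch)) {
      warning(sum(mismatch), " record(s) with context inconsistent with ",
              "the genome were dropped")
      dt <- dt[!mismatch]
    }
  }
  new_methylome(dt, sample = sample, genotype = genotype)
}

#' Write a methylome table in the methylation-ratio TSV dialect
#'
#' @param table An `md_methylome`.
#' @param path Output path.
#' @export
write_methratio <- function(table, path) {
  out <- data.table::data.table(
    chrom = table$chrom, pos = table$pos, strand = table$strand,
    context = table$context,
    ratio = round(ifelse(table$ct_count > 0,
                         table$c_count / table$ct_count, 0), 4),
    eff_CT = table$ct_count, C = table$c_count)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Coverage-filter a methylome table
#'
#' Retains cytosine positions with at least `min_cov` bisulfite-informative
#' calls (the effective C+T count).  Idempotent; monotone in `min_cov`.
#'
#' @param table An `md_methylome`.
#' @param min_cov Minimum effective coverage (default 4).
#' @return The filtered methylome table.
#' @export
filter_coverage <- function(table, min_cov = 4L) {
  stopifnot(min_cov >= 1L)
  keep <- table$ct_count >= min_cov
  new_methylome(table[which(keep), ],
                sample = attr(table, "sample"),
                genotype = attr(table, "genotype"))
}

context_match <- function(ctx_col, context) {
  if (context == "C") rep(TRUE, length(ctx_col)) else ctx_col == context
}

#' Weighted methylation level over a region
#'
#' The coverage-weighted level: total methylated calls divided by total
#' informative calls over all matching cytosines — not a mean of per-site
#' ratios.  `NA` (undefined) when the region holds no informative calls.
#'
#' @param table An `md_methylome`.
#' @param chrom,start,end Region (1-based inclusive); all three NULL means
#'   the whole table.  `chrom` alone restricts to whole chromosomes (may be
#'   a vector).
#' @param context One of "CG", "CHG", "CHH" or "C" (pooled).
#' @return A single level in \[0,1\], or `NA_real_` when coverage is zero.
#' @export
weighted_level <- function(table, chrom = NULL, start = NULL, end = NULL,
                           context = "C") {
  stopifnot(context %in% c("CG", "CHG", "CHH", "C"))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(chrom)) keep <- keep & table$chrom %in% chrom
  if (!is.null(start)) keep <- keep & table$pos >= start & table$pos <= end
  keep <- keep & context_match(table$context, context)
  n <- sum(table$ct_count[keep])
  if (n == 0L) return(NA_real_)
  sum(table$c_count[keep]) / n
}

#' Windowed methylation profile
#'
#' Tiles every chromosome with sliding windows and reports the weighted
#' level per window; windows without informative calls are `NA`, never 0.
#'
#' @param table An `md_methylome`.
#' @param genome An `md_genome` (provides chromosome lengths).
#' @param window_bp Window width.
#' @param step_bp Step between window starts (default `window_bp`, i.e.
#'   non-overlapping tiling).
#' @param context "CG", "CHG", "CHH" or "C".
#' @param chroms Chromosomes to profile (default: nuclear chromosomes).
#' @return `data.table` with chrom, start, end, level.
#' @export
window_profile <- function(table, genome, window_bp, step_bp = window_bp,
                           context = "C", chroms = nuclear_chroms(genome)) {
  stopifnot(window_bp >= step_bp, step_bp >= 1L)
  cl <- chrom_lengths(genome)
  out <- lapply(chroms, function(nm) {
    L <- cl[[nm]]
    starts <- seq(1L, max(1L, L), by = step_bp)
    ends <- pmin(starts + window_bp - 1L, L)
    keep <- table$chrom == nm & context_match(table$context, context)
    dt <- table[which(keep), ]
    k <- n <- numeric(length(starts))
    if (nrow(dt)) {
      # assign each record to every window covering it
      for (w in seq_along(starts)) {
        sel <- dt$pos >= starts[w] & dt$pos <= ends[w]
        k[w] <- sum(dt$c_count[sel]); n[w] <- sum(dt$ct_count[sel])
      }
    }
    data.table::data.table(chrom = nm, start = starts, end = ends,
                           level = ifelse(n > 0, k / n, NA_real_))
  })
  data.table::rbindlist(out)
}

#' Write a profile as bedGraph
#'
#' Undefined windows are omitted; levels are rounded to 4 decimals and
#' coordinates converted to bedGraph's 0-based half-open convention.
#'
#' @param profile Output of [window_profile()].
#' @param path Output path.
#' @param name Track name.
#' @export
write_bedgraph <- function(profile, path, name = "methylation") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  p <- profile[!is.na(profile$level)]
  writeLines(sprintf("%s\t%d\t%d\t%.4f", p$chrom, p$start - 1L, p$end,
                     round(p$level, 4)), con)
  invisible(path)
}

#' Estimate the bisulfite non-conversion rate
#'
#' The pooled all-context weighted level over the organelle-flagged control
#' chromosomes, which are biologically unmethylated; any apparent
#' methylation there reflects failed bisulfite conversion.  The nuclear
#' level of a methylation-free genotype can then be compared against this
#' floor.
#'
#' @param table An `md_methylome`.
#' @param genome An `md_genome` with at least one organelle-flagged
#'   chromosome carrying records.
#' @return The estimated non-conversion rate.
#' @export
estimate_nonconversion <- function(table, genome) {
  if (!length(genome$organelle))
    stop("genome has no organelle-flagged control chromosome")
  lv <- weighted_level(table, chrom = genome$organelle, context = "C")
  if (is.na(lv))
    stop("no informative calls on organelle control chromosome(s)")
  lv
}
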