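revcomp <- function(s) {
  vapply(s, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1), USE.NAMES = FALSE)
}

#' Build the transposon-extremity database
#'
#' Extracts the strand-normalized 5' and 3' terminal sequences (default
#' 300 bp) of every annotated transposon, the reference against which
#' split reads are matched.  Families without intact extremities in the
#' reference are excluded.  Transposons shorter than twice the extremity
#' length contribute truncated, non-overlapping halves.
#'
#' @param ann An `md_annotation` with transposon features.
#' @param genome An `md_genome`.
#' @param ext_len Extremity length in bp (default 300).
#' @param excluded_families Families dropped from the database.
#' @return An object of class `md_te_db`: a list keyed by te_id with
#'   elements te_id, family, chrom, strand, start, end, ext5, ext3
#'   (extremities in transposon orientation).
#' @export
build_extremity_db <- function(ann, genome, ext_len = 300L,
                               excluded_families = c("ARNOLDY2", "ATCOPIA62",
                                                     "ATCOPIA95", "TA12",
                                                     "TAG1")) {
  tes <- ann$tes[!(ann$tes$family %in% excluded_families), , drop = FALSE]
  cl <- chrom_lengths(genome)
  db <- lapply(seq_len(nrow(tes)), function(i) {
    t <- tes[i, ]
    if (t$start < 1L || t$end > cl[[t$chrom]])
      stop("TE span outside chromosome: ", t$te_id)
    L <- t$end - t$start + 1L
    e <- min(ext_len, L %/% 2L)
    s <- substring(genome$seqs[[t$chrom]], t$start, t$end)
    if (t$strand == "-") s <- revcomp(s)
    list(te_id = t$te_id, family = t$family, chrom = t$chrom,
         strand = t$strand, start = t$start, end = t$end,
         ext5 = substring(s, 1L, e),
         ext3 = substring(s, nchar(s) - e + 1L, nchar(s)))
  })
  names(db) <- tes$te_id
  structure(db, class = "md_te_db")
}

#' Exact-match genome index
#'
#' The alignment backend used by the insertion caller on synthetic-scale
#' genomes: exact substring search with a uniqueness check over both
#' strands.  Real-data use plugs an external aligner in upstream (SAM in).
#'
#' @param genome An `md_genome`.
#' @return An object of class `md_genome_index`.
#' @export
genome_index <- function(genome) {
  structure(list(dss = Biostrings::DNAStringSet(genome$seqs)),
            class = "md_genome_index")
}

# all exact occurrences of `pattern` in the indexed genome, both strands
locate_exact <- function(index, pattern) {
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pattern else revcomp(pattern)
    m <- Biostrings::vmatchPattern(pat, index$dss)
    for (i in seq_along(m)) {
      ir <- m[[i]]
      if (length(ir))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = names(index$dss)[i], start = IRanges::start(ir),
          end = IRanges::end(ir), strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  do.call(rbind, hits)
}

#' Read paired-end alignment records from SAM
#'
#' @param path Path to a SAM file with sequences retained on unmapped
#'   records.
#' @return data.frame of alignment records (qname, flag, mapped, proper,
#'   first, chrom, pos, strand, cigar, seq, mate_mapped, isize).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq",
             "mrnm", "mpos", "isize")))[[1]]
  flag <- res$flag
  data.frame(qname = res$qname, flag = flag,
             mapped = bitwAnd(flag, 4L) == 0L,
             proper = bitwAnd(flag, 2L) != 0L,
             first = bitwAnd(flag, 64L) != 0L,
             chrom = as.character(res$rname),
             pos = res$pos,
             strand = as.character(res$strand),
             cigar = res$cigar,
             seq = as.character(res$seq),
             mate_mapped = bitwAnd(flag, 8L) == 0L,
             mate_chrom = as.character(res$mrnm),
             mate_pos = res$mpos,
             isize = res$isize,
             stringsAsFactors = FALSE)
}

#' Select read pairs eligible for split-read analysis
#'
#' Keeps pairs where at least one mate is unmapped or the pair is
#' discordant: not flagged as a proper pair, insert size at or above
#' `max_insert`, or both mates on the same strand.  Unpaired read names
#' are skipped with a message.
#'
#' @param records data.frame from [read_sam()].
#' @param max_insert Insert size from which a pair counts as discordant
#'   (default 3000).
#' @return data.frame of records belonging to selected pairs.
#' @export
select_candidate_reads <- function(records, max_insert = 3000L) {
  cnt <- table(records$qname)
  unpaired <- names(cnt)[cnt != 2L]
  if (length(unpaired))
    message("skipping ", length(unpaired), " read name(s) without exactly 2 records")
  rec <- records[!(records$qname %in% unpaired), , drop = FALSE]
  if (!nrow(rec)) return(rec)
  rec <- rec[order(rec$qname, !rec$first), ]
  i1 <- seq(1L, nrow(rec), by = 2L); i2 <- i1 + 1L
  any_unmapped <- !rec$mapped[i1] | !rec$mapped[i2]
  both_mapped <- !any_unmapped
  not_proper <- !rec$proper[i1]
  big_insert <- both_mapped & !is.na(rec$isize[i1]) &
    abs(rec$isize[i1]) >= max_insert
  same_strand <- both_mapped & rec$strand[i1] == rec$strand[i2]
  keep <- any_unmapped | (both_mapped & (not_proper | big_insert | same_strand))
  rec[rep(keep, each = 2L), , drop = FALSE]
}

# longest end-anchored exact match of one read end against one extremity;
# returns 0 when none reaches min_match
longest_suffix_prefix <- function(read, ext, min_match) {
  cap <- min(nchar(read), nchar(ext))
  if (cap < min_match) return(0L)
  Ls <- cap:min_match
  n <- nchar(read)
  hit <- substring(read, n - Ls + 1L, n) == substring(ext, 1L, Ls)
  if (any(hit)) Ls[which(hit)[1]] else 0L
}

longest_prefix_suffix <- function(read, ext, min_match) {
  cap <- min(nchar(read), nchar(ext))
  if (cap < min_match) return(0L)
  Ls <- cap:min_match
  e <- nchar(ext)
  hit <- substring(read, 1L, Ls) == substring(ext, e - Ls + 1L, e)
  if (any(hit)) Ls[which(hit)[1]] else 0L
}

#' Match one read end against the transposon extremities
#'
#' Searches both read orientations for the longest end-anchored exact
#' match of at least `min_match` nt: a read suffix matching the start of a
#' 5' extremity, or a read prefix matching the end of a 3' extremity.
#' The best (longest) match wins; equal-length matches to different
#' transposons are resolved to the lexicographically first te_id and
#' flagged ambiguous.
#'
#' @param read_seq Read sequence.
#' @param db An `md_te_db`.
#' @param min_match Minimum matched length (default 20).
#' @return NULL when no match, else list(te_id, te_end ("5p"/"3p"),
#'   match_len, orient ("+" read as-is, "-" reverse-complemented),
#'   oriented_seq, te_at ("left"/"right" end of the oriented read),
#'   genomic_seq, ambiguous).
#' @export
clip_map_te <- function(read_seq, db, min_match = 20L) {
  best <- NULL; best_len <- 0L; ambiguous <- FALSE
  for (orient in c("+", "-")) {
    r <- if (orient == "+") read_seq else revcomp(read_seq)
    for (te in db) {
      for (end in c("5p", "3p")) {
        len <- if (end == "5p") longest_suffix_prefix(r, te$ext5, min_match)
               else longest_prefix_suffix(r, te$ext3, min_match)
        if (len == 0L) next
        if (len > best_len) {
          best_len <- len
          ambiguous <- FALSE
          best <- list(te_id = te$te_id, te_end = end, match_len = len,
                       orient = orient, oriented_seq = r,
                       te_at = if (end == "5p") "right" else "left")
        } else if (len == best_len && !is.null(best) &&
                   te$te_id != best$te_id) {
          ambiguous <- TRUE
          if (te$te_id < best$te_id)
            best <- list(te_id = te$te_id, te_end = end, match_len = len,
                         orient = orient, oriented_seq = r,
                         te_at = if (end == "5p") "right" else "left")
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  n <- nchar(best$oriented_seq)
  best$genomic_seq <- if (best$te_at == "right")
    substring(best$oriented_seq, 1L, n - best$match_len)
  else substring(best$oriented_seq, best$match_len + 1L, n)
  best$ambiguous <- ambiguous
  best
}

#' Recursively clip and map the genomic portion of a split read
#'
#' The non-transposon portion of a clipped read is mapped to the reference
#' by exact unique search; when the junction-adjacent bases prevent a
#' match (e.g. target-site microvariation), one base is trimmed from the
#' junction side and the search repeated until the remaining segment would
#' fall below `min_len`.  The breakpoint is the reference coordinate of
#' the base adjacent to the clip, corrected for the trimmed bases.
#' Segments matching more than one location are discarded.
#'
#' @param genomic_seq Non-transposon portion of the oriented read.
#' @param te_at Which end of the oriented read held the transposon match
#'   ("left" or "right"); determines the trimming side.
#' @param index An `md_genome_index`.
#' @param min_len Minimum mappable segment (default 20).
#' @return NULL when unmappable, else list(chrom, strand, start, end,
#'   trim, breakpoint).
#' @export
recursive_genome_clip <- function(genomic_seq, te_at, index, min_len = 20L) {
  n <- nchar(genomic_seq)
  d <- 0L
  while (n - d >= min_len) {
    seg <- if (te_at == "right") substring(genomic_seq, 1L, n - d)
           else substring(genomic_seq, 1L + d, n)
    hits <- locate_exact(index, seg)
    if (nrow(hits) == 1L) {
      h <- hits[1, ]
      breakpoint <- if (te_at == "right") {
        if (h$strand == "+") h$end + d else h$start - d
      } else {
        if (h$strand == "+") h$start - d else h$end + d
      }
      return(list(chrom = h$chrom, strand = h$strand, start = h$start,
                  end = h$end, trim = d, breakpoint = as.integer(breakpoint)))
    }
    if (nrow(hits) > 1L) return(NULL)   # multi-mapping
    d <- d + 1L
  }
  NULL
}

#' Validate the mate of a clipped candidate read
#'
#' A clipped candidate is kept only when its mate supports the insertion
#' by one of three criteria, tried in order: (a) the mate is properly
#' mapped on the reference within `max_insert` bp of the breakpoint and on
#' the strand opposite the candidate read; (b) the mate lies within the
#' same transposon's extremity sequence; (c) the mate is itself
#' clip-mapped to the same transposon with its genomic portion on the
#' opposite strand.
#'
#' @param cand Candidate description as produced inside
#'   [call_te_insertions()]: needs native_strand, g_strand, chrom,
#'   breakpoint, te_id.
#' @param mate_rec The mate's alignment record (one row of [read_sam()]).
#' @param db An `md_te_db`.
#' @param index An `md_genome_index`.
#' @param max_insert Maximum insert size for criterion (a).
#' @param min_match Minimum clip length for criterion (c).
#' @return One of "proper_pair", "same_te", "clip_opposite", or NULL
#'   (reject).
#' @export
validate_mate <- function(cand, mate_rec, db, index, max_insert = 3000L,
                          min_match = 20L) {
  if (is.null(mate_rec) || nrow(mate_rec) != 1L) return(NULL)
  # (a) proper mate on the reference, opposite strand, close by
  if (mate_rec$mapped && !is.na(mate_rec$strand) &&
      mate_rec$strand != cand$native_strand &&
      identical(mate_rec$chrom, cand$chrom) &&
      abs(mate_rec$pos - cand$breakpoint) < max_insert)
    return("proper_pair")
  # (b) mate within the same TE's extremities
  te <- db[[cand$te_id]]
  if (!is.null(te) && !is.na(mate_rec$seq) && nzchar(mate_rec$seq)) {
    for (s in c(mate_rec$seq, revcomp(mate_rec$seq)))
      if (grepl(s, te$ext5, fixed = TRUE) || grepl(s, te$ext3, fixed = TRUE))
        return("same_te")
    # (c) mate itself clip-maps to the same TE, opposite genomic strand
    m <- clip_map_te(mate_rec$seq, db, min_match = min_match)
    if (!is.null(m) && m$te_id == cand$te_id && nchar(m$genomic_seq) >= min_match) {
      gm <- recursive_genome_clip(m$genomic_seq, m$te_at, index,
                                  min_len = min_match)
      # mates of one fragment are sequenced from opposite strands, so the
      # orientation-corrected (native) strands must differ
      if (!is.null(gm)) {
        mate_native <- if (m$orient == "+") gm$strand
                       else c(`+` = "-", `-` = "+")[[gm$strand]]
        if (mate_native != cand$native_strand) return("clip_opposite")
      }
    }
  }
  NULL
}

modal_value <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])   # ties: smallest value
}

#' Cluster validated split reads and call insertions with TSDs
#'
#' Breakpoints from the same transposon extremity within `merge_window` bp
#' are merged into clusters; clusters of at least `min_reads` reads on the
#' left-junction side are paired with right-junction clusters of the same
#' transposon.  The interval between the right-junction consensus
#' breakpoint (start of the duplicated target site) and the left-junction
#' consensus breakpoint (its end) is the candidate target-site
#' duplication; a call is emitted only when its length lies in
#' \[`tsd_min`, `tsd_max`\] bp and the two sides used opposite transposon
#' ends.
#'
#' @param candidates data.frame of validated candidates with columns
#'   read_id, chrom, te_id, te_end, side ("left"/"right"), breakpoint,
#'   ambiguous.
#' @param merge_window Cluster merge window in bp (default 100).
#' @param min_reads Minimum reads per cluster (default 4).
#' @param tsd_min,tsd_max TSD length bounds (default 4 and 19, i.e. more
#'   than 3 bp and less than 20 bp).
#' @param include_ambiguous Keep reads with ambiguous TE assignment
#'   (default FALSE).
#' @return data.frame of calls: chrom, te_id, tsd_start, tsd_end, tsd_len,
#'   n_reads_5prime, n_reads_3prime, filter_status.
#' @export
cluster_and_call <- function(candidates, merge_window = 100L, min_reads = 4L,
                             tsd_min = 4L, tsd_max = 19L,
                             include_ambiguous = FALSE) {
  empty <- data.frame(chrom = character(), te_id = character(),
                      tsd_start = integer(), tsd_end = integer(),
                      tsd_len = integer(), n_reads_5prime = integer(),
                      n_reads_3prime = integer(),
                      filter_status = character(), stringsAsFactors = FALSE)
  cand <- candidates
  if (!include_ambiguous && nrow(cand)) cand <- cand[!cand$ambiguous, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(cand$chrom, cand$te_id, cand$side, cand$breakpoint,
                     cand$read_id), ]

  cluster_side <- function(d) {
    d <- d[order(d$breakpoint), ]
    grp <- cumsum(c(1L, diff(d$breakpoint) > merge_window))
    lapply(split(d, grp), function(cl)
      list(n = nrow(cl), consensus = modal_value(cl$breakpoint),
           te_end = names(which.max(table(cl$te_end)))))
  }

  calls <- list()
  for (key in unique(paste(cand$chrom, cand$te_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- cand[cand$chrom == parts[1] & cand$te_id == parts[2], , drop = FALSE]
    left <- d[d$side == "left", , drop = FALSE]
    right <- d[d$side == "right", , drop = FALSE]
    if (!nrow(left) || !nrow(right)) next
    cl_l <- Filter(function(x) x$n >= min_reads, cluster_side(left))
    cl_r <- Filter(function(x) x$n >= min_reads, cluster_side(right))
    for (L in cl_l) for (R in cl_r) {
      if (L$te_end == R$te_end) next
      a <- R$consensus; b <- L$consensus
      tsd_len <- b - a + 1L
      if (tsd_len < tsd_min || tsd_len > tsd_max) next
      n5 <- if (L$te_end == "5p") L$n else R$n
      n3 <- if (L$te_end == "5p") R$n else L$n
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = parts[1], te_id = parts[2], tsd_start = a, tsd_end = b,
        tsd_len = tsd_len, n_reads_5prime = n5, n_reads_3prime = n3,
        filter_status = "PASS", stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  res <- do.call(rbind, calls)
  res[order(res$chrom, res$tsd_start), , drop = FALSE]
}

interval_distance <- function(s1, e1, s2, e2) {
  ifelse(e1 < s2, s2 - e1, ifelse(e2 < s1, s1 - e2, 0L))
}

#' Filter insertion calls against aberrant regions and donor loci
#'
#' Marks calls within `cent_margin` of a centromeric span, within
#' `end_margin` of a chromosome extremity, within `n_margin` of an N-run,
#' or whose TSD interval intersects the donor transposon's own annotated
#' span.
#'
#' @param calls Output of [cluster_and_call()].
#' @param mask An `md_mask` from [build_chromosome_mask()].
#' @param ann An `md_annotation` (donor transposon spans).
#' @return `calls` with updated filter_status; only rows with status
#'   "PASS" constitute the final call set.
#' @export
filter_insertion_calls <- function(calls, mask, ann) {
  if (!nrow(calls)) return(calls)
  status <- calls$filter_status
  for (i in seq_len(nrow(calls))) {
    ch <- calls$chrom[i]; a <- calls$tsd_start[i]; b <- calls$tsd_end[i]
    L <- mask$chrom_lengths[[ch]]
    if (min(a - 1L, L - b) < mask$end_margin) { status[i] <- "chrom_end"; next }
    cen <- mask$centromeres[mask$centromeres$chrom == ch, , drop = FALSE]
    if (nrow(cen) && any(interval_distance(a, b, cen$start, cen$end) <=
                         mask$cent_margin)) { status[i] <- "centromere"; next }
    nr <- mask$n_runs[mask$n_runs$chrom == ch, , drop = FALSE]
    if (nrow(nr) && any(interval_distance(a, b, nr$start, nr$end) <=
                        mask$n_margin)) { status[i] <- "n_run"; next }
    donor <- ann$tes[ann$tes$te_id == calls$te_id[i], , drop = FALSE]
    if (nrow(donor) && donor$chrom == ch &&
        interval_distance(a, b, donor$start, donor$end) == 0L) {
      status[i] <- "donor_span"; next
    }
  }
  calls$filter_status <- status
  calls
}

#' Detect non-reference transposon insertions from paired-end alignments
#'
#' End-to-end split-read pipeline: candidate pairs are selected from the
#' alignment records, read ends are matched against the transposon
#' extremity database, the genomic portion is recursively clipped and
#' mapped, mates are validated, breakpoint clusters from the two junction
#' sides are paired into TSD calls, and calls in aberrant regions or
#' spanning the donor locus are filtered.
#'
#' @param sam Path to a SAM file or a data.frame from [read_sam()].
#' @param genome An `md_genome`.
#' @param ann An `md_annotation`.
#' @param min_clip Minimum matched length on either side of the junction
#'   (default 20).
#' @param min_reads Minimum reads per cluster (default 4).
#' @param tsd_min,tsd_max TSD length bounds (defaults 4, 19).
#' @param ext_len Extremity length (default 300).
#' @param merge_window Cluster merge window (default 100).
#' @param excluded_families Families excluded from the extremity database.
#' @param mask Optional precomputed `md_mask`.
#' @return list with `calls` (filtered, PASS only), `all_calls` (with
#'   filter_status) and `candidates` (per-read evidence).
#' @export
call_te_insertions <- function(sam, genome, ann, min_clip = 20L,
                               min_reads = 4L, tsd_min = 4L, tsd_max = 19L,
                               ext_len = 300L, merge_window = 100L,
                               excluded_families = character(),
                               mask = NULL) {
  records <- if (is.character(sam)) read_sam(sam) else sam
  db <- build_extremity_db(ann, genome, ext_len = ext_len,
                           excluded_families = excluded_families)
  index <- genome_index(genome)
  sel <- select_candidate_reads(records)
  cand_rows <- list()
  if (nrow(sel)) {
    sel <- sel[order(sel$qname, !sel$first), ]
    for (q in unique(sel$qname)) {
      pair <- sel[sel$qname == q, , drop = FALSE]
      for (j in 1:2) {
        rec <- pair[j, ]; mate <- pair[3 - j, ]
        if (is.na(rec$seq) || !nzchar(rec$seq)) next
        if (nchar(rec$seq) < 2L * min_clip) next
        m <- clip_map_te(rec$seq, db, min_match = min_clip)
        if (is.null(m)) next
        if (nchar(m$genomic_seq) < min_clip) next
        g <- recursive_genome_clip(m$genomic_seq, m$te_at, index,
                                   min_len = min_clip)
        if (is.null(g)) next
        native_strand <- if (m$orient == "+") g$strand
                         else c(`+` = "-", `-` = "+")[[g$strand]]
        side <- if ((m$te_end == "5p") == (g$strand == "+")) "left" else "right"
        cand <- list(read_id = paste0(q, "/", j), chrom = g$chrom,
                     te_id = m$te_id, te_end = m$te_end, side = side,
                     breakpoint = g$breakpoint, g_strand = g$strand,
                     native_strand = native_strand, ambiguous = m$ambiguous)
        support <- validate_mate(cand, mate, db, index,
                                 min_match = min_clip)
        if (is.null(support)) next
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          read_id = cand$read_id, chrom = cand$chrom, te_id = cand$te_id,
          te_end = cand$te_end, side = cand$side,
          breakpoint = cand$breakpoint, ambiguous = cand$ambiguous,
          mate_support = support, stringsAsFactors = FALSE)
      }
    }
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows)
    else data.frame(read_id = character(), chrom = character(),
                    te_id = character(), te_end = character(),
                    side = character(), breakpoint = integer(),
                    ambiguous = logical(), mate_support = character(),
                    stringsAsFactors = FALSE)
  calls <- cluster_and_call(candidates, merge_window = merge_window,
                            min_reads = min_reads, tsd_min = tsd_min,
                            tsd_max = tsd_max)
  if (is.null(mask)) mask <- build_chromosome_mask(genome)
  all_calls <- filter_insertion_calls(calls, mask, ann)
  list(calls = all_calls[all_calls$filter_status == "PASS", , drop = FALSE],
       all_calls = all_calls, candidates = candidates)
}
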