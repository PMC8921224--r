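# shared toy genome with transposons for caller tests
ins_sim <- local({
  cfg <- sim_config(seed = 61, n_genes = 25, n_tes = 6, margin_bp = 12000)
  simulate_genome(cfg)
})

test_that("extremity database extracts strand-normalized ends and truncates", {
  g <- genome_from_strings(c(c1 = random_genome_string(5000, 62)))
  tes <- data.frame(te_id = c("t1", "t2", "t3"),
                    family = c("COPIA", "GYPSY", "TAG1"),
                    chrom = "c1", strand = c("+", "-", "+"),
                    start = c(101L, 2001L, 4001L),
                    end = c(1100L, 2400L, 4900L), stringsAsFactors = FALSE)
  ann <- make_annotation(data.frame(gene_id = character(), chrom = character(),
                                    strand = character(), start = integer(),
                                    end = integer(), stringsAsFactors = FALSE),
                         exons = data.frame(gene_id = character(),
                                            start = integer(), end = integer()),
                         tes = tes)
  db <- build_extremity_db(ann, g, ext_len = 300)
  expect_identical(names(db), c("t1", "t2"))      # TAG1 family excluded
  expect_equal(nchar(db$t1$ext5), 300L)
  expect_equal(db$t1$ext5, substring(g$seqs[["c1"]], 101, 400))
  expect_equal(db$t1$ext3, substring(g$seqs[["c1"]], 801, 1100))
  # minus-strand TE: 5' extremity is the reverse complement of the last bases
  rc <- methdose:::revcomp(substring(g$seqs[["c1"]], 2001, 2400))
  expect_equal(db$t2$ext5, substring(rc, 1, 200))  # 400-bp TE -> 200-bp halves
  expect_equal(nchar(db$t2$ext3), 200L)
})

test_that("candidate pair selection keeps unmapped and discordant pairs only", {
  rec <- data.frame(
    qname = rep(c("p_proper", "p_unmap", "p_same", "p_far"), each = 2),
    flag = 0L,
    mapped = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    proper = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    first = rep(c(TRUE, FALSE), 4),
    chrom = "c1", pos = 1L,
    strand = c("+", "-", "+", NA, "+", "+", "+", "-"),
    cigar = "100M", seq = "ACGT", mate_mapped = TRUE, mate_chrom = "c1",
    mate_pos = 1L,
    isize = c(250L, -250L, 0L, 0L, 300L, -300L, 5000L, -5000L),
    stringsAsFactors = FALSE)
  sel <- select_candidate_reads(rec)
  expect_setequal(unique(sel$qname), c("p_unmap", "p_same", "p_far"))
  # unpaired names are skipped with a message
  expect_message(select_candidate_reads(rec[-1, ]), "without exactly 2")
})

test_that("read ends are matched to extremities with floor and tie rules", {
  db <- build_extremity_db(ins_sim$ann, ins_sim$genome)
  te <- db[[1]]
  genome_bit <- random_genome_string(70, 63)
  read <- paste0(genome_bit, substring(te$ext5, 1, 30))
  m <- clip_map_te(read, db)
  expect_equal(m$te_id, te$te_id)
  expect_equal(m$te_end, "5p")
  expect_equal(m$match_len, 30L)
  expect_equal(m$genomic_seq, genome_bit)
  # reverse-complemented read is recognised through orientation search
  m2 <- clip_map_te(methdose:::revcomp(read), db)
  expect_equal(m2$te_id, te$te_id)
  expect_equal(m2$match_len, 30L)
  # 19-nt anchor is below the floor
  short <- paste0(random_genome_string(81, 64), substring(te$ext5, 1, 19))
  expect_null(clip_map_te(short, db))
  # a 3' junction read anchors the other extremity
  read3 <- paste0(substring(te$ext3, nchar(te$ext3) - 24, nchar(te$ext3)),
                  random_genome_string(75, 65))
  m3 <- clip_map_te(read3, db)
  expect_equal(m3$te_end, "3p")
  expect_equal(m3$match_len, 25L)
  # equal-length matches to two TEs tie-break lexicographically, flagged
  db2 <- db
  db2[[2]]$ext5 <- db[[1]]$ext5
  mt <- clip_map_te(read, db2)
  expect_true(mt$ambiguous)
  expect_equal(mt$te_id, min(db2[[1]]$te_id, db2[[2]]$te_id))
})

test_that("recursive clipping maps clean and junction-mutated tails", {
  idx <- genome_index(ins_sim$genome)
  ref <- ins_sim$genome$seqs[["chr1"]]
  tail70 <- substring(ref, 30001, 30070)
  hit <- recursive_genome_clip(tail70, te_at = "right", idx)
  expect_equal(hit$trim, 0L)
  expect_equal(hit$breakpoint, 30070L)
  expect_equal(hit$strand, "+")
  # mutate the 5 junction-adjacent bases: mapped only after trimming 5
  mut <- paste0(substring(tail70, 1, 65),
                chartr("ACGT", "TGCA", substring(tail70, 66, 70)))
  hit2 <- recursive_genome_clip(mut, te_at = "right", idx)
  expect_equal(hit2$trim, 5L)
  expect_equal(hit2$breakpoint, 30070L)
  # for a left-anchored transposon the genomic part starts at the junction
  hit3 <- recursive_genome_clip(substring(ref, 40001, 40060), te_at = "left",
                                idx)
  expect_equal(hit3$breakpoint, 40001L)
  # tail that never maps is discarded once it shrinks below the floor
  expect_null(recursive_genome_clip(strrep("A", 30), te_at = "right", idx))
})

test_that("mate validation applies criteria in order", {
  db <- build_extremity_db(ins_sim$ann, ins_sim$genome)
  idx <- genome_index(ins_sim$genome)
  te <- db[[1]]
  cand <- list(native_strand = "-", g_strand = "+", chrom = "chr1",
               breakpoint = 30070L, te_id = te$te_id)
  mate_proper <- data.frame(mapped = TRUE, strand = "+", chrom = "chr1",
                            pos = 30070L - 800L,
                            seq = random_genome_string(50, 70),
                            stringsAsFactors = FALSE)
  expect_equal(validate_mate(cand, mate_proper, db, idx), "proper_pair")
  # same strand fails criterion (a); unrelated sequence fails (b)/(c)
  mate_bad <- transform(mate_proper, strand = "-",
                        seq = random_genome_string(50, 66))
  expect_null(validate_mate(cand, mate_bad, db, idx))
  # distance at/above the insert bound fails (a)
  mate_far <- transform(mate_proper, pos = 30070L + 3500L)
  expect_null(validate_mate(cand, mate_far, db, idx))
  # mate inside the same transposon extremity satisfies (b)
  mate_te <- data.frame(mapped = FALSE, strand = NA, chrom = NA,
                        pos = NA_integer_,
                        seq = substring(te$ext5, 50, 140),
                        stringsAsFactors = FALSE)
  expect_equal(validate_mate(cand, mate_te, db, idx), "same_te")
  # clipped mate whose native strand is opposite the candidate's satisfies (c)
  ref <- ins_sim$genome$seqs[["chr1"]]
  mate_clip_seq <- paste0(substring(ref, 30011, 30070),
                          substring(te$ext5, 1, 40))
  mate_clip <- data.frame(mapped = FALSE, strand = NA, chrom = NA,
                          pos = NA_integer_, seq = mate_clip_seq,
                          stringsAsFactors = FALSE)
  expect_equal(validate_mate(cand, mate_clip, db, idx), "clip_opposite")
  # same native strand is rejected under (c)
  mate_same <- transform(mate_clip, seq = methdose:::revcomp(mate_clip_seq))
  expect_null(validate_mate(cand, mate_same, db, idx))
})

test_that("cluster pairing yields TSDs inside the open interval (3, 20)", {
  mk <- function(side, te_end, bp, n, id0 = 0)
    data.frame(read_id = sprintf("r%03d", id0 + seq_len(n)), chrom = "c1",
               te_id = "TE1", te_end = te_end, side = side, breakpoint = bp,
               ambiguous = FALSE, stringsAsFactors = FALSE)
  cands <- rbind(mk("left", "5p", 1009L, 5), mk("right", "3p", 1001L, 4, 10))
  calls <- cluster_and_call(cands)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$tsd_start, 1001L)
  expect_equal(calls$tsd_end, 1009L)
  expect_equal(calls$tsd_len, 9L)
  expect_equal(calls$n_reads_5prime, 5L)
  expect_equal(calls$n_reads_3prime, 4L)
  # 3 reads on one side: no call
  expect_equal(nrow(cluster_and_call(
    rbind(mk("left", "5p", 1009L, 3), mk("right", "3p", 1001L, 4, 10)))), 0L)
  # boundary overlaps 3 bp and 20 bp are rejected
  expect_equal(nrow(cluster_and_call(
    rbind(mk("left", "5p", 1003L, 5), mk("right", "3p", 1001L, 5, 10)))), 0L)
  expect_equal(nrow(cluster_and_call(
    rbind(mk("left", "5p", 1020L, 5), mk("right", "3p", 1001L, 5, 10)))), 0L)
  # ambiguous reads are excluded by default
  amb <- rbind(mk("left", "5p", 1009L, 5), mk("right", "3p", 1001L, 4, 10))
  amb$ambiguous[1:2] <- TRUE
  expect_equal(nrow(cluster_and_call(amb)), 0L)
  expect_equal(nrow(cluster_and_call(amb, include_ambiguous = TRUE)), 1L)
})

test_that("region filters remove chromosome-end, masked and donor-span calls", {
  # the N run is kept below the centromere-analogue threshold so only the
  # 500-bp N-run margin applies to it
  g <- genome_from_strings(c(c1 = paste0(random_genome_string(6000, 67),
                                         strrep("N", 600),
                                         random_genome_string(43400, 68))))
  tes <- data.frame(te_id = "TE1", family = "F", chrom = "c1", strand = "+",
                    start = 20001L, end = 21000L, stringsAsFactors = FALSE)
  ann <- make_annotation(data.frame(gene_id = character(), chrom = character(),
                                    strand = character(), start = integer(),
                                    end = integer(), stringsAsFactors = FALSE),
                         exons = data.frame(gene_id = character(),
                                            start = integer(), end = integer()),
                         tes = tes)
  mask <- build_chromosome_mask(g)
  call_at <- function(a) data.frame(chrom = "c1", te_id = "TE1",
                                    tsd_start = a, tsd_end = a + 8L,
                                    tsd_len = 9L, n_reads_5prime = 5L,
                                    n_reads_3prime = 5L,
                                    filter_status = "PASS",
                                    stringsAsFactors = FALSE)
  total_len <- nchar(g$seqs[["c1"]])
  got <- filter_insertion_calls(rbind(
    call_at(total_len - 2500L),   # 2.5 kb from the chromosome end
    call_at(7000L),               # 400 bp from the N run (ends 6600)
    call_at(7250L),               # 650 bp from the N run: retained
    call_at(20500L),              # inside the donor span
    call_at(30000L)), mask, ann)  # clean
  expect_equal(got$filter_status,
               c("chrom_end", "n_run", "PASS", "donor_span", "PASS"))
})

test_that("planted insertions are recovered end-to-end with exact TSDs", {
  rs <- simulate_insertion_readset(ins_sim)
  res <- call_te_insertions(rs$sam, ins_sim$genome, ins_sim$ann)
  truth <- rs$truth[order(rs$truth$tsd_start), ]
  calls <- res$calls[order(res$calls$tsd_start), ]
  expect_equal(nrow(calls), nrow(truth))
  expect_equal(calls$te_id, truth$te_id)
  expect_equal(calls$tsd_start, truth$tsd_start)
  expect_equal(calls$tsd_end, truth$tsd_end)
  expect_true(all(calls$n_reads_5prime >= 4 & calls$n_reads_3prime >= 4))
})

test_that("insertion calls are invariant to read input order", {
  rs <- simulate_insertion_readset(ins_sim)
  rec <- read_sam(rs$sam)
  set.seed(69)
  shuffled <- rec[sample(nrow(rec)), ]
  a <- call_te_insertions(rec, ins_sim$genome, ins_sim$ann)$calls
  b <- call_te_insertions(shuffled, ins_sim$genome, ins_sim$ann)$calls
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("boundary TSDs, thin support and masked decoys are never called", {
  cfg <- ins_sim$config
  mask <- build_chromosome_mask(ins_sim$genome)
  L <- nchar(ins_sim$genome$seqs[["chr1"]])
  ins <- data.frame(
    te_id = ins_sim$ann$tes$te_id[1:5], chrom = "chr1",
    pos = c(20000L, 26000L, 32000L, 38000L, L - 2500L),
    tsd_len = c(3L, 20L, 9L, 9L, 9L),
    n_reads = c(8L, 8L, 3L, 8L, 8L),
    label = c("tsd3", "tsd20", "thin", "good", "near_end"),
    stringsAsFactors = FALSE)
  rs <- simulate_insertion_readset(ins_sim, insertions = ins)
  res <- call_te_insertions(rs$sam, ins_sim$genome, ins_sim$ann)
  # only the clean planted insertion survives
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$tsd_start, 38000L - 9L + 1L)
  # the near-end decoy is called but removed by the region filter
  ne <- res$all_calls[res$all_calls$filter_status == "chrom_end", ]
  expect_equal(nrow(ne), 1L)
  expect_equal(ne$tsd_end, L - 2500L)
})
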