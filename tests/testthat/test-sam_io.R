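test_that("trinucleotide entropy matches hand-computed values", {
  expect_identical(sequence_entropy("AAAAAAAAAA"), 0)

  # ACGTACGTACGT: 10 3-mers, counts ACG:3 CGT:3 GTA:2 TAC:2
  # H = -(2*0.3*log2(0.3) + 2*0.2*log2(0.2)) = 1.9710 bits, normalizer log2(10)
  expect_equal(sequence_entropy("ACGTACGTACGT"), 59.3315, tolerance = 1e-4)

  # every one of the 64 3-mers present with near-equal frequency
  bases <- c("A", "C", "G", "T")
  all64 <- paste(apply(expand.grid(bases, bases, bases), 1, paste,
                       collapse = ""), collapse = "")
  expect_gt(sequence_entropy(all64), 95)

  expect_error(sequence_entropy("AC"), "shorter than 3")
  # N-containing 3-mers are ignored: only AAA is counted here
  expect_identical(sequence_entropy("AANAAA"), 0)
  expect_error(sequence_entropy("NNNNN"), "undefined")
})

test_that("MAPQ and length filters are inclusive at their thresholds", {
  sam <- tempfile(fileext = ".sam")
  sq30 <- strrep("ACGTT", 6)           # 30 bp
  sq29 <- substr(sq30, 1, 29)
  write_test_sam(list(
    c("r_q0", "0", "1", "0", "30M", sq30, "30"),
    c("r_q29", "0", "51", "29", "30M", sq30, "30"),
    c("r_q30", "0", "101", "30", "30M", sq30, "30"),
    c("r_len29", "0", "151", "60", "29M", sq29, "29")
  ), sam)

  aset <- load_alignments(sam, min_mapq = 30, min_length = 30)
  expect_identical(sort(aset$reads$read_id), "r_q30")
  expect_identical(unname(aset$filter_log[["low_mapq"]]), 2L)
  expect_identical(unname(aset$filter_log[["short_alignment"]]), 1L)
  expect_identical(sum(aset$filter_log), aset$input_n - n_reads(aset))

  # both boundary reads pass with relaxed thresholds
  aset2 <- load_alignments(sam, min_mapq = 29, min_length = 29)
  expect_setequal(aset2$reads$read_id, c("r_q29", "r_q30", "r_len29"))
})

test_that("reference bases are reconstructed from CIGAR and MD", {
  sam <- tempfile(fileext = ".sam")
  # read 1: ungapped with one mismatch (ref C read T at query pos 3)
  # read 2: 2S leading soft clip, 4M, 2-base deletion, 4M, mismatch in 2nd block
  # read 3: 3M, 2-base insertion, 3M, no mismatches
  write_test_sam(list(
    c("mm", "0", "10", "60", "8M", "AATAGGCA", "2C5"),
    c("clip_del", "0", "20", "60", "2S4M2D4M", "TTACGTGGCA", "4^CA2T1"),
    c("ins", "0", "30", "60", "3M2I3M", "ACGTTGCA", "6")
  ), sam, rlen = 2000L)

  aset <- load_alignments(sam, min_mapq = 0, min_length = 1)
  rd <- aset$reads[match(c("mm", "clip_del", "ins"), aset$reads$read_id), ]

  expect_identical(rd$core[1], "AATAGGCA")
  expect_identical(rd$ref[1], "AACAGGCA")

  expect_identical(rd$core[2], "ACGTGGCA")   # soft clip removed
  expect_identical(rd$ref[2], "ACGTGGTA")    # mismatch T at 7th aligned base

  expect_identical(rd$core[3], "ACGTTGCA")
  expect_identical(rd$ref[3], "ACG--GCA")    # insertion leaves reference gaps

  # reference span excludes soft clips, includes deletions
  expect_identical(rd$end[2] - rd$start[2], 10L)
})

test_that("reads without MD fall back to the reference FASTA or error", {
  sam <- tempfile(fileext = ".sam")
  fa <- tempfile(fileext = ".fa")
  refseq <- paste(rep("ACGT", 50), collapse = "")
  writeLines(c(">chr1 test", refseq), fa)
  # read at 1-based pos 5 spans ACGTACGT; query has mismatch at its 1st base
  write_test_sam(list(c("nomd", "0", "5", "60", "8M", "TCGTACGT", NA)),
                 sam, rlen = 200L)

  expect_error(load_alignments(sam, min_mapq = 0, min_length = 1),
               "nomd")
  aset <- load_alignments(sam, reference = fa, min_mapq = 0, min_length = 1)
  expect_identical(aset$reads$ref, "ACGTACGT")
})

test_that("simulated alignments round-trip through SAM", {
  cfg <- sim_config(n_reads = 100L, seed = 606L, label = "rt")
  ref <- make_reference(cfg)
  aset <- simulate_reads(ref, cfg)
  sam <- tempfile(fileext = ".sam")
  write_sam(aset, sam, ref_length = nchar(ref), ground_truth = cfg)

  back <- load_alignments(sam, min_mapq = 0, min_length = 1)
  expect_identical(n_reads(back), 100L)
  ord <- match(aset$reads$read_id, back$reads$read_id)
  expect_identical(back$reads$seq[ord], aset$reads$seq)
  expect_identical(back$reads$strand[ord], aset$reads$strand)
  # MD-reconstructed reference equals the simulator's ground truth
  expect_identical(back$reads$ref[ord], aset$reads$ref)
  expect_identical(back$reads$start[ord], aset$reads$start)
})

test_that("entropy filter removes low-complexity reads and is idempotent", {
  polyA <- strrep("A", 50)
  rnd <- random_dna(50, seed = 99)
  reads <- data.frame(read_id = c("poly", "rnd"), rname = "chr1",
                      start = c(0L, 100L), end = c(50L, 150L),
                      strand = "+", mapq = 60L,
                      seq = c(polyA, rnd), core = c(polyA, rnd),
                      ref = c(polyA, rnd), stringsAsFactors = FALSE)
  aset <- alignment_set(reads, "toy")

  kept <- filter_entropy(aset, 50)
  expect_identical(kept$reads$read_id, "rnd")
  expect_identical(unname(kept$filter_log[["low_entropy"]]), 1L)

  # threshold 0 still removes the poly-A read (entropy exactly 0, strict >)
  expect_identical(filter_entropy(aset, 0)$reads$read_id, "rnd")
  # but retains anything with >= 2 distinct 3-mers, however repetitive
  ac_rep <- strrep("AC", 25)
  reads2 <- reads
  reads2$read_id <- c("acrep", "rnd")
  reads2$seq <- reads2$core <- reads2$ref <- c(ac_rep, rnd)
  expect_identical(n_reads(filter_entropy(alignment_set(reads2, "toy2"), 0)),
                   2L)

  # idempotence
  expect_identical(filter_entropy(kept, 50)$reads, kept$reads)

  # simulated random-sequence reads are nearly all high-complexity
  cfg <- sim_config(n_reads = 100L, read_length_mean = 40,
                    read_length_sd = 0, seed = 321L)
  sim <- simulate_reads(make_reference(cfg), cfg)
  expect_gte(n_reads(filter_entropy(sim, 50)), 95L)
})

test_that("deduplication keeps one read per coordinate key by MAPQ then id", {
  mk <- function(id, start, end, strand, mapq)
    data.frame(read_id = id, rname = "chr1", start = start, end = end,
               strand = strand, mapq = mapq, seq = "ACGTACGT",
               core = "ACGTACGT", ref = "ACGTACGT", stringsAsFactors = FALSE)
  reads <- rbind(mk("a", 0L, 8L, "+", 30L), mk("b", 0L, 8L, "+", 37L),
                 mk("c", 0L, 8L, "-", 37L),          # other strand: kept
                 mk("d2", 10L, 18L, "+", 20L), mk("d1", 10L, 18L, "+", 20L))
  aset <- alignment_set(reads, "dups")
  out <- deduplicate(aset)
  expect_setequal(out$reads$read_id, c("b", "c", "d1"))
  expect_identical(unname(out$filter_log[["duplicate"]]), 2L)

  # idempotent, and retained reads keep their original order
  expect_identical(deduplicate(out)$reads, out$reads)
  expect_identical(out$reads$read_id, c("b", "c", "d1"))

  # 50-read fixture where 10 share one key -> 41 survivors
  many <- do.call(rbind, lapply(1:50, function(i) {
    if (i <= 10) mk(sprintf("dup%02d", i), 500L, 550L, "+", i)
    else mk(sprintf("unq%02d", i), 500L + i, 550L + i, "+", 30L)
  }))
  out2 <- deduplicate(alignment_set(many, "many"))
  expect_identical(n_reads(out2), 41L)
  expect_true("dup10" %in% out2$reads$read_id)   # highest MAPQ among the 10
})

test_that("filter log accounts for every input record", {
  pair <- fixture_pair()
  sub <- alignment_set(pair$ancient$reads[1:500, ], "sub")
  out <- filter_entropy(deduplicate(sub), 50)
  expect_identical(sum(out$filter_log) + n_reads(out), out$input_n)
  rep_file <- tempfile(fileext = ".tsv")
  write_filter_report(out, rep_file)
  tab <- read.delim(rep_file)
  expect_identical(names(tab), c("filter_name", "reads_removed",
                                 "reads_remaining"))
  expect_identical(tail(tab$reads_remaining, 1), n_reads(out))
})

test_that("empty results warn rather than error", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(list(c("low", "0", "1", "5", "30M", strrep("ACGTT", 6), "30")),
                 sam)
  expect_warning(aset <- load_alignments(sam, min_mapq = 30, min_length = 30),
                 "no reads")
  expect_identical(n_reads(aset), 0L)
  expect_identical(sum(aset$filter_log), aset$input_n)
})
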