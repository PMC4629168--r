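# Shared fixtures, built once per test run and memoised: the canonical
# damaged/damage-free library pair and a flat (zero-amplitude) library at
# the scale the simulation-based checks use.

.fixtures <- new.env(parent = emptyenv())

fixture_pair <- function() {
  if (is.null(.fixtures$pair)) {
    cfg <- sim_config(n_reads = 50000L, seed = 20211L, label = "ancient_sim")
    .fixtures$pair <- simulate_library_pair(cfg)
  }
  .fixtures$pair
}

fixture_flat <- function() {
  if (is.null(.fixtures$flat)) {
    cfg <- sim_config(n_reads = 50000L, damage_amplitude = 0, seed = 30307L,
                      label = "flat_sim")
    .fixtures$flat <- simulate_reads(make_reference(cfg), cfg)
  }
  .fixtures$flat
}

# Minimal single-reference SAM writer for handcrafted records.
# records: list of character vectors
#   c(qname, flag, pos1, mapq, cigar, seq, md_or_NA)
write_test_sam <- function(records, path, rname = "chr1", rlen = 1000L) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", rname, rlen))
  for (r in records) {
    fields <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t*\t0\t0\t%s\t*",
                      r[1], r[2], rname, r[3], r[4], r[5], r[6])
    if (!is.na(r[7])) fields <- paste0(fields, "\tMD:Z:", r[7])
    lines <- c(lines, fields)
  }
  writeLines(lines, path)
  path
}

# Random DNA string helper for entropy / dedup fixtures.
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
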