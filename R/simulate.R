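#' Configuration for the deamination read simulator
#'
#' Bundles and validates the parameters of the synthetic aligned-read
#' generator. The damage model gives every reference cytosine at read
#' position `i` (1-based from the 5' end, in read orientation) a
#' probability `damage_amplitude * exp(-damage_rate * i) + baseline` of
#' being read as thymine — the exponentially decaying 5' C-to-T excess
#' characteristic of postmortem cytosine deamination. Independently, every
#' base is replaced by a uniformly chosen different base with probability
#' `seq_error`. An "ancient-like" library uses a positive amplitude
#' (defaults 0.15 amplitude, 0.3 per-position decay rate, in line with
#' strongly damaged archaeological libraries); a "modern-like" library sets
#' the amplitude to 0 and keeps only the flat baseline.
#'
#' @param n_reads number of reads to simulate
#' @param ref_length reference length in bp
#' @param gc_content probability that a reference base is G or C
#' @param read_length_mean,read_length_sd normal read-length distribution,
#'   truncated below at `read_length_min`
#' @param read_length_min hard minimum read length (30 bp, matching the
#'   mapping-length filter)
#' @param damage_amplitude deamination amplitude `a` in `[0, 1)`
#' @param damage_rate decay rate `r` per position, `>= 0`
#' @param baseline position-independent C-to-T floor in `[0, 0.05]`
#' @param seq_error per-base uniform sequencing error rate in `[0, 0.02]`
#' @param strand_fraction_forward fraction of reads on the forward strand
#' @param seed integer seed; reference and reads derive distinct
#'   substreams from it
#' @param label source label carried into the AlignmentSet
#' @return a `sim_config` list
#' @export
sim_config <- function(n_reads = 10000L,
                       ref_length = 100000L,
                       gc_content = 0.5,
                       read_length_mean = 55,
                       read_length_sd = 12,
                       read_length_min = 30L,
                       damage_amplitude = 0.15,
                       damage_rate = 0.3,
                       baseline = 0.005,
                       seq_error = 0.002,
                       strand_fraction_forward = 0.5,
                       seed = NULL,
                       label = "simulated") {
  .assert_scalar_num(n_reads, "n_reads", 1)
  .assert_scalar_num(ref_length, "ref_length", 1)
  .assert_scalar_num(gc_content, "gc_content", 0, 1)
  .assert_scalar_num(read_length_mean, "read_length_mean", 1)
  .assert_scalar_num(read_length_sd, "read_length_sd", 0)
  .assert_scalar_num(read_length_min, "read_length_min", 1)
  .assert_scalar_num(damage_amplitude, "damage_amplitude", 0, 1 - 1e-12)
  .assert_scalar_num(damage_rate, "damage_rate", 0)
  .assert_scalar_num(baseline, "baseline", 0, 0.05)
  .assert_scalar_num(seq_error, "seq_error", 0, 0.02)
  .assert_scalar_num(strand_fraction_forward, "strand_fraction_forward", 0, 1)
  if (damage_amplitude * exp(-damage_rate) + baseline + seq_error > 1)
    stop("damage_amplitude * exp(-damage_rate) + baseline + seq_error ",
         "must not exceed 1")
  if (ref_length < read_length_min)
    stop("ref_length must be at least the minimum read length")
  structure(list(n_reads = as.integer(n_reads),
                 ref_length = as.integer(ref_length),
                 gc_content = gc_content,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 read_length_min = as.integer(read_length_min),
                 damage_amplitude = damage_amplitude,
                 damage_rate = damage_rate,
                 baseline = baseline,
                 seq_error = seq_error,
                 strand_fraction_forward = strand_fraction_forward,
                 seed = seed,
                 label = label),
            class = "sim_config")
}

#' Simulate a random reference sequence
#'
#' I.i.d. bases with `P(G or C) = gc_content`, deterministic under the
#' config seed.
#'
#' @param config a [sim_config()]
#' @param path optional FASTA output path (written via Biostrings)
#' @return a single character string of bases; when `path` is given the
#'   FASTA is written as a side effect
#' @export
make_reference <- function(config, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ref <- .with_seed(config$seed, {
    p <- config$gc_content / 2
    q <- (1 - config$gc_content) / 2
    paste(sample(c("A", "C", "G", "T"), config$ref_length, replace = TRUE,
                 prob = c(q, p, p, q)), collapse = "")
  })
  if (!is.null(path)) {
    dna <- Biostrings::DNAStringSet(ref)
    names(dna) <- "sim_ref"
    Biostrings::writeXStringSet(dna, path)
  }
  ref
}

#' Simulate aligned reads with 5' deamination damage
#'
#' Draws read positions and strands uniformly, applies the per-position
#' C-to-T deamination channel and the uniform sequencing-error channel (see
#' [sim_config()]), and returns the reads as an [alignment_set()] whose
#' reference bases are the simulator's ground truth. Reverse-strand reads
#' are stored in reference orientation, as in a SAM file, so their 5' end
#' is the right edge of the alignment and their deamination channel is
#' G-to-A in reference orientation.
#'
#' @param reference reference sequence string from [make_reference()]
#' @param config a [sim_config()]
#' @return an `AlignmentSet` with MAPQ 60 reads on reference `"sim_ref"`
#' @export
simulate_reads <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"), is.character(reference),
            length(reference) == 1L)
  reflen <- nchar(reference)
  if (reflen < config$read_length_min)
    stop("reference shorter than the minimum read length")
  n <- config$n_reads

  .with_seed(.child_seed(config$seed, 1L), {
    L <- pmin(pmax(as.integer(round(stats::rnorm(
      n, config$read_length_mean, config$read_length_sd))),
      config$read_length_min), reflen)
    start <- as.integer(floor(stats::runif(n) * (reflen - L + 1)))  # 0-based
    fwd <- stats::runif(n) < config$strand_fraction_forward

    refsub <- substr(rep(reference, n), start + 1L, start + L)

    # flatten to one char vector; damage + error act per base
    chars <- strsplit(paste(refsub, collapse = ""), "", fixed = TRUE)[[1]]
    pos_lr <- sequence(L)                       # left-to-right offset
    read_pos <- ifelse(rep(fwd, L), pos_lr, rep(L, L) - pos_lr + 1L)
    pdam <- config$damage_amplitude * exp(-config$damage_rate * read_pos) +
      config$baseline

    # deamination: C->T on forward reads, G->A (ref orientation) on reverse
    target <- ifelse(rep(fwd, L), "C", "G")
    product <- ifelse(rep(fwd, L), "T", "A")
    hit <- chars == target & stats::runif(length(chars)) < pdam
    chars[hit] <- product[hit]

    # uniform sequencing error: substitute to one of the three other bases
    err <- stats::runif(length(chars)) < config$seq_error
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      cur <- match(chars[err], bases)
      shift <- sample.int(3L, sum(err), replace = TRUE)
      chars[err] <- bases[(cur + shift - 1L) %% 4L + 1L]
    }

    big <- paste(chars, collapse = "")
    ends <- cumsum(L)
    seqs <- substring(big, ends - L + 1L, ends)

    reads <- data.frame(
      read_id = sprintf("sim_%07d", seq_len(n)),
      rname = "sim_ref",
      start = start,
      end = start + L,
      strand = ifelse(fwd, "+", "-"),
      mapq = 60L,
      seq = seqs,
      core = seqs,
      ref = refsub,
      stringsAsFactors = FALSE)
    alignment_set(reads, source_label = config$label)
  })
}

#' Simulate the canonical ancient-like / modern-like library pair
#'
#' Convenience wrapper generating one damaged ("ancient-like") and one
#' damage-free ("modern-like") library from independent references. When
#' the modern config carries no seed of its own, one is derived from the
#' ancient seed so the two libraries never share a random stream.
#'
#' @param ancient_config config for the damaged library (default
#'   [sim_config()] defaults: amplitude 0.15, rate 0.3)
#' @param modern_config config for the damage-free library (default: the
#'   ancient config with amplitude 0)
#' @param dir optional directory; when given, writes
#'   `ancient.sam`/`modern.sam` and the two reference FASTAs there
#' @return list with `ancient` and `modern` AlignmentSets (and `paths`
#'   when `dir` was given)
#' @export
simulate_library_pair <- function(ancient_config = sim_config(label = "ancient_sim"),
                                  modern_config = NULL,
                                  dir = NULL) {
  stopifnot(inherits(ancient_config, "sim_config"))
  if (is.null(modern_config)) {
    modern_config <- ancient_config
    modern_config$damage_amplitude <- 0
    modern_config$label <- "modern_sim"
    modern_config$seed <- NULL
  }
  stopifnot(inherits(modern_config, "sim_config"))
  if (is.null(modern_config$seed) ||
      identical(modern_config$seed, ancient_config$seed))
    modern_config$seed <- .child_seed(ancient_config$seed, 7919L)

  ra <- make_reference(ancient_config)
  rm_ <- make_reference(modern_config)
  anc <- simulate_reads(ra, ancient_config)
  mod <- simulate_reads(rm_, modern_config)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa_a <- file.path(dir, "ancient_ref.fa"); fa_m <- file.path(dir, "modern_ref.fa")
    Biostrings::writeXStringSet(stats::setNames(Biostrings::DNAStringSet(ra), "sim_ref"), fa_a)
    Biostrings::writeXStringSet(stats::setNames(Biostrings::DNAStringSet(rm_), "sim_ref"), fa_m)
    sam_a <- file.path(dir, "ancient.sam"); sam_m <- file.path(dir, "modern.sam")
    write_sam(anc, sam_a, ref_length = nchar(ra), ground_truth = ancient_config)
    write_sam(mod, sam_m, ref_length = nchar(rm_), ground_truth = modern_config)
    paths <- list(ancient_sam = sam_a, modern_sam = sam_m,
                  ancient_fasta = fa_a, modern_fasta = fa_m)
  }
  list(ancient = anc, modern = mod, paths = paths)
}

#' Write an AlignmentSet as a SAM file
#'
#' Emits a valid single-reference SAM with correct CIGAR (`<len>M`,
#' simulated reads are ungapped), MD and NM tags derived from the stored
#' reference bases, and the ground-truth simulation parameters in a `@CO`
#' header line as JSON.
#'
#' @param aset an `AlignmentSet` (ungapped alignments)
#' @param path output SAM path
#' @param ref_length reference sequence length for the `@SQ` line
#' @param ground_truth optional [sim_config()] echoed into the header
#' @return `path`, invisibly
#' @export
write_sam <- function(aset, path, ref_length, ground_truth = NULL) {
  stopifnot(inherits(aset, "AlignmentSet"))
  rd <- aset$reads
  if (nrow(rd) && any(grepl("-", rd$ref, fixed = TRUE)))
    stop("write_sam supports ungapped alignments only")
  rname <- if (nrow(rd)) rd$rname[1] else "sim_ref"
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", rname, as.integer(ref_length)))
  if (!is.null(ground_truth)) {
    gt <- unclass(ground_truth)
    gt$seed <- if (is.null(gt$seed)) NA else gt$seed
    hdr <- c(hdr, paste0("@CO\tground_truth=",
                         jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA)))
  }
  lines <- hdr
  if (nrow(rd)) {
    md <- character(nrow(rd)); nm <- integer(nrow(rd))
    for (i in seq_len(nrow(rd))) {
      m <- .md_string(rd$seq[i], rd$ref[i])
      md[i] <- m$md; nm[i] <- m$nm
    }
    flag <- ifelse(rd$strand == "+", 0L, 16L)
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tMD:Z:%s\tNM:i:%d",
                              rd$read_id, flag, rd$rname, rd$start + 1L,
                              rd$mapq, nchar(rd$seq), rd$seq, md, nm))
  }
  writeLines(lines, path)
  invisible(path)
}

# MD tag for an ungapped alignment: runs of matches interleaved with the
# reference base at each mismatch
.md_string <- function(seq, ref) {
  q <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  mism <- which(q != r)
  if (!length(mism)) return(list(md = as.character(length(q)), nm = 0L))
  parts <- character(0)
  prev <- 0L
  for (m in mism) {
    parts <- c(parts, as.character(m - prev - 1L), r[m])
    prev <- m
  }
  parts <- c(parts, as.character(length(q) - prev))
  list(md = paste(parts, collapse = ""), nm = length(mism))
}
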