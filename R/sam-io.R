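#' Load aligned reads from SAM/BAM with the standard aDNA filtering stack
#'
#' Reads primary, mapped alignments and retains those with mapping quality
#' at least `min_mapq` (the usual aDNA threshold of 30) and aligned query
#' length at least `min_length` (30 bp, the BWA-MEM default minimum).
#' Reference bases at every aligned query position are reconstructed from
#' the MD tag, or from `reference` (a FASTA file) for records lacking one.
#' Unmapped, secondary and supplementary records are always dropped.
#'
#' @param path SAM or BAM file
#' @param reference optional reference FASTA used when records lack MD tags
#' @param min_mapq minimum mapping quality (inclusive), default 30
#' @param min_length minimum aligned query length in bp (inclusive), default 30
#' @param source_label label stored in the returned set; defaults to the
#'   file name
#' @return an [alignment_set()] with a populated filter log
#' @export
load_alignments <- function(path, reference = NULL,
                            min_mapq = 30L, min_length = 30L,
                            source_label = basename(path)) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  .assert_scalar_num(min_mapq, "min_mapq", 0)
  .assert_scalar_num(min_length, "min_length", 1)

  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("could not parse SAM file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  }

  total <- Rsamtools::countBam(bam)$records
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq"),
    tag = "MD", flag = flags)
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]

  n_primary <- length(rec$qname)
  log <- c(not_primary_mapped = total - n_primary)

  mapq <- rec$mapq
  mapq[is.na(mapq)] <- 0L
  keep_q <- mapq >= min_mapq
  log["low_mapq"] <- sum(!keep_q)

  idx <- which(keep_q)
  cigar <- rec$cigar[idx]
  alen <- .aligned_query_length(cigar)
  keep_l <- alen >= min_length
  log["short_alignment"] <- sum(!keep_l)
  idx <- idx[keep_l]

  if (!length(idx)) {
    warning("no reads passed the filters; returning an empty AlignmentSet")
    empty <- data.frame(read_id = character(0), rname = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), mapq = integer(0),
                        seq = character(0), core = character(0),
                        ref = character(0), stringsAsFactors = FALSE)
    return(alignment_set(empty, source_label, log, input_n = total))
  }

  seqs <- as.character(rec$seq[idx])
  cig <- rec$cigar[idx]
  md <- if (is.null(rec$tag$MD)) rep(NA_character_, length(idx))
        else rec$tag$MD[idx]
  rname <- as.character(rec$rname[idx])
  pos0 <- rec$pos[idx] - 1L     # SAM is 1-based; internal is 0-based half-open
  rlen <- .aligned_ref_length(cig)

  refseqs <- NULL
  if (!is.null(reference)) {
    refseqs <- Biostrings::readDNAStringSet(reference)
    names(refseqs) <- sub("\\s.*$", "", names(refseqs))
  }

  rec_ref <- .reconstruct_all(seqs, cig, md, rname, pos0, refseqs,
                              rec$qname[idx])

  reads <- data.frame(read_id = rec$qname[idx],
                      rname = rname,
                      start = pos0,
                      end = pos0 + rlen,
                      strand = as.character(rec$strand[idx]),
                      mapq = mapq[idx],
                      seq = seqs,
                      core = rec_ref$core,
                      ref = rec_ref$ref,
                      stringsAsFactors = FALSE)
  alignment_set(reads, source_label, log, input_n = total)
}

# query length consumed by aligned ops (M/I/=/X), i.e. excluding soft clips
.aligned_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    m <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", m))
    op <- substr(m, nchar(m), nchar(m))
    sum(n[op %in% c("M", "I", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

.aligned_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    m <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", m))
    op <- substr(m, nchar(m), nchar(m))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Reconstruct, for every read, the soft-clip-trimmed query ('core') and the
# reference base aligned to each core position ('-' at insertions).
# MD-tag based when available, reference-FASTA based otherwise.
.reconstruct_all <- function(seqs, cigar, md, rname, pos0, refseqs, qnames) {
  n <- length(seqs)
  core <- character(n); ref <- character(n)

  # fast path: ungapped alignment, MD a plain match count -> ref == seq
  simple <- grepl("^\\d+M$", cigar) & !is.na(md) & grepl("^\\d+$", md)
  core[simple] <- seqs[simple]
  ref[simple] <- seqs[simple]

  for (i in which(!simple)) {
    if (!is.na(md[i])) {
      r <- .reconstruct_md(seqs[i], cigar[i], md[i])
    } else if (!is.null(refseqs)) {
      r <- .reconstruct_fasta(seqs[i], cigar[i], rname[i], pos0[i], refseqs)
    } else {
      stop("read '", qnames[i],
           "' has no MD tag and no reference FASTA was supplied",
           call. = FALSE)
    }
    core[i] <- r$core
    ref[i] <- r$ref
  }
  list(core = core, ref = ref)
}

.parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(n = as.integer(sub("[A-Z=]$", "", m)),
       op = substr(m, nchar(m), nchar(m)))
}

.reconstruct_md <- function(seq, cigar, md) {
  cg <- .parse_cigar(cigar)
  q <- strsplit(seq, "", fixed = TRUE)[[1]]
  core <- character(0); ref <- character(0)
  qi <- 1L
  for (k in seq_along(cg$op)) {
    n <- cg$n[k]
    switch(cg$op[k],
           "S" = { qi <- qi + n },
           "H" = NULL, "P" = NULL,
           "M" = , "=" = , "X" = {
             core <- c(core, q[qi:(qi + n - 1L)])
             ref <- c(ref, q[qi:(qi + n - 1L)])  # placeholder: match = query base
             qi <- qi + n
           },
           "I" = {
             core <- c(core, q[qi:(qi + n - 1L)])
             ref <- c(ref, rep("-", n))
             qi <- qi + n
           },
           "D" = NULL, "N" = NULL)
  }
  # overwrite mismatch positions using the MD tag; MD walks M and D ops only
  aligned_idx <- which(ref != "-")
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  j <- 1L
  for (tok in toks) {
    if (grepl("^\\d+$", tok)) {
      j <- j + as.integer(tok)
    } else if (startsWith(tok, "^")) {
      # deleted reference bases: occupy no query position
    } else {
      if (j > length(aligned_idx))
        stop("MD tag '", md, "' inconsistent with CIGAR '", cigar, "'")
      ref[aligned_idx[j]] <- toupper(tok)
      j <- j + 1L
    }
  }
  list(core = paste(core, collapse = ""), ref = paste(ref, collapse = ""))
}

.reconstruct_fasta <- function(seq, cigar, rname, pos0, refseqs) {
  if (!rname %in% names(refseqs))
    stop("reference sequence '", rname, "' not found in FASTA")
  cg <- .parse_cigar(cigar)
  q <- strsplit(seq, "", fixed = TRUE)[[1]]
  rchars <- strsplit(as.character(refseqs[[rname]]), "", fixed = TRUE)[[1]]
  core <- character(0); ref <- character(0)
  qi <- 1L; ri <- pos0 + 1L
  for (k in seq_along(cg$op)) {
    n <- cg$n[k]
    switch(cg$op[k],
           "S" = { qi <- qi + n },
           "H" = NULL, "P" = NULL,
           "M" = , "=" = , "X" = {
             core <- c(core, q[qi:(qi + n - 1L)])
             ref <- c(ref, rchars[ri:(ri + n - 1L)])
             qi <- qi + n; ri <- ri + n
           },
           "I" = {
             core <- c(core, q[qi:(qi + n - 1L)])
             ref <- c(ref, rep("-", n))
             qi <- qi + n
           },
           "D" = , "N" = { ri <- ri + n })
  }
  list(core = paste(core, collapse = ""), ref = paste(ref, collapse = ""))
}

#' PRINSEQ-style trinucleotide sequence entropy
#'
#' Shannon entropy of the overlapping 3-mer composition, scaled to
#' `[0, 100]`: `100 * H / log2(min(K, 64))` where `K` is the number of
#' counted 3-mer windows and `H` the entropy (base 2) of their frequency
#' distribution. 3-mers containing `N` are not counted. A sequence with a
#' single distinct 3-mer scores 0.
#'
#' @param seq character vector of DNA sequences (length >= 3 each)
#' @return numeric vector of entropy scores in `[0, 100]`
#' @export
sequence_entropy <- function(seq) {
  vapply(seq, .entropy1, numeric(1), USE.NAMES = FALSE)
}

.entropy1 <- function(s) {
  n <- nchar(s)
  if (n < 3L) stop("sequence shorter than 3 bp: entropy undefined")
  km <- substring(s, 1:(n - 2L), 3:n)
  km <- km[!grepl("N", km, fixed = TRUE)]
  K <- length(km)
  if (K == 0L) stop("no countable 3-mers (all contain N): entropy undefined")
  counts <- table(km)
  if (length(counts) == 1L) return(0)
  p <- as.numeric(counts) / K
  H <- -sum(p * log2(p))
  100 * H / log2(min(K, 64L))
}

#' Remove low-complexity reads by entropy
#'
#' Retains reads whose [sequence_entropy()] strictly exceeds `threshold`
#' (reads with entropy less than or equal to the threshold are removed,
#' the convention of the entropy filter used in sedaDNA processing).
#'
#' @param aset an `AlignmentSet`
#' @param threshold entropy cutoff in `[0, 100]`, default 50
#' @return filtered `AlignmentSet`; removals appear in the filter log
#' @export
filter_entropy <- function(aset, threshold = 50) {
  stopifnot(inherits(aset, "AlignmentSet"))
  .assert_scalar_num(threshold, "threshold", 0, 100)
  if (!n_reads(aset)) return(.subset_aset(aset, logical(0), "low_entropy"))
  keep <- sequence_entropy(aset$reads$seq) > threshold
  .subset_aset(aset, keep, "low_entropy")
}

#' Remove coordinate duplicates
#'
#' Keeps at most one read per (reference, start, end, strand) key, the
#' standard proxy for PCR duplicates after mapping. Among duplicates the
#' highest-MAPQ read wins; ties go to the lexicographically smallest read
#' id. Retained reads keep their original order.
#'
#' @param aset an `AlignmentSet`
#' @return deduplicated `AlignmentSet`
#' @export
deduplicate <- function(aset) {
  stopifnot(inherits(aset, "AlignmentSet"))
  rd <- aset$reads
  if (!nrow(rd)) return(.subset_aset(aset, logical(0), "duplicate"))
  key <- paste(rd$rname, rd$start, rd$end, rd$strand, sep = "\r")
  ord <- order(key, -rd$mapq, rd$read_id)
  winner_rows <- ord[!duplicated(key[ord])]
  keep <- seq_len(nrow(rd)) %in% winner_rows
  .subset_aset(aset, keep, "duplicate")
}
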