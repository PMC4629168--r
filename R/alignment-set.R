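#' Aligned-read container
#'
#' An `AlignmentSet` holds filtered aligned reads together with the
#' reference bases reconstructed for every aligned query position, which is
#' all that downstream damage counting needs. The per-read table has columns:
#'
#' \describe{
#'   \item{read_id}{query name}
#'   \item{rname}{reference sequence name}
#'   \item{start, end}{0-based half-open reference span of the alignment}
#'   \item{strand}{`"+"` or `"-"`}
#'   \item{mapq}{mapping quality}
#'   \item{seq}{full query sequence as stored in the SAM record
#'     (reference orientation, soft clips included)}
#'   \item{core}{query sequence with soft-clipped bases removed}
#'   \item{ref}{reference base aligned to each `core` position, `"-"` at
#'     insertions; same length as `core`}
#' }
#'
#' A `filter_log` attribute records how many reads each filter removed, so
#' that `input - retained` is always accounted for.
#'
#' @param reads data.frame with the columns above
#' @param source_label character tag describing where the reads came from
#' @param filter_log named integer vector of reads removed per filter
#' @param input_n number of records in the original input
#' @return an object of class `AlignmentSet`
#' @export
alignment_set <- function(reads, source_label = "unlabelled",
                          filter_log = integer(0), input_n = nrow(reads)) {
  need <- c("read_id", "rname", "start", "end", "strand", "mapq",
            "seq", "core", "ref")
  miss <- setdiff(need, names(reads))
  if (length(miss))
    stop("reads is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(reads) && any(nchar(reads$core) != nchar(reads$ref)))
    stop("'core' and 'ref' must have equal lengths per read")
  if (nrow(reads) && !all(reads$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (sum(filter_log) != input_n - nrow(reads))
    stop("filter_log counts must sum to input reads minus retained reads")
  structure(list(reads = reads,
                 source_label = source_label,
                 filter_log = as.integer(filter_log) |>
                   stats::setNames(names(filter_log)),
                 input_n = as.integer(input_n)),
            class = "AlignmentSet")
}

#' Number of reads in an AlignmentSet
#' @param aset an `AlignmentSet`
#' @return integer read count
#' @export
n_reads <- function(aset) {
  stopifnot(inherits(aset, "AlignmentSet"))
  nrow(aset$reads)
}

#' @export
print.AlignmentSet <- function(x, ...) {
  cat(sprintf("AlignmentSet '%s': %d reads (from %d input records)\n",
              x$source_label, nrow(x$reads), x$input_n))
  if (length(x$filter_log)) {
    cat("filters applied:\n")
    for (nm in names(x$filter_log))
      cat(sprintf("  %-24s removed %d\n", nm, x$filter_log[[nm]]))
  }
  invisible(x)
}

# subset while keeping provenance; extra removals are logged under `label`
.subset_aset <- function(aset, keep, label = NULL) {
  removed <- sum(!keep)
  log <- aset$filter_log
  if (!is.null(label)) log[label] <- removed + if (label %in% names(log)) log[[label]] else 0L
  alignment_set(aset$reads[keep, , drop = FALSE],
                source_label = aset$source_label,
                filter_log = log, input_n = aset$input_n)
}

#' Write the filter report of an AlignmentSet as TSV
#'
#' Columns: `filter_name`, `reads_removed`, `reads_remaining`, with one row
#' per filter in application order.
#'
#' @param aset an `AlignmentSet`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_filter_report <- function(aset, path) {
  stopifnot(inherits(aset, "AlignmentSet"))
  remaining <- aset$input_n - cumsum(as.integer(aset$filter_log))
  df <- data.frame(filter_name = names(aset$filter_log),
                   reads_removed = as.integer(aset$filter_log),
                   reads_remaining = remaining)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
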