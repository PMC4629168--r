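#' 5' C-to-T substitution profile
#'
#' Counts, for each read position `i = 1..max_pos` measured from the read's
#' 5' end in read orientation, how many reads carry a reference cytosine at
#' that position (`ref_c_counts`) and how many of those read a thymine
#' (`ct_counts`). Forward-strand reads are walked left to right; reverse
#' reads are walked from the right edge of the alignment with both read and
#' reference bases complemented, so a reference G aligned to a read A is
#' counted as C-to-T in read orientation. Only aligned (non-gap) pairs
#' contribute; soft-clipped bases are skipped (position 1 is the first
#' aligned base) and reads shorter than `i` contribute nothing at `i`.
#' Mismatches other than C-to-T enter the denominator only.
#'
#' The per-position frequency `ct_counts/ref_c_counts` is the quantity whose
#' exponential decay toward the read interior is the molecular signature of
#' postmortem cytosine deamination.
#'
#' @param aset an [alignment_set()]
#' @param max_pos number of 5' positions to profile (default 20)
#' @return a `DamageProfile`: list with `positions`, `ref_c_counts`,
#'   `ct_counts`, `freq` (NA where the denominator is 0), `n_reads`,
#'   `source_label`
#' @export
substitution_profile <- function(aset, max_pos = 20L) {
  stopifnot(inherits(aset, "AlignmentSet"))
  if (!is.numeric(max_pos) || length(max_pos) != 1L || max_pos < 2)
    stop("'max_pos' must be a single integer >= 2")
  max_pos <- as.integer(max_pos)
  mats <- damage_matrices(aset, max_pos)
  .profile_from_counts(colSums(mats$refC), colSums(mats$ct),
                       n_reads = n_reads(aset),
                       source_label = aset$source_label)
}

.profile_from_counts <- function(ref_c, ct, n_reads = NA_integer_,
                                 source_label = "unlabelled") {
  freq <- ifelse(ref_c > 0, ct / ref_c, NA_real_)
  if (all(ref_c == 0))
    warning("no reference cytosines in the first ", length(ref_c),
            " positions; all frequencies undefined")
  structure(list(positions = seq_along(ref_c),
                 ref_c_counts = as.integer(ref_c),
                 ct_counts = as.integer(ct),
                 freq = freq,
                 n_reads = n_reads,
                 source_label = source_label),
            class = "DamageProfile")
}

#' Per-read damage indicator matrices
#'
#' Internal workhorse behind [substitution_profile()], exposed because the
#' resampling test reuses it: computing the two `n_reads x max_pos` logical
#' matrices (reference-C at oriented position i; C-to-T at oriented position
#' i) once per library lets each subsample profile be a column sum over a
#' row subset.
#'
#' @inheritParams substitution_profile
#' @return list with logical matrices `refC` and `ct`
#' @export
damage_matrices <- function(aset, max_pos = 20L) {
  rd <- aset$reads
  n <- nrow(rd)
  max_pos <- as.integer(max_pos)
  refC <- matrix(FALSE, n, max_pos)
  ct <- matrix(FALSE, n, max_pos)
  if (!n) return(list(refC = refC, ct = ct))
  len <- nchar(rd$core)
  fwd <- rd$strand == "+"
  for (i in seq_len(max_pos)) {
    qpos <- ifelse(fwd, i, len - i + 1L)
    ok <- i <= len
    qb <- substr(rd$core, qpos, qpos)
    rb <- substr(rd$ref, qpos, qpos)
    qb[!fwd] <- .comp(qb[!fwd])
    rb[!fwd] <- .comp(rb[!fwd])
    isC <- ok & rb == "C"
    refC[, i] <- isC
    ct[, i] <- isC & qb == "T"
  }
  list(refC = refC, ct = ct)
}

#' @export
print.DamageProfile <- function(x, ...) {
  cat(sprintf("DamageProfile '%s': %d positions, %s reads\n",
              x$source_label, length(x$positions),
              ifelse(is.na(x$n_reads), "?", x$n_reads)))
  f1 <- x$freq[1]
  cat(sprintf("  C-to-T at position 1: %s\n",
              ifelse(is.na(f1), "undefined", sprintf("%.4f", f1))))
  invisible(x)
}

#' Write / read a damage profile as TSV
#'
#' Columns `position`, `ref_c_count`, `ct_count`, `frequency`; undefined
#' frequencies are written as `NA`. `read_profile()` restores an identical
#' `DamageProfile`.
#'
#' @param profile a `DamageProfile`
#' @param path file path
#' @return `path` invisibly (`write_profile`); a `DamageProfile`
#'   (`read_profile`)
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "DamageProfile"))
  df <- data.frame(position = profile$positions,
                   ref_c_count = profile$ref_c_counts,
                   ct_count = profile$ct_counts,
                   frequency = profile$freq)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "NA", stringsAsFactors = FALSE)
  need <- c("position", "ref_c_count", "ct_count", "frequency")
  if (!all(need %in% names(df)))
    stop("profile TSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$position), ]
  suppressWarnings(
    .profile_from_counts(df$ref_c_count, df$ct_count,
                         source_label = basename(path)))
}

#' Plot a damage profile with its fitted exponential
#'
#' Position against C-to-T frequency, with the fitted
#' `N * exp(-rate * x)` curve overlaid when a fit is supplied.
#'
#' @param profile a `DamageProfile`
#' @param fit optional `ExpFitResult` from [fit_exponential()]
#' @param ... passed to [plot()]
#' @return invisibly, NULL
#' @export
plot_profile <- function(profile, fit = NULL, ...) {
  stopifnot(inherits(profile, "DamageProfile"))
  plot(profile$positions, profile$freq,
       xlab = "position from 5' end",
       ylab = "C-to-T substitution frequency",
       pch = 19, ...)
  if (!is.null(fit) && isTRUE(fit$converged)) {
    xx <- seq(min(profile$positions), max(profile$positions), length.out = 200)
    graphics::lines(xx, fit$amplitude_N * exp(-fit$rate * xx), col = "red")
    graphics::legend("topright", bty = "n",
                     legend = sprintf("gof p = %.3g", fit$gof_p))
  }
  invisible(NULL)
}
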