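#' Empirical distribution of goodness-of-fit p-values by resampling
#'
#' Draws `M` subsamples of `n` reads, uniformly with replacement, from a
#' reference library, and records for each the goodness-of-fit p-value of
#' the exponential decay fit to its 5' C-to-T profile. This is the
#' empirical yardstick of the authenticity test: a bona fide ancient
#' library yields a distribution concentrated near 0, a modern library a
#' roughly uniform one.
#'
#' Subsamples whose fit fails contribute a p-value of 1 (no evidence of
#' decay); their count is reported in `n_failed_fits` so the sensitivity of
#' downstream results to the policy can be judged.
#'
#' @param reference a non-empty [alignment_set()]
#' @param n subsample size in reads (the paper-scale default for small test
#'   sets is 150)
#' @param M number of subsamples, default 10000
#' @param seed integer seed making the distribution reproducible
#' @param max_pos number of 5' positions profiled, default 20
#' @return a `PValueDistribution`: list with `values` (length `M`),
#'   `subsample_size`, `n_subsamples`, `seed`, `source_label`,
#'   `n_failed_fits`
#' @export
build_distribution <- function(reference, n, M = 10000L, seed = NULL,
                               max_pos = 20L) {
  stopifnot(inherits(reference, "AlignmentSet"))
  if (!n_reads(reference)) stop("reference AlignmentSet is empty")
  .assert_scalar_num(n, "n", 1)
  .assert_scalar_num(M, "M", 1)
  n <- as.integer(n); M <- as.integer(M)

  mats <- damage_matrices(reference, max_pos)
  N <- n_reads(reference)
  x_all <- seq_len(max_pos)

  values <- numeric(M)
  failed <- 0L
  .with_seed(seed, {
    for (j in seq_len(M)) {
      idx <- sample.int(N, n, replace = TRUE)
      refc <- colSums(mats$refC[idx, , drop = FALSE])
      ct <- colSums(mats$ct[idx, , drop = FALSE])
      ok <- refc > 0
      if (sum(ok) < 2L) {
        values[j] <- 1
        failed <- failed + 1L
        next
      }
      fit <- .fit_xy(x_all[ok], ct[ok] / refc[ok])
      if (!fit$converged) failed <- failed + 1L
      values[j] <- fit$gof_p
    }
  })
  structure(list(values = values, subsample_size = n, n_subsamples = M,
                 seed = seed, source_label = reference$source_label,
                 n_failed_fits = failed),
            class = "PValueDistribution")
}

#' @export
print.PValueDistribution <- function(x, ...) {
  cat(sprintf(paste0("PValueDistribution from '%s': %d subsamples of %d ",
                     "reads\n  median gof p = %.4g, %d failed fits\n"),
              x$source_label, x$n_subsamples, x$subsample_size,
              stats::median(x$values), x$n_failed_fits))
  invisible(x)
}

#' Empirical p-value of a test set against a reference distribution
#'
#' Ancient mode counts reference subsamples whose goodness-of-fit p-value
#' is greater than or equal to `p_test` (null hypothesis: the test reads
#' carry ancient-DNA damage comparable to, or more pronounced than, the
#' reference library). Modern mode counts subsamples less than or equal to
#' `p_test` (null: the test reads match the absence of damage seen in
#' modern DNA). Both comparisons are inclusive. The empirical p-value is
#' that count divided by the number of subsamples, so its resolution is
#' `1/M`; a value of 0 is printed as `< 1/M`.
#'
#' @param p_test goodness-of-fit p-value of the test read set
#' @param dist a `PValueDistribution`
#' @param mode `"ancient"` or `"modern"`
#' @return an `AuthTestResult`: list with `mode`, `p_test`, `empirical_p`,
#'   `count_extreme`, `n_subsamples` plus provenance fields
#' @export
empirical_pvalue <- function(p_test, dist, mode = c("ancient", "modern")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dist, "PValueDistribution"))
  .assert_scalar_num(p_test, "p_test", 0, 1)
  count <- if (mode == "ancient") sum(dist$values >= p_test)
           else sum(dist$values <= p_test)
  structure(list(mode = mode,
                 p_test = p_test,
                 empirical_p = count / dist$n_subsamples,
                 count_extreme = as.integer(count),
                 n_subsamples = dist$n_subsamples,
                 subsample_size = dist$subsample_size,
                 reference_label = dist$source_label,
                 seed = dist$seed,
                 test_label = NA_character_),
            class = "AuthTestResult")
}

#' @export
print.AuthTestResult <- function(x, ...) {
  ep <- if (x$empirical_p == 0)
    sprintf("< %g", 1 / x$n_subsamples) else sprintf("%.4g", x$empirical_p)
  cat(sprintf(paste0("Authenticity test (%s mode)\n",
                     "  test gof p-value: %.4g\n",
                     "  empirical p = %s (%d / %d subsamples of %d reads ",
                     "from '%s')\n"),
              x$mode, x$p_test, ep, x$count_extreme, x$n_subsamples,
              x$subsample_size, x$reference_label))
  invisible(x)
}

#' Run the full authenticity test
#'
#' Computes the goodness-of-fit p-value of the whole test set
#' (profile, exponential fit, one-sided t-test), builds the reference
#' p-value distribution at a subsample size matched to the test set
#' (or `n` if given), and scores the test value against it.
#'
#' @param test_set test reads as an [alignment_set()]
#' @param reference reference library as an [alignment_set()]
#' @param mode `"ancient"` or `"modern"` (which null hypothesis the
#'   reference represents)
#' @param n subsample size; defaults to the number of test reads
#' @param M number of subsamples, default 10000
#' @param seed integer seed
#' @param max_pos number of 5' positions profiled, default 20
#' @return an `AuthTestResult` (see [empirical_pvalue()])
#' @export
run_test <- function(test_set, reference, mode = c("ancient", "modern"),
                     n = NULL, M = 10000L, seed = NULL, max_pos = 20L) {
  mode <- match.arg(mode)
  stopifnot(inherits(test_set, "AlignmentSet"))
  if (!n_reads(test_set)) stop("test AlignmentSet is empty")
  if (is.null(n)) n <- n_reads(test_set)
  p_test <- fit_exponential(substitution_profile(test_set, max_pos))$gof_p
  dist <- build_distribution(reference, n = n, M = M, seed = seed,
                             max_pos = max_pos)
  res <- empirical_pvalue(p_test, dist, mode)
  res$test_label <- test_set$source_label
  res
}

#' Power curve of the authenticity test
#'
#' For each subsample size `s` in `sizes`, builds one reference
#' distribution of `M` goodness-of-fit p-values at subsample size `s`, then
#' `repeats` times draws `s` reads with replacement from the test library,
#' computes that draw's goodness-of-fit p-value and scores it against the
#' distribution. Emulates the test-performance evaluation in which both an
#' ancient and a modern library are tested against a bona fide ancient
#' reference while the number of sampled reads varies.
#'
#' @param test_library library the test draws come from
#' @param reference library the p-value distributions are built from
#' @param sizes integer vector of subsample sizes (paper scale:
#'   `seq(100, 1000, by = 100)`)
#' @param repeats test repetitions per size (paper scale: 1000)
#' @param mode `"ancient"` or `"modern"`
#' @param M subsamples per reference distribution, default 1000
#' @param seed integer seed
#' @param max_pos number of 5' positions profiled
#' @return data.frame with columns `size`, `replicate`, `empirical_p`
#'   (long format, one row per test repetition)
#' @export
power_curve <- function(test_library, reference, sizes, repeats,
                        mode = c("ancient", "modern"), M = 1000L,
                        seed = NULL, max_pos = 20L) {
  mode <- match.arg(mode)
  stopifnot(inherits(test_library, "AlignmentSet"),
            inherits(reference, "AlignmentSet"))
  if (!length(sizes)) stop("'sizes' must be non-empty")
  .assert_scalar_num(repeats, "repeats", 1)

  tmats <- damage_matrices(test_library, max_pos)
  Ntest <- n_reads(test_library)
  x_all <- seq_len(max_pos)

  out <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    s <- as.integer(sizes[k])
    dist <- build_distribution(reference, n = s, M = M,
                               seed = .child_seed(seed, 2L * k),
                               max_pos = max_pos)
    ep <- numeric(repeats)
    .with_seed(.child_seed(seed, 2L * k + 1L), {
      for (r in seq_len(repeats)) {
        idx <- sample.int(Ntest, s, replace = TRUE)
        refc <- colSums(tmats$refC[idx, , drop = FALSE])
        ct <- colSums(tmats$ct[idx, , drop = FALSE])
        ok <- refc > 0
        p_test <- if (sum(ok) < 2L) 1 else .fit_xy(x_all[ok], ct[ok] / refc[ok])$gof_p
        ep[r] <- empirical_pvalue(p_test, dist, mode)$empirical_p
      }
    })
    out[[k]] <- data.frame(size = s, replicate = seq_len(repeats),
                           empirical_p = ep)
  }
  do.call(rbind, out)
}

#' Per-size summary of a power curve
#'
#' @param pc data.frame from [power_curve()]
#' @return data.frame with per-size `n`, `mean`, `q25`, `median`, `q75`
#' @export
summarize_power <- function(pc) {
  stopifnot(all(c("size", "empirical_p") %in% names(pc)))
  agg <- function(f) tapply(pc$empirical_p, pc$size, f)
  sizes <- sort(unique(pc$size))
  data.frame(size = sizes,
             n = as.integer(agg(length)),
             mean = as.numeric(agg(mean)),
             q25 = as.numeric(agg(function(v) stats::quantile(v, 0.25))),
             median = as.numeric(agg(stats::median)),
             q75 = as.numeric(agg(function(v) stats::quantile(v, 0.75))))
}

#' Write a p-value distribution (TSV values + JSON header)
#'
#' The values go to `path` one per line under a `gof_p` header column; the
#' provenance (subsample size, number of subsamples, seed, source, failed
#' fits) goes to `paste0(path, ".json")`.
#'
#' @param dist a `PValueDistribution`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "PValueDistribution"))
  utils::write.table(data.frame(gof_p = dist$values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hdr <- dist[c("subsample_size", "n_subsamples", "seed", "source_label",
                "n_failed_fits")]
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write an authenticity test result as JSON
#'
#' @param result an `AuthTestResult`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_test_result <- function(result, path) {
  stopifnot(inherits(result, "AuthTestResult"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
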