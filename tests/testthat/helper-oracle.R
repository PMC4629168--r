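# Independent oracles used to cross-check the implementation. These are
# deliberately naive: exhaustive per-base loops for damage counting and a
# dense profiled grid search for the exponential fit. They share no code
# with the package internals they verify.

# Exhaustive per-base recount of the 5' C-to-T profile.
brute_profile <- function(aset, max_pos = 20L) {
  revcomp1 <- function(s)
    paste(rev(strsplit(chartr("ACGTN-", "TGCAN-", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  ref_c <- integer(max_pos); ct <- integer(max_pos)
  rd <- aset$reads
  for (i in seq_len(nrow(rd))) {
    s <- rd$core[i]; r <- rd$ref[i]
    if (rd$strand[i] == "-") {
      s <- revcomp1(s); r <- revcomp1(r)
    }
    for (k in seq_len(min(max_pos, nchar(s)))) {
      if (substr(r, k, k) == "C") {
        ref_c[k] <- ref_c[k] + 1L
        if (substr(s, k, k) == "T") ct[k] <- ct[k] + 1L
      }
    }
  }
  list(ref_c_counts = ref_c, ct_counts = ct)
}

# Dense grid search over (N, rate) for y ~ N * exp(-rate * x), using the
# conditional-linearity of N to profile the rate on successively refined
# grids, plus a finite-difference Jacobian for the rate standard error and
# the one-sided t-test p-value.
oracle_exp_fit <- function(x, y) {
  rss_at <- function(rate) {
    e <- exp(-rate * x)
    N <- sum(y * e) / sum(e * e)
    c(N = N, rss = sum((y - N * e)^2))
  }
  lo <- -2; hi <- 4
  for (round in 1:6) {
    grid <- seq(lo, hi, length.out = 801)
    rss <- vapply(grid, function(r) rss_at(r)["rss"], numeric(1))
    best <- which.min(rss)
    step <- grid[2] - grid[1]
    lo <- grid[best] - 2 * step
    hi <- grid[best] + 2 * step
  }
  rate <- grid[best]
  N <- rss_at(rate)["N"]
  rss <- rss[best]
  n <- length(y); df <- n - 2L
  h <- 1e-6
  J <- cbind(exp(-rate * x),
             (N * exp(-(rate + h) * x) - N * exp(-(rate - h) * x)) / (2 * h))
  sigma2 <- rss / df
  covm <- sigma2 * solve(crossprod(J))
  se <- sqrt(covm[2, 2])
  tval <- rate / se
  list(amplitude_N = unname(N), rate = rate, rate_se = se, t_value = tval,
       df = df, gof_p = stats::pt(tval, df, lower.tail = FALSE), rss = rss)
}
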