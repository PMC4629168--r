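# internal helpers shared across modules

# complement that preserves gaps and N
.comp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

.revstr <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.revcomp <- function(x) .revstr(.comp(x))

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed that stays inside 32-bit integer range
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 1000003 * as.double(k)) %% 2147483647)
}

.assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
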