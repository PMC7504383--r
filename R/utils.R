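# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. `seed = NULL` means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Truncated-normal draws by rejection; bounds are strict enough and sds small
# enough everywhere in this package that acceptance rates stay near 1.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper, sd >= 0)
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal rejection sampler failed to converge")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
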