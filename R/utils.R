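# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

# Truncated-Gaussian draws (+/- 2 sd), redrawing out-of-range values.
rtruncnorm2 <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  repeat {
    bad <- which(abs(x) > 2 * sd)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), 0, sd)
  }
  x
}
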