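# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
logspace <- function(from, to, n) 10^seq(log10(from), log10(to), length.out = n)

# Coefficient of determination against the mean of the observations.
r_squared <- function(obs, fit) {
  sstot <- sum((obs - mean(obs))^2)
  ssres <- sum((obs - fit)^2)
  if (sstot == 0) return(if (ssres == 0) 1 else -Inf)
  1 - ssres / sstot
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
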