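# run expr with a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# moving average with edge padding (odd window)
smooth_ma <- function(x, k) {
  if (k <= 1 || length(x) < 3) return(x)
  k <- min(k, length(x) - (length(x) + 1) %% 2)
  if (k %% 2 == 0) k <- k + 1
  h <- (k - 1) / 2
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1):(h + length(x))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
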