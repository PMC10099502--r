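## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's random-number stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## round-half-up (the printed-percentage convention), as opposed to the
## IEEE round-half-even of base round()
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## group-wise maximum of a vector; `group` must be integer codes 1..n
group_max <- function(x, group, n) {
  out <- rep(-Inf, n)
  ## vapply over split is fast enough at the sizes used here
  sp <- split(x, group)
  out[as.integer(names(sp))] <- vapply(sp, max, numeric(1))
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic per-stage seeds spawned from one master seed
stage_seeds <- function(master_seed, n = 8L) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
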