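## Halton quasi-random draws for maximum simulated likelihood.

#' Configuration for simulation draws
#'
#' Settings for the quasi-random draws used by [mixed_logit()].  One Halton
#' sequence is generated per random coefficient (one prime base per
#' dimension); the first `burn` points are discarded, the sequence is
#' shuffled with a seeded permutation (shuffled Halton), and the points are
#' mapped through the standard normal quantile function.
#'
#' @param n_draws draws per chooser per random coefficient (default 500).
#' @param burn initial Halton points discarded per dimension (default 10).
#' @param seed integer seed for the shuffling permutation.
#' @param primes optional integer vector of prime bases; extended
#'   automatically when more dimensions are needed.
#' @return An object of class `halton_config`.
#' @examples
#' cfg <- halton_config(n_draws = 50, seed = 1)
#' dr <- halton_draws(cfg, n_choosers = 4, n_random_coefs = 2)
#' dim(dr)  # 4 x 50 x 2
#' @export
halton_config <- function(n_draws = 500L, burn = 10L, seed = 1L,
                          primes = NULL) {
  n_draws <- as.integer(n_draws)
  burn <- as.integer(burn)
  if (n_draws < 1L) stopf("n_draws must be >= 1")
  if (burn < 0L) stopf("burn must be >= 0")
  if (!is.null(primes) && anyDuplicated(primes))
    stopf("prime bases must be distinct")
  structure(list(n_draws = n_draws, burn = burn, seed = as.integer(seed),
                 primes = primes),
            class = "halton_config")
}

## radical-inverse of integers k in the given base, vectorised over k
radical_inverse <- function(k, base) {
  r <- numeric(length(k))
  f <- 1 / base
  k <- as.double(k)
  while (any(k > 0)) {
    r <- r + f * (k %% base)
    k <- k %/% base
    f <- f / base
  }
  r
}

#' Raw Halton sequence
#'
#' First `n` points of the Halton sequence in a given base (indices start
#' at 1, so the base-2 sequence opens 0.5, 0.25, 0.75, ...), after dropping
#' `burn` initial points.
#'
#' @param n number of points returned.
#' @param base integer base (usually prime).
#' @param burn points discarded from the start of the sequence.
#' @return Numeric vector in (0, 1).
#' @export
halton_sequence <- function(n, base, burn = 0L) {
  radical_inverse(seq.int(burn + 1L, burn + n), base)
}

first_primes <- function(n) {
  ## smallest n primes; enough for any realistic number of random coefs
  cand <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L,
            43L, 47L, 53L, 59L, 61L, 67L, 71L)
  while (length(cand) < n) {
    k <- cand[length(cand)] + 2L
    repeat {
      if (all(k %% cand[cand * cand <= k] != 0L)) break
      k <- k + 2L
    }
    cand <- c(cand, k)
  }
  cand[seq_len(n)]
}

#' Standard-normal Halton draws for simulated likelihood
#'
#' Generates an `n_choosers x n_draws x n_random_coefs` array of
#' quasi-random standard-normal draws.  Each dimension uses its own prime
#' base; the pooled sequence is shuffled with a seeded permutation before
#' being blocked by chooser, which breaks the high correlation between
#' coordinates of high-prime Halton sequences.
#'
#' @inheritParams halton_sequence
#' @param cfg a [halton_config()].
#' @param n_choosers number of choosers (first array dimension).
#' @param n_random_coefs number of random coefficients (third dimension).
#' @return Numeric array, standard-normal scale; deterministic given `cfg`.
#' @export
halton_draws <- function(cfg, n_choosers, n_random_coefs) {
  stopifnot(inherits(cfg, "halton_config"))
  if (n_random_coefs < 1L) stopf("need at least one random coefficient")
  primes <- cfg$primes %||% first_primes(n_random_coefs)
  if (length(primes) < n_random_coefs)
    primes <- c(primes, setdiff(first_primes(n_random_coefs + length(primes)),
                                primes))[seq_len(n_random_coefs)]
  ntot <- n_choosers * cfg$n_draws
  out <- array(NA_real_, dim = c(n_choosers, cfg$n_draws, n_random_coefs))
  perms <- with_seed(cfg$seed,
                     replicate(n_random_coefs, sample.int(ntot), simplify = FALSE))
  for (j in seq_len(n_random_coefs)) {
    h <- halton_sequence(ntot, primes[j], burn = cfg$burn)
    out[, , j] <- matrix(stats::qnorm(h[perms[[j]]]),
                         nrow = n_choosers, ncol = cfg$n_draws, byrow = TRUE)
  }
  out
}
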