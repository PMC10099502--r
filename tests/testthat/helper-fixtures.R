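# Shared fixtures, built in code.

# A tiny hand-made choice problem: `n` choosers, `m` alternatives each,
# two attributes, one chosen alternative per chooser.
tiny_choice_data <- function(n = 5L, m = 3L, seed = 1L) {
  set.seed(seed)
  data.frame(
    respondent_id = rep(sprintf("r%02d", seq_len(n)), each = m),
    outlet_id = rep(sprintf("o%d", seq_len(m)), n),
    distance_km = round(runif(n * m, 0.2, 3), 3),
    methods_offered = sample(1:6, n * m, replace = TRUE),
    chosen = as.vector(replicate(n, sample(c(1L, rep(0L, m - 1L))))))
}

# Weighted conditional-logit log-likelihood by explicit enumeration over
# alternatives (independent oracle for the estimation code).
bruteforce_clogit_ll <- function(beta, data, attributes, w = NULL) {
  ids <- unique(data$respondent_id)
  if (is.null(w)) w <- rep(1, length(ids))
  ll <- 0
  for (i in seq_along(ids)) {
    rows <- data[data$respondent_id == ids[i], , drop = FALSE]
    u <- as.matrix(rows[, attributes]) %*% beta
    ll <- ll + w[i] * (u[rows$chosen == 1] - log(sum(exp(u))))
  }
  as.numeric(ll)
}

# Simulated mixed-logit log-likelihood by direct per-draw enumeration
# (independent of the package's kernel).
bruteforce_msl_ll <- function(beta, s, data, attributes, random_attributes,
                              draws, w = NULL) {
  ids <- unique(data$respondent_id)
  if (is.null(w)) w <- rep(1, length(ids))
  R <- ncol(draws)
  ll <- 0
  for (i in seq_along(ids)) {
    rows <- data[data$respondent_id == ids[i], , drop = FALSE]
    Z <- as.matrix(rows[, attributes])
    pc <- 0
    for (r in seq_len(R)) {
      b <- beta
      for (j in seq_along(random_attributes)) {
        k <- match(random_attributes[j], attributes)
        b[k] <- b[k] + s[j] * draws[i, r, j]
      }
      u <- Z %*% b
      p <- exp(u) / sum(exp(u))
      pc <- pc + p[rows$chosen == 1]
    }
    ll <- ll + w[i] * log(pc / R)
  }
  as.numeric(ll)
}

kenya_attrs <- c("distance_km", "methods_offered", "open7",
                 "stockout_injectables", "provider_trained", "fp_signage",
                 "public", "pharmacy")
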