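## Willingness to travel: attribute coefficients re-expressed in km.
##
## Choice-model coefficients are scale dependent, but the ratio of an
## attribute's coefficient to the distance coefficient is not: wtt_k =
## -beta_k / beta_d is the extra Euclidean distance (km) a chooser would
## accept for one unit of attribute k.  With beta_d < 0, valued attributes
## get positive wtt.  Ratios use the estimated coefficient means only, so
## one wtt per attribute is reported per sample.

wtt_point <- function(beta, distance_attr) {
  bd <- beta[[distance_attr]]
  if (!is.finite(bd) || abs(bd) < 1e-8)
    stopf("distance coefficient not identified")
  others <- setdiff(names(beta), distance_attr)
  setNames(-beta[others] / bd, others)
}

#' Willingness to travel per attribute
#'
#' Point estimates of willingness to travel, `-beta_k / beta_d`, in km per
#' unit of each non-distance attribute.
#'
#' @param fit an `fpc_mixlogit` or `fpc_clogit` fit (anything with a
#'   `coef()` vector containing the distance attribute).
#' @param distance_attr name of the distance coefficient (default
#'   `"distance_km"`).
#' @return A data frame of class `wtt_table` with columns `attribute` and
#'   `wtt_km`.
#' @examples
#' willingness_to_travel(
#'   structure(list(coefficients = c(distance_km = -0.5, fp_signage = 0.3)),
#'             class = "fpc_clogit"))  # 0.6 km
#' @export
willingness_to_travel <- function(fit, distance_attr = "distance_km") {
  beta <- stats::coef(fit)
  if (!distance_attr %in% names(beta))
    stopf("'%s' not among the fitted attributes", distance_attr)
  r <- wtt_point(beta, distance_attr)
  structure(data.frame(attribute = names(r), wtt_km = unname(r),
                       stringsAsFactors = FALSE),
            class = c("wtt_table", "data.frame"))
}

delta_ratio_var <- function(bk, bd, vk, vd, ckd) {
  vk / bd^2 + bk^2 * vd / bd^4 - 2 * bk * ckd / bd^3
}

#' Willingness to travel with confidence intervals
#'
#' Adds a confidence interval to each willingness-to-travel ratio, either by
#' the delta method (first-order variance of the ratio, deterministic) or by
#' simulation (Krinsky-Robb style: draw coefficient vectors from the normal
#' approximation of the estimates, form ratios, take empirical quantiles).
#'
#' @inheritParams willingness_to_travel
#' @param level confidence level (default 0.95).
#' @param method `"delta"` (default) or `"simulation"`.
#' @param n_sim draws for the simulation method (default 10000).
#' @param seed seed for the simulation method.
#' @return A `wtt_table` data frame with columns `attribute`, `wtt_km`,
#'   `ci_low`, `ci_high`, `method`.
#' @export
wtt_confidence_interval <- function(fit, distance_attr = "distance_km",
                                    level = 0.95,
                                    method = c("delta", "simulation"),
                                    n_sim = 10000L, seed = 1L) {
  method <- match.arg(method)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)[names(beta), names(beta), drop = FALSE]
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stopf("estimate covariance is not positive semi-definite")
  pt <- wtt_point(beta, distance_attr)
  others <- names(pt)
  bd <- beta[[distance_attr]]
  alpha <- 1 - level
  if (method == "delta") {
    se <- vapply(others, function(k)
      sqrt(max(0, delta_ratio_var(beta[[k]], bd, V[k, k],
                                  V[distance_attr, distance_attr],
                                  V[k, distance_attr]))), numeric(1))
    z <- stats::qnorm(1 - alpha / 2)
    lo <- pt - z * se; hi <- pt + z * se
  } else {
    draws <- with_seed(seed, {
      ch <- chol(V + diag(1e-12 * max(1, max(abs(diag(V)))), nrow(V)))
      matrix(stats::rnorm(n_sim * length(beta)), n_sim) %*% ch
    })
    draws <- sweep(draws, 2, beta, "+")
    colnames(draws) <- names(beta)
    lo <- hi <- setNames(numeric(length(others)), others)
    for (k in others) {
      r <- -draws[, k] / draws[, distance_attr]
      qs <- stats::quantile(r, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      lo[k] <- qs[1]; hi[k] <- qs[2]
    }
  }
  structure(data.frame(attribute = others, wtt_km = unname(pt),
                       ci_low = unname(lo), ci_high = unname(hi),
                       method = method, stringsAsFactors = FALSE),
            class = c("wtt_table", "data.frame"))
}

#' Forest plot of willingness-to-travel estimates
#'
#' @param x a `wtt_table` with confidence intervals.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.wtt_table <- function(x, ...) {
  n <- nrow(x)
  has_ci <- all(c("ci_low", "ci_high") %in% names(x))
  xr <- if (has_ci) range(x$ci_low, x$ci_high, 0) else range(x$wtt_km, 0)
  graphics::plot(x$wtt_km, seq_len(n), xlim = xr, ylim = c(0.5, n + 0.5),
                 pch = 19, yaxt = "n", xlab = "Willingness to travel (km)",
                 ylab = "", ...)
  graphics::axis(2, at = seq_len(n), labels = x$attribute, las = 1,
                 cex.axis = 0.8)
  if (has_ci)
    graphics::segments(x$ci_low, seq_len(n), x$ci_high, seq_len(n))
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
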