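## Multinomial logit for method-use / linkage category, and the
## inverse-probability weights derived from it.
##
## The six categories are: 1 no method (reference), 2 traditional,
## 3 long-acting not linked, 4 short-acting not linked, 5 long-acting
## linked, 6 short-acting linked.  Estimation is for the full surveyed
## population; the fitted probabilities of the two linked categories give
## the selection weights for the outlet-choice models.

mnl_ll <- function(Bvec, X, Yind, J) {
  p <- ncol(X)
  B <- matrix(Bvec, p, J - 1)
  eta <- X %*% B
  m <- pmax(apply(eta, 1, max), 0)
  lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
  sum(rowSums(Yind * eta)) - sum(lse)
}

mnl_grad <- function(Bvec, X, Yind, J) {
  p <- ncol(X)
  B <- matrix(Bvec, p, J - 1)
  eta <- X %*% B
  m <- pmax(apply(eta, 1, max), 0)
  den <- exp(-m) + rowSums(exp(eta - m))
  P <- exp(eta - m) / den
  as.vector(crossprod(X, Yind - P))
}

#' Multinomial logit for method-use and linkage status
#'
#' Maximum-likelihood multinomial logit with the first category as
#' reference.  Covariates are standardised internally (the likelihood is
#' globally concave, so a quasi-Newton optimiser from a zero start finds
#' the optimum); estimates are mapped back to the original scale.
#' Standard errors come from the inverse observed information, or a robust
#' sandwich if requested.
#'
#' @param formula model formula; the response must be the category, an
#'   integer in `1..J` or a factor whose first level is the reference.
#' @param data data frame of respondents (one row each), e.g. the
#'   respondent table joined to [summarize_environment()] output.
#' @param vcov_type `"hessian"` (default, inverse observed information) or
#'   `"sandwich"`.
#' @return An object of class `fpc_mnl`: coefficient matrix (non-reference
#'   categories x covariates), covariance, log-likelihood (and that of the
#'   intercept-only model), n.  Methods: `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `predict`.
#' @examples
#' site <- site_preset("kenya", n_respondents = 400)
#' study <- simulate_study(site, seed = 3)
#' fit <- mnl(category ~ educ_college + married + parity,
#'            data = study$respondents)
#' head(predict(fit))
#' @export
mnl <- function(formula, data, vcov_type = c("hessian", "sandwich")) {
  vcov_type <- match.arg(vcov_type)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  J <- max(y)
  if (J < 2) stopf("need at least two categories")
  if (!all(seq_len(J) %in% y))
    stopf("every category in 1..%d needs at least one observation", J)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("design matrix rank-deficient (column '%s' redundant)",
          colnames(X)[qrX$pivot[qrX$rank + 1]])
  ## standardise non-intercept columns
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  has_int <- "(Intercept)" %in% colnames(X)
  for (k in seq_len(ncol(X))) {
    if (colnames(X)[k] == "(Intercept)") next
    ctr[k] <- if (has_int) mean(X[, k]) else 0
    s <- stats::sd(X[, k]); scl[k] <- if (s > 0) s else 1
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- nrow(X); p <- ncol(X)
  Yind <- matrix(0, n, J - 1)
  for (j in 2:J) Yind[, j - 1] <- as.numeric(y == j)
  opt <- stats::optim(numeric(p * (J - 1)),
                      fn = function(b) -mnl_ll(b, Xs, Yind, J),
                      gr = function(b) -mnl_grad(b, Xs, Yind, J),
                      method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-14))
  par <- newton_polish(function(b) -mnl_grad(b, Xs, Yind, J), opt$par)
  Bs <- matrix(par, p, J - 1)
  if (max(abs(Bs)) > 15) {
    bad <- which(abs(Bs) == max(abs(Bs)), arr.ind = TRUE)[1, 1]
    stopf("possible perfect separation on covariate '%s'", colnames(X)[bad])
  }
  ## map back: beta_k = beta_k_std / scale_k; intercept absorbs the centers
  B <- Bs / scl
  if (has_int) {
    ii <- which(colnames(X) == "(Intercept)")
    B[ii, ] <- Bs[ii, ] - colSums(B[-ii, , drop = FALSE] * ctr[-ii])
  }
  dimnames(B) <- list(colnames(X), paste0("cat", 2:J))
  ## covariance on the original scale via numeric hessian of the gradient
  Hn <- numeric_hessian(function(b) mnl_grad(b, X, Yind, J), as.vector(B))
  Vh <- inv_neg_hessian(Hn)
  V <- Vh
  if (vcov_type == "sandwich") {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    P <- exp(eta - m) / (exp(-m) + rowSums(exp(eta - m)))
    Sc <- matrix(0, n, p * (J - 1))
    for (j in seq_len(J - 1))
      Sc[, ((j - 1) * p + 1):(j * p)] <- X * (Yind[, j] - P[, j])
    V <- Vh %*% crossprod(Sc) %*% Vh
  }
  pn <- as.vector(outer(colnames(X), paste0("cat", 2:J),
                        function(a, b) paste(b, a, sep = ":")))
  dimnames(V) <- list(pn, pn)
  ll <- mnl_ll(as.vector(B), X, Yind, J)
  ## intercept-only log-likelihood for reference
  tab <- tabulate(y, J) / n
  ll0 <- sum(tabulate(y, J) * log(tab))
  structure(list(coefficients = t(B), vcov = V, logLik = ll, logLik0 = ll0,
                 n = n, J = J, formula = formula, xlevels = NULL,
                 terms = attr(mf, "terms"),
                 se = matrix(sqrt(pmax(diag(V), 0)), p, J - 1,
                             dimnames = dimnames(B)) |> t(),
                 grad_max = max(abs(mnl_grad(as.vector(Bs), Xs, Yind, J))),
                 vcov_type = vcov_type),
            class = "fpc_mnl")
}

#' @export
print.fpc_mnl <- function(x, ...) {
  cat("Multinomial logit,", x$J, "categories (reference = 1), n =", x$n, "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  cat("Log-likelihood:", format(x$logLik),
      " (intercept-only:", format(x$logLik0), ")\n")
  invisible(x)
}

#' @export
summary.fpc_mnl <- function(object, ...) {
  z <- object$coefficients / object$se
  list(coefficients = object$coefficients, se = object$se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), logLik = object$logLik,
       n = object$n)
}

#' @export
coef.fpc_mnl <- function(object, ...) object$coefficients

#' @export
vcov.fpc_mnl <- function(object, ...) object$vcov

#' @export
logLik.fpc_mnl <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' Predicted category probabilities
#'
#' @param object an `fpc_mnl` fit.
#' @param newdata data frame with the model covariates (default: refit
#'   data not stored; supply explicitly).
#' @param ... unused.
#' @return Matrix n x J of probabilities; rows sum to 1.
#' @export
predict.fpc_mnl <- function(object, newdata, ...) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata)
  X <- stats::model.matrix(tt, mf)
  B <- t(object$coefficients)
  miss <- setdiff(rownames(B), colnames(X))
  if (length(miss))
    stopf("missing covariate column(s): %s", paste(miss, collapse = ", "))
  eta <- cbind(0, X %*% B[colnames(X), , drop = FALSE])
  m <- apply(eta, 1, max)
  P <- exp(eta - m)
  P <- P / rowSums(P)
  colnames(P) <- paste0("cat", seq_len(object$J))
  P
}

#' Inverse-probability weights for the linked sample
#'
#' For each respondent in the estimation (linked) categories, the raw
#' weight is the reciprocal of the fitted probability of her own observed
#' linked category; weights are then rescaled to mean 1 over the estimation
#' sample, which stabilises the weighted likelihood without changing
#' relative weighting.
#'
#' @param probs matrix of fitted category probabilities (n x J), e.g. from
#'   [predict.fpc_mnl()].
#' @param categories observed category per respondent (integer 1..J).
#' @param respondent_id ids aligned with `probs` rows.
#' @param estimation_categories categories forming the estimation sample
#'   (default `c(5, 6)`, the linked-user categories).
#' @param floor smallest admissible fitted probability; smaller values
#'   signal model misfit and raise an error listing the respondents.
#' @return Data frame `respondent_id`, `category`, `p_hat`, `weight_raw`,
#'   `weight` (normalised to mean 1), restricted to the estimation sample.
#' @export
compute_ipw <- function(probs, categories, respondent_id,
                        estimation_categories = c(5L, 6L), floor = 1e-6) {
  stopifnot(nrow(probs) == length(categories),
            length(respondent_id) == length(categories))
  keep <- categories %in% estimation_categories
  if (!any(keep)) stopf("no respondents in the estimation categories")
  p_hat <- probs[cbind(which(keep), categories[keep])]
  low <- p_hat < floor
  if (any(low))
    stopf("fitted category probability below %g for respondent(s): %s",
          floor, paste(respondent_id[keep][low], collapse = ", "))
  w_raw <- 1 / p_hat
  data.frame(respondent_id = respondent_id[keep],
             category = categories[keep],
             p_hat = p_hat, weight_raw = w_raw,
             weight = w_raw / mean(w_raw),
             stringsAsFactors = FALSE)
}
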