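## Conditional logit on radius-limited choice sets, with optional
## inverse-probability weights.  The log-likelihood is the IPW-weighted
## sum over choosers of log softmax(z'beta) over each chooser's
## alternatives; it is globally concave, so a quasi-Newton optimiser from a
## zero start is sufficient.

## Assemble the internal estimation representation from a long table.
## Rows are sorted by chooser; each chooser must have >= 2 alternatives and
## exactly one chosen row.
prep_choice_data <- function(data, attributes, chooser = "respondent_id",
                             weights = NULL) {
  miss <- setdiff(c(attributes, chooser, "chosen"), names(data))
  if (length(miss))
    stopf("choice data lack column(s): %s", paste(miss, collapse = ", "))
  ids <- unique(data[[chooser]])
  g <- match(data[[chooser]], ids)
  o <- order(g)
  data <- data[o, , drop = FALSE]
  g <- g[o]
  n <- length(ids)
  sizes <- tabulate(g, n)
  if (any(sizes < 2))
    stopf("every chooser needs >= 2 alternatives; %d chooser(s) have fewer",
          sum(sizes < 2))
  nch <- tapply(data$chosen, g, sum)
  if (any(nch != 1))
    stopf("every chooser needs exactly one chosen alternative")
  Z <- as.matrix(data[, attributes, drop = FALSE])
  storage.mode(Z) <- "double"
  if (anyNA(Z)) stopf("missing values in attributes")
  w <- rep(1, n)
  if (!is.null(weights)) {
    if (is.data.frame(weights)) {
      w <- weights$weight[match(ids, weights$respondent_id)]
      if (anyNA(w)) stopf("weights missing for some choosers")
    } else if (length(weights) == n) {
      w <- as.numeric(weights)
    } else stopf("weights must be an IPW table or one value per chooser")
    if (any(w <= 0)) stopf("weights must be positive")
  }
  chosen <- which(data$chosen == 1L)
  ## identification: attributes must vary within at least one choice set
  dev <- Z - rowsum(Z, g)[g, , drop = FALSE] / sizes[g]
  novar <- apply(abs(dev), 2, max) < 1e-12
  if (any(novar))
    stopf("attribute(s) constant within every choice set: %s",
          paste(attributes[novar], collapse = ", "))
  qrd <- qr(dev)
  if (qrd$rank < ncol(Z))
    stopf("attributes collinear within choice sets: %s",
          paste(attributes[qrd$pivot[(qrd$rank + 1):ncol(Z)]],
                collapse = ", "))
  list(Z = Z, group = g, chosen = chosen, n = n, ids = ids, w = w,
       sizes = sizes, attributes = attributes,
       gstart = c(0L, cumsum(sizes)),  # 0-based offsets for the C++ kernel
       scale = pmax(apply(abs(dev), 2, max), 1e-8))
}

## weighted conditional-logit log-likelihood and gradient at beta
clogit_ll <- function(beta, pp, gradient = TRUE) {
  eta <- drop(pp$Z %*% beta)
  m <- group_max(eta, pp$group, pp$n)
  e <- exp(eta - m[pp$group])
  denom <- drop(rowsum(e, pp$group))
  ll <- sum(pp$w * (eta[pp$chosen] - m - log(denom)))
  if (!gradient) return(list(ll = ll))
  P <- e / denom[pp$group]
  wvec <- numeric(length(eta))
  wvec[pp$chosen] <- pp$w
  grad <- drop(crossprod(pp$Z, wvec - pp$w[pp$group] * P))
  list(ll = ll, grad = grad, P = P)
}

## per-chooser score matrix at beta (for sandwich covariance)
clogit_scores <- function(beta, pp) {
  eta <- drop(pp$Z %*% beta)
  m <- group_max(eta, pp$group, pp$n)
  e <- exp(eta - m[pp$group])
  denom <- drop(rowsum(e, pp$group))
  P <- e / denom[pp$group]
  zbar <- rowsum(P * pp$Z, pp$group)
  pp$w * (pp$Z[pp$chosen, , drop = FALSE] - zbar)
}

## central-difference Hessian from an analytic gradient
numeric_hessian <- function(gradfun, theta, h = 1e-5) {
  K <- length(theta)
  H <- matrix(0, K, K)
  for (k in seq_len(K)) {
    hk <- h * (1 + abs(theta[k]))
    up <- theta; up[k] <- up[k] + hk
    dn <- theta; dn[k] <- dn[k] - hk
    H[, k] <- (gradfun(up) - gradfun(dn)) / (2 * hk)
  }
  (H + t(H)) / 2
}

## symmetric inverse of the negative Hessian with eigenvalue clipping:
## near-singular information (e.g. a weakly identified random-coefficient
## scale) yields honestly huge variances in the weak direction instead of
## an indefinite covariance from an unstable solve()
inv_neg_hessian <- function(H, floor_frac = 1e-10) {
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lam <- -eg$values
  if (max(lam) <= 0)
    stopf("information matrix is not positive definite at the optimum")
  lam <- pmax(lam, floor_frac * max(lam))
  V <- eg$vectors %*% (t(eg$vectors) / lam)
  (V + t(V)) / 2
}

make_coef_table <- function(est, se) {
  z <- est / se
  data.frame(estimate = est, std_error = se, z = z,
             p_value = 2 * stats::pnorm(-abs(z)))
}

#' Conditional logit for outlet choice
#'
#' Fits McFadden's conditional logit by maximum likelihood on a long-format
#' choice-set table, optionally weighted by inverse-probability weights that
#' correct for selection into the linked sample.  Standard errors are robust
#' (sandwich) by default because IPW weighting invalidates the information
#' equality.
#'
#' @param data choice-set table (e.g. from [build_choice_sets()]) with one
#'   row per (chooser, alternative), a 0/1 `chosen` column and the attribute
#'   columns.
#' @param attributes character vector of attribute column names entering
#'   utility (include `"distance_km"`).
#' @param chooser name of the chooser id column (default `respondent_id`).
#' @param weights `NULL` for unit weights, an [compute_ipw()] table, or a
#'   numeric vector with one weight per chooser.
#' @param vcov_type `"sandwich"` (default) or `"hessian"` (inverse observed
#'   information).
#' @param reltol convergence tolerance passed to [stats::optim()].
#' @return An object of class `fpc_clogit` with methods `print`, `summary`,
#'   `coef`, `vcov`, `logLik` and `predict` (in-sample choice
#'   probabilities).
#' @examples
#' study <- simulate_study(site_preset("kenya", n_respondents = 150),
#'                         truth = truth_preset(random = FALSE), seed = 7,
#'                         all_linked = TRUE)
#' cs <- build_choice_sets(study$respondents, study$outlets, 3,
#'                         links = study$links)
#' fit <- cond_logit(cs, c("distance_km", "methods_offered", "public"))
#' coef(fit)
#' @export
cond_logit <- function(data, attributes, chooser = "respondent_id",
                       weights = NULL, vcov_type = c("sandwich", "hessian"),
                       reltol = 1e-12) {
  vcov_type <- match.arg(vcov_type)
  pp <- prep_choice_data(data, attributes, chooser, weights)
  fit <- clogit_optim(pp, reltol)
  beta <- fit$beta
  gr <- clogit_ll(beta, pp)
  H <- numeric_hessian(function(b) clogit_ll(b, pp)$grad, beta)
  Hinv <- inv_neg_hessian(H)
  V <- if (vcov_type == "sandwich") {
    S <- clogit_scores(beta, pp)
    Hinv %*% crossprod(S) %*% Hinv
  } else Hinv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(attributes, attributes)
  se <- sqrt(pmax(diag(V), 0))
  structure(list(coefficients = setNames(beta, attributes),
                 vcov = V, se = setNames(se, attributes),
                 logLik = gr$ll, n_choosers = pp$n,
                 n_rows = nrow(pp$Z),
                 weighted = !is.null(weights),
                 attributes = attributes, vcov_type = vcov_type,
                 convergence = fit$convergence,
                 grad_max = fit$grad_max_std,  # on internally scaled attributes
                 table = make_coef_table(setNames(beta, attributes), se),
                 pp = pp),
            class = "fpc_clogit")
}

## Newton refinement of a quasi-Newton solution: the BFGS stopping rule is
## on function change, while the optimum contract is a small gradient
newton_polish <- function(gradfun, theta, tol = 1e-9, max_steps = 8L) {
  for (it in seq_len(max_steps)) {
    g <- gradfun(theta)
    if (max(abs(g)) < tol) break
    H <- numeric_hessian(gradfun, theta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    theta <- theta - step
  }
  theta
}

## BFGS in scaled attribute space; separation guard on the scaled estimates
clogit_optim <- function(pp, reltol = 1e-12, start = NULL) {
  sc <- pp$scale
  Zs <- sweep(pp$Z, 2, sc, "/")
  pps <- pp; pps$Z <- Zs
  b0 <- if (is.null(start)) numeric(ncol(Zs)) else start * sc
  opt <- stats::optim(b0,
                      fn = function(b) -clogit_ll(b, pps, gradient = FALSE)$ll,
                      gr = function(b) -clogit_ll(b, pps)$grad,
                      method = "BFGS",
                      control = list(maxit = 500L, reltol = reltol))
  par <- newton_polish(function(b) -clogit_ll(b, pps)$grad, opt$par)
  if (max(abs(par)) > 50)
    stopf("possible separation: attribute '%s' diverges",
          pp$attributes[which.max(abs(par))])
  list(beta = par / sc, convergence = opt$convergence,
       grad_max_std = max(abs(clogit_ll(par, pps)$grad)))
}

#' @export
print.fpc_clogit <- function(x, ...) {
  cat("Conditional logit (", x$n_choosers, " choosers, ",
      if (x$weighted) "IPW-weighted" else "unweighted", ")\n", sep = "")
  print(round(x$table, 4))
  cat("Log-likelihood:", format(x$logLik), "\n")
  invisible(x)
}

#' @export
summary.fpc_clogit <- function(object, ...) object

#' @export
coef.fpc_clogit <- function(object, ...) object$coefficients

#' @export
vcov.fpc_clogit <- function(object, ...) object$vcov

#' @export
logLik.fpc_clogit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n_choosers, class = "logLik")
}

#' @export
predict.fpc_clogit <- function(object, ...) {
  pp <- object$pp
  eta <- drop(pp$Z %*% object$coefficients)
  m <- group_max(eta, pp$group, pp$n)
  e <- exp(eta - m[pp$group])
  e / drop(rowsum(e, pp$group))[pp$group]
}

#' Backward screening of outlet attributes
#'
#' Overfit-then-prune screening for the conditional logit: fit with all
#' candidate attributes (after removing within-choice-set collinear ones,
#' which are logged), then repeatedly drop the attribute with the largest
#' Wald p-value above `p_drop` and refit, until every retained attribute has
#' p <= `p_drop`.  Distance is never dropped.
#'
#' @inheritParams cond_logit
#' @param candidates character vector of candidate attribute columns.
#' @param p_drop retention threshold on the Wald p-value (default 0.3).
#' @param distance_attr attribute never dropped (default `"distance_km"`).
#' @return List with `retained` (character vector) and `log` (data frame of
#'   screening steps: step, action, attribute, p_value).
#' @export
screen_attributes <- function(data, candidates, chooser = "respondent_id",
                              weights = NULL, p_drop = 0.3,
                              distance_attr = "distance_km") {
  if (!distance_attr %in% candidates)
    candidates <- c(distance_attr, candidates)
  log <- data.frame(step = integer(0), action = character(0),
                    attribute = character(0), p_value = numeric(0))
  step <- 0L
  ## pre-drop attributes collinear within choice sets
  repeat {
    ok <- tryCatch({prep_choice_data(data, candidates, chooser, weights); TRUE},
                   error = function(e) e)
    if (isTRUE(ok)) break
    msg <- conditionMessage(ok)
    m <- regmatches(msg, regexec(
      "(constant within every choice set|collinear within choice sets): (.*)$",
      msg))[[1]]
    if (!length(m)) stop(ok)
    drop1 <- strsplit(m[3], ", ")[[1]][1]
    if (drop1 == distance_attr)
      stopf("distance attribute not identified in the choice sets")
    step <- step + 1L
    log <- rbind(log, data.frame(step = step, action = "drop_collinear",
                                 attribute = drop1, p_value = NA_real_))
    candidates <- setdiff(candidates, drop1)
  }
  repeat {
    fit <- cond_logit(data, candidates, chooser, weights)
    p <- fit$table$p_value
    names(p) <- candidates
    p <- p[setdiff(candidates, distance_attr)]
    if (!length(p) || max(p) <= p_drop) break
    worst <- names(which.max(p))
    step <- step + 1L
    log <- rbind(log, data.frame(step = step, action = "drop_p_value",
                                 attribute = worst, p_value = max(p)))
    candidates <- setdiff(candidates, worst)
  }
  list(retained = candidates, log = log, fit = fit)
}
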