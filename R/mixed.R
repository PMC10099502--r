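## Mixed (random-coefficient) logit by maximum simulated likelihood.
##
## Chooser i's coefficient vector is beta_i = beta + s (*) eta_ir, with eta
## quasi-random standard-normal Halton draws and s the diagonal
## random-coefficient scale.  The simulated likelihood averages the
## conditional-logit probability of the chosen alternative over the R draws;
## with s = 0 (or no random attributes) the objective reduces exactly to the
## conditional logit.  s enters unconstrained and is reported as |s| — the
## square roots of the diagonal of the coefficient covariance — which avoids
## boundary problems in the optimiser.

## Draw matrices per random attribute: n_choosers x n_draws, standard
## normal, fixed over the optimisation.
draw_matrices <- function(H, n, R, Kr) {
  lapply(seq_len(Kr), function(j) matrix(H[, , j], n, R))
}

## simulated log-likelihood, analytic gradient, per-chooser scores and row
## probabilities, all from the compiled kernel
msl_parts <- function(theta, pp, Edr, ridx, gradient = TRUE, scores = FALSE,
                      probs = FALSE) {
  r <- msl_eval_cpp(theta, pp$Z, pp$gstart, pp$chosen - 1L, pp$w, Edr,
                    as.integer(ridx - 1L), gradient, scores, probs)
  r
}

#' Mixed logit by maximum simulated likelihood
#'
#' Fits a random-coefficient conditional logit: coefficients on
#' `random_attributes` vary across choosers as independent normals (diagonal
#' covariance), and the likelihood integral is simulated with shuffled
#' Halton draws mapped to the standard-normal scale.  The fit is started
#' from the conditional-logit estimates (SD scales at 0.1), which the
#' globally concave fixed-coefficient model makes a reliable warm start.
#' With an empty `random_attributes` the model is exactly the conditional
#' logit.
#'
#' @inheritParams cond_logit
#' @param random_attributes subset of `attributes` given random
#'   coefficients (default `"distance_km"`).
#' @param draws a [halton_config()]; fewer than 25 draws triggers a warning
#'   about simulation noise.
#' @param start optional named start: list(beta =, s =).
#' @return An object of class `fpc_mixlogit`: means `coefficients`,
#'   random-coefficient scales `sd` (reported as absolute values),
#'   covariance of all estimates, simulated log-likelihood, draw
#'   configuration and convergence diagnostics.  Methods: `print`,
#'   `summary`, `coef`, `vcov`, `logLik`.
#' @examples
#' study <- simulate_study(site_preset("kenya", n_respondents = 200),
#'                         seed = 11, all_linked = TRUE)
#' cs <- build_choice_sets(study$respondents, study$outlets, 3,
#'                         links = study$links)
#' fit <- mixed_logit(cs, c("distance_km", "public"),
#'                    random_attributes = "distance_km",
#'                    draws = halton_config(n_draws = 100, seed = 2))
#' summary(fit)
#' @export
mixed_logit <- function(data, attributes,
                        random_attributes = "distance_km",
                        chooser = "respondent_id", weights = NULL,
                        draws = halton_config(),
                        vcov_type = c("sandwich", "hessian"),
                        start = NULL, reltol = 1e-10, maxit = 400L) {
  vcov_type <- match.arg(vcov_type)
  if (!all(random_attributes %in% attributes))
    stopf("random_attributes must be a subset of attributes")
  if (draws$n_draws < 25 && length(random_attributes))
    warning("fewer than 25 simulation draws; estimates will be noisy")
  pp <- prep_choice_data(data, attributes, chooser, weights)
  ridx <- match(random_attributes, attributes)
  Kr <- length(ridx)
  K <- length(attributes)

  ## warm start from the conditional logit
  cl <- clogit_optim(pp, reltol = 1e-10)
  if (is.null(start)) {
    theta0 <- c(cl$beta, rep(0.1, Kr))
  } else {
    theta0 <- c(start$beta, if (Kr) start$s else numeric(0))
  }

  E <- if (Kr == 0L) list() else
    draw_matrices(halton_draws(draws, pp$n, Kr), pp$n, draws$n_draws, Kr)
  ## scaled parameter space for optimisation; fn and gr are called at the
  ## same point by BFGS, so one kernel evaluation serves both
  sc <- c(pp$scale, if (Kr) pp$scale[ridx] else numeric(0))
  cache <- new.env(parent = emptyenv())
  eval_at <- function(th) {
    if (is.null(cache$th) || !identical(th, cache$th)) {
      cache$th <- th
      cache$r <- msl_parts(th / sc, pp, E, ridx)
    }
    cache$r
  }
  obj <- function(th) {
    r <- eval_at(th)
    if (!is.finite(r$ll)) return(1e10)
    -r$ll
  }
  gra <- function(th) {
    r <- eval_at(th)
    if (!is.finite(r$ll)) return(rep(0, length(th)))
    -r$grad / sc
  }
  opt <- stats::optim(theta0 * sc, obj, gra, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0)
    stopf("mixed logit failed to converge after %d iterations (optim code %d, objective %.6f)",
          maxit, opt$convergence, opt$value)
  theta <- opt$par / sc
  at <- msl_parts(theta, pp, E, ridx, scores = TRUE)
  Hn <- numeric_hessian(function(t) {
    r <- msl_parts(t, pp, E, ridx); r$grad
  }, theta)
  Hinv <- inv_neg_hessian(Hn)
  V <- if (vcov_type == "sandwich")
    Hinv %*% crossprod(at$scores) %*% Hinv else Hinv
  V <- (V + t(V)) / 2
  pn <- c(attributes, if (Kr) paste0("sd_", random_attributes))
  dimnames(V) <- list(pn, pn)
  se <- sqrt(pmax(diag(V), 0))
  beta <- setNames(theta[seq_len(K)], attributes)
  s_raw <- theta[-seq_len(K)]
  sd_rep <- setNames(abs(s_raw), if (Kr) random_attributes else character(0))
  est <- c(beta, setNames(sd_rep, if (Kr) paste0("sd_", random_attributes)))
  structure(list(coefficients = beta, sd = sd_rep, s_raw = s_raw,
                 vcov = V, se = setNames(se, pn),
                 logLik = at$ll, n_choosers = pp$n,
                 attributes = attributes,
                 random_attributes = random_attributes,
                 draws = draws, weighted = !is.null(weights),
                 vcov_type = vcov_type,
                 convergence = opt$convergence,
                 grad_max = max(abs(at$grad)),
                 table = make_coef_table(est, se),
                 pp = pp, E = E, ridx = ridx),
            class = "fpc_mixlogit")
}

#' @export
print.fpc_mixlogit <- function(x, ...) {
  cat("Mixed logit, MSL with ", x$draws$n_draws, " Halton draws (",
      x$n_choosers, " choosers, ",
      if (x$weighted) "IPW-weighted" else "unweighted", ")\n", sep = "")
  print(round(x$table, 4))
  cat("Simulated log-likelihood:", format(x$logLik), "\n")
  invisible(x)
}

#' @export
summary.fpc_mixlogit <- function(object, ...) object

#' @export
coef.fpc_mixlogit <- function(object, ...) object$coefficients

#' @export
vcov.fpc_mixlogit <- function(object, ...) object$vcov

#' @export
logLik.fpc_mixlogit <- function(object, ...) {
  structure(object$logLik, df = nrow(object$vcov),
            nobs = object$n_choosers, class = "logLik")
}

#' Simulated choice probabilities of a mixed logit
#'
#' In-sample simulated probabilities, averaged over the draws; within each
#' chooser's choice set they sum to one.
#' @param object an `fpc_mixlogit` fit.
#' @param ... unused.
#' @return Numeric vector, one probability per row of the estimation data.
#' @export
predict.fpc_mixlogit <- function(object, ...) {
  theta <- c(unname(object$coefficients), object$s_raw)
  msl_parts(theta, object$pp, object$E, object$ridx, gradient = FALSE,
            probs = TRUE)$probs
}

#' Likelihood-ratio test of mixed versus conditional logit
#'
#' Tests whether allowing random coefficients improves fit: statistic
#' `2 (LL_mixed - LL_clogit)` (floored at 0), degrees of freedom equal to
#' the number of random coefficients, p-value from the chi-square upper
#' tail.  Because the null pins the SD parameters to the boundary of their
#' space, the chi-square reference is conservative.
#'
#' @param clog an `fpc_clogit` fit.
#' @param mixl an `fpc_mixlogit` fit on the same data, weights and
#'   fixed-attribute set.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(clog, mixl) {
  stopifnot(inherits(clog, "fpc_clogit"), inherits(mixl, "fpc_mixlogit"))
  if (!identical(clog$attributes, mixl$attributes))
    stopf("models are not nested: different attribute sets")
  if (clog$n_choosers != mixl$n_choosers)
    stopf("models are not nested: different estimation samples")
  stat <- max(0, 2 * (mixl$logLik - clog$logLik))
  df <- length(mixl$random_attributes)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
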