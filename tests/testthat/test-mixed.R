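make_small_study <- function(n = 300, seed = 1, truth = truth_preset()) {
  site <- site_preset("kenya", n_outlets_total = 15, n_respondents = n)
  st <- simulate_study(site, truth = truth, seed = seed, all_linked = TRUE)
  drop_small_choice_sets(
    build_choice_sets(st$respondents, st$outlets, 3, links = st$links))
}

test_that("an empty random set reproduces the conditional logit", {
  cs <- make_small_study(n = 250, seed = 2)
  attrs <- c("distance_km", "methods_offered", "public")
  fc <- cond_logit(cs, attrs)
  fm <- mixed_logit(cs, attrs, random_attributes = character(0),
                    draws = halton_config(50, seed = 1))
  expect_equal(coef(fm), coef(fc), tolerance = 1e-6)
  expect_equal(logLik(fm)[1], logLik(fc)[1], tolerance = 1e-8)
})

test_that("with s = 0 the simulated objective equals the conditional logit", {
  cs <- make_small_study(n = 60, seed = 3)
  attrs <- c("distance_km", "methods_offered")
  pp <- fpchoice:::prep_choice_data(cs, attrs)
  H <- halton_draws(halton_config(40, seed = 4), pp$n, 1)
  E <- fpchoice:::draw_matrices(H, pp$n, 40, 1)
  beta <- c(-0.8, 0.2)
  msl <- fpchoice:::msl_parts(c(beta, 0), pp, E, ridx = 1L)
  cl <- fpchoice:::clogit_ll(beta, pp)
  expect_equal(msl$ll, cl$ll, tolerance = 1e-12)
  expect_equal(msl$grad[1:2], unname(cl$grad), tolerance = 1e-10)
})

test_that("the simulated log-likelihood matches brute-force enumeration", {
  d <- tiny_choice_data(n = 5, m = 3)
  attrs <- c("distance_km", "methods_offered")
  w <- c(1, 0.5, 2, 1, 1.5)
  pp <- fpchoice:::prep_choice_data(d, attrs, weights = w)
  R <- 30
  H <- halton_draws(halton_config(R, seed = 7), pp$n, 1)
  E <- fpchoice:::draw_matrices(H, pp$n, R, 1)
  theta <- c(-1.1, 0.4, 0.6)
  got <- fpchoice:::msl_parts(theta, pp, E, ridx = 1L)$ll
  ## oracle: per-draw softmax enumeration on the sorted data, with the
  ## chooser order used internally
  dd <- d[order(match(d$respondent_id, unique(d$respondent_id))), ]
  want <- bruteforce_msl_ll(theta[1:2], theta[3], dd, attrs,
                            "distance_km", H, w = pp$w)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("analytic gradients match numerical differentiation", {
  cs <- make_small_study(n = 80, seed = 5)
  attrs <- c("distance_km", "methods_offered", "public")
  pp <- fpchoice:::prep_choice_data(cs, attrs)
  H <- halton_draws(halton_config(25, seed = 2), pp$n, 2)
  E <- fpchoice:::draw_matrices(H, pp$n, 25, 2)
  ridx <- c(1L, 3L)
  theta <- c(-0.9, 0.25, 1.4, 0.35, 0.6)
  g <- fpchoice:::msl_parts(theta, pp, E, ridx)$grad
  for (k in seq_along(theta)) {
    h <- 1e-6
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    num <- (fpchoice:::msl_parts(up, pp, E, ridx, gradient = FALSE)$ll -
              fpchoice:::msl_parts(dn, pp, E, ridx, gradient = FALSE)$ll) /
      (2 * h)
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})

test_that("simulated probabilities sum to one within each choice set", {
  cs <- make_small_study(n = 100, seed = 6)
  fit <- mixed_logit(cs, c("distance_km", "methods_offered", "public"),
                     random_attributes = c("distance_km", "public"),
                     draws = halton_config(60, seed = 3))
  p <- predict(fit)
  sums <- tapply(p, cs$respondent_id, sum)
  expect_true(all(abs(sums - 1) < 1e-8))
})

test_that("random-coefficient scales are recovered on moderate data", {
  tr <- truth_params(c(distance_km = -1, methods_offered = 0.15,
                       public = 2),
                     beta_sd = c(distance_km = 0.5))
  site <- site_preset("kenya", n_outlets_total = 20, n_respondents = 800)
  st <- simulate_study(site, truth = tr, seed = 19, all_linked = TRUE)
  cs <- build_choice_sets(st$respondents, st$outlets, 3, links = st$links)
  fit <- mixed_logit(cs, c("distance_km", "methods_offered", "public"),
                     random_attributes = "distance_km",
                     draws = halton_config(150, seed = 4))
  est <- c(coef(fit), fit$sd)
  truth <- c(tr$beta_mean, 0.5)
  expect_true(all(abs(est - truth) <= 3 * fit$se))
})

test_that("estimates are stable when the number of draws doubles", {
  cs <- make_small_study(n = 250, seed = 8)
  attrs <- c("distance_km", "methods_offered", "public")
  f1 <- mixed_logit(cs, attrs, random_attributes = "distance_km",
                    draws = halton_config(100, seed = 5))
  f2 <- mixed_logit(cs, attrs, random_attributes = "distance_km",
                    draws = halton_config(200, seed = 5))
  expect_true(all(abs(c(coef(f1) - coef(f2), f1$sd - f2$sd)) <= f1$se))
})

test_that("few draws trigger a warning", {
  cs <- make_small_study(n = 60, seed = 9)
  expect_warning(
    mixed_logit(cs, c("distance_km", "methods_offered"),
                random_attributes = "distance_km",
                draws = halton_config(10, seed = 1)),
    "draws")
})

test_that("the likelihood-ratio test follows its chi-square reference", {
  clog <- structure(list(logLik = -100, attributes = c("a", "b"),
                         n_choosers = 50), class = "fpc_clogit")
  mixl <- structure(list(logLik = -95, attributes = c("a", "b"),
                         random_attributes = c("a", "b", "b2"),
                         n_choosers = 50), class = "fpc_mixlogit")
  out <- lr_test(clog, mixl)
  expect_equal(out$statistic, 10)
  expect_equal(out$df, 3)
  expect_equal(out$p_value, 0.0185661, tolerance = 1e-5)
  ## identical log-likelihoods: statistic 0, p = 1
  mix0 <- mixl; mix0$logLik <- -100; mix0$random_attributes <- "a"
  out0 <- lr_test(clog, mix0)
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)
  ## non-nested models are refused
  bad <- mixl; bad$attributes <- c("a", "c")
  expect_error(lr_test(clog, bad), "nested")
})
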