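test_that("the fitted log-likelihood equals brute-force enumeration", {
  d <- tiny_choice_data(n = 5, m = 3)
  w <- c(0.5, 2, 1, 1.2, 0.8)
  attrs <- c("distance_km", "methods_offered")
  fit <- cond_logit(d, attrs, weights = w)
  expect_equal(fit$logLik,
               bruteforce_clogit_ll(coef(fit), d, attrs, w),
               tolerance = 1e-10)
  ## and at an arbitrary parameter value, via the internal objective
  pp <- fpchoice:::prep_choice_data(d, attrs, weights = w)
  beta <- c(-0.7, 0.3)
  expect_equal(fpchoice:::clogit_ll(beta, pp, gradient = FALSE)$ll,
               bruteforce_clogit_ll(beta, d, attrs, w), tolerance = 1e-10)
})

test_that("known coefficients are recovered from simulated choices", {
  site <- site_preset("kenya", n_respondents = 1200)
  tr <- truth_preset(random = FALSE)
  st <- simulate_study(site, truth = tr, seed = 17, all_linked = TRUE)
  cs <- build_choice_sets(st$respondents, st$outlets, 3, links = st$links)
  fit <- cond_logit(cs, kenya_attrs)
  hits <- abs(coef(fit) - tr$beta_mean[kenya_attrs]) <= 3 * fit$se
  expect_gte(mean(hits), 0.8)
  expect_lt(fit$grad_max, 1e-5)
  ## probabilities sum to one within each choice set
  p <- predict(fit)
  expect_equal(as.vector(tapply(p, cs$respondent_id, sum)),
               rep(1, fit$n_choosers), tolerance = 1e-12)
})

test_that("balanced symmetric choices give a null distance effect", {
  ## two choosers with mirrored distance differences and mirrored choices
  d <- data.frame(respondent_id = rep(c("a", "b"), each = 2),
                  outlet_id = rep(c("o1", "o2"), 2),
                  distance_km = c(1, 2, 1, 2),
                  chosen = c(1L, 0L, 0L, 1L))
  fit <- cond_logit(d, "distance_km")
  expect_lt(abs(coef(fit)), 1e-6)
})

test_that("unidentifiable attributes are rejected by name", {
  d <- tiny_choice_data()
  d$same <- 5  # constant within (and across) all choice sets
  expect_error(cond_logit(d, c("distance_km", "same")), "same")
  d$dup <- 2 * d$distance_km
  expect_error(cond_logit(d, c("distance_km", "dup")), "collinear")
})

test_that("probabilities are invariant to alternative-constant utility shifts", {
  d <- tiny_choice_data(n = 8, m = 3, seed = 3)
  attrs <- c("distance_km", "methods_offered")
  f1 <- cond_logit(d, attrs)
  ## add a per-chooser constant to one attribute: within-set differences,
  ## hence probabilities and estimates, must not change
  shift <- ave(seq_len(nrow(d)), d$respondent_id, FUN = function(i) i[1])
  d2 <- d; d2$distance_km <- d2$distance_km + shift
  f2 <- cond_logit(d2, attrs)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(predict(f1), predict(f2), tolerance = 1e-6)
})

test_that("screening drops noise, keeps signal and logs collinearity", {
  ## a pure-noise attribute has a uniform null p-value, so backward
  ## elimination at threshold q drops it with probability about 1 - q
  site <- site_preset("kenya", n_outlets_total = 15, n_respondents = 120)
  tr <- truth_params(c(distance_km = -1, methods_offered = 0.3))
  dropped_30 <- dropped_05 <- logical(100)
  for (r in seq_len(100)) {
    st <- simulate_study(site, truth = tr, seed = 1000 + r,
                         all_linked = TRUE)
    cs <- drop_small_choice_sets(
      build_choice_sets(st$respondents, st$outlets, 3, links = st$links))
    set.seed(2000 + r)
    cs$noise <- rnorm(nrow(cs))
    cand <- c("distance_km", "methods_offered", "noise")
    dropped_30[r] <- !("noise" %in%
                         screen_attributes(cs, cand, p_drop = 0.3)$retained)
    dropped_05[r] <- !("noise" %in%
                         screen_attributes(cs, cand, p_drop = 0.05)$retained)
  }
  expect_gte(mean(dropped_30), 0.55)  # ~70% expected
  expect_gte(mean(dropped_05), 0.87)  # ~95% expected
  ## strongly predictive attributes are all retained
  st <- simulate_study(site_preset("kenya", n_respondents = 800),
                       truth = truth_params(c(distance_km = -1,
                                              methods_offered = 0.3,
                                              public = 2)), seed = 9,
                       all_linked = TRUE)
  cs <- build_choice_sets(st$respondents, st$outlets, 3, links = st$links)
  scr <- screen_attributes(cs, c("distance_km", "methods_offered", "public"),
                           p_drop = 0.3)
  expect_setequal(scr$retained, c("distance_km", "methods_offered", "public"))
  ## perfectly collinear attribute removed before fitting, with a log entry
  cs$dist2 <- 2 * cs$distance_km
  scr2 <- screen_attributes(cs, c("distance_km", "dist2", "public"),
                            p_drop = 0.3)
  expect_false("dist2" %in% scr2$retained)
  expect_true("drop_collinear" %in% scr2$log$action)
})
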