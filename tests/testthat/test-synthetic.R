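test_that("outlet generation honours counts, containment and determinism", {
  cfg <- site_config("s", c(public = 10, private = 20, pharmacy = 15),
                     outer_ring_radius = 5, inner_ring_radius = 2,
                     choice_radius = 3, n_respondents = 10)
  out <- generate_outlets(cfg, attribute_preset("kenya"), seed = 1)
  expect_equal(nrow(out), 45)
  expect_equal(as.vector(table(out$type)[c("public", "private", "pharmacy")]),
               c(10, 20, 15))
  expect_true(all(sqrt(out$x_km^2 + out$y_km^2) <= 5))
  expect_identical(out, generate_outlets(cfg, attribute_preset("kenya"), 1))
  expect_false(identical(out$x_km,
                         generate_outlets(cfg, attribute_preset("kenya"),
                                          2)$x_km))
  expect_true(all(out$methods_offered %in% 1:12))
  expect_true(all(out$price_ocp >= 0))
  ## degenerate Bernoulli: prevalence 1 for public signage
  am <- attribute_preset("kenya")
  am$prevalence["fp_signage", "public"] <- 1
  out2 <- generate_outlets(cfg, am, seed = 3)
  expect_true(all(out2$fp_signage[out2$type == "public"] == 1))
  cfg0 <- cfg; cfg0$n_outlets[] <- 0L
  expect_error(generate_outlets(cfg0, am, 1), "empty supply environment")
})

test_that("respondent generation is contained, seeded and spec-driven", {
  cfg <- site_config("s", c(public = 1, private = 1, pharmacy = 1),
                     5, 2, 3, n_respondents = 200)
  r <- generate_respondents(cfg, seed = 4)
  expect_equal(nrow(r), 200)
  expect_true(all(sqrt(r$x_km^2 + r$y_km^2) <= 2))
  expect_identical(r, generate_respondents(cfg, seed = 4))
  cm <- covariate_preset()
  cm$parity <- list(type = "categorical", values = 0:3, p = c(1, 0, 0, 0))
  expect_true(all(generate_respondents(cfg, cm, 5)$parity == 0))
  cm$parity <- list(type = "beta", p = 1)
  expect_error(generate_respondents(cfg, cm, 5), "distribution")
})

test_that("selection sampling converges to closed-form MNL probabilities", {
  cfg <- site_config("s", c(public = 1, private = 1, pharmacy = 1),
                     5, 2, 3, n_respondents = 60000)
  resp <- generate_respondents(cfg, seed = 10)
  ## all coefficients zero: uniform over the six categories
  sel0 <- matrix(0, 5, 1, dimnames = list(NULL, "(Intercept)"))
  tr0 <- truth_params(c(distance_km = -1), selection_coefs = sel0)
  cat0 <- simulate_selection(resp, tr0, seed = 2)
  shares <- tabulate(cat0, 6) / length(cat0)
  se <- sqrt((1/6) * (5/6) / length(cat0))
  expect_true(all(abs(shares - 1/6) < 3 * se))
  ## strong positive effect of marriage on category 6 only
  sel <- matrix(0, 5, 2, dimnames = list(NULL, c("(Intercept)", "married")))
  sel[5, "married"] <- 2
  tr <- truth_params(c(distance_km = -1), selection_coefs = sel)
  resp2 <- generate_respondents(
    site_config("s", c(public = 1, private = 1, pharmacy = 1), 5, 2, 3,
                n_respondents = 20000), seed = 11)
  cat2 <- simulate_selection(resp2, tr, seed = 3)
  ## closed-form oracle: p6 = e^2/(5 + e^2) for married, 1/6 for unmarried
  p6_m <- exp(2) / (5 + exp(2))
  sh_m <- mean(cat2[resp2$married == 1] == 6)
  sh_u <- mean(cat2[resp2$married == 0] == 6)
  n_m <- sum(resp2$married == 1)
  expect_lt(abs(sh_m - p6_m), 3 * sqrt(p6_m * (1 - p6_m) / n_m))
  expect_gt(sh_m, sh_u)
  ## reproducible
  expect_identical(cat2, simulate_selection(resp2, tr, seed = 3))
})

test_that("outlet choice matches the closed-form binary logit", {
  n <- 50000
  resp <- data.frame(respondent_id = sprintf("r%05d", 1:n),
                     x_km = 0, y_km = 0)
  cs <- data.frame(respondent_id = rep(resp$respondent_id, each = 2),
                   outlet_id = rep(c("near", "far"), n),
                   distance_km = rep(c(0.5, 1.5), n))
  tr <- truth_params(c(distance_km = -1))
  sim <- simulate_outlet_choice(cs, resp, tr, seed = 21)
  p_near <- mean(sim$choices$outlet_id == "near")
  p_true <- exp(1) / (1 + exp(1))  # utility gap = 1
  expect_lt(abs(p_near - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("identical alternatives are chosen uniformly", {
  n <- 20000
  resp <- data.frame(respondent_id = sprintf("r%05d", 1:n), x_km = 0, y_km = 0)
  cs <- data.frame(respondent_id = rep(resp$respondent_id, each = 3),
                   outlet_id = rep(c("a", "b", "c"), n),
                   distance_km = 1)
  tr <- truth_params(c(distance_km = -2.5))
  sim <- simulate_outlet_choice(cs, resp, tr, seed = 8)
  shares <- table(sim$choices$outlet_id) / n
  expect_true(all(abs(shares - 1/3) < 3 * sqrt((1/3) * (2/3) / n)))
})

test_that("a complete synthetic study is coherent and reproducible", {
  site <- site_preset("kenya", n_outlets_total = 30, n_respondents = 300)
  st <- simulate_study(site, seed = 123)
  expect_true(all(st$respondents$category %in% 1:6))
  linked <- st$respondents[st$respondents$category %in% 5:6, ]
  expect_true(all(linked$chosen_outlet %in% st$outlets$outlet_id))
  unlinked <- st$respondents[!st$respondents$category %in% 5:6, ]
  expect_true(all(is.na(unlinked$chosen_outlet)))
  st2 <- simulate_study(site, seed = 123)
  expect_identical(st$respondents, st2$respondents)
  expect_identical(st$outlets, st2$outlets)
  ## uganda-like preset carries its radius rule
  expect_equal(site_preset("uganda")$choice_radius, 2)
  expect_equal(site_preset("kenya")$choice_radius, 3)
})

test_that("population-average coefficients account for preference shifts", {
  tr <- truth_preset(heterogeneous = TRUE)
  pb <- population_beta(tr)
  p_m <- covariate_preset()$married$p
  expect_equal(pb[["public"]],
               tr$beta_mean[["public"]] + p_m * tr$beta_shift["married", "public"])
  expect_equal(population_beta(truth_preset()), truth_preset()$beta_mean)
})

test_that("a study round-trips through delimited text", {
  site <- site_preset("kenya", n_outlets_total = 12, n_respondents = 60)
  st <- simulate_study(site, seed = 5)
  dir <- tempfile("study")
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  rr <- utils::read.csv(file.path(dir, "respondents.csv"))
  expect_equal(nrow(rr), 60)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$beta_mean$distance_km, st$truth$beta_mean[["distance_km"]])
})
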