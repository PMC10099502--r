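test_that("euclidean distance is exact and validated", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 1), c(1, 1)), 0)
  set.seed(1)
  p <- matrix(rnorm(20), ncol = 2)
  q <- matrix(rnorm(20), ncol = 2)
  expect_equal(euclidean_distance(p, q),
               sqrt(rowSums((p - q)^2)))  # brute-force recomputation
  expect_error(euclidean_distance(c(NA, 0), c(0, 0)), "finite")
})

test_that("choice sets respect the radius and always keep the chosen outlet", {
  resp <- data.frame(respondent_id = "r1", x_km = 0, y_km = 0)
  outl <- data.frame(outlet_id = c("a", "b", "c"),
                     x_km = c(0.5, 2.9, 3.1), y_km = 0,
                     type = c("public", "private", "pharmacy"))
  cs <- build_choice_sets(resp, outl, 3)
  expect_equal(sort(cs$outlet_id), c("a", "b"))
  ## chosen outlet beyond the radius is retained and flagged
  cs2 <- build_choice_sets(resp, outl, 3,
                           links = data.frame(respondent_id = "r1",
                                              outlet_id = "c"))
  expect_equal(nrow(cs2), 3)
  expect_equal(cs2$out_of_radius[cs2$outlet_id == "c"], 1L)
  expect_equal(sum(cs2$chosen), 1L)
  expect_equal(exclusions(cs2)$reason, "chosen_outside_radius")
  ## degenerate radius: only the chosen outlet survives, flagged
  cs3 <- build_choice_sets(resp, outl, 0,
                           links = data.frame(respondent_id = "r1",
                                              outlet_id = "b"))
  expect_equal(cs3$outlet_id, "b")
  expect_equal(cs3$out_of_radius, 1L)
  expect_error(
    build_choice_sets(resp, outl, 3,
                      links = data.frame(respondent_id = "r1",
                                         outlet_id = "zzz")),
    "zzz")
})

test_that("choice-set membership equals a brute-force double loop", {
  set.seed(42)
  n <- 50; m <- 50
  resp <- data.frame(respondent_id = sprintf("r%02d", 1:n),
                     x_km = runif(n, -2, 2), y_km = runif(n, -2, 2))
  outl <- data.frame(outlet_id = sprintf("o%02d", 1:m),
                     x_km = runif(m, -4, 4), y_km = runif(m, -4, 4),
                     type = sample(c("public", "private", "pharmacy"), m,
                                   replace = TRUE),
                     outreach = rbinom(m, 1, 0.3),
                     methods_offered = sample(1:12, m, replace = TRUE))
  radius <- 2.5
  cs <- build_choice_sets(resp, outl, radius)
  ## independent pair enumeration
  expected <- 0L
  for (i in 1:n) for (j in 1:m) {
    d <- sqrt((resp$x_km[i] - outl$x_km[j])^2 +
                (resp$y_km[i] - outl$y_km[j])^2)
    if (d <= radius) expected <- expected + 1L
  }
  expect_equal(nrow(cs), expected)
  ## environment summary equals brute force
  env <- summarize_environment(resp, outl, radius)
  for (i in c(1, 17, 50)) {
    d <- sqrt((resp$x_km[i] - outl$x_km)^2 + (resp$y_km[i] - outl$y_km)^2)
    inr <- d <= radius
    expect_equal(env$n_outlets[i], sum(inr))
    expect_equal(env$n_public[i], sum(inr & outl$type == "public"))
    expect_equal(env$n_outreach[i], sum(inr & outl$outreach == 1))
    expect_equal(env$mean_methods[i],
                 if (any(inr)) mean(outl$methods_offered[inr]) else NA_real_)
  }
  ## monotonicity: shrinking the radius never grows a set
  cs_small <- build_choice_sets(resp, outl, 1.5)
  n_by <- table(cs$respondent_id)
  n_by_small <- table(factor(cs_small$respondent_id,
                             levels = names(n_by)))
  expect_true(all(as.integer(n_by_small) <= as.integer(n_by)))
  ## permutation invariance: relabelling outlets leaves membership unchanged
  perm <- sample(m)
  cs_p <- build_choice_sets(resp, outl[perm, ], radius)
  key <- function(x) sort(paste(x$respondent_id, x$outlet_id))
  expect_equal(key(cs_p), key(cs))
})

test_that("environment summaries handle empty neighbourhoods", {
  resp <- data.frame(respondent_id = "r1", x_km = 0, y_km = 0)
  outl <- data.frame(outlet_id = c("a", "b", "c"), x_km = c(9, 0.1, 0.2),
                     y_km = 0, type = "private", outreach = 0,
                     methods_offered = c(5, 2, 4))
  env <- summarize_environment(resp, outl, 1)
  expect_equal(env$mean_methods, 3)  # mean of {2, 4}
  env0 <- summarize_environment(resp, outl, 0.01)
  expect_equal(env0$n_outlets, 0)
  expect_true(is.na(env0$mean_methods))
})

test_that("linkage rate rounds half-up to one decimal and validates", {
  expect_equal(linkage_rate(400, 141), 35.3)  # 35.25 rounds up, not to even
  expect_equal(linkage_rate(10, 0), 0.0)
  expect_equal(linkage_rate(3, 1), 33.3)
  expect_error(linkage_rate(0, 0), "n_users")
  expect_error(linkage_rate(10, 11), "n_linked")
})

test_that("choosers with too few alternatives are filtered with a report", {
  resp <- data.frame(respondent_id = c("a", "b"), x_km = c(0, 9), y_km = 0)
  outl <- data.frame(outlet_id = c("o1", "o2"), x_km = c(0.2, 0.4),
                     y_km = 0, type = "private")
  links <- data.frame(respondent_id = c("a", "b"), outlet_id = "o1")
  cs <- build_choice_sets(resp, outl, 1, links = links)
  out <- drop_small_choice_sets(cs)
  expect_equal(unique(out$respondent_id), "a")
  ex <- exclusions(out)
  expect_true(any(ex$reason == "too_few_alternatives" &
                    ex$respondent_id == "b"))
})
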