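## Synthetic study generator: a complete linked household-outlet study with
## known ground truth, so that every estimation stage can be validated by
## parameter recovery.
##
## Geometry: the site centre sits at the origin of a planar km grid.  Outlets
## are placed uniformly at random in the outer-ring disc, surveyed households
## uniformly in the nested inner-ring disc, mirroring a design in which the
## outlet census covers a wider area than the household frame so that every
## household's full supply environment is observed.

#' Site configuration
#'
#' @param site_id label for the site.
#' @param n_outlets named integer vector with counts for `public`, `private`
#'   and `pharmacy` outlets.
#' @param outer_ring_radius radius (km) of the outlet census disc.
#' @param inner_ring_radius radius (km) of the household disc; must be
#'   smaller than `outer_ring_radius`.
#' @param choice_radius radius (km) defining each respondent's choice set
#'   (3 for the Kenya-like design, 2 for the Uganda-like design); must not
#'   exceed `outer_ring_radius`.
#' @param n_respondents number of surveyed women.
#' @return An object of class `site_config`.
#' @seealso [site_preset()] for ready-made Kenya-like and Uganda-like sites.
#' @export
site_config <- function(site_id, n_outlets, outer_ring_radius,
                        inner_ring_radius, choice_radius, n_respondents) {
  stopifnot(all(c("public", "private", "pharmacy") %in% names(n_outlets)))
  if (any(n_outlets < 0) || n_respondents < 0) stopf("counts must be >= 0")
  if (inner_ring_radius >= outer_ring_radius)
    stopf("inner_ring_radius must be < outer_ring_radius")
  if (choice_radius > outer_ring_radius)
    stopf("choice_radius must be <= outer_ring_radius")
  structure(list(site_id = site_id,
                 n_outlets = n_outlets[c("public", "private", "pharmacy")],
                 outer_ring_radius = outer_ring_radius,
                 inner_ring_radius = inner_ring_radius,
                 choice_radius = choice_radius,
                 n_respondents = as.integer(n_respondents)),
            class = "site_config")
}

#' Preset site configurations
#'
#' Desk-scale sites whose outlet-type mixes scale down the two study
#' settings: a pharmacy-heavy Kenya-like site (census mix 921 pharmacies :
#' 614 private : 233 public, choice radius 3 km) and a private-heavy
#' Uganda-like site (826 private : 56 public : 18 pharmacies, choice radius
#' 2 km).
#'
#' @param which `"kenya"` or `"uganda"`.
#' @param n_outlets_total total outlets, split proportionally to the study
#'   mix (default 30).
#' @param n_respondents respondents (default 1500).
#' @return A [site_config()].
#' @export
site_preset <- function(which = c("kenya", "uganda"), n_outlets_total = 30L,
                        n_respondents = 1500L) {
  which <- match.arg(which)
  mix <- switch(which,
                kenya  = c(public = 233, private = 614, pharmacy = 921),
                uganda = c(public = 56, private = 826, pharmacy = 18))
  n <- round(n_outlets_total * mix / sum(mix))
  n <- pmax(n, 1L)  # keep every type represented at desk scale
  site_config(site_id = paste0(which, "_site"), n_outlets = n,
              outer_ring_radius = if (which == "kenya") 5 else 4,
              inner_ring_radius = if (which == "kenya") 2 else 1.5,
              choice_radius = if (which == "kenya") 3 else 2,
              n_respondents = n_respondents)
}

#' Outlet attribute model
#'
#' Per outlet type: Bernoulli prevalences for the binary structural-quality
#' attributes, a truncated count distribution on 1..12 for the number of
#' methods offered (shifted binomial matching the target mean), and
#' log-normal prices matching target medians.
#'
#' @param prevalence matrix (attributes x types `public`,`private`,`pharmacy`)
#'   of probabilities in `[0, 1]`; rows must include `stockout_injectables`,
#'   `provider_trained`, `fp_signage`, `open7`, `outreach`, `counselling`,
#'   `job_aids`.
#' @param methods_mean named vector of mean methods offered per type
#'   (in `[1, 12]`).
#' @param price_ocp_median,price_injection_median named vectors of median
#'   prices per type (local currency, >= 0).
#' @param price_sdlog log-scale SD of the log-normal price distributions.
#' @return An object of class `attribute_model`.
#' @seealso [attribute_preset()] for models matching the two study audits.
#' @export
attribute_model <- function(prevalence, methods_mean, price_ocp_median,
                            price_injection_median, price_sdlog = 0.5) {
  types <- c("public", "private", "pharmacy")
  stopifnot(all(types %in% colnames(prevalence)),
            all(types %in% names(methods_mean)))
  if (any(prevalence < 0 | prevalence > 1)) stopf("prevalences must be in [0,1]")
  if (any(methods_mean < 1 | methods_mean > 12))
    stopf("methods_mean must be in [1, 12]")
  if (any(price_ocp_median < 0) || any(price_injection_median < 0))
    stopf("prices must be >= 0")
  structure(list(prevalence = prevalence[, types],
                 methods_mean = methods_mean[types],
                 price_ocp_median = price_ocp_median[types],
                 price_injection_median = price_injection_median[types],
                 price_sdlog = price_sdlog),
            class = "attribute_model")
}

#' Preset outlet attribute models
#'
#' Attribute prevalences and medians shaped like the two outlet audits
#' (e.g. for the Kenya-like model: public outlets rarely open 7 days a week
#' but most likely to conduct outreach and have trained providers;
#' pharmacies cheapest for injections but offering the fewest methods).
#'
#' @param which `"kenya"` or `"uganda"`.
#' @return An [attribute_model()].
#' @export
attribute_preset <- function(which = c("kenya", "uganda")) {
  which <- match.arg(which)
  if (which == "kenya") {
    prev <- rbind(
      stockout_injectables = c(0.054, 0.194, 0.202),
      provider_trained     = c(0.453, 0.388, 0.239),
      fp_signage           = c(0.359, 0.363, 0.170),
      open7                = c(0.130, 0.510, 0.516),
      outreach             = c(0.646, 0.140, 0.007),
      counselling          = c(0.973, 0.912, 0.758),
      job_aids             = c(0.659, 0.415, 0.128))
    mm <- c(4.70, 4.35, 3.23)
    ocp <- c(2.02, 40.41, 102.70)
    inj <- c(3.15, 113.03, 18.72)
  } else {
    prev <- rbind(
      stockout_injectables = c(0.232, 0.205, 0.127),
      provider_trained     = c(0.536, 0.310, 0.356),
      fp_signage           = c(0.214, 0.126, 0.000),
      open7                = c(0.607, 0.811, 0.864),
      outreach             = c(0.750, 0.090, 0.017),
      counselling          = c(0.964, 0.792, 0.525),
      job_aids             = c(0.786, 0.196, 0.051))
    mm <- c(4.30, 3.57, 3.35)
    ocp <- c(160.71, 1038.84, 2128.32)
    inj <- c(285.71, 2333.84, 466.10)
  }
  types <- c("public", "private", "pharmacy")
  colnames(prev) <- types
  names(mm) <- names(ocp) <- names(inj) <- types
  attribute_model(prev, mm, ocp, inj)
}

#' Ground-truth utility and selection parameters
#'
#' The data-generating parameters of a synthetic study.  Outlet choice
#' follows a random-coefficients utility: chooser i values outlet m as
#' `U_im = z_im' beta_i + e_im` with `beta_i ~ N(beta_mean + shift(x_i),
#' diag(beta_sd^2))` and independent standard Gumbel errors, so the
#' conditional-logit structure holds draw by draw.  `beta_shift` lets
#' attribute-preference means depend on respondent observables, which is
#' what makes selection on those observables consequential and hence
#' correctable by inverse-probability weighting.
#'
#' @param beta_mean named vector of mean utility weights, one per outlet
#'   attribute used in choice (must include `distance_km`, conventionally
#'   negative).
#' @param beta_sd named nonnegative vector of random-coefficient SDs
#'   (entries for attributes absent from it are taken as 0).
#' @param selection_coefs matrix (5 non-reference categories x covariates,
#'   with an `(Intercept)` column) of multinomial-logit coefficients for
#'   method-use/linkage category; category 1 (no method) is the reference.
#' @param beta_shift optional matrix (covariates x attributes) shifting
#'   `beta_mean` by `x_i' beta_shift` for respondent i.
#' @param seed integer seed recorded with the truth.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(beta_mean, beta_sd = NULL, selection_coefs = NULL,
                         beta_shift = NULL, seed = 1L) {
  if (!"distance_km" %in% names(beta_mean))
    stopf("beta_mean must include a 'distance_km' entry")
  sd_full <- setNames(numeric(length(beta_mean)), names(beta_mean))
  if (!is.null(beta_sd)) {
    if (any(beta_sd < 0)) stopf("beta_sd must be >= 0 elementwise")
    sd_full[names(beta_sd)] <- beta_sd
  }
  if (!is.null(beta_shift) &&
      !all(colnames(beta_shift) %in% names(beta_mean)))
    stopf("beta_shift columns must name attributes in beta_mean")
  structure(list(beta_mean = beta_mean, beta_sd = sd_full,
                 selection_coefs = selection_coefs,
                 beta_shift = beta_shift, seed = as.integer(seed)),
            class = "truth_params")
}

#' Preset ground truth
#'
#' Default truth for the synthetic presets: distance disutility -1 per km,
#' attribute weights placed so that the implied willingness-to-travel ratios
#' are of the magnitude seen in urban East African outlet-choice studies
#' (e.g. ~2 km for a public outlet, 0.15 km per extra method), random
#' coefficients on distance, methods offered and the public indicator, and a
#' selection model in which marriage and parity raise the odds of the linked
#' categories while college education raises the odds of the unlinked-user
#' categories.
#'
#' @param random logical; include nonzero random-coefficient SDs (default TRUE).
#' @param heterogeneous logical; include the observable preference shifts
#'   (married women more distance-averse and more public-sector-leaning)
#'   that make IPW correction matter (default FALSE).
#' @param seed recorded seed.
#' @return A [truth_params()].
#' @export
truth_preset <- function(random = TRUE, heterogeneous = FALSE, seed = 1L) {
  beta_mean <- c(distance_km = -1.0, methods_offered = 0.15, open7 = 0.15,
                 stockout_injectables = -0.15, provider_trained = 0.30,
                 fp_signage = 0.40, public = 2.0, pharmacy = 0.50)
  beta_sd <- if (random)
    c(distance_km = 0.5, methods_offered = 0.08, public = 0.8) else NULL
  sel <- rbind(
    traditional    = c(`(Intercept)` = -1.30, educ_college = 0.0,
                       married = 0.0, parity = 0.00),
    larc_unlinked  = c(-2.20, 0.5, 0.0, 0.20),
    short_unlinked = c(-1.10, 0.5, 0.0, 0.20),
    larc_linked    = c(-2.80, 0.0, 0.7, 0.35),
    short_linked   = c(-1.60, 0.0, 0.7, 0.35))
  colnames(sel) <- c("(Intercept)", "educ_college", "married", "parity")
  shift <- NULL
  if (heterogeneous) {
    ## selection-stress scenario: the preference shift acts on the
    ## public-sector coefficient only, leaving the distance weight alone,
    ## so that selection on marriage moves the willingness-to-travel ratio
    ## itself (a proportional shift of both coefficients would cancel in
    ## the ratio and leave nothing to correct), and linkage depends on
    ## marriage strongly enough that the selected sample is visibly
    ## unrepresentative
    shift <- rbind(married = c(public = 2.0))
    sel[c("larc_linked", "short_linked"), "married"] <- 2.5
  }
  truth_params(beta_mean, beta_sd, sel, beta_shift = shift, seed = seed)
}

#' Default respondent covariate model
#'
#' Simple marginal distributions for the respondent covariates used in the
#' selection model: age group, college education, marriage, parity (0-3+)
#' and top-wealth-quintile membership, with prevalences of the order seen in
#' urban household surveys in the region.
#'
#' @return A named list of distribution specs understood by
#'   [generate_respondents()].
#' @export
covariate_preset <- function() {
  list(age_2549 = list(type = "bernoulli", p = 0.66),
       educ_college = list(type = "bernoulli", p = 0.30),
       married = list(type = "bernoulli", p = 0.55),
       parity = list(type = "categorical", values = 0:3,
                     p = c(0.35, 0.22, 0.18, 0.25)),
       wealth_top = list(type = "bernoulli", p = 0.45))
}

## uniform points on a disc of given radius
runif_disc <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x_km = r * cos(th), y_km = r * sin(th))
}

## mean-matched shifted binomial on 1..12
draw_methods <- function(n, mean) {
  1L + stats::rbinom(n, size = 11L, prob = (mean - 1) / 11)
}

#' Generate synthetic outlets
#'
#' Outlets are placed uniformly at random in the outer-ring disc; binary
#' attributes are Bernoulli draws at the type-specific prevalences, methods
#' offered a shifted binomial on 1..12 matching the type mean, and prices
#' log-normal matching the type medians.
#'
#' @param cfg a [site_config()].
#' @param attrs an [attribute_model()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return Data frame of outlets (`outlet_id`, `type`, `x_km`, `y_km`,
#'   attribute columns).
#' @export
generate_outlets <- function(cfg, attrs, seed) {
  stopifnot(inherits(cfg, "site_config"), inherits(attrs, "attribute_model"))
  n <- sum(cfg$n_outlets)
  if (n == 0) stopf("empty supply environment")
  with_seed(seed, {
    type <- rep(names(cfg$n_outlets), cfg$n_outlets)
    xy <- runif_disc(n, cfg$outer_ring_radius)
    out <- data.frame(outlet_id = sprintf("O%04d", seq_len(n)), type = type,
                      x_km = xy[, 1], y_km = xy[, 2],
                      stringsAsFactors = FALSE)
    for (a in rownames(attrs$prevalence))
      out[[a]] <- stats::rbinom(n, 1L, attrs$prevalence[a, type])
    out$methods_offered <- draw_methods(n, attrs$methods_mean[type])
    out$price_ocp <- stats::rlnorm(n, log(attrs$price_ocp_median[type]),
                                   attrs$price_sdlog)
    out$price_injection <- stats::rlnorm(
      n, log(attrs$price_injection_median[type]), attrs$price_sdlog)
    out
  })
}

#' Generate synthetic respondents
#'
#' Respondents are placed uniformly in the inner-ring disc; covariates are
#' drawn independently from the marginal distributions in `covariate_model`
#' (`bernoulli` with probability `p`, or `categorical` with `values` and
#' probabilities `p`).
#'
#' @param cfg a [site_config()].
#' @param covariate_model named list of distribution specs (default
#'   [covariate_preset()]).
#' @param seed integer seed.
#' @return Data frame of respondents (`respondent_id`, `x_km`, `y_km`,
#'   covariate columns).
#' @export
generate_respondents <- function(cfg, covariate_model = covariate_preset(),
                                 seed = 1L) {
  stopifnot(inherits(cfg, "site_config"))
  n <- cfg$n_respondents
  if (n < 1) stopf("n_respondents must be >= 1")
  with_seed(seed, {
    xy <- runif_disc(n, cfg$inner_ring_radius)
    resp <- data.frame(respondent_id = sprintf("R%05d", seq_len(n)),
                       x_km = xy[, 1], y_km = xy[, 2],
                       stringsAsFactors = FALSE)
    for (nm in names(covariate_model)) {
      sp <- covariate_model[[nm]]
      resp[[nm]] <- switch(
        sp$type,
        bernoulli = stats::rbinom(n, 1L, sp$p),
        categorical = sample(sp$values, n, replace = TRUE, prob = sp$p),
        stopf("unknown covariate distribution type '%s' for '%s'",
              sp$type %||% "<missing>", nm))
    }
    resp
  })
}

#' Method-use / linkage categories
#'
#' The six categories of the selection model, in order: 1 no method
#' (reference), 2 traditional method, 3 long-acting method not linked to an
#' outlet, 4 short-acting method not linked, 5 long-acting method linked,
#' 6 short-acting method linked.
#' @return Character vector of length 6.
#' @export
category_labels <- function() {
  c("none", "traditional", "larc_unlinked", "short_unlinked",
    "larc_linked", "short_linked")
}

## design matrix for a coefficient matrix with named columns
selection_design <- function(respondents, coef_names) {
  X <- matrix(1, nrow(respondents), length(coef_names),
              dimnames = list(NULL, coef_names))
  for (nm in setdiff(coef_names, "(Intercept)")) {
    if (!nm %in% names(respondents))
      stopf("selection covariate '%s' not found in respondents", nm)
    X[, nm] <- respondents[[nm]]
  }
  X
}

#' Simulate selection into method-use / linkage categories
#'
#' Assigns each respondent a category in 1..6 by sampling from the
#' multinomial-logit probabilities implied by `truth$selection_coefs`
#' (category 1 is the reference with coefficients zero).  Because the
#' coefficients depend only on observed covariates, linkage is missing at
#' random given observables — the identifying assumption of the IPW
#' correction.
#'
#' @param respondents respondent table (must contain every covariate named
#'   in the coefficient matrix columns).
#' @param truth a [truth_params()] with non-`NULL` `selection_coefs`.
#' @param seed integer seed.
#' @return Integer vector of categories (1..6), one per respondent.
#' @export
simulate_selection <- function(respondents, truth, seed = 1L) {
  stopifnot(inherits(truth, "truth_params"))
  B <- truth$selection_coefs
  if (is.null(B)) stopf("truth has no selection_coefs")
  X <- selection_design(respondents, colnames(B))
  eta <- cbind(0, X %*% t(B))          # n x 6, category 1 reference
  p <- exp(eta - apply(eta, 1, max))
  p <- p / rowSums(p)
  with_seed(seed, {
    u <- stats::runif(nrow(p))
    cum <- t(apply(p, 1, cumsum))
    as.integer(rowSums(u > cum) + 1L)
  })
}

#' Simulate outlet choice under random-coefficient utility
#'
#' For each chooser, draws `beta_i ~ N(beta_mean + shift(x_i),
#' diag(beta_sd^2))`, adds independent standard Gumbel errors per
#' alternative, and picks the maximum-utility outlet in the chooser's choice
#' set.  Choosers with empty choice sets are reported, not silently dropped.
#'
#' @param choice_sets long table from [build_choice_sets()] (rows for the
#'   choosers of interest); `chosen` is ignored and overwritten.
#' @param respondents respondent table (for `beta_shift` covariates).
#' @param truth a [truth_params()].
#' @param seed integer seed.
#' @return List with `choices` (data frame `respondent_id`, `outlet_id`),
#'   `draws` (matrix of realised `beta_i`, chooser x attribute, for oracle
#'   tests) and `excluded` (ids of choosers without alternatives).
#' @export
simulate_outlet_choice <- function(choice_sets, respondents, truth,
                                   seed = 1L) {
  stopifnot(inherits(truth, "truth_params"))
  attrs <- names(truth$beta_mean)
  miss <- setdiff(attrs, names(choice_sets))
  if (length(miss))
    stopf("choice sets lack attribute column(s): %s",
          paste(miss, collapse = ", "))
  ids <- unique(choice_sets$respondent_id)
  excluded <- setdiff(respondents$respondent_id, ids)
  g <- match(choice_sets$respondent_id, ids)
  Z <- as.matrix(choice_sets[, attrs])
  n <- length(ids)
  mu <- matrix(truth$beta_mean, n, length(attrs), byrow = TRUE,
               dimnames = list(NULL, attrs))
  if (!is.null(truth$beta_shift)) {
    ri <- match(ids, respondents$respondent_id)
    for (cv in rownames(truth$beta_shift)) {
      x <- respondents[[cv]][ri]
      for (a in colnames(truth$beta_shift))
        mu[, a] <- mu[, a] + x * truth$beta_shift[cv, a]
    }
  }
  with_seed(seed, {
    eps <- matrix(stats::rnorm(n * length(attrs)), n)
    beta_i <- mu + eps %*% diag(truth$beta_sd[attrs], length(attrs))
    colnames(beta_i) <- attrs
    util <- rowSums(Z * beta_i[g, , drop = FALSE]) +
      -log(-log(stats::runif(nrow(Z))))  # standard Gumbel
    ## argmax within chooser
    best <- tapply(seq_along(util), g, function(ix) ix[which.max(util[ix])])
    choices <- data.frame(
      respondent_id = ids,
      outlet_id = choice_sets$outlet_id[unlist(best)],
      stringsAsFactors = FALSE)
    list(choices = choices, draws = beta_i, excluded = excluded)
  })
}

#' Generate a complete synthetic study
#'
#' Runs the full generator: outlets, respondents, selection into the six
#' method-use/linkage categories, and outlet choices for the linked
#' categories (5 and 6).  Stage seeds are spawned deterministically from
#' `seed`.
#'
#' @param cfg a [site_config()].
#' @param attrs an [attribute_model()].
#' @param truth a [truth_params()].
#' @param covariate_model covariate spec, default [covariate_preset()].
#' @param seed master integer seed.
#' @param all_linked if `TRUE`, skip the selection stage and let every
#'   respondent choose an outlet (useful for choice-model parameter-recovery
#'   studies).
#' @return An object of class `fpc_study`: list with `respondents` (with
#'   `category` and `chosen_outlet`), `outlets`, `links`, `truth`, `draws`
#'   (realised chooser coefficients), `excluded` and the `site` config.
#' @export
simulate_study <- function(cfg, attrs = attribute_preset("kenya"),
                           truth = truth_preset(),
                           covariate_model = covariate_preset(),
                           seed = 1L, all_linked = FALSE) {
  sds <- stage_seeds(seed, 4L)
  outlets <- generate_outlets(cfg, attrs, seed = sds[1])
  resp <- generate_respondents(cfg, covariate_model, seed = sds[2])
  if (all_linked) {
    resp$category <- 6L
  } else {
    resp$category <- simulate_selection(resp, truth, seed = sds[3])
  }
  choosers <- resp[resp$category %in% c(5L, 6L), , drop = FALSE]
  links <- NULL; draws <- NULL; excluded <- character(0)
  if (nrow(choosers)) {
    cs <- build_choice_sets(choosers, outlets, cfg$choice_radius)
    sim <- simulate_outlet_choice(cs, choosers, truth, seed = sds[4])
    links <- sim$choices
    draws <- sim$draws
    excluded <- sim$excluded
    ## choosers with no in-radius outlet revert to the unlinked category
    drop <- resp$respondent_id %in% excluded
    resp$category[drop] <- resp$category[drop] - 2L
  }
  resp$chosen_outlet <- if (is.null(links)) NA_character_ else
    links$outlet_id[match(resp$respondent_id, links$respondent_id)]
  structure(list(respondents = resp, outlets = outlets, links = links,
                 truth = truth, draws = draws, excluded = excluded,
                 site = cfg, seed = as.integer(seed)),
            class = "fpc_study")
}

#' Population-average utility coefficients
#'
#' The mean of `beta_i` over the respondent population implied by a truth
#' with observable preference shifts: `beta_mean + E[x]' beta_shift`, with
#' `E[x]` computed analytically from the covariate model.  This is the
#' estimand that an IPW-corrected choice model targets.
#'
#' @param truth a [truth_params()].
#' @param covariate_model covariate spec, default [covariate_preset()].
#' @return Named vector like `truth$beta_mean`.
#' @export
population_beta <- function(truth, covariate_model = covariate_preset()) {
  b <- truth$beta_mean
  if (is.null(truth$beta_shift)) return(b)
  for (cv in rownames(truth$beta_shift)) {
    sp <- covariate_model[[cv]]
    if (is.null(sp)) stopf("covariate '%s' missing from covariate model", cv)
    ex <- switch(sp$type,
                 bernoulli = sp$p,
                 categorical = sum(sp$values * sp$p))
    for (a in colnames(truth$beta_shift))
      b[a] <- b[a] + ex * truth$beta_shift[cv, a]
  }
  b
}

#' Write a synthetic study to delimited text
#'
#' Writes `respondents.csv`, `outlets.csv`, `choices.csv` and `truth.json`
#' (UTF-8, comma-separated, '.' decimal separator) to a directory.
#'
#' @param study an `fpc_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "fpc_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("respondents.csv", "outlets.csv", "choices.csv",
                            "truth.json"))
  utils::write.csv(study$respondents, paths[1], row.names = FALSE)
  utils::write.csv(study$outlets, paths[2], row.names = FALSE)
  links <- study$links %||% data.frame(respondent_id = character(0),
                                       outlet_id = character(0))
  utils::write.csv(links, paths[3], row.names = FALSE)
  tr <- study$truth
  jsonlite::write_json(
    list(beta_mean = as.list(tr$beta_mean), beta_sd = as.list(tr$beta_sd),
         selection_coefs = tr$selection_coefs,
         beta_shift = tr$beta_shift, seed = tr$seed,
         site = unclass(study$site)),
    paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
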