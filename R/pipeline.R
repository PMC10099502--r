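## End-to-end pipeline: generate (or load) -> validate -> choice sets ->
## environment summaries -> selection MNL + IPW -> screening -> mixed logit
## -> LR test -> willingness to travel, with every artifact written as
## delimited or structured text.

#' Pipeline run configuration
#'
#' @param out_dir directory for stage artifacts.
#' @param preset `"kenya"` or `"uganda"`: synthetic-site preset used when no
#'   external tables are supplied.
#' @param respondents,outlets,links optional externally supplied tables; if
#'   all `NULL`, a synthetic study is generated from the preset.
#' @param attributes outlet attribute columns entering the choice models.
#' @param random_attributes attributes with random coefficients.
#' @param selection_formula RHS formula (as character) of the selection MNL.
#' @param choice_radius km; default from the preset.
#' @param ipw logical, apply the selection correction (default TRUE);
#'   `FALSE` uses unit weights.
#' @param screen logical, run backward screening before the final models.
#' @param p_drop screening threshold (default 0.3).
#' @param n_draws,halton_burn simulation draw settings.
#' @param ci_method `"delta"` or `"simulation"`.
#' @param n_respondents,n_outlets_total synthetic-study sizes.
#' @param seed master seed; per-stage seeds are spawned from it
#'   deterministically.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("fpchoice_run"),
                       preset = c("kenya", "uganda"),
                       respondents = NULL, outlets = NULL, links = NULL,
                       attributes = c("distance_km", "methods_offered",
                                      "open7", "stockout_injectables",
                                      "provider_trained", "fp_signage",
                                      "public", "pharmacy"),
                       random_attributes = c("distance_km",
                                             "methods_offered", "public"),
                       selection_formula =
                         "category ~ educ_college + married + parity + wealth_top",
                       choice_radius = NULL, ipw = TRUE,
                       screen = FALSE, p_drop = 0.3,
                       n_draws = 500L, halton_burn = 10L,
                       ci_method = c("delta", "simulation"),
                       n_respondents = 1500L, n_outlets_total = 30L,
                       seed = 1L) {
  preset <- match.arg(preset)
  ci_method <- match.arg(ci_method)
  ext <- !vapply(list(respondents, outlets), is.null, logical(1))
  if (xor(ext[1], ext[2]))
    stopf("supply both respondents and outlets, or neither")
  structure(list(out_dir = out_dir, preset = preset,
                 respondents = respondents, outlets = outlets, links = links,
                 attributes = attributes,
                 random_attributes = random_attributes,
                 selection_formula = selection_formula,
                 choice_radius = choice_radius, ipw = isTRUE(ipw),
                 screen = isTRUE(screen), p_drop = p_drop,
                 n_draws = as.integer(n_draws),
                 halton_burn = as.integer(halton_burn),
                 ci_method = ci_method,
                 n_respondents = as.integer(n_respondents),
                 n_outlets_total = as.integer(n_outlets_total),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#' `seed` is mandatory.
#' @param path path to a YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stopf("config must set a seed")
  unknown <- setdiff(names(y), names(formals(run_config)))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

#' Validate input tables
#'
#' Structural checks on respondent, outlet and link tables: unique ids,
#' finite coordinates, categories in 1..6, binary attributes in {0,1},
#' methods offered in 1..12, link ids resolvable.  Reports all violations
#' rather than stopping at the first.
#'
#' @param respondents,outlets,links input tables (`links` optional).
#' @return Data frame with columns `check`, `id`, `message`; zero rows when
#'   clean.
#' @export
validate_inputs <- function(respondents, outlets, links = NULL) {
  v <- list()
  add <- function(check, id, message)
    v[[length(v) + 1L]] <<- data.frame(check = check, id = as.character(id),
                                       message = message,
                                       stringsAsFactors = FALSE)
  dup <- respondents$respondent_id[duplicated(respondents$respondent_id)]
  for (d in unique(dup)) add("respondent_id_unique", d, "duplicated id")
  dup <- outlets$outlet_id[duplicated(outlets$outlet_id)]
  for (d in unique(dup)) add("outlet_id_unique", d, "duplicated id")
  for (tb in list(respondents = respondents, outlets = outlets)) {
    bad <- !is.finite(tb$x_km) | !is.finite(tb$y_km)
    idc <- if ("respondent_id" %in% names(tb)) tb$respondent_id else tb$outlet_id
    for (i in which(bad)) add("coordinates_finite", idc[i],
                              "non-finite coordinate")
  }
  if ("category" %in% names(respondents)) {
    bad <- !(respondents$category %in% 1:6)
    for (i in which(bad))
      add("category_domain", respondents$respondent_id[i],
          sprintf("category %s outside 1..6", respondents$category[i]))
  }
  if ("methods_offered" %in% names(outlets)) {
    bad <- !(outlets$methods_offered %in% 1:12)
    for (i in which(bad))
      add("methods_domain", outlets$outlet_id[i],
          "methods_offered outside 1..12")
  }
  for (a in intersect(c("open7", "stockout_injectables", "provider_trained",
                        "fp_signage", "outreach", "counselling", "job_aids"),
                      names(outlets))) {
    bad <- !(outlets[[a]] %in% 0:1)
    for (i in which(bad))
      add("attribute_binary", outlets$outlet_id[i],
          sprintf("%s not in {0,1}", a))
  }
  if (!is.null(links)) {
    for (i in which(!(links$respondent_id %in% respondents$respondent_id)))
      add("link_respondent", links$respondent_id[i], "unknown respondent")
    for (i in which(!(links$outlet_id %in% outlets$outlet_id)))
      add("link_outlet", links$outlet_id[i], "unknown outlet")
  }
  if (!length(v))
    return(data.frame(check = character(0), id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

write_fit_json <- function(fit, path) {
  x <- list(coefficients = as.list(stats::coef(fit)),
            se = as.list(fit$se), logLik = fit$logLik,
            n_choosers = fit$n_choosers, vcov_type = fit$vcov_type)
  if (inherits(fit, "fpc_mixlogit")) {
    x$sd <- as.list(fit$sd)
    x$draws <- list(n_draws = fit$draws$n_draws, burn = fit$draws$burn,
                    seed = fit$draws$seed)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full outlet-choice pipeline
#'
#' Executes the stages in order — generate or load inputs, validate, build
#' choice sets, summarise supply environments, fit the selection MNL and
#' compute IPW (unit weights when `ipw = FALSE`), optional attribute
#' screening, conditional and mixed logit, likelihood-ratio test, and
#' willingness to travel with confidence intervals — writing each stage's
#' artifact as delimited or structured text under `cfg$out_dir`.  Identical
#' configuration and seed give identical artifacts.
#'
#' @param cfg a [run_config()].
#' @return A `fpc_run` report: per-stage record counts, exclusions, fit
#'   summaries, the LR test, the willingness-to-travel table, and a config
#'   echo.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(cfg$seed, 6L)
  report <- list(config = unclass(cfg)[setdiff(names(cfg),
                                               c("respondents", "outlets", "links"))],
                 software = list(
                   package = paste("fpchoice",
                                   as.character(utils::packageVersion("fpchoice"))),
                   r = R.version.string),
                 stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[fpchoice] %-14s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  ## -- inputs ---------------------------------------------------------
  if (is.null(cfg$respondents)) {
    study <- stage("generate", {
      site <- site_preset(cfg$preset, n_outlets_total = cfg$n_outlets_total,
                          n_respondents = cfg$n_respondents)
      simulate_study(site, attribute_preset(cfg$preset),
                     truth_preset(), seed = seeds[1])
    })
    respondents <- study$respondents
    outlets <- study$outlets
    links <- study$links
    radius <- cfg$choice_radius %||% study$site$choice_radius
    write_study(study, cfg$out_dir)
  } else {
    respondents <- cfg$respondents; outlets <- cfg$outlets
    links <- cfg$links
    radius <- cfg$choice_radius %||%
      stopf("choice_radius is required with external tables")
  }
  report$stages$inputs <- list(n_respondents = nrow(respondents),
                               n_outlets = nrow(outlets),
                               n_linked = if (is.null(links)) 0L else nrow(links))

  viol <- stage("validate", validate_inputs(respondents, outlets, links))
  utils::write.csv(viol, file.path(cfg$out_dir, "validation.csv"),
                   row.names = FALSE)
  if (nrow(viol)) stopf("input validation found %d violation(s)", nrow(viol))
  report$stages$validate <- list(violations = nrow(viol))

  ## -- choice sets + environment -------------------------------------
  linked <- respondents[respondents$respondent_id %in% links$respondent_id, ]
  cs <- stage("choice_sets", {
    x <- build_choice_sets(linked, outlets, radius, links = links)
    drop_small_choice_sets(x)
  })
  excl <- exclusions(cs)
  utils::write.csv(as.data.frame(cs),
                   file.path(cfg$out_dir, "choice_sets.csv"),
                   row.names = FALSE)
  utils::write.csv(excl, file.path(cfg$out_dir, "exclusions.csv"),
                   row.names = FALSE)
  report$stages$choice_sets <- list(
    n_choosers = length(unique(cs$respondent_id)), n_rows = nrow(cs),
    n_excluded_empty = sum(excl$reason == "empty_choice_set"),
    n_excluded_small = sum(excl$reason == "too_few_alternatives"),
    n_chosen_out_of_radius = sum(excl$reason == "chosen_outside_radius"))

  env <- stage("environment",
               summarize_environment(respondents, outlets, radius))
  utils::write.csv(env, file.path(cfg$out_dir, "environment.csv"),
                   row.names = FALSE)
  report$stages$environment <- list(n = nrow(env))

  ## -- selection model + IPW -----------------------------------------
  if (cfg$ipw) {
    sel <- stage("selection_mnl", {
      dat <- merge(respondents, env, by = "respondent_id")
      fit <- mnl(stats::as.formula(cfg$selection_formula), data = dat)
      probs <- predict(fit, dat)
      ipw <- compute_ipw(probs, dat$category, dat$respondent_id)
      list(fit = fit, ipw = ipw)
    })
    write_fit_json(sel$fit, file.path(cfg$out_dir, "mnl_fit.json"))
    utils::write.csv(sel$ipw, file.path(cfg$out_dir, "ipw.csv"),
                     row.names = FALSE)
    weights <- sel$ipw
    report$stages$selection <- list(n = sel$fit$n,
                                    logLik = sel$fit$logLik,
                                    n_weighted = nrow(sel$ipw))
  } else {
    weights <- NULL
    report$stages$selection <- list(skipped = TRUE)
  }

  ## -- screening + choice models -------------------------------------
  attrs <- cfg$attributes
  if (cfg$screen) {
    scr <- stage("screening",
                 screen_attributes(cs, attrs, weights = weights,
                                   p_drop = cfg$p_drop))
    utils::write.csv(scr$log, file.path(cfg$out_dir, "screening_log.csv"),
                     row.names = FALSE)
    attrs <- scr$retained
    report$stages$screening <- list(retained = attrs,
                                    dropped = nrow(scr$log))
  }
  clog <- stage("cond_logit", cond_logit(cs, attrs, weights = weights))
  write_fit_json(clog, file.path(cfg$out_dir, "clogit_fit.json"))
  rand <- intersect(cfg$random_attributes, attrs)
  mix <- stage("mixed_logit",
               mixed_logit(cs, attrs, random_attributes = rand,
                           weights = weights,
                           draws = halton_config(cfg$n_draws,
                                                 burn = cfg$halton_burn,
                                                 seed = seeds[2])))
  write_fit_json(mix, file.path(cfg$out_dir, "mixedlogit_fit.json"))
  lrt <- lr_test(clog, mix)
  report$stages$models <- list(
    clogit = list(logLik = clog$logLik, coef = as.list(coef(clog))),
    mixed = list(logLik = mix$logLik, coef = as.list(coef(mix)),
                 sd = as.list(mix$sd)),
    lr_test = lrt)

  ## -- willingness to travel -----------------------------------------
  wtt <- stage("wtt",
               wtt_confidence_interval(mix, method = cfg$ci_method,
                                       seed = seeds[3]))
  utils::write.csv(wtt, file.path(cfg$out_dir, "wtt.csv"), row.names = FALSE)
  report$stages$wtt <- list(table = wtt)

  report$counts_reconcile <-
    report$stages$choice_sets$n_choosers +
    report$stages$choice_sets$n_excluded_empty +
    report$stages$choice_sets$n_excluded_small ==
    report$stages$inputs$n_linked
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  structure(report, class = "fpc_run")
}

#' @export
print.fpc_run <- function(x, ...) {
  cat("fpchoice pipeline run\n")
  cat("  respondents:", x$stages$inputs$n_respondents,
      " outlets:", x$stages$inputs$n_outlets,
      " linked:", x$stages$inputs$n_linked, "\n")
  cat("  choosers:", x$stages$choice_sets$n_choosers,
      " (", x$stages$choice_sets$n_excluded_empty, "excluded )\n")
  if (!is.null(x$stages$models)) {
    cat("  LR mixed vs conditional:",
        format(x$stages$models$lr_test$statistic, digits = 4),
        "on", x$stages$models$lr_test$df, "df, p =",
        format.pval(x$stages$models$lr_test$p_value, digits = 3), "\n")
    cat("Willingness to travel (km):\n")
    print(x$stages$wtt$table, row.names = FALSE)
  }
  invisible(x)
}
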