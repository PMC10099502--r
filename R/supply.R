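## Supply environment: choice-set construction, distance, descriptives.
##
## Coordinates throughout are planar kilometres with the site centre at the
## origin; distances are Euclidean (straight-line), the metric used for the
## radius rules (3 km for the Kenya-like design, 2 km for the Uganda-like
## design).

#' Euclidean distance between planar points
#'
#' Straight-line distance in km between points given as length-2 vectors or
#' two-column matrices of planar km coordinates.
#'
#' @param p,q numeric vectors `c(x, y)` or matrices with columns x, y.
#' @return Nonnegative distance(s) in km.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_distance <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stopf("coordinates must be finite")
  as.numeric(sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2))
}

## all pairwise distances respondents x outlets (n x m)
cross_distances <- function(respondents, outlets) {
  dx <- outer(respondents$x_km, outlets$x_km, "-")
  dy <- outer(respondents$y_km, outlets$y_km, "-")
  sqrt(dx * dx + dy * dy)
}

#' Build radius-limited choice sets
#'
#' Expands respondents x outlets into the long-format table used by the
#' choice models: one row per (respondent, outlet) pair with the outlet
#' within `choice_radius` km of the respondent's residence.  When a table
#' of chosen outlets (`links`) is supplied, the chosen outlet is always
#' retained even if it lies beyond the radius, in which case its row is
#' flagged `out_of_radius = 1`; dropping it would discard the dependent
#' variable of the choice model.
#'
#' @param respondents data frame with columns `respondent_id`, `x_km`, `y_km`.
#' @param outlets data frame with columns `outlet_id`, `x_km`, `y_km`,
#'   `type`, plus any attribute columns (carried through).
#' @param choice_radius radius in km (3 for the Kenya-like design, 2 for the
#'   Uganda-like design).
#' @param links optional data frame `respondent_id`, `outlet_id` of chosen
#'   outlets; only respondents appearing in `links` get a `chosen` flag.
#' @return A data frame (class `fpc_choice_sets`) with columns
#'   `respondent_id`, `outlet_id`, `distance_km`, `chosen`, `out_of_radius`,
#'   `public`, `pharmacy` and all outlet attribute columns.  The exclusion
#'   report — respondents with empty sets and counts of out-of-radius chosen
#'   outlets — is attached as `attr(, "exclusions")` (see [exclusions()]).
#' @export
build_choice_sets <- function(respondents, outlets, choice_radius,
                              links = NULL) {
  stopifnot(all(c("respondent_id", "x_km", "y_km") %in% names(respondents)),
            all(c("outlet_id", "x_km", "y_km") %in% names(outlets)))
  if (!all(is.finite(respondents$x_km)) || !all(is.finite(respondents$y_km)) ||
      !all(is.finite(outlets$x_km)) || !all(is.finite(outlets$y_km)))
    stopf("coordinates must be finite")
  if (choice_radius < 0) stopf("choice_radius must be nonnegative")
  if (!is.null(links)) {
    bad <- setdiff(links$outlet_id, outlets$outlet_id)
    if (length(bad))
      stopf("chosen outlet id(s) absent from outlets table: %s",
            paste(bad, collapse = ", "))
  }
  D <- cross_distances(respondents, outlets)
  keep <- D <= choice_radius
  chosen_col <- rep(NA, nrow(respondents))
  if (!is.null(links))
    chosen_col <- links$outlet_id[match(respondents$respondent_id,
                                        links$respondent_id)]
  chosen_j <- match(chosen_col, outlets$outlet_id)  # column index or NA
  ## force the chosen outlet into the set; flag it when beyond the radius
  oor_i <- which(!is.na(chosen_j) &
                   !keep[cbind(seq_along(chosen_j), chosen_j)])
  keep[cbind(oor_i, chosen_j[oor_i])] <- TRUE
  idx <- which(t(keep), arr.ind = TRUE)  # transpose: respondent-major order
  ri <- idx[, 2L]; oj <- idx[, 1L]
  cs <- data.frame(
    respondent_id = respondents$respondent_id[ri],
    outlet_id = outlets$outlet_id[oj],
    distance_km = D[cbind(ri, oj)],
    chosen = ifelse(is.na(chosen_j[ri]), NA_integer_,
                    as.integer(oj == chosen_j[ri])),
    out_of_radius = as.integer(ri %in% oor_i & oj == chosen_j[ri]),
    stringsAsFactors = FALSE)
  empty <- as.character(respondents$respondent_id[rowSums(keep) == 0])
  oor <- as.character(respondents$respondent_id[oor_i])
  ## carry outlet attributes (everything but coordinates)
  attr_cols <- setdiff(names(outlets), c("x_km", "y_km"))
  cs <- merge(cs, outlets[, attr_cols, drop = FALSE], by = "outlet_id",
              sort = FALSE)
  cs <- cs[order(match(cs$respondent_id, respondents$respondent_id),
                 cs$distance_km), ]
  if ("type" %in% names(cs)) {
    cs$public <- as.integer(cs$type == "public")
    cs$pharmacy <- as.integer(cs$type == "pharmacy")
  }
  rownames(cs) <- NULL
  excl <- data.frame(
    reason = c(rep("empty_choice_set", length(empty)),
               rep("chosen_outside_radius", length(oor))),
    respondent_id = c(empty, oor), stringsAsFactors = FALSE)
  attr(cs, "exclusions") <- excl
  attr(cs, "choice_radius") <- choice_radius
  class(cs) <- c("fpc_choice_sets", "data.frame")
  cs
}

#' Exclusion report of a choice-set table
#'
#' @param x a table returned by [build_choice_sets()].
#' @return Data frame with columns `reason`
#'   (`empty_choice_set` / `chosen_outside_radius`) and `respondent_id`.
#' @export
exclusions <- function(x) attr(x, "exclusions")

#' Drop choosers with too few alternatives
#'
#' Choice models need at least two alternatives per chooser; respondents
#' whose radius contains only their chosen outlet carry no information
#' about trade-offs.  This filter removes them and extends the exclusion
#' report rather than dropping them silently.
#'
#' @param cs a table from [build_choice_sets()].
#' @param min_alternatives smallest admissible choice-set size (default 2).
#' @return The filtered table, with the removed respondents appended to
#'   `attr(, "exclusions")` under reason `too_few_alternatives`.
#' @export
drop_small_choice_sets <- function(cs, min_alternatives = 2L) {
  sizes <- table(cs$respondent_id)
  small <- names(sizes)[sizes < min_alternatives]
  if (!length(small)) return(cs)
  excl <- rbind(attr(cs, "exclusions"),
                data.frame(reason = "too_few_alternatives",
                           respondent_id = small, stringsAsFactors = FALSE))
  out <- cs[!(cs$respondent_id %in% small), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  attr(out, "choice_radius") <- attr(cs, "choice_radius")
  class(out) <- class(cs)
  out
}

#' Supply-environment summaries per respondent
#'
#' For each respondent, counts of outlets by type within the radius, the
#' count offering outreach, and the mean number of contraceptive methods
#' available at in-radius outlets.  Respondents with no in-radius outlet get
#' zero counts and `NA` for the mean.
#'
#' @inheritParams build_choice_sets
#' @return Data frame with columns `respondent_id`, `n_outlets`,
#'   `n_public`, `n_private`, `n_pharmacy`, `n_outreach`, `mean_methods`.
#' @export
summarize_environment <- function(respondents, outlets, choice_radius) {
  D <- cross_distances(respondents, outlets)
  keep <- D <= choice_radius
  typ <- outlets$type
  outreach <- outlets$outreach %||% rep(0L, nrow(outlets))
  methods <- outlets$methods_offered %||% rep(NA_real_, nrow(outlets))
  n_in <- rowSums(keep)
  data.frame(
    respondent_id = respondents$respondent_id,
    n_outlets = n_in,
    n_public = as.vector(keep %*% (typ == "public")),
    n_private = as.vector(keep %*% (typ == "private")),
    n_pharmacy = as.vector(keep %*% (typ == "pharmacy")),
    n_outreach = as.vector(keep %*% (outreach == 1)),
    mean_methods = ifelse(n_in > 0,
                          as.vector(keep %*% methods) / pmax(n_in, 1),
                          NA_real_),
    stringsAsFactors = FALSE)
}

#' Outlet linkage rate
#'
#' Percentage of modern-method users who could be linked to the outlet where
#' they obtained their method, rounded half-up to one decimal (the printed
#' convention of study descriptives).
#'
#' @param n_users number of users (denominator), at least 1.
#' @param n_linked number linked to an outlet, `0 <= n_linked <= n_users`.
#' @return Percentage with one decimal.
#' @examples
#' linkage_rate(795, 272)  # 34.2
#' @export
linkage_rate <- function(n_users, n_linked) {
  if (any(n_users < 1)) stopf("n_users must be >= 1")
  if (any(n_linked < 0) || any(n_linked > n_users))
    stopf("n_linked must be between 0 and n_users")
  round_half_up(100 * n_linked / n_users, 1)
}
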