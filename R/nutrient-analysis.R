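# Problem-nutrient classification and best-food-source identification
# from the best-diet and per-nutrient maximized-diet profiles.

#' Classify problem nutrients
#'
#' A nutrient is an *absolute* problem nutrient when it stays below the
#' RNI cutoff both in the nutritionally best diet and in its own
#' maximized diet (its requirement cannot be met within the observed
#' dietary pattern); a *partial* problem nutrient falls below the cutoff
#' in the best diet but reaches it in its own maximized diet (attainable
#' only at the expense of other nutrients); otherwise it is not a problem
#' nutrient. The comparison is strict: exactly 100 % of the RNI is not a
#' problem.
#'
#' @param best_profile Tibble with `nutrient_id`, `pct_rni` from the best
#'   diet (e.g. `solve_best_diet(...)$nutrients`).
#' @param max_profiles Tibble with `nutrient_id`, `pct_rni` giving each
#'   nutrient's %RNI in its own maximized diet ([extreme_profiles()] with
#'   `direction = "max"`).
#' @param rni_cutoff Percent-of-RNI cutoff (default 100).
#' @param nutrients Nutrient dictionary.
#' @return Tibble `nutrient_id`, `best_pct_rni`, `max_pct_rni`, `class`
#'   (factor: absolute, partial, none), one row per target micronutrient.
#' @export
classify_problem_nutrients <- function(best_profile, max_profiles,
                                       rni_cutoff = 100,
                                       nutrients = default_nutrients()) {
  micros <- target_micronutrients(nutrients)
  best <- setNames(best_profile$pct_rni, best_profile$nutrient_id)
  maxd <- setNames(max_profiles$pct_rni, max_profiles$nutrient_id)
  missing <- c(setdiff(micros, names(best)), setdiff(micros, names(maxd)))
  if (length(missing)) {
    abort(paste0("Missing %RNI for nutrient(s): ", paste(unique(missing), collapse = ", ")))
  }
  if (anyNA(best[micros]) || anyNA(maxd[micros])) {
    abort("NA %RNI supplied to classification; solve the diets first.")
  }
  tibble(
    nutrient_id = micros,
    best_pct_rni = unname(best[micros]),
    max_pct_rni = unname(maxd[micros])
  ) %>%
    mutate(class = factor(
      case_when(
        .data$best_pct_rni < rni_cutoff & .data$max_pct_rni < rni_cutoff ~ "absolute",
        .data$best_pct_rni < rni_cutoff & .data$max_pct_rni >= rni_cutoff ~ "partial",
        TRUE ~ "none"
      ),
      levels = c("absolute", "partial", "none")
    ))
}

#' Subgroup-level nutrient shares of a diet
#'
#' For every food subgroup (with breast milk counted as its own
#' subgroup), the percent contribution to each nutrient's total content
#' of the diet. Shares of a nutrient sum to 100 across subgroups whenever
#' the total is positive; a nutrient with zero total gets share 0 and
#' `undefined = TRUE`.
#'
#' @param diet A `diet_solution` (or a servings tibble/vector).
#' @param params A `cfr_params`.
#' @return Tibble `subgroup`, `group`, `nutrient_id`, `share_pct`,
#'   `undefined`.
#' @export
nutrient_source_shares <- function(diet, params) {
  servings <- if (inherits(diet, "diet_solution")) {
    if (diet$status != "optimal") abort("Diet is not optimal; no shares to compute.")
    diet$servings
  } else {
    diet
  }
  if (is.data.frame(servings)) servings <- setNames(servings$servings, servings$food_id)
  x <- setNames(rep(0, nrow(params$foods)), params$foods$food_id)
  x[names(servings)] <- servings

  per_serving <- sweep(params$composition, 2, params$foods$portion_g / 100, `*`)
  weekly_by_food <- sweep(per_serving, 2, x, `*`)     # nutrient x food

  sub_of_food <- params$foods$subgroup
  grp_of_sub <- params$foods %>% distinct(.data$subgroup, .data$group)
  subs <- unique(sub_of_food)
  by_sub <- vapply(subs, function(s) {
    rowSums(weekly_by_food[, sub_of_food == s, drop = FALSE])
  }, numeric(nrow(weekly_by_food)))
  by_sub <- cbind(by_sub, breast_milk = unname(params$breast_milk$weekly_nutrients))
  totals <- rowSums(by_sub)

  out <- as_tibble(by_sub, rownames = "nutrient_id") %>%
    tidyr::pivot_longer(-"nutrient_id", names_to = "subgroup", values_to = "weekly_amount") %>%
    mutate(
      total = unname(totals[.data$nutrient_id]),
      undefined = .data$total <= 0,
      share_pct = unname(ifelse(.data$undefined, 0, 100 * .data$weekly_amount / .data$total))
    ) %>%
    left_join(grp_of_sub, by = "subgroup") %>%
    mutate(group = ifelse(.data$subgroup == "breast_milk", "breast_milk", .data$group)) %>%
    select("subgroup", "group", "nutrient_id", "share_pct", "undefined")
  out
}

#' Identify the best food sources in a diet
#'
#' A good food source is a subgroup contributing at least
#' `share_threshold` percent of a nutrient's diet content; a *best*
#' source does so for at least `min_nutrients` of the target
#' micronutrients in the nutritionally best diet.
#'
#' @inheritParams nutrient_source_shares
#' @param share_threshold Minimum percent contribution (default 5).
#' @param min_nutrients Minimum count of supported micronutrients
#'   (default 5).
#' @return Tibble `subgroup`, `group`, `n_nutrients_supported`,
#'   `is_best_source`, plus a list-column `supported` naming the
#'   supported micronutrients.
#' @export
best_food_sources <- function(diet, params, share_threshold = 5, min_nutrients = 5) {
  micros <- target_micronutrients(params$nutrients)
  shares <- nutrient_source_shares(diet, params) %>%
    filter(.data$nutrient_id %in% micros)
  shares %>%
    group_by(.data$subgroup, .data$group) %>%
    summarise(
      n_nutrients_supported = sum(.data$share_pct >= share_threshold & !.data$undefined),
      supported = list(.data$nutrient_id[.data$share_pct >= share_threshold & !.data$undefined]),
      .groups = "drop"
    ) %>%
    mutate(is_best_source = .data$n_nutrients_supported >= min_nutrients) %>%
    arrange(desc(.data$n_nutrients_supported), .data$subgroup)
}
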