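# Conversion of one target group's 24 h recalls into the weekly diet-model
# parameters: median consumer portions, percentile gram bounds per food,
# percentile serving bounds per food group/subgroup, observed medians, and
# the fixed breast-milk term.

group_recalls <- function(recalls, target_group) {
  recalls %>%
    filter(.data$target_group == !!target_group) %>%
    group_by(.data$child_id, .data$food_id) %>%
    summarise(grams = sum(.data$grams), .groups = "drop")
}

group_children <- function(recalls, target_group) {
  unique(recalls$child_id[recalls$target_group == target_group])
}

#' Median consumer portion of a food
#'
#' The serving size (grams per serving) of a food for a target group is
#' the median daily intake among the children who actually consumed it
#' (grams summed within a child's recall day first). Median convention:
#' mean of the two middle order statistics at even n.
#'
#' @param recalls A `cfr_recalls` tibble.
#' @param food_id Food identifier.
#' @param target_group Target group identifier.
#' @return Median grams per consumer-day (a single number).
#' @export
median_consumer_portion <- function(recalls, food_id, target_group) {
  g <- group_recalls(recalls, target_group)
  x <- g$grams[g$food_id == food_id]
  if (length(x) == 0) {
    abort(sprintf("No consumers of '%s' in target group '%s'.", food_id, target_group))
  }
  median(x)
}

#' Weekly gram bounds for one food item
#'
#' Per-child weekly grams are daily recall grams multiplied by 7
#' (non-consumers contribute zeros by default); the bounds are the
#' `p_lo`/`p_hi` percentiles (linear interpolation) of that distribution,
#' with the lower bound floored at 0. Foods consumed by fewer than two
#' children keep bounds `(0, 7 x max observed grams)` so that every
#' reported food remains modellable.
#'
#' @inheritParams median_consumer_portion
#' @param p_lo,p_hi Percentiles (default 10 and 90).
#' @param include_nonconsumers Include zeros for children who did not eat
#'   the food (default `TRUE`).
#' @return Named numeric vector `c(lo, hi)` in grams/week.
#' @export
weekly_item_gram_bounds <- function(recalls, food_id, target_group,
                                    p_lo = 10, p_hi = 90,
                                    include_nonconsumers = TRUE) {
  if (p_lo >= p_hi) abort("`p_lo` must be smaller than `p_hi`.")
  g <- group_recalls(recalls, target_group)
  children <- unique(g$child_id)
  cons <- g %>% filter(.data$food_id == !!food_id)
  if (nrow(cons) == 0) {
    abort(sprintf("No consumers of '%s' in target group '%s'.", food_id, target_group))
  }
  if (nrow(cons) < 2) {
    return(c(lo = 0, hi = 7 * max(cons$grams)))
  }
  weekly <- if (include_nonconsumers) {
    7 * c(cons$grams, rep(0, length(children) - nrow(cons)))
  } else {
    7 * cons$grams
  }
  c(lo = max(0, pctl(weekly, p_lo)), hi = pctl(weekly, p_hi))
}

# Per-child weekly servings of a set of foods, given per-food portions.
child_weekly_servings <- function(recalls, food_ids, target_group, portions) {
  g <- group_recalls(recalls, target_group)
  children <- unique(g$child_id)
  member <- g %>% filter(.data$food_id %in% food_ids)
  missing <- setdiff(unique(member$food_id), names(portions))
  if (length(missing)) {
    abort(paste0("No portion size for food(s): ", paste(missing, collapse = ", ")))
  }
  per_child <- member %>%
    mutate(servings = .data$grams / portions[.data$food_id]) %>%
    group_by(.data$child_id) %>%
    summarise(servings = sum(.data$servings), .groups = "drop")
  out <- setNames(rep(0, length(children)), children)
  out[per_child$child_id] <- per_child$servings
  7 * out
}

#' Weekly serving bounds for a food group or subgroup
#'
#' Per child, group servings per day are the sum over member foods of
#' grams divided by that food's portion size; bounds are the
#' `p_lo`/`p_hi` percentiles of 7 times that per-child distribution over
#' all children in the target group.
#'
#' @inheritParams weekly_item_gram_bounds
#' @param food_ids Member food ids of the group/subgroup.
#' @param portions Named vector of portion sizes (g/serving) covering all
#'   consumed member foods.
#' @return Named numeric vector `c(lo, hi)` in servings/week.
#' @export
weekly_group_serving_bounds <- function(recalls, food_ids, target_group, portions,
                                        p_lo = 10, p_hi = 90,
                                        include_nonconsumers = TRUE) {
  if (p_lo >= p_hi) abort("`p_lo` must be smaller than `p_hi`.")
  weekly <- child_weekly_servings(recalls, food_ids, target_group, portions)
  if (!include_nonconsumers) weekly <- weekly[weekly > 0]
  if (length(weekly) == 0 || all(weekly == 0)) {
    return(c(lo = 0, hi = 0))
  }
  c(lo = max(0, pctl(weekly, p_lo)), hi = pctl(weekly, p_hi))
}

#' Observed median weekly servings of a food group
#'
#' Median over all children in the target group of 7 times daily group
#' servings; the reference against which best-diet food-group patterns
#' are compared when proposing recommendations.
#'
#' @inheritParams weekly_group_serving_bounds
#' @return Servings/week (a single number).
#' @export
observed_median_group_servings <- function(recalls, food_ids, target_group, portions) {
  weekly <- child_weekly_servings(recalls, food_ids, target_group, portions)
  if (length(weekly) == 0) return(0)
  median(weekly)
}

#' Construct diet-model parameters directly
#'
#' Low-level constructor used by [build_model_parameters()] and by the
#' synthetic test harness; all amounts are weekly unless suffixed
#' otherwise.
#'
#' @param target_group_id,age_band,livelihood Group labels.
#' @param energy_kcal_day Daily energy requirement E (kcal); the weekly
#'   energy equality target is 7E.
#' @param foods Tibble `food_id`, `name`, `group`, `subgroup`,
#'   `portion_g`, `gram_lo`, `gram_hi`, `n_consumers`,
#'   `obs_median_servings_wk`.
#' @param bounds Tibble `level` ("group"/"subgroup"), `target_id`, `lo`,
#'   `hi`, `observed_median` (servings/week).
#' @param composition Matrix (nutrient x food) of densities per 100 g for
#'   the included foods, or a composition tibble to take them from.
#' @param rni Named daily RNI vector for this age band.
#' @param breast_milk_g_day Daily breast-milk intake (g).
#' @param breast_milk_composition Named per-100 g vector.
#' @param nutrients Nutrient dictionary.
#' @param thresholds Threshold list (see `cfrlp:::default_thresholds`).
#' @return A `cfr_params` object.
#' @export
cfr_params <- function(target_group_id, age_band, livelihood,
                       energy_kcal_day, foods, bounds,
                       composition, rni,
                       breast_milk_g_day, breast_milk_composition,
                       nutrients = default_nutrients(),
                       thresholds = list()) {
  foods <- as_tibble(foods)
  bounds <- as_tibble(bounds)
  th <- utils::modifyList(default_thresholds(), thresholds)
  if (nrow(foods) == 0) abort("`foods` is empty: nothing to model.")
  if (any(foods$portion_g <= 0)) abort("Every included food needs a positive portion size.")
  if (any(foods$gram_lo > foods$gram_hi)) abort("Item gram bounds must satisfy lo <= hi.")
  if (nrow(bounds) && any(bounds$lo > bounds$hi)) abort("Serving bounds must satisfy lo <= hi.")

  if (is.data.frame(composition)) {
    comp_tbl <- composition
    missing <- setdiff(foods$food_id, comp_tbl$food_id)
    if (length(missing)) {
      abort(paste0("Food(s) absent from composition table: ", paste(missing, collapse = ", ")))
    }
    rows <- match(foods$food_id, comp_tbl$food_id)
    composition <- t(as.matrix(comp_tbl[rows, nutrients$nutrient_id, drop = FALSE]))
    colnames(composition) <- foods$food_id
  }
  if (!all(nutrients$nutrient_id %in% rownames(composition))) {
    abort("`composition` matrix must have one row per dictionary nutrient.")
  }
  composition <- composition[nutrients$nutrient_id, foods$food_id, drop = FALSE]

  bm_weekly_g <- 7 * breast_milk_g_day
  bm_comp <- setNames(rep(0, nrow(nutrients)), nutrients$nutrient_id)
  bm_comp[names(breast_milk_composition)] <- breast_milk_composition
  bm_weekly_nutrients <- bm_weekly_g * bm_comp / 100

  weekly_target <- 7 * energy_kcal_day
  bm_weekly_kcal <- unname(bm_weekly_nutrients["energy"])
  if (bm_weekly_kcal > weekly_target) {
    abort(sprintf(
      "Breast milk alone exceeds the energy target (%g > %g kcal/week).",
      bm_weekly_kcal, weekly_target
    ))
  }

  structure(
    list(
      target_group_id = target_group_id,
      age_band = age_band,
      livelihood = livelihood,
      energy_kcal_day = energy_kcal_day,
      foods = foods,
      bounds = bounds,
      composition = composition,
      rni = rni,
      nutrients = nutrients,
      breast_milk = list(
        g_day = breast_milk_g_day,
        weekly_g = bm_weekly_g,
        weekly_nutrients = bm_weekly_nutrients
      ),
      energy = list(
        weekly_target_kcal = weekly_target,
        bm_weekly_kcal = bm_weekly_kcal,
        comp_weekly_kcal = weekly_target - bm_weekly_kcal
      ),
      thresholds = th
    ),
    class = "cfr_params"
  )
}

#' @export
print.cfr_params <- function(x, ...) {
  cat("<cfr_params> ", x$target_group_id, "\n", sep = "")
  cat(sprintf(
    "  %d foods, %d group/subgroup bounds; E = %g kcal/d (7d target %g kcal)\n",
    nrow(x$foods), nrow(x$bounds), x$energy_kcal_day, x$energy$weekly_target_kcal
  ))
  cat(sprintf(
    "  breast milk fixed at %g g/d (%g kcal/week); complementary budget %g kcal/week\n",
    x$breast_milk$g_day, x$energy$bm_weekly_kcal, x$energy$comp_weekly_kcal
  ))
  invisible(x)
}

#' Build diet-model parameters for one target group
#'
#' Assembles the complete weekly linear-programming inputs from
#' exclusion-filtered recalls: every food consumed by at least one child
#' in the group enters with its median consumer portion and percentile
#' gram bounds; food groups and subgroups receive percentile serving
#' bounds and observed medians; breast milk is fixed at the configured
#' daily grams times 7 with nutrients from the configured composition
#' vector; the weekly energy equality target is 7 times the group's
#' daily energy requirement.
#'
#' @param recalls A `cfr_recalls` tibble (exclusions already applied).
#' @param composition A `cfr_composition` tibble.
#' @param config A `cfr_config`.
#' @param target_group Target group id (must appear in
#'   `config$target_groups`).
#' @return A `cfr_params` object.
#' @export
build_model_parameters <- function(recalls, composition, config, target_group) {
  tg <- config$target_groups %>% filter(.data$target_group_id == !!target_group)
  if (nrow(tg) != 1) abort(paste0("Unknown target group: ", target_group))
  g <- group_recalls(recalls, target_group)
  if (nrow(g) == 0) abort(paste0("No recall records for target group ", target_group))
  th <- config$thresholds

  food_ids <- sort(unique(g$food_id))
  missing <- setdiff(food_ids, composition$food_id)
  if (length(missing)) {
    abort(paste0("Recalled food(s) absent from composition table: ", paste(missing, collapse = ", ")))
  }

  foods <- purrr::map(food_ids, function(f) {
    portion <- median_consumer_portion(recalls, f, target_group)
    b <- weekly_item_gram_bounds(
      recalls, f, target_group,
      p_lo = th$p_lo, p_hi = th$p_hi,
      include_nonconsumers = th$include_nonconsumers
    )
    n_cons <- sum(g$food_id == f)
    tibble(
      food_id = f, portion_g = portion,
      gram_lo = unname(b["lo"]), gram_hi = unname(b["hi"]),
      n_consumers = n_cons
    )
  }) %>% list_rbind()

  meta <- composition %>%
    select("food_id", "name", "group", "subgroup") %>%
    filter(.data$food_id %in% food_ids)
  foods <- foods %>% left_join(meta, by = "food_id")
  portions <- setNames(foods$portion_g, foods$food_id)

  obs_item <- child_weekly_servings_by_food <- foods %>%
    mutate(obs_median_servings_wk = map_dbl(.data$food_id, function(f) {
      observed_median_group_servings(recalls, f, target_group, portions)
    }))
  foods <- obs_item %>%
    select(
      "food_id", "name", "group", "subgroup", "portion_g",
      "gram_lo", "gram_hi", "n_consumers", "obs_median_servings_wk"
    )

  level_bounds <- function(level) {
    split_ids <- split(foods$food_id, foods[[level]])
    purrr::imap(split_ids, function(ids, label) {
      b <- weekly_group_serving_bounds(
        recalls, ids, target_group, portions,
        p_lo = th$p_lo, p_hi = th$p_hi,
        include_nonconsumers = th$include_nonconsumers
      )
      tibble(
        level = level, target_id = label,
        lo = unname(b["lo"]), hi = unname(b["hi"]),
        observed_median = observed_median_group_servings(recalls, ids, target_group, portions)
      )
    }) %>% list_rbind()
  }
  bounds <- bind_rows(level_bounds("group"), level_bounds("subgroup"))

  bm <- breast_milk_for_band(config, tg$age_band)
  cfr_params(
    target_group_id = target_group,
    age_band = tg$age_band,
    livelihood = tg$livelihood,
    energy_kcal_day = tg$energy_kcal_day,
    foods = foods,
    bounds = bounds,
    composition = composition,
    rni = rni_vector(config, tg$age_band),
    breast_milk_g_day = bm$grams_per_day,
    breast_milk_composition = config$breast_milk_composition,
    nutrients = config$nutrients,
    thresholds = th
  )
}
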