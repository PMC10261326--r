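# Study configuration: nutrients, target groups, RNIs, breast milk,
# decision thresholds. Everything the diet models need that is not data.

#' Default nutrient dictionary
#'
#' Thirteen tracked nutrients: energy and protein plus the eleven target
#' micronutrients examined for adequacy (calcium, iron, zinc, vitamin A,
#' riboflavin, thiamin, niacin, vitamin B6, folate, vitamin B12 and
#' vitamin C). Energy and protein are tracked through every diet model but
#' are never classified as problem nutrients.
#'
#' @return A tibble with columns `nutrient_id`, `name`, `unit`,
#'   `is_target_micronutrient`.
#' @export
default_nutrients <- function() {
  tibble(
    nutrient_id = c(
      "energy", "protein", "calcium", "iron", "zinc", "vitamin_a",
      "riboflavin", "thiamin", "niacin", "vitamin_b6", "folate",
      "vitamin_b12", "vitamin_c"
    ),
    name = c(
      "Energy", "Protein", "Calcium", "Iron", "Zinc", "Vitamin A",
      "Riboflavin", "Thiamin", "Niacin", "Vitamin B6", "Folate",
      "Vitamin B12", "Vitamin C"
    ),
    unit = c(
      "kcal", "g", "mg", "mg", "mg", "ug_re",
      "mg", "mg", "mg", "mg", "ug", "ug", "mg"
    ),
    is_target_micronutrient = c(FALSE, FALSE, rep(TRUE, 11))
  )
}

#' Ids of the target micronutrients
#' @param nutrients Nutrient dictionary tibble (default [default_nutrients()]).
#' @return Character vector of 11 nutrient ids.
#' @export
target_micronutrients <- function(nutrients = default_nutrients()) {
  nutrients$nutrient_id[nutrients$is_target_micronutrient]
}

#' Default breast-milk assumptions per age band
#'
#' Breast milk is assumed, not measured: it contributes 67, 55 and 39 % of
#' the median energy requirement at 6-8, 9-11 and 12-23 months, which with
#' an energy density of 0.66 kcal/g (2.76 kJ/g) corresponds to daily
#' intakes of 570, 520 and 420 g.
#'
#' @return Tibble with one row per age band: `age_band`, `energy_fraction`,
#'   `grams_per_day`, `energy_density_kcal_g`.
#' @export
default_breast_milk <- function() {
  tibble(
    age_band = c("m6_8", "m9_11", "m12_23"),
    energy_fraction = c(0.67, 0.55, 0.39),
    grams_per_day = c(570, 520, 420),
    energy_density_kcal_g = 0.66
  )
}

#' Placeholder breast-milk composition (synthetic)
#'
#' Per-100 g nutrient composition of mature breast milk used by the
#' synthetic study configuration. These are plausible literature-style
#' values assembled for simulation; real analyses must supply their own
#' vector in the study config.
#'
#' @return Named numeric vector (per 100 g).
#' @export
synthetic_breast_milk_composition <- function() {
  c(
    energy = 66, protein = 1.0, calcium = 28, iron = 0.03, zinc = 0.12,
    vitamin_a = 50, riboflavin = 0.035, thiamin = 0.021, niacin = 0.15,
    vitamin_b6 = 0.011, folate = 6, vitamin_b12 = 0.05, vitamin_c = 4
  )
}

#' Placeholder daily RNI values per age band (synthetic)
#'
#' Daily Recommended Nutrient Intakes used by the synthetic study
#' configuration, in the dictionary units, at 15 % zinc and 5 % iron
#' bioavailability. The two younger bands share infant values; the 12-23
#' month band uses young-child values. Real analyses must supply the RNI
#' table in the study config.
#'
#' @return Tibble `age_band`, `nutrient_id`, `rni`.
#' @export
synthetic_rni_table <- function() {
  infant <- c(
    calcium = 400, iron = 18.6, zinc = 4.1, vitamin_a = 400,
    riboflavin = 0.4, thiamin = 0.3, niacin = 4, vitamin_b6 = 0.3,
    folate = 80, vitamin_b12 = 0.7, vitamin_c = 30, protein = 11
  )
  child <- c(
    calcium = 500, iron = 11.6, zinc = 4.1, vitamin_a = 400,
    riboflavin = 0.5, thiamin = 0.5, niacin = 6, vitamin_b6 = 0.5,
    folate = 150, vitamin_b12 = 0.9, vitamin_c = 30, protein = 13
  )
  bind_rows(
    tibble(age_band = "m6_8", nutrient_id = names(infant), rni = unname(infant)),
    tibble(age_band = "m9_11", nutrient_id = names(infant), rni = unname(infant)),
    tibble(age_band = "m12_23", nutrient_id = names(child), rni = unname(child))
  )
}

default_thresholds <- function() {
  list(
    adequacy_cutoff = 65,      # minimized %RNI >= 65 defines population adequacy
    rni_cutoff = 100,          # problem-nutrient cutoff, strict <
    source_share_pct = 5,      # a good source contributes >= 5% of a nutrient
    source_min_nutrients = 5,  # ...for at least 5 micronutrients
    p_lo = 10, p_hi = 90,      # weekly bound percentiles
    keep_k = 8,                # screened candidates kept for the search
    max_set_size = 5,          # largest CFR combination tested
    energy_tolerance = 0,      # relative slack on the energy equality
    include_nonconsumers = TRUE, # zeros enter bound distributions
    niacin_tryptophan_note = TRUE # annotate reports: tryptophan not modelled
  )
}

#' Assemble a study configuration
#'
#' Collects everything the pipeline needs beyond the data files: the
#' nutrient dictionary, the target groups (age band x livelihood, with
#' daily energy requirement), the RNI table, the breast-milk assumptions
#' and the decision thresholds. Defaults left `NULL` are filled from the
#' package defaults and echoed with a message.
#'
#' @param target_groups Tibble with columns `target_group_id`, `age_band`
#'   (`m6_8`, `m9_11` or `m12_23`), `livelihood`, `energy_kcal_day`.
#' @param rni Tibble `age_band`, `nutrient_id`, `rni` (daily amounts in
#'   dictionary units). Must cover all 11 target micronutrients per band
#'   in use.
#' @param breast_milk Tibble as [default_breast_milk()]; rows override the
#'   defaults by `age_band`.
#' @param breast_milk_composition Named per-100 g nutrient vector.
#' @param nutrients Nutrient dictionary tibble.
#' @param thresholds Named list merged over the defaults (see
#'   `cfrlp:::default_thresholds`).
#' @param exclusions Character vector of food ids to drop from recalls
#'   (condiments, foods of no nutritional value, therapeutic foods,
#'   uncommon foods), or a tibble `food_id`, `reason`.
#' @param zinc_bioavailability,iron_bioavailability Labels recording which
#'   RNI column was chosen (defaults "15%" and "5%"); they select the
#'   supplied RNI values and are never applied as multipliers.
#' @param quiet Suppress the default-echo messages.
#' @return An object of class `cfr_config`.
#' @export
study_config <- function(target_groups,
                         rni,
                         breast_milk = NULL,
                         breast_milk_composition = NULL,
                         nutrients = default_nutrients(),
                         thresholds = list(),
                         exclusions = character(),
                         zinc_bioavailability = "15%",
                         iron_bioavailability = "5%",
                         quiet = FALSE) {
  target_groups <- as_tibble(target_groups)
  req_cols <- c("target_group_id", "age_band", "livelihood", "energy_kcal_day")
  if (!all(req_cols %in% names(target_groups))) {
    abort(paste0("`target_groups` needs columns: ", paste(req_cols, collapse = ", ")))
  }
  bad_band <- setdiff(unique(target_groups$age_band), c("m6_8", "m9_11", "m12_23"))
  if (length(bad_band)) abort(paste0("Unknown age band(s): ", paste(bad_band, collapse = ", ")))

  bm <- default_breast_milk()
  if (!is.null(breast_milk)) {
    breast_milk <- as_tibble(breast_milk)
    bm <- bm %>%
      filter(!.data$age_band %in% breast_milk$age_band) %>%
      bind_rows(breast_milk) %>%
      arrange(match(.data$age_band, c("m6_8", "m9_11", "m12_23")))
  } else if (!quiet) {
    inform("Breast-milk defaults applied: 570/520/420 g/d at 0.66 kcal/g (67/55/39% of energy).")
  }

  if (is.null(breast_milk_composition)) {
    breast_milk_composition <- synthetic_breast_milk_composition()
    if (!quiet) inform("Using the synthetic placeholder breast-milk composition vector.")
  }

  th <- utils::modifyList(default_thresholds(), thresholds)
  if (!quiet && length(thresholds) == 0) {
    inform(sprintf(
      "Thresholds: adequacy >= %g%% RNI (minimized diets), problem-nutrient cutoff %g%% RNI, best source >= %g%% of >= %g nutrients, bounds P%g-P%g.",
      th$adequacy_cutoff, th$rni_cutoff, th$source_share_pct,
      th$source_min_nutrients, th$p_lo, th$p_hi
    ))
  }
  if (th$p_lo >= th$p_hi) abort("`p_lo` must be smaller than `p_hi`.")

  rni <- as_tibble(rni)
  micros <- target_micronutrients(nutrients)
  for (band in unique(target_groups$age_band)) {
    have <- rni$nutrient_id[rni$age_band == band]
    missing <- setdiff(micros, have)
    if (length(missing)) {
      abort(sprintf(
        "RNI missing for target micronutrient(s) in band %s: %s",
        band, paste(missing, collapse = ", ")
      ))
    }
    if (any(rni$rni[rni$age_band == band & rni$nutrient_id %in% micros] <= 0)) {
      abort(sprintf("RNI values must be > 0 (band %s).", band))
    }
  }

  if (is.character(exclusions)) {
    exclusions <- tibble(food_id = exclusions, reason = rep("excluded", length(exclusions)))
  }
  exclusions <- as_tibble(exclusions)

  structure(
    list(
      nutrients = nutrients,
      target_groups = target_groups,
      rni = rni,
      breast_milk = bm,
      breast_milk_composition = breast_milk_composition,
      thresholds = th,
      exclusions = exclusions,
      bioavailability = list(zinc = zinc_bioavailability, iron = iron_bioavailability)
    ),
    class = "cfr_config"
  )
}

#' Read a study configuration from YAML or JSON
#'
#' The file mirrors the arguments of [study_config()]: top-level keys
#' `target_groups`, `rni`, `breast_milk`, `breast_milk_composition`,
#' `nutrients`, `thresholds`, `exclusions`. Missing blocks fall back to
#' the package defaults (echoed via messages).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param quiet Suppress default-echo messages.
#' @return A `cfr_config` object.
#' @export
load_study_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  listcol_to_tibble <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) return(as_tibble(x))
    as_tibble(bind_rows(lapply(x, as_tibble)))
  }
  nutrients <- listcol_to_tibble(raw$nutrients) %||% default_nutrients()
  bm_comp <- if (!is.null(raw$breast_milk_composition)) unlist(raw$breast_milk_composition) else NULL
  study_config(
    target_groups = listcol_to_tibble(raw$target_groups),
    rni = listcol_to_tibble(raw$rni),
    breast_milk = listcol_to_tibble(raw$breast_milk),
    breast_milk_composition = bm_comp,
    nutrients = nutrients,
    thresholds = raw$thresholds %||% list(),
    exclusions = raw$exclusions %||% character(),
    zinc_bioavailability = raw$zinc_bioavailability %||% "15%",
    iron_bioavailability = raw$iron_bioavailability %||% "5%",
    quiet = quiet
  )
}

#' @export
print.cfr_config <- function(x, ...) {
  cat("<cfr_config>\n")
  cat(sprintf(
    "  %d target groups (%s)\n", nrow(x$target_groups),
    paste(unique(x$target_groups$livelihood), collapse = ", ")
  ))
  cat(sprintf(
    "  %d nutrients tracked, %d target micronutrients\n",
    nrow(x$nutrients), sum(x$nutrients$is_target_micronutrient)
  ))
  cat(sprintf(
    "  adequacy cutoff %g%% RNI, problem-nutrient cutoff %g%% RNI\n",
    x$thresholds$adequacy_cutoff, x$thresholds$rni_cutoff
  ))
  invisible(x)
}

# RNI vector (micros + protein if present) for one age band.
rni_vector <- function(config, age_band) {
  r <- config$rni %>% filter(.data$age_band == !!age_band)
  setNames(r$rni, r$nutrient_id)
}

breast_milk_for_band <- function(config, age_band) {
  row <- config$breast_milk %>% filter(.data$age_band == !!age_band)
  if (nrow(row) != 1) abort(paste0("No breast-milk assumption for band ", age_band))
  as.list(row)
}
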