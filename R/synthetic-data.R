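# Synthetic food systems and 24 h recall surveys with plantable ground
# truth. The generator emulates the statistical structure the pipeline
# assumes -- milk/grain/fat/sugar-dominated complementary diets, skewed
# consumption frequencies, lognormal portions, three age bands by three
# livelihood groups -- and plants nutrient gaps (system-wide scarcity)
# and fixes (nutrient-rich subgroups) whose recovery is checkable.

AGE_BANDS <- c("m6_8", "m9_11", "m12_23")

# Baseline catalog: plausible per-100 g densities assembled for
# simulation (labelled synthetic throughout; no external table is
# reproduced). Folate is deliberately concentrated in beans so that the
# planted best-source subgroup is identifiable.
synthetic_catalog <- function() {
  tribble(
    ~food_id, ~group, ~subgroup, ~base_portion_g, ~prob,
    ~energy, ~protein, ~calcium, ~iron, ~zinc, ~vitamin_a, ~riboflavin,
    ~thiamin, ~niacin, ~vitamin_b6, ~folate, ~vitamin_b12, ~vitamin_c,
    "cow_milk", "dairy", "animal_milk", 120, 0.60, 64, 3.3, 113, 0.03, 0.40, 46, 0.170, 0.040, 0.09, 0.036, 5, 0.45, 0.0,
    "goat_milk", "dairy", "animal_milk", 120, 0.50, 69, 3.6, 134, 0.05, 0.30, 57, 0.140, 0.050, 0.28, 0.046, 1, 0.07, 1.3,
    "camel_milk", "dairy", "animal_milk", 120, 0.60, 61, 3.0, 105, 0.05, 0.40, 40, 0.120, 0.030, 0.40, 0.040, 1, 0.20, 2.4,
    "milk_powder", "dairy", "animal_milk", 25, 0.25, 496, 26.0, 912, 0.50, 3.30, 258, 1.200, 0.280, 0.60, 0.300, 37, 3.20, 8.6,
    "maize_flour", "grains", "grain_products", 40, 0.90, 365, 9.4, 7, 2.40, 1.70, 0, 0.200, 0.380, 3.60, 0.400, 25, 0.00, 0.0,
    "rice", "grains", "grain_products", 50, 0.45, 360, 7.1, 9, 0.80, 1.20, 0, 0.050, 0.070, 1.60, 0.150, 8, 0.00, 0.0,
    "sorghum", "grains", "grain_products", 40, 0.35, 329, 10.6, 13, 3.40, 1.70, 0, 0.100, 0.330, 3.70, 0.440, 20, 0.00, 0.0,
    "millet_flour", "grains", "grain_products", 40, 0.25, 378, 11.0, 8, 3.00, 1.70, 0, 0.290, 0.420, 4.70, 0.380, 35, 0.00, 0.0,
    "potato", "starchy_plants", "starchy_roots", 60, 0.45, 77, 2.0, 12, 0.80, 0.30, 0, 0.030, 0.080, 1.10, 0.300, 15, 0.00, 19.7,
    "green_banana", "starchy_plants", "starchy_roots", 60, 0.30, 89, 1.1, 5, 0.30, 0.15, 3, 0.070, 0.030, 0.67, 0.370, 20, 0.00, 8.7,
    "cassava", "starchy_plants", "starchy_roots", 50, 0.20, 160, 1.4, 16, 0.30, 0.30, 1, 0.050, 0.090, 0.85, 0.090, 27, 0.00, 20.6,
    "black_beans", "legumes", "beans", 30, 0.22, 341, 21.6, 123, 5.00, 3.70, 0, 0.190, 0.900, 1.96, 0.290, 444, 0.00, 0.0,
    "pinto_beans", "legumes", "beans", 30, 0.17, 347, 21.4, 113, 5.10, 2.30, 0, 0.210, 0.710, 1.20, 0.470, 525, 0.00, 6.3,
    "mung_beans", "legumes", "beans", 30, 0.14, 347, 23.9, 132, 6.70, 2.70, 6, 0.230, 0.620, 2.25, 0.380, 625, 0.00, 4.8,
    "vegetable_oil", "fats_oils", "added_fats", 8, 0.80, 884, 0.0, 0, 0.00, 0.00, 0, 0.000, 0.000, 0.00, 0.000, 0, 0.00, 0.0,
    "fortified_margarine", "fats_oils", "added_fats", 8, 0.30, 717, 0.2, 3, 0.00, 0.00, 800, 0.040, 0.000, 0.00, 0.000, 1, 0.10, 0.0,
    "ghee", "fats_oils", "added_fats", 8, 0.25, 876, 0.3, 4, 0.00, 0.00, 840, 0.030, 0.000, 0.00, 0.000, 0, 0.00, 0.0,
    "sugar", "fats_oils", "added_sugar", 10, 0.85, 387, 0.0, 1, 0.05, 0.00, 0, 0.020, 0.000, 0.00, 0.000, 0, 0.00, 0.0,
    "kale", "vegetables", "leafy_vegetables", 20, 0.30, 49, 4.3, 150, 1.50, 0.60, 241, 0.130, 0.110, 1.00, 0.270, 30, 0.00, 120.0,
    "amaranth_leaves", "vegetables", "leafy_vegetables", 20, 0.25, 23, 2.5, 215, 2.30, 0.90, 146, 0.160, 0.030, 0.66, 0.190, 35, 0.00, 43.0,
    "tomato", "vegetables", "other_vegetables", 15, 0.35, 18, 0.9, 10, 0.30, 0.17, 42, 0.020, 0.040, 0.59, 0.080, 15, 0.00, 13.7,
    "onion", "vegetables", "other_vegetables", 10, 0.35, 40, 1.1, 23, 0.20, 0.17, 0, 0.030, 0.050, 0.12, 0.120, 19, 0.00, 7.4,
    "banana", "fruit", "fruits", 60, 0.25, 89, 1.1, 5, 0.26, 0.15, 3, 0.070, 0.030, 0.67, 0.370, 20, 0.00, 8.7,
    "orange", "fruit", "fruits", 60, 0.15, 47, 0.9, 40, 0.10, 0.07, 11, 0.040, 0.090, 0.28, 0.060, 30, 0.00, 53.0,
    "papaya", "fruit", "fruits", 60, 0.10, 43, 0.5, 20, 0.25, 0.08, 47, 0.030, 0.020, 0.36, 0.040, 37, 0.00, 61.0,
    "goat_meat", "meat", "red_meat", 25, 0.20, 109, 20.6, 13, 2.80, 4.00, 0, 0.500, 0.110, 3.80, 0.280, 5, 1.10, 0.0,
    "mutton", "meat", "red_meat", 25, 0.10, 294, 16.6, 9, 1.50, 3.30, 0, 0.210, 0.110, 6.00, 0.130, 18, 2.60, 0.0
  )
}

synthetic_availability <- function() {
  list(
    settled = setdiff(synthetic_catalog()$food_id, "camel_milk"),
    pastoralist = setdiff(
      synthetic_catalog()$food_id,
      c("amaranth_leaves", "papaya", "cassava", "millet_flour")
    ),
    agro_pastoralist = setdiff(
      synthetic_catalog()$food_id,
      c("camel_milk", "rice", "orange", "papaya", "mutton")
    )
  )
}

# Daily energy requirements consistent with the breast-milk assumptions:
# E = breast-milk kcal / energy fraction, so that breast milk contributes
# exactly 67/55/39 % of E at 570/520/420 g/d and 0.66 kcal/g.
synthetic_energy_requirements <- function() {
  bm <- default_breast_milk()
  setNames(
    bm$grams_per_day * bm$energy_density_kcal_g / bm$energy_fraction,
    bm$age_band
  )
}

#' Specify a synthetic dietary study
#'
#' Defines the study conditions the generator emulates: ~95 children per
#' age band per livelihood group, a 27-food catalog dominated by dairy,
#' grains, added fats and added sugar, livelihood-specific availability,
#' lognormal portions with age-scaled medians calibrated so each band's
#' expected complementary energy matches its budget (energy requirement
#' minus the assumed breast-milk share), planted system-wide gaps for
#' iron and zinc, and planted nutrient-rich subgroups (beans for folate,
#' animal milk for vitamin B12) of which beans is constructed to be the
#' uniquely necessary recommendation for folate adequacy.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_children Children per age band per livelihood (default 95).
#' @param livelihoods Livelihood groups to simulate.
#' @param planted_gaps Nutrients made scarce system-wide (every density
#'   clamped low enough that even the maximized diets stay below the RNI).
#' @param planted_fixes Tibble `subgroup`, `nutrient_id`, `floor`
#'   (per-100 g density floor applied to the subgroup's foods).
#' @param portion_sdlog Lognormal dispersion of portions (default 0.4).
#' @param energy_noise_sdlog Lognormal dispersion of per-child total
#'   complementary energy around the band budget (default 0.1).
#' @param density_jitter_sdlog Lognormal jitter of per-food densities
#'   around the catalog baselines (default 0.12).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(seed = 1,
                           n_children = 95,
                           livelihoods = c("settled", "pastoralist", "agro_pastoralist"),
                           planted_gaps = c("iron", "zinc"),
                           planted_fixes = tibble(
                             subgroup = c(
                               "beans", "beans", "beans", "beans", "beans",
                               "animal_milk"
                             ),
                             nutrient_id = c(
                               "folate", "thiamin", "riboflavin", "niacin",
                               "vitamin_b6", "vitamin_b12"
                             ),
                             floor = c(700, 1.2, 1.2, 8, 1.0, 0.35)
                           ),
                           portion_sdlog = 0.4,
                           energy_noise_sdlog = 0.1,
                           density_jitter_sdlog = 0.12) {
  availability <- synthetic_availability()
  unknown <- setdiff(livelihoods, names(availability))
  if (length(unknown)) abort(paste0("Unknown livelihood(s): ", paste(unknown, collapse = ", ")))
  if (length(livelihoods) == 0) abort("At least one livelihood group is required.")
  catalog <- synthetic_catalog()

  clash <- intersect(planted_gaps, planted_fixes$nutrient_id)
  if (length(clash)) {
    abort(paste0(
      "Contradictory plant: nutrient(s) both gapped and fixed: ",
      paste(clash, collapse = ", ")
    ))
  }

  energy_req <- synthetic_energy_requirements()
  bm <- default_breast_milk()
  budget_day <- setNames(
    energy_req - bm$grams_per_day * bm$energy_density_kcal_g,
    bm$age_band
  )

  # Age-band portion scale calibrated so expected complementary energy
  # equals the band budget (lognormal mean correction included).
  expected_energy_scale1 <- sum(
    catalog$prob * catalog$base_portion_g * exp(portion_sdlog^2 / 2) * catalog$energy / 100
  )
  band_portion_scale <- budget_day / expected_energy_scale1

  structure(
    list(
      seed = seed,
      n_children = n_children,
      livelihoods = livelihoods,
      catalog = catalog,
      availability = availability[livelihoods],
      planted_gaps = planted_gaps,
      planted_fixes = as_tibble(planted_fixes),
      winner = list(level = "subgroup", target_id = "beans", group = "legumes"),
      portion_sdlog = portion_sdlog,
      energy_noise_sdlog = energy_noise_sdlog,
      density_jitter_sdlog = density_jitter_sdlog,
      energy_kcal_day = energy_req,
      comp_energy_kcal_day = budget_day,
      band_portion_scale = band_portion_scale
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  cat(sprintf(
    "  seed %d; %d children per band per livelihood; livelihoods: %s\n",
    x$seed, x$n_children, paste(x$livelihoods, collapse = ", ")
  ))
  cat(sprintf(
    "  planted gaps: %s; planted fixes: %s\n",
    paste(x$planted_gaps, collapse = ", "),
    paste(sprintf("%s(%s)", x$planted_fixes$subgroup, x$planted_fixes$nutrient_id), collapse = ", ")
  ))
  invisible(x)
}

# Run `expr` under a derived deterministic seed, restoring the caller's
# RNG state afterwards.
with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(expr)
}

# Density ceiling that guarantees a planted gap: even if the whole
# complementary energy budget came from the single least energy-dense
# food, the nutrient would stay below 90 % of the RNI in every band.
gap_ceiling <- function(spec, nutrient_id) {
  rni <- synthetic_rni_table()
  bm <- default_breast_milk()
  bm_comp <- synthetic_breast_milk_composition()
  min_e_density <- min(spec$catalog$energy[spec$catalog$energy > 0]) / 100  # kcal/g
  ceilings <- map_dbl(AGE_BANDS, function(band) {
    r <- rni$rni[rni$age_band == band & rni$nutrient_id == nutrient_id]
    if (length(r) == 0) abort(paste0("No RNI for gapped nutrient ", nutrient_id))
    bm_daily <- bm$grams_per_day[bm$age_band == band] * bm_comp[[nutrient_id]] / 100
    max_weekly_g <- 7 * spec$comp_energy_kcal_day[[band]] / min_e_density
    (0.9 * r - bm_daily) * 7 * 100 / max_weekly_g
  })
  ceiling_val <- min(ceilings)
  if (ceiling_val <= 0) abort(paste0("Cannot plant gap for ", nutrient_id, ": breast milk alone is near the RNI."))
  ceiling_val
}

#' Generate the synthetic food-composition table
#'
#' Deterministic in the spec's seed: catalog baseline densities receive
#' multiplicative lognormal jitter, planted fixes impose per-100 g
#' density floors on their subgroup, and planted gaps clamp every food's
#' density below a ceiling computed so that no feasible diet can reach
#' the RNI in any band.
#'
#' @param spec A `synthetic_spec`.
#' @return A `cfr_composition` tibble.
#' @export
generate_food_system <- function(spec) {
  nutr <- default_nutrients()$nutrient_id
  comp <- spec$catalog %>%
    mutate(name = gsub("_", " ", .data$food_id), .after = "food_id") %>%
    select("food_id", "name", "group", "subgroup", all_of(nutr))

  with_substream(spec$seed, 101, {
    for (n in setdiff(nutr, "energy")) {
      jitter <- rlnorm(nrow(comp), 0, spec$density_jitter_sdlog)
      comp[[n]] <- comp[[n]] * jitter
    }
  })

  for (i in seq_len(nrow(spec$planted_fixes))) {
    fx <- spec$planted_fixes[i, ]
    sel <- comp$subgroup == fx$subgroup
    if (!any(sel)) abort(paste0("Planted fix targets unknown subgroup ", fx$subgroup))
    comp[[fx$nutrient_id]][sel] <- pmax(comp[[fx$nutrient_id]][sel], fx$floor)
  }
  for (n in spec$planted_gaps) {
    comp[[n]] <- pmin(comp[[n]], gap_ceiling(spec, n))
  }
  validate_composition(comp)
}

#' Generate synthetic 24 h recalls
#'
#' One recall day per child. Each child draws foods by availability and
#' per-food consumption probability (at least one staple is guaranteed),
#' grams per food from a lognormal around the age-scaled median portion,
#' and total grams are then rescaled so the child's complementary energy
#' sits near the band's budget (the energy requirement minus the assumed
#' breast-milk share), with lognormal noise. Deterministic in the seed.
#'
#' @param spec A `synthetic_spec`.
#' @param composition Food system from [generate_food_system()].
#' @return A `cfr_recalls` tibble covering every (livelihood x age band)
#'   target group in the spec.
#' @export
generate_recalls <- function(spec, composition) {
  e_density <- setNames(composition$energy / 100, composition$food_id)  # kcal/g
  rows <- list()
  with_substream(spec$seed, 202, {
    for (lv in spec$livelihoods) {
      avail <- spec$availability[[lv]]
      cat_av <- spec$catalog %>% filter(.data$food_id %in% avail)
      for (band in AGE_BANDS) {
        if (spec$n_children == 0) next
        scale_b <- spec$band_portion_scale[[band]]
        tg <- paste(lv, band, sep = "_")
        for (ch in seq_len(spec$n_children)) {
          eaten <- runif(nrow(cat_av)) < cat_av$prob
          if (!any(eaten)) eaten[which.max(cat_av$prob)] <- TRUE
          f <- cat_av[eaten, ]
          grams <- rlnorm(nrow(f), log(f$base_portion_g * scale_b), spec$portion_sdlog)
          kcal <- sum(grams * e_density[f$food_id])
          target <- spec$comp_energy_kcal_day[[band]] * rlnorm(1, 0, spec$energy_noise_sdlog)
          grams <- grams * target / kcal
          rows[[length(rows) + 1L]] <- tibble(
            child_id = sprintf("%s_c%03d", tg, ch),
            target_group = tg,
            food_id = f$food_id,
            grams = grams
          )
        }
      }
    }
  })
  empty <- tibble(
    child_id = character(), target_group = character(),
    food_id = character(), grams = double()
  )
  validate_recalls(bind_rows(empty, list_rbind(rows)))
}

#' Study configuration matching a synthetic spec
#'
#' Target groups (livelihood x age band) with the spec's energy
#' requirements, the synthetic placeholder RNI table and breast-milk
#' composition, and default thresholds.
#'
#' @param spec A `synthetic_spec`.
#' @return A `cfr_config`.
#' @export
synthetic_study_config <- function(spec) {
  tg <- tidyr::expand_grid(livelihood = spec$livelihoods, age_band = AGE_BANDS) %>%
    mutate(
      target_group_id = paste(.data$livelihood, .data$age_band, sep = "_"),
      energy_kcal_day = unname(spec$energy_kcal_day[.data$age_band])
    ) %>%
    select("target_group_id", "age_band", "livelihood", "energy_kcal_day")
  study_config(
    target_groups = tg,
    rni = synthetic_rni_table(),
    breast_milk_composition = synthetic_breast_milk_composition(),
    quiet = TRUE
  )
}

#' Ground truth planted in a synthetic spec
#'
#' Expectations derived from the spec alone (never from running the
#' pipeline): gapped nutrients should classify as absolute problem
#' nutrients in every target group; fixed subgroups should be flagged as
#' best sources wherever available; the planted winner identity should
#' appear in every winning CFR set.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `gap_nutrients`, `fixes`, `winner`.
#' @export
ground_truth <- function(spec) {
  list(
    gap_nutrients = spec$planted_gaps,
    fixes = spec$planted_fixes,
    winner = spec$winner
  )
}
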