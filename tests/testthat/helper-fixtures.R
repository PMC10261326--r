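# Shared fixtures: tiny in-memory tables, toy LP instances with box
# bounds, and the dense-grid enumeration oracle used to cross-check the
# simplex solutions.

micros <- target_micronutrients()

tiny_composition <- function() {
  suppressWarnings(validate_composition(tibble::tibble(
    food_id = c("maize_flour", "cow_milk", "black_beans"),
    name = c("maize flour", "cow milk", "black beans"),
    group = c("grains", "dairy", "legumes"),
    subgroup = c("grain_products", "animal_milk", "beans"),
    energy = c(365, 64, 341),
    protein = c(9.4, 3.3, 21.6),
    calcium = c(7, 113, 123),
    iron = c(2.7, 0.03, 5),
    zinc = c(1.7, 0.4, 3.7),
    vitamin_a = c(0, 46, 0),
    riboflavin = c(0.2, 0.17, 0.19),
    thiamin = c(0.38, 0.04, 0.9),
    niacin = c(3.6, 0.09, 2),
    vitamin_b6 = c(0.4, 0.036, 0.29),
    folate = c(25, 5, 444),
    vitamin_b12 = c(0, 0.45, 0),
    vitamin_c = c(0, 0, 0)
  )))
}

tiny_recalls <- function(df) {
  validate_recalls(df)
}

# A config with one target group per age band, settled livelihood.
tiny_config <- function(...) {
  study_config(
    target_groups = tibble::tibble(
      target_group_id = paste0("settled_", c("m6_8", "m9_11", "m12_23")),
      age_band = c("m6_8", "m9_11", "m12_23"),
      livelihood = "settled",
      energy_kcal_day = c(562, 624, 711)
    ),
    rni = synthetic_rni_table(),
    quiet = TRUE,
    ...
  )
}

# Toy model parameters with explicit bounds; composition is a plain
# nutrient x food matrix, portions default to 100 g so that per-serving
# coefficients equal per-100 g densities.
toy_params <- function(comp_mat, gram_lo, gram_hi, energy_kcal_day,
                       portion_g = rep(100, ncol(comp_mat)),
                       bounds = NULL,
                       rni = NULL,
                       breast_milk_g_day = 100,
                       bm_comp = c(energy = 0.5),
                       thresholds = list()) {
  nutr <- default_nutrients()
  full <- matrix(0, nrow(nutr), ncol(comp_mat),
    dimnames = list(nutr$nutrient_id, colnames(comp_mat))
  )
  full[rownames(comp_mat), ] <- comp_mat
  foods <- tibble::tibble(
    food_id = colnames(comp_mat),
    name = colnames(comp_mat),
    group = paste0("g_", colnames(comp_mat)),
    subgroup = paste0("s_", colnames(comp_mat)),
    portion_g = portion_g,
    gram_lo = gram_lo,
    gram_hi = gram_hi,
    n_consumers = 5L,
    obs_median_servings_wk = 1
  )
  if (is.null(bounds)) {
    bounds <- tibble::tibble(
      level = character(), target_id = character(),
      lo = double(), hi = double(), observed_median = double()
    )
  }
  if (is.null(rni)) {
    rni <- setNames(rep(10, length(micros)), micros)
  }
  cfr_params(
    target_group_id = "toy", age_band = "m6_8", livelihood = "toy",
    energy_kcal_day = energy_kcal_day,
    foods = foods, bounds = bounds,
    composition = full, rni = rni,
    breast_milk_g_day = breast_milk_g_day,
    breast_milk_composition = bm_comp,
    thresholds = thresholds
  )
}

# Dense-grid oracle over the box { lo <= x <= hi } intersected with the
# energy equality e.x = target: all but the last coordinate move on a
# regular grid, the last is solved from the equality. `value_fn` maps the
# matrix of feasible servings (columns = foods) to the objective.
grid_enumerate <- function(e, target, lo, hi, step, value_fn) {
  n <- length(e)
  if (n == 1) {
    x <- target / e
    if (x < lo - 1e-9 || x > hi + 1e-9) return(NULL)
    return(value_fn(matrix(x, ncol = 1)))
  }
  free <- seq_len(n - 1)
  grids <- lapply(free, function(i) seq(lo[i], hi[i], by = step))
  gm <- as.matrix(do.call(expand.grid, grids))
  xl <- (target - as.vector(gm %*% e[free])) / e[n]
  ok <- xl >= lo[n] - 1e-9 & xl <= hi[n] + 1e-9
  if (!any(ok)) return(NULL)
  value_fn(cbind(gm[ok, , drop = FALSE], xl[ok]))
}

grid_extreme <- function(obj, e, target, lo, hi, step = 0.01,
                         direction = c("max", "min")) {
  direction <- match.arg(direction)
  grid_enumerate(e, target, lo, hi, step, function(X) {
    vals <- as.vector(X %*% obj)
    if (direction == "max") max(vals) else min(vals)
  })
}

# Grid oracle for the capped-adequacy best-diet objective.
grid_best <- function(comp_mat, e, target, lo, hi, bm_weekly, rni, step = 0.01) {
  grid_enumerate(e, target, lo, hi, step, function(X) {
    weekly <- X %*% t(comp_mat)                       # points x nutrients
    daily <- sweep(weekly, 2, bm_weekly[colnames(weekly)], `+`) / 7
    z <- sweep(daily, 2, rni[colnames(weekly)], `/`)
    z[z > 1] <- 1
    max(rowSums(z))
  })
}

# Random feasible box-bounded toy instance with n foods (energy target
# drawn from an interior point, so the instance is always feasible).
random_toy_instance <- function(n, n_nutrients = 3, span = 1.0) {
  nutr_ids <- micros[seq_len(n_nutrients)]
  comp <- matrix(runif(n_nutrients * n, 0, 50), n_nutrients, n,
    dimnames = list(nutr_ids, paste0("f", seq_len(n)))
  )
  energy <- runif(n, 100, 500)
  comp <- rbind(energy = energy, comp)
  lo <- runif(n, 0, 0.3)
  hi <- lo + runif(n, 0.3, span)
  x0 <- lo + runif(n) * (hi - lo)
  target_weekly <- sum(energy * x0)
  params <- toy_params(
    comp_mat = comp,
    gram_lo = lo * 100, gram_hi = hi * 100,
    energy_kcal_day = (target_weekly + 3.5) / 7,  # 700 g/wk breast milk at 0.5 kcal/100g
    rni = setNames(rep(20, length(micros)), micros)
  )
  list(
    params = params, comp = comp, energy = energy,
    lo = lo, hi = hi, target = target_weekly,
    nutr_ids = nutr_ids
  )
}
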