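# Diet LP construction and solution, cross-checked against dense grid
# enumeration and hand arithmetic.

test_that("a single food with an exactly reachable energy target is forced", {
  # 1 food at 100 g/serving, 350 kcal/100 g; target leaves room for exactly
  # 4 servings next to breast milk
  comp <- matrix(c(350, 10), 2, 1, dimnames = list(c("energy", "calcium"), "f1"))
  params <- toy_params(
    comp_mat = comp, gram_lo = 0, gram_hi = 1000,
    energy_kcal_day = (4 * 350 + 3.5) / 7,
    bm_comp = c(energy = 0.5)
  )
  sol <- solve_nutrient_extreme(build_diet_lp(params), "calcium", "min")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$servings$servings, 4, tolerance = 1e-7)
})

test_that("CFR constraints add rows and absent targets error before solving", {
  inst <- random_toy_instance(3)
  cfr <- tibble::tibble(level = "subgroup", target_id = "s_f1", servings_per_week = 0.1)
  lp <- build_diet_lp(inst$params, cfr)
  expect_equal(length(lp$cfr_rows), 1L)
  expect_error(
    build_diet_lp(inst$params, tibble::tibble(
      level = "subgroup", target_id = "no_such", servings_per_week = 1
    )),
    "absent from this food system"
  )
})

test_that("a CFR lower bound above the group's upper bound errors", {
  comp <- matrix(c(350, 10), 2, 1, dimnames = list(c("energy", "calcium"), "f1"))
  params <- toy_params(
    comp_mat = comp, gram_lo = 0, gram_hi = 1000,
    energy_kcal_day = 300,
    bounds = tibble::tibble(
      level = "subgroup", target_id = "s_f1", lo = 0, hi = 3, observed_median = 1
    )
  )
  expect_error(
    build_diet_lp(params, tibble::tibble(
      level = "subgroup", target_id = "s_f1", servings_per_week = 5
    )),
    "exceeds the subgroup 's_f1' upper serving bound"
  )
})

test_that("best diet saturates all scores when a single food covers every RNI", {
  # densities chosen so that feasible servings push every nutrient past its RNI
  rni <- setNames(rep(10, length(micros)), micros)
  comp <- rbind(
    energy = 100,
    matrix(500, length(micros), 1, dimnames = list(micros, NULL))
  )
  colnames(comp) <- "superfood"
  params <- toy_params(
    comp_mat = comp, gram_lo = 0, gram_hi = 10000,
    energy_kcal_day = (20 * 100 + 3.5) / 7, rni = rni
  )
  sol <- solve_best_diet(build_diet_lp(params))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 11, tolerance = 1e-7)
})

test_that("a nutrient absent from foods and breast milk scores zero", {
  comp <- matrix(c(350, 20), 2, 1, dimnames = list(c("energy", "calcium"), "f1"))
  params <- toy_params(
    comp_mat = comp, gram_lo = 0, gram_hi = 1000, energy_kcal_day = 200
  )
  sol <- solve_best_diet(build_diet_lp(params))
  zinc <- sol$nutrients[sol$nutrients$nutrient_id == "zinc", ]
  expect_equal(zinc$amount_day, 0)
  expect_equal(zinc$pct_rni, 0)
})

test_that("3-food toy optima match the dense-grid oracle", {
  set.seed(101)
  for (i in 1:5) {
    inst <- random_toy_instance(3, span = 0.8)
    lp <- build_diet_lp(inst$params)
    nid <- inst$nutr_ids[1]
    obj <- inst$comp[nid, ]
    for (dir in c("min", "max")) {
      sol <- solve_nutrient_extreme(lp, nid, dir)
      expect_equal(sol$status, "optimal")
      g <- grid_extreme(obj, inst$energy, inst$target, inst$lo, inst$hi,
        step = 0.01, direction = dir
      )
      lp_weekly <- sol$objective * 7 -
        unname(inst$params$breast_milk$weekly_nutrients[nid])
      tol <- 0.011 * (sum(abs(obj)) + abs(obj[3]) * sum(abs(inst$energy / inst$energy[3])))
      expect_lt(abs(lp_weekly - g), max(tol, 1e-6))
    }
    # best diet objective against the grid oracle
    best <- solve_best_diet(lp)
    gb <- grid_best(
      inst$comp[inst$nutr_ids, , drop = FALSE], inst$energy, inst$target,
      inst$lo, inst$hi,
      bm_weekly = inst$params$breast_milk$weekly_nutrients[inst$nutr_ids],
      rni = inst$params$rni[inst$nutr_ids], step = 0.01
    )
    expect_gte(best$objective + 1e-7, gb)          # LP never below the grid
    expect_lt(best$objective - gb, 0.05)           # and within grid resolution
  }
})

test_that("nutrient_profile evaluates diets exactly", {
  comp <- matrix(
    c(
      350, 64,    # energy
      7, 113,     # calcium
      25, 5       # folate
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("energy", "calcium", "folate"), c("maize", "milk"))
  )
  params <- toy_params(
    comp_mat = comp, gram_lo = c(0, 0), gram_hi = c(1000, 1000),
    portion_g = c(40, 120), energy_kcal_day = 400,
    bm_comp = c(energy = 66, calcium = 28)
  )

  # zero servings: the breast-milk-only profile
  p0 <- nutrient_profile(c(maize = 0, milk = 0), params)
  expect_equal(
    p0$amount_day[p0$nutrient_id == "calcium"],
    700 * 28 / 100 / 7
  )

  # hand-computed two-food diet, exact to 1e-9
  s <- c(maize = 3, milk = 2)
  prof <- nutrient_profile(s, params)
  calcium_weekly <- 3 * 40 / 100 * 7 + 2 * 120 / 100 * 113 + 700 * 28 / 100
  expect_equal(
    prof$amount_day[prof$nutrient_id == "calcium"],
    calcium_weekly / 7,
    tolerance = 1e-9
  )

  # linearity: doubling servings doubles the complementary part
  prof2 <- nutrient_profile(2 * s, params)
  bm_ca <- 700 * 28 / 100 / 7
  expect_equal(
    prof2$amount_day[prof2$nutrient_id == "calcium"] - bm_ca,
    2 * (prof$amount_day[prof$nutrient_id == "calcium"] - bm_ca),
    tolerance = 1e-9
  )

  expect_error(nutrient_profile(c(pizza = 1), params), "Unknown food id")
})

test_that("minimizing a nutrient held only by an optional food drops that food", {
  comp <- matrix(
    c(
      300, 300,
      0, 80       # folate only in f2
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("energy", "folate"), c("f1", "f2"))
  )
  params <- toy_params(
    comp_mat = comp, gram_lo = c(0, 0), gram_hi = c(1000, 1000),
    energy_kcal_day = 300
  )
  sol <- solve_nutrient_extreme(build_diet_lp(params), "folate", "min")
  expect_equal(sol$servings$servings[sol$servings$food_id == "f2"], 0, tolerance = 1e-9)
})

test_that("min <= best-diet value <= max for every nutrient (sandwich)", {
  set.seed(202)
  inst <- random_toy_instance(4, n_nutrients = 4)
  lp <- build_diet_lp(inst$params)
  best <- solve_best_diet(lp)
  for (nid in inst$nutr_ids) {
    mn <- solve_nutrient_extreme(lp, nid, "min")$objective
    mx <- solve_nutrient_extreme(lp, nid, "max")$objective
    bv <- best$nutrients$amount_day[best$nutrients$nutrient_id == nid]
    expect_lte(mn, bv + 1e-7)
    expect_lte(bv, mx + 1e-7)
  }
})

test_that("optimal diets satisfy the energy equality and declared bounds", {
  set.seed(303)
  for (i in 1:5) {
    inst <- random_toy_instance(3)
    lp <- build_diet_lp(inst$params)
    sol <- solve_nutrient_extreme(lp, inst$nutr_ids[1], "max")
    x <- sol$servings$servings
    expect_equal(sum(x * inst$energy), inst$target, tolerance = 1e-6)
    expect_true(all(x >= inst$lo - 1e-7))
    expect_true(all(x <= inst$hi + 1e-7))
  }
})

test_that("repeated solves of one instance return identical servings", {
  set.seed(404)
  inst <- random_toy_instance(4)
  lp <- build_diet_lp(inst$params)
  s1 <- solve_best_diet(lp)$servings$servings
  s2 <- solve_best_diet(lp)$servings$servings
  expect_identical(s1, s2)
})

test_that("infeasible programs are reported with a diagnosis, not an error", {
  comp <- matrix(c(100, 5), 2, 1, dimnames = list(c("energy", "calcium"), "f1"))
  params <- toy_params(
    comp_mat = comp, gram_lo = 0, gram_hi = 100,  # at most 1 serving = 100 kcal
    energy_kcal_day = 500
  )
  sol <- solve_best_diet(build_diet_lp(params))
  expect_equal(sol$status, "infeasible")
  expect_match(sol$diagnosis, "upper bounds admit at most")
})

test_that("diet LPs export as readable text", {
  inst <- random_toy_instance(3)
  lp <- build_diet_lp(inst$params)
  path <- withr::local_tempfile(fileext = ".lp")
  write_lp(lp, path)
  txt <- readLines(path)
  expect_match(txt[1], "diet LP")
  expect_true(any(grepl("energy:", txt)))
})
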