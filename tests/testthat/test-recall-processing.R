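# Recall processing: portions, percentile bounds, observed medians and
# the assembled model parameters.

rec_of <- function(...) {
  validate_recalls(tibble::tibble(...))
}

test_that("median consumer portion follows the standard median conventions", {
  rec <- rec_of(
    child_id = c("c1", "c2", "c3"), target_group = "g",
    food_id = "maize_flour", grams = c(40, 60, 80)
  )
  expect_equal(median_consumer_portion(rec, "maize_flour", "g"), 60)

  # even n: mean of the two middle order statistics (sorted-list oracle)
  rec2 <- rec_of(
    child_id = c("c1", "c2"), target_group = "g",
    food_id = "maize_flour", grams = c(40, 60)
  )
  sorted <- sort(c(40, 60))
  expect_equal(
    median_consumer_portion(rec2, "maize_flour", "g"),
    mean(sorted[1:2])
  )

  rec3 <- rec_of(
    child_id = "c1", target_group = "g", food_id = "maize_flour", grams = 55
  )
  expect_equal(median_consumer_portion(rec3, "maize_flour", "g"), 55)

  expect_error(median_consumer_portion(rec3, "cow_milk", "g"), "No consumers")
})

test_that("medians are computed over consumers only, per child-day", {
  # within-day duplicates summed first; non-consumers never enter
  rec <- rec_of(
    child_id = c("c1", "c1", "c2", "c3"), target_group = "g",
    food_id = c("cow_milk", "cow_milk", "cow_milk", "maize_flour"),
    grams = c(30, 20, 100, 40)
  )
  expect_equal(median_consumer_portion(rec, "cow_milk", "g"), median(c(50, 100)))
})

test_that("weekly item gram bounds include non-consumer zeros and floor at 0", {
  # 10 children, a single consumer of 70 g/day
  rec <- rec_of(
    child_id = paste0("c", 1:10), target_group = "g",
    food_id = c("cow_milk", rep("maize_flour", 9)),
    grams = c(70, rep(40, 9))
  )
  b <- weekly_item_gram_bounds(rec, "cow_milk", "g")
  expect_equal(unname(b["lo"]), 0)
  expect_gt(unname(b["hi"]), 0)   # single-consumer rule: (0, 7 x observed)
  expect_equal(unname(b["hi"]), 7 * 70)

  # degenerate distribution: everyone eats exactly 30 g/day
  rec2 <- rec_of(
    child_id = paste0("c", 1:8), target_group = "g",
    food_id = "maize_flour", grams = 30
  )
  expect_equal(
    unname(weekly_item_gram_bounds(rec2, "maize_flour", "g")),
    c(210, 210)
  )

  expect_error(weekly_item_gram_bounds(rec2, "maize_flour", "g", p_lo = 90, p_hi = 10), "p_lo")
})

test_that("item bounds equal the brute-force interpolated percentile", {
  grams <- 1:20
  rec <- rec_of(
    child_id = paste0("c", 1:20), target_group = "g",
    food_id = "maize_flour", grams = grams
  )
  b <- weekly_item_gram_bounds(rec, "maize_flour", "g")
  oracle <- function(p) {
    # linear interpolation between order statistics of {7, 14, ..., 140}
    x <- sort(7 * grams)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  expect_equal(unname(b["lo"]), oracle(0.10))
  expect_equal(unname(b["hi"]), oracle(0.90))
})

test_that("group serving bounds follow the per-child servings distribution", {
  # one food, every child eats exactly one portion per day -> (7, 7)
  rec <- rec_of(
    child_id = paste0("c", 1:6), target_group = "g",
    food_id = "maize_flour", grams = 40
  )
  portions <- c(maize_flour = 40)
  expect_equal(
    unname(weekly_group_serving_bounds(rec, "maize_flour", "g", portions)),
    c(7, 7)
  )

  # nobody consumes the group -> (0, 0)
  expect_equal(
    unname(weekly_group_serving_bounds(rec, "cow_milk", "g", c(cow_milk = 100))),
    c(0, 0)
  )

  # mixed two-food group against a spreadsheet-style oracle
  rec2 <- rec_of(
    child_id = c("c1", "c1", "c2", "c3", "c4"), target_group = "g",
    food_id = c("maize_flour", "cow_milk", "maize_flour", "cow_milk", "maize_flour"),
    grams = c(40, 60, 20, 120, 80)
  )
  portions2 <- c(maize_flour = 40, cow_milk = 120)
  per_child <- c(
    c1 = 40 / 40 + 60 / 120,   # 1.5
    c2 = 20 / 40,              # 0.5
    c3 = 120 / 120,            # 1.0
    c4 = 80 / 40               # 2.0
  )
  b <- weekly_group_serving_bounds(
    rec2, c("maize_flour", "cow_milk"), "g", portions2
  )
  expect_equal(
    unname(b),
    unname(stats::quantile(7 * per_child, c(0.1, 0.9), type = 7))
  )
  expect_equal(
    observed_median_group_servings(rec2, c("maize_flour", "cow_milk"), "g", portions2),
    median(7 * per_child)
  )
})

test_that("observed median group servings handle half-zero distributions", {
  rec <- rec_of(
    child_id = paste0("c", 1:4), target_group = "g",
    food_id = c("maize_flour", "maize_flour", "cow_milk", "cow_milk"),
    grams = c(80, 80, 100, 100)
  )
  # half the children at 0, half at 2 servings/day -> median 7/week
  expect_equal(
    observed_median_group_servings(rec, "maize_flour", "g", c(maize_flour = 40)),
    7
  )
})

test_that("build_model_parameters assembles the weekly program", {
  comp <- tiny_composition()
  cfg <- tiny_config()
  rec <- rec_of(
    child_id = rep(paste0("c", 1:4), each = 2),
    target_group = "settled_m6_8",
    food_id = rep(c("maize_flour", "cow_milk"), 4),
    grams = c(40, 100, 50, 150, 45, 120, 60, 110)
  )
  params <- build_model_parameters(rec, comp, cfg, "settled_m6_8")
  expect_s3_class(params, "cfr_params")
  expect_equal(params$energy$weekly_target_kcal, 7 * 562)
  expect_equal(params$breast_milk$weekly_g, 7 * 570)
  # breast-milk energy from its composition vector: 66 kcal/100 g
  expect_equal(params$energy$bm_weekly_kcal, 7 * 570 * 0.66)
  expect_setequal(params$foods$food_id, c("maize_flour", "cow_milk"))
  expect_true(all(c("group", "subgroup") %in% unique(params$bounds$level)))

  # complementary foods must cover exactly the non-breast-milk share
  expect_equal(
    params$energy$comp_weekly_kcal,
    7 * 562 - 7 * 570 * 0.66
  )
})

test_that("two identical children collapse bounds to their common intake x 7", {
  comp <- tiny_composition()
  cfg <- tiny_config()
  rec <- rec_of(
    child_id = c("c1", "c2"), target_group = "settled_m6_8",
    food_id = "maize_flour", grams = c(50, 50)
  )
  params <- build_model_parameters(rec, comp, cfg, "settled_m6_8")
  f <- params$foods[params$foods$food_id == "maize_flour", ]
  expect_equal(f$gram_lo, 350)
  expect_equal(f$gram_hi, 350)
})

test_that("an energy target below the fixed breast-milk energy is rejected", {
  comp <- tiny_composition()
  cfg <- study_config(
    target_groups = tibble::tibble(
      target_group_id = "tiny_e", age_band = "m6_8",
      livelihood = "settled", energy_kcal_day = 300  # < 570 * 0.66 = 376.2
    ),
    rni = synthetic_rni_table(), quiet = TRUE
  )
  rec <- rec_of(
    child_id = "c1", target_group = "tiny_e", food_id = "maize_flour", grams = 50
  )
  expect_error(
    build_model_parameters(rec, comp, cfg, "tiny_e"),
    "Breast milk alone exceeds"
  )
})

test_that("an empty recall set for a group cannot be modelled", {
  comp <- tiny_composition()
  cfg <- tiny_config()
  rec <- rec_of(
    child_id = "c1", target_group = "settled_m9_11", food_id = "maize_flour", grams = 50
  )
  expect_error(build_model_parameters(rec, comp, cfg, "settled_m6_8"), "No recall records")
})

test_that("scaling all intakes by c scales portions and gram bounds by c", {
  base <- tibble::tibble(
    child_id = rep(paste0("c", 1:6), each = 1),
    target_group = "g",
    food_id = rep(c("maize_flour", "cow_milk"), 3),
    grams = c(40, 100, 55, 150, 70, 130)
  )
  for (cc in c(0.5, 3)) {
    rec1 <- validate_recalls(base)
    rec2 <- validate_recalls(dplyr::mutate(base, grams = grams * cc))
    expect_equal(
      median_consumer_portion(rec2, "maize_flour", "g"),
      cc * median_consumer_portion(rec1, "maize_flour", "g")
    )
    b1 <- weekly_item_gram_bounds(rec1, "cow_milk", "g")
    b2 <- weekly_item_gram_bounds(rec2, "cow_milk", "g")
    expect_equal(unname(b2), cc * unname(b1))
    # servings are invariant when portions rescale proportionally
    p1 <- c(maize_flour = median_consumer_portion(rec1, "maize_flour", "g"))
    p2 <- cc * p1
    expect_equal(
      unname(weekly_group_serving_bounds(rec1, "maize_flour", "g", p1)),
      unname(weekly_group_serving_bounds(rec2, "maize_flour", "g", p2))
    )
  }
})

test_that("bound ordering min <= median <= max holds on random recall sets", {
  set.seed(42)
  for (i in 1:10) {
    n <- 20
    eaten <- runif(n) < 0.6
    if (sum(eaten) < 2) eaten[1:2] <- TRUE
    rec <- validate_recalls(tibble::tibble(
      child_id = paste0("c", 1:n),
      target_group = "g",
      food_id = ifelse(eaten, "maize_flour", "cow_milk"),
      grams = round(rlnorm(n, log(40), 0.5), 1)
    ))
    b <- weekly_item_gram_bounds(rec, "maize_flour", "g")
    weekly <- c(7 * rec$grams[rec$food_id == "maize_flour"], rep(0, sum(!eaten)))
    expect_lte(b[["lo"]], median(weekly))
    expect_lte(median(weekly), b[["hi"]])
  }
})
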