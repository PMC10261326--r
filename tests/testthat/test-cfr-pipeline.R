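# Candidate generation, screening, worst-case evaluation and the
# systematic combination search.

# Small but realistic fixture: one settled age band from the synthetic
# generator, reused across tests in this file.
cfr_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- synthetic_spec(seed = 99, n_children = 25, livelihoods = "settled")
      comp <- generate_food_system(spec)
      rec <- suppressMessages(generate_recalls(spec, comp))
      cfg <- synthetic_study_config(spec)
      params <- build_model_parameters(rec, comp, cfg, "settled_m12_23")
      best <- solve_best_diet(build_diet_lp(params))
      memo <<- list(params = params, best = best)
    }
    memo
  }
})

test_that("candidate frequencies follow the half-up rounding rule", {
  fx <- cfr_fixture()
  cands <- generate_candidates(fx$best, fx$params)
  expect_gt(nrow(cands), 0)
  for (i in seq_len(nrow(cands))) {
    hi <- fx$params$bounds$hi[
      fx$params$bounds$level == cands$level[i] &
        fx$params$bounds$target_id == cands$target_id[i]
    ]
    oracle <- min(max(1, floor(cands$best_servings[i] + 0.5)), floor(hi))
    expect_equal(cands$servings_per_week[i], oracle)
    expect_lte(cands$servings_per_week[i], hi)
    expect_gte(cands$servings_per_week[i], 1)
    expect_equal(cands$servings_per_week[i] %% 1, 0)
  }
})

test_that("the pattern rule is strict: servings equal to the median do not fire", {
  fx <- cfr_fixture()
  cands <- generate_candidates(fx$best, fx$params)
  pattern <- cands[cands$provenance == "pattern_rule", ]
  if (nrow(pattern) > 0) {
    expect_true(all(pattern$best_servings > pattern$observed_median))
  }
  # groups at or below their observed median never appear
  grp_srv <- dplyr::group_by(
    dplyr::mutate(fx$best$servings,
      group = fx$params$foods$group[match(food_id, fx$params$foods$food_id)]
    ),
    group
  )
  grp_srv <- dplyr::summarise(grp_srv, servings = sum(servings))
  at_or_below <- dplyr::inner_join(
    grp_srv,
    dplyr::filter(fx$params$bounds, level == "group"),
    by = c(group = "target_id")
  )
  at_or_below <- at_or_below$group[at_or_below$servings <= at_or_below$observed_median]
  expect_false(any(at_or_below %in% cands$target_id[cands$level == "group"]))
})

test_that("best-source subgroups become source-rule candidates, subgroup beating group", {
  fx <- cfr_fixture()
  src <- best_food_sources(fx$best, fx$params)
  cands <- generate_candidates(fx$best, fx$params, src)
  flagged <- setdiff(src$subgroup[src$is_best_source], "breast_milk")
  in_bounds <- fx$params$bounds$target_id[
    fx$params$bounds$level == "subgroup" & floor(fx$params$bounds$hi) >= 1
  ]
  expect_true(all(intersect(flagged, in_bounds) %in%
    cands$target_id[cands$level == "subgroup"]))
  # breast milk is never recommendable
  expect_false("breast_milk" %in% cands$target_id)
  # no candidate group is the parent of a candidate subgroup
  parents <- unique(fx$params$foods$group[
    fx$params$foods$subgroup %in% cands$target_id[cands$level == "subgroup"]
  ])
  expect_false(any(parents %in% cands$target_id[cands$level == "group"]))
})

test_that("the empty CFR set reproduces the no-CFR worst-case baseline", {
  fx <- cfr_fixture()
  base <- evaluate_cfr_set(NULL, fx$params)
  expect_true(base$feasible)
  direct <- extreme_profiles(build_diet_lp(fx$params), "min")
  expect_equal(base$minimized$min_pct_rni, direct$pct_rni)
  expect_equal(base$n_adequate, sum(direct$pct_rni >= 65))
})

test_that("adequacy is counted with >= at the cutoff", {
  fx <- cfr_fixture()
  base <- evaluate_cfr_set(NULL, fx$params)
  # set the cutoff to an achieved minimized value: that nutrient counts
  v <- base$minimized$min_pct_rni[base$minimized$min_pct_rni > 0][1]
  at_cut <- evaluate_cfr_set(NULL, fx$params, adequacy_cutoff = v)
  expect_true(at_cut$minimized$adequate[at_cut$minimized$min_pct_rni == v][1])
  above <- evaluate_cfr_set(NULL, fx$params, adequacy_cutoff = v + 1e-9)
  expect_equal(at_cut$n_adequate - above$n_adequate,
    sum(base$minimized$min_pct_rni == v))
})

test_that("adding CFR to a feasible set never lowers any minimized value", {
  fx <- cfr_fixture()
  cands <- generate_candidates(fx$best, fx$params)
  scr <- suppressMessages(screen_candidates(cands, fx$params))
  base <- evaluate_cfr_set(NULL, fx$params)
  prev <- base
  for (k in seq_len(min(3, nrow(scr)))) {
    cur <- evaluate_cfr_set(scr[seq_len(k), ], fx$params)
    if (!cur$feasible) break
    expect_true(all(cur$minimized$min_pct_rni >= prev$minimized$min_pct_rni - 1e-6))
    expect_gte(cur$n_adequate, prev$n_adequate)
    prev <- cur
  }
})

test_that("screening keeps per-nutrient winners and drops solo-infeasible candidates", {
  fx <- cfr_fixture()
  cands <- generate_candidates(fx$best, fx$params)

  # single candidate: returned unchanged
  expect_equal(
    suppressMessages(screen_candidates(cands[1, ], fx$params)),
    cands[1, ]
  )

  scr <- suppressMessages(screen_candidates(cands, fx$params))
  expect_lte(nrow(scr), fx$params$thresholds$keep_k)
  expect_true(all(scr$target_id %in% cands$target_id))
  # each screened candidate is feasible alone
  for (i in seq_len(nrow(scr))) {
    expect_true(evaluate_cfr_set(scr[i, ], fx$params)$feasible)
  }

  # two candidates each uniquely best for one nutrient are both kept:
  # per-nutrient top-2 union always contains every candidate of a pair
  if (nrow(cands) >= 2) {
    scr2 <- suppressMessages(screen_candidates(cands[1:2, ], fx$params))
    expect_equal(nrow(scr2), 2L)
  }
})

test_that("the systematic search enumerates every subset exactly once", {
  fx <- cfr_fixture()
  cands <- generate_candidates(fx$best, fx$params)
  scr <- suppressMessages(screen_candidates(cands, fx$params))
  K <- nrow(scr)
  max_size <- fx$params$thresholds$max_set_size
  tab <- systematic_search(scr, fx$params)
  expected_rows <- sum(choose(K, seq_len(min(K, max_size))))
  expect_equal(nrow(tab), expected_rows)
  expect_equal(anyDuplicated(tab$members), 0L)
  expect_equal(tab$rank, seq_len(nrow(tab)))

  # 3 screened candidates -> 7 subsets
  tab3 <- systematic_search(scr[seq_len(min(3, K)), ], fx$params)
  expect_equal(nrow(tab3), 2^min(3, K) - 1)
})

test_that("ranking prefers adequacy, then smaller sets", {
  fx <- cfr_fixture()
  cands <- generate_candidates(fx$best, fx$params)
  scr <- suppressMessages(screen_candidates(cands, fx$params))
  tab <- systematic_search(scr, fx$params)
  feas <- tab[tab$feasible, ]
  expect_true(all(diff(feas$n_adequate) <= 0))
  ties <- split(feas, feas$n_adequate)
  for (t in ties) {
    expect_true(all(diff(t$size) >= 0))
  }
  # the empty-set baseline is a lower bound for every feasible subset
  base <- evaluate_cfr_set(NULL, fx$params)
  expect_true(all(feas$n_adequate >= base$n_adequate))
})

test_that("the winner is the top-ranked feasible set", {
  fx <- cfr_fixture()
  cands <- generate_candidates(fx$best, fx$params)
  scr <- suppressMessages(screen_candidates(cands, fx$params))
  tab <- systematic_search(scr, fx$params)
  win <- select_best_cfr_set(tab)
  expect_identical(win, tab$cfr_set[[which(tab$feasible)[1]]])
})

test_that("infeasible sets are kept in the table flagged NF", {
  # engineered: a CFR set whose energy requirement exceeds the budget
  comp <- matrix(
    c(700, 10), 2, 1,
    dimnames = list(c("energy", "calcium"), "dense")
  )
  params <- toy_params(
    comp_mat = comp, gram_lo = 0, gram_hi = 1e4,
    energy_kcal_day = 100,
    bounds = tibble::tibble(
      level = "subgroup", target_id = "s_dense", lo = 0, hi = 50,
      observed_median = 0
    )
  )
  # 20 servings x 700 kcal = 14000 kcal/week >> 700 kcal/week budget
  cfr <- tibble::tibble(
    level = "subgroup", target_id = "s_dense", servings_per_week = 20,
    portion_g = 100
  )
  res <- evaluate_cfr_set(cfr, params)
  expect_false(res$feasible)
  expect_true(is.na(res$n_adequate))
  tab <- systematic_search(cfr, params)
  expect_equal(nrow(tab), 1L)
  expect_false(tab$feasible[1])
  expect_null(select_best_cfr_set(tab))
})

test_that("diet cost is recorded when a price table is supplied", {
  fx <- cfr_fixture()
  prices <- tibble::tibble(
    food_id = fx$params$foods$food_id,
    price_per_100g = seq(0.1, 1, length.out = nrow(fx$params$foods))
  )
  res <- evaluate_cfr_set(NULL, fx$params, prices = prices)
  expect_true(is.finite(res$diet_cost))
  expect_gt(res$diet_cost, 0)
})
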