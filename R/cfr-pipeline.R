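# Candidate CFR generation from the best diet, screening in minimized
# diets, exhaustive combination testing under the worst-case adequacy
# criterion, and selection of the best set per target group.

# Best-diet weekly servings summed at a group/subgroup level.
diet_level_servings <- function(diet, params, level) {
  servings <- setNames(diet$servings$servings, diet$servings$food_id)
  params$foods %>%
    mutate(s = servings[.data$food_id]) %>%
    group_by(target_id = .data[[level]]) %>%
    summarise(servings = sum(.data$s), .groups = "drop") %>%
    mutate(level = level, .before = 1)
}

# Presentation portion of a group/subgroup: median member-food portion.
level_portion <- function(params, level, target_id) {
  median(params$foods$portion_g[params$foods[[level]] == target_id])
}

#' Generate candidate complementary feeding recommendations
#'
#' Candidates come from two rules applied to the nutritionally best diet:
#' (i) the *pattern rule* proposes food groups served more often in the
#' best diet than the observed median for that group; (ii) the *source
#' rule* proposes the best-source subgroups (at least
#' `source_share_pct` % of at least `source_min_nutrients`
#' micronutrients). A subgroup candidate replaces a candidate for its
#' parent group when both fire. The recommended weekly frequency is the
#' best-diet servings of the target rounded half-up, clamped to
#' `[1, upper serving bound]`; breast milk is never a candidate (it is a
#' fixed model term).
#'
#' @param best_diet An optimal `diet_solution` from [solve_best_diet()].
#' @param params A `cfr_params`.
#' @param sources Optional precomputed [best_food_sources()] table.
#' @return A CFR tibble: `level`, `target_id`, `servings_per_week`,
#'   `portion_g`, `provenance`, `best_servings`, `observed_median`,
#'   `n_nutrients_supported`.
#' @export
generate_candidates <- function(best_diet, params, sources = NULL) {
  if (best_diet$status != "optimal") abort("Best diet is not optimal; no candidates.")
  th <- params$thresholds
  if (is.null(sources)) {
    sources <- best_food_sources(
      best_diet, params,
      share_threshold = th$source_share_pct,
      min_nutrients = th$source_min_nutrients
    )
  }

  empty <- tibble(
    level = character(), target_id = character(), servings_per_week = double(),
    portion_g = double(), provenance = character(), best_servings = double(),
    observed_median = double(), n_nutrients_supported = integer()
  )

  bound_for <- function(level, target_id) {
    b <- params$bounds %>% filter(.data$level == !!level, .data$target_id == !!target_id)
    if (nrow(b) == 1) b$hi else Inf
  }

  make_candidate <- function(level, target_id, provenance, best_servings,
                             observed_median, n_sup) {
    hi <- bound_for(level, target_id)
    if (hi < 1) return(NULL)     # cannot recommend even one weekly serving
    r <- min(max(1, round_half_up(best_servings)), floor(hi))
    tibble(
      level = level, target_id = target_id, servings_per_week = r,
      portion_g = level_portion(params, level, target_id),
      provenance = provenance, best_servings = best_servings,
      observed_median = observed_median, n_nutrients_supported = n_sup
    )
  }

  grp_serv <- diet_level_servings(best_diet, params, "group")
  sub_serv <- diet_level_servings(best_diet, params, "subgroup")

  pattern <- params$bounds %>%
    filter(.data$level == "group") %>%
    left_join(grp_serv, by = c("level", "target_id")) %>%
    filter(!is.na(.data$servings), .data$servings > .data$observed_median)
  pattern_cands <- purrr::pmap(
    pattern[, c("target_id", "servings", "observed_median")],
    function(target_id, servings, observed_median) {
      make_candidate("group", target_id, "pattern_rule", servings, observed_median, NA_integer_)
    }
  )

  src <- sources %>% filter(.data$is_best_source, .data$subgroup != "breast_milk")
  source_cands <- purrr::pmap(
    src[, c("subgroup", "n_nutrients_supported")],
    function(subgroup, n_nutrients_supported) {
      s <- sub_serv$servings[sub_serv$target_id == subgroup]
      med <- params$bounds %>%
        filter(.data$level == "subgroup", .data$target_id == subgroup) %>%
        pull(.data$observed_median)
      make_candidate(
        "subgroup", subgroup, "source_rule",
        if (length(s)) s else 0, if (length(med)) med else 0,
        n_nutrients_supported
      )
    }
  )

  cands <- bind_rows(c(pattern_cands, source_cands))
  if (nrow(cands) == 0) return(empty)

  # subgroup wins over its parent group when both fire
  sub_parents <- params$foods %>%
    distinct(.data$subgroup, .data$group) %>%
    filter(.data$subgroup %in% cands$target_id[cands$level == "subgroup"]) %>%
    pull(.data$group)
  cands <- cands %>%
    filter(!(.data$level == "group" & .data$target_id %in% sub_parents)) %>%
    distinct(.data$level, .data$target_id, .keep_all = TRUE) %>%
    arrange(.data$target_id)
  cands
}

#' Evaluate a CFR set against the worst-case adequacy criterion
#'
#' Runs one minimized diet per target micronutrient with every CFR in
#' the set active as a lower bound, and counts the nutrients whose
#' minimized %RNI reaches the adequacy cutoff. An infeasible constraint
#' set (the recommendations cannot be met under the energy equality) is a
#' result, flagged `feasible = FALSE` ("NF"), not an error.
#'
#' @param cfr_set CFR tibble (possibly empty: the no-CFR baseline).
#' @param params A `cfr_params`.
#' @param adequacy_cutoff Percent of RNI (default from `params`
#'   thresholds, 65): minimized %RNI at or above it counts as adequate.
#' @param prices Optional tibble `food_id`, `price_per_100g`; when
#'   supplied, the cost of the cheapest feasible diet under the set is
#'   recorded for tie-breaking.
#' @return A `cfr_result` object.
#' @export
evaluate_cfr_set <- function(cfr_set, params,
                             adequacy_cutoff = NULL, prices = NULL) {
  adequacy_cutoff <- adequacy_cutoff %||% params$thresholds$adequacy_cutoff
  cfr_set <- if (is.null(cfr_set)) tibble() else as_tibble(cfr_set)
  lp <- build_diet_lp(params, cfr_constraints = if (nrow(cfr_set)) cfr_set else NULL)
  minimized <- extreme_profiles(lp, "min")
  feasible <- all(minimized$feasible)
  if (!feasible) {
    return(structure(
      list(
        cfr_set = cfr_set, minimized = NULL, n_adequate = NA_integer_,
        sum_min_pct = NA_real_, feasible = FALSE, diet_cost = NA_real_,
        adequacy_cutoff = adequacy_cutoff,
        target_group_id = params$target_group_id
      ),
      class = "cfr_result"
    ))
  }
  minimized <- minimized %>%
    mutate(adequate = .data$pct_rni >= adequacy_cutoff) %>%
    select("nutrient_id", min_pct_rni = "pct_rni", "adequate")

  diet_cost <- NA_real_
  if (!is.null(prices)) {
    pr <- setNames(prices$price_per_100g, prices$food_id)
    cost_coef <- (params$foods$portion_g / 100) * pr[params$foods$food_id]
    if (anyNA(cost_coef)) {
      warn("Price table does not cover all foods; diet cost skipped.")
    } else {
      con <- lp_constraints(lp)
      res <- lp_solve_raw(unname(cost_coef)[lp$active], con, maximize = FALSE)
      if (res$status == "optimal") diet_cost <- res$value
    }
  }

  structure(
    list(
      cfr_set = cfr_set, minimized = minimized,
      n_adequate = sum(minimized$adequate),
      sum_min_pct = sum(minimized$min_pct_rni),
      feasible = TRUE, diet_cost = diet_cost,
      adequacy_cutoff = adequacy_cutoff,
      target_group_id = params$target_group_id
    ),
    class = "cfr_result"
  )
}

#' @export
print.cfr_result <- function(x, ...) {
  cat("<cfr_result> ", x$target_group_id, "\n", sep = "")
  if (nrow(x$cfr_set)) {
    cat(sprintf(
      "  CFR: %s\n",
      paste(sprintf("%s %g/wk", x$cfr_set$target_id, x$cfr_set$servings_per_week), collapse = "; ")
    ))
  } else {
    cat("  CFR: none (baseline)\n")
  }
  if (!x$feasible) {
    cat("  NF: not feasible within the set constraints\n")
  } else {
    cat(sprintf(
      "  %d of %d nutrients adequate (minimized %%RNI >= %g)\n",
      x$n_adequate, nrow(x$minimized), x$adequacy_cutoff
    ))
  }
  invisible(x)
}

#' Screen candidate CFR for the systematic search
#'
#' Each candidate is evaluated alone in the eleven minimized diets;
#' candidates that render the constraints infeasible on their own are
#' dropped with a message. Per nutrient, the two candidates achieving the
#' highest minimized %RNI are retained; the union is truncated to
#' `keep_k` by total minimized adequacy (sum of minimized %RNI across
#' nutrients, descending), so that the surviving subset is the one most
#' likely to raise all micronutrients jointly.
#'
#' @param candidates CFR tibble from [generate_candidates()].
#' @param params A `cfr_params`.
#' @param keep_k Maximum number of screened candidates (default from
#'   `params` thresholds, 8).
#' @return Screened CFR tibble in a deterministic order.
#' @export
screen_candidates <- function(candidates, params, keep_k = NULL) {
  keep_k <- keep_k %||% params$thresholds$keep_k
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) return(candidates)

  evals <- purrr::map(seq_len(nrow(candidates)), function(i) {
    evaluate_cfr_set(candidates[i, ], params)
  })
  feasible <- map_lgl(evals, "feasible")
  if (any(!feasible)) {
    inform(paste0(
      "Dropped candidate(s) infeasible alone: ",
      paste(candidates$target_id[!feasible], collapse = ", ")
    ))
  }
  candidates <- candidates[feasible, ]
  evals <- evals[feasible]
  if (nrow(candidates) <= 1) return(candidates)

  min_mat <- vapply(evals, function(e) {
    setNames(e$minimized$min_pct_rni, e$minimized$nutrient_id)
  }, numeric(nrow(evals[[1]]$minimized)))   # nutrient x candidate

  top2 <- unique(as.integer(apply(min_mat, 1, function(v) {
    order(-v, candidates$target_id)[seq_len(min(2, length(v)))]
  })))
  totals <- colSums(min_mat)
  keep <- top2[order(-totals[top2], candidates$target_id[top2])]
  keep <- keep[seq_len(min(keep_k, length(keep)))]
  candidates[sort(keep), ]
}

#' Systematically test all CFR combinations
#'
#' Evaluates every non-empty subset of the screened candidates up to
#' `max_set_size` and ranks the results by (1) adequate-nutrient count,
#' descending; (2) set size, ascending; (3) summed minimized %RNI,
#' descending; (4) diet cost, ascending, when prices are supplied;
#' (5) the subset label, alphabetically. Infeasible subsets stay in the
#' table flagged NF and rank last.
#'
#' @inheritParams evaluate_cfr_set
#' @param screened Screened CFR tibble.
#' @param max_set_size Largest combination tested (default from `params`
#'   thresholds, 5).
#' @return Tibble, one row per subset: `members`, `size`, `feasible`,
#'   `n_adequate`, `sum_min_pct`, `diet_cost`, `rank`, one
#'   `min_<nutrient>` column per micronutrient, and a list-column
#'   `cfr_set`.
#' @export
systematic_search <- function(screened, params, max_set_size = NULL,
                              adequacy_cutoff = NULL, prices = NULL) {
  max_set_size <- max_set_size %||% params$thresholds$max_set_size
  screened <- as_tibble(screened) %>% arrange(.data$target_id)
  K <- nrow(screened)
  if (K == 0) {
    return(tibble(
      members = character(), size = integer(), feasible = logical(),
      n_adequate = integer(), sum_min_pct = double(), diet_cost = double(),
      rank = integer(), cfr_set = list()
    ))
  }

  subsets <- unlist(
    lapply(seq_len(min(K, max_set_size)), function(k) {
      asplit(utils::combn(K, k), 2)
    }),
    recursive = FALSE
  )

  rows <- purrr::map(subsets, function(idx) {
    set <- screened[idx, ]
    res <- evaluate_cfr_set(set, params, adequacy_cutoff = adequacy_cutoff, prices = prices)
    wide <- if (res$feasible) {
      setNames(as.list(res$minimized$min_pct_rni), paste0("min_", res$minimized$nutrient_id))
    } else {
      list()
    }
    tibble(
      members = paste(set$target_id, collapse = "+"),
      size = nrow(set),
      feasible = res$feasible,
      n_adequate = res$n_adequate,
      sum_min_pct = res$sum_min_pct,
      diet_cost = res$diet_cost,
      !!!wide,
      cfr_set = list(set)
    )
  }) %>% list_rbind()

  rows <- rows %>%
    arrange(
      desc(.data$feasible),
      desc(tidyr::replace_na(.data$n_adequate, -1L)),
      .data$size,
      desc(tidyr::replace_na(.data$sum_min_pct, -Inf)),
      tidyr::replace_na(.data$diet_cost, Inf),
      .data$members
    ) %>%
    mutate(rank = row_number())
  rows
}

#' Winning CFR set of a systematic search
#'
#' @param search_table Output of [systematic_search()].
#' @return The top-ranked feasible row's CFR tibble, or `NULL` when no
#'   subset is feasible.
#' @export
select_best_cfr_set <- function(search_table) {
  feas <- search_table %>% filter(.data$feasible)
  if (nrow(feas) == 0) return(NULL)
  feas$cfr_set[[1]]
}
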