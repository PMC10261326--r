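# One-call orchestration of the full analysis and rendering of the
# result tables (problem nutrients, best sources, CFR candidates,
# systematic search, consolidation).

analyse_target_group <- function(recalls, composition, config, tg_id, prices = NULL,
                                 quiet = TRUE) {
  th <- config$thresholds
  params <- build_model_parameters(recalls, composition, config, tg_id)
  lp <- build_diet_lp(params)
  best <- solve_best_diet(lp)
  if (best$status != "optimal") {
    abort(
      sprintf(
        "Baseline diet LP infeasible for %s: %s", tg_id,
        best$diagnosis %||% "unknown cause"
      ),
      class = "cfrlp_infeasible_baseline"
    )
  }
  max_profiles <- extreme_profiles(lp, "max")
  problems <- classify_problem_nutrients(
    best$nutrients, max_profiles,
    rni_cutoff = th$rni_cutoff, nutrients = config$nutrients
  )
  sources <- best_food_sources(
    best, params,
    share_threshold = th$source_share_pct,
    min_nutrients = th$source_min_nutrients
  )
  baseline <- evaluate_cfr_set(NULL, params, prices = prices)
  candidates <- generate_candidates(best, params, sources = sources)
  screened <- screen_candidates(candidates, params)
  search <- systematic_search(screened, params, prices = prices)
  selected <- select_best_cfr_set(search)
  selected_result <- if (!is.null(selected)) {
    evaluate_cfr_set(selected, params, prices = prices)
  } else {
    NULL
  }
  if (!quiet) {
    inform(sprintf(
      "%s: best objective %.3f, %d problem nutrient(s), %d candidate(s), winner n_adequate %s",
      tg_id, best$objective, sum(problems$class != "none"), nrow(candidates),
      if (is.null(selected_result)) "NF" else selected_result$n_adequate
    ))
  }
  list(
    params = params, best = best, max_profiles = max_profiles,
    problems = problems, sources = sources, baseline = baseline,
    candidates = candidates, screened = screened, search = search,
    selected = selected, selected_result = selected_result
  )
}

#' Run the full CFR pipeline
#'
#' Executes recall processing, the best and per-nutrient extreme diet
#' models, problem-nutrient classification, best-source identification,
#' candidate generation, screening, the systematic combination search
#' and cross-age consolidation, for every target group in the
#' configuration. Inputs are either real tables (`config` +
#' `composition` + `recalls`) or a synthetic spec (`simulate`), from
#' which all three are generated.
#'
#' @param config A `cfr_config` (ignored when `simulate` is given).
#' @param composition A `cfr_composition` table.
#' @param recalls A `cfr_recalls` table.
#' @param simulate Optional `synthetic_spec`: generate the food system,
#'   recalls and configuration instead of supplying them.
#' @param prices Optional price table (`food_id`, `price_per_100g`) for
#'   the diet-cost tie-break.
#' @param out_dir Optional directory: when given, `report.json` and the
#'   CSV/markdown tables are written there.
#' @param quiet Suppress per-group progress messages.
#' @return A `study_report` object.
#' @export
run_pipeline <- function(config = NULL, composition = NULL, recalls = NULL,
                         simulate = NULL, prices = NULL, out_dir = NULL,
                         quiet = TRUE) {
  if (!is.null(simulate)) {
    if (!inherits(simulate, "synthetic_spec")) abort("`simulate` must be a synthetic_spec.")
    composition <- generate_food_system(simulate)
    recalls <- generate_recalls(simulate, composition)
    config <- synthetic_study_config(simulate)
  }
  if (is.null(config) || is.null(composition) || is.null(recalls)) {
    abort("Supply `config`, `composition` and `recalls`, or a `simulate` spec.", class = "cfrlp_config_error")
  }

  tg_ids <- config$target_groups$target_group_id
  groups <- lapply(tg_ids, function(tg) {
    analyse_target_group(recalls, composition, config, tg, prices = prices, quiet = quiet)
  })
  names(groups) <- tg_ids

  consolidation <- list()
  for (lv in unique(config$target_groups$livelihood)) {
    tg_lv <- config$target_groups %>% filter(.data$livelihood == lv)
    if (!setequal(tg_lv$age_band, AGE_BANDS)) next
    by_band <- setNames(tg_lv$target_group_id, tg_lv$age_band)
    sets <- lapply(by_band, function(tg) groups[[tg]]$selected)
    idents <- consolidate_identities(sets)
    n_adequate <- vapply(by_band, function(tg) {
      r <- groups[[tg]]$selected_result
      if (is.null(r) || !r$feasible) NA_integer_ else as.integer(r$n_adequate)
    }, integer(1))
    consolidation[[lv]] <- apply_consolidated(
      idents,
      per_age_params = lapply(by_band, function(tg) groups[[tg]]$params),
      per_age_sets = sets,
      per_age_best = lapply(by_band, function(tg) groups[[tg]]$best),
      age_specific_n_adequate = n_adequate
    )
  }

  report <- structure(
    list(
      groups = groups,
      consolidation = consolidation,
      provenance = list(
        seed = if (!is.null(simulate)) simulate$seed else NA_integer_,
        simulated = !is.null(simulate),
        solver = "boot::simplex",
        config_hash = rlang::hash(config),
        thresholds = config$thresholds,
        notes = c(
          "best-diet objective: maximize summed capped adequacy over the 11 target micronutrients",
          if (isTRUE(config$thresholds$niacin_tryptophan_note)) {
            "niacin classification ignores tryptophan conversion"
          }
        )
      )
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) render_tables(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (tg in names(x$groups)) {
    g <- x$groups[[tg]]
    sel <- if (is.null(g$selected_result) || !g$selected_result$feasible) {
      "NF"
    } else {
      sprintf(
        "%d adequate via {%s}", g$selected_result$n_adequate,
        paste(g$selected$target_id, collapse = ", ")
      )
    }
    cat(sprintf(
      "  %s: %d problem nutrient(s); %s\n",
      tg, sum(g$problems$class != "none"), sel
    ))
  }
  for (lv in names(x$consolidation)) {
    cat(sprintf(
      "  consolidated %s: %s\n", lv,
      paste(x$consolidation[[lv]]$identities$target_id, collapse = ", ")
    ))
  }
  invisible(x)
}

report_to_list <- function(report) {
  df <- function(x) if (is.null(x)) NULL else as.data.frame(x)
  list(
    provenance = report$provenance,
    groups = lapply(report$groups, function(g) {
      list(
        target_group = g$params$target_group_id,
        energy_kcal_day = g$params$energy_kcal_day,
        breast_milk_g_day = g$params$breast_milk$g_day,
        foods = df(g$params$foods),
        bounds = df(g$params$bounds),
        best_objective = g$best$objective,
        best_diet = df(g$best$servings),
        best_profile = df(g$best$nutrients),
        max_profiles = df(g$max_profiles),
        problem_nutrients = df(g$problems %>% mutate(class = as.character(.data$class))),
        best_sources = df(g$sources %>% select(-"supported")),
        baseline = list(
          feasible = g$baseline$feasible,
          n_adequate = g$baseline$n_adequate,
          minimized = df(g$baseline$minimized)
        ),
        candidates = df(g$candidates),
        screened = df(g$screened),
        search = df(g$search %>% select(-"cfr_set")),
        selected = df(g$selected),
        selected_result = if (is.null(g$selected_result)) NULL else list(
          feasible = g$selected_result$feasible,
          n_adequate = g$selected_result$n_adequate,
          minimized = df(g$selected_result$minimized)
        )
      )
    }),
    consolidation = lapply(report$consolidation, function(cr) {
      list(
        identities = df(cr$identities),
        cfr = df(cr$cfr),
        bands = df(cr$bands)
      )
    })
  )
}

#' Write report tables and JSON
#'
#' Writes `report.json` (the machine-readable report), per-group CSVs
#' (`problem_nutrients_*`, `best_sources_*`, `cfr_candidates_*`,
#' `cfr_search_*`, `parameters_*`), per-livelihood `consolidated_*.csv`,
#' and a human-readable `summary.md` in which infeasible cells are
#' rendered literally as "NF".
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
render_tables <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  jsonlite::write_json(
    report_to_list(report),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  md <- c("# Study report", "")
  for (tg in names(report$groups)) {
    g <- report$groups[[tg]]
    tdir <- file.path(out_dir, "tables")
    readr::write_csv(g$problems, file.path(tdir, paste0("problem_nutrients_", tg, ".csv")))
    readr::write_csv(
      g$sources %>% select(-"supported"),
      file.path(tdir, paste0("best_sources_", tg, ".csv"))
    )
    readr::write_csv(g$candidates, file.path(tdir, paste0("cfr_candidates_", tg, ".csv")))
    readr::write_csv(
      g$search %>% select(-"cfr_set"),
      file.path(tdir, paste0("cfr_search_", tg, ".csv"))
    )
    jsonlite::write_json(
      list(
        target_group = g$params$target_group_id,
        energy = g$params$energy,
        breast_milk_g_day = g$params$breast_milk$g_day,
        foods = as.data.frame(g$params$foods),
        bounds = as.data.frame(g$params$bounds)
      ),
      file.path(out_dir, paste0("parameters_", tg, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    md <- c(
      md,
      paste0("## ", tg),
      "",
      sprintf(
        "- problem nutrients: %s",
        paste(sprintf(
          "%s (%s)",
          g$problems$nutrient_id[g$problems$class != "none"],
          g$problems$class[g$problems$class != "none"]
        ), collapse = ", ")
      ),
      sprintf(
        "- selected CFR: %s",
        if (is.null(g$selected_result) || !g$selected_result$feasible) "NF" else {
          paste(sprintf(
            "%s %g/wk", g$selected$target_id, g$selected$servings_per_week
          ), collapse = "; ")
        }
      ),
      sprintf(
        "- nutrients adequate under selected CFR (minimized %%RNI >= %g): %s",
        report$provenance$thresholds$adequacy_cutoff,
        if (is.null(g$selected_result) || !g$selected_result$feasible) "NF" else g$selected_result$n_adequate
      ),
      ""
    )
  }
  for (lv in names(report$consolidation)) {
    cr <- report$consolidation[[lv]]
    readr::write_csv(cr$cfr, file.path(out_dir, "tables", paste0("consolidated_", lv, ".csv")))
    md <- c(
      md,
      paste0("## consolidated: ", lv),
      "",
      sprintf("- identities (2-of-3 rule): %s",
              if (nrow(cr$identities)) paste(cr$identities$target_id, collapse = ", ") else "(none)"),
      vapply(seq_len(nrow(cr$bands)), function(i) {
        b <- cr$bands[i, ]
        sprintf(
          "- %s: %s (age-specific: %s)", b$age_band,
          if (!b$feasible) "NF" else as.character(b$n_adequate),
          if (is.na(b$age_specific_n_adequate)) "NF" else as.character(b$age_specific_n_adequate)
        )
      }, character(1)),
      ""
    )
  }
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
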