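# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @export
print.diet_solution <- function(x, ...) {
  cat("<diet_solution> ", x$target_group_id, " (", x$objective_type, ")\n", sep = "")
  if (x$status != "optimal") {
    cat("  infeasible: ", x$diagnosis, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  objective %.4f; %d foods at positive servings\n",
              x$objective, sum(x$servings$servings > 1e-9)))
  invisible(x)
}

#' Tidy a diet solution
#'
#' One row per tracked nutrient with the daily amount and %RNI of the
#' modelled 7-day diet (breast milk included).
#'
#' @param x A `diet_solution`.
#' @param ... Unused.
#' @return A tibble `nutrient_id`, `unit`, `amount_day`, `pct_rni`.
#' @export
tidy.diet_solution <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble(
      nutrient_id = character(), unit = character(),
      amount_day = double(), pct_rni = double()
    ))
  }
  x$nutrients
}

#' @rdname tidy.diet_solution
#' @export
glance.diet_solution <- function(x, ...) {
  tibble(
    target_group = x$target_group_id,
    objective_type = x$objective_type,
    status = x$status,
    objective = x$objective,
    n_foods_used = if (x$status == "optimal") sum(x$servings$servings > 1e-9) else NA_integer_
  )
}

#' Tidy a CFR evaluation
#'
#' One row per target micronutrient with the minimized (worst-case)
#' %RNI under the CFR set and its adequacy call.
#'
#' @param x A `cfr_result`.
#' @param ... Unused.
#' @return A tibble `nutrient_id`, `min_pct_rni`, `adequate` (empty when
#'   the set is not feasible).
#' @export
tidy.cfr_result <- function(x, ...) {
  if (!x$feasible) {
    return(tibble(nutrient_id = character(), min_pct_rni = double(), adequate = logical()))
  }
  x$minimized
}

#' @rdname tidy.cfr_result
#' @export
glance.cfr_result <- function(x, ...) {
  tibble(
    target_group = x$target_group_id,
    n_cfr = nrow(x$cfr_set),
    feasible = x$feasible,
    n_adequate = x$n_adequate,
    sum_min_pct = x$sum_min_pct,
    diet_cost = x$diet_cost
  )
}

#' Tidy a consolidation result
#'
#' @param x A `consolidation_result`.
#' @param ... Unused.
#' @return The per-band summary tibble (`age_band`, `feasible`,
#'   `n_adequate`, `age_specific_n_adequate`).
#' @export
tidy.consolidation_result <- function(x, ...) x$bands

#' Tidy a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return One row per (target group, micronutrient) with the problem
#'   classification and the minimized %RNI under the selected CFR set.
#' @export
tidy.study_report <- function(x, ...) {
  purrr::imap(x$groups, function(g, tg) {
    out <- g$problems %>% mutate(target_group = tg, .before = 1)
    if (!is.null(g$selected_result) && g$selected_result$feasible) {
      out <- out %>% left_join(g$selected_result$minimized, by = "nutrient_id")
    } else {
      out$min_pct_rni <- NA_real_
      out$adequate <- NA
    }
    out
  }) %>% list_rbind()
}

#' @rdname tidy.study_report
#' @export
glance.study_report <- function(x, ...) {
  purrr::imap(x$groups, function(g, tg) {
    tibble(
      target_group = tg,
      n_foods = nrow(g$params$foods),
      n_problem = sum(g$problems$class != "none"),
      n_absolute = sum(g$problems$class == "absolute"),
      n_candidates = nrow(g$candidates),
      n_adequate_selected =
        if (is.null(g$selected_result) || !g$selected_result$feasible) {
          NA_integer_
        } else {
          as.integer(g$selected_result$n_adequate)
        }
    )
  }) %>% list_rbind()
}

#' Plot a diet solution's nutrient adequacy
#'
#' Bar chart of %RNI per target micronutrient with a reference line at
#' 100 %.
#'
#' @param object A `diet_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diet_solution <- function(object, ...) {
  if (object$status != "optimal") abort("Cannot plot an infeasible diet.")
  df <- object$nutrients %>% filter(!is.na(.data$pct_rni))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$nutrient_id, .data$pct_rni),
    y = .data$pct_rni
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "% of RNI",
      title = paste0(object$target_group_id, ": ", object$objective_type, " diet")
    )
}

#' Plot worst-case adequacy under a CFR set
#'
#' Bar chart of the minimized %RNI per micronutrient with the adequacy
#' cutoff marked.
#'
#' @param object A `cfr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cfr_result <- function(object, ...) {
  if (!object$feasible) abort("Cannot plot an infeasible (NF) CFR set.")
  ggplot2::ggplot(object$minimized, ggplot2::aes(
    x = stats::reorder(.data$nutrient_id, .data$min_pct_rni),
    y = .data$min_pct_rni,
    fill = .data$adequate
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$adequacy_cutoff, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen", `FALSE` = "indianred")) +
    ggplot2::labs(
      x = NULL, y = "minimized % of RNI (worst case)",
      fill = "adequate",
      title = object$target_group_id
    )
}
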