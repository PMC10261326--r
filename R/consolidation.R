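# Consolidation of age-specific CFR sets into one set per livelihood
# group: the 2-of-3 rule on CFR identities, re-application to every age
# band with age-specific portions and frequencies, and NF reporting.

#' Consolidate CFR identities across age bands (2-of-3 rule)
#'
#' An identity is the (level, target label) of a recommendation, e.g.
#' subgroup "beans": identities proposed for at least two of the three
#' age bands are retained (and later applied to all bands); identities
#' proposed for a single band are eliminated. Order of the bands is
#' irrelevant.
#'
#' @param sets_by_age Named list with elements `m6_8`, `m9_11`, `m12_23`,
#'   each a CFR tibble or `NULL`/empty.
#' @return Tibble `level`, `target_id`, `n_sets` (2 or 3).
#' @export
consolidate_identities <- function(sets_by_age) {
  bands <- c("m6_8", "m9_11", "m12_23")
  if (!all(bands %in% names(sets_by_age))) {
    abort("`sets_by_age` must have elements m6_8, m9_11, m12_23 (possibly empty).")
  }
  ids <- purrr::map(bands, function(b) {
    s <- sets_by_age[[b]]
    if (is.null(s) || nrow(s) == 0) return(tibble(level = character(), target_id = character()))
    as_tibble(s) %>% distinct(.data$level, .data$target_id)
  }) %>% list_rbind()
  ids %>%
    count(.data$level, .data$target_id, name = "n_sets") %>%
    filter(.data$n_sets >= 2) %>%
    arrange(.data$target_id)
}

#' Apply a consolidated CFR set to every age band
#'
#' Each retained identity is applied to each band with that band's own
#' portion sizes and frequencies: the band's original recommended weekly
#' servings when the identity was in its age-specific set, otherwise a
#' frequency derived from the band's nutritionally best diet by the same
#' half-up rounding rule used at candidate generation. Identities absent
#' from a band's food system are flagged not-applicable there. The
#' consolidated set is then re-tested per band with the worst-case
#' adequacy criterion; bands where the set cannot satisfy the energy
#' equality are reported NF.
#'
#' @param identities Tibble from [consolidate_identities()].
#' @param per_age_params Named list (`m6_8`, `m9_11`, `m12_23`) of
#'   `cfr_params`.
#' @param per_age_sets Named list of the bands' age-specific winning CFR
#'   tibbles (entries may be `NULL`).
#' @param per_age_best Named list of the bands' best `diet_solution`s
#'   (used to derive frequencies for newly added identities).
#' @param age_specific_n_adequate Optional named integer vector: each
#'   band's adequate-nutrient count under its own age-specific set, for
#'   the comparison column.
#' @return A `consolidation_result`: list with `identities`, `cfr` (the
#'   applied per-band recommendations), `bands` (per-band feasibility,
#'   adequate counts and the age-specific comparison) and `results`
#'   (per-band `cfr_result`s).
#' @export
apply_consolidated <- function(identities, per_age_params, per_age_sets = NULL,
                               per_age_best = NULL,
                               age_specific_n_adequate = NULL) {
  bands <- c("m6_8", "m9_11", "m12_23")
  bands <- bands[bands %in% names(per_age_params)]
  if (length(bands) == 0) abort("`per_age_params` supplies no known age band.")

  applied <- purrr::map(bands, function(b) {
    params <- per_age_params[[b]]
    own <- per_age_sets[[b]]
    best <- per_age_best[[b]]
    purrr::pmap(identities[, c("level", "target_id")], function(level, target_id) {
      present <- any(params$foods[[level]] == target_id)
      if (!present) {
        return(tibble(
          age_band = b, level = level, target_id = target_id,
          servings_per_week = NA_real_, portion_g = NA_real_,
          frequency_source = "not_applicable", applicable = FALSE
        ))
      }
      own_row <- if (!is.null(own) && nrow(own)) {
        own %>% filter(.data$level == !!level, .data$target_id == !!target_id)
      } else {
        tibble()
      }
      hi <- params$bounds %>%
        filter(.data$level == !!level, .data$target_id == !!target_id) %>%
        pull(.data$hi)
      hi <- if (length(hi)) hi else Inf
      if (nrow(own_row) == 1) {
        serv <- own_row$servings_per_week
        src <- "own_set"
      } else {
        if (is.null(best) || best$status != "optimal" || hi < 1) {
          return(tibble(
            age_band = b, level = level, target_id = target_id,
            servings_per_week = NA_real_, portion_g = NA_real_,
            frequency_source = "not_applicable", applicable = FALSE
          ))
        }
        ds <- diet_level_servings(best, params, level)
        s <- ds$servings[ds$target_id == target_id]
        serv <- min(max(1, round_half_up(if (length(s)) s else 0)), floor(hi))
        src <- "best_diet"
      }
      tibble(
        age_band = b, level = level, target_id = target_id,
        servings_per_week = serv,
        portion_g = level_portion(params, level, target_id),
        frequency_source = src, applicable = TRUE
      )
    }) %>% list_rbind()
  }) %>% list_rbind()

  results <- purrr::map(bands, function(b) {
    set <- applied %>% filter(.data$age_band == b, .data$applicable)
    evaluate_cfr_set(set, per_age_params[[b]])
  })
  names(results) <- bands

  band_summary <- purrr::map(bands, function(b) {
    res <- results[[b]]
    tibble(
      age_band = b,
      feasible = res$feasible,
      n_adequate = res$n_adequate,
      age_specific_n_adequate =
        if (!is.null(age_specific_n_adequate) && b %in% names(age_specific_n_adequate)) {
          as.integer(age_specific_n_adequate[[b]])
        } else {
          NA_integer_
        }
    )
  }) %>% list_rbind()

  structure(
    list(
      identities = identities,
      cfr = applied,
      bands = band_summary,
      results = results
    ),
    class = "consolidation_result"
  )
}

#' @export
print.consolidation_result <- function(x, ...) {
  cat("<consolidation_result>\n")
  cat(sprintf(
    "  consolidated identities: %s\n",
    if (nrow(x$identities)) paste(x$identities$target_id, collapse = ", ") else "(none)"
  ))
  for (i in seq_len(nrow(x$bands))) {
    b <- x$bands[i, ]
    cat(sprintf(
      "  %s: %s\n", b$age_band,
      if (!b$feasible) "NF" else sprintf("%d nutrients adequate", b$n_adequate)
    ))
  }
  invisible(x)
}
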