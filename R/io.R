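# Readers and writers for the tabular artifacts the pipeline touches:
# food composition (per 100 g), 24 h recalls, and result tables.

#' Read a food-composition table
#'
#' Expects a CSV with columns `food_id`, `name`, `group`, `subgroup`
#' followed by one column per nutrient (densities per 100 g edible
#' portion). Nutrient columns not present in the dictionary are dropped
#' with a warning; dictionary nutrients missing from the file are filled
#' with zeros (a conservative choice: the diet models never credit a
#' nutrient that was not measured). Missing values within a nutrient
#' column are set to 0 with a warned count.
#'
#' @param path CSV file path.
#' @param nutrients Nutrient dictionary tibble ([default_nutrients()]).
#' @return A tibble, one row per food, with class `cfr_composition`.
#' @export
load_composition_table <- function(path, nutrients = default_nutrients()) {
  if (!file.exists(path)) abort(paste0("Composition file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_composition(df, nutrients)
}

#' Validate (or coerce) an in-memory composition table
#'
#' @param df Data frame shaped like the composition CSV.
#' @inheritParams load_composition_table
#' @return A validated `cfr_composition` tibble.
#' @export
validate_composition <- function(df, nutrients = default_nutrients()) {
  df <- as_tibble(df)
  id_cols <- c("food_id", "name", "group", "subgroup")
  if (!all(id_cols %in% names(df))) {
    abort(paste0("Composition table needs columns: ", paste(id_cols, collapse = ", ")))
  }
  dup <- df$food_id[duplicated(df$food_id)]
  if (length(dup)) {
    abort(paste0("Duplicate food id(s) in composition table: ", paste(unique(dup), collapse = ", ")))
  }
  known <- nutrients$nutrient_id
  extra <- setdiff(names(df), c(id_cols, known))
  if (length(extra)) {
    warn(paste0("Ignoring unknown nutrient column(s): ", paste(extra, collapse = ", ")))
    df <- df %>% select(-all_of(extra))
  }
  absent <- setdiff(known, names(df))
  if (length(absent)) {
    warn(paste0("Nutrient column(s) absent, filled with 0: ", paste(absent, collapse = ", ")))
    for (n in absent) df[[n]] <- 0
  }
  n_missing <- sum(is.na(df[known]))
  if (n_missing > 0) {
    warn(sprintf("%d missing nutrient value(s) set to 0.", n_missing))
    df <- df %>% mutate(across(all_of(known), ~ tidyr::replace_na(.x, 0)))
  }
  for (n in known) {
    neg <- which(df[[n]] < 0)
    if (length(neg)) {
      abort(sprintf(
        "Negative %s density for food '%s' (row %d).", n, df$food_id[neg[1]], neg[1]
      ))
    }
  }
  df <- df %>% select(all_of(id_cols), all_of(known))
  class(df) <- c("cfr_composition", class(df))
  df
}

#' Read 24-hour dietary recalls
#'
#' Expects a CSV with columns `child_id`, `target_group`, `food_id`,
#' `grams`. Rows for excluded foods (condiments, foods of no nutritional
#' value, therapeutic foods, foods deemed uncommon) are dropped and
#' counted in a provenance attribute; duplicate (child, food) rows within
#' a recall are summed.
#'
#' @param path CSV file path.
#' @param composition Composition table; every recalled food must appear
#'   in it (after exclusion), otherwise a hard error lists the unknown ids.
#' @param exclude Character vector of food ids to drop, or a tibble with
#'   `food_id` (and optionally `reason`).
#' @return A tibble `child_id`, `target_group`, `food_id`, `grams` with
#'   class `cfr_recalls` and attribute `provenance` (excluded row/gram
#'   counts by food).
#' @export
load_recalls <- function(path, composition = NULL, exclude = character()) {
  if (!file.exists(path)) abort(paste0("Recall file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_recalls(df, composition = composition, exclude = exclude)
}

#' Validate (or coerce) an in-memory recall table
#'
#' @param df Data frame shaped like the recall CSV.
#' @inheritParams load_recalls
#' @return A validated `cfr_recalls` tibble.
#' @export
validate_recalls <- function(df, composition = NULL, exclude = character()) {
  df <- as_tibble(df)
  req <- c("child_id", "target_group", "food_id", "grams")
  if (!all(req %in% names(df))) {
    abort(paste0("Recall table needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(is.na(df$grams)) || any(df$grams <= 0)) {
    abort("Recall `grams` must all be positive and non-missing.")
  }
  excl_ids <- if (is.data.frame(exclude)) exclude$food_id else exclude
  dropped <- df %>% filter(.data$food_id %in% excl_ids)
  kept <- df %>% filter(!.data$food_id %in% excl_ids)
  provenance <- dropped %>%
    group_by(.data$food_id) %>%
    summarise(n_rows = n(), grams = sum(.data$grams), .groups = "drop")
  if (nrow(provenance) && nrow(dropped)) {
    inform(sprintf(
      "Excluded %d recall row(s) (%g g) for %d food(s): %s",
      nrow(dropped), sum(dropped$grams), nrow(provenance),
      paste(provenance$food_id, collapse = ", ")
    ))
  }
  if (!is.null(composition)) {
    unknown <- setdiff(unique(kept$food_id), composition$food_id)
    if (length(unknown)) {
      abort(paste0(
        "Recalled food id(s) absent from the composition table: ",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  kept <- kept %>%
    group_by(.data$child_id, .data$target_group, .data$food_id) %>%
    summarise(grams = sum(.data$grams), .groups = "drop")
  attr(kept, "provenance") <- provenance
  class(kept) <- c("cfr_recalls", class(kept))
  kept
}

#' Write composition / recall tables back to CSV
#'
#' Round-trip companions to [load_composition_table()] and
#' [load_recalls()]: writing then re-reading reproduces the values.
#'
#' @param x Table to write.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_composition_table
#' @export
write_recalls <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
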