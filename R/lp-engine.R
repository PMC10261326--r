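# Formulation and solution of the 7-day diet linear programs.
#
# Decision variables are continuous weekly servings per food (>= 0);
# breast milk is a fixed constant, never a variable. Constraint rows:
# the weekly energy equality, per-food gram bounds, group/subgroup
# serving bounds, and optional CFR lower bounds. Solved with the
# two-phase simplex in the boot package behind a thin status-mapping
# wrapper, so another backend can be substituted in one place. A
# presolve fixes zero-capacity foods at zero servings and drops rows
# that can never bind, which both shrinks the tableau and avoids
# degenerate pivots.

#' Build a diet linear program
#'
#' Pure function of the model parameters and an optional list of CFR
#' constraints: the same inputs always produce the same program.
#'
#' @param params A `cfr_params` object.
#' @param cfr_constraints A CFR tibble (`level`, `target_id`,
#'   `servings_per_week`) entering as lower bounds on the summed servings
#'   of the targeted group/subgroup, or `NULL`.
#' @return A `diet_lp` object.
#' @export
build_diet_lp <- function(params, cfr_constraints = NULL) {
  foods <- params$foods
  n_all <- nrow(foods)
  eps <- 1e-9

  var_lo_all <- foods$gram_lo / foods$portion_g
  var_hi_all <- foods$gram_hi / foods$portion_g

  member_all <- function(level, target_id) which(foods[[level]] == target_id)
  raw_rows <- purrr::pmap(params$bounds, function(level, target_id, lo, hi, ...) {
    dots <- list(...)
    list(level = level, target_id = target_id, idx = member_all(level, target_id),
         lo = lo, hi = hi, observed_median = dots$observed_median %||% 0)
  })
  raw_rows <- keep(raw_rows, ~ length(.x$idx) > 0)

  # presolve step 1: a zero group/subgroup serving bound zeroes out its
  # member foods; foods with zero gram capacity leave the program
  var_hi_eff <- var_hi_all
  for (gr in raw_rows) {
    if (gr$hi <= eps) var_hi_eff[gr$idx] <- 0
  }
  active <- which(var_hi_eff > eps)
  pos <- match(seq_len(n_all), active)            # full index -> active position

  infeasible_reason <- NULL
  dropped_lo <- which(var_lo_all > var_hi_eff + 1e-6)
  if (length(dropped_lo)) {
    infeasible_reason <- sprintf(
      "food '%s' has a positive lower gram bound but zero capacity after presolve",
      foods$food_id[dropped_lo[1]]
    )
  }

  n <- length(active)
  dens <- params$composition[, active, drop = FALSE]
  per_serving <- sweep(dens, 2, foods$portion_g[active] / 100, `*`)
  energy_coef <- per_serving["energy", ]
  var_lo <- var_lo_all[active]
  var_hi <- var_hi_eff[active]

  # presolve step 2: map rows onto active variables, merge rows with
  # identical member sets (e.g. a group with a single subgroup) keeping
  # the tighter bounds, and drop rows that can never bind
  group_rows <- purrr::map(raw_rows, function(gr) {
    gr$idx <- pos[gr$idx]
    gr$idx <- gr$idx[!is.na(gr$idx)]
    gr
  })
  group_rows <- keep(group_rows, ~ length(.x$idx) > 0)
  sig <- map_chr(group_rows, ~ paste(sort(.x$idx), collapse = ","))
  group_rows <- lapply(split(seq_along(group_rows), sig), function(is) {
    rows <- group_rows[is]
    merged <- rows[[1]]
    merged$lo <- max(map_dbl(rows, "lo"))
    merged$hi <- min(map_dbl(rows, "hi"))
    grp <- keep(rows, ~ .x$level == "group")
    if (length(grp)) {
      merged$level <- "group"
      merged$target_id <- grp[[1]]$target_id
      merged$observed_median <- grp[[1]]$observed_median
    }
    merged
  })
  names(group_rows) <- NULL
  group_rows <- keep(group_rows, function(gr) {
    gr$lo > eps || gr$hi < sum(var_hi[gr$idx]) - eps
  })
  for (gr in group_rows) {
    if (gr$lo > sum(var_hi[gr$idx]) + 1e-6 && is.null(infeasible_reason)) {
      infeasible_reason <- sprintf(
        "%s '%s' requires at least %g servings but capacity is %g",
        gr$level, gr$target_id, gr$lo, sum(var_hi[gr$idx])
      )
    }
  }

  cfr_rows <- list()
  if (!is.null(cfr_constraints) && nrow(as_tibble(cfr_constraints)) > 0) {
    cfr_constraints <- as_tibble(cfr_constraints)
    cfr_rows <- purrr::pmap(
      cfr_constraints[, c("level", "target_id", "servings_per_week")],
      function(level, target_id, servings_per_week) {
        idx_all <- member_all(level, target_id)
        if (length(idx_all) == 0) {
          abort(sprintf("CFR targets %s '%s', absent from this food system.", level, target_id))
        }
        brow <- params$bounds %>%
          filter(.data$level == !!level, .data$target_id == !!target_id)
        if (nrow(brow) == 1 && servings_per_week > brow$hi + 1e-9) {
          abort(sprintf(
            "CFR lower bound %g exceeds the %s '%s' upper serving bound %g.",
            servings_per_week, level, target_id, brow$hi
          ))
        }
        idx <- pos[idx_all]
        idx <- idx[!is.na(idx)]
        list(level = level, target_id = target_id, idx = idx, servings = servings_per_week)
      }
    )
    for (cr in cfr_rows) {
      capacity <- if (length(cr$idx)) sum(var_hi[cr$idx]) else 0
      if (capacity < cr$servings - 1e-9 && is.null(infeasible_reason)) {
        infeasible_reason <- sprintf(
          "CFR on %s '%s' requires %g servings/week but capacity is %g",
          cr$level, cr$target_id, cr$servings, capacity
        )
      }
    }
    cfr_rows <- keep(cfr_rows, ~ length(.x$idx) > 0 && .x$servings > 0)
  }

  structure(
    list(
      params = params,
      foods = foods,
      n_all = n_all,
      active = active,
      n = n,
      per_serving = per_serving,
      energy_coef = energy_coef,
      energy_rhs = params$energy$comp_weekly_kcal,
      var_lo = var_lo,
      var_hi = var_hi,
      group_rows = group_rows,
      cfr_rows = cfr_rows,
      cfr = if (length(cfr_rows)) as_tibble(cfr_constraints) else NULL,
      infeasible_reason = infeasible_reason
    ),
    class = "diet_lp"
  )
}

#' @export
print.diet_lp <- function(x, ...) {
  cat(sprintf(
    "<diet_lp> %d foods (%d active), %d group rows, %d CFR rows; complementary energy = %g kcal/week\n",
    x$n_all, x$n, length(x$group_rows), length(x$cfr_rows), x$energy_rhs
  ))
  invisible(x)
}

# Assemble the shared constraint block over the active servings vector,
# optionally padded with `extra` additional columns of zeros.
lp_constraints <- function(lp, extra = 0) {
  n <- lp$n
  tol <- lp$params$thresholds$energy_tolerance
  pad <- function(m) {
    if (extra == 0 || is.null(m)) return(m)
    cbind(m, matrix(0, nrow = nrow(m), ncol = extra))
  }
  unit_row <- function(idx) {
    r <- numeric(n); r[idx] <- 1; r
  }

  A1 <- NULL; b1 <- numeric(0)   # <= rows
  A2 <- NULL; b2 <- numeric(0)   # >= rows
  A3 <- NULL; b3 <- numeric(0)   # == rows

  # A CFR lower bound that sits exactly on the matching upper bound (the
  # clamp at candidate generation makes this common) would create a
  # degenerate <=/>= pair; emit it as a single equality row instead.
  sig_of <- function(idx) paste(sort(idx), collapse = ",")
  group_sig <- map_chr(lp$group_rows, ~ sig_of(.x$idx))
  skip_hi <- rep(FALSE, length(lp$group_rows))
  skip_var_hi <- rep(FALSE, n)

  for (cr in lp$cfr_rows) {
    row <- unit_row(cr$idx)
    gmatch <- which(group_sig == sig_of(cr$idx))
    tied_group <- length(gmatch) == 1 &&
      is.finite(lp$group_rows[[gmatch[1]]]$hi) &&
      cr$servings >= lp$group_rows[[gmatch[1]]]$hi - 1e-9
    tied_var <- length(cr$idx) == 1 && cr$servings >= lp$var_hi[cr$idx] - 1e-9
    if (tied_group) {
      A3 <- rbind(A3, row); b3 <- c(b3, lp$group_rows[[gmatch[1]]]$hi)
      skip_hi[gmatch[1]] <- TRUE
    } else if (tied_var) {
      A3 <- rbind(A3, row); b3 <- c(b3, lp$var_hi[cr$idx])
      skip_var_hi[cr$idx] <- TRUE
    } else {
      A2 <- rbind(A2, row); b2 <- c(b2, cr$servings)
    }
  }

  fin_hi <- which(is.finite(lp$var_hi) & !skip_var_hi)
  if (length(fin_hi)) {
    A1 <- rbind(A1, do.call(rbind, lapply(fin_hi, unit_row)))
    b1 <- c(b1, lp$var_hi[fin_hi])
  }
  pos_lo <- which(lp$var_lo > 1e-12)
  if (length(pos_lo)) {
    A2 <- rbind(A2, do.call(rbind, lapply(pos_lo, unit_row)))
    b2 <- c(b2, lp$var_lo[pos_lo])
  }
  for (j in seq_along(lp$group_rows)) {
    gr <- lp$group_rows[[j]]
    row <- unit_row(gr$idx)
    if (!skip_hi[j] && is.finite(gr$hi) && gr$hi < sum(lp$var_hi[gr$idx]) - 1e-12) {
      A1 <- rbind(A1, row); b1 <- c(b1, gr$hi)
    }
    if (gr$lo > 1e-12) { A2 <- rbind(A2, row); b2 <- c(b2, gr$lo) }
  }
  if (tol > 0) {
    A1 <- rbind(A1, lp$energy_coef); b1 <- c(b1, lp$energy_rhs * (1 + tol))
    lo_rhs <- lp$energy_rhs * (1 - tol)
    if (lo_rhs > 0) { A2 <- rbind(A2, lp$energy_coef); b2 <- c(b2, lo_rhs) }
  } else {
    A3 <- rbind(A3, lp$energy_coef); b3 <- c(b3, lp$energy_rhs)
  }
  list(A1 = pad(A1), b1 = b1, A2 = pad(A2), b2 = b2, A3 = pad(A3), b3 = b3)
}

# Thin wrapper over the simplex backend with uniform status mapping.
# Degenerate tableaus occasionally make the textbook pivot fail; retrying
# with a different pivoting tolerance resolves those cases.
lp_solve_raw <- function(obj, con, maximize) {
  run <- function(eps) {
    boot::simplex(
      a = obj,
      A1 = con$A1, b1 = con$b1,
      A2 = con$A2, b2 = con$b2,
      A3 = con$A3, b3 = con$b3,
      maxi = maximize,
      n.iter = max(500L, 50L * length(obj)),
      eps = eps
    )
  }
  res <- tryCatch(run(1e-10), error = function(e) NULL)
  if (is.null(res)) res <- tryCatch(run(1e-7), error = function(e) NULL)
  if (is.null(res)) res <- tryCatch(run(1e-5), error = function(e) NULL)
  if (is.null(res)) {
    abort("LP solver failed on a non-degenerate tableau; instance exported via write_lp() may help.")
  }
  status <- if (res$solved == 1) "optimal" else "infeasible"
  list(status = status, x = unname(res$soln), value = unname(res$value))
}

# Heuristic diagnosis of why no feasible diet exists.
infeasibility_diagnosis <- function(lp) {
  if (!is.null(lp$infeasible_reason)) return(lp$infeasible_reason)
  max_energy <- sum(pmin(lp$var_hi, 1e9) * lp$energy_coef)
  min_energy <- sum(lp$var_lo * lp$energy_coef)
  cfr_energy <- sum(map_dbl(lp$cfr_rows, function(cr) {
    min(lp$energy_coef[cr$idx]) * cr$servings
  }))
  if (max_energy < lp$energy_rhs) {
    sprintf(
      "upper bounds admit at most %.0f kcal/week of complementary food, below the %.0f kcal target",
      max_energy, lp$energy_rhs
    )
  } else if (min_energy > lp$energy_rhs) {
    sprintf(
      "lower bounds force at least %.0f kcal/week, above the %.0f kcal target",
      min_energy, lp$energy_rhs
    )
  } else if (cfr_energy + min_energy > lp$energy_rhs) {
    sprintf(
      "CFR servings plus lower bounds force at least %.0f kcal/week, above the %.0f kcal target",
      cfr_energy + min_energy, lp$energy_rhs
    )
  } else {
    "no feasible servings vector satisfies the bound and energy constraints jointly"
  }
}

# Expand an active-variable solution to the full food list.
expand_servings <- function(lp, x_active) {
  x <- numeric(lp$n_all)
  x[lp$active] <- x_active
  x
}

new_diet_solution <- function(lp, status, x_active = NULL, objective = NA_real_,
                              objective_type = "best", diagnosis = NULL) {
  params <- lp$params
  if (status != "optimal") {
    return(structure(
      list(
        status = status, objective = NA_real_, objective_type = objective_type,
        servings = NULL, nutrients = NULL,
        target_group_id = params$target_group_id,
        diagnosis = diagnosis %||% infeasibility_diagnosis(lp)
      ),
      class = "diet_solution"
    ))
  }
  servings <- tibble(
    food_id = lp$foods$food_id,
    servings = expand_servings(lp, x_active)
  )
  nutrients <- nutrient_profile(servings, params)
  structure(
    list(
      status = "optimal", objective = objective, objective_type = objective_type,
      servings = servings, nutrients = nutrients,
      target_group_id = params$target_group_id, diagnosis = NULL
    ),
    class = "diet_solution"
  )
}

#' Evaluate the nutrient profile of a servings vector
#'
#' Daily amount of each nutrient is the weekly complementary-food content
#' (servings times per-serving composition) plus the fixed weekly
#' breast-milk contribution, divided by 7; %RNI is 100 times the daily
#' amount over the daily RNI (NA where no RNI applies, e.g. energy).
#'
#' @param servings Named numeric vector or tibble (`food_id`, `servings`)
#'   of weekly servings; bounds are not enforced (pure evaluation).
#' @param params A `cfr_params` object.
#' @return Tibble `nutrient_id`, `unit`, `amount_day`, `pct_rni`.
#' @export
nutrient_profile <- function(servings, params) {
  if (is.data.frame(servings)) {
    servings <- setNames(servings$servings, servings$food_id)
  }
  unknown <- setdiff(names(servings), params$foods$food_id)
  if (length(unknown)) {
    abort(paste0("Unknown food id(s) in servings: ", paste(unknown, collapse = ", ")))
  }
  x <- setNames(rep(0, nrow(params$foods)), params$foods$food_id)
  x[names(servings)] <- servings
  per_serving <- sweep(params$composition, 2, params$foods$portion_g / 100, `*`)
  weekly <- as.numeric(per_serving %*% x) + unname(params$breast_milk$weekly_nutrients)
  amount_day <- weekly / 7
  ids <- params$nutrients$nutrient_id
  rni <- params$rni[ids]
  tibble(
    nutrient_id = ids,
    unit = params$nutrients$unit,
    amount_day = unname(amount_day),
    pct_rni = unname(ifelse(is.na(rni) | rni <= 0, NA_real_, 100 * amount_day / rni))
  )
}

#' Solve the nutritionally best diet
#'
#' Maximizes summed capped adequacy over the 11 target micronutrients:
#' each nutrient contributes an auxiliary score z in \[0, 1\] bounded by
#' its daily intake over its RNI, so the optimum rewards adequacy across
#' nutrients without crediting surpluses beyond 100 % RNI. A second
#' lexicographic pass minimizes total absolute deviation of food-group
#' servings from their observed medians among alternative optima, so the
#' reported diet is deterministic and resembles observed patterns.
#'
#' @param lp A `diet_lp` built without CFR constraints (CFR rows are
#'   permitted, e.g. for evaluation experiments, but classification uses
#'   the unconstrained program).
#' @param tie_break Run the median-deviation tie-break pass (default TRUE).
#' @return A `diet_solution` with `objective` = summed adequacy (max 11).
#' @export
solve_best_diet <- function(lp, tie_break = TRUE) {
  params <- lp$params
  if (!is.null(lp$infeasible_reason)) {
    return(new_diet_solution(lp, "infeasible", objective_type = "best"))
  }
  micros <- target_micronutrients(params$nutrients)
  k <- length(micros)
  n <- lp$n
  con <- lp_constraints(lp, extra = k)

  # z_m <= 1 and 7*RNI_m*z_m - (weekly intake from foods) <= bm_weekly_m
  zcap <- cbind(matrix(0, k, n), diag(k))
  link <- cbind(-lp$per_serving[micros, , drop = FALSE], diag(7 * params$rni[micros]))
  bm <- unname(params$breast_milk$weekly_nutrients[micros])
  con$A1 <- rbind(con$A1, zcap, link)
  con$b1 <- c(con$b1, rep(1, k), bm)

  obj <- c(rep(0, n), rep(1, k))
  res <- lp_solve_raw(obj, con, maximize = TRUE)
  if (res$status != "optimal") {
    return(new_diet_solution(lp, res$status, objective_type = "best"))
  }
  x <- res$x[seq_len(n)]
  opt <- res$value

  grp <- keep(lp$group_rows, ~ .x$level == "group")
  if (tie_break && length(grp)) {
    m <- length(grp)
    con2 <- lp_constraints(lp, extra = k + m)
    con2$A1 <- rbind(
      con2$A1,
      cbind(zcap, matrix(0, k, m)),
      cbind(link, matrix(0, k, m))
    )
    con2$b1 <- c(con2$b1, rep(1, k), bm)
    # keep summed adequacy at its optimum
    keep_opt <- c(rep(0, n), rep(1, k), rep(0, m))
    con2$A2 <- rbind(con2$A2, keep_opt)
    con2$b2 <- c(con2$b2, max(0, opt - 1e-7))
    # |group servings - observed median| <= d_g
    for (j in seq_along(grp)) {
      gr <- grp[[j]]
      row <- numeric(n + k + m)
      row[gr$idx] <- 1
      med <- gr$observed_median %||% 0
      drow <- row; drow[n + k + j] <- -1
      con2$A1 <- rbind(con2$A1, drow)            # sum - d <= med
      con2$b1 <- c(con2$b1, med)
      if (med > 0) {
        urow <- row; urow[n + k + j] <- 1
        con2$A2 <- rbind(con2$A2, urow)          # sum + d >= med
        con2$b2 <- c(con2$b2, med)
      }
    }
    obj2 <- c(rep(0, n + k), rep(1, m))
    res2 <- lp_solve_raw(obj2, con2, maximize = FALSE)
    if (res2$status == "optimal") x <- res2$x[seq_len(n)]
  }

  new_diet_solution(lp, "optimal", x, objective = opt, objective_type = "best")
}

#' Solve a per-nutrient minimized or maximized diet
#'
#' The worst-case ("minimized") and best-case ("maximized") content of a
#' single nutrient over all diets satisfying the bound, energy and CFR
#' constraints. The minimized diet underpins the population-adequacy
#' criterion; the maximized diet underpins absolute problem-nutrient
#' classification.
#'
#' @param lp A `diet_lp`.
#' @param nutrient_id One tracked nutrient id.
#' @param direction `"min"` or `"max"`.
#' @return A `diet_solution`; `objective` is the daily amount of the
#'   nutrient in the optimal diet.
#' @export
solve_nutrient_extreme <- function(lp, nutrient_id, direction = c("min", "max")) {
  direction <- match.arg(direction)
  params <- lp$params
  if (!nutrient_id %in% rownames(lp$per_serving)) {
    abort(paste0("Unknown nutrient id: ", nutrient_id))
  }
  objective_type <- paste0(direction, "_", nutrient_id)
  if (!is.null(lp$infeasible_reason)) {
    return(new_diet_solution(lp, "infeasible", objective_type = objective_type))
  }
  con <- lp_constraints(lp)
  obj <- lp$per_serving[nutrient_id, ]
  res <- lp_solve_raw(obj, con, maximize = identical(direction, "max"))
  if (res$status != "optimal") {
    return(new_diet_solution(lp, res$status, objective_type = objective_type))
  }
  daily <- (res$value + unname(params$breast_milk$weekly_nutrients[nutrient_id])) / 7
  new_diet_solution(
    lp, "optimal", res$x,
    objective = daily,
    objective_type = objective_type
  )
}

#' Per-nutrient %RNI across each nutrient's own extreme diet
#'
#' Runs one LP per target micronutrient and collects, for each nutrient,
#' its %RNI in the diet where that nutrient itself is minimized (or
#' maximized).
#'
#' @inheritParams solve_nutrient_extreme
#' @return Tibble `nutrient_id`, `pct_rni`, `feasible`. When the shared
#'   constraint set is infeasible every row is marked infeasible with NA
#'   pct_rni.
#' @export
extreme_profiles <- function(lp, direction = c("min", "max")) {
  direction <- match.arg(direction)
  micros <- target_micronutrients(lp$params$nutrients)
  purrr::map(micros, function(nid) {
    sol <- solve_nutrient_extreme(lp, nid, direction)
    if (sol$status != "optimal") {
      tibble(nutrient_id = nid, pct_rni = NA_real_, feasible = FALSE)
    } else {
      tibble(
        nutrient_id = nid,
        pct_rni = sol$nutrients$pct_rni[sol$nutrients$nutrient_id == nid],
        feasible = TRUE
      )
    }
  }) %>% list_rbind()
}

#' Export a diet LP as a readable text file
#'
#' Writes the objective-free constraint system (energy row, bounds,
#' group and CFR rows) in a plain LP-like text format for debugging.
#'
#' @param lp A `diet_lp`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_lp <- function(lp, path) {
  ids <- lp$foods$food_id[lp$active]
  lines <- c(
    sprintf("\\ diet LP: %s (%d foods active of %d)", lp$params$target_group_id, lp$n, lp$n_all),
    "Subject To",
    sprintf(
      " energy: %s = %.6g",
      paste(sprintf("%.6g %s", lp$energy_coef, ids), collapse = " + "),
      lp$energy_rhs
    ),
    unlist(lapply(lp$group_rows, function(gr) {
      sprintf(
        " %s_%s: %g <= %s <= %g", gr$level, gr$target_id, gr$lo,
        paste(ids[gr$idx], collapse = " + "), gr$hi
      )
    })),
    unlist(lapply(lp$cfr_rows, function(cr) {
      sprintf(
        " cfr_%s: %s >= %g", cr$target_id,
        paste(ids[cr$idx], collapse = " + "), cr$servings
      )
    })),
    "Bounds",
    sprintf(" %.6g <= %s <= %.6g", lp$var_lo, ids, lp$var_hi),
    "End"
  )
  writeLines(lines, path)
  invisible(path)
}
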