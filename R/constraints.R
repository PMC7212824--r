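# Constraint assembly: every constraint is a labeled linear row
# lb <= sum_k a_k x_k <= ub over the 55 subcategory amounts x (g/day).
# Three families: nutritional (DRI bounds and percent-of-energy bands),
# acceptability (observed-intake percentile boxes and the total-weight
# band) and healthy (food-group policy bounds).

#' Energy conversion factors (kcal per g)
#'
#' Conventional Atwater-type factors used to express percent-of-energy
#' bounds as linear constraints: fat 9, protein 4, carbohydrate 4
#' (sugars included), alcohol 7 kcal/g.
#'
#' @param fat,protein,carbohydrate,alcohol kcal per g.
#' @return Named numeric vector.
#' @export
energy_factors <- function(fat = 9, protein = 4, carbohydrate = 4, alcohol = 7) {
  out <- c(fat = fat, protein = protein, carbohydrate = carbohydrate,
           alcohol = alcohol)
  if (any(out <= 0)) stop("energy_factors must be positive")
  out
}

# One constraint row.
new_constraint <- function(label, kind, a, lb = -Inf, ub = Inf) {
  stopifnot(length(a) == 55)
  lb <- unname(lb); ub <- unname(ub)
  if (is.finite(lb) && is.finite(ub) && lb > ub) {
    stop("constraint '", label, "': lb (", lb, ") > ub (", ub, ")")
  }
  list(label = label, kind = kind, a = unname(as.numeric(a)), lb = lb, ub = ub)
}

# nutrient label -> content column(s) and %E energy factor
.nutrient_map <- function() {
  list(
    energy       = list(cols = "energy_kcal"),
    protein      = list(cols = "protein_g", factor = "protein"),
    total_fat    = list(cols = "total_fat_g", factor = "fat"),
    sfa          = list(cols = "sfa_g", factor = "fat"),
    pufa         = list(cols = "pufa_g", factor = "fat"),
    carbohydrate = list(cols = "carb_g", factor = "carbohydrate"),
    total_sugar  = list(cols = c("free_sugar_g", "intrinsic_sugar_g"),
                        factor = "carbohydrate"),
    free_sugar   = list(cols = "free_sugar_g", factor = "carbohydrate"),
    cholesterol  = list(cols = "cholesterol_mg"),
    fiber        = list(cols = "fiber_g"),
    calcium      = list(cols = "calcium_mg"),
    iron         = list(cols = "iron_mg"),
    zinc         = list(cols = "zinc_mg"),
    vitamin_b12  = list(cols = "vitb12_ug"),
    alcohol      = list(cols = "alcohol_g", factor = "alcohol"))
}

# per-gram coefficient row for a nutrient (content is per 100 g)
nutrient_row <- function(nutrient, content) {
  m <- .nutrient_map()[[nutrient]]
  if (is.null(m)) stop("unknown nutrient '", nutrient, "'")
  rowSums(content[, m$cols, drop = FALSE]) / 100
}

#' Load the shipped (or a custom) bounds configuration
#'
#' The YAML file holds, per sex, one entry per nutrient with `lb`, `ub`
#' and `unit` in `{per_day, percent_energy}`, plus a `policy` section
#' for the healthy constraints. Entries with `enabled: false` (the
#' female iron range) are dropped unless explicitly requested.
#'
#' @param sex `"M"` or `"F"`.
#' @param path YAML path; defaults to the configuration shipped with
#'   the package, which reproduces the published adult bounds.
#' @param include_disabled include entries marked `enabled: false`
#'   (used to reproduce the iron infeasibility experiment).
#' @return data.frame with columns `nutrient`, `lb`, `ub`, `unit`.
#' @export
default_bounds <- function(sex, path = NULL, include_disabled = FALSE) {
  stopifnot(sex %in% c("M", "F"))
  cfg <- .read_bounds_config(path)
  sec <- cfg[[if (sex == "M") "male" else "female"]]
  rows <- lapply(names(sec), function(nm) {
    e <- sec[[nm]]
    if (isFALSE(e$enabled) && !include_disabled) return(NULL)
    data.frame(nutrient = nm, lb = as.numeric(e$lb), ub = as.numeric(e$ub),
               unit = e$unit, stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Default healthy-constraint policy
#'
#' Food-group bounds in g/day: red meat 10--30, processed meat 0,
#' alcoholic beverages 0, fruit & vegetables 400--500, pulses >= 20,
#' fish >= 20. Group membership comes from the registry flags.
#'
#' @param path optional YAML path (same file as [default_bounds()]).
#' @return Named list of `c(lb, ub)` pairs keyed by registry flag name.
#' @export
default_policy <- function(path = NULL) {
  cfg <- .read_bounds_config(path)
  lapply(cfg$policy, function(e) {
    c(lb = as.numeric(e$lb), ub = if (is.null(e$ub)) Inf else as.numeric(e$ub))
  })
}

.read_bounds_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_bounds.yaml", package = "ghgediet")
  }
  if (!nzchar(path) || !file.exists(path)) stop("bounds config not found")
  yaml::read_yaml(path)
}

#' Nutritional constraints
#'
#' Per-day bounds become `lb <= sum_k n_k x_k <= ub` with `n_k` the
#' consumption-weighted nutrient content per gram. A percent-of-energy
#' band `p_lb <= 100 * E_j N_j / E_tot <= p_ub` is linearized exactly
#' and homogeneously as the pair
#' `sum_k (E_j f_jk - p_lb/100 * e_k) x_k >= 0` and
#' `sum_k (E_j f_jk - p_ub/100 * e_k) x_k <= 0`,
#' where `e_k` is energy per gram and `E_j` the kcal/g factor of
#' nutrient j; the form is valid whatever the total energy, so it
#' composes correctly with the energy band itself.
#'
#' @param bounds data.frame as returned by [default_bounds()].
#' @param content 55 x 15 per-100g nutrient matrix
#'   ([weighted_nutrient_content()]).
#' @param factors [energy_factors()].
#' @return List of constraint rows (kind `"nutritional"`).
#' @export
nutrient_constraints <- function(bounds, content, factors = energy_factors()) {
  stopifnot(is.data.frame(bounds),
            all(c("nutrient", "lb", "ub", "unit") %in% names(bounds)))
  if (nrow(content) != 55) stop("content must cover all 55 subcategories")
  if (anyNA(bounds$lb) || anyNA(bounds$ub)) stop("missing bound entry")
  e_k <- content[, "energy_kcal"] / 100
  out <- list()
  for (i in seq_len(nrow(bounds))) {
    b <- bounds[i, ]
    f <- nutrient_row(b$nutrient, content)
    if (b$unit == "per_day") {
      out[[length(out) + 1L]] <- new_constraint(
        paste0("nutrient:", b$nutrient), "nutritional", f, b$lb, b$ub)
    } else if (b$unit == "percent_energy") {
      Ej <- factors[[.nutrient_map()[[b$nutrient]]$factor]]
      out[[length(out) + 1L]] <- new_constraint(
        paste0("nutrient:", b$nutrient, ":%E_lb"), "nutritional",
        Ej * f - (b$lb / 100) * e_k, lb = 0, ub = Inf)
      out[[length(out) + 1L]] <- new_constraint(
        paste0("nutrient:", b$nutrient, ":%E_ub"), "nutritional",
        Ej * f - (b$ub / 100) * e_k, lb = -Inf, ub = 0)
    } else {
      stop("unknown bound unit '", b$unit, "' for ", b$nutrient)
    }
  }
  out
}

#' Acceptability constraints
#'
#' One total-weight band (all-ones row, bounds = `weight_range` times
#' the observed mean total diet weight), a `[p5, p90]` box per
#' subcategory, and optionally a `[p5, p90]` sum constraint per
#' category. Subcategories whose 5th and 90th percentiles are both zero
#' are fixed to zero. Bounds are kept at full precision; rounding is a
#' reporting concern.
#'
#' @param stats a `population_stats`.
#' @param weight_range total-weight band as a fraction of the observed
#'   mean, default `c(0.8, 1.4)`.
#' @param include_category_sums also emit category-level percentile
#'   constraints (default TRUE; subcategory boxes usually dominate).
#' @return List of constraint rows (kind `"acceptability"`).
#' @export
acceptability_constraints <- function(stats, weight_range = c(0.8, 1.4),
                                      include_category_sums = TRUE) {
  stopifnot(inherits(stats, "population_stats"))
  if (length(stats$p5) != 55 || anyNA(stats$p5) || anyNA(stats$p90)) {
    stop("acceptability_constraints: incomplete subcategory statistics")
  }
  reg <- subcategory_registry()
  out <- list(new_constraint("acceptability:total_weight", "acceptability",
                             rep(1, 55),
                             weight_range[1] * stats$mean_total,
                             weight_range[2] * stats$mean_total))
  for (k in 1:55) {
    a <- numeric(55); a[k] <- 1
    lb <- stats$p5[k]; ub <- stats$p90[k]
    lab <- sprintf("box:%d", k)
    if (lb == 0 && ub == 0) lab <- sprintf("box:%d:fixed_zero", k)
    out[[length(out) + 1L]] <- new_constraint(lab, "acceptability", a, lb, ub)
  }
  if (include_category_sums) {
    for (g in 1:15) {
      a <- as.numeric(reg$category_id == g)
      out[[length(out) + 1L]] <- new_constraint(
        sprintf("cat:%d", g), "acceptability", a,
        stats$cat_p5[g], stats$cat_p90[g])
    }
  }
  out
}

#' Healthy (policy) constraints
#'
#' Food-group bounds over registry-flag membership: red meat, processed
#' meat, alcoholic beverages, fruit & vegetables (excluding pulses and
#' fruit juices by construction of the flags), pulses and fish. Lower
#' bounds such as the >= 20 g/day for pulses and fish deliberately
#' override percentile lower bounds when boxes are intersected during
#' problem assembly.
#'
#' @param registry subcategory registry (flags must be present).
#' @param policy named list of `c(lb, ub)` pairs, see [default_policy()];
#'   names must be registry flag columns or a `subcats` vector may be
#'   supplied via `list(lb=, ub=, subcats=)`.
#' @return List of constraint rows (kind `"healthy"`).
#' @export
healthy_constraints <- function(registry = subcategory_registry(),
                                policy = default_policy()) {
  out <- list()
  for (nm in names(policy)) {
    p <- policy[[nm]]
    if (is.list(p) && !is.null(p$subcats)) {
      bad <- setdiff(p$subcats, registry$subcategory_id)
      if (length(bad)) stop("policy references unknown subcategory ", bad[1])
      member <- registry$subcategory_id %in% p$subcats
      lb <- p$lb; ub <- p$ub
    } else {
      if (!nm %in% names(registry)) stop("policy references unknown group '", nm, "'")
      member <- registry[[nm]]
      lb <- p[["lb"]]; ub <- p[["ub"]]
    }
    out[[length(out) + 1L]] <- new_constraint(
      paste0("healthy:", nm), "healthy", as.numeric(member), lb, ub)
  }
  out
}

#' Assemble the GHGE-minimization linear program
#'
#' Concatenates constraint lists over the 55 subcategory amounts, takes
#' the GHGE coefficients as objective, and intersects single-variable
#' box constraints. A syntactically empty box (lb > ub on the same
#' variable after intersection) raises an immediate infeasibility error
#' naming the subcategory. Non-negativity of the amounts is implicit.
#'
#' @param ghge a `ghge_table` covering all 55 subcategories.
#' @param constraint_lists list of constraint lists
#'   ([nutrient_constraints()], [acceptability_constraints()],
#'   [healthy_constraints()]).
#' @param sex label carried through to the solution (`"M"`, `"F"` or NA).
#' @param content optional 55 x 15 content matrix stored for nutrient
#'   reporting and [optimize_nutrient()].
#' @param factors [energy_factors()].
#' @return An object of class `lp_problem`: list with `c` (objective,
#'   kg CO2e per g), `A` (m x 55 matrix), `lb`, `ub`, `label`, `kind`,
#'   `sex` and `meta`.
#' @export
assemble_problem <- function(ghge, constraint_lists, sex = NA_character_,
                             content = NULL, factors = energy_factors()) {
  cons <- do.call(c, constraint_lists)
  if (!length(cons)) stop("assemble_problem: no constraints")
  cvec <- ghge_coefficients(ghge)
  if (anyNA(cvec)) {
    stop("assemble_problem: GHGE table missing subcategory(ies) ",
         paste(which(is.na(cvec)), collapse = ", "))
  }
  A <- do.call(rbind, lapply(cons, `[[`, "a"))
  lb <- vapply(cons, `[[`, numeric(1), "lb")
  ub <- vapply(cons, `[[`, numeric(1), "ub")
  label <- vapply(cons, `[[`, character(1), "label")
  kind <- vapply(cons, `[[`, character(1), "kind")

  # intersect single-variable boxes (positive unit-like rows)
  nz <- rowSums(A != 0)
  is_box <- nz == 1 & apply(A, 1, function(r) all(r >= 0))
  var_of <- ifelse(is_box, max.col(A != 0, ties.method = "first"), NA_integer_)
  keep <- rep(TRUE, length(cons))
  merged <- list()
  for (v in unique(stats::na.omit(var_of))) {
    idx <- which(!is.na(var_of) & var_of == v)
    if (length(idx) < 1) next
    co <- A[idx, v]
    lo <- max(lb[idx] / co, na.rm = TRUE)
    hi <- min(ub[idx] / co, na.rm = TRUE)
    if (lo > hi + 1e-12) {
      stop(structure(class = c("ghgediet_empty_box", "error", "condition"),
                     list(message = paste0(
                       "infeasible box for subcategory ", v, ": lower bound ",
                       signif(lo, 6), " exceeds upper bound ", signif(hi, 6),
                       " (", paste(label[idx], collapse = " & "), ")"),
                       call = sys.call())))
    }
    keep[idx] <- FALSE
    a <- numeric(55); a[v] <- 1
    merged[[length(merged) + 1L]] <- new_constraint(
      sprintf("box:%d%s", v, if (lo == 0 && hi == 0) ":fixed_zero" else ""),
      paste(sort(unique(kind[idx])), collapse = "+"), a, lo, hi)
  }
  A <- rbind(A[keep, , drop = FALSE], do.call(rbind, lapply(merged, `[[`, "a")))
  lb <- c(lb[keep], vapply(merged, `[[`, numeric(1), "lb"))
  ub <- c(ub[keep], vapply(merged, `[[`, numeric(1), "ub"))
  label <- c(label[keep], vapply(merged, `[[`, character(1), "label"))
  kind <- c(kind[keep], vapply(merged, `[[`, character(1), "kind"))

  structure(list(c = unname(cvec), A = unname(A), lb = lb, ub = ub,
                 label = label, kind = kind, sex = sex,
                 meta = list(content = content, factors = factors,
                             ghge = ghge, registry = subcategory_registry())),
            class = "lp_problem")
}

#' @export
print.lp_problem <- function(x, ...) {
  cat("<lp_problem> 55 variables, ", nrow(x$A), " constraints (",
      paste(names(table(x$kind)), table(x$kind), sep = ":", collapse = ", "),
      "), sex=", x$sex, "\n", sep = "")
  invisible(x)
}

#' Build the full problem for one sex from pipeline outputs
#'
#' Convenience wrapper: nutritional + acceptability + healthy
#' constraints with the shipped defaults.
#'
#' @param stats `population_stats` with content.
#' @param ghge `ghge_table`.
#' @param bounds optional bounds data.frame (default per `stats$sex`).
#' @param policy healthy policy list.
#' @param include_female_iron include the disabled female iron range.
#' @param weight_range,include_category_sums see
#'   [acceptability_constraints()].
#' @param factors [energy_factors()].
#' @return An `lp_problem`.
#' @export
build_problem <- function(stats, ghge, bounds = NULL,
                          policy = default_policy(),
                          include_female_iron = FALSE,
                          weight_range = c(0.8, 1.4),
                          include_category_sums = TRUE,
                          factors = energy_factors()) {
  if (is.null(bounds)) {
    bounds <- default_bounds(stats$sex, include_disabled = include_female_iron)
  }
  assemble_problem(
    ghge,
    list(nutrient_constraints(bounds, stats$content, factors),
         acceptability_constraints(stats, weight_range, include_category_sums),
         healthy_constraints(policy = policy)),
    sex = stats$sex, content = stats$content, factors = factors)
}
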