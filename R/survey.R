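# Survey processing: 3-day diary records -> per-subject mean daily
# intakes over the 55 subcategories -> sex-stratified population
# statistics (mean, 5th, 90th percentile; non-consumers included) and
# consumption-weighted nutrient content per 100 g of each subcategory.

#' Read a diary CSV
#'
#' Columns: `subject_id,sex,age,day,item_id,amount_g`; `sex` in
#' `{M, F}`; amounts in grams as consumed.
#'
#' @param path file path.
#' @return data.frame of diary records.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) stop("diary file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("subject_id", "sex", "age", "day", "item_id", "amount_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("diary schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  validate_diary(df)
  df
}

validate_diary <- function(diary) {
  if (any(!diary$sex %in% c("M", "F"))) stop("diary: sex must be 'M' or 'F'")
  if (any(diary$amount_g < 0)) stop("diary: negative amount_g")
  if (any(diary$day < 1)) stop("diary: day index must be >= 1")
  invisible(diary)
}

# Resolve diary item ids: unknown ids are an error, ids excluded by
# filter_catalog contribute nothing.
.resolve_items <- function(diary, catalog) {
  known <- catalog$items$item_id
  excluded <- attr(catalog, "excluded_items")
  unknown <- setdiff(diary$item_id, c(known, excluded))
  if (length(unknown)) {
    stop("diary references unknown item_id ", unknown[1])
  }
  diary[diary$item_id %in% known, , drop = FALSE]
}

#' Mean daily subcategory intake of one subject
#'
#' Sums diary amounts per subcategory and divides by the number of
#' distinct diary days (data-driven diary length, default design 3
#' days). Items excluded by [filter_catalog()] contribute nothing.
#'
#' @param records diary rows of a single subject.
#' @param catalog a (typically filtered) `food_catalog`.
#' @return Named numeric 55-vector, g/day.
#' @export
subject_daily_intake <- function(records, catalog) {
  stopifnot(inherits(catalog, "food_catalog"))
  if (length(unique(records$subject_id)) > 1) {
    stop("subject_daily_intake: records span several subjects")
  }
  out <- stats::setNames(numeric(55), as.character(1:55))
  if (!nrow(records)) return(out)
  validate_diary(records)
  n_days <- length(unique(records$day))
  rec <- .resolve_items(records, catalog)
  if (!nrow(rec)) return(out)
  sub <- catalog$items$subcategory_id[match(rec$item_id, catalog$items$item_id)]
  tot <- tapply(rec$amount_g, sub, sum)
  out[names(tot)] <- tot / n_days
  out
}

#' Per-subject intake matrix for a whole diary table
#'
#' Vectorized equivalent of [subject_daily_intake()] over all subjects.
#'
#' @param diary full diary data.frame.
#' @param catalog a `food_catalog`.
#' @return Object of class `subject_intakes`: list with `subject_id`,
#'   `sex`, `age` and `intake` (subjects x 55 matrix, g/day).
#' @export
compute_subject_intakes <- function(diary, catalog) {
  stopifnot(inherits(catalog, "food_catalog"))
  validate_diary(diary)
  dt <- data.table::as.data.table(diary)
  days <- dt[, list(n_days = length(unique(day))), by = "subject_id"]
  meta <- unique(dt[, c("subject_id", "sex", "age")])
  if (anyDuplicated(meta$subject_id)) {
    stop("diary: inconsistent sex/age within subject_id")
  }
  rec <- .resolve_items(as.data.frame(dt), catalog)
  rec$subcategory_id <- catalog$items$subcategory_id[
    match(rec$item_id, catalog$items$item_id)]
  agg <- data.table::as.data.table(rec)[
    , list(total = sum(amount_g)), by = c("subject_id", "subcategory_id")]
  agg <- merge(agg, days, by = "subject_id")
  mat <- matrix(0, nrow = nrow(meta), ncol = 55,
                dimnames = list(as.character(meta$subject_id), as.character(1:55)))
  mat[cbind(match(agg$subject_id, meta$subject_id), agg$subcategory_id)] <-
    agg$total / agg$n_days
  structure(list(subject_id = meta$subject_id, sex = meta$sex,
                 age = meta$age, intake = mat),
            class = "subject_intakes")
}

#' Sex-stratified population intake statistics
#'
#' Mean, 5th and 90th percentile of mean daily intake per subcategory
#' (and per category), with non-consumers included (zero intakes count).
#' The percentile convention defaults to the empirical distribution
#' function with averaging at discontinuities (`type = 2`, the common
#' statistics-package default), configurable among the conventions of
#' [stats::quantile()].
#'
#' @param intakes a `subject_intakes` object.
#' @param sex `"M"` or `"F"`.
#' @param qtype percentile definition (default 2).
#' @return Object of class `population_stats`: list with `sex`,
#'   `n_subjects`, per-subcategory `mean`/`p5`/`p90` (named 55-vectors,
#'   g/day), per-category `cat_mean`/`cat_p5`/`cat_p90` (15-vectors) and
#'   `mean_total` (mean total diet weight, g/day). The nutrient `content`
#'   slot is filled by [survey_stats()].
#' @export
population_stats <- function(intakes, sex, qtype = 2) {
  stopifnot(inherits(intakes, "subject_intakes"), sex %in% c("M", "F"))
  keep <- intakes$sex == sex
  if (!any(keep)) stop("population_stats: no subjects of sex ", sex)
  m <- intakes$intake[keep, , drop = FALSE]
  reg <- subcategory_registry()
  catm <- t(apply(m, 1, function(r) tapply(r, reg$category_id, sum)))
  q <- function(mat, p) apply(mat, 2, stats::quantile, probs = p,
                              type = qtype, names = FALSE)
  structure(list(
    sex = sex, n_subjects = sum(keep), qtype = qtype,
    mean = colMeans(m), p5 = q(m, 0.05), p90 = q(m, 0.90),
    cat_mean = colMeans(catm), cat_p5 = q(catm, 0.05), cat_p90 = q(catm, 0.90),
    mean_total = mean(rowSums(m)), content = NULL),
    class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat("<population_stats> sex=", x$sex, ", n=", x$n_subjects,
      ", mean total weight=", round(x$mean_total, 1), " g/day\n", sep = "")
  invisible(x)
}

#' Consumption-weighted nutrient content per 100 g of each subcategory
#'
#' For every subcategory, the content per 100 g is the mean of its
#' member items' compositions weighted by the total amount consumed in
#' the requested sex stratum. Never-consumed subcategories fall back to
#' the unweighted mean of their member items (with a warning);
#' subcategories with no catalog items at all get zero content.
#'
#' @param diary full diary data.frame.
#' @param catalog a `food_catalog`.
#' @param sex `"M"` or `"F"`.
#' @return 55 x 15 matrix (subcategories x [nutrient_names()]), per 100 g.
#' @export
weighted_nutrient_content <- function(diary, catalog, sex) {
  stopifnot(inherits(catalog, "food_catalog"), sex %in% c("M", "F"))
  rec <- .resolve_items(diary[diary$sex == sex, , drop = FALSE], catalog)
  w <- tapply(rec$amount_g, rec$item_id, sum)
  comp <- item_composition(catalog)
  it <- catalog$items
  content <- matrix(0, nrow = 55, ncol = length(nutrient_names()),
                    dimnames = list(as.character(1:55), nutrient_names()))
  unweighted <- integer(0)
  for (k in 1:55) {
    idx <- which(it$subcategory_id == k)
    if (!length(idx)) next
    wk <- as.vector(w[as.character(it$item_id[idx])])
    wk[is.na(wk)] <- 0
    if (sum(wk) <= 0) {
      unweighted <- c(unweighted, k)
      wk <- rep(1, length(idx))
    }
    content[k, ] <- colSums(comp[idx, , drop = FALSE] * wk) / sum(wk)
  }
  if (length(unweighted)) {
    warning("weighted_nutrient_content: no observed consumption for subcategory(ies) ",
            paste(unweighted, collapse = ", "), "; using unweighted item mean")
  }
  content
}

#' Full population statistics including nutrient content
#'
#' Convenience wrapper chaining [compute_subject_intakes()],
#' [population_stats()] and [weighted_nutrient_content()].
#'
#' @inheritParams weighted_nutrient_content
#' @inheritParams population_stats
#' @return A `population_stats` object with the `content` slot filled.
#' @export
survey_stats <- function(diary, catalog, sex, qtype = 2) {
  intakes <- compute_subject_intakes(diary, catalog)
  st <- population_stats(intakes, sex, qtype = qtype)
  st$content <- suppressWarnings(weighted_nutrient_content(diary, catalog, sex))
  st
}

#' Nutrient totals and GHGE of the mean observed diet
#'
#' Evaluates the observed diet (per-subcategory mean intakes) against
#' the nutrient-content matrix and the GHGE coefficient table:
#' per-day nutrient totals, percent-of-energy shares of the energy-
#' yielding nutrients (using the configured energy factors), total diet
#' weight, and total GHGE.
#'
#' @param stats a `population_stats` with `content` filled.
#' @param ghge a `ghge_table`.
#' @param factors energy conversion factors, see [energy_factors()].
#' @return List with `nutrients` (named vector, per day),
#'   `percent_energy` (named vector, % of energy), `total_weight`
#'   (g/day) and `ghge` (kg CO2e/day).
#' @export
observed_summary <- function(stats, ghge, factors = energy_factors()) {
  stopifnot(inherits(stats, "population_stats"), !is.null(stats$content))
  diet_summary(stats$mean, stats$content, ghge, factors)
}

# Shared evaluation of an arbitrary diet vector.
diet_summary <- function(x, content, ghge, factors = energy_factors()) {
  x <- as.numeric(x)
  if (length(x) != nrow(content)) stop("diet_summary: dimension mismatch")
  totals <- drop(crossprod(content / 100, x))
  cvec <- ghge_coefficients(ghge)
  if (anyNA(cvec)) stop("diet_summary: GHGE table does not cover all 55 subcategories")
  energy <- totals[["energy_kcal"]]
  pe <- c(
    total_fat = totals[["total_fat_g"]] * factors[["fat"]],
    sfa = totals[["sfa_g"]] * factors[["fat"]],
    pufa = totals[["pufa_g"]] * factors[["fat"]],
    carbohydrate = totals[["carb_g"]] * factors[["carbohydrate"]],
    total_sugar = (totals[["free_sugar_g"]] + totals[["intrinsic_sugar_g"]]) *
      factors[["carbohydrate"]],
    free_sugar = totals[["free_sugar_g"]] * factors[["carbohydrate"]],
    alcohol = totals[["alcohol_g"]] * factors[["alcohol"]])
  pe <- if (energy > 0) 100 * pe / energy else pe * NA_real_
  list(nutrients = totals, percent_energy = pe,
       total_weight = sum(x), ghge = sum(cvec * x))
}

#' Write population statistics to CSV files
#'
#' Emits the intake statistics (`sex,subcategory_id,mean,p5,p90`) and,
#' if present, the nutrient content per 100 g.
#'
#' @param stats a `population_stats`.
#' @param stats_path CSV path for the intake statistics.
#' @param content_path optional CSV path for the content matrix.
#' @return `stats_path`, invisibly.
#' @export
write_population_stats <- function(stats, stats_path, content_path = NULL) {
  df <- data.frame(sex = stats$sex, subcategory_id = 1:55,
                   mean = stats$mean, p5 = stats$p5, p90 = stats$p90)
  data.table::fwrite(df, stats_path)
  if (!is.null(content_path) && !is.null(stats$content)) {
    out <- data.frame(subcategory_id = 1:55, stats$content)
    data.table::fwrite(out, content_path)
  }
  invisible(stats_path)
}
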