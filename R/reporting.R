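# Observed-vs-optimized reporting: nutrient and food-group comparison
# tables with bound annotations, and per-category contribution shares
# of selected nutrients.

#' Signed integer percent change
#'
#' `100 * (optimized - observed) / observed`, rounded half away from
#' zero to an integer (the usual convention in printed tables:
#' 68.51 -> 69, 9.7 -> 10, 36.9 -> 37). Undefined for a zero baseline.
#'
#' @param observed baseline value(s), must be > 0 for a defined result.
#' @param optimized new value(s).
#' @return Integer vector; `NA` where `observed` is 0.
#' @export
percent_change <- function(observed, optimized) {
  if (any(observed < 0, na.rm = TRUE)) stop("percent_change: negative baseline")
  raw <- 100 * (optimized - observed) / observed
  raw[observed == 0] <- NA_real_
  as.integer(sign(raw) * floor(abs(raw) + 0.5))
}

#' GHGE of a diet
#'
#' Dot product of the diet vector with the per-gram emission
#' coefficients.
#'
#' @param x diet vector, g/day over the 55 subcategories.
#' @param ghge a `ghge_table`.
#' @return kg CO2e/day.
#' @export
ghge_of_diet <- function(x, ghge) {
  cvec <- ghge_coefficients(ghge)
  if (length(x) != length(cvec)) stop("ghge_of_diet: dimension mismatch")
  if (anyNA(cvec)) stop("ghge_of_diet: GHGE table does not cover all subcategories")
  sum(cvec * x)
}

#' Percentage contribution of food categories to a nutrient's intake
#'
#' @param x diet vector, g/day over the 55 subcategories.
#' @param content 55 x 15 per-100g nutrient matrix.
#' @param nutrient nutrient label (see [nutrient_names()] mapping used
#'   by the constraints, e.g. `"protein"`, `"iron"`).
#' @param registry subcategory registry.
#' @return Named numeric 15-vector of percentages summing to 100, or
#'   all-`NA` when the nutrient total is zero.
#' @export
category_contributions <- function(x, content, nutrient,
                                   registry = subcategory_registry()) {
  a <- nutrient_row(nutrient, content)
  per_sub <- a * x
  per_cat <- tapply(per_sub, registry$category_id, sum)
  tot <- sum(per_cat)
  if (tot <= 0) return(stats::setNames(rep(NA_real_, 15), names(per_cat)))
  stats::setNames(as.vector(100 * per_cat / tot), names(per_cat))
}

#' Observed-vs-optimized comparison report
#'
#' Builds the two standard comparison tables: per-nutrient (observed
#' intake, optimized intake, configured bounds) and per-subcategory
#' (observed mean, optimized amount, signed percent change, bound
#' annotation). Annotations follow the usual footnote style:
#' `b` at the 90th-percentile upper bound, `c` at a nonzero
#' 5th-percentile lower bound, `d` fixed to zero because both
#' percentiles are zero, `e` set to zero by policy.
#'
#' @param stats `population_stats` of the observed diet (same sex).
#' @param solution an optimal `diet_solution`.
#' @param ghge a `ghge_table`.
#' @param tol binding tolerance for the annotations.
#' @return Object of class `diet_comparison`: list with `nutrients`,
#'   `subcategories`, `ghge` (observed, optimized, percent change) and
#'   `sex`.
#' @export
comparison_report <- function(stats, solution, ghge, tol = 1e-6) {
  stopifnot(inherits(stats, "population_stats"),
            inherits(solution, "diet_solution"))
  if (solution$status != "optimal") stop("comparison_report: solution not optimal")
  if (!identical(stats$sex, solution$problem$sex) &&
      !is.na(solution$problem$sex)) {
    stop("comparison_report: sex mismatch between stats and solution")
  }
  x <- solution$x
  obs <- observed_summary(stats, ghge, solution$problem$meta$factors)
  opt <- solution$totals
  reg <- solution$problem$meta$registry

  nut <- data.frame(
    nutrient = names(obs$nutrients),
    observed = as.numeric(obs$nutrients),
    optimized = as.numeric(opt$nutrients), row.names = NULL)

  policy_zero <- reg$processed_meat | reg$alcoholic
  fixed_zero <- stats$p5 == 0 & stats$p90 == 0
  scale <- pmax(stats$p90, 1)
  at_p90 <- !fixed_zero & abs(x - stats$p90) <= tol * scale
  at_p5 <- !fixed_zero & stats$p5 > 0 & abs(x - stats$p5) <= tol * scale
  ann <- rep("", 55)
  ann[at_p90] <- "b"
  ann[at_p5] <- "c"
  ann[fixed_zero] <- "d"
  ann[policy_zero] <- "e"
  sub <- data.frame(
    subcategory_id = 1:55,
    subcategory = reg$subcategory,
    category_id = reg$category_id,
    observed = as.numeric(stats$mean),
    optimized = as.numeric(x),
    percent_change = percent_change(stats$mean, as.numeric(x)),
    annotation = ann, row.names = NULL)

  structure(list(
    nutrients = nut, subcategories = sub,
    ghge = list(observed = obs$ghge, optimized = opt$ghge,
                percent_change = percent_change(obs$ghge, opt$ghge)),
    sex = stats$sex), class = "diet_comparison")
}

#' @export
print.diet_comparison <- function(x, ...) {
  cat("Diet comparison (sex=", x$sex, ")\n", sep = "")
  cat(sprintf("GHGE: observed %.1f vs optimized %.1f kg CO2e/day (%+d%%)\n",
              x$ghge$observed, x$ghge$optimized, x$ghge$percent_change))
  cat("\nNutrients (per day):\n")
  nut <- x$nutrients
  nut$observed <- signif(nut$observed, 4)
  nut$optimized <- signif(nut$optimized, 4)
  print(nut, row.names = FALSE)
  cat("\nSubcategories (g/day, annotations: b=at p90, c=at p5, d=fixed zero, e=policy zero):\n")
  sub <- x$subcategories
  sub$observed <- round(sub$observed, 1)
  sub$optimized <- round(sub$optimized, 1)
  print(sub[, c("subcategory_id", "subcategory", "observed", "optimized",
                "percent_change", "annotation")], row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to CSV files
#'
#' @param comparison a `diet_comparison`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(comparison$nutrients, file.path(dir, "nutrients.csv"))
  data.table::fwrite(comparison$subcategories, file.path(dir, "subcategories.csv"))
  invisible(dir)
}

#' Stacked-bar plot of category contributions (optional)
#'
#' Compares the category shares of selected nutrients between the
#' observed and optimized diet. Requires ggplot2.
#'
#' @param stats `population_stats`.
#' @param solution optimal `diet_solution`.
#' @param nutrients nutrient labels to display.
#' @return A ggplot object.
#' @export
plot_category_contributions <- function(stats, solution,
                                        nutrients = c("protein", "iron",
                                                      "calcium", "vitamin_b12")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_category_contributions requires ggplot2")
  }
  content <- solution$problem$meta$content
  reg <- solution$problem$meta$registry
  rows <- list()
  for (nm in nutrients) {
    for (diet in c("observed", "optimized")) {
      x <- if (diet == "observed") stats$mean else solution$x
      sh <- category_contributions(x, content, nm, reg)
      rows[[length(rows) + 1L]] <- data.frame(
        nutrient = nm, diet = diet, category_id = as.integer(names(sh)),
        percent = as.numeric(sh))
    }
  }
  df <- do.call(rbind, rows)
  df$category <- category_registry()$category[df$category_id]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diet, y = .data$percent,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~nutrient) +
    ggplot2::labs(y = "% of total intake", x = NULL)
}
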