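# GHGE coefficient database: literature life-cycle-assessment data
# points (kg CO2e per kg food) are aggregated per "indicator product"
# and then averaged per food subcategory; uncertainty ranges are
# descriptive only and never enter the optimization.

#' Global Warming Potential factors (100-year horizon)
#'
#' Multipliers converting 1 kg of a greenhouse gas into kg CO2
#' equivalents: CO2 = 1, CH4 = 25, N2O = 298.
#'
#' @return Named numeric vector.
#' @export
gwp_factors <- function() {
  c(CO2 = 1, CH4 = 25, N2O = 298)
}

#' Convert a gas mass to CO2 equivalents
#'
#' @param mass mass in kg, non-negative.
#' @param gas gas identifier, one of `names(gwp_factors())`.
#' @param factors GWP factor table; defaults to [gwp_factors()].
#' @return mass in kg CO2e.
#' @export
gwp_to_co2e <- function(mass, gas, factors = gwp_factors()) {
  if (any(mass < 0)) stop("gwp_to_co2e: mass must be non-negative")
  if (!all(gas %in% names(factors))) {
    stop("gwp_to_co2e: unknown gas '", setdiff(gas, names(factors))[1], "'")
  }
  unname(mass * factors[gas])
}

#' Mean emission value of an indicator product
#'
#' @param values numeric vector of literature data points, kg CO2e/kg.
#' @return Arithmetic mean, kg CO2e/kg.
#' @export
indicator_mean <- function(values) {
  if (!length(values)) stop("indicator_mean: no data points")
  if (any(values <= 0)) stop("indicator_mean: values must be positive")
  mean(values)
}

#' Uncertainty range of an indicator product
#'
#' The range rule depends on how many literature data points back the
#' indicator: with four or more points the lower and upper quartiles
#' are used; with two or three points the minimum and maximum; with a
#' single point a -50%/+50% band, narrowed to -25%/+25% when the point
#' is a national estimate judged reliable against international values.
#'
#' @param values numeric vector of data points, kg CO2e/kg.
#' @param national_reliable logical; only consulted for a single point.
#' @param qtype quartile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return Named numeric vector `c(lo, hi)` with attribute `rule` in
#'   `{"quartiles","minmax","pm50","pm25"}`.
#' @export
uncertainty_range <- function(values, national_reliable = FALSE, qtype = 7) {
  if (!length(values)) stop("uncertainty_range: no data points")
  if (any(values <= 0)) stop("uncertainty_range: values must be positive")
  n <- length(values)
  if (n >= 4) {
    q <- unname(stats::quantile(values, c(0.25, 0.75), type = qtype))
    out <- c(lo = q[1], hi = q[2]); rule <- "quartiles"
  } else if (n >= 2) {
    out <- c(lo = min(values), hi = max(values)); rule <- "minmax"
  } else if (isTRUE(national_reliable)) {
    out <- c(lo = 0.75 * values, hi = 1.25 * values); rule <- "pm25"
  } else {
    out <- c(lo = 0.5 * values, hi = 1.5 * values); rule <- "pm50"
  }
  # containment: skewed samples can place the mean outside the quartile
  # band; the descriptive range is widened to always bracket the mean
  m <- mean(values)
  out <- c(lo = min(out[["lo"]], m), hi = max(out[["hi"]], m))
  attr(out, "rule") <- rule
  out
}

#' Subcategory emission coefficient from its indicator products
#'
#' The subcategory value is the unweighted mean of its component
#' indicator-product means, converted from per-kg to per-gram.
#'
#' @param indicator_means numeric vector, kg CO2e/kg.
#' @param subcategory_id optional id used in the error message.
#' @return Coefficient in kg CO2e per g.
#' @export
subcategory_ghge <- function(indicator_means, subcategory_id = NULL) {
  if (!length(indicator_means)) {
    stop("subcategory_ghge: no indicator products cover subcategory ",
         if (is.null(subcategory_id)) "?" else subcategory_id)
  }
  mean(indicator_means) / 1000
}

#' Build the per-subcategory GHGE coefficient table
#'
#' Composes [indicator_mean()], [uncertainty_range()] and
#' [subcategory_ghge()]: data points are averaged per indicator
#' product, indicators are mapped (possibly many-to-many) onto
#' subcategories, and each covered subcategory receives the mean of its
#' indicator means as objective coefficient. Uncertainty ranges are
#' averaged alongside for reporting; they never affect the coefficient.
#'
#' @param points data.frame with columns `indicator_id`,
#'   `value_kgco2e_per_kg`, `national_reliable` (logical), `source`.
#' @param mapping data.frame with columns `indicator_id`,
#'   `subcategory_id`.
#' @param required subcategory ids that must be covered (default all
#'   ids in `mapping`); an uncovered required subcategory is an error.
#' @param qtype quartile convention, see [uncertainty_range()].
#' @return A `ghge_table` data.frame with one row per covered
#'   subcategory: `subcategory_id`, `c_kgco2e_per_g`, `lo`, `hi` (same
#'   per-gram units), `rule`, `n_points`, `indicator_ids`.
#' @export
build_ghge_table <- function(points, mapping, required = NULL, qtype = 7) {
  points <- as.data.frame(points)
  mapping <- as.data.frame(mapping)
  stopifnot(all(c("indicator_id", "value_kgco2e_per_kg") %in% names(points)),
            all(c("indicator_id", "subcategory_id") %in% names(mapping)))
  if (is.null(points$national_reliable)) points$national_reliable <- FALSE
  unk <- setdiff(mapping$indicator_id, points$indicator_id)
  if (length(unk)) {
    stop("build_ghge_table: mapping references indicator(s) with no data points: ",
         paste(unk, collapse = ", "))
  }
  ind <- lapply(split(points, points$indicator_id), function(p) {
    rng <- uncertainty_range(p$value_kgco2e_per_kg,
                             national_reliable = all(p$national_reliable),
                             qtype = qtype)
    data.frame(indicator_id = p$indicator_id[1],
               mean = indicator_mean(p$value_kgco2e_per_kg),
               lo = rng[["lo"]], hi = rng[["hi"]],
               rule = attr(rng, "rule"), n_points = nrow(p))
  })
  ind <- do.call(rbind, ind)
  m <- merge(mapping, ind, by = "indicator_id")
  rows <- lapply(split(m, m$subcategory_id), function(g) {
    data.frame(
      subcategory_id = g$subcategory_id[1],
      c_kgco2e_per_g = subcategory_ghge(g$mean, g$subcategory_id[1]),
      lo = mean(g$lo) / 1000, hi = mean(g$hi) / 1000,
      rule = paste(sort(unique(g$rule)), collapse = ";"),
      n_points = sum(g$n_points),
      indicator_ids = paste(g$indicator_id, collapse = ";"))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$subcategory_id), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(required)) {
    uncov <- setdiff(required, tab$subcategory_id)
    if (length(uncov)) {
      stop("build_ghge_table: no GHGE indicator covers subcategory(ies) ",
           paste(uncov, collapse = ", "))
    }
  }
  class(tab) <- c("ghge_table", "data.frame")
  tab
}

#' Objective coefficient vector over the 55 subcategories
#'
#' @param ghge a `ghge_table`.
#' @return Numeric 55-vector of kg CO2e per g, named by subcategory id.
#' @export
ghge_coefficients <- function(ghge) {
  cvec <- rep(NA_real_, 55)
  names(cvec) <- as.character(1:55)
  cvec[as.character(ghge$subcategory_id)] <- ghge$c_kgco2e_per_g
  cvec
}

#' Write / read a GHGE table as CSV
#' @param ghge a `ghge_table`.
#' @param path file path.
#' @return `path` (write) or a `ghge_table` (read).
#' @export
write_ghge_table <- function(ghge, path) {
  out <- as.data.frame(ghge)
  for (col in c("c_kgco2e_per_g", "lo", "hi")) {
    out[[col]] <- .format_roundtrip(out[[col]])
  }
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_ghge_table
#' @export
read_ghge_table <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  class(tab) <- c("ghge_table", "data.frame")
  tab
}
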