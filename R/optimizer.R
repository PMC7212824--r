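# GHGE minimization and the infeasibility diagnostic: when the full
# problem has no solution, a suspect constraint is removed and the
# achievable range of its quantity over the remaining feasible set is
# computed by optimizing that quantity in both directions.

#' Solve the GHGE-minimizing linear program
#'
#' Deterministic: the same problem always yields the same solution.
#' Multiple optimal vertices are possible in degenerate problems, so
#' downstream checks should assert on the objective value and binding
#' pattern rather than the full amount vector.
#'
#' @param problem an `lp_problem`.
#' @return An object of class `diet_solution`: list with `status`
#'   (`optimal`/`infeasible`/`unbounded`/`error`), `x` (named 55-vector
#'   of g/day), `objective` (kg CO2e/day), `totals` (nutrient and
#'   percent-of-energy summary when content is available), `binding`
#'   (active constraints) and `problem`.
#' @export
solve_min_ghge <- function(problem) {
  stopifnot(inherits(problem, "lp_problem"))
  res <- solve_lp(problem, problem$c)
  sol <- structure(list(status = res$status, x = NULL, objective = NA_real_,
                        totals = NULL, binding = NULL, problem = problem,
                        diagnostics = res[setdiff(names(res), c("x", "status"))]),
                   class = "diet_solution")
  if (res$status != "optimal") return(sol)
  x <- stats::setNames(res$x, as.character(1:55))
  sol$x <- x
  sol$objective <- sum(problem$c * x)
  if (!is.null(problem$meta$content)) {
    sol$totals <- diet_summary(x, problem$meta$content, problem$meta$ghge,
                               problem$meta$factors)
  }
  sol$binding <- active_constraints(sol)
  sol
}

#' @export
print.diet_solution <- function(x, ...) {
  cat("<diet_solution> status=", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", GHGE=", signif(x$objective, 4), " kg CO2e/day, total weight=",
        round(sum(x$x), 1), " g/day, ", nrow(x$binding), " binding constraints",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Optimize a nutrient over the remaining feasible set
#'
#' Removes the nutrient's own bound constraints from the problem and
#' maximizes (or minimizes) its daily intake subject to everything
#' else. This is the core of the infeasibility diagnostic: if the
#' maximized value falls short of the removed lower bound, no diet can
#' satisfy the full constraint set.
#'
#' @param problem an `lp_problem` with `content` metadata.
#' @param nutrient nutrient label (e.g. `"iron"`).
#' @param direction `"max"` or `"min"`.
#' @return List with `status`, `value` (per-day intake at the extremum)
#'   and `x` (an achieving diet).
#' @export
optimize_nutrient <- function(problem, nutrient, direction = c("max", "min")) {
  direction <- match.arg(direction)
  stopifnot(inherits(problem, "lp_problem"))
  if (is.null(problem$meta$content)) {
    stop("optimize_nutrient: problem carries no nutrient content")
  }
  a <- nutrient_row(nutrient, problem$meta$content)
  drop <- grep(paste0("^nutrient:", nutrient, "(:|$)"), problem$label,
               value = TRUE)
  res <- solve_lp(problem, a, drop_labels = drop,
                  maximize = direction == "max")
  list(status = res$status,
       value = if (res$status == "optimal") res$value else NA_real_,
       x = if (res$status == "optimal") stats::setNames(res$x, as.character(1:55)),
       nutrient = nutrient, direction = direction)
}

#' Diagnose an infeasible problem by single-constraint removal
#'
#' For each suspect constraint label: remove it, re-solve, and -- when
#' the relaxed problem is feasible -- compute the achievable
#' `[min, max]` range of the suspect quantity over the remaining
#' feasible set. A suspect whose removal restores feasibility and whose
#' achievable maximum falls below its former lower bound (or minimum
#' above its upper bound) explains the infeasibility.
#'
#' @param problem an `lp_problem` (typically one for which
#'   [solve_min_ghge()] returned `infeasible`).
#' @param suspects constraint labels to probe; defaults to all
#'   nutritional per-day constraints.
#' @return data.frame with one row per suspect: `label`,
#'   `restores_feasibility`, `achievable_min`, `achievable_max`, `lb`,
#'   `ub` and `gap` (shortfall of the achievable range against the
#'   removed bound; 0 when the bound is attainable). Attribute `note`
#'   flags a problem that was already feasible.
#' @export
diagnose_infeasibility <- function(problem, suspects = NULL) {
  stopifnot(inherits(problem, "lp_problem"))
  if (is.null(suspects)) {
    suspects <- problem$label[problem$kind == "nutritional" &
                                !grepl(":%E_", problem$label)]
  }
  base <- solve_lp(problem, problem$c)
  out <- data.frame(label = character(0), restores_feasibility = logical(0),
                    achievable_min = numeric(0), achievable_max = numeric(0),
                    lb = numeric(0), ub = numeric(0), gap = numeric(0))
  if (base$status == "optimal") {
    attr(out, "note") <- "problem is feasible; nothing to diagnose"
    return(out)
  }
  for (lab in suspects) {
    idx <- which(problem$label == lab)
    if (!length(idx)) stop("diagnose_infeasibility: unknown label '", lab, "'")
    a <- problem$A[idx[1], ]
    lb <- problem$lb[idx[1]]; ub <- problem$ub[idx[1]]
    rel <- solve_lp(problem, problem$c, drop_labels = lab)
    if (rel$status != "optimal") {
      out <- rbind(out, data.frame(label = lab, restores_feasibility = FALSE,
                                   achievable_min = NA_real_,
                                   achievable_max = NA_real_,
                                   lb = lb, ub = ub, gap = NA_real_))
      next
    }
    lo <- solve_lp(problem, a, drop_labels = lab, maximize = FALSE)
    hi <- solve_lp(problem, a, drop_labels = lab, maximize = TRUE)
    amin <- if (lo$status == "optimal") lo$value else NA_real_
    amax <- if (hi$status == "optimal") hi$value else Inf
    gap <- 0
    if (is.finite(lb) && !is.na(amax) && amax < lb) gap <- lb - amax
    if (is.finite(ub) && !is.na(amin) && amin > ub) gap <- max(gap, amin - ub)
    out <- rbind(out, data.frame(label = lab, restores_feasibility = TRUE,
                                 achievable_min = amin, achievable_max = amax,
                                 lb = lb, ub = ub, gap = gap))
  }
  rownames(out) <- NULL
  out
}

#' Report constraints binding at a solution
#'
#' A constraint is binding-low when its row value sits at the lower
#' bound within a relative tolerance (with an absolute floor for
#' near-zero bounds), binding-high analogously. Single-variable boxes
#' are reported per subcategory.
#'
#' @param solution an optimal `diet_solution`.
#' @param tol relative tolerance (default 1e-6).
#' @param abs_floor absolute tolerance floor (default 1e-9).
#' @return data.frame with `label`, `kind`, `value`, `lb`, `ub`, `side`
#'   (`lower`/`upper`/`both`).
#' @export
active_constraints <- function(solution, tol = 1e-6, abs_floor = 1e-9) {
  stopifnot(inherits(solution, "diet_solution"))
  if (solution$status != "optimal") stop("active_constraints: solution not optimal")
  p <- solution$problem
  v <- drop(p$A %*% solution$x)
  fin <- function(b) ifelse(is.finite(b), abs(b), 0)
  tl <- pmax(tol * pmax(fin(p$lb), fin(p$ub), 1), abs_floor)
  low <- is.finite(p$lb) & (v - p$lb <= tl)
  high <- is.finite(p$ub) & (p$ub - v <= tl)
  sel <- low | high
  data.frame(label = p$label[sel], kind = p$kind[sel], value = v[sel],
             lb = p$lb[sel], ub = p$ub[sel],
             side = ifelse(low[sel] & high[sel], "both",
                           ifelse(low[sel], "lower", "upper")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Verify a diet against every constraint of a problem
#'
#' Arithmetic check, independent of the solver: evaluates each row and
#' reports violations beyond a normalized tolerance.
#'
#' @param problem an `lp_problem`.
#' @param x diet vector (g/day, length 55).
#' @param tol normalized tolerance (default 1e-8).
#' @return TRUE if feasible; otherwise a data.frame of violated rows.
#' @export
check_feasible <- function(problem, x, tol = 1e-8) {
  v <- drop(problem$A %*% x)
  scale <- pmax(abs(problem$lb), abs(problem$ub), 1, na.rm = TRUE)
  bad <- (is.finite(problem$lb) & v < problem$lb - tol * scale) |
    (is.finite(problem$ub) & v > problem$ub + tol * scale) |
    any(x < -tol)
  if (!any(bad)) return(TRUE)
  data.frame(label = problem$label[bad], value = v[bad],
             lb = problem$lb[bad], ub = problem$ub[bad], row.names = NULL)
}
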