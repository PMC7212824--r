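# Independent oracles, implemented separately from the package code
# paths they check.

# Brute-force LP oracle for problems with few free variables:
# enumerate every intersection of `nv` constraint hyperplanes (bounds
# taken at either side, plus the axes), keep feasible points, return
# the best objective. Deliberately naive.
oracle_lp <- function(cvec, A, lb, ub, nv = length(cvec), maximize = FALSE) {
  planes <- list()
  for (i in seq_len(nrow(A))) {
    if (is.finite(lb[i])) planes[[length(planes) + 1L]] <- c(A[i, ], lb[i])
    if (is.finite(ub[i]) && (!is.finite(lb[i]) || ub[i] != lb[i])) {
      planes[[length(planes) + 1L]] <- c(A[i, ], ub[i])
    }
  }
  for (j in seq_len(nv)) {
    e <- numeric(nv); e[j] <- 1
    planes[[length(planes) + 1L]] <- c(e, 0)
  }
  P <- do.call(rbind, planes)
  best <- NULL
  for (combo in utils::combn(nrow(P), nv, simplify = FALSE)) {
    M <- P[combo, seq_len(nv), drop = FALSE]
    if (abs(det(M)) < 1e-9) next
    x <- tryCatch(solve(M, P[combo, nv + 1]), error = function(e) NULL)
    if (is.null(x) || any(x < -1e-9)) next
    v <- drop(A %*% x)
    if (any(v < lb - 1e-9, na.rm = TRUE) || any(v > ub + 1e-9, na.rm = TRUE)) next
    val <- sum(cvec * x)
    if (is.null(best) || (!maximize && val < best$value - 1e-12) ||
        (maximize && val > best$value + 1e-12)) {
      best <- list(value = val, x = x)
    }
  }
  best
}

# sort-and-index percentile oracle: empirical distribution function
# with averaging at discontinuities (quantile type 2)
oracle_quantile_t2 <- function(x, p) {
  x <- unname(sort(x))
  n <- length(x)
  np <- n * p
  if (abs(np - round(np)) < 1e-12 && np >= 1) {
    (x[np] + x[min(np + 1, n)]) / 2
  } else {
    x[min(max(ceiling(np), 1), n)]
  }
}

# type-7 quartile oracle (linear interpolation between order statistics)
oracle_quartile_t7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# item-level nutrient totals of the mean observed diet of one sex,
# computed straight from diary records (never through subcategory
# aggregation)
oracle_mean_diet_nutrients <- function(diary, catalog, sex) {
  strat <- diary[diary$sex == sex, ]
  d <- strat[strat$item_id %in% catalog$items$item_id, ]
  n_subj <- length(unique(strat$subject_id))
  days <- stats::aggregate(day ~ subject_id, strat,
                           function(x) length(unique(x)))
  comp <- as.matrix(catalog$items[, nutrient_names()])
  rownames(comp) <- catalog$items$item_id
  tot <- numeric(length(nutrient_names()))
  names(tot) <- nutrient_names()
  for (i in seq_len(nrow(d))) {
    nd <- days$day[days$subject_id == d$subject_id[i]]
    tot <- tot + d$amount_g[i] / 100 * comp[as.character(d$item_id[i]), ] / nd
  }
  tot / n_subj
}
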