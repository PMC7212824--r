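# build a 3-active-variable lp_problem from rows over vars 1:3
mk_prob3 <- function(cvec3, rows, lb, ub, content = NULL) {
  cons <- list()
  for (i in seq_along(lb)) {
    a <- numeric(55); a[1:3] <- rows[[i]]
    cons[[i]] <- ghgediet:::new_constraint(paste0("r", i), "nutritional",
                                           a, lb[i], ub[i])
  }
  for (k in 4:55) {
    a <- numeric(55); a[k] <- 1
    cons[[length(cons) + 1L]] <- ghgediet:::new_constraint(
      sprintf("box:%d:fixed_zero", k), "acceptability", a, 0, 0)
  }
  cvec <- c(cvec3, rep(1, 52))
  ghge <- data.frame(subcategory_id = 1:55, c_kgco2e_per_g = cvec, lo = cvec,
                     hi = cvec, rule = "pm50", n_points = 1, indicator_ids = "")
  class(ghge) <- c("ghge_table", "data.frame")
  assemble_problem(ghge, list(cons), content = content)
}

test_that("solver agrees with vertex enumeration on the toy problem", {
  toy <- make_toy_problem()
  sol <- solve_min_ghge(toy$problem)
  expect_equal(sol$status, "optimal")
  # independent oracle over the three active variables
  keep <- rowSums(toy$problem$A[, 4:55] != 0) == 0
  want <- oracle_lp(toy$problem$c[1:3],
                    toy$problem$A[keep, 1:3, drop = FALSE],
                    toy$problem$lb[keep], toy$problem$ub[keep])
  expect_equal(sol$objective, want$value, tolerance = 1e-9)
  expect_equal(sol$objective, toy$oracle$objective, tolerance = 1e-12)
  # feasibility certificate
  expect_true(isTRUE(check_feasible(toy$problem, sol$x)))
})

test_that("degenerate cases: contradiction, lower-bound optimum, zero objective", {
  # contradictory box -> infeasible (bypasses syntactic screening:
  # two-row contradiction on a sum)
  pr <- mk_prob3(c(1, 1, 1),
                 list(c(1, 1, 0), c(1, 1, 0)), lb = c(5, -Inf), ub = c(Inf, 3))
  expect_equal(solve_min_ghge(pr)$status, "infeasible")
  # positive costs with a single lower bound: optimum at that bound
  pr2 <- mk_prob3(c(2, 3, 4), list(c(1, 1, 1)), lb = 10, ub = Inf)
  s2 <- solve_min_ghge(pr2)
  expect_equal(s2$objective, 20) # all mass on the cheapest variable
  expect_equal(sum(s2$x[1:3]), 10)
  # zero objective: optimum 0, any feasible point
  pr3 <- mk_prob3(c(0, 0, 0), list(c(1, 1, 1)), lb = 10, ub = 30)
  s3 <- solve_min_ghge(pr3)
  expect_equal(s3$status, "optimal")
  expect_equal(s3$objective, 0)
  expect_true(isTRUE(check_feasible(pr3, s3$x)))
  # unbounded detection
  pr4 <- mk_prob3(c(-1, 0, 0), list(c(0, 1, 0)), lb = 0, ub = 5)
  expect_equal(solve_min_ghge(pr4)$status, "unbounded")
})

test_that("solver matches the enumeration oracle on random 3-variable programs", {
  set.seed(17)
  n_checked <- 0
  for (rep in 1:40) {
    m <- sample(2:5, 1)
    rows <- lapply(seq_len(m), function(i) round(runif(3, -1, 2), 2))
    lb <- round(runif(m, 0, 5), 2)
    ub <- lb + round(runif(m, 0, 10), 2)
    # mix in one-sided rows
    drop_lb <- runif(m) < 0.3
    drop_ub <- runif(m) < 0.3 & !drop_lb
    lb[drop_lb] <- -Inf; ub[drop_ub] <- Inf
    cvec3 <- round(runif(3, 0.1, 3), 2)
    pr <- mk_prob3(cvec3, rows, lb, ub)
    sol <- solve_min_ghge(pr)
    keep <- rowSums(pr$A[, 4:55] != 0) == 0
    want <- oracle_lp(cvec3, pr$A[keep, 1:3, drop = FALSE],
                      pr$lb[keep], pr$ub[keep])
    if (is.null(want)) {
      expect_equal(sol$status, "infeasible")
    } else {
      n_checked <- n_checked + 1
      expect_equal(sol$status, "optimal")
      expect_equal(sol$objective, want$value, tolerance = 1e-9)
      expect_true(isTRUE(check_feasible(pr, sol$x)))
    }
  }
  expect_gt(n_checked, 10)
})

test_that("solver agrees with boot::simplex where available", {
  skip_if_not_installed("boot")
  set.seed(23)
  for (rep in 1:10) {
    # maximize c'x s.t. Ax <= b, x >= 0, via minimizing -c'x
    A <- matrix(round(runif(9, 0.1, 2), 2), 3)
    b <- round(runif(3, 5, 20), 2)
    cvec3 <- round(runif(3, 0.1, 3), 2)
    pr <- mk_prob3(-cvec3, lapply(1:3, function(i) A[i, ]),
                   lb = rep(-Inf, 3), ub = b)
    sol <- solve_min_ghge(pr)
    bs <- boot::simplex(a = cvec3, A1 = A, b1 = b, maxi = TRUE)
    expect_equal(-sol$objective, unname(bs$value), tolerance = 1e-7)
  }
})

test_that("optimize_nutrient removes the nutrient's own bounds and optimizes it", {
  content <- flat_content()
  content[, "iron_mg"] <- seq(0.5, 6, length.out = 55)
  pr <- mk_prob3(c(2, 3, 4), list(c(1, 1, 1)), lb = 10, ub = 30,
                 content = content)
  mx <- optimize_nutrient(pr, "iron", "max")
  # iron per g: content/100; var 3 has the largest of vars 1:3
  want <- oracle_lp(-content[1:3, "iron_mg"] / 100,
                    matrix(c(1, 1, 1), 1), 10, 30)
  expect_equal(mx$value, -want$value, tolerance = 1e-9)
  mn <- optimize_nutrient(pr, "iron", "min")
  expect_gte(mn$value, 0) # non-negative contents, no forcing lower bounds
  expect_lte(mn$value, mx$value)
  expect_error(optimize_nutrient(mk_prob3(c(1, 1, 1), list(c(1, 1, 1)), 0, 10),
                                 "iron"), "content")
})

test_that("active_constraints applies relative tolerance with absolute floor", {
  pr <- mk_prob3(c(2, 3, 4), list(c(1, 1, 1)), lb = 10, ub = 30)
  sol <- solve_min_ghge(pr)
  b <- sol$binding
  expect_true("r1" %in% b$label[b$side == "lower"]) # total at lb 10
  # variable exactly at a bound
  x <- sol$x; x["1"] <- 10; x["2"] <- 0; x["3"] <- 0
  sol2 <- sol; sol2$x <- x
  b2 <- active_constraints(sol2)
  expect_true(all(c("r1") %in% b2$label))
  # value 1e-12 above lb with tol 1e-6 is still binding-low
  x["1"] <- 10 + 1e-12
  sol3 <- sol; sol3$x <- x
  b3 <- active_constraints(sol3, tol = 1e-6)
  expect_true("r1" %in% b3$label[b3$side == "lower"])
})

test_that("iron-scarce scenario reproduces the infeasibility diagnostic", {
  art <- cached_scenario("iron_scarce", seed = 1, n_subjects = 600L,
                         n_items = 300L, n_infant_formula = 40L)
  fc <- filtered(art)
  st <- survey_stats(art$diary, fc, "F")
  pr <- build_problem(st, art$ghge, include_female_iron = TRUE)
  sol <- solve_min_ghge(pr)
  expect_equal(sol$status, "infeasible")

  rep <- diagnose_infeasibility(pr, suspects = "nutrient:iron")
  expect_true(rep$restores_feasibility[1])
  expect_lt(rep$achievable_max[1], 17)
  expect_gt(rep$gap[1], 0)

  # diagnostic consistency: re-adding the bound at <= max is feasible,
  # above it infeasible
  mx <- rep$achievable_max[1]
  clamp <- function(lo) {
    bnds <- default_bounds("F", include_disabled = TRUE)
    bnds$lb[bnds$nutrient == "iron"] <- lo
    bnds$ub[bnds$nutrient == "iron"] <- 19
    build_problem(st, art$ghge, bounds = bnds)
  }
  expect_equal(solve_min_ghge(clamp(mx - 0.05))$status, "optimal")
  expect_equal(solve_min_ghge(clamp(mx + 0.05))$status, "infeasible")

  # feasible problem yields an empty report with a note
  prF <- build_problem(st, art$ghge)
  rep0 <- diagnose_infeasibility(prF, suspects = "nutrient:calcium")
  expect_equal(nrow(rep0), 0)
  expect_match(attr(rep0, "note"), "feasible")

  # two independently violated suspects are both flagged
  bnds <- default_bounds("F", include_disabled = TRUE)
  bnds$lb[bnds$nutrient == "vitamin_b12"] <- 40
  bnds$ub[bnds$nutrient == "vitamin_b12"] <- 50
  pr2 <- build_problem(st, art$ghge, bounds = bnds)
  rep2 <- diagnose_infeasibility(pr2, suspects = c("nutrient:iron",
                                                   "nutrient:vitamin_b12"))
  expect_false(rep2$restores_feasibility[rep2$label == "nutrient:iron"])
  expect_false(rep2$restores_feasibility[rep2$label == "nutrient:vitamin_b12"])
})

test_that("relaxation monotonicity and feasible-point lower bound hold", {
  art <- small_scenario()
  fc <- filtered(art)
  st <- survey_stats(art$diary, fc, "M")
  pr <- build_problem(st, art$ghge)
  sol <- solve_min_ghge(pr)
  expect_equal(sol$status, "optimal")
  expect_true(isTRUE(check_feasible(pr, sol$x)))

  # widening any single bound never increases the optimum
  set.seed(31)
  for (i in sample(seq_along(pr$lb), 8)) {
    pr2 <- pr
    if (is.finite(pr2$lb[i])) pr2$lb[i] <- pr2$lb[i] * 0.5
    if (is.finite(pr2$ub[i])) pr2$ub[i] <- pr2$ub[i] * 1.5
    s2 <- solve_min_ghge(pr2)
    expect_equal(s2$status, "optimal")
    expect_lte(s2$objective, sol$objective + 1e-9)
  }

  # optimum is a lower bound over sampled feasible points (convex
  # combinations of the optimum and the planted diet)
  planted <- attr(art$diary, "planted_diets")$M
  expect_true(isTRUE(check_feasible(pr, planted, tol = 1e-6)))
  for (w in seq(0, 1, by = 0.1)) {
    x <- w * planted + (1 - w) * unname(sol$x)
    expect_gte(sum(pr$c * x), sol$objective - 1e-9)
  }
})
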