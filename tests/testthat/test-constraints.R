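test_that("per-day nutrient bounds become content-weighted rows", {
  b <- default_bounds("M")
  expect_equal(unlist(b[b$nutrient == "energy", c("lb", "ub")]),
               c(lb = 2400, ub = 2460))
  cons <- nutrient_constraints(b, flat_content())
  en <- cons[[which(vapply(cons, `[[`, "", "label") == "nutrient:energy")]]
  expect_equal(en$lb, 2400)
  expect_equal(en$ub, 2460)
  expect_equal(en$a, rep(2, 55)) # 200 kcal per 100 g -> 2 per g
  expect_error(nutrient_constraints(b, flat_content()[1:10, ]), "55")
  bad <- b; bad$lb[1] <- bad$ub[1] + 1
  expect_error(nutrient_constraints(bad, flat_content()), "lb")
})

test_that("percent-energy rows are exact homogeneous linearizations", {
  b <- default_bounds("M")
  cons <- nutrient_constraints(b, flat_content())
  labs <- vapply(cons, `[[`, "", "label")
  fat_lb <- cons[[which(labs == "nutrient:total_fat:%E_lb")]]
  fat_ub <- cons[[which(labs == "nutrient:total_fat:%E_ub")]]
  # single-food diet: fat share of energy is 5*9/200 = 22.5% < 24.5%
  # so the lower-bound row must be violated at ANY positive amount
  for (amt in c(1, 100, 5000)) {
    x <- rep(0, 55); x[7] <- amt
    expect_lt(sum(fat_lb$a * x), 0)
    expect_lt(sum(fat_ub$a * x), 0) # and the upper bound satisfied
  }
  # scaling invariance for random diets and every %E row
  set.seed(21)
  pe_rows <- cons[grepl(":%E_", labs)]
  for (i in 1:20) {
    x <- runif(55, 0, 100)
    lam <- runif(1, 0.01, 50)
    for (cn in pe_rows) {
      expect_equal(sign(sum(cn$a * x)), sign(sum(cn$a * (lam * x))))
    }
  }
})

test_that("hand-written coefficients match on a two-subcategory toy", {
  content <- flat_content()
  content[,] <- 0
  content["1", c("energy_kcal", "protein_g", "carb_g")] <- c(300, 10, 60)
  content["2", c("energy_kcal", "total_fat_g", "sfa_g")] <- c(900, 100, 15)
  b <- data.frame(nutrient = c("protein", "sfa"),
                  lb = c(50, NA), ub = c(90, NA), unit = "per_day")
  b$lb[2] <- 7; b$ub[2] <- 10; b$unit[2] <- "percent_energy"
  cons <- nutrient_constraints(b, content)
  # protein row: 0.10 per g for sub 1, 0 for sub 2
  expect_equal(cons[[1]]$a[1:2], c(0.10, 0))
  # sfa %E lower row: 9*sfa_per_g - 0.07*energy_per_g
  expect_equal(cons[[2]]$a[1:2],
               c(9 * 0 - 0.07 * 3, 9 * 0.15 - 0.07 * 9))
  expect_equal(cons[[3]]$a[1:2],
               c(-0.10 * 3, 9 * 0.15 - 0.10 * 9))
})

test_that("acceptability constraints reproduce the published weight-band arithmetic", {
  art <- small_scenario()
  fc <- filtered(art)
  st <- survey_stats(art$diary, fc, "M")
  # published worked examples, full precision then printed rounding
  stM <- st; stM$mean_total <- 2281
  consM <- acceptability_constraints(stM)
  expect_equal(consM[[1]]$lb, 0.8 * 2281)
  expect_equal(round(consM[[1]]$lb), 1825)
  expect_equal(round(consM[[1]]$ub), 3193)
  stF <- st; stF$mean_total <- 2088
  expect_equal(round(acceptability_constraints(stF)[[1]]$ub), 2923)

  # p5 = p90 = 0 -> fixed-at-zero box
  k0 <- which(st$p5 == 0 & st$p90 == 0)[1]
  labs <- vapply(consM, `[[`, "", "label")
  box <- consM[[which(labs == sprintf("box:%d:fixed_zero", k0))]]
  expect_equal(c(box$lb, box$ub), c(0, 0))

  # category sum rows present, incomplete stats rejected
  expect_true(any(grepl("^cat:", labs)))
  bad <- st; bad$p5 <- bad$p5[1:10]
  expect_error(acceptability_constraints(bad), "incomplete")
})

test_that("healthy constraints carry the policy bounds", {
  cons <- healthy_constraints()
  labs <- vapply(cons, `[[`, "", "label")
  get <- function(nm) cons[[which(labs == paste0("healthy:", nm))]]
  expect_equal(c(get("red_meat")$lb, get("red_meat")$ub), c(10, 30))
  expect_equal(c(get("processed_meat")$lb, get("processed_meat")$ub), c(0, 0))
  expect_equal(c(get("fruit_veg")$lb, get("fruit_veg")$ub), c(400, 500))
  expect_equal(get("pulse")$lb, 20)
  expect_equal(get("fish")$lb, 20)
  expect_true(is.infinite(get("fish")$ub))
  reg <- subcategory_registry()
  expect_equal(get("red_meat")$a, as.numeric(reg$red_meat))
  expect_error(healthy_constraints(policy = list(oddgroup = c(lb = 1, ub = 2))),
               "unknown group")
  expect_error(
    healthy_constraints(policy = list(custom = list(lb = 1, ub = 2, subcats = 99))),
    "99")
})

test_that("assemble_problem concatenates, intersects boxes and flags contradictions", {
  art <- small_scenario()
  ghge <- art$ghge
  mk_box <- function(k, lb, ub, lab = sprintf("box:%d", k), kind = "acceptability") {
    a <- numeric(55); a[k] <- 1
    ghgediet:::new_constraint(lab, kind, a, lb, ub)
  }
  # counts: 16 + 57 + 6 rows with no single-variable overlap
  l1 <- lapply(1:16, function(i) ghgediet:::new_constraint(
    paste0("n", i), "nutritional", runif(55), 0, 10))
  l2 <- c(lapply(1:55, function(k) mk_box(k, 0, 100)),
          lapply(1:2, function(i) ghgediet:::new_constraint(
            paste0("a", i), "acceptability", rep(1, 55), 0, 1e5)))
  l3 <- lapply(1:6, function(i) ghgediet:::new_constraint(
    paste0("h", i), "healthy", runif(55), 0, 50))
  pr <- assemble_problem(ghge, list(l1, l2, l3))
  expect_equal(nrow(pr$A), 79)
  expect_equal(anyDuplicated(pr$label), 0)

  # pulses-style intersection: percentile ub 36.9 with healthy lb 20
  pr2 <- assemble_problem(ghge, list(list(
    mk_box(10, 0, 36.9),
    mk_box(10, 20, Inf, lab = "healthy:pulse", kind = "healthy"))))
  i <- which(pr2$label == "box:10")
  expect_equal(c(pr2$lb[i], pr2$ub[i]), c(20, 36.9))

  # fixed zero vs policy lower bound 20: immediate infeasibility naming it
  expect_error(assemble_problem(ghge, list(list(
    mk_box(7, 0, 0),
    mk_box(7, 20, Inf, lab = "healthy:x", kind = "healthy")))),
    "subcategory 7")

  # intersection soundness: merged boxes never enlarge the feasible set
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(1:55, 1)
    b1 <- sort(runif(2, 0, 100)); b2 <- sort(runif(2, 0, 100))
    if (max(b1[1], b2[1]) > min(b1[2], b2[2])) next
    prm <- assemble_problem(ghge, list(list(
      mk_box(k, b1[1], b1[2]), mk_box(k, b2[1], b2[2], lab = "other"))))
    i <- which(prm$label == sprintf("box:%d", k))
    x <- runif(1, prm$lb[i], prm$ub[i])
    expect_true(x >= b1[1] - 1e-9 && x <= b1[2] + 1e-9)
    expect_true(x >= b2[1] - 1e-9 && x <= b2[2] + 1e-9)
  }
})

test_that("shipped defaults reproduce every published nutritional bound once", {
  art <- small_scenario()
  fc <- filtered(art)
  st <- survey_stats(art$diary, fc, "M")
  pr <- build_problem(st, art$ghge)
  per_day <- list(energy = c(2400, 2460), protein = c(60, 92),
                  cholesterol = c(250, 300), fiber = c(24, 26),
                  calcium = c(900, 1100), iron = c(9, 11), zinc = c(11, 13),
                  vitamin_b12 = c(2, 3), alcohol = c(0, 0))
  for (nm in names(per_day)) {
    i <- which(pr$label == paste0("nutrient:", nm))
    expect_length(i, 1)
    expect_equal(c(pr$lb[i], pr$ub[i]), unname(per_day[[nm]]))
  }
  for (nm in c("total_fat", "sfa", "pufa", "carbohydrate", "total_sugar",
               "free_sugar")) {
    expect_length(which(pr$label == paste0("nutrient:", nm, ":%E_lb")), 1)
    expect_length(which(pr$label == paste0("nutrient:", nm, ":%E_ub")), 1)
  }
  # female iron excluded by default, available on request
  prF <- build_problem(survey_stats(art$diary, fc, "F"), art$ghge)
  expect_length(which(prF$label == "nutrient:iron"), 0)
  prFi <- build_problem(survey_stats(art$diary, fc, "F"), art$ghge,
                        include_female_iron = TRUE)
  i <- which(prFi$label == "nutrient:iron")
  expect_equal(c(prFi$lb[i], prFi$ub[i]), c(17, 19))
})
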