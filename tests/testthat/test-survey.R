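test_that("subject_daily_intake divides by diary days and resolves items", {
  ct <- food_catalog(make_items(3, subcats = c(5, 5, 31)))
  # 300 g pasta on day 1 only, days 1..3 recorded
  d <- make_diary(1, "M", c(1, 3, 3), c(300, 50, 50), c(1, 2, 3))
  x <- subject_daily_intake(d, ct)
  expect_equal(unname(x["5"]), 100)
  expect_equal(unname(x["31"]), 100 / 3)

  # empty diary -> zero vector
  expect_equal(sum(subject_daily_intake(d[0, ], ct)), 0)

  # additivity: two same-subcategory items each day
  d2 <- make_diary(1, "F", rep(c(1, 2), 3), rep(c(50, 70), 3),
                   rep(1:3, each = 2))
  expect_equal(unname(subject_daily_intake(d2, ct)["5"]), 120)

  # unknown item errors, excluded item contributes nothing
  expect_error(subject_daily_intake(make_diary(1, "M", 99, 10, 1), ct), "99")
  items <- make_items(2, subcats = c(5, 31))
  items$flags[2] <- "infant_formula"
  fct <- suppressMessages(filter_catalog(food_catalog(items)))
  d3 <- make_diary(1, "M", c(1, 2), c(90, 500), c(1, 1))
  x3 <- subject_daily_intake(d3, fct)
  expect_equal(unname(x3["31"]), 0)
  expect_equal(unname(x3["5"]), 90)
})

test_that("population_stats matches constants, arithmetic and the percentile oracle", {
  ct <- food_catalog(make_items(1, subcats = 5))
  diary <- do.call(rbind, lapply(1:100, function(i) {
    make_diary(i, "M", 1, i, 1) # subject i eats i grams on one day
  }))
  ints <- compute_subject_intakes(diary, ct)
  st <- population_stats(ints, "M")
  expect_equal(unname(st$mean["5"]), 50.5)
  expect_equal(unname(st$p5["5"]), oracle_quantile_t2(1:100, 0.05))
  expect_equal(unname(st$p90["5"]), oracle_quantile_t2(1:100, 0.90))

  # constant population: mean = p5 = p90
  diary_c <- do.call(rbind, lapply(1:20, function(i) make_diary(i, "F", 1, 100, 1)))
  stc <- population_stats(compute_subject_intakes(diary_c, ct), "F")
  expect_equal(unname(c(stc$mean["5"], stc$p5["5"], stc$p90["5"])), rep(100, 3))

  expect_error(population_stats(ints, "F"), "no subjects")

  # oracle agreement on random zero-inflated data
  set.seed(3)
  vals <- ifelse(runif(60) < 0.4, 0, rlnorm(60, 3, 1))
  diary_r <- do.call(rbind, lapply(seq_along(vals), function(i) {
    make_diary(i, "M", 1, vals[i], 1)
  }))
  diary_r <- diary_r[diary_r$amount_g > 0 | seq_len(nrow(diary_r)) %% 2 == 0, ]
  str <- population_stats(compute_subject_intakes(diary_r, ct), "M")
  sub_means <- compute_subject_intakes(diary_r, ct)$intake[, "5"]
  expect_equal(unname(str$p5["5"]), oracle_quantile_t2(sub_means, 0.05))
  expect_equal(unname(str$p90["5"]), oracle_quantile_t2(sub_means, 0.90))
  expect_true(all(str$p5 <= str$p90))
})

test_that("statistics are invariant to subject order and the other sex", {
  art <- small_scenario()
  fc <- filtered(art)
  st <- survey_stats(art$diary, fc, "M")
  # permute subject blocks
  perm <- art$diary[order(-art$diary$subject_id, art$diary$day), ]
  stp <- survey_stats(perm, fc, "M")
  expect_equal(stp$mean, st$mean)
  expect_equal(stp$p5, st$p5)
  expect_equal(stp$p90, st$p90)
  # add a subject of the other sex: male stats unchanged
  extra <- make_diary(99999, "F", fc$items$item_id[1], 123, 1)
  ste <- survey_stats(rbind(art$diary, extra), fc, "M")
  expect_equal(ste$mean, st$mean)
  expect_equal(ste$mean_total, st$mean_total)
})

test_that("weighted_nutrient_content weights by consumed amounts", {
  items <- make_items(2, subcats = c(21, 21))
  items$iron_mg <- c(10, 0)
  ct <- food_catalog(items)
  # equal amounts -> midpoint
  d <- rbind(make_diary(1, "M", 1, 100, 1), make_diary(2, "M", 2, 100, 1))
  w <- suppressWarnings(weighted_nutrient_content(d, ct, "M"))
  expect_equal(unname(w["21", "iron_mg"]), 5)
  # unequal 300 vs 100 -> 7.5
  d2 <- rbind(make_diary(1, "M", 1, 300, 1), make_diary(2, "M", 2, 100, 1))
  w2 <- suppressWarnings(weighted_nutrient_content(d2, ct, "M"))
  expect_equal(unname(w2["21", "iron_mg"]), 7.5)
  # single-item subcategory -> that composition
  ct1 <- food_catalog(make_items(1, subcats = 34))
  d3 <- make_diary(1, "F", 1, 50, 1)
  w3 <- suppressWarnings(weighted_nutrient_content(d3, ct1, "F"))
  expect_equal(unname(w3["34", "protein_g"]), 8)
  # never-consumed subcategory falls back to unweighted mean with warning
  expect_warning(weighted_nutrient_content(d3[0, ], ct1, "F"), "unweighted")
})

test_that("weighted content lies in the item envelope per nutrient", {
  art <- small_scenario()
  fc <- filtered(art)
  content <- suppressWarnings(weighted_nutrient_content(art$diary, fc, "F"))
  comp <- as.matrix(fc$items[, nutrient_names()])
  for (k in unique(fc$items$subcategory_id)) {
    idx <- fc$items$subcategory_id == k
    lo <- apply(comp[idx, , drop = FALSE], 2, min)
    hi <- apply(comp[idx, , drop = FALSE], 2, max)
    expect_true(all(content[k, ] >= lo - 1e-9 & content[k, ] <= hi + 1e-9))
  }
})

test_that("observed_summary matches an item-level brute-force oracle", {
  # zero diet
  art <- small_scenario()
  fc <- filtered(art)
  st <- survey_stats(art$diary, fc, "M")
  st0 <- st; st0$mean <- stats::setNames(numeric(55), as.character(1:55))
  s0 <- observed_summary(st0, art$ghge)
  expect_equal(sum(s0$nutrients), 0)
  expect_equal(s0$ghge, 0)

  # one subcategory, 100 g/day, known iron content
  st1 <- st0
  st1$mean["21"] <- 100
  st1$content[,] <- 0
  st1$content["21", "iron_mg"] <- 2
  expect_equal(unname(observed_summary(st1, art$ghge)$nutrients["iron_mg"]), 2)

  # small fixture: totals equal per-item summation
  ct <- food_catalog(make_items(4, subcats = c(5, 5, 21, 31)))
  diary <- rbind(
    make_diary(1, "M", c(1, 3), c(120, 60), c(1, 1)),
    make_diary(1, "M", c(2, 4), c(80, 200), c(2, 2)),
    make_diary(2, "M", c(1, 4), c(150, 100), c(1, 2)))
  gp <- list(points = data.frame(indicator_id = 1:3,
                                 value_kgco2e_per_kg = c(1, 12, 1.3),
                                 national_reliable = FALSE, source = "s"),
             mapping = data.frame(indicator_id = 1:3,
                                  subcategory_id = c(5, 21, 31)))
  tab <- build_ghge_table(gp$points, gp$mapping)
  # complete to 55 for coefficient lookup
  full <- data.frame(subcategory_id = 1:55, c_kgco2e_per_g = 1e-3, lo = 0,
                     hi = 1, rule = "pm50", n_points = 1, indicator_ids = "")
  full$c_kgco2e_per_g[tab$subcategory_id] <- tab$c_kgco2e_per_g
  class(full) <- c("ghge_table", "data.frame")
  stx <- survey_stats(diary, ct, "M")
  got <- observed_summary(stx, full)
  want <- oracle_mean_diet_nutrients(diary, ct, "M")
  expect_equal(got$nutrients, want, tolerance = 1e-12)

  # aggregation linearity: summary of summed diets = sum of summaries
  stA <- stx; stB <- stx
  set.seed(1); stB$mean <- stats::setNames(runif(55, 0, 50), as.character(1:55))
  stAB <- stx; stAB$mean <- stA$mean + stB$mean
  sA <- observed_summary(stA, full); sB <- observed_summary(stB, full)
  sAB <- observed_summary(stAB, full)
  expect_equal(sAB$nutrients, sA$nutrients + sB$nutrients)
  expect_equal(sAB$ghge, sA$ghge + sB$ghge)
})
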