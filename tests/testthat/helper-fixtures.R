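# Shared fixtures: in-code catalog builders and memoized scenario
# artifacts so expensive generations run once per test session.

# minimal item table with valid compositions; flags via tokens
make_items <- function(n = 3, subcats = NULL) {
  if (is.null(subcats)) subcats <- rep(1L, n)
  reg <- subcategory_registry()
  data.frame(
    item_id = seq_len(n),
    name = paste("item", seq_len(n)),
    category_id = reg$category_id[match(subcats, reg$subcategory_id)],
    subcategory_id = subcats,
    energy_kcal = 200, protein_g = 8, fat_g = 5, sfa_g = 2, pufa_g = 1,
    carb_g = 30, sugar_g = 5, cholesterol_mg = 10, fiber_g = 2,
    calcium_mg = 50, iron_mg = 1.5, zinc_mg = 1, vitb12_ug = 0.2,
    alcohol_g = 0, flags = "")
}

# one-subject diary builder
make_diary <- function(subject_id, sex, item_id, amount_g, day,
                       age = 30) {
  data.frame(subject_id = subject_id, sex = sex, age = age, day = day,
              item_id = item_id, amount_g = amount_g)
}

# memoized scenario artifacts (shared across test files)
.scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(name, seed = 1, ...) {
  extra <- list(...)
  key <- paste(name, seed, paste(names(extra), unlist(extra), collapse = "_"),
               sep = "_")
  if (is.null(.scenario_cache[[key]])) {
    sc <- do.call(diet_scenario, c(list(name = name, seed = seed), extra))
    .scenario_cache[[key]] <- generate_scenario(sc)
  }
  .scenario_cache[[key]]
}

# small but structurally complete scenario for fast tests
small_scenario <- function(name = "default_feasible", seed = 1) {
  cached_scenario(name, seed, n_subjects = 300L, n_items = 200L,
                  n_infant_formula = 30L)
}

filtered <- function(art) suppressMessages(filter_catalog(art$catalog))

# uniform content matrix helper: every subcategory identical
flat_content <- function() {
  m <- matrix(0, 55, length(nutrient_names()),
              dimnames = list(as.character(1:55), nutrient_names()))
  m[, "energy_kcal"] <- 200
  m[, "protein_g"] <- 8
  m[, "total_fat_g"] <- 5
  m[, "sfa_g"] <- 2
  m[, "pufa_g"] <- 1
  m[, "carb_g"] <- 30
  m[, "intrinsic_sugar_g"] <- 5
  m[, "fiber_g"] <- 2
  m[, "iron_mg"] <- 1.5
  m
}

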