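# Canonical food-group taxonomy: 15 categories partitioned into 55
# subcategories, with policy-relevant class flags assigned at the
# subcategory level (red meat, processed meat, alcoholic beverages,
# fruit & vegetables, pulses, fish, free-sugar foods).

#' Nutrient column names used throughout the package
#'
#' All compositions are stored per 100 g edible portion:
#' energy (kcal), protein/fat/SFA/PUFA/carbohydrate/free sugar/
#' intrinsic sugar/fiber/alcohol (g), cholesterol/calcium/iron/zinc (mg),
#' vitamin B12 (ug).
#'
#' @return Character vector of the 15 nutrient column names.
#' @export
nutrient_names <- function() {
  c("energy_kcal", "protein_g", "total_fat_g", "sfa_g", "pufa_g",
    "carb_g", "free_sugar_g", "intrinsic_sugar_g", "cholesterol_mg",
    "fiber_g", "calcium_mg", "iron_mg", "zinc_mg", "vitb12_ug",
    "alcohol_g")
}

#' Registry of the 15 food categories and 55 subcategories
#'
#' Returns the fixed taxonomy used by every module: each subcategory
#' maps to exactly one category, and carries the boolean class flags
#' that drive sugar classification and the healthy (policy) constraints.
#'
#' Class membership follows standard food-based dietary guideline usage:
#' red meat is beef/veal, pork and other mammalian meats (horse, lamb,
#' goat); processed meat is its own subcategory; fruit & vegetables
#' exclude pulses, potatoes and fruit juices; free-sugar subcategories
#' are those whose sugars are added or from honey/syrups/juices
#' (biscuits, cakes, sweet drinks, preserved fruit, ...), while sugars
#' in fresh fruit, vegetables, milk and plain yogurt are intrinsic.
#'
#' @return A data.frame with one row per subcategory: `subcategory_id`
#'   (1--55), `subcategory`, `category_id` (1--15), `category`, and
#'   logical flag columns `red_meat`, `processed_meat`, `alcoholic`,
#'   `fruit_veg`, `pulse`, `fish`, `free_sugar_class`.
#' @export
subcategory_registry <- function() {
  cats <- c(
    "Cereals, cereal products, and substitutes", "Pulses", "Vegetables",
    "Potatoes and tapioca", "Fruit", "Meat, meat products, and substitutes",
    "Fish and seafood", "Milk, milk products, and their substitutes",
    "Oils and fats", "Sweet products and substitutes", "Meal substitute",
    "Eggs", "Non-alcoholic beverages", "Miscellaneous",
    "Alcoholic beverages")
  sub_names <- c(
    "Bread and flour", "Pizza", "Breakfast cereals",
    "Pasta with eggs, filled", "Pasta, pasta substitute and flour",
    "Rice", "Biscuits", "Cakes and sweet snacks",
    "Savory fine bakery products",
    "Pulses, fresh or processed",
    "Leafy, fruiting and other vegetables, fresh",
    "Roots and onions, fresh", "Vegetables, processed",
    "Spices and herbs",
    "Potatoes and potato-based dishes, excl. crisps", "Potato crisps",
    "Citrus and stone fruits, fresh", "Exotic fruits",
    "Nuts, seeds, dried fruit, olives", "Fruit, canned",
    "Beef and veal, not preserved", "Pork, not preserved",
    "Poultry and game, not preserved", "Processed meat",
    "Other meats, not preserved", "Meat substitute",
    "Offals, blood, and their products",
    "Crustaceans, shellfish, mussels", "Fish, fresh", "Fish, preserved",
    "Milk, milk-based beverages", "Yogurt and fermented milk",
    "Milk-based dessert and substitute", "Cheese and substitutes",
    "Olive oil", "Other vegetable oil", "Butter, creams", "Other fats",
    "Ice cream and substitutes", "Chocolate and substitutes",
    "Sugar, fructose, honey, nutritive sweeteners",
    "Candies, jam, and other sweet products",
    "Cacao and cacao-based powder", "Artificial sweeteners",
    "Meal substitute", "Eggs",
    "Tap water", "Mineral water",
    "Herbal tea, tea, coffee, and substitutes",
    "Fruit and vegetable juices", "Other soft drinks",
    "Miscellaneous",
    "Regular wine and substitute",
    "Sweet wine, spumante, liquor", "Beer, cider, and substitute")
  cat_of_sub <- c(rep(1L, 9), 2L, rep(3L, 4), rep(4L, 2), rep(5L, 4),
                  rep(6L, 7), rep(7L, 3), rep(8L, 4), rep(9L, 4),
                  rep(10L, 6), 11L, 12L, rep(13L, 5), 14L, rep(15L, 3))
  stopifnot(length(sub_names) == 55L, length(cat_of_sub) == 55L)
  reg <- data.frame(
    subcategory_id = 1:55,
    subcategory = sub_names,
    category_id = cat_of_sub,
    category = cats[cat_of_sub],
    stringsAsFactors = FALSE)
  flag <- function(ids) reg$subcategory_id %in% ids
  reg$red_meat <- flag(c(21, 22, 25))
  reg$processed_meat <- flag(24)
  reg$alcoholic <- flag(53:55)
  reg$fruit_veg <- flag(c(11:14, 17:20))
  reg$pulse <- flag(10)
  reg$fish <- flag(28:30)
  reg$free_sugar_class <- flag(c(7, 8, 20, 33, 39, 40, 41, 42, 50, 51, 53, 54, 55))
  reg
}

#' Category label registry
#'
#' @return data.frame with `category_id` and `category` (15 rows).
#' @export
category_registry <- function() {
  reg <- subcategory_registry()
  unique(reg[, c("category_id", "category")])
}
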