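# Food catalog: item-level food database with nutrient compositions per
# 100 g edible portion plus classification flags. The catalog CSV schema
# carries total sugar; the free/intrinsic split is derived at load time
# from the subcategory-level free-sugar flag.

.catalog_csv_cols <- c(
  "item_id", "name", "category_id", "subcategory_id", "energy_kcal",
  "protein_g", "fat_g", "sfa_g", "pufa_g", "carb_g", "sugar_g",
  "cholesterol_mg", "fiber_g", "calcium_mg", "iron_mg", "zinc_mg",
  "vitb12_ug", "alcohol_g", "flags")

.flag_tokens <- c("red_meat", "processed_meat", "alcoholic", "fruit_veg",
                  "pulse", "fish", "infant_formula", "supplement",
                  "free_sugar_class")

.item_numeric_cols <- c(
  "energy_kcal", "protein_g", "fat_g", "sfa_g", "pufa_g", "carb_g",
  "sugar_g", "cholesterol_mg", "fiber_g", "calcium_mg", "iron_mg",
  "zinc_mg", "vitb12_ug", "alcohol_g")

#' Construct a food catalog
#'
#' Validates an item table against the fixed 55-subcategory registry and
#' derives the free/intrinsic sugar partition for each item.
#'
#' @param items data.frame with the catalog columns (see
#'   [load_catalog()]); flag columns may be given as logicals or via a
#'   `flags` character column of semicolon-separated tokens.
#' @param registry subcategory registry, defaults to
#'   [subcategory_registry()].
#' @return An object of class `food_catalog`: a list with `items`
#'   (validated data.frame, one row per food) and `registry`.
#' @export
food_catalog <- function(items, registry = subcategory_registry()) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  if ("flags" %in% names(items) && !all(.flag_tokens %in% names(items))) {
    toks <- strsplit(ifelse(is.na(items$flags), "", items$flags), ";", fixed = TRUE)
    for (f in .flag_tokens) {
      items[[f]] <- vapply(toks, function(t) f %in% trimws(t), logical(1))
    }
  }
  for (f in .flag_tokens) {
    if (is.null(items[[f]])) items[[f]] <- FALSE
    items[[f]] <- as.logical(items[[f]])
  }
  need <- setdiff(.catalog_csv_cols, "flags")
  miss <- setdiff(need, names(items))
  if (length(miss)) {
    stop("catalog schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  for (col in .item_numeric_cols) {
    v <- items[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("catalog schema error: non-numeric '", col, "' in row ", bad[1])
      }
      items[[col]] <- vn
    }
  }
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup)) {
    stop("catalog schema error: duplicate item_id ", dup[1], " in row ",
         which(items$item_id == dup[1])[2])
  }
  neg <- which(apply(items[.item_numeric_cols] < 0, 1, any))
  if (length(neg)) {
    stop("catalog validation error: negative composition value in row ", neg[1],
         " (item_id ", items$item_id[neg[1]], ")")
  }
  eps <- 1e-6
  bad <- which(items$sfa_g + items$pufa_g > items$fat_g + eps)
  if (length(bad)) {
    stop("catalog validation error: sfa + pufa > total fat in row ", bad[1])
  }
  bad <- which(items$sugar_g > items$carb_g + eps)
  if (length(bad)) {
    stop("catalog validation error: sugar > carbohydrate in row ", bad[1])
  }
  bad <- which(!(items$subcategory_id %in% registry$subcategory_id))
  if (length(bad)) {
    stop("catalog validation error: unknown subcategory_id ",
         items$subcategory_id[bad[1]], " in row ", bad[1])
  }
  cat_map <- registry$category_id[match(items$subcategory_id, registry$subcategory_id)]
  bad <- which(items$category_id != cat_map)
  if (length(bad)) {
    stop("catalog validation error: subcategory ", items$subcategory_id[bad[1]],
         " does not belong to category ", items$category_id[bad[1]],
         " in row ", bad[1])
  }
  bad <- which(items$red_meat & items$fruit_veg)
  if (length(bad)) {
    stop("catalog validation error: item flagged both red_meat and fruit_veg in row ",
         bad[1])
  }
  sug <- classify_sugars(items$sugar_g,
                         free_sugar_class = items$free_sugar_class)
  items$free_sugar_g <- sug$free_sugar_g
  items$intrinsic_sugar_g <- sug$intrinsic_sugar_g
  items$total_fat_g <- items$fat_g
  structure(list(items = items, registry = registry), class = "food_catalog")
}

#' @export
print.food_catalog <- function(x, ...) {
  cat("<food_catalog> ", nrow(x$items), " items over ",
      length(unique(x$items$subcategory_id)), " subcategories\n", sep = "")
  invisible(x)
}

#' Load a food catalog from CSV
#'
#' Expected columns: `item_id,name,category_id,subcategory_id,
#' energy_kcal,protein_g,fat_g,sfa_g,pufa_g,carb_g,sugar_g,
#' cholesterol_mg,fiber_g,calcium_mg,iron_mg,zinc_mg,vitb12_ug,
#' alcohol_g,flags`, where `flags` holds semicolon-separated tokens
#' among `red_meat;processed_meat;alcoholic;fruit_veg;pulse;fish;
#' infant_formula;supplement;free_sugar_class`.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return A [food_catalog()].
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- data.table::fread(path, colClasses = list(character = c("name", "flags")),
                          data.table = FALSE, na.strings = NULL)
  miss <- setdiff(.catalog_csv_cols, names(df))
  if (length(miss)) {
    stop("catalog schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  food_catalog(df)
}

#' Write a food catalog to CSV
#'
#' Numeric columns are written with round-trip precision so that
#' `load_catalog(write_catalog(x, f))` reproduces them bit-equal.
#'
#' @param catalog a `food_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "food_catalog"))
  it <- catalog$items
  flags <- apply(as.matrix(it[.flag_tokens]), 1,
                 function(r) paste(.flag_tokens[as.logical(r)], collapse = ";"))
  out <- it[, setdiff(.catalog_csv_cols, "flags")]
  out$flags <- flags
  for (col in .item_numeric_cols) out[[col]] <- .format_roundtrip(out[[col]])
  data.table::fwrite(out, path)
  invisible(path)
}

#' Drop infant-formula and supplement items
#'
#' Restricts the catalog to ordinary foods: items flagged
#' `infant_formula` or `supplement` are excluded from analysis (infant
#' products are irrelevant for an adult population and emission values
#' for supplements are inconsistent). Original item order is preserved;
#' the excluded item ids are kept as an attribute so diary records that
#' reference them are silently zeroed rather than treated as unknown.
#'
#' @param catalog a `food_catalog`.
#' @return The filtered `food_catalog`, with attributes
#'   `excluded_items` (ids) and `filter_counts` (retained/excluded).
#' @export
filter_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "food_catalog"))
  drop <- catalog$items$infant_formula | catalog$items$supplement
  out <- catalog
  out$items <- catalog$items[!drop, , drop = FALSE]
  rownames(out$items) <- NULL
  attr(out, "excluded_items") <- catalog$items$item_id[drop]
  attr(out, "filter_counts") <- c(retained = sum(!drop), excluded = sum(drop))
  message("filter_catalog: retained ", sum(!drop), " items, excluded ", sum(drop))
  if (!nrow(out$items)) warning("filter_catalog: no items retained")
  out
}

#' Partition total sugar into free and intrinsic sugar
#'
#' Items in a free-sugar class (biscuits, cakes, sweet snacks,
#' milk-based desserts, sweetened drinks, juices, preserved fruit,
#' honey/sugar, alcoholic beverages) have all their sugar counted as
#' free; sugars of fresh fruit and vegetables and of milk and plain
#' yogurt -- and by default of any other unflagged food -- are counted
#' as intrinsic. The partition always sums exactly to the total.
#'
#' @param total_sugar numeric vector, g/100 g, non-negative.
#' @param free_sugar_class logical vector (recycled).
#' @param ... ignored; accepts further flag columns for convenience.
#' @return data.frame with `free_sugar_g` and `intrinsic_sugar_g`.
#' @export
classify_sugars <- function(total_sugar, free_sugar_class = FALSE, ...) {
  if (any(is.na(total_sugar)) || any(total_sugar < 0)) {
    stop("classify_sugars: total_sugar must be non-negative")
  }
  free_sugar_class <- rep_len(as.logical(free_sugar_class), length(total_sugar))
  data.frame(
    free_sugar_g = ifelse(free_sugar_class, total_sugar, 0),
    intrinsic_sugar_g = ifelse(free_sugar_class, 0, total_sugar))
}

# Per-100g composition matrix of the items, in nutrient_names() order.
item_composition <- function(catalog) {
  it <- catalog$items
  m <- as.matrix(it[, nutrient_names()])
  rownames(m) <- it$item_id
  m
}

# shortest decimal representation that parses back bit-equal
.format_roundtrip <- function(v) {
  vapply(v, function(x) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, x)
      if (as.numeric(s) == x) return(s)
    }
    sprintf("%.17g", x)
  }, character(1))
}
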