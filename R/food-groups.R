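#' Default food-grouping configuration
#'
#' The 18 food groups of the plant-based diet-index scoring scheme: 7
#' healthy-plant, 5 unhealthy-plant and 6 animal groups, in the canonical
#' order used throughout the package (coding-vector bit strings and
#' enumeration order depend on it).
#'
#' Each group carries a `components` list-column naming the intake columns
#' of a cohort table that sum to the group's intake. By default every group
#' is its own single component; recategorization variants redefine
#' components (e.g. merging the potato items into vegetables).
#'
#' @param item_map Optional tibble with columns `item` and `group` mapping
#'   food-item names to group names, used by [map_items_to_groups()].
#' @return A tibble with columns `group`, `super_category`
#'   (`"healthy_plant"`, `"unhealthy_plant"` or `"animal"`) and
#'   `components` (list of character vectors), plus an `item_map` attribute.
#' @export
#' @examples
#' food_groups()
food_groups <- function(item_map = NULL) {
  healthy <- c(
    "whole_grains", "fruits", "vegetables", "nuts", "legumes",
    "vegetable_oils", "tea_coffee"
  )
  unhealthy <- c(
    "fruit_juices", "refined_grains", "potatoes",
    "sugar_sweetened_beverages", "sweets_desserts"
  )
  animal <- c(
    "animal_fat", "dairy", "eggs", "fish_seafood", "meat",
    "misc_animal_foods"
  )
  out <- tibble::tibble(
    group = c(healthy, unhealthy, animal),
    super_category = rep(
      c("healthy_plant", "unhealthy_plant", "animal"),
      c(length(healthy), length(unhealthy), length(animal))
    ),
    components = as.list(c(healthy, unhealthy, animal))
  )
  attr(out, "item_map") <- item_map
  out
}

#' Items composing the potatoes food group
#'
#' The potatoes group is the sum of these four item-level intake columns;
#' recategorization models 4 and 5 split white potato away from the rest.
#'
#' @return Character vector of item column names.
#' @export
potato_items <- function() {
  c("white_potato", "french_fries", "salty_snacks", "low_fat_salty_snacks")
}

#' Plant food groups of a grouping configuration
#'
#' @param grouping A grouping tibble as returned by [food_groups()].
#' @return Character vector of plant (healthy + unhealthy) group names in
#'   configuration order.
#' @export
plant_groups <- function(grouping = food_groups()) {
  grouping$group[grouping$super_category != "animal"]
}

validate_grouping <- function(grouping) {
  stopifnot(is.data.frame(grouping))
  need <- c("group", "super_category", "components")
  if (!all(need %in% names(grouping))) {
    stop("grouping must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(grouping$group)) {
    stop("duplicated group names in grouping", call. = FALSE)
  }
  bad <- setdiff(
    unique(grouping$super_category),
    c("healthy_plant", "unhealthy_plant", "animal")
  )
  if (length(bad)) {
    stop("unknown super_category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(grouping)
}

#' Coding vector for a named diet index
#'
#' Scoring direction per food group. `"positive"` assigns quintile score 1
#' (lowest intake) to 5 (highest); `"reverse"` assigns 6 minus the positive
#' score. PDI scores all plant groups positively; hPDI only the
#' healthy-plant groups; uPDI only the unhealthy-plant groups. Animal groups
#' are reversely scored in all three.
#'
#' @param index One of `"pdi"`, `"hpdi"`, `"updi"`.
#' @param grouping A grouping tibble as returned by [food_groups()].
#' @return A tibble with columns `group` and `direction`
#'   (`"positive"`/`"reverse"`), with a `label` attribute.
#' @export
#' @examples
#' index_coding("hpdi")
index_coding <- function(index = c("pdi", "hpdi", "updi"),
                         grouping = food_groups()) {
  index <- match.arg(index)
  validate_grouping(grouping)
  sc <- grouping$super_category
  direction <- switch(index,
    pdi  = ifelse(sc == "animal", "reverse", "positive"),
    hpdi = ifelse(sc == "healthy_plant", "positive", "reverse"),
    updi = ifelse(sc == "unhealthy_plant", "positive", "reverse")
  )
  coding <- tibble::tibble(group = grouping$group, direction = direction)
  attr(coding, "label") <- index
  coding
}

validate_coding <- function(coding, grouping) {
  if (!setequal(coding$group, grouping$group) ||
      anyDuplicated(coding$group)) {
    stop("coding must cover every group in the grouping exactly once",
         call. = FALSE)
  }
  if (!all(coding$direction %in% c("positive", "reverse"))) {
    stop("coding direction must be 'positive' or 'reverse'", call. = FALSE)
  }
  invisible(coding)
}

#' Map item-level intakes to food-group intakes
#'
#' Sums food-item intakes into the groups given by the configuration's item
#' map. Items with no group assignment are excluded and logged (mirroring
#' FFQ items that fit no group), available via the `"unmatched"` attribute.
#'
#' @param items A tibble in long format with columns `id`, `item` and
#'   `servings` (servings/day).
#' @param config A grouping tibble from [food_groups()] whose `item_map`
#'   attribute maps `item` to `group`.
#' @return A wide tibble, one row per `id`, one column per matched group
#'   (sum of member items; 0 where a participant reported none of a matched
#'   group's items), with attribute `"unmatched"`: a tibble of excluded
#'   item names and their row counts.
#' @export
map_items_to_groups <- function(items, config) {
  if (!is.data.frame(items) || nrow(items) == 0) {
    stop("items table is empty", call. = FALSE)
  }
  stopifnot(all(c("id", "item", "servings") %in% names(items)))
  item_map <- attr(config, "item_map")
  if (is.null(item_map)) {
    stop("config carries no item_map; supply one via food_groups(item_map=)",
         call. = FALSE)
  }
  if (anyDuplicated(item_map$item)) {
    stop("item_map assigns some item to more than one group", call. = FALSE)
  }
  joined <- dplyr::left_join(items, item_map, by = "item")
  unmatched <- joined |>
    dplyr::filter(is.na(.data$group)) |>
    dplyr::count(.data$item, name = "n_rows")
  wide <- joined |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$id, .data$group) |>
    dplyr::summarise(servings = sum(.data$servings), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "group", values_from = "servings", values_fill = 0
    )
  attr(wide, "unmatched") <- unmatched
  wide
}
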