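#' Frequency-category vocabularies
#'
#' Food items are recorded in nine ordered consumption-frequency categories;
#' the daily-meal-frequency item uses its own five categories. These closed
#' vocabularies are the only values accepted by the scoring functions.
#'
#' @return Character vector of category labels, in increasing frequency order
#'   for food items.
#' @export
ffq_food_categories <- function() {
  c("never or seldom",
    "once a month",
    "one to two times a week",
    "two to three times a week",
    "three to four times a week",
    "five to six times a week",
    "once daily",
    "twice daily",
    "more than three times daily")
}

#' @rdname ffq_food_categories
#' @export
ffq_meal_categories <- function() {
  c("one meal a day",
    "two meals a day",
    "three meals a day",
    "more than four meals a day",
    "irregular")
}

# group -> number of scored items; the 46-point budget of the score
.rfs_group_points <- c(
  meals = 1L, grains = 1L, legumes = 4L, vegetables = 16L, seaweeds = 2L,
  fruits_juices = 12L, fish = 5L, dairy = 3L, nuts = 1L, tea = 1L
)

#' Construct a food panel
#'
#' A food panel is the ordered list of scored items together with the food
#' group each belongs to. The Recommended Food Score awards at most one point
#' per item, so the per-group point totals equal the group item counts:
#' daily meal frequency 1, grains 1, legumes 4, vegetables 16, seaweeds 2,
#' fruits/juices 12, fish 5, dairy 3, nuts 1, tea 1 -- 46 points in all.
#'
#' @param items Character vector of unique item identifiers.
#' @param groups Character vector (same length) giving each item's group;
#'   with `validate_points = TRUE` these must be the ten canonical group
#'   names with the canonical per-group item counts.
#' @param validate_points Enforce the canonical 46-point allocation?
#'   Disable for reduced custom groupings (e.g. methodological
#'   experiments with a subset panel); the component model and scorers
#'   accept any grouping, but only the canonical panel carries the
#'   46-point interpretation.
#' @return An object of class `food_panel`: a data.frame with columns
#'   `item` and `group` (in scoring column order), plus a `group_points`
#'   attribute.
#' @examples
#' panel <- default_food_panel()
#' nrow(panel)            # 46
#' table(panel$group)
#' @export
food_panel <- function(items, groups, validate_points = TRUE) {
  items <- as.character(items)
  groups <- as.character(groups)
  if (length(items) != length(groups))
    stop("`items` and `groups` must have the same length")
  if (anyDuplicated(items))
    stop("duplicated item identifiers: ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  if (validate_points) {
    unknown <- setdiff(unique(groups), names(.rfs_group_points))
    if (length(unknown))
      stop("unknown food group(s): ", paste(unknown, collapse = ", "))
    counts <- table(factor(groups, levels = names(.rfs_group_points)))
    bad <- names(counts)[counts != .rfs_group_points]
    if (length(bad))
      stop("group item counts must match the point allocation; mismatched: ",
           paste(bad, collapse = ", "))
  }
  panel <- data.frame(item = items, group = groups, stringsAsFactors = FALSE)
  attr(panel, "group_points") <-
    if (validate_points) .rfs_group_points else table(groups)
  class(panel) <- c("food_panel", "data.frame")
  panel
}

#' @rdname food_panel
#' @details `default_food_panel()` returns a schema-level 46-item template
#'   with generic item names (`vegetables_01`, ...) and the canonical group
#'   sizes; studies with named food lists supply their own items.
#' @export
default_food_panel <- function() {
  groups <- rep(names(.rfs_group_points), times = .rfs_group_points)
  n_in_group <- unlist(lapply(.rfs_group_points, seq_len), use.names = FALSE)
  items <- ifelse(.rfs_group_points[groups] == 1L, groups,
                  sprintf("%s_%02d", groups, n_in_group))
  food_panel(items, groups)
}

#' @rdname food_panel
#' @param x Object to test or validate.
#' @export
is_food_panel <- function(x) inherits(x, "food_panel")

# split panel row indices by group, preserving order of first appearance
# (canonical order for the default panel)
panel_group_index <- function(panel) {
  split(seq_len(nrow(panel)),
        factor(panel$group, levels = unique(panel$group)))
}
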