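#' Binary item indicator from a frequency category
#'
#' A food item earns its point when consumed at least once a week, i.e. at
#' category "one to two times a week" or any more frequent category (the
#' nine-level scale has no plain "once a week" level, so that category is the
#' cut). The daily-meal-frequency item earns its point only for the regular
#' eating pattern "three meals a day".
#'
#' @param category Character vector of frequency categories.
#' @param item_kind `"food"` or `"meals"`.
#' @return Integer vector of 0/1 indicators.
#' @examples
#' item_indicator("once a month", "food")             # 0
#' item_indicator("one to two times a week", "food")  # 1
#' item_indicator("three meals a day", "meals")       # 1
#' @export
item_indicator <- function(category, item_kind = c("food", "meals")) {
  item_kind <- match.arg(item_kind)
  vocab <- if (item_kind == "food") ffq_food_categories() else
    ffq_meal_categories()
  idx <- match(category, vocab)
  if (anyNA(idx))
    stop("unknown ", item_kind, " frequency category: ",
         paste(unique(category[is.na(idx)]), collapse = ", "))
  if (item_kind == "food") {
    as.integer(idx >= match("one to two times a week", vocab))
  } else {
    as.integer(category == "three meals a day")
  }
}

# pull the per-item category columns for a panel out of an FFQ response table,
# erroring on structural problems rather than imputing
.ffq_category_matrix <- function(responses, panel) {
  stopifnot(is_food_panel(panel))
  if (!is.data.frame(responses))
    stop("`responses` must be a data.frame of FFQ categories")
  missing_items <- setdiff(panel$item, names(responses))
  if (length(missing_items))
    stop("FFQ response is missing scored item(s): ",
         paste(missing_items, collapse = ", "))
  if ("subject_id" %in% names(responses) &&
      anyDuplicated(responses$subject_id))
    stop("duplicated subject ids in FFQ responses")
  for (it in panel$item)
    if (anyNA(responses[[it]]))
      stop("missing frequency category for item: ", it)
  responses[panel$item]
}

#' Binary item-indicator matrix
#'
#' Expands FFQ responses into the n x 46 binary matrix of item indicators
#' (column order = panel order) that feeds the unweighted RFS, the HisCoM
#' fit and the PLS-DA fit. Row sums equal [compute_rfs()].
#'
#' @param responses A data.frame with one row per subject: an optional
#'   `subject_id` column plus one frequency-category column per panel item.
#' @param panel A [food_panel()].
#' @return Integer matrix (n x number of items) with items as column names;
#'   row names are subject ids when present.
#' @export
indicator_matrix <- function(responses, panel = default_food_panel()) {
  cats <- .ffq_category_matrix(responses, panel)
  n <- nrow(cats)
  g <- matrix(0L, nrow = n, ncol = nrow(panel),
              dimnames = list(
                if ("subject_id" %in% names(responses))
                  as.character(responses$subject_id) else NULL,
                panel$item))
  if (n == 0L) return(g)
  kinds <- ifelse(panel$group == "meals", "meals", "food")
  for (j in seq_len(nrow(panel)))
    g[, j] <- item_indicator(cats[[j]], kinds[j])
  g
}

#' Recommended Food Score
#'
#' The unweighted RFS tallies one point per recommended food consumed at
#' least once a week plus one point for a regular three-meals-a-day eating
#' pattern: an integer from 0 to 46 where higher means better diet quality.
#'
#' @inheritParams indicator_matrix
#' @return Integer vector of scores, one per subject, in `[0, 46]`.
#' @examples
#' panel <- default_food_panel()
#' resp <- as.data.frame(as.list(setNames(
#'   ifelse(panel$group == "meals", "three meals a day",
#'          "one to two times a week"), panel$item)),
#'   optional = TRUE, check.names = FALSE)
#' compute_rfs(resp, panel)  # 46
#' @export
compute_rfs <- function(responses, panel = default_food_panel()) {
  as.integer(rowSums(indicator_matrix(responses, panel)))
}
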