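# small grouping used to exercise the component model cheaply
toy_panel <- function() {
  food_panel(sprintf("it%d", 1:8), rep(c("a", "b", "c"), c(3, 3, 2)),
             validate_points = FALSE)
}

# one-row FFQ response with every food item at `food_cat` and the meals
# item at `meal_cat`
uniform_response <- function(panel = default_food_panel(),
                             food_cat = "never or seldom",
                             meal_cat = "irregular",
                             subject_id = "S1") {
  cats <- ifelse(panel$group == "meals", meal_cat, food_cat)
  out <- as.data.frame(as.list(stats::setNames(cats, panel$item)),
                       check.names = FALSE, stringsAsFactors = FALSE)
  cbind(data.frame(subject_id = subject_id, stringsAsFactors = FALSE), out)
}

# random FFQ table drawn uniformly over the category vocabularies
random_ffq <- function(n, panel = default_food_panel(), seed = 1) {
  set.seed(seed)
  out <- data.frame(subject_id = sprintf("R%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(panel))) {
    vocab <- if (panel$group[j] == "meals") ffq_meal_categories()
             else ffq_food_categories()
    out[[panel$item[j]]] <- sample(vocab, n, replace = TRUE)
  }
  out
}

# random binary indicator matrix for a panel
random_g <- function(n, panel, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * nrow(panel), 1, p), n, nrow(panel),
         dimnames = list(NULL, panel$item))
}

# within-group unit-L2 normalization of a weight vector (the identified
# pattern scale used to compare fitted and planted weights)
group_normalize <- function(w, panel) {
  idx <- split(seq_len(nrow(panel)), factor(panel$group,
                                            levels = unique(panel$group)))
  unlist(lapply(idx, function(j) w[j] / sqrt(sum(w[j]^2))),
         use.names = FALSE)
}
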