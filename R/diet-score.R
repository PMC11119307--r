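#' Score one food item as high (1) or low/no (0) consumption
#'
#' @param item Name of a scored item (see [score_item_names()]).
#' @param response For a frequency item, an integer scale code 0-6
#'   (see [frequency_levels()]); for a binary habit, 0/1 or TRUE/FALSE.
#'   Vectorised; `NA` propagates.
#' @param definition Score definition, default
#'   [default_score_definition()].
#' @return Integer 0/1 vector, same length as `response`.
#' @export
#' @examples
#' item_indicator("green_leafy", 4L)  # 3-4 times weekly -> high
#' item_indicator("coffee", 5L)       # below daily -> low
item_indicator <- function(item, response,
                           definition = default_score_definition()) {
  validate_score_definition(definition)
  if (length(item) != 1L || !item %in% names(definition)) {
    stop("unknown item name: ", paste(item, collapse = ", "), call. = FALSE)
  }
  spec <- definition[[item]]
  if (spec$kind == "frequency") {
    response <- as.integer(response)
    bad <- !is.na(response) & (response < 0L | response > 6L)
    if (any(bad)) {
      stop("item '", item, "': frequency response must be an integer in 0..6",
           call. = FALSE)
    }
    as.integer(response >= spec$min_level)
  } else {
    if (is.logical(response)) response <- as.integer(response)
    response <- as.integer(response)
    bad <- !is.na(response) & !response %in% c(0L, 1L)
    if (any(bad)) {
      stop("item '", item, "': binary response must be 0/1 or TRUE/FALSE",
           call. = FALSE)
    }
    as.integer(response == 1L)
  }
}

#' Compute the anti-inflammatory diet score for one subject
#'
#' The score is the number of the eleven items consumed at a high level,
#' so it ranges 0-11; higher means better compliance with an
#' anti-inflammatory diet.
#'
#' @param record Named list or one-row data frame holding the item
#'   responses (names as in [score_item_names()]).
#' @param missing_policy `"count_as_low"` (default): a missing item
#'   contributes 0 and is counted in `n_missing_items`; `"strict"`: any
#'   missing item is an error.
#' @param definition Score definition.
#' @return List of class `"diet_score"` with `score`, `tercile`
#'   (under the published cut-points), `n_missing_items`.
#' @export
#' @examples
#' rec <- as.list(setNames(rep(6L, 8), score_item_names()[1:8]))
#' rec[c("olive_oil", "rosemary", "salvia")] <- 1L
#' compute_score(rec)$score  # 11
compute_score <- function(record,
                          missing_policy = c("count_as_low", "strict"),
                          definition = default_score_definition()) {
  missing_policy <- match.arg(missing_policy)
  validate_score_definition(definition)
  items <- names(definition)
  absent <- setdiff(items, names(record))
  resp <- lapply(items, function(nm) {
    if (nm %in% absent) NA_integer_ else record[[nm]]
  })
  names(resp) <- items
  miss <- vapply(resp, function(x) length(x) != 1L || is.na(x), logical(1))
  if (missing_policy == "strict" && any(miss)) {
    stop("missing item(s) under strict policy: ",
         paste(items[miss], collapse = ", "), call. = FALSE)
  }
  s <- 0L
  for (nm in items[!miss]) {
    s <- s + item_indicator(nm, resp[[nm]], definition)
  }
  out <- list(score = as.integer(s),
              tercile = categorize_score(s),
              n_missing_items = sum(miss))
  class(out) <- "diet_score"
  out
}

#' @export
print.diet_score <- function(x, ...) {
  cat("anti-inflammatory diet score:", x$score, "/ 11",
      sprintf("(%s tercile", as.character(x$tercile)))
  if (x$n_missing_items > 0) cat(",", x$n_missing_items, "item(s) missing")
  cat(")\n")
  invisible(x)
}

#' Published score cut-points
#'
#' The published categorisation is low: score <= 5, medium: 6-7,
#' high: >= 8, based on the terciles of the controls' distribution.
#'
#' @param low_max Largest score in the low category.
#' @param medium_max Largest score in the medium category.
#' @return List of class `"score_cutpoints"`.
#' @export
score_cutpoints <- function(low_max = 5L, medium_max = 7L) {
  low_max <- as.integer(low_max); medium_max <- as.integer(medium_max)
  if (is.na(low_max) || is.na(medium_max) || low_max >= medium_max) {
    stop("need low_max < medium_max", call. = FALSE)
  }
  structure(list(low_max = low_max, medium_max = medium_max),
            class = "score_cutpoints")
}

#' Assign scores to terciles
#'
#' @param score Integer score(s) in 0..11; `NA` propagates.
#' @param cutpoints A [score_cutpoints()] object; default is the
#'   published low <= 5 / medium 6-7 / high >= 8.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
#' @examples
#' categorize_score(c(5L, 6L, 8L))
categorize_score <- function(score, cutpoints = score_cutpoints()) {
  stopifnot(inherits(cutpoints, "score_cutpoints"))
  score <- as.integer(score)
  if (any(!is.na(score) & (score < 0L | score > 11L))) {
    stop("score out of range 0..11", call. = FALSE)
  }
  out <- ifelse(is.na(score), NA_character_,
         ifelse(score <= cutpoints$low_max, "low",
         ifelse(score <= cutpoints$medium_max, "medium", "high")))
  factor(out, levels = c("low", "medium", "high"))
}

#' Derive score cut-points from the controls' distribution
#'
#' Cut-points are placed at the empirical 1/3 and 2/3 quantiles
#' (left-continuous, i.e. the smallest observation at or above each
#' probability) of the control scores, rounded down to integers. Tied
#' scores at a boundary fall into the lower category via the `<=` rule of
#' [categorize_score()]. If both cut-points coincide the result is flagged
#' degenerate (attribute `degenerate`).
#'
#' @param control_scores Integer scores in 0..11 of the control series;
#'   `NA` dropped.
#' @return A [score_cutpoints()] object, or (degenerate case) a list with
#'   equal cut-points carrying `attr(, "degenerate") = TRUE`.
#' @export
control_tercile_cutpoints <- function(control_scores) {
  x <- as.integer(control_scores)
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no control scores supplied", call. = FALSE)
  if (any(x < 0L | x > 11L)) stop("score out of range 0..11", call. = FALSE)
  q <- floor(stats::quantile(x, probs = c(1, 2) / 3, type = 1, names = FALSE))
  if (q[1] >= q[2]) {
    out <- structure(list(low_max = as.integer(q[1]),
                          medium_max = as.integer(q[2])),
                     class = "score_cutpoints", degenerate = TRUE)
    warning("degenerate cut-points: empirical terciles coincide",
            call. = FALSE)
    return(out)
  }
  score_cutpoints(q[1], q[2])
}

#' Score every subject in a study table
#'
#' Adds `diet_score`, `diet_n_missing` and `diet_tercile` columns computed
#' from the eleven item columns.
#'
#' @param data Subject data frame with the item columns named as in
#'   [score_item_names()].
#' @param cutpoints Tercile cut-points (default published).
#' @param missing_policy Passed to the per-item handling: under
#'   `"count_as_low"` a missing item contributes 0; under `"strict"` any
#'   missing response is an error.
#' @param definition Score definition.
#' @return `data` with the three added columns.
#' @export
score_subjects <- function(data, cutpoints = score_cutpoints(),
                           missing_policy = c("count_as_low", "strict"),
                           definition = default_score_definition()) {
  missing_policy <- match.arg(missing_policy)
  validate_score_definition(definition)
  items <- names(definition)
  absent <- setdiff(items, names(data))
  if (length(absent) > 0L) {
    stop("missing item column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ind <- matrix(0L, nrow = nrow(data), ncol = length(items),
                dimnames = list(NULL, items))
  miss <- matrix(FALSE, nrow = nrow(data), ncol = length(items))
  for (j in seq_along(items)) {
    v <- item_indicator(items[j], data[[items[j]]], definition)
    miss[, j] <- is.na(v)
    ind[, j] <- ifelse(is.na(v), 0L, v)
  }
  if (missing_policy == "strict" && any(miss)) {
    stop("missing item responses under strict policy (",
         sum(rowSums(miss) > 0), " subject(s))", call. = FALSE)
  }
  data$diet_score <- as.integer(rowSums(ind))
  data$diet_n_missing <- as.integer(rowSums(miss))
  data$diet_tercile <- categorize_score(data$diet_score, cutpoints)
  data
}
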