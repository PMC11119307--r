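#' Seven-point food-frequency scale
#'
#' Intake frequency is recorded on an ordered seven-point scale, coded
#' 0 to 6: never (0), less than monthly (1), less than weekly (2),
#' 1-2 times weekly (3), 3-4 times weekly (4), 5-7 times weekly (5),
#' daily (6).
#'
#' @return Named integer vector mapping scale labels to codes 0-6.
#' @export
#' @examples
#' frequency_levels()["daily"]
frequency_levels <- function() {
  c(never = 0L, lt_monthly = 1L, lt_weekly = 2L, weekly_1_2 = 3L,
    weekly_3_4 = 4L, weekly_5_7 = 5L, daily = 6L)
}

#' Default anti-inflammatory score definition
#'
#' Eleven food items are scored 1 for high consumption and 0 otherwise.
#' Eight are frequency items on the seven-point scale with an item-specific
#' high-consumption threshold; three are yes/no culinary habits. The
#' thresholds are: green leafy vegetables and salad at >= 3 times/week
#' (scale level 4 and above), vegetables in general and citrus fruits at
#' >= 5 times/week (level 5 and above), fruits in general and coffee at
#' daily (level 6), nuts and n-3-rich fish at weekly and more (level 3 and
#' above). The habits are exclusive use of olive oil for cooking and
#' dressing, regular use of fresh rosemary, and regular use of fresh salvia.
#'
#' @return Named list; each element has `kind` ("frequency" or "binary")
#'   and, for frequency items, `min_level` (the lowest qualifying code).
#' @seealso [item_indicator()], [compute_score()]
#' @export
default_score_definition <- function() {
  list(
    green_leafy = list(kind = "frequency", min_level = 4L),
    salad       = list(kind = "frequency", min_level = 4L),
    veg_general = list(kind = "frequency", min_level = 5L),
    citrus      = list(kind = "frequency", min_level = 5L),
    fruits      = list(kind = "frequency", min_level = 6L),
    coffee      = list(kind = "frequency", min_level = 6L),
    nuts        = list(kind = "frequency", min_level = 3L),
    fish_n3     = list(kind = "frequency", min_level = 3L),
    olive_oil   = list(kind = "binary"),
    rosemary    = list(kind = "binary"),
    salvia      = list(kind = "binary")
  )
}

#' Names of the eleven scored items
#' @return Character vector of the canonical item column names.
#' @export
score_item_names <- function() names(default_score_definition())

validate_score_definition <- function(definition) {
  if (!is.list(definition) || is.null(names(definition)) ||
      anyDuplicated(names(definition)) > 0L) {
    stop("score definition must be a uniquely named list", call. = FALSE)
  }
  for (nm in names(definition)) {
    item <- definition[[nm]]
    kind <- item$kind
    if (is.null(kind) || !kind %in% c("frequency", "binary")) {
      stop("item '", nm, "': kind must be 'frequency' or 'binary'",
           call. = FALSE)
    }
    if (kind == "frequency") {
      ml <- item$min_level
      if (is.null(ml) || length(ml) != 1L || is.na(ml) ||
          ml < 0L || ml > 6L || ml != as.integer(ml)) {
        stop("item '", nm, "': min_level must be an integer in 0..6",
             call. = FALSE)
      }
    }
  }
  invisible(definition)
}

#' Read or write a score definition file
#'
#' The definition is stored as YAML mapping item name to
#' `{kind: frequency|binary, min_level: <int>}`. The packaged default is
#' in `system.file("extdata", "anti_inflammatory_score.yaml",
#' package = "aidiet")`.
#'
#' @param path File path.
#' @param definition A score definition list (see
#'   [default_score_definition()]).
#' @return `read_score_definition()` returns the validated definition list.
#' @export
read_score_definition <- function(path) {
  def <- yaml::read_yaml(path)
  def <- lapply(def, function(item) {
    if (!is.null(item$min_level)) item$min_level <- as.integer(item$min_level)
    item
  })
  validate_score_definition(def)
  def
}

#' @rdname read_score_definition
#' @export
write_score_definition <- function(definition, path) {
  validate_score_definition(definition)
  yaml::write_yaml(definition, path)
  invisible(path)
}
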