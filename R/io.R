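subject_factor_levels <- function() {
  list(sex = c("female", "male"),
       education = c("<8", "8-13", ">13"),
       hair_colour = c("dark", "light_brown", "fair_red"),
       photo_type = c("III-IV", "I-II"),
       skin_colour = c("dark", "fair"),
       nevi = c("0-59", ">=60"),
       lentigines = c("none_few_moderate", "high"),
       bmi_cat = c("<=24.9", "25.0-29.9", ">=30"),
       smoking = c("never", "current", "ex"),
       sun_hours_cat = c("low", "medium", "high"),
       genotype = c("GG", "GC", "CC"),
       genotype_pooled = c("GG", "C_carrier"),
       diet_tercile = c("low", "medium", "high"))
}

#' Read or write a subject table
#'
#' Subject CSV schema: one row per subject; `status` coded 1 = case,
#' 0 = control; food items `green_leafy, salad, veg_general, citrus,
#' fruits, nuts, coffee, fish_n3` coded 0-6 on the seven-point frequency
#' scale and `olive_oil, rosemary, salvia` coded 0/1; covariate columns
#' as written by [simulate_study()] (factor levels restored on read);
#' empty cells are missing. Unknown category labels are an error, not
#' coerced to `NA`.
#'
#' @param path CSV file path.
#' @param data Subject data frame.
#' @return `read_subjects()` returns the subject data frame with factor
#'   columns restored.
#' @export
read_subjects <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  levs <- subject_factor_levels()
  for (col in intersect(names(levs), names(d))) {
    bad <- !is.na(d[[col]]) & !d[[col]] %in% levs[[col]]
    if (any(bad)) {
      stop("column '", col, "': unknown level(s) ",
           paste(unique(d[[col]][bad]), collapse = ", "), call. = FALSE)
    }
    d[[col]] <- factor(d[[col]], levels = levs[[col]])
  }
  if ("genotype" %in% names(d) && !"genotype_pooled" %in% names(d)) {
    d$genotype_pooled <- pool_c_carriers(d$genotype)
  }
  d
}

#' @rdname read_subjects
#' @export
write_subjects <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
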