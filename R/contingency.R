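#' Test-result container
#'
#' @param statistic Test statistic.
#' @param df Degrees of freedom (or `NA` for exact tests).
#' @param p_value Two-sided p-value.
#' @param test_name Short label.
#' @return List of class `"aid_test"`.
#' @keywords internal
aid_test <- function(statistic, df, p_value, test_name) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), test_name = test_name),
            class = "aid_test")
}

#' @export
print.aid_test <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.na(x$df)) paste0(", df = ", x$df) else " (exact)",
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Exposure-by-status contingency table
#'
#' Cross-tabulates an exposure (k levels) against case/control status.
#' Subjects with a missing exposure or status are excluded and counted in
#' the `n_missing` attribute.
#'
#' @param data Subject data frame with a 0/1 `status` column
#'   (1 = case).
#' @param exposure Column name of the exposure, or a factor/vector of
#'   length `nrow(data)`.
#' @param status Column name of the status variable.
#' @return k x 2 integer matrix (columns `case`, `control`) with
#'   attributes `exposure`, `n_missing`.
#' @export
crosstab <- function(data, exposure, status = "status") {
  st <- data[[status]]
  if (is.null(st)) stop("no status column '", status, "'", call. = FALSE)
  if (is.character(exposure) && length(exposure) == 1L) {
    label <- exposure
    ex <- data[[exposure]]
    if (is.null(ex)) stop("no exposure column '", exposure, "'", call. = FALSE)
  } else {
    label <- "exposure"
    ex <- exposure
    stopifnot(length(ex) == nrow(data))
  }
  if (!is.factor(ex)) ex <- factor(ex)
  keep <- !is.na(ex) & !is.na(st)
  if (!any(keep)) stop("no usable subjects for '", label, "'", call. = FALSE)
  tab <- table(ex[keep], factor(st[keep], levels = c(1, 0),
                                labels = c("case", "control")))
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), c("case", "control")))
  attr(out, "exposure") <- label
  attr(out, "n_missing") <- sum(!keep)
  out
}

#' Crude odds ratio with Woolf confidence interval
#'
#' For exposed/unexposed cases a, b and exposed/unexposed controls c, d,
#' OR = ad / bc with 95% CI exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))
#' and a two-sided Wald p-value on the log scale. With `continuity = TRUE`
#' and any zero cell, 0.5 is added to all four cells (Haldane-Anscombe);
#' otherwise a zero cell is an error.
#'
#' @param a,b,c,d Cell counts: exposed cases, unexposed cases, exposed
#'   controls, unexposed controls. Alternatively `a` may be a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))`.
#' @param continuity Add 0.5 to all cells when any cell is zero.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `"effect_estimate"` with `or`, `ci_low`,
#'   `ci_high`, `p_value`, `adjusted_for` (empty: crude).
#' @export
#' @examples
#' crude_or(93, 121, 58, 176)  # OR ~ 2.33
crude_or <- function(a, b = NULL, c = NULL, d = NULL, continuity = FALSE,
                     conf_level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  if (any(cells == 0)) {
    if (!continuity) {
      stop("zero cell; set continuity = TRUE for the 0.5 correction",
           call. = FALSE)
    }
    cells <- cells + 0.5
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  effect_estimate(
    or = unname(or),
    ci_low = unname(exp(log(or) - z * se)),
    ci_high = unname(exp(log(or) + z * se)),
    p_value = unname(2 * stats::pnorm(-abs(log(or) / se))),
    adjusted_for = character(0))
}

effect_estimate <- function(or, ci_low, ci_high, p_value, adjusted_for,
                            n = NA_integer_, available = TRUE) {
  structure(list(or = or, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, adjusted_for = adjusted_for,
                 n = n, available = available),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (!isTRUE(x$available)) {
    cat("effect estimate unavailable (stratum too small to fit)\n")
    return(invisible(x))
  }
  lbl <- if (length(x$adjusted_for) == 0) "crude" else
    paste0("adjusted for ", paste(x$adjusted_for, collapse = ", "))
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %s [%s]\n",
              x$or, x$ci_low, x$ci_high,
              format.pval(x$p_value, digits = 3), lbl))
  invisible(x)
}

#' Pearson chi-square test on a k x 2 table
#'
#' No continuity correction. Expected counts of zero (an empty row or
#' column) are an error.
#'
#' @param table k x 2 count matrix, e.g. from [crosstab()].
#' @return [aid_test()] result with df = k - 1.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("expected count zero: empty row or column", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  aid_test(unname(res$statistic), unname(res$parameter),
           unname(res$p.value), "Pearson chi-square")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison with midrank tie handling. Groups with
#' fewer than 8 observations each are compared by exact enumeration (ties
#' permitting); otherwise the normal approximation with tie-corrected
#' variance is used, without continuity correction. The reported statistic
#' is U for the first sample: the number of (x, y) pairs with x > y,
#' counting ties as 1/2.
#'
#' @param x,y Numeric samples.
#' @return [aid_test()] result.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$statistic  # 0
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- length(x) < 8L && length(y) < 8L
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  p <- res$p.value
  if (is.na(p)) p <- 1  # degenerate: all values tied across both samples
  aid_test(unname(res$statistic), NA_integer_, min(1, p), "Mann-Whitney U")
}
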