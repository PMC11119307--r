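#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()] with a tight convergence tolerance),
#' complete-case on the model variables. Non-convergence and complete
#' separation (diverging coefficients) are explicit errors, never silent.
#'
#' @param formula Model formula; the outcome must be 0/1 (1 = case).
#' @param data Subject data frame.
#' @param max_abs_beta Threshold on |beta| used to flag separation
#'   (default 15 on the log-odds scale).
#' @return Object of class `"aid_logit"`: coefficients, covariance,
#'   log-likelihood, per-term odds ratios with Wald 95% CIs
#'   (`$or_table`), the rows used (`$rows`), and the underlying glm fit.
#' @export
#' @examples
#' d <- data.frame(status = rep(c(1, 1, 1, 0, 0, 0), 10),
#'                 x = rep(c(1, 1, 0, 1, 0, 0), 10))
#' exp(coef(fit_logistic(status ~ x, d))["x"])  # 4
fit_logistic <- function(formula, data, max_abs_beta = 15) {
  vars <- all.vars(formula)
  absent <- setdiff(vars, names(data))
  if (length(absent) > 0L) {
    stop("model variable(s) not in data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  cc <- stats::complete.cases(data[vars])
  d <- data[cc, vars, drop = FALSE]
  # convergence and separation are diagnosed explicitly below, so the
  # glm.fit boundary warnings are redundant here
  fit <- suppressWarnings(
    stats::glm(formula, data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  if (nrow(d) < length(stats::coef(fit))) {
    stop("fewer complete-case rows than parameters", call. = FALSE)
  }
  if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("rank-deficient model: aliased coefficient(s) ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  if (any(abs(beta) > max_abs_beta)) {
    stop("complete or quasi-complete separation: |beta| > ", max_abs_beta,
         " for ", paste(names(beta)[abs(beta) > max_abs_beta],
                        collapse = ", "), call. = FALSE)
  }
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  z <- stats::qnorm(0.975)
  or_table <- data.frame(
    term = names(beta),
    beta = unname(beta),
    se = unname(se),
    or = unname(exp(beta)),
    ci_low = unname(exp(beta - z * se)),
    ci_high = unname(exp(beta + z * se)),
    p_value = unname(2 * stats::pnorm(-abs(beta / se))),
    row.names = NULL)
  structure(list(coefficients = beta, vcov = V,
                 logLik = as.numeric(stats::logLik(fit)),
                 df = length(beta), n = nrow(d),
                 converged = fit$converged, formula = formula,
                 or_table = or_table, rows = rownames(d), glm = fit),
            class = "aid_logit")
}

#' @export
print.aid_logit <- function(x, digits = 3, ...) {
  cat("logistic regression:", deparse(x$formula), "\n")
  cat("n =", x$n, " log-likelihood =", format(x$logLik, digits = 6), "\n")
  tab <- x$or_table
  tab$p_value <- format.pval(tab$p_value, digits = digits)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.aid_logit <- function(object, ...) object$or_table

#' @export
coef.aid_logit <- function(object, ...) object$coefficients

#' @export
vcov.aid_logit <- function(object, ...) object$vcov

#' @export
logLik.aid_logit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.aid_logit <- function(object, ...) object$n

#' @export
predict.aid_logit <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) stats::predict(object$glm, type = type)
  else stats::predict(object$glm, newdata = newdata, type = type)
}

#' Wald test for linear trend on an ordinal term
#'
#' The exposure is entered as an ordinal integer code (tercile 0/1/2) and
#' the single coefficient is tested with z = beta / SE against the
#' standard normal, two-sided.
#'
#' @param fit An [fit_logistic()] object containing the ordinal term.
#' @param term Coefficient name of the ordinal term.
#' @return [aid_test()] result (the `statistic` is z).
#' @export
wald_trend_test <- function(fit, term) {
  stopifnot(inherits(fit, "aid_logit"))
  if (!term %in% names(fit$coefficients)) {
    stop("term '", term, "' not in the fitted model", call. = FALSE)
  }
  beta <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- beta / se
  aid_test(z, NA_integer_, 2 * stats::pnorm(-abs(z)), "Wald trend test")
}

#' Likelihood-ratio test for nested logistic models
#'
#' Both fits must use exactly the same rows (enforced by row-id
#' comparison) and the null model's terms must be a subset of the full
#' model's.
#'
#' @param fit_null,fit_full Nested [fit_logistic()] objects.
#' @return [aid_test()] result; statistic = 2 (l_full - l_null), df =
#'   parameter-count difference (df 0 when the models coincide).
#' @export
likelihood_ratio_test <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "aid_logit"), inherits(fit_full, "aid_logit"))
  if (!setequal(fit_null$rows, fit_full$rows)) {
    stop("fits use different rows; refit both on the common complete cases",
         call. = FALSE)
  }
  lab_null <- attr(stats::terms(fit_null$formula), "term.labels")
  lab_full <- attr(stats::terms(fit_full$formula), "term.labels")
  if (!all(lab_null %in% lab_full)) {
    stop("models are not nested", call. = FALSE)
  }
  df <- fit_full$df - fit_null$df
  if (df < 0L) stop("models are not nested", call. = FALSE)
  stat <- max(0, 2 * (fit_full$logLik - fit_null$logLik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  aid_test(stat, df, p, "likelihood-ratio test")
}

#' Model-A covariate set
#'
#' The primary adjustment set: sex, age, education, number of common
#' nevi, skin photo-type, solar lentigines and sunburns in childhood.
#'
#' @return Character vector of covariate column names.
#' @export
model_a_covariates <- function() {
  c("sex", "age", "education", "nevi", "photo_type", "lentigines",
    "sunburn_child")
}

#' Multivariate model presets A-H
#'
#' Model A adjusts for the [model_a_covariates()]; B-H each add one
#' robustness covariate: B body-mass index, C COX-2 inhibitor use,
#' D aspirin use, E the pooled -765G>C genotype (restricting to genotyped
#' subjects), F smoking, G chronic disease excluding cardiovascular
#' disease, H chronic disease including it.
#'
#' @return Named list (`A` .. `H`) of covariate name vectors.
#' @export
model_presets <- function() {
  a <- model_a_covariates()
  list(A = a,
       B = c(a, "bmi_cat"),
       C = c(a, "cox2_inhibitor"),
       D = c(a, "aspirin"),
       E = c(a, "genotype_pooled"),
       F = c(a, "smoking"),
       G = c(a, "chronic_excl_cvd"),
       H = c(a, "chronic_incl_cvd"))
}

#' Likelihood-ratio test for gene-diet interaction
#'
#' Compares the adjusted model with exposure-by-modifier product terms
#' against the same model without them, on the common complete cases.
#' Degrees of freedom are (levels(exposure) - 1) x (levels(modifier) - 1)
#' as realised in the fitted design.
#'
#' @param data Subject data frame (scored, with pooled genotype).
#' @param exposure Exposure factor column (default diet tercile).
#' @param modifier Effect-modifier factor column (default pooled
#'   genotype).
#' @param covariates Adjustment covariates (default model A).
#' @param outcome Status column.
#' @return [aid_test()] result.
#' @export
interaction_test <- function(data, exposure = "diet_tercile",
                             modifier = "genotype_pooled",
                             covariates = model_a_covariates(),
                             outcome = "status") {
  vars <- c(outcome, exposure, modifier, covariates)
  cc <- stats::complete.cases(data[vars])
  d <- droplevels(data[cc, vars, drop = FALSE])
  if (length(unique(d[[modifier]])) < 2L) {
    stop("interaction not estimable: '", modifier,
         "' has a single level on the complete cases", call. = FALSE)
  }
  if (length(unique(d[[exposure]])) < 2L) {
    stop("interaction not estimable: '", exposure,
         "' has a single level on the complete cases", call. = FALSE)
  }
  cross <- table(d[[exposure]], d[[modifier]])
  if (any(cross == 0)) {
    warning("empty exposure-by-modifier cell(s); interaction test run on ",
            "the available cells", call. = FALSE)
  }
  f_null <- stats::reformulate(c(exposure, modifier, covariates),
                               response = outcome)
  f_full <- stats::reformulate(
    c(exposure, modifier, covariates, paste(exposure, modifier, sep = ":")),
    response = outcome)
  likelihood_ratio_test(fit_logistic(f_null, d), fit_logistic(f_full, d))
}

#' Adjusted exposure estimates within strata
#'
#' Fits the adjusted logistic model separately within each level of a
#' stratifying variable and reports the exposure effect estimates per
#' stratum. A stratum with too few complete-case rows to fit (or where
#' the fit fails, e.g. by separation) is flagged unavailable rather than
#' dropped.
#'
#' @param data Subject data frame.
#' @param exposure Exposure factor column (default diet tercile).
#' @param stratum Stratifying column (default pooled genotype; >= 2
#'   levels required).
#' @param covariates Adjustment covariates (default model A).
#' @param outcome Status column.
#' @return Data frame with one row per stratum x non-reference exposure
#'   level: `stratum`, `level`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `n`, `available`, `note`.
#' @export
stratified_estimates <- function(data, exposure = "diet_tercile",
                                 stratum = "genotype_pooled",
                                 covariates = model_a_covariates(),
                                 outcome = "status") {
  sv <- data[[stratum]]
  if (is.null(sv)) stop("no stratum column '", stratum, "'", call. = FALSE)
  if (!is.factor(sv)) sv <- factor(sv)
  levs <- levels(droplevels(sv[!is.na(sv)]))
  if (length(levs) < 2L) {
    stop("stratum variable needs >= 2 observed levels", call. = FALSE)
  }
  ex_levels <- levels(factor(data[[exposure]]))
  out <- list()
  for (lv in levs) {
    d <- data[!is.na(sv) & sv == lv, , drop = FALSE]
    vars <- c(outcome, exposure, covariates)
    n_cc <- sum(stats::complete.cases(d[vars]))
    res <- tryCatch({
      fit <- fit_logistic(stats::reformulate(c(exposure, covariates),
                                             response = outcome), d)
      tab <- fit$or_table
      rows <- tab[grepl(paste0("^", exposure), tab$term), , drop = FALSE]
      data.frame(stratum = lv,
                 level = sub(paste0("^", exposure), "", rows$term),
                 or = rows$or, ci_low = rows$ci_low, ci_high = rows$ci_high,
                 p_value = rows$p_value, n = fit$n, available = TRUE,
                 note = NA_character_)
    }, error = function(e) {
      data.frame(stratum = lv, level = ex_levels[-1],
                 or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, n = n_cc, available = FALSE,
                 note = conditionMessage(e))
    })
    out[[lv]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
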