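descriptive_variables <- function() {
  c("sex", "education", "hair_colour", "photo_type", "skin_colour",
    "freckles", "nevi", "lentigines", "family_history",
    "chronic_excl_cvd", "chronic_incl_cvd", "genotype",
    "sun_hours_cat", "sunburn_child", "bmi_cat", "smoking",
    "diet_tercile", "cox2_inhibitor", "aspirin")
}

#' Descriptive case-control comparison
#'
#' For every categorical study variable present in the data: counts and
#' percentages by status, the Pearson chi-square p-value, and crude odds
#' ratios (Woolf CIs, 0.5 continuity correction on zero cells) per level
#' against the first level as reference. Age is summarised as mean/SD and
#' median with a Mann-Whitney p-value. A variable that is entirely
#' missing is flagged and skipped rather than aborting the run.
#'
#' @param data Scored subject data frame with a 0/1 `status` column.
#' @return List with `tables` (one data frame per variable), `age`, and
#'   `skipped`.
#' @export
run_descriptives <- function(data) {
  tables <- list()
  skipped <- character(0)
  for (v in intersect(descriptive_variables(), names(data))) {
    if (all(is.na(data[[v]]))) {
      skipped <- c(skipped, v)
      next
    }
    tab <- crosstab(data, v)
    p_chi <- tryCatch(chi_square_test(tab)$p_value,
                      error = function(e) NA_real_)
    rows <- data.frame(variable = v, level = rownames(tab),
                       n_case = tab[, "case"], n_control = tab[, "control"],
                       pct_case = 100 * tab[, "case"] / sum(tab[, "case"]),
                       pct_control = 100 * tab[, "control"] /
                         sum(tab[, "control"]),
                       or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p_chi_square = p_chi, row.names = NULL)
    if (nrow(tab) >= 2L) {
      for (i in 2:nrow(tab)) {
        est <- crude_or(tab[i, "case"], tab[1, "case"],
                        tab[i, "control"], tab[1, "control"],
                        continuity = TRUE)
        rows$or[i] <- est$or
        rows$ci_low[i] <- est$ci_low
        rows$ci_high[i] <- est$ci_high
      }
    }
    tables[[v]] <- rows
  }
  age <- NULL
  if ("age" %in% names(data)) {
    a_case <- data$age[data$status == 1]
    a_ctrl <- data$age[data$status == 0]
    age <- list(mean_case = mean(a_case, na.rm = TRUE),
                sd_case = stats::sd(a_case, na.rm = TRUE),
                mean_control = mean(a_ctrl, na.rm = TRUE),
                sd_control = stats::sd(a_ctrl, na.rm = TRUE),
                median_case = stats::median(a_case, na.rm = TRUE),
                median_control = stats::median(a_ctrl, na.rm = TRUE),
                p_mann_whitney = mann_whitney_u(a_case, a_ctrl)$p_value)
  }
  list(tables = tables, age = age, skipped = skipped)
}

#' Fit the multivariate model presets
#'
#' For each requested preset (see [model_presets()]) fits the adjusted
#' logistic model of status on the diet tercile, reports the T2 and T3
#' odds ratios against the low tercile with Wald 95% CIs, the Wald trend
#' p-value (tercile entered as ordinal 0/1/2 in a parallel fit on the
#' same rows), and the complete-case n actually used.
#'
#' @param data Scored subject data frame.
#' @param presets Character vector of preset letters (default A-H).
#' @return Data frame, one row per preset.
#' @export
run_models <- function(data, presets = names(model_presets())) {
  all_presets <- model_presets()
  unknown <- setdiff(presets, names(all_presets))
  if (length(unknown) > 0L) {
    stop("unknown model preset(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (p in presets) {
    covs <- all_presets[[p]]
    absent <- setdiff(covs, names(data))
    if (length(absent) > 0L) {
      stop("preset ", p, ": covariate(s) not in data: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    vars <- c("status", "diet_tercile", covs)
    d <- data[stats::complete.cases(data[vars]), , drop = FALSE]
    fit <- fit_logistic(stats::reformulate(c("diet_tercile", covs),
                                           response = "status"), d)
    tab <- fit$or_table
    t2 <- tab[tab$term == "diet_tercilemedium", ]
    t3 <- tab[tab$term == "diet_tercilehigh", ]
    d$diet_ord <- as.integer(d$diet_tercile) - 1L
    fit_trend <- fit_logistic(stats::reformulate(c("diet_ord", covs),
                                                 response = "status"), d)
    p_trend <- wald_trend_test(fit_trend, "diet_ord")$p_value
    out[[p]] <- data.frame(
      model = p, covariates = paste(covs, collapse = "+"),
      or_t2 = t2$or, ci_low_t2 = t2$ci_low, ci_high_t2 = t2$ci_high,
      or_t3 = t3$or, ci_low_t3 = t3$ci_low, ci_high_t3 = t3$ci_high,
      p_trend = p_trend, n = fit$n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-environment section: interaction and stratified estimates
#'
#' Likelihood-ratio test for diet-tercile by pooled-genotype interaction
#' on top of the model-A adjustment, plus genotype-stratified adjusted
#' tercile estimates. Requires a minimum number of genotyped subjects;
#' with no usable genotype data the section is skipped with a warning.
#'
#' @param data Scored subject data frame with `genotype_pooled`.
#' @param covariates Adjustment set (default model A).
#' @param min_genotyped Minimum genotyped subjects (default 50).
#' @return List with `interaction` ([aid_test()] result), `stratified`
#'   (see [stratified_estimates()]) and `n_genotyped`; or `NULL` when
#'   skipped.
#' @export
run_gene_environment <- function(data, covariates = model_a_covariates(),
                                 min_genotyped = 50L) {
  if (!"genotype_pooled" %in% names(data) ||
      sum(!is.na(data$genotype_pooled)) < min_genotyped) {
    warning("gene-environment section skipped: fewer than ", min_genotyped,
            " genotyped subjects", call. = FALSE)
    return(NULL)
  }
  list(interaction = interaction_test(data, covariates = covariates),
       stratified = stratified_estimates(data, covariates = covariates),
       n_genotyped = sum(!is.na(data$genotype_pooled)))
}

#' Run the full study analysis
#'
#' Scores the subjects (published cut-points unless `cutpoints` is
#' given), then produces the descriptive tables, the multivariate model
#' presets, and the gene-environment section, bundled with run metadata.
#'
#' @param data Subject data frame (e.g. from [simulate_study()] or
#'   [read_subjects()]).
#' @param models Preset letters to fit (default A-H; presets whose
#'   covariates are absent raise an error).
#' @param cutpoints Score cut-points; default published. Pass
#'   `control_tercile_cutpoints()` output to re-derive them from the
#'   controls.
#' @return List of class `"aid_report"`.
#' @export
analyze_study <- function(data, models = names(model_presets()),
                          cutpoints = score_cutpoints()) {
  if (!"status" %in% names(data)) {
    stop("data must contain a 0/1 'status' column", call. = FALSE)
  }
  data <- score_subjects(data, cutpoints = cutpoints)
  if ("genotype" %in% names(data) && !"genotype_pooled" %in% names(data)) {
    data$genotype_pooled <- pool_c_carriers(data$genotype)
  }
  desc <- run_descriptives(data)
  mods <- run_models(data, models)
  ge <- if ("genotype_pooled" %in% names(data)) {
    withCallingHandlers(run_gene_environment(data),
                        warning = function(w) invokeRestart("muffleWarning"))
  } else NULL
  prov <- attr(data, "provenance")
  structure(list(descriptives = desc, models = mods,
                 gene_environment = ge,
                 meta = list(n_cases = sum(data$status == 1, na.rm = TRUE),
                             n_controls = sum(data$status == 0,
                                              na.rm = TRUE),
                             cutpoints = unclass(cutpoints),
                             provenance = prov,
                             version = as.character(
                               utils::packageVersion("aidiet")))),
            class = "aid_report")
}

#' @export
print.aid_report <- function(x, ...) {
  cat("case-control analysis:", x$meta$n_cases, "cases /",
      x$meta$n_controls, "controls\n")
  if (!is.null(x$descriptives$tables$diet_tercile)) {
    cat("\nanti-inflammatory diet score terciles:\n")
    print(format(x$descriptives$tables$diet_tercile, digits = 3),
          row.names = FALSE)
  }
  cat("\nmultivariate models (tercile ORs vs low):\n")
  m <- x$models
  m$covariates <- NULL
  print(format(m, digits = 3), row.names = FALSE)
  if (!is.null(x$gene_environment)) {
    cat(sprintf("\ngene-diet interaction LRT: p = %s (n genotyped = %d)\n",
                format.pval(x$gene_environment$interaction$p_value,
                            digits = 3),
                x$gene_environment$n_genotyped))
    cat("stratified adjusted estimates:\n")
    print(format(x$gene_environment$stratified, digits = 3),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes machine-readable JSON (`report.json`) plus per-table CSVs
#' (descriptives, model results, stratified estimates) into a directory.
#'
#' @param report An [analyze_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "aid_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(models = report$models,
         descriptives = report$descriptives$tables,
         age = report$descriptives$age,
         gene_environment = if (!is.null(report$gene_environment)) {
           list(interaction_p =
                  report$gene_environment$interaction$p_value,
                stratified = report$gene_environment$stratified,
                n_genotyped = report$gene_environment$n_genotyped)
         },
         meta = report$meta),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  utils::write.csv(do.call(rbind, report$descriptives$tables),
                   file.path(dir, "descriptives.csv"), row.names = FALSE)
  utils::write.csv(report$models, file.path(dir, "models.csv"),
                   row.names = FALSE)
  if (!is.null(report$gene_environment)) {
    utils::write.csv(report$gene_environment$stratified,
                     file.path(dir, "stratified.csv"), row.names = FALSE)
  }
  invisible(dir)
}
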