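#' Synthetic-study generator configuration
#'
#' All simulation parameters for the frequency-matched melanoma
#' case-control study the analysis pipeline expects. The defaults ARE the
#' packaged calibration (see [calibration_default()]): covariate
#' prevalences follow the control marginals of the study tables, the
#' -765G>C genotype distribution follows the printed frequencies
#' (60.7 / 33.7 / 5.6%), the eleven food items are Bernoulli with a shared
#' latent healthy-eating factor so the control score distribution has mean
#' 6.2 and SD near 2.1, and the disease model is logit-linear in the diet
#' tercile and the model-A covariates with the published odds ratios as
#' the configured truths (tercile T2 0.83, T3 0.29; nevi 5.41, photo-type
#' 2.80, lentigines 3.60, childhood sunburn 2.50, education 1.43 / 2.87).
#'
#' @param n_cases,n_controls Study sizes (defaults 273 / 269).
#' @param population_n Source-population size; `NULL` (default) sizes it
#'   automatically from a pilot prevalence estimate.
#' @param seed Integer seed recorded in the provenance; when `NULL`,
#'   [simulate_study()] falls back to 20240523.
#' @param sex_p_male Probability male.
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#' @param covariate_probs Named list of category probabilities (see
#'   defaults for the expected names and level order).
#' @param genotype_probs Probabilities of GG/GC/CC; ignored when
#'   `allele_c_freq` is given.
#' @param allele_c_freq Optional allele-C frequency; genotypes are then
#'   drawn from Hardy-Weinberg proportions p^2, 2pq, q^2.
#' @param item_p Named marginal high-consumption probabilities for the 11
#'   scored items.
#' @param item_loading Loading `b` of the shared standard-normal latent
#'   factor: item i is high with probability plogis(a_i + b u), a_i solved
#'   so the marginal equals `item_p[i]`. Controls the score SD and
#'   between-item correlation.
#' @param disease Named list of disease-model parameters on the log-odds
#'   scale: `intercept`, `beta_t2`, `beta_t3` (diet terciles vs low),
#'   `gamma_t2`, `gamma_t3` (additional tercile effects in C-allele
#'   carriers; 0 = no gene-diet interaction), `sex_male`, `age_per_year`
#'   (centred at 52 y), `education_mid`, `education_high`, `nevi_high`,
#'   `photo_i_ii`, `lentigines_high`, `sunburn`.
#' @param missingness Named numeric of per-column missingness rates
#'   applied to the drawn study (default: genotype unobserved with
#'   probability 0.441, mirroring 303/542 genotyped subjects).
#' @param match_mode `"frequency"` (controls apportioned over sex x 5-year
#'   age strata to the case distribution) or `"none"` (simple random
#'   controls).
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(
    n_cases = 273L, n_controls = 269L, population_n = NULL, seed = NULL,
    sex_p_male = 0.448,
    age_mean = 51.9, age_sd = 15.6, age_range = c(18, 90),
    covariate_probs = list(
      education = c("<8" = 0.219, "8-13" = 0.666, ">13" = 0.115),
      hair_colour = c(dark = 0.665, light_brown = 0.253, fair_red = 0.082),
      photo_type = c("III-IV" = 0.578, "I-II" = 0.422),
      skin_colour = c(dark = 0.413, fair = 0.587),
      freckles = 0.187,
      nevi = c("0-59" = 0.870, ">=60" = 0.130),
      lentigines = c(none_few_moderate = 0.412, high = 0.588),
      family_history = 0.034,
      chronic_excl_cvd = 0.297,
      chronic_incl_cvd = 0.320,
      sunburn_child = 0.248,
      bmi_cat = c("<=24.9" = 0.493, "25.0-29.9" = 0.388, ">=30" = 0.119),
      smoking = c(never = 0.468, current = 0.368, ex = 0.164),
      cox2_inhibitor = 0.108,
      aspirin = 0.037,
      sun_hours_cat = c(low = 0.341, medium = 0.345, high = 0.314)),
    genotype_probs = c(GG = 0.607, GC = 0.337, CC = 0.056),
    allele_c_freq = NULL,
    item_p = c(green_leafy = 0.62, salad = 0.68, veg_general = 0.52,
               citrus = 0.48, fruits = 0.62, coffee = 0.80, nuts = 0.38,
               fish_n3 = 0.42, olive_oil = 0.88, rosemary = 0.45,
               salvia = 0.28),
    item_loading = 0.76,
    disease = list(intercept = -4.35,
                   beta_t2 = log(0.83), beta_t3 = log(0.29),
                   gamma_t2 = 0, gamma_t3 = 0,
                   sex_male = log(1.11), age_per_year = 0.005,
                   education_mid = log(1.43), education_high = log(2.87),
                   nevi_high = log(5.41), photo_i_ii = log(2.80),
                   lentigines_high = log(3.60), sunburn = log(2.50)),
    missingness = c(genotype = 0.441),
    match_mode = c("frequency", "none")) {
  match_mode <- match.arg(match_mode)
  stopifnot(n_cases >= 1, n_controls >= 1,
            sex_p_male >= 0, sex_p_male <= 1,
            age_range[1] < age_range[2], age_sd > 0,
            item_loading >= 0)
  if (!setequal(names(item_p), score_item_names())) {
    stop("item_p must be named by the 11 scored items", call. = FALSE)
  }
  probs_ok <- function(p) all(p >= 0 & p <= 1)
  if (!probs_ok(unlist(covariate_probs)) || !probs_ok(item_p) ||
      !probs_ok(unlist(missingness))) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(allele_c_freq)) {
    stopifnot(allele_c_freq >= 0, allele_c_freq <= 1)
    q <- allele_c_freq
    genotype_probs <- c(GG = (1 - q)^2, GC = 2 * (1 - q) * q, CC = q^2)
  } else {
    genotype_probs <- genotype_probs / sum(genotype_probs)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 population_n = population_n, seed = seed,
                 sex_p_male = sex_p_male, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 covariate_probs = covariate_probs,
                 genotype_probs = genotype_probs,
                 allele_c_freq = allele_c_freq,
                 item_p = item_p[score_item_names()],
                 item_loading = item_loading,
                 disease = disease, missingness = missingness,
                 match_mode = match_mode),
            class = "generator_config")
}

#' Packaged calibration configuration
#'
#' The generator configuration whose defaults reproduce, in expectation,
#' the study's headline descriptives: control mean score 6.2 (cases 5.5),
#' genotype frequencies 60.7 / 33.7 / 5.6%, and the published covariate
#' marginals, with the published adjusted diet effects as the configured
#' disease-model truths.
#'
#' @return A [generator_config()] object.
#' @export
calibration_default <- function() generator_config()

# Gauss-Hermite nodes/weights for E[g(u)], u ~ N(0,1) (Golub-Welsch)
gauss_hermite_normal <- local({
  cache <- NULL
  function(n = 40L) {
    if (!is.null(cache)) return(cache)
    k <- seq_len(n - 1L)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1L)] <- sqrt(k / 2)
    J <- J + t(J)
    e <- eigen(J, symmetric = TRUE)
    cache <<- list(x = sqrt(2) * e$values, w = e$vectors[1, ]^2)
    cache
  }
})

# solve a so that E_{u~N(0,1)} plogis(a + b u) = p
solve_item_intercept <- function(p, b) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (b == 0) return(stats::qlogis(p))
  gh <- gauss_hermite_normal()
  marg <- function(a) sum(gh$w * stats::plogis(a + b * gh$x)) - p
  stats::uniroot(marg, c(-20, 20), tol = 1e-10)$root
}

# frequency-scale level conditional on the high/low indicator: triangular
# weights peaked just at/below the item threshold
draw_levels <- function(high, min_level) {
  sample_levels <- function(levels, k, w) {
    if (length(levels) == 1L) rep(levels, k)
    else sample(levels, k, replace = TRUE, prob = w)
  }
  n <- length(high)
  out <- integer(n)
  hi_levels <- min_level:6
  lo_levels <- 0:(min_level - 1)
  n_hi <- sum(high == 1L)
  if (n_hi > 0) {
    out[high == 1L] <- sample_levels(hi_levels, n_hi,
                                     rev(seq_along(hi_levels)))
  }
  if (n - n_hi > 0) {
    out[high == 0L] <- sample_levels(lo_levels, n - n_hi,
                                     seq_along(lo_levels))
  }
  out
}

draw_cat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

#' Draw a source population
#'
#' Samples `n` individuals with covariates from the configured
#' prevalences (independently, which is stated in the provenance),
#' genotypes from the configured distribution (Hardy-Weinberg when an
#' allele frequency is given), and food-frequency responses from the
#' latent-factor item model. Deterministic given the RNG state.
#'
#' @param config A [generator_config()].
#' @param n Population size (default `config$population_n`).
#' @return Data frame, one row per individual, in the subject schema of
#'   [read_subjects()] (without `status`).
#' @export
sample_population <- function(config, n = config$population_n) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("population size must be >= 1", call. = FALSE)
  cp <- config$covariate_probs
  # truncated-normal age
  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean,
                      config$age_sd)
  pop <- data.frame(
    sex = factor(ifelse(stats::runif(n) < config$sex_p_male, "male",
                        "female"), levels = c("female", "male")),
    age = age,
    education = draw_cat(n, cp$education),
    hair_colour = draw_cat(n, cp$hair_colour),
    photo_type = draw_cat(n, cp$photo_type),
    skin_colour = draw_cat(n, cp$skin_colour),
    freckles = stats::rbinom(n, 1L, cp$freckles),
    nevi = draw_cat(n, cp$nevi),
    lentigines = draw_cat(n, cp$lentigines),
    family_history = stats::rbinom(n, 1L, cp$family_history),
    chronic_excl_cvd = stats::rbinom(n, 1L, cp$chronic_excl_cvd),
    chronic_incl_cvd = stats::rbinom(n, 1L, cp$chronic_incl_cvd),
    sunburn_child = stats::rbinom(n, 1L, cp$sunburn_child),
    bmi_cat = draw_cat(n, cp$bmi_cat),
    smoking = draw_cat(n, cp$smoking),
    cox2_inhibitor = stats::rbinom(n, 1L, cp$cox2_inhibitor),
    aspirin = stats::rbinom(n, 1L, cp$aspirin),
    sun_hours_cat = draw_cat(n, cp$sun_hours_cat),
    genotype = factor(sample(names(config$genotype_probs), n,
                             replace = TRUE, prob = config$genotype_probs),
                      levels = c("GG", "GC", "CC")))
  # FFQ items: shared latent healthy-eating factor
  u <- stats::rnorm(n)
  b <- config$item_loading
  def <- default_score_definition()
  for (nm in names(def)) {
    a <- solve_item_intercept(config$item_p[[nm]], b)
    high <- stats::rbinom(n, 1L, stats::plogis(a + b * u))
    if (def[[nm]]$kind == "frequency") {
      pop[[nm]] <- draw_levels(high, def[[nm]]$min_level)
    } else {
      pop[[nm]] <- high
    }
  }
  pop
}

#' Assign disease status from the logistic disease model
#'
#' Computes each individual's diet score (published cut-points), builds
#' the configured logit-linear predictor and draws disease status.
#'
#' @param population Output of [sample_population()].
#' @param config A [generator_config()].
#' @return `population` with added `diet_score`, `diet_tercile` and 0/1
#'   `status` columns.
#' @export
assign_disease <- function(population, config) {
  stopifnot(inherits(config, "generator_config"))
  d <- config$disease
  pop <- score_subjects(population)
  t2 <- pop$diet_tercile == "medium"
  t3 <- pop$diet_tercile == "high"
  carrier <- pop$genotype %in% c("GC", "CC")
  lp <- d$intercept +
    d$beta_t2 * t2 + d$beta_t3 * t3 +
    d$gamma_t2 * (t2 & carrier) + d$gamma_t3 * (t3 & carrier) +
    d$sex_male * (pop$sex == "male") +
    d$age_per_year * (pop$age - 52) +
    d$education_mid * (pop$education == "8-13") +
    d$education_high * (pop$education == ">13") +
    d$nevi_high * (pop$nevi == ">=60") +
    d$photo_i_ii * (pop$photo_type == "I-II") +
    d$lentigines_high * (pop$lentigines == "high") +
    d$sunburn * (pop$sunburn_child == 1L)
  pop$status <- stats::rbinom(nrow(pop), 1L, stats::plogis(lp))
  pop
}

age_stratum <- function(age) {
  cut(age, breaks = seq(18, 98, by = 5), right = FALSE,
      include.lowest = TRUE)
}

# largest-remainder apportionment of `total` over `weights`
apportion <- function(weights, total) {
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Draw a frequency-matched case-control study
#'
#' Samples `n_cases` diseased individuals at random, then controls from
#' the non-diseased so the control distribution over sex x 5-year age
#' strata matches the cases' (largest-remainder apportionment; with equal
#' case and control totals the per-cell counts match exactly). Configured
#' missingness is applied afterwards.
#'
#' @param population Output of [assign_disease()].
#' @param config A [generator_config()].
#' @return Data frame of class `"aid_study"` with an `id` column and a
#'   `provenance` attribute; cases first, then controls.
#' @export
draw_case_control <- function(population, config) {
  stopifnot(inherits(config, "generator_config"),
            "status" %in% names(population))
  diseased <- which(population$status == 1L)
  healthy <- which(population$status == 0L)
  if (length(diseased) < config$n_cases) {
    stop("population has ", length(diseased), " diseased individuals; ",
         config$n_cases, " cases requested", call. = FALSE)
  }
  cases <- sample(diseased, config$n_cases)
  if (config$match_mode == "frequency") {
    cell <- interaction(population$sex, age_stratum(population$age),
                        drop = FALSE)
    case_counts <- table(cell[cases])
    targets <- apportion(as.numeric(case_counts), config$n_controls)
    names(targets) <- names(case_counts)
    targets <- targets[targets > 0]
    controls <- integer(0)
    for (cl in names(targets)) {
      avail <- healthy[cell[healthy] == cl]
      if (length(avail) < targets[[cl]]) {
        stop("infeasible matching cell '", cl, "': need ", targets[[cl]],
             " control(s), ", length(avail), " available", call. = FALSE)
      }
      controls <- c(controls,
                    if (length(avail) == 1L) avail
                    else sample(avail, targets[[cl]]))
    }
  } else {
    if (length(healthy) < config$n_controls) {
      stop("not enough non-diseased individuals for the control series",
           call. = FALSE)
    }
    controls <- sample(healthy, config$n_controls)
  }
  study <- population[c(cases, controls), , drop = FALSE]
  rownames(study) <- NULL
  study <- cbind(id = sprintf("S%05d", seq_len(nrow(study))), study)
  # configured missingness
  for (col in names(config$missingness)) {
    rate <- config$missingness[[col]]
    if (rate > 0 && col %in% names(study)) {
      study[[col]][stats::runif(nrow(study)) < rate] <- NA
    }
  }
  study$genotype_pooled <- pool_c_carriers(study$genotype)
  class(study) <- c("aid_study", "data.frame")
  attr(study, "provenance") <- list(
    seed = config$seed, config_hash = config_hash(config),
    population_n = nrow(population),
    prevalence = mean(population$status))
  study
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate a complete study dataset
#'
#' Runs the exposure-first causal chain: covariates and diet, then
#' disease, then case-control sampling with frequency matching. The
#' population size is taken from the config or, when `NULL`, sized
#' automatically from a 20,000-individual pilot prevalence estimate with
#' a 30% safety margin.
#'
#' @param config A [generator_config()] (default: the packaged
#'   calibration).
#' @param seed Integer seed; defaults to `config$seed`, falling back to
#'   20240523.
#' @return An `"aid_study"` data frame (see [draw_case_control()]).
#' @export
#' @examples
#' \donttest{
#' study <- simulate_study(generator_config(n_cases = 100,
#'                                          n_controls = 100), seed = 7)
#' table(study$status)
#' }
simulate_study <- function(config = calibration_default(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- 20240523L
  config$seed <- as.integer(seed)
  set.seed(config$seed)
  n_pop <- config$population_n
  if (is.null(n_pop)) {
    pilot <- assign_disease(sample_population(config, 20000L), config)
    prev <- max(mean(pilot$status), 1e-4)
    n_pop <- ceiling(1.3 * max(config$n_cases / prev,
                               config$n_controls / (1 - prev)))
  }
  pop <- assign_disease(sample_population(config, n_pop), config)
  draw_case_control(pop, config)
}
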