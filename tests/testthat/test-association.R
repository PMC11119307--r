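test_that("crosstab reproduces the printed tercile count cells", {
  tab2 <- data.frame(
    status = rep(c(1, 0), c(273, 269)),
    diet_tercile = factor(c(rep(c("low", "medium", "high"),
                                c(137, 95, 41)),
                            rep(c("low", "medium", "high"),
                                c(107, 78, 84))),
                          levels = c("low", "medium", "high")))
  ct <- crosstab(tab2, "diet_tercile")
  expect_identical(ct[, "case"], c(low = 137L, medium = 95L, high = 41L))
  expect_identical(ct[, "control"], c(low = 107L, medium = 78L,
                                      high = 84L))
  expect_identical(attr(ct, "n_missing"), 0L)
  # unit counts
  small <- data.frame(status = c(1, 0),
                      e = factor(c("low", "high"),
                                 levels = c("low", "high")))
  expect_identical(as.integer(crosstab(small, "e")), c(1L, 0L, 0L, 1L))
  # missing exposures excluded and counted; all-missing errors
  tab2$diet_tercile[1:10] <- NA
  expect_identical(attr(crosstab(tab2, "diet_tercile"), "n_missing"), 10L)
  tab2$diet_tercile[] <- NA
  expect_error(crosstab(tab2, "diet_tercile"), "no usable subjects")
})

test_that("crude odds ratio and Woolf interval match hand arithmetic", {
  # childhood sunburn counts: (93 * 176) / (121 * 58)
  est <- crude_or(93, 121, 58, 176)
  expect_equal(est$or, 93 * 176 / (121 * 58), tolerance = 1e-12)
  expect_equal(est$or, 2.3323, tolerance = 1e-4)
  se <- sqrt(1 / 93 + 1 / 121 + 1 / 58 + 1 / 176)
  expect_equal(log(est$ci_low), log(est$or) - qnorm(0.975) * se,
               tolerance = 1e-12)
  expect_identical(length(est$adjusted_for), 0L)
  # identity table and inversion symmetry
  expect_equal(crude_or(1, 1, 1, 1)$or, 1)
  expect_equal(crude_or(58, 176, 93, 121)$or, 1 / est$or,
               tolerance = 1e-12)
  # CI brackets the estimate and narrows as all cells scale up
  expect_true(est$ci_low <= est$or && est$or <= est$ci_high)
  est4 <- crude_or(4 * 93, 4 * 121, 4 * 58, 4 * 176)
  expect_lt(log(est4$ci_high) - log(est4$ci_low),
            log(est$ci_high) - log(est$ci_low))
  # zero cells
  expect_error(crude_or(0, 5, 5, 5), "zero cell")
  expect_equal(crude_or(0, 5, 5, 5, continuity = TRUE)$or,
               0.5 * 5.5 / (5.5 * 5.5), tolerance = 1e-12)
})

test_that("chi-square test matches the closed-form 2x2 statistic", {
  expect_equal(chi_square_test(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chi_square_test(rbind(c(10, 10), c(10, 10)))$p_value, 1)
  # n(ad - bc)^2 / (r1 r2 c1 c2)
  got <- chi_square_test(rbind(c(20, 10), c(10, 20)))
  expect_equal(got$statistic, 60 * (20 * 20 - 10 * 10)^2 / 30^4,
               tolerance = 1e-12)
  expect_identical(got$df, 1L)
  expect_equal(chi_square_test(cbind(c(5, 7, 9), c(5, 7, 9)))$statistic,
               0, tolerance = 1e-12)
  expect_error(chi_square_test(rbind(c(0, 0), c(5, 5))), "zero")
})

test_that("Mann-Whitney U counts exceeding pairs and handles ties", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$statistic, 0)
  expect_equal(mann_whitney_u(c(1, 3), 2)$statistic, 1)
  # identical samples: two-sided p is 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney_u(rep(2, 5), rep(2, 6))$p_value, 1)
  # large-sample normal approximation agrees with a direct z oracle
  set.seed(3)
  x <- round(rnorm(60), 1)
  y <- round(rnorm(70, 0.3), 1)
  got <- mann_whitney_u(x, y)
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ties <- table(c(x, y))
  n <- length(x) + length(y)
  v <- length(x) * length(y) / 12 *
    (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - length(x) * length(y) / 2) / sqrt(v)
  expect_equal(got$statistic, u)
  expect_equal(got$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("logistic fit on a saturated 2x2 design equals the crude OR", {
  d <- data.frame(status = rep(c(1, 1, 1, 0, 0, 0), 10),
                  x = rep(c(1, 1, 0, 1, 0, 0), 10))
  fit <- fit_logistic(status ~ x, d)
  expect_equal(exp(unname(coef(fit)["x"])), 4.0, tolerance = 1e-9)
  # dual route: matches crude_or on the same cells to 6 significant digits
  ct <- crude_or(20, 10, 10, 20)
  expect_equal(exp(unname(coef(fit)["x"])), ct$or, tolerance = 1e-6)
  expect_equal(fit$or_table$ci_low[fit$or_table$term == "x"], ct$ci_low,
               tolerance = 1e-6)
  expect_identical(fit$n, 60L)
})

test_that("logistic fit flags null effects, separation and bad inputs", {
  set.seed(42)
  d <- direct_design(4000, beta_x = 0)
  fit <- fit_logistic(status ~ x + z, d)
  expect_lt(abs(coef(fit)["x"]), 0.15)
  # perfectly predictive exposure
  sep <- data.frame(status = rep(c(1, 0), each = 20),
                    x = rep(c(1, 0), each = 20))
  expect_error(fit_logistic(status ~ x, sep), "separation")
  expect_error(fit_logistic(status ~ nope, d), "not in data")
  # complete-case behaviour: missing rows are dropped, n records it
  d$z[1:100] <- NA
  expect_identical(fit_logistic(status ~ x + z, d)$n, 3900L)
})

test_that("Wald trend test equals the normal-CDF oracle", {
  set.seed(9)
  n <- 3000
  t_ord <- sample(0:2, n, replace = TRUE)
  d <- data.frame(t_ord = t_ord,
                  status = rbinom(n, 1, plogis(-0.2 - 0.45 * t_ord)))
  fit <- fit_logistic(status ~ t_ord, d)
  tr <- wald_trend_test(fit, "t_ord")
  z <- coef(fit)["t_ord"] / sqrt(vcov(fit)["t_ord", "t_ord"])
  expect_equal(tr$statistic, unname(z), tolerance = 1e-12)
  expect_equal(tr$p_value, unname(2 * pnorm(-abs(z))), tolerance = 1e-12)
  expect_lt(tr$p_value, 0.05)  # monotone protective truth at large n
  expect_error(wald_trend_test(fit, "ghost"), "not in the fitted model")
})

test_that("likelihood-ratio test is non-negative, coding-invariant and
           enforces nesting on identical rows", {
  set.seed(5)
  d <- direct_design(800, beta_x = 0.7)
  cc <- d[complete.cases(d), ]
  f0 <- fit_logistic(status ~ z, cc)
  f1 <- fit_logistic(status ~ z + x, cc)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_gte(lrt$statistic, 0)
  expect_identical(lrt$df, 1L)
  # identical model: statistic 0, p 1
  self <- likelihood_ratio_test(f1, f1)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # invariant to reparameterising the categorical coding
  cc$xf <- factor(cc$x, levels = c(1, 0))
  f1b <- fit_logistic(status ~ z + xf, cc)
  expect_equal(likelihood_ratio_test(f0, f1b)$statistic, lrt$statistic,
               tolerance = 1e-9)
  # different rows refuse to compare
  f0small <- fit_logistic(status ~ z, cc[-1, ])
  expect_error(likelihood_ratio_test(f0small, f1), "different rows")
  # non-nested specs refuse to compare
  cc$w <- rnorm(nrow(cc))
  fw <- fit_logistic(status ~ w, cc)
  expect_error(likelihood_ratio_test(fw, f1), "not nested")
})

test_that("adding the true exposure at large n is decisively detected", {
  set.seed(17)
  d <- direct_design(10000, beta_x = 0.5)
  f0 <- fit_logistic(status ~ z, d)
  f1 <- fit_logistic(status ~ z + x, d)
  expect_lt(likelihood_ratio_test(f0, f1)$p_value, 0.001)
})

test_that("logistic estimates recover known log-odds over replicates", {
  # 200 replicates at n = 5,000: mean estimate within 3 MC SEs of truth
  set.seed(20240523)
  truth <- log(0.29)
  est <- replicate(200, {
    d <- direct_design(5000, beta_x = truth)
    unname(coef(fit_logistic(status ~ x + z, d))["x"])
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * mc_se)
})

test_that("interaction test needs a varying modifier and detects crossover", {
  set.seed(31)
  d <- direct_study(8000, beta_t3 = -0.8, gamma_t3 = 1.6)
  strong <- interaction_test(d, covariates = "z")
  expect_lt(strong$p_value, 0.001)
  expect_identical(strong$df, 2L)
  d$genotype_pooled[] <- "GG"
  expect_error(interaction_test(d, covariates = "z"),
               "interaction not estimable")
})

test_that("stratified estimates are per-stratum fits with an
           unavailability flag for tiny strata", {
  set.seed(13)
  half <- direct_study(3000, beta_t3 = -1)
  half$genotype_pooled[] <- "GG"
  other <- half
  other$genotype_pooled[] <- "C_carrier"
  both <- rbind(half, other)  # identical data in the two strata
  res <- stratified_estimates(both, covariates = "z")
  expect_identical(nrow(res), 4L)
  gg <- res[res$stratum == "GG", ]
  cc <- res[res$stratum == "C_carrier", ]
  expect_equal(gg$or, cc$or, tolerance = 1e-9)
  expect_true(all(res$available))
  # a 3-subject stratum cannot support the fit
  tiny <- rbind(half, other[1:3, ])
  res2 <- stratified_estimates(tiny, covariates = "z")
  expect_false(any(res2$available[res2$stratum == "C_carrier"]))
  expect_true(all(res2$available[res2$stratum == "GG"]))
  expect_error(stratified_estimates(half, covariates = "z"),
               ">= 2 observed levels")
})
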