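# Shared fixtures: FFQ record builders, an independent brute-force scorer,
# and small direct logistic designs (cheaper than full study simulations
# where only the fitting machinery is under test).

ffq_items <- c("green_leafy", "salad", "veg_general", "citrus", "fruits",
               "nuts", "coffee", "fish_n3")
habit_items <- c("olive_oil", "rosemary", "salvia")

make_record <- function(...) {
  rec <- as.list(c(setNames(rep(0L, length(ffq_items)), ffq_items),
                   setNames(rep(0L, length(habit_items)), habit_items)))
  over <- list(...)
  rec[names(over)] <- over
  rec
}

max_record <- function() {
  make_record(green_leafy = 6L, salad = 6L, veg_general = 6L, citrus = 6L,
              fruits = 6L, nuts = 6L, coffee = 6L, fish_n3 = 6L,
              olive_oil = 1L, rosemary = 1L, salvia = 1L)
}

random_record <- function(na_prob = 0) {
  rec <- make_record()
  for (nm in ffq_items) rec[[nm]] <- sample(0:6, 1)
  for (nm in habit_items) rec[[nm]] <- sample(0:1, 1)
  if (na_prob > 0) {
    for (nm in c(ffq_items, habit_items)) {
      if (runif(1) < na_prob) rec[[nm]] <- NA_integer_
    }
  }
  rec
}

# Independent oracle: qualifying-level sets enumerated directly from the
# seven-point scale, written without reference to the scoring code.
oracle_score <- function(rec) {
  qualifying <- list(green_leafy = 4:6, salad = 4:6, veg_general = 5:6,
                     citrus = 5:6, fruits = 6L, coffee = 6L, nuts = 3:6,
                     fish_n3 = 3:6)
  s <- 0L
  for (nm in names(qualifying)) {
    v <- rec[[nm]]
    if (!is.null(v) && length(v) == 1L && !is.na(v) &&
        v %in% qualifying[[nm]]) {
      s <- s + 1L
    }
  }
  for (nm in c("olive_oil", "rosemary", "salvia")) {
    v <- rec[[nm]]
    if (!is.null(v) && length(v) == 1L && !is.na(v) && v == 1L) s <- s + 1L
  }
  s
}

# direct logistic design: binary exposure + one continuous covariate
direct_design <- function(n, beta_x = 0, beta_z = 0.5, intercept = -0.4) {
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  data.frame(x = x, z = z,
             status = rbinom(n, 1, plogis(intercept + beta_x * x +
                                            beta_z * z)))
}

# minimal analysable study table without the generator (used by the
# association tests): diet tercile + pooled genotype + model-A covariates
direct_study <- function(n, p_t = c(0.4, 0.3, 0.3), beta_t2 = 0,
                         beta_t3 = 0, p_carrier = 0.4, gamma_t3 = 0) {
  tercile <- factor(sample(c("low", "medium", "high"), n, replace = TRUE,
                           prob = p_t), levels = c("low", "medium", "high"))
  carrier <- factor(sample(c("GG", "C_carrier"), n, replace = TRUE,
                           prob = c(1 - p_carrier, p_carrier)),
                    levels = c("GG", "C_carrier"))
  z <- rnorm(n)
  lp <- -0.3 + beta_t2 * (tercile == "medium") +
    beta_t3 * (tercile == "high") +
    gamma_t3 * (tercile == "high" & carrier == "C_carrier") + 0.4 * z
  data.frame(status = rbinom(n, 1, plogis(lp)), diet_tercile = tercile,
             genotype_pooled = carrier, z = z)
}
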