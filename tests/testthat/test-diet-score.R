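test_that("item indicators follow the published per-item thresholds", {
  # green leafy / salad qualify from 3-4 times weekly (level 4)
  expect_identical(item_indicator("green_leafy", 4L), 1L)
  expect_identical(item_indicator("green_leafy", 3L), 0L)
  expect_identical(item_indicator("salad", c(3L, 4L, 6L)), c(0L, 1L, 1L))
  # citrus / vegetables in general from 5-7 times weekly (level 5)
  expect_identical(item_indicator("citrus", c(4L, 5L)), c(0L, 1L))
  expect_identical(item_indicator("veg_general", 5L), 1L)
  # fruits / coffee only at daily: 5-7 weekly is still below daily
  expect_identical(item_indicator("coffee", 5L), 0L)
  expect_identical(item_indicator("fruits", 6L), 1L)
  # nuts / n-3 fish from weekly (level 3); never cannot be high
  expect_identical(item_indicator("fish_n3", 3L), 1L)
  expect_identical(item_indicator("nuts", 0L), 0L)
  # habits are yes/no
  expect_identical(item_indicator("olive_oil", c(0L, 1L)), c(0L, 1L))
  expect_error(item_indicator("polenta", 3L), "unknown item")
  expect_error(item_indicator("nuts", 9L), "0..6")
  expect_error(item_indicator("rosemary", 4L), "binary")
})

test_that("score sums the eleven indicators and spans 0..11", {
  expect_identical(compute_score(max_record())$score, 11L)
  expect_identical(compute_score(make_record())$score, 0L)
  # hand-summed mixed record: 1+0+1+0+1+1+1+0+1+0+0 = 6
  rec <- make_record(green_leafy = 4L, salad = 2L, veg_general = 5L,
                     citrus = 3L, fruits = 6L, nuts = 3L, coffee = 6L,
                     fish_n3 = 2L, olive_oil = 1L, rosemary = 0L,
                     salvia = 0L)
  expect_identical(compute_score(rec)$score, 6L)
})

test_that("missing items count as low by default and error under strict", {
  rec <- max_record()
  rec$coffee <- NA_integer_
  rec$salvia <- NULL
  res <- compute_score(rec)
  expect_identical(res$score, 9L)
  expect_identical(res$n_missing_items, 2L)
  expect_error(compute_score(rec, missing_policy = "strict"),
               "missing item")
})

test_that("published cut-points partition 0..11 into the printed terciles", {
  got <- categorize_score(0:11)
  expect_equal(as.character(got),
               rep(c("low", "medium", "high"), c(6, 2, 4)))
  # each score maps to exactly one contiguous category
  expect_false(anyNA(got))
  expect_true(all(diff(as.integer(got)) >= 0))
  expect_error(categorize_score(12L), "out of range")
})

test_that("control-derived cut-points match hand-enumerated terciles", {
  # uniform over 0..11: empirical 1/3, 2/3 quantiles at 3 and 7
  cp <- control_tercile_cutpoints(rep(0:11, each = 10))
  expect_identical(c(cp$low_max, cp$medium_max), c(3L, 7L))
  # a control distribution whose terciles fall at 5 and 7 reproduces the
  # published cut-points
  cp2 <- control_tercile_cutpoints(rep(c(5L, 7L, 9L), each = 30))
  expect_identical(c(cp2$low_max, cp2$medium_max), c(5L, 7L))
  expect_warning(cp3 <- control_tercile_cutpoints(rep(6L, 50)),
                 "degenerate")
  expect_true(isTRUE(attr(cp3, "degenerate")))
  expect_error(control_tercile_cutpoints(integer(0)), "no control scores")
})

test_that("score is bounded, monotone and matches the brute-force oracle", {
  set.seed(20240523)
  for (i in 1:1000) {
    rec <- random_record(na_prob = if (i %% 5 == 0) 0.15 else 0)
    res <- compute_score(rec)
    expect_gte(res$score, 0L)
    expect_lte(res$score, 11L)
    expect_identical(res$score, oracle_score(rec))
    # raising one item's response never decreases the score
    nm <- sample(names(rec), 1)
    v <- rec[[nm]]
    cap <- if (nm %in% habit_items) 1L else 6L
    if (!is.na(v) && v < cap) {
      rec2 <- rec
      rec2[[nm]] <- v + 1L
      expect_gte(compute_score(rec2)$score, res$score)
    }
  }
})

test_that("vectorised table scoring agrees with per-record scoring", {
  set.seed(7)
  recs <- lapply(1:40, function(i) random_record(na_prob = 0.1))
  tab <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  scored <- score_subjects(tab)
  expect_equal(scored$diet_score,
               vapply(recs, function(r) compute_score(r)$score, integer(1)))
  expect_equal(scored$diet_tercile, categorize_score(scored$diet_score))
  expect_error(score_subjects(tab, missing_policy = "strict"), "strict")
  expect_error(score_subjects(tab[, -1]), "missing item column")
})

test_that("score definition round-trips through YAML and ships as extdata", {
  path <- tempfile(fileext = ".yaml")
  write_score_definition(default_score_definition(), path)
  expect_identical(read_score_definition(path), default_score_definition())
  shipped <- read_score_definition(
    system.file("extdata", "anti_inflammatory_score.yaml",
                package = "aidiet"))
  expect_identical(shipped, default_score_definition())
})
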