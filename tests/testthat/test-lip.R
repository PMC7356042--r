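test_that("fold change is the ratio of group means", {
  expect_equal(fold_change(c(100, 110, 90), c(100, 110, 90)), 1)
  expect_equal(fold_change(c(200, 220, 180), c(100, 110, 90)), 2)
  expect_error(fold_change(c(100, -5), c(100, 100)), "positive")
  expect_error(fold_change(numeric(0), c(1, 2)), "non-empty")
})

test_that("fold change is symmetric and scale invariant", {
  set.seed(13)
  for (i in 1:20) {
    a <- rlnorm(3, 10, 0.3)
    b <- rlnorm(3, 10, 0.3)
    expect_equal(fold_change(a, b) * fold_change(b, a), 1)
    k <- runif(1, 0.1, 50)
    expect_equal(fold_change(k * a, k * b), fold_change(a, b))
  }
})

test_that("the t-test matches an independently coded t formula", {
  trt <- c(200, 220, 180)
  ctl <- c(100, 110, 90)
  expect_equal(test_difference(trt, ctl), oracle_student_p(trt, ctl), tolerance = 1e-6)
  set.seed(17)
  for (i in 1:20) {
    a <- rlnorm(sample(2:6, 1), 11, 0.2)
    b <- rlnorm(sample(2:6, 1), 11, 0.2)
    expect_equal(test_difference(a, b), oracle_student_p(a, b), tolerance = 1e-9)
    expect_equal(
      test_difference(a, b, method = "welch"),
      t.test(a, b)$p.value,
      tolerance = 1e-12
    )
  }
})

test_that("the parametric p approximates a permutation p on well-behaved data", {
  set.seed(19)
  a <- rlnorm(8, 11.53, 0.15) # ~1.25x shift: moderate, non-degenerate p
  b <- rlnorm(8, 11.3, 0.15)
  p_t <- test_difference(a, b)
  pool <- c(a, b)
  n <- length(a)
  obs <- abs(mean(a) - mean(b))
  reps <- 20000
  stat <- replicate(reps, {
    idx <- sample(length(pool), n)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- (1 + sum(stat >= obs)) / (1 + reps)
  # MC error ~ sqrt(p(1-p)/reps) plus t-vs-permutation approximation slack
  expect_lt(abs(p_t - p_perm), 0.05)
})

test_that("degenerate zero-variance inputs follow the stated conventions", {
  expect_equal(test_difference(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_warning(p <- test_difference(c(5, 5), c(7, 7)), "zero variance")
  expect_equal(p, 0)
  expect_error(test_difference(5, c(1, 2)), "two replicates")
})

make_areas <- function(fc1 = 2, fc10 = 2, base = 1e5, noise = 0) {
  grid <- tidyr::expand_grid(condition = c("control", "1", "10"), replicate = 1:3)
  mult <- c(control = 1, `1` = fc1, `10` = fc10)[grid$condition]
  jitter <- if (noise > 0) exp(rnorm(nrow(grid), 0, noise)) else (1 + 0.01 * grid$replicate)
  tibble::tibble(
    precursor_id = "pep1", condition = grid$condition,
    replicate = grid$replicate, area = base * mult * jitter
  )
}

test_that("lip_quantify agrees with the scalar reference implementation", {
  set.seed(23)
  areas <- purrr::map_dfr(1:8, function(i) {
    a <- make_areas(fc1 = runif(1, 0.8, 2.5), fc10 = runif(1, 0.8, 2.5), noise = 0.15)
    a$precursor_id <- paste0("pep", i)
    a
  })
  stats <- lip_quantify(areas, c("1", "10"))
  for (i in 1:8) {
    id <- paste0("pep", i)
    a <- areas[areas$precursor_id == id, ]
    ctl <- a$area[a$condition == "control"]
    for (cc in c("1", "10")) {
      trt <- a$area[a$condition == cc]
      expect_equal(stats[[paste0("fc_", cc)]][stats$precursor_id == id],
        fold_change(trt, ctl),
        tolerance = 1e-12
      )
      expect_equal(stats[[paste0("p_", cc)]][stats$precursor_id == id],
        test_difference(trt, ctl),
        tolerance = 1e-9
      )
    }
  }
  # and for the Welch and log variants
  stats_w <- lip_quantify(areas, c("1", "10"), method = "log_welch")
  a <- areas[areas$precursor_id == "pep3", ]
  expect_equal(
    stats_w$p_10[stats_w$precursor_id == "pep3"],
    test_difference(a$area[a$condition == "10"], a$area[a$condition == "control"],
      method = "log_welch"
    ),
    tolerance = 1e-9
  )
})

test_that("statistics are invariant under a global area rescaling", {
  set.seed(29)
  areas <- make_areas(fc1 = 1.6, fc10 = 1.7, noise = 0.1)
  s1 <- lip_quantify(areas, c("1", "10"))
  areas2 <- dplyr::mutate(areas, area = area * 7.3)
  s2 <- lip_quantify(areas2, c("1", "10"))
  expect_equal(s1$fc_1, s2$fc_1)
  expect_equal(s1$p_1, s2$p_1)
  expect_equal(s1$protected, s2$protected)
})

test_that("the dual-concentration protection rule selects and rejects correctly", {
  # a peptide with the reference profile (fc ~1.7, tiny p at both
  # concentrations) is selected
  stats <- tibble::tibble(
    precursor_id = c("tab1_row1", "one_sided", "big_but_ns"),
    fc_1 = c(1.73, 1.80, 1.90),
    p_1 = c(0.0001, 0.0004, 0.20),
    fc_10 = c(1.74, 0.95, 1.85),
    p_10 = c(0.0003, 0.0002, 0.30)
  )
  sel <- select_protected(stats, alpha = 0.05, concentrations = c("1", "10"))
  expect_equal(sel$precursor_id, "tab1_row1")
  expect_error(select_protected(stats, concentrations = c("1", "7")), "missing")

  # a missing concentration entry in the raw areas is an error
  areas <- make_areas()
  expect_error(lip_quantify(areas, c("1", "10", "100")), "missing")
})

test_that("glance and tidy summarise lip results", {
  areas <- make_areas(fc1 = 2, fc10 = 2)
  s <- lip_quantify(areas, c("1", "10"))
  g <- glance(s)
  expect_equal(g$n_precursors, 1L)
  expect_equal(g$alpha, 0.05)
  expect_s3_class(tidy(s), "tbl_df")
})
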