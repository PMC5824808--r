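test_that("pct_genome_altered covers the toy cases", {
  grid <- tiny_grid()
  expect_equal(pct_genome_altered(profile_from_states(grid, rep(1, 10),
                                                      rep(1, 10))), 0)
  expect_equal(pct_genome_altered(profile_from_states(grid, rep(2, 10),
                                                      rep(0, 10))), 100)
  # 2 of 20 Mb altered
  p <- profile_from_states(grid, c(0, rep(1, 9)), rep(1, 10))
  expect_equal(pct_genome_altered(p), 10)
})

test_that("within/between rank-sum test has exact small-sample p", {
  # groups {1,2} within vs {3,4} between: exact two-sided p = 1/3
  r <- within_vs_between_test(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$p_value, 1 / 3)
  expect_error(within_vs_between_test(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               ">= 2 pairs")
  # shifted alternative is detected
  set.seed(1)
  w <- stats::rnorm(20)
  b <- stats::rnorm(20) + 10
  r2 <- within_vs_between_test(c(w, b), rep(c(TRUE, FALSE), each = 20))
  expect_lt(r2$p_value, 0.01)
  # null calibration: p approximately uniform
  ps <- replicate(200, within_vs_between_test(
    stats::rnorm(16), rep(c(TRUE, FALSE), 8))$p_value)
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
})

test_that("diversity correlation matches hand computation", {
  w <- c(1, 2, 3, 4)
  expect_equal(diversity_correlation(w, 2 * w)$r_squared, 1)
  x <- c(1, 3, 2, 5)
  y <- c(2, 5, 4, 4)
  r <- diversity_correlation(x, y)
  expect_equal(r$r_squared, stats::cor(x, y)^2)
  expect_equal(r$p_value, stats::cor.test(x, y)$p.value)
  expect_error(diversity_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  # independent patients: mean R^2 small at n = 8
  set.seed(2)
  r2s <- replicate(400, diversity_correlation(stats::rnorm(8),
                                              stats::rnorm(8))$r_squared)
  expect_lt(mean(r2s), 0.2)
})

test_that("permutation p for Spearman matches exhaustive enumeration", {
  pairs <- data.frame(patient_id = "p1",
                      physical = c(1, 1, 2, 2, 3, 3),
                      evolutionary = c(2, 1, 4, 3, 9, 6))
  r <- physical_vs_evolutionary(pairs, n_perm = 1e4, seed = 1)
  expect_gt(r$rho, 0.8)
  # exhaustive reference (6! = 720 <= n_perm so the code enumerates)
  perms <- cryptclock:::permutations_of(6)
  ref <- apply(perms, 1, function(i)
    stats::cor(pairs$physical, pairs$evolutionary[i], method = "spearman"))
  pexact <- mean(abs(ref) >= abs(r$rho) - 1e-12)
  expect_equal(r$p_value, pexact)
  # monotone and anti-monotone extremes
  mono <- data.frame(patient_id = "p", physical = 1:5,
                     evolutionary = c(2, 4, 5, 7, 9))
  expect_equal(physical_vs_evolutionary(mono)$rho, 1)
  mono$evolutionary <- rev(mono$evolutionary)
  expect_equal(physical_vs_evolutionary(mono)$rho, -1)
  expect_error(physical_vs_evolutionary(
    data.frame(patient_id = "p", physical = rep(1, 4),
               evolutionary = 1:4)), "constant")
  # Holm correction across patients
  two <- rbind(pairs, within(pairs, patient_id <- "p2"))
  r2 <- physical_vs_evolutionary(two, seed = 2)
  expect_equal(r2$p_corrected, stats::p.adjust(r2$p_value, "holm"))
})

test_that("gej regression recovers noiseless coefficients exactly", {
  set.seed(3)
  n <- 200
  d <- data.frame(progressor = stats::runif(n) < 0.5,
                  time_point_second = stats::runif(n) < 0.5,
                  max_gej_cm = stats::runif(n, 0, 10),
                  biopsy_distance_cm = stats::runif(n, 0, 5))
  beta <- c(14, 19, 6.5, -1.5, -1)
  d$evolutionary_distance <- beta[1] + beta[2] * d$progressor +
    beta[3] * d$time_point_second + beta[4] * d$max_gej_cm +
    beta[5] * d$biopsy_distance_cm
  fit <- suppressWarnings(gej_regression(d))  # "essentially perfect fit"
  expect_lt(max(abs(fit$table$estimate - beta)), 1e-6)
  # collinear design errors with the predictor named
  d2 <- d
  d2$biopsy_distance_cm <- 2 * d2$max_gej_cm
  expect_error(gej_regression(d2), "collinear")
  expect_error(gej_regression(d[, -1]), "missing columns")
})

test_that("gej regression is calibrated under a null predictor", {
  set.seed(4)
  tstats <- replicate(100, {
    n <- 60
    d <- data.frame(progressor = stats::runif(n) < 0.5,
                    time_point_second = stats::runif(n) < 0.5,
                    max_gej_cm = stats::runif(n, 0, 10),
                    biopsy_distance_cm = stats::runif(n, 0, 5))
    d$evolutionary_distance <- 10 + 5 * d$progressor + stats::rnorm(n, 0, 3)
    gej_regression(d)$table["max_gej_cm", "t_value"]
  })
  expect_gte(mean(abs(tstats) < 2), 0.9)
})

test_that("alterations_vs_gej computes per-patient and pooled r", {
  d5 <- data.frame(patient_id = "p1",
                   gej_distance_cm = c(0, 2, 4, 6, 8),
                   alterations = c(20, 15, 11, 6, 2))
  r <- alterations_vs_gej(d5)
  expect_equal(r$pooled$r,
               stats::cor(d5$gej_distance_cm, d5$alterations))
  expect_lt(r$pooled$r, 0)
  expect_warning(alterations_vs_gej(rbind(
    d5, data.frame(patient_id = "p2", gej_distance_cm = 1,
                   alterations = 3))), "skipped")
})
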