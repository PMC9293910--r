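test_that("pearson_bootstrap recovers exact and antisymmetric correlations", {
  x <- c(1, 2, 3, 5, 8, 9, 12)
  y <- 2 * x + 1
  res <- pearson_bootstrap(x, y, n_boot = 200, seed = 1)
  expect_equal(res$r, 1)
  res_neg <- pearson_bootstrap(-x, y, n_boot = 200, seed = 1)
  expect_equal(res_neg$r, -1)
  set.seed(3)
  xn <- rnorm(23); yn <- 0.8 * xn + 0.6 * rnorm(23)
  res2 <- pearson_bootstrap(xn, yn, n_boot = 500, seed = 2)
  expect_true(res2$ci_low <= res2$r && res2$r <= res2$ci_high)
  expect_true(res2$ci_low >= -1 && res2$ci_high <= 1)
  expect_error(pearson_bootstrap(rep(1, 5), 1:5), "constant")
})

test_that("linear calibration matches the closed-form normal equations", {
  scores <- c(2, 4, 5, 7, 11)
  ratings <- 0.5 * scores + 2
  fit <- calibrate_linear(scores, ratings)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 2)
  set.seed(9)
  s <- rnorm(23, 30, 5); r <- 0.1 * s + rnorm(23)
  fit2 <- calibrate_linear(s, r)
  want <- oracle_ols(s, r)
  expect_equal(fit2$slope, unname(want["slope"]), tolerance = 1e-10)
  expect_equal(fit2$intercept, unname(want["intercept"]), tolerance = 1e-10)
  expect_equal(mean(fit2$fitted), mean(r))                 # OLS with intercept
  expect_lt(abs(sum(fit2$residuals * s)), 1e-8 * sd(s) * 23)  # orthogonality
})

test_that("the exclusion permutation test obeys its bounds and detects signal", {
  set.seed(5)
  n <- 23; ids <- sprintf("p%02d", 1:n)
  scores <- seq_len(n)
  ratings <- 0.4 * scores + rnorm(n, 0, 0.2)
  bad <- c(2, 6, 10, 14, 18, 22)
  ratings[bad] <- ratings[bad] + c(3, -3, 3, -3, 3, -3)
  res <- correlation_increase_permutation(scores, ratings, ids, ids[bad],
                                          n_perm = 2000, seed = 1)
  expect_gte(res$p_value, 1 / (res$n_perm + 1))
  expect_lte(res$p_value, 0.01)
  expect_gt(res$delta_r_observed, 0)
  # exhaustive branch when the subset count is small
  res_ex <- correlation_increase_permutation(scores[1:8], ratings[1:8],
                                             ids[1:8], ids[1:2],
                                             n_perm = 100, seed = 1)
  expect_true(res_ex$exhaustive)
  expect_equal(res_ex$n_perm, choose(8, 2))
  expect_error(correlation_increase_permutation(scores, ratings, ids,
                                                ids[1:21]), "fewer than 3")
  expect_error(correlation_increase_permutation(scores, ratings, ids,
                                                c("nope")), "subset")
})

test_that("class discrepancies vanish on-line and track injected disagreement", {
  set.seed(7)
  classes <- rep(LETTERS[1:8], length.out = 23)
  scores <- rnorm(23, 30, 5)
  on_line <- 0.2 * scores + 1
  fit <- calibrate_linear(scores, on_line)
  disc <- class_discrepancy(fit, classes)
  expect_equal(disc$discrepancy, rep(0, 8), tolerance = 1e-10)
  # grand weighted mean of residuals is zero (OLS with intercept)
  ratings <- on_line + rnorm(23, 0, 0.5)
  ratings[classes == "B"] <- ratings[classes == "B"] + 1  # raters like B more
  fit2 <- calibrate_linear(scores, ratings)
  disc2 <- class_discrepancy(fit2, classes)
  expect_equal(sum(disc2$discrepancy * disc2$n_paths), 0, tolerance = 1e-9)
  expect_lt(disc2$discrepancy[disc2$class == "B"], 0)  # model under-estimates B
  expect_warning(class_discrepancy(fit2, rep(LETTERS[1:7], length.out = 23)),
                 "class")
})

test_that("repetition trend equals the closed-form slope", {
  res <- repetition_trend(c(3, 4.4, 5.8), c(0, 1, 2))
  expect_equal(res$slope, 1.4)
  expect_equal(repetition_trend(c(4, 4, 4), c(0, 1, 2))$slope, 0)
  set.seed(2)
  reps <- rep(0:2, each = 7)
  mr <- 3 + 0.9 * reps + rnorm(21, 0, 0.3)
  expect_equal(repetition_trend(mr, reps)$slope,
               unname(oracle_ols(reps, mr)["slope"]), tolerance = 1e-10)
  expect_error(repetition_trend(c(1, 2), c(1, 1)), "levels")
})

test_that("slope recovery returns a bracketing interval on clean data", {
  set1 <- study1_fixture()
  j <- simulate_judgments(set1$items$path_id, set1$items$rarity,
                          linking_params(seed = 9))
  rec <- recover_linking_slope(j, set1$items$rarity, n_boot = 300, seed = 2)
  expect_true(rec$ci_low <= rec$slope && rec$slope <= rec$ci_high)
  expect_gt(rec$slope, 0.8)
  expect_lt(rec$slope, 1.6)
})
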