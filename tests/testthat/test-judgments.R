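test_that("simulated ratings respect the design and the scale", {
  set1 <- study1_fixture()
  j <- simulate_judgments(set1$items$path_id, set1$items$rarity,
                          linking_params(seed = 4))
  expect_equal(nrow(j), 30 * 23)
  expect_true(all(j$rating %in% 1:7))
  j2 <- simulate_judgments(set1$items$path_id, set1$items$rarity,
                           linking_params(seed = 4))
  expect_identical(j, j2)
  j3 <- simulate_judgments(set1$items$path_id, set1$items$rarity,
                           linking_params(seed = 5))
  expect_false(identical(j$rating, j3$rating))
  expect_error(simulate_judgments(character(0), numeric(0)), "empty")
})

test_that("a zero slope produces no rarity-rating correlation", {
  set1 <- study1_fixture()
  j <- simulate_judgments(set1$items$path_id, set1$items$rarity,
                          linking_params(slope = 0, n_participants = 200,
                                         seed = 8))
  m <- path_means(j)
  r <- cor(set1$items$rarity, m$mean_rating[match(set1$items$path_id,
                                                  m$path_id)])
  expect_lt(abs(r), 0.1)
})

test_that("a noiseless positive link is monotone in the predictor", {
  set1 <- study1_fixture()
  j <- simulate_judgments(set1$items$path_id, set1$items$rarity,
                          linking_params(participant_sd = 0, trial_sd = 0,
                                         n_participants = 5, seed = 2))
  m <- path_means(j)
  mr <- m$mean_rating[match(set1$items$path_id, m$path_id)]
  ord <- order(set1$items$rarity)
  expect_true(all(diff(mr[ord]) >= 0))  # ties allowed (rounding)
  expect_gt(cor(set1$items$rarity, mr, method = "spearman"), 0.9)
})

test_that("the rarity-rating correlation is non-decreasing in the slope", {
  set1 <- study1_fixture()
  rs <- vapply(c(0.2, 0.6, 1.0, 1.4, 1.8), function(b) {
    j <- simulate_judgments(set1$items$path_id, set1$items$rarity,
                            linking_params(slope = b, seed = 13))
    m <- path_means(j)
    cor(set1$items$rarity, m$mean_rating[match(set1$items$path_id, m$path_id)])
  }, numeric(1))
  expect_true(all(diff(rs) > -0.02))  # same noise seed; slack for rounding
})
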