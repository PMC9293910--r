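test_that("the 23-path set has the specified composition", {
  set1 <- study1_fixture()
  expect_equal(nrow(set1$items), 23)
  expect_equal(sum(set1$items$class == "A"), 2)
  expect_equal(unname(table(set1$items$class)[LETTERS[2:8]]),
               rep(3L, 7), ignore_attr = TRUE)
  keys <- vapply(set1$paths, canonical_key, character(1))
  expect_equal(anyDuplicated(keys), 0)
  # class-A members are the only rarity-0 paths
  expect_equal(set1$items$rarity < 1e-9, set1$items$class == "A")
  expect_identical(build_study1_set(7)$items, set1$items)
  expect_false(identical(
    vapply(build_study1_set(8)$paths, canonical_key, character(1)),
    vapply(set1$paths, canonical_key, character(1))))
})

test_that("repetition stimuli are length-equated out-and-back variants", {
  s2 <- build_study2_set()
  expect_equal(nrow(s2$items), 21)
  expect_equal(unname(table(s2$items$condition)), rep(7L, 3),
               ignore_attr = TRUE)
  lens <- vapply(s2$paths, path_length, numeric(1))
  expect_lt(max(lens) - min(lens), 1e-9)
  # deterministic without a seed
  expect_identical(build_study2_set()$items, s2$items)
  # repetition versions revisit the origin the stated number of times
  origin_visits <- function(pid) {
    tr <- compose_path(s2$paths[[pid]])
    sum(sqrt(tr$frames$x^2 + tr$frames$y^2) < 1e-9)
  }
  expect_equal(origin_visits("s2-b2-rep0"), 1)  # start only
  expect_equal(origin_visits("s2-b2-rep1"), 2)  # start + 1 return
  expect_equal(origin_visits("s2-b2-rep2"), 3)  # start + 2 returns
  # repetition versions close; rarity rises with repetition for each basic
  for (b in 1:7) {
    r0 <- s2$items$rarity[s2$items$path_id == sprintf("s2-b%d-rep0", b)]
    r1 <- s2$items$rarity[s2$items$path_id == sprintf("s2-b%d-rep1", b)]
    r2 <- s2$items$rarity[s2$items$path_id == sprintf("s2-b%d-rep2", b)]
    expect_equal(r1, 1)
    expect_equal(r2, 1)
    expect_lt(r0, 1)
  }
  # no basic movement's second primitive retraces its first
  for (b in 1:7) {
    s <- s2$paths[[sprintf("s2-b%d-rep0", b)]]$segments
    expect_false(s[2] == retrace_primitive(s[1]))
  }
})

test_that("the bordered set selects 12 paths across classes and ratings", {
  set1 <- study1_fixture()
  j <- simulate_judgments(set1$items$path_id, set1$items$rarity,
                          linking_params(seed = 11))
  s3 <- build_study3_set(set1, j, seed = 3)
  expect_equal(length(s3$paths), 12)
  expect_equal(nrow(s3$items), 24)
  expect_setequal(unique(s3$items$condition), c("bordered", "unbordered"))
  # one of the first eight selections per a-priori class
  cls8 <- set1$items$class[match(names(s3$paths)[1:8], set1$items$path_id)]
  expect_equal(cls8, LETTERS[1:8])
  # the extra four paths all carry mean ratings >= 4.25
  means <- tapply(j$rating, j$path_id, mean)
  expect_true(all(means[names(s3$paths)[9:12]] >= 4.25))
  expect_identical(build_study3_set(set1, j, seed = 3)$items, s3$items)
  expect_equal(length(s3$worlds), 12)
  expect_true(all(vapply(s3$worlds, function(w) w$has_obstacles, logical(1))))
  # too few high-rated paths -> construction error
  low <- j; low$rating <- pmin(low$rating, 3L)
  expect_error(build_study3_set(set1, low, seed = 3), "4.25")
})
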