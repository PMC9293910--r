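test_that("compose_path renders equal-arc-length frames", {
  tr <- compose_path(path_spec(0), frames_per_primitive = 3)
  expect_equal(tr$frames$x, rep(0, 4))
  expect_equal(tr$frames$y, c(0, 1, 2, 3) / 3)
  tr2 <- compose_path(path_spec(c(0, 1)), frames_per_primitive = 3)
  expect_equal(nrow(tr2$frames), 7)
  expect_equal(tr2$frames$frame, 0:6)
  expect_equal(unlist(tr2$frames[7, c("x", "y")]), c(x = 1, y = 1))
  # consecutive frame points are distinct
  expect_true(all(rowSums(abs(diff(as.matrix(tr2$frames[, 2:3])))) > 0))
  expect_error(path_spec(c(0, 16)), "0-15")
  expect_error(path_spec(integer(0)), "at least one")
})

test_that("path_length and net_displacement match hand geometry", {
  expect_equal(path_length(path_spec(rep(0, 4))), 4)
  expect_equal(net_displacement(path_spec(rep(0, 4))), 4)
  expect_equal(path_length(path_spec(c(0, 1))), 2)
  expect_equal(net_displacement(path_spec(c(0, 1))), sqrt(2))
  expect_equal(net_displacement(path_spec(c(0, 0, 2, 2))), 0)
  # scaled paths scale both quantities
  s <- path_spec(c(0, 1), scale = 2.5)
  expect_equal(path_length(s), 5)
  expect_equal(net_displacement(s), 2.5 * sqrt(2))
})

test_that("rarity is 0 for straight paths, 1 for closed paths, in [0,1]", {
  expect_identical(rarity(path_spec(rep(0, 4))), 0)
  expect_equal(rarity(path_spec(c(0, 1))), 1 - sqrt(2) / 2)
  expect_equal(rarity(path_spec(c(0, 0, 2, 2))), 1)
  expect_equal(rarity(path_spec(c(8, 10, 12, 14))), 1)
  mat <- sample_segment_matrix(300, 4, seed = 11)
  r <- apply(mat, 1, function(s) rarity(path_spec(s)))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("transform_path commutes with the point symmetry on renderings", {
  expect_equal(transform_path(path_spec(rep(1, 4)), "rot90")$segments,
               rep(0L, 4))
  mat <- sample_segment_matrix(25, 4, seed = 5)
  for (g in list_symmetries()) {
    M <- effcomm:::.symmetry_matrices[[effcomm:::.resolve_symmetry(g)]]
    for (i in seq_len(5)) {
      sp <- path_spec(mat[i, ])
      a <- effcomm:::.traj_points(transform_path(sp, g), 4)
      b <- effcomm:::.traj_points(sp, 4) %*% t(M)
      expect_equal(a, b, tolerance = 1e-12)
      expect_equal(rarity(transform_path(sp, g)), rarity(sp))
    }
  }
  expect_error(transform_path(path_spec(0), "shear"), "unsupported")
})

test_that("inverse symmetries undo transform_path", {
  inverses <- c(identity = "identity", rot90 = "rot270", rot180 = "rot180",
                rot270 = "rot90", reflect_x = "reflect_x",
                reflect_y = "reflect_y", reflect_d = "reflect_d",
                reflect_a = "reflect_a")
  mat <- sample_segment_matrix(10, 3, seed = 9)
  for (i in seq_len(10)) {
    sp <- path_spec(mat[i, ])
    for (g in names(inverses)) {
      back <- transform_path(transform_path(sp, g), inverses[[g]])
      expect_equal(back$segments, sp$segments)
    }
  }
})

test_that("canonicalize is idempotent and matches the rendered-orbit oracle", {
  expect_equal(canonical_key(path_spec(rep(0, 4))),
               canonical_key(path_spec(rep(1, 4))))
  mat <- sample_segment_matrix(20, 4, seed = 3)
  for (i in seq_len(20)) {
    sp <- path_spec(mat[i, ])
    expect_equal(canonicalize(canonicalize(sp))$segments,
                 canonicalize(sp)$segments)
  }
  # exhaustive n = 2: grouping by canonical key equals grouping by the
  # geometric orbit signature computed on rendered coordinates
  all2 <- as.matrix(expand.grid(0:15, 0:15))
  keys <- apply(all2, 1, function(s) canonical_key(path_spec(s)))
  sigs <- apply(all2, 1, oracle_orbit_signature)
  expect_equal(length(unique(keys)), length(unique(sigs)))
  # same partition: key<->signature is a bijection on observed pairs
  expect_true(all(tapply(sigs, keys, function(x) length(unique(x))) == 1))
  expect_true(all(tapply(keys, sigs, function(x) length(unique(x))) == 1))
})

test_that("enumerate_path_space counts match brute-force orbit counting", {
  expect_equal(enumerate_path_space(1)$count, 3)
  e2 <- enumerate_path_space(2)
  all2 <- as.matrix(expand.grid(0:15, 0:15))
  expect_equal(e2$count, length(unique(apply(all2, 1, oracle_orbit_signature))))
  expect_error(enumerate_path_space(6), "memory")
  expect_error(enumerate_path_space(0), ">= 1")
})
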