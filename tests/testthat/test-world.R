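test_that("build_world lays out goals and validates geometry", {
  w <- build_world(c(0, 0, 2, 2), goal_spacing = 0.5)
  expect_equal(nrow(w$goals), 25)  # 5 x 5 lattice, no obstacles
  expect_false(w$has_obstacles)
  expect_error(build_world(c(0, 0, 0, 2)), "degenerate")
  # obstacle covering the arena except a corridor: goals survive only there
  wall <- list(type = "polygon",
               vertices = matrix(c(0.75, -1, 3, -1, 3, 3, 0.75, 3),
                                 ncol = 2, byrow = TRUE))
  wc <- build_world(c(0, 0, 2, 2), obstacles = list(wall))
  expect_true(all(wc$goals[, 1] <= 0.75))
  expect_true(nrow(wc$goals) < 25)
  # a world whose lattice is fully blocked is rejected
  everything <- list(type = "polygon",
                     vertices = matrix(c(-1, -1, 3, -1, 3, 3, -1, 3),
                                       ncol = 2, byrow = TRUE))
  expect_error(build_world(c(0, 0, 2, 2), obstacles = list(everything)),
               "no candidate goals")
})

test_that("cost_to_go is Euclidean without obstacles and near-Euclidean on the grid", {
  w <- build_world(c(-1, -1, 4, 5))
  expect_equal(cost_to_go(w, c(1, 1), c(1, 1)), 0)
  expect_equal(cost_to_go(w, c(0, 0), c(3, 4)), 5)
  g <- cost_to_go(w, c(0, 0), c(3, 4), method = "grid")
  expect_lt(abs(g - 5) / 5, 0.09)  # 8-connected discretization bound
  expect_error(cost_to_go(w, c(99, 0), c(0, 0)), "not passable")
})

test_that("grid cost around an obstacle matches an independent Dijkstra oracle", {
  wall <- list(type = "polygon",
               vertices = matrix(c(0.9, -0.5, 1.35, -0.5, 1.35, 1.6, 0.9, 1.6),
                                 ncol = 2, byrow = TRUE))
  h <- 0.25
  w <- build_world(c(0, 0, 2.5, 2.5), obstacles = list(wall),
                   grid_resolution = h)
  from <- c(0.3, 0.3); to <- c(2.2, 0.3)
  got <- cost_to_go(w, from, to)
  from_cell <- c((effcomm:::.cell_index(w, from) - 1) %% w$nx + 1,
                 (effcomm:::.cell_index(w, from) - 1) %/% w$nx + 1)
  to_cell <- c((effcomm:::.cell_index(w, to) - 1) %% w$nx + 1,
               (effcomm:::.cell_index(w, to) - 1) %/% w$nx + 1)
  want <- oracle_grid_distance(w$blocked, h, to_cell, from_cell)
  expect_equal(got, want, tolerance = 1e-9)
  expect_gt(got, sqrt(sum((from - to)^2)))  # detour around the wall
})

test_that("unreachable goals yield Inf with a warning", {
  wall <- list(type = "polygon",
               vertices = matrix(c(0.9, -1, 1.1, -1, 1.1, 3, 0.9, 3),
                                 ncol = 2, byrow = TRUE))
  w <- build_world(c(0, 0, 2, 2), obstacles = list(wall))
  expect_warning(d <- cost_to_go(w, c(0.25, 1), c(1.75, 1)), "unreachable")
  expect_identical(d, Inf)
})

test_that("bordered worlds keep the trajectory in a connected corridor", {
  tr <- compose_path(path_spec(c(0, 4, 8, 1)))
  wb <- make_bordered_world(tr, margin = 0.4)
  expect_true(wb$has_obstacles)
  pts <- effcomm:::.traj_points(tr)
  expect_true(all(is_passable(wb, pts)))
  # lakes begin strictly beyond the margin
  d <- effcomm:::.dist_to_polyline(wb$goals[, 1], wb$goals[, 2], pts)
  slack <- wb$grid_resolution * sqrt(2) / 2  # cell-center quantization
  expect_true(all(d <= 0.4 + slack | d > 0.4 + 2 - slack))
  expect_error(make_bordered_world(tr, margin = 0.01), "pinch")
})

test_that("a margin wider than the arena leaves the world obstacle-free", {
  tr <- compose_path(path_spec(c(0, 0, 0, 0)))
  wb <- make_bordered_world(tr, margin = 50)
  expect_false(wb$has_obstacles)
  s_b <- communicativeness_score(tr, wb)
  s_u <- communicativeness_score(tr, world_for(tr))
  expect_lt(abs(s_b - s_u), 1e-6)
})
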