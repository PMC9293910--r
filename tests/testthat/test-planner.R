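test_that("beta = 0 reduces every quantity to its uniform closed form", {
  tr <- compose_path(path_spec(c(0, 0, 1, 1)))
  w <- world_for(tr)
  cfg <- model_config(beta = 0)
  expect_equal(step_likelihood(w, c(0, 0), c(0, 1 / 3), w$goals[1, ], cfg),
               1 / 16)
  expect_equal(trajectory_loglik(w, tr, w$goals[5, ], cfg), -12 * log(16))
  cv <- world_directedness_curve(w, tr, cfg)
  expect_equal(cv$loglik, -(1:12) * log(16), tolerance = 1e-12)
  expect_equal(communicativeness_score(cv), 12 * log(16))
  gp <- goal_posterior(w, tr, cfg)
  expect_equal(gp$weights, rep(1 / nrow(w$goals), nrow(w$goals)))
})

test_that("candidate-step probabilities normalize and sharpen with beta", {
  tr <- compose_path(path_spec(c(0, 1)))
  w <- world_for(tr)
  cfg <- model_config(beta = 2)
  s <- c(0.2, 0.1); L <- 1 / 3
  goal <- c(0.2, 2)
  # summing the returned probability over each candidate taken as "observed"
  thetas <- pi / 2 + 2 * pi * (0:15) / 16
  total <- sum(vapply(thetas, function(th) {
    step_likelihood(w, s, L * c(cos(th), sin(th)), goal, cfg)
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-9)
  # a strongly rational agent almost surely takes a unit step straight at
  # a goal dead ahead
  p_straight <- step_likelihood(w, c(0, 0), c(0, 1), c(0, 1.5),
                                model_config(beta = 50))
  expect_gt(p_straight, 0.99)
  expect_error(step_likelihood(w, s, c(0, 0), goal, cfg), "positive length")
})

test_that("trajectory log-likelihood is additive over concatenation", {
  cfg <- model_config()
  sp12 <- path_spec(c(0, 1, 8, 2))
  tr12 <- compose_path(sp12)
  w <- world_for(tr12)
  g <- c(1, 2)
  full <- trajectory_loglik(w, tr12, g, cfg)
  pts <- effcomm:::.traj_points(tr12)
  part <- 0
  for (t in seq_len(nrow(pts) - 1)) {
    part <- part + log(step_likelihood(w, pts[t, ], pts[t + 1, ] - pts[t, ],
                                       g, cfg))
  }
  expect_equal(full, part, tolerance = 1e-10)
})

test_that("the marginal curve equals brute-force goal enumeration", {
  tr <- compose_path(path_spec(c(0, 1)))
  w <- build_world(c(-1.5, -1.5, 2.5, 2.5), goal_spacing = 1)  # 5 x 5 goals
  expect_equal(nrow(w$goals), 25)
  cfg <- model_config()
  cv <- world_directedness_curve(w, tr, cfg)
  pts <- effcomm:::.traj_points(tr)
  probs <- matrix(NA_real_, 6, nrow(w$goals))
  for (gi in seq_len(nrow(w$goals))) {
    for (t in 1:6) {
      probs[t, gi] <- step_likelihood(w, pts[t, ], pts[t + 1, ] - pts[t, ],
                                      w$goals[gi, ], cfg)
    }
  }
  direct <- log(rowMeans(apply(probs, 2, cumprod)))  # linear-space product
  expect_equal(cv$loglik, direct, tolerance = 1e-8)
})

test_that("world-directedness never increases over time", {
  mat <- sample_segment_matrix(8, 4, seed = 31)
  cfg <- model_config()
  for (i in seq_len(nrow(mat))) {
    tr <- compose_path(path_spec(mat[i, ]))
    cv <- world_directedness_curve(world_for(tr), tr, cfg)
    expect_true(all(diff(cv$loglik) <= 1e-9))
    expect_gte(cv$score, 0)
  }
})

test_that("straight paths score below closed loops of equal length", {
  tr_straight <- compose_path(path_spec(c(0, 0, 0, 0)))
  tr_loop <- compose_path(path_spec(c(0, 1, 2, 3)))
  w <- world_for(list(tr_straight, tr_loop))
  cfg <- model_config()
  expect_lt(communicativeness_score(tr_straight, w, cfg),
            communicativeness_score(tr_loop, w, cfg))
})

test_that("scores are invariant under square symmetries of the scene", {
  sp <- path_spec(c(0, 4, 8, 1))
  cfg <- model_config()
  tr <- compose_path(sp)
  s0 <- communicativeness_score(tr, world_for(tr), cfg)
  for (g in c("rot90", "rot180", "reflect_x", "reflect_d")) {
    tg <- compose_path(transform_path(sp, g))
    expect_equal(communicativeness_score(tg, world_for(tg), cfg), s0,
                 tolerance = 1e-6)
  }
})

test_that("repeating an out-and-back path raises its score monotonically", {
  cfg <- model_config()
  base <- c(0, 1)
  cycle <- c(base, retrace_primitive(rev(base)))
  scores <- vapply(1:3, function(k) {
    tr <- compose_path(path_spec(rep(cycle, k)))
    communicativeness_score(tr, world_for(tr), cfg)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("goal posterior weights are a proper distribution peaked ahead", {
  tr <- compose_path(path_spec(c(0, 0, 0, 0)))
  w <- world_for(tr)
  gp <- goal_posterior(w, tr, model_config())
  expect_equal(sum(gp$weights), 1, tolerance = 1e-9)
  expect_true(all(gp$weights >= 0))
  best <- gp$goals[which.max(gp$weights), ]
  endpoint <- c(0, 4)
  expect_gte(best[2], endpoint[2])  # ahead of (or at) the final position
})

test_that("blocked alternatives in a corridor lower the score", {
  cfg <- model_config(cost_method = "grid")
  for (segs in list(c(0, 4, 8, 1), c(8, 10, 12, 14), c(5, 5, 0, 0))) {
    tr <- compose_path(path_spec(segs))
    s_b <- communicativeness_score(tr, make_bordered_world(tr), cfg)
    s_u <- communicativeness_score(tr, world_for(tr), cfg)
    expect_lte(s_b, s_u)
  }
})

test_that("trajectories leaving the world are rejected", {
  tr <- compose_path(path_spec(c(0, 0, 0, 0)))
  w <- build_world(c(-1, -1, 1, 2))  # too short for the path
  expect_error(world_directedness_curve(w, tr, model_config()), "invalid trajectory")
})
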