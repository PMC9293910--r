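# The inverse-planning observer. An agent pursuing a world-directed goal g
# is modelled as noisy-rational: at state s it chooses among candidate steps
# a with probability proportional to exp(-beta * (|a| + cost_to_go(s + a, g)))
# (a Boltzmann policy over the immediate step cost plus the remaining
# cost-to-go). Marginalising the observed step sequence over a uniform prior
# on a lattice of candidate goals gives a per-frame log marginal likelihood
# that the movement is world-directed; the negative of its final value is
# the communicativeness score.

#' Observer model configuration
#'
#' @param beta Rationality (inverse temperature), >= 0; default 2. At
#'   `beta = 0` the agent acts uniformly at random over candidate steps; as
#'   `beta` grows the agent approaches a deterministic shortest-path planner.
#' @param n_headings Number of candidate step headings per state (default
#'   16): the observed step plus `n_headings - 1` alternatives of the same
#'   length at uniformly spaced headings.
#' @param frames_per_primitive Frames per motion primitive used when scoring
#'   rendered paths (default 3, so a four-primitive path has 12 scored steps).
#' @param goal_spacing Candidate-goal lattice pitch (default 0.5).
#' @param grid_resolution Navigation-grid pitch (default 0.1).
#' @param log_floor Per-step floor for log-probabilities (default -745).
#' @param cost_method Cost-to-go method passed to [cost_to_go()]; `"auto"`
#'   uses exact Euclidean distances in obstacle-free worlds and the
#'   navigation grid otherwise. Use `"grid"` for like-for-like comparisons
#'   between bordered and unbordered worlds.
#' @return A list of class `effcomm_config`.
#' @export
model_config <- function(beta = 2, n_headings = 16L, frames_per_primitive = 3L,
                         goal_spacing = 0.5, grid_resolution = 0.1,
                         log_floor = -745,
                         cost_method = c("auto", "euclidean", "grid")) {
  cost_method <- match.arg(cost_method)
  stopifnot(beta >= 0, n_headings >= 2, goal_spacing > 0, grid_resolution > 0,
            frames_per_primitive >= 1, log_floor < 0)
  structure(list(beta = beta, n_headings = as.integer(n_headings),
                 frames_per_primitive = as.integer(frames_per_primitive),
                 goal_spacing = goal_spacing, grid_resolution = grid_resolution,
                 log_floor = log_floor, cost_method = cost_method),
            class = "effcomm_config")
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# candidate step endpoints for one state: K headings uniformly spaced
# starting at the observed heading, all of the observed step's length.
# Returns K x 2 matrix; row 1 is the observed step's endpoint.
.candidate_endpoints <- function(s, step, K) {
  L <- sqrt(sum(step^2))
  theta0 <- atan2(step[2], step[1])
  theta <- theta0 + 2 * pi * (seq_len(K) - 1L) / K
  cbind(s[1] + L * cos(theta), s[2] + L * sin(theta))
}

# per-goal cost-to-go from a set of points, vectorised
.costs_to_goal <- function(world, pts, goal, use_grid) {
  if (!use_grid) {
    sqrt((pts[, 1] - goal[1])^2 + (pts[, 2] - goal[2])^2)
  } else {
    .distance_field(world, goal)[.cell_index(world, pts)]
  }
}

.use_grid <- function(world, config) {
  switch(config$cost_method,
         auto = world$has_obstacles, euclidean = FALSE, grid = TRUE)
}

#' Probability of one observed step under a goal
#'
#' The Boltzmann policy probability of the observed step at state `s` given
#' goal `g`: candidates are the observed step plus `n_headings - 1`
#' same-length steps at uniformly spaced headings, excluding blocked ones
#' (outside bounds or ending in an obstacle); each candidate `a` has
#' probability proportional to `exp(-beta * (|a| + cost_to_go(s + a, g)))`.
#'
#' @param world An [build_world()] object.
#' @param s Length-2 passable state.
#' @param step_obs Length-2 observed displacement (non-zero).
#' @param g Length-2 goal location.
#' @param config An [model_config()].
#' @return The observed step's probability (candidate probabilities sum to 1).
#' @export
step_likelihood <- function(world, s, step_obs, g, config = model_config()) {
  stopifnot(inherits(world, "effcomm_world"))
  if (sqrt(sum(step_obs^2)) <= 0) stop("observed step must have positive length")
  if (!is_passable(world, s)) stop("state is not passable in this world")
  ends <- .candidate_endpoints(as.numeric(s), as.numeric(step_obs),
                               config$n_headings)
  open <- is_passable(world, ends)
  if (!open[1]) stop("observed step endpoint is blocked")
  if (!any(open)) stop("degenerate state: all candidate steps are blocked")
  L <- sqrt(sum(step_obs^2))
  cost <- rep(Inf, config$n_headings)
  cost[open] <- L + .costs_to_goal(world, ends[open, , drop = FALSE],
                                   as.numeric(g), .use_grid(world, config))
  if (config$beta == 0) {
    u <- ifelse(open, 0, -Inf)
  } else {
    u <- -config$beta * cost
  }
  if (all(!is.finite(u))) stop("degenerate state: goal unreachable from every candidate")
  exp(u[1] - .logsumexp(u))
}

# matrix of observed-step log-probabilities: T steps x |G| goals
.step_logprob_matrix <- function(world, traj, config) {
  pts <- .traj_points(traj)
  if (!all(is_passable(world, pts))) {
    stop("invalid trajectory: frames outside bounds or inside an obstacle")
  }
  if (any(rowSums(abs(diff(pts))) == 0)) {
    stop("invalid trajectory: consecutive frames coincide")
  }
  Tn <- nrow(pts) - 1L
  K <- config$n_headings
  goals <- world$goals
  G <- nrow(goals)
  use_grid <- .use_grid(world, config)
  # candidate endpoints and step lengths for every step, precomputed
  ends <- vector("list", Tn)
  lens <- numeric(Tn)
  open <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    step <- pts[t + 1L, ] - pts[t, ]
    lens[t] <- sqrt(sum(step^2))
    ends[[t]] <- .candidate_endpoints(pts[t, ], step, K)
    open[[t]] <- is_passable(world, ends[[t]])
    if (!any(open[[t]])) stop("degenerate state: all candidate steps blocked")
  }
  out <- matrix(NA_real_, nrow = Tn, ncol = G)
  for (gi in seq_len(G)) {
    goal <- goals[gi, ]
    for (t in seq_len(Tn)) {
      op <- open[[t]]
      cost <- rep(Inf, K)
      cost[op] <- lens[t] + .costs_to_goal(world, ends[[t]][op, , drop = FALSE],
                                           goal, use_grid)
      u <- if (config$beta == 0) ifelse(op, 0, -Inf) else -config$beta * cost
      lse <- .logsumexp(u)
      out[t, gi] <- if (is.finite(lse)) u[1] - lse else -Inf
    }
  }
  pmax(out, config$log_floor)
}

#' Log-likelihood of a trajectory under one goal
#'
#' Sum over consecutive frame steps of the log Boltzmann step probability
#' given goal `g`, floored per step at `config$log_floor`.
#'
#' @param world An [build_world()] object.
#' @param traj An `effcomm_trajectory` inside the world.
#' @param g Length-2 goal location.
#' @param config An [model_config()].
#' @return Scalar log-likelihood.
#' @export
trajectory_loglik <- function(world, traj, g, config = model_config()) {
  pts <- .traj_points(traj)
  if (!all(is_passable(world, pts))) {
    stop("invalid trajectory: frames outside bounds or inside an obstacle")
  }
  total <- 0
  for (t in seq_len(nrow(pts) - 1L)) {
    p <- step_likelihood(world, pts[t, ], pts[t + 1L, ] - pts[t, ], g, config)
    total <- total + max(log(p), config$log_floor)
  }
  total
}

#' Per-frame world-directedness of a trajectory
#'
#' For each frame step `t`, the log marginal likelihood that the movement so
#' far is world-directed: `l_t = log sum_g (1/|G|) p(a_1..t | g)` over the
#' world's goal lattice with a uniform goal prior, computed stably in log
#' space. The curve is non-increasing in `t`; its final value, negated, is
#' the communicativeness score.
#'
#' @param world An [build_world()] object.
#' @param traj An `effcomm_trajectory` inside the world.
#' @param config An [model_config()].
#' @return An object of class `effcomm_curve`: list with `frames` (1..T),
#'   `loglik` (per-frame `l_t`), and `score` (`-l_T`).
#' @export
world_directedness_curve <- function(world, traj, config = model_config()) {
  M <- .step_logprob_matrix(world, traj, config)
  G <- ncol(M)
  cum <- apply(M, 2, cumsum)
  if (nrow(M) == 1L) cum <- matrix(cum, nrow = 1L)
  loglik <- apply(cum, 1, .logsumexp) - log(G)
  structure(list(frames = seq_len(nrow(M)), loglik = loglik,
                 score = -loglik[length(loglik)]),
            class = "effcomm_curve")
}

#' @export
print.effcomm_curve <- function(x, ...) {
  cat(sprintf("<world-directedness curve: %d steps, final loglik %.3f, score %.3f>\n",
              length(x$frames), x$loglik[length(x$loglik)], x$score))
  invisible(x)
}

#' Communicativeness score of a trajectory
#'
#' The negative log of the (marginal) probability that the full trajectory is
#' world-directed: `-l_T` from [world_directedness_curve()]. Higher scores
#' mean the movement more strongly reveals that it lacks a world-directed
#' goal.
#'
#' @param x An `effcomm_curve`, or an `effcomm_trajectory` (in which case
#'   `world` and `config` are used to compute the curve first).
#' @param world,config Used when `x` is a trajectory; `world` defaults to
#'   [world_for()] applied to the trajectory.
#' @return Non-negative scalar score.
#' @export
communicativeness_score <- function(x, world = NULL, config = model_config()) {
  if (inherits(x, "effcomm_curve")) return(x$score)
  stopifnot(inherits(x, "effcomm_trajectory"))
  if (is.null(world)) {
    world <- world_for(x, goal_spacing = config$goal_spacing,
                       grid_resolution = config$grid_resolution)
  }
  world_directedness_curve(world, x, config)$score
}

#' Posterior over candidate goals given a trajectory
#'
#' Normalised weights over the world's goal lattice, proportional to
#' `exp(trajectory log-likelihood)` per goal under a uniform prior.
#'
#' @param world An [build_world()] object.
#' @param traj An `effcomm_trajectory`.
#' @param config An [model_config()].
#' @return List with `goals` (matrix of lattice points) and `weights`
#'   (non-negative, summing to 1).
#' @export
goal_posterior <- function(world, traj, config = model_config()) {
  M <- .step_logprob_matrix(world, traj, config)
  ll <- colSums(M)
  floor_total <- nrow(M) * config$log_floor
  if (all(ll <= floor_total + 1e-12)) {
    warning("all goals at the log floor; returning a uniform posterior")
    w <- rep(1 / length(ll), length(ll))
  } else {
    w <- exp(ll - .logsumexp(ll))
    w <- w / sum(w)
  }
  list(goals = world$goals, weights = w)
}
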