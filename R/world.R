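# Worlds: a bounded 2-D arena with optional impassable obstacle regions
# ("lakes"), a lattice of candidate world-directed goal locations, and an
# auxiliary 8-connected navigation grid used to compute obstacle-avoiding
# cost-to-go. With no obstacles, cost-to-go is the exact Euclidean distance;
# on the grid it is the 8-connected shortest path (within the usual <= ~8%
# discretization bound of Euclidean distance).

#' Construct a world
#'
#' @param bounds Numeric length-4 vector `c(xmin, ymin, xmax, ymax)` in arena
#'   units; must have positive area.
#' @param obstacles List of obstacle descriptors. Each is either
#'   `list(type = "polygon", vertices = <n x 2 matrix>)` (an impassable
#'   polygon) or `list(type = "band", polyline = <n x 2 matrix>, margin = m,
#'   width = w)` (all points at distance in `(m, m + w]` of the polyline are
#'   impassable; this is how bordered "lake" corridors are represented).
#' @param goal_spacing Pitch of the candidate-goal lattice (default 0.5).
#' @param grid_resolution Pitch `h` of the navigation grid (default 0.1).
#' @return An object of class `effcomm_world`.
#' @export
build_world <- function(bounds, obstacles = list(), goal_spacing = 0.5,
                        grid_resolution = 0.1) {
  stopifnot(is.numeric(bounds), length(bounds) == 4)
  if (bounds[3] <= bounds[1] || bounds[4] <= bounds[2]) {
    stop("degenerate world: bounds must have positive area")
  }
  stopifnot(goal_spacing > 0, grid_resolution > 0)
  h <- grid_resolution
  nx <- max(1L, as.integer(ceiling((bounds[3] - bounds[1]) / h)))
  ny <- max(1L, as.integer(ceiling((bounds[4] - bounds[2]) / h)))
  cx <- bounds[1] + (seq_len(nx) - 0.5) * h
  cy <- bounds[2] + (seq_len(ny) - 0.5) * h
  blocked <- matrix(FALSE, nrow = nx, ncol = ny)
  if (length(obstacles) > 0) {
    gx <- rep(cx, times = ny)
    gy <- rep(cy, each = nx)
    for (ob in obstacles) {
      blocked <- blocked | matrix(.obstacle_mask(ob, gx, gy), nrow = nx)
    }
  }
  has_obstacles <- any(blocked)
  gxs <- seq(bounds[1], bounds[3], by = goal_spacing)
  gys <- seq(bounds[2], bounds[4], by = goal_spacing)
  goals <- cbind(rep(gxs, times = length(gys)), rep(gys, each = length(gxs)))
  if (has_obstacles) {
    ci <- .cell_index_xy(goals[, 1], goals[, 2], bounds, h, nx, ny)
    goals <- goals[!blocked[ci], , drop = FALSE]
  }
  if (nrow(goals) == 0L) stop("world configuration leaves no candidate goals")
  structure(list(bounds = as.numeric(bounds), obstacles = obstacles,
                 goal_spacing = goal_spacing, grid_resolution = h,
                 nx = nx, ny = ny, blocked = blocked,
                 has_obstacles = has_obstacles, goals = goals,
                 cache = new.env(parent = emptyenv())),
            class = "effcomm_world")
}

#' @export
print.effcomm_world <- function(x, ...) {
  cat(sprintf(
    "<world [%g,%g]x[%g,%g]: %d goals, %d obstacle(s), grid %dx%d (h=%g)>\n",
    x$bounds[1], x$bounds[3], x$bounds[2], x$bounds[4], nrow(x$goals),
    length(x$obstacles), x$nx, x$ny, x$grid_resolution))
  invisible(x)
}

# TRUE where (gx, gy) falls inside the obstacle
.obstacle_mask <- function(ob, gx, gy) {
  if (identical(ob$type, "polygon")) {
    v <- ob$vertices
    as.logical(pracma::inpolygon(gx, gy, v[, 1], v[, 2], boundary = TRUE))
  } else if (identical(ob$type, "band")) {
    d <- .dist_to_polyline(gx, gy, ob$polyline)
    d > ob$margin & d <= ob$margin + ob$width
  } else {
    stop("unknown obstacle type: ", ob$type)
  }
}

# minimum distance from points (px, py) to a polyline (vertex matrix)
.dist_to_polyline <- function(px, py, poly) {
  m <- nrow(poly) - 1L
  best <- rep(Inf, length(px))
  for (i in seq_len(m)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    vx <- poly[i + 1L, 1] - ax; vy <- poly[i + 1L, 2] - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

# linear cell index of points (clamped into the grid)
.cell_index_xy <- function(x, y, bounds, h, nx, ny) {
  i <- pmin(nx, pmax(1L, as.integer(floor((x - bounds[1]) / h)) + 1L))
  j <- pmin(ny, pmax(1L, as.integer(floor((y - bounds[2]) / h)) + 1L))
  (j - 1L) * nx + i
}

.cell_index <- function(world, pts) {
  pts <- matrix(pts, ncol = 2)
  .cell_index_xy(pts[, 1], pts[, 2], world$bounds, world$grid_resolution,
                 world$nx, world$ny)
}

#' Is a point passable in a world?
#'
#' A point is passable when it lies inside the arena bounds and its
#' containing navigation-grid cell is not blocked by an obstacle.
#'
#' @param world An [build_world()] object.
#' @param pts An `n x 2` matrix (or length-2 vector) of points.
#' @return Logical vector.
#' @export
is_passable <- function(world, pts) {
  pts <- matrix(pts, ncol = 2)
  inside <- pts[, 1] >= world$bounds[1] & pts[, 1] <= world$bounds[3] &
    pts[, 2] >= world$bounds[2] & pts[, 2] <= world$bounds[4]
  if (!world$has_obstacles) return(inside)
  ci <- .cell_index(world, pts)
  inside & !world$blocked[ci]
}

# navigation graph over passable cells, built lazily and cached
.nav_graph <- function(world) {
  if (!is.null(world$cache$graph)) return(world$cache$graph)
  nx <- world$nx; ny <- world$ny; h <- world$grid_resolution
  pass <- !world$blocked
  id <- function(i, j) (j - 1L) * nx + i
  edges_from <- integer(0); edges_to <- integer(0); w <- numeric(0)
  # neighbour offsets covering each undirected edge once
  offs <- list(c(1L, 0L, h), c(0L, 1L, h),
               c(1L, 1L, h * sqrt(2)), c(-1L, 1L, h * sqrt(2)))
  ii <- rep(seq_len(nx), times = ny)
  jj <- rep(seq_len(ny), each = nx)
  for (o in offs) {
    i2 <- ii + o[1]; j2 <- jj + o[2]
    ok <- i2 >= 1L & i2 <= nx & j2 <= ny & pass[cbind(ii, jj)]
    ok[ok] <- pass[cbind(i2[ok], j2[ok])]
    edges_from <- c(edges_from, id(ii[ok], jj[ok]))
    edges_to <- c(edges_to, id(i2[ok], j2[ok]))
    w <- c(w, rep(o[3], sum(ok)))
  }
  g <- igraph::make_empty_graph(n = nx * ny, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  igraph::E(g)$weight <- w
  world$cache$graph <- g
  g
}

# grid distance field (vector over all cells) from a goal, cached per goal cell
.distance_field <- function(world, goal) {
  gcell <- .cell_index(world, goal)
  key <- as.character(gcell)
  if (!is.null(world$cache$fields[[key]])) return(world$cache$fields[[key]])
  g <- .nav_graph(world)
  d <- as.numeric(igraph::distances(g, v = gcell, algorithm = "dijkstra"))
  if (is.null(world$cache$fields)) world$cache$fields <- list()
  world$cache$fields[[key]] <- d
  d
}

#' Cost-to-go between a point and a goal
#'
#' The expected movement cost of efficiently reaching `goal` from `point`:
#' with no obstacles, the Euclidean distance; with obstacles, the length of
#' the shortest obstacle-avoiding path on the 8-connected navigation grid
#' (diagonal steps cost `h * sqrt(2)`), which overestimates the Euclidean
#' distance by at most ~8-9%. An unreachable goal yields `Inf`.
#'
#' @param world An [build_world()] object.
#' @param point Length-2 passable point.
#' @param goal Length-2 passable goal location.
#' @param method `"auto"` (Euclidean when the world has no obstacles, grid
#'   otherwise), `"euclidean"`, or `"grid"`.
#' @return Non-negative distance in arena units (`Inf` if unreachable).
#' @export
cost_to_go <- function(world, point, goal, method = c("auto", "euclidean", "grid")) {
  method <- match.arg(method)
  stopifnot(inherits(world, "effcomm_world"))
  if (!is_passable(world, point)) stop("point is not passable in this world")
  if (!is_passable(world, goal)) stop("goal is not passable in this world")
  use_grid <- switch(method, auto = world$has_obstacles,
                     euclidean = FALSE, grid = TRUE)
  if (!use_grid) {
    return(sqrt(sum((as.numeric(point) - as.numeric(goal))^2)))
  }
  d <- .distance_field(world, goal)[.cell_index(world, point)]
  if (!is.finite(d)) {
    warning("goal unreachable from point; returning Inf")
  }
  d
}

# padded bounding box of one or more trajectories
.padded_bounds <- function(trajs, pad = 1) {
  if (inherits(trajs, "effcomm_trajectory")) trajs <- list(trajs)
  xs <- unlist(lapply(trajs, function(t) t$frames$x))
  ys <- unlist(lapply(trajs, function(t) t$frames$y))
  c(min(xs) - pad, min(ys) - pad, max(xs) + pad, max(ys) + pad)
}

#' Default world for one or more trajectories
#'
#' An empty arena whose bounds are the bounding box of the trajectories
#' padded by `pad` on all sides, so that goals "beyond" the movement are
#' representable.
#'
#' @param trajs An `effcomm_trajectory` or list of them.
#' @param pad Padding in arena units (default 1).
#' @param goal_spacing,grid_resolution Passed to [build_world()].
#' @return An `effcomm_world` without obstacles.
#' @export
world_for <- function(trajs, pad = 1, goal_spacing = 0.5, grid_resolution = 0.1) {
  build_world(.padded_bounds(trajs, pad), obstacles = list(),
              goal_spacing = goal_spacing, grid_resolution = grid_resolution)
}

#' Surround a trajectory with obstacle "lakes", leaving a corridor
#'
#' Builds the bordered-condition world for a trajectory: impassable regions
#' flank the path on both sides, offset by `margin`, so that the same
#' movement becomes consistent with efficient world-directed travel through
#' the corridor. The lakes are constructed as a distance buffer around the
#' rendered polyline (all points at distance in `(margin, margin + width]`
#' are impassable), which stays well-defined for self-intersecting and
#' closed paths. Arena bounds are the trajectory bounding box padded by
#' `pad`, as in [world_for()].
#'
#' @param traj An `effcomm_trajectory`.
#' @param margin Corridor half-width in arena units (> 0; default 0.4).
#' @param width Lake thickness beyond the corridor (default 2).
#' @param pad Arena padding (default 1).
#' @param goal_spacing,grid_resolution Passed to [build_world()].
#' @return An `effcomm_world` whose corridor contains every trajectory frame.
#' @export
make_bordered_world <- function(traj, margin = 0.4, width = 2, pad = 1,
                                goal_spacing = 0.5, grid_resolution = 0.1) {
  stopifnot(inherits(traj, "effcomm_trajectory"), margin > 0, width > 0)
  poly <- .traj_points(traj)
  ob <- list(type = "band", polyline = poly, margin = margin, width = width)
  world <- build_world(.padded_bounds(traj, pad), obstacles = list(ob),
                       goal_spacing = goal_spacing,
                       grid_resolution = grid_resolution)
  if (!all(is_passable(world, poly))) {
    stop("margin too small: corridor self-pinches onto the trajectory")
  }
  if (world$has_obstacles) {
    # corridor must stay connected along the whole trajectory
    d <- .distance_field(world, poly[1, ])[.cell_index(world, poly)]
    if (!all(is.finite(d))) {
      stop("margin too small: corridor is pinched into disconnected pieces")
    }
  }
  world
}
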