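# Path specifications and their rendered trajectories.

#' Create a path specification
#'
#' A path is an ordered chain of motion primitives starting at `origin`.
#' `scale` uniformly rescales the rendered geometry (used e.g. to equate the
#' total distance traveled across stimuli); it does not affect rarity or
#' movement class, which are scale-invariant.
#'
#' @param segments Integer vector of primitive ids (0-15), length >= 1.
#' @param origin Numeric length-2 start point, default `c(0, 0)`.
#' @param scale Positive scalar geometric scale factor, default 1.
#' @return An object of class `effcomm_path`.
#' @examples
#' p <- path_spec(c(0, 1))  # north then east
#' rarity(p)
#' @export
path_spec <- function(segments, origin = c(0, 0), scale = 1) {
  segments <- as.integer(segments)
  if (length(segments) < 1L) stop("path must contain at least one segment")
  if (anyNA(segments) || any(segments < 0L | segments > 15L)) {
    stop("invalid path spec: segment ids must be integers in 0-15")
  }
  stopifnot(is.numeric(origin), length(origin) == 2,
            is.numeric(scale), length(scale) == 1, scale > 0)
  structure(list(segments = segments, origin = as.numeric(origin),
                 scale = as.numeric(scale)),
            class = "effcomm_path")
}

#' @export
print.effcomm_path <- function(x, ...) {
  cat("<path:", paste(x$segments, collapse = ","),
      "| origin", sprintf("(%g,%g)", x$origin[1], x$origin[2]),
      if (x$scale != 1) sprintf("| scale %g", x$scale) else "", ">\n")
  invisible(x)
}

#' Render a path specification into a frame-sampled trajectory
#'
#' Each primitive contributes `frames_per_primitive` equal arc-length
#' sub-steps (arcs are subdivided into equal sub-arcs, straight segments into
#' equal sub-segments), so a path of `m` primitives yields
#' `1 + m * frames_per_primitive` frames, the first at the path origin.
#'
#' @param spec An [path_spec()] object.
#' @param frames_per_primitive Integer >= 1; default 3 frames per primitive,
#'   so that four-primitive paths are scored over 12 frame steps.
#' @return An object of class `effcomm_trajectory`: a list with `frames`
#'   (data frame `frame`, `x`, `y`), `frames_per_primitive`, and `source`
#'   (the generating spec).
#' @examples
#' tr <- compose_path(path_spec(0), frames_per_primitive = 3)
#' tr$frames  # (0,0), (0,1/3), (0,2/3), (0,1)
#' @export
compose_path <- function(spec, frames_per_primitive = 3L) {
  stopifnot(inherits(spec, "effcomm_path"))
  k <- as.integer(frames_per_primitive)
  if (is.na(k) || k < 1L) stop("frames_per_primitive must be >= 1")
  m <- length(spec$segments)
  pts <- matrix(0, nrow = 1L + m * k, ncol = 2)
  pts[1, ] <- c(0, 0)
  cur <- c(0, 0)
  row <- 2L
  for (id in spec$segments) {
    sub <- .render_primitive(id, cur, k)
    pts[row:(row + k - 1L), ] <- sub
    cur <- sub[k, ]
    row <- row + k
  }
  pts <- pts * spec$scale
  pts[, 1] <- pts[, 1] + spec$origin[1]
  pts[, 2] <- pts[, 2] + spec$origin[2]
  structure(list(
    frames = data.frame(frame = 0:(m * k), x = pts[, 1], y = pts[, 2]),
    frames_per_primitive = k,
    source = spec
  ), class = "effcomm_trajectory")
}

#' @export
print.effcomm_trajectory <- function(x, ...) {
  n <- nrow(x$frames)
  cat(sprintf("<trajectory: %d frames, (%.2f,%.2f) -> (%.2f,%.2f)>\n",
              n, x$frames$x[1], x$frames$y[1],
              x$frames$x[n], x$frames$y[n]))
  invisible(x)
}

#' Plot a rendered trajectory
#'
#' Static line drawing of the path with start and end markers; a convenience
#' for inspecting stimuli (video rendering is out of scope).
#'
#' @param x An `effcomm_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.effcomm_trajectory <- function(x, ...) {
  f <- x$frames
  graphics::plot(f$x, f$y, type = "l", asp = 1, xlab = "x", ylab = "y", ...)
  graphics::points(f$x[1], f$y[1], pch = 16)
  graphics::points(f$x[nrow(f)], f$y[nrow(f)], pch = 1)
  invisible(x)
}

# internal: frame matrix of a trajectory or spec
.traj_points <- function(x, frames_per_primitive = 3L) {
  if (inherits(x, "effcomm_path")) x <- compose_path(x, frames_per_primitive)
  stopifnot(inherits(x, "effcomm_trajectory"))
  cbind(x$frames$x, x$frames$y)
}

#' Distance traveled along a path
#'
#' The actual distance traveled `d(p)`: the sum of the primitive segment
#' lengths (times the path scale).
#'
#' @param spec An [path_spec()] object.
#' @return Path length in arena units.
#' @export
path_length <- function(spec) {
  stopifnot(inherits(spec, "effcomm_path"))
  sum(.primitive_table$length[spec$segments + 1L]) * spec$scale
}

#' Net start-to-end displacement of a path
#'
#' The shortest distance between the beginning and the end of the path,
#' `d*(p)`: the Euclidean norm of the summed primitive displacements.
#'
#' @param spec An [path_spec()] object.
#' @return Straight-line start-to-end distance in arena units.
#' @export
net_displacement <- function(spec) {
  stopifnot(inherits(spec, "effcomm_path"))
  dx <- sum(.primitive_table$dx[spec$segments + 1L])
  dy <- sum(.primitive_table$dy[spec$segments + 1L])
  sqrt(dx^2 + dy^2) * spec$scale
}

#' Path rarity
#'
#' Rarity quantifies how uncommon a movement would be if produced in pursuit
#' of a world-directed goal, operationalised as deviation from the shortest
#' path: `r(p) = 1 - d*(p) / d(p)`, where `d*(p)` is the straight-line
#' start-to-end distance and `d(p)` the distance actually traveled. A
#' maximally efficient path has rarity 0; any path that returns to its start
#' has rarity 1.
#'
#' @param spec An [path_spec()] object with positive length.
#' @return Rarity in `[0, 1]`.
#' @examples
#' rarity(path_spec(c(0, 0, 0, 0)))  # straight: 0
#' rarity(path_spec(c(0, 1)))        # 1 - sqrt(2)/2
#' @export
rarity <- function(spec) {
  len <- path_length(spec)
  if (len <= 0) stop("rarity undefined for a zero-length path")
  1 - net_displacement(spec) / len
}
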