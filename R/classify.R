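# Movement classes A-H for four-primitive paths.
#
# The eight classes capture qualitative properties of how (in)efficiently a
# path moves from start to end: A maximally efficient; B retraces itself back
# to its origin; C moves toward multiple quadrants; D moves toward only one
# quadrant; E partially retraces itself; F self-intersects without closing;
# G repeats a component pattern; H closes without retracing. The informal
# descriptions are made total and deterministic by testing formal predicates
# in a fixed precedence order (A, B, G, H, E, F, D, C), first match wins.

.classify_eps <- 1e-9
# rendering density used by the geometric predicates (self-intersection,
# quadrant membership); arcs are approximated by 8 chords per quarter turn
.classify_fpp <- 8L

# does the polyline (m x 2 matrix of vertices) intersect itself?
# Tests all non-adjacent segment pairs, touching counts as intersecting;
# collinear overlap is detected through bounding-box overlap.
.polyline_self_intersects <- function(pts) {
  m <- nrow(pts) - 1L
  if (m < 3L) return(FALSE)
  ax <- pts[1:m, 1]; ay <- pts[1:m, 2]
  bx <- pts[2:(m + 1L), 1]; by <- pts[2:(m + 1L), 2]
  pairs <- which(outer(seq_len(m), seq_len(m), function(i, j) j >= i + 2L),
                 arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  eps <- 1e-9
  cross <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
  d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
  d3 <- cross(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
  d4 <- cross(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
  straddle <- (d1 * d2 < -eps) & (d3 * d4 < -eps)
  if (any(straddle)) return(TRUE)
  # touching or collinear candidates: some orientation ~ 0 and boxes overlap
  near0 <- (abs(d1) <= eps | abs(d2) <= eps | abs(d3) <= eps | abs(d4) <= eps)
  if (!any(near0)) return(FALSE)
  onseg <- function(ox, oy, px, py, qx, qy) {
    # q collinear-ish with o->p assumed; is q within the box?
    qx >= pmin(ox, px) - eps & qx <= pmax(ox, px) + eps &
      qy >= pmin(oy, py) - eps & qy <= pmax(oy, py) + eps
  }
  touch <-
    (abs(d1) <= eps & onseg(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])) |
    (abs(d2) <= eps & onseg(ax[i], ay[i], bx[i], by[i], bx[j], by[j])) |
    (abs(d3) <= eps & onseg(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])) |
    (abs(d4) <= eps & onseg(ax[j], ay[j], bx[j], by[j], bx[i], by[i]))
  any(touch & near0)
}

# all points (excluding the origin row) inside one closed quadrant?
.in_one_quadrant <- function(pts) {
  p <- pts[-1, , drop = FALSE]
  eps <- 1e-9
  for (sx in c(1, -1)) {
    for (sy in c(1, -1)) {
      if (all(sx * p[, 1] >= -eps) && all(sy * p[, 2] >= -eps)) return(TRUE)
    }
  }
  FALSE
}

#' Movement class of a four-primitive path
#'
#' Assigns exactly one of the eight a-priori movement classes to a
#' four-primitive path:
#' \describe{
#'   \item{A}{maximally efficient paths (rarity 0);}
#'   \item{B}{paths that retrace themselves back to their origin (the second
#'     half is the first half reversed);}
#'   \item{G}{paths whose four segments repeat a two-segment block, forming a
#'     pattern;}
#'   \item{H}{paths that start and end in the same position without retracing;}
#'   \item{E}{paths that partially retrace themselves (some segment is
#'     immediately followed by its reversal) without closing;}
#'   \item{F}{paths that intersect themselves but do not close;}
#'   \item{D}{paths that move toward only one quadrant;}
#'   \item{C}{paths that move toward multiple quadrants (the remainder).}
#' }
#' Predicates are applied in the precedence order A, B, G, H, E, F, D, C, so
#' the classification is total and deterministic.
#'
#' @param spec An [path_spec()] object with exactly 4 segments.
#' @return A single character label in `LETTERS[1:8]`.
#' @examples
#' classify_path(path_spec(c(0, 0, 0, 0)))  # "A"
#' classify_path(path_spec(c(0, 0, 2, 2)))  # "B"
#' @export
classify_path <- function(spec) {
  stopifnot(inherits(spec, "effcomm_path"))
  s <- spec$segments
  if (length(s) != 4L) {
    stop("movement classes are defined for 4-segment paths; got ", length(s))
  }
  closed <- net_displacement(spec) < .classify_eps
  if (rarity(spec) < .classify_eps) return("A")
  if (closed && s[3] == retrace_primitive(s[2]) &&
      s[4] == retrace_primitive(s[1])) return("B")
  if (s[3] == s[1] && s[4] == s[2]) return("G")
  if (closed) return("H")
  if (any(s[2:4] == retrace_primitive(s[1:3]))) return("E")
  pts <- .traj_points(spec, .classify_fpp)
  if (.polyline_self_intersects(pts)) return("F")
  if (.in_one_quadrant(pts)) return("D")
  "C"
}

# cache for enumerated+classified canonical path spaces (keyed by n/convention)
.effcomm_cache <- new.env(parent = emptyenv())

# canonical 4-primitive space with class labels and rarities, computed once
.canonical_space4 <- function() {
  if (is.null(.effcomm_cache$space4)) {
    enum <- enumerate_path_space(4)
    classes <- vapply(enum$paths, classify_path, character(1))
    rars <- vapply(enum$paths, rarity, numeric(1))
    keys <- vapply(enum$paths, canonical_key, character(1))
    .effcomm_cache$space4 <- list(paths = enum$paths, class = classes,
                                  rarity = rars, key = keys,
                                  count = enum$count)
  }
  .effcomm_cache$space4
}
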