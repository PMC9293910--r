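# The eight square symmetries (dihedral group of the square) acting on paths.
# Because every primitive maps to another primitive under each symmetry, a
# symmetry acts on a path spec as a permutation of primitive ids, and two
# paths are "the same shape" when one's id sequence is a symmetry image of
# the other's.

.symmetry_matrices <- list(
  identity   = matrix(c(1, 0, 0, 1), 2),
  rot90      = matrix(c(0, 1, -1, 0), 2),   # 90 degrees counter-clockwise
  rot180     = matrix(c(-1, 0, 0, -1), 2),
  rot270     = matrix(c(0, -1, 1, 0), 2),
  reflect_x  = matrix(c(1, 0, 0, -1), 2),   # over the x-axis
  reflect_y  = matrix(c(-1, 0, 0, 1), 2),
  reflect_d  = matrix(c(0, 1, 1, 0), 2),    # over y = x
  reflect_a  = matrix(c(0, -1, -1, 0), 2)   # over y = -x
)

# composite names the stimulus constructions use; both lie in the group
.symmetry_aliases <- c(
  rot90ccw_reflectx = "reflect_a",  # rotate 90 ccw, then reflect over x-axis
  rot180ccw = "rot180"
)

.resolve_symmetry <- function(symmetry) {
  if (symmetry %in% names(.symmetry_aliases)) {
    symmetry <- .symmetry_aliases[[symmetry]]
  }
  if (!symmetry %in% names(.symmetry_matrices)) {
    stop("unsupported symmetry: ", symmetry)
  }
  symmetry
}

# primitive id permutation induced by each symmetry, built from geometry:
# match the transformed displacement (and, for arcs, transformed center and
# orientation) against the primitive table
.build_symmetry_permutations <- function() {
  tb <- .primitive_table
  perms <- list()
  for (nm in names(.symmetry_matrices)) {
    M <- .symmetry_matrices[[nm]]
    flip <- det(M) < 0
    perm <- integer(16)
    for (i in seq_len(16)) {
      r <- tb[i, ]
      d <- M %*% c(r$dx, r$dy)
      if (r$kind == "arc") {
        turn <- if (flip) setdiff(c("CW", "CCW"), r$turn) else r$turn
        ctr <- M %*% c(r$cx, r$cy)
        j <- which(tb$kind == "arc" & !is.na(tb$turn) & tb$turn == turn &
                     abs(tb$cx - ctr[1]) < 1e-9 & abs(tb$cy - ctr[2]) < 1e-9)
      } else {
        j <- which(tb$kind == r$kind &
                     abs(tb$dx - d[1]) < 1e-9 & abs(tb$dy - d[2]) < 1e-9)
      }
      stopifnot(length(j) == 1L)
      perm[i] <- tb$id[j]
    }
    perms[[nm]] <- perm
  }
  perms
}

# perm[id + 1] = image id under the symmetry
.symmetry_permutations <- .build_symmetry_permutations()

#' Names of the supported path symmetries
#'
#' The eight symmetries of the square plus two composite aliases used when
#' constructing repetition stimuli (`"rot90ccw_reflectx"`, `"rot180ccw"`).
#'
#' @return Character vector of symmetry names accepted by [transform_path()].
#' @export
list_symmetries <- function() {
  c(names(.symmetry_matrices), names(.symmetry_aliases))
}

#' Apply a square symmetry to a path
#'
#' Returns the path spec whose rendered trajectory equals the symmetry applied
#' (about the origin) to the original rendered trajectory. Rarity, length and
#' movement class are preserved, as every symmetry is an isometry.
#'
#' @param spec An [path_spec()] object.
#' @param symmetry One of [list_symmetries()].
#' @return A transformed `effcomm_path`.
#' @examples
#' transform_path(path_spec(rep(1, 4)), "rot90")  # E,E,E,E -> N,N,N,N
#' @export
transform_path <- function(spec, symmetry) {
  stopifnot(inherits(spec, "effcomm_path"))
  nm <- .resolve_symmetry(symmetry)
  perm <- .symmetry_permutations[[nm]]
  M <- .symmetry_matrices[[nm]]
  path_spec(perm[spec$segments + 1L],
            origin = as.numeric(M %*% spec$origin),
            scale = spec$scale)
}

# encode id sequences (rows of a matrix) as base-16 integers whose numeric
# order equals lexicographic order of the sequences
.encode_segments <- function(mat) {
  n <- ncol(mat)
  key <- numeric(nrow(mat))
  for (j in seq_len(n)) key <- key * 16 + mat[, j]
  key
}

.decode_segments <- function(key, n) {
  out <- matrix(0L, nrow = length(key), ncol = n)
  for (j in n:1) {
    out[, j] <- as.integer(key %% 16)
    key <- key %/% 16
  }
  out
}

# minimal lexicographic key over the 8-symmetry orbit of each row
.canonical_keys <- function(mat) {
  best <- rep(Inf, nrow(mat))
  for (perm in .symmetry_permutations) {
    img <- matrix(perm[mat + 1L], nrow = nrow(mat))
    best <- pmin(best, .encode_segments(img))
  }
  best
}

#' Canonical form of a path under rotation and reflection
#'
#' Two paths receive the same canonical form exactly when one is a rotation
#' or reflection (one of the 8 square symmetries) of the other. The canonical
#' representative is the lexicographically least id sequence in the orbit,
#' under the fixed primitive ordering 0-15. Idempotent. Path reversal is not
#' part of the equivalence.
#'
#' @param spec An [path_spec()] object.
#' @return The canonical `effcomm_path` (origin `(0,0)`, scale preserved).
#' @export
canonicalize <- function(spec) {
  stopifnot(inherits(spec, "effcomm_path"))
  mat <- matrix(spec$segments, nrow = 1)
  key <- .canonical_keys(mat)
  path_spec(as.integer(.decode_segments(key, length(spec$segments))),
            scale = spec$scale)
}

#' Stable string key of a path's canonical form
#'
#' @param spec An [path_spec()] object.
#' @return A character key shared by all rotations/reflections of the path.
#' @export
canonical_key <- function(spec) {
  paste(canonicalize(spec)$segments, collapse = "-")
}

# admissibility mask for a chaining convention, applied to an id-sequence
# matrix; `all` admits every sequence, `no_retrace` forbids a primitive
# followed by its reversal, `tangent` requires the next start tangent to
# equal the previous end tangent
.convention_mask <- function(mat, convention) {
  if (convention == "all") return(rep(TRUE, nrow(mat)))
  ok <- rep(TRUE, nrow(mat))
  tb <- .primitive_table
  for (j in seq_len(ncol(mat) - 1L)) {
    a <- mat[, j]
    b <- mat[, j + 1L]
    if (convention == "no_retrace") {
      ok <- ok & (b != .retrace_table[a + 1L])
    } else if (convention == "tangent") {
      ok <- ok & (tb$end_heading[a + 1L] == tb$heading[b + 1L])
    } else {
      stop("unknown chaining convention: ", convention)
    }
  }
  ok
}

#' Enumerate the canonical path space
#'
#' Enumerates all admissible primitive sequences of length `n` and collapses
#' them to one representative per equivalence class under the 8 square
#' symmetries. By default every one of the `16^n` sequences is admissible
#' ("in all possible combinations"); alternative chaining conventions are
#' provided for count comparisons: `"no_retrace"` (a primitive is never
#' followed by its own reversal) and `"tangent"` (tangent-continuous chains).
#'
#' @param n Number of primitives per path (>= 1; `n > 5` is refused, as the
#'   full sequence space grows as `16^n`).
#' @param convention Chaining convention; one of `"all"` (default),
#'   `"no_retrace"`, `"tangent"`.
#' @return A list with `paths` (list of canonical `effcomm_path` objects,
#'   ordered by canonical key), `count`, `n`, and `convention`.
#' @examples
#' enumerate_path_space(1)$count  # 3
#' @export
enumerate_path_space <- function(n, convention = c("all", "no_retrace", "tangent")) {
  convention <- match.arg(convention)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (n > 5L) stop("n > 5 exceeds the enumeration memory budget (16^n sequences)")
  mat <- as.matrix(expand.grid(rep(list(0:15), n), KEEP.OUT.ATTRS = FALSE))
  mat <- mat[.convention_mask(mat, convention), , drop = FALSE]
  keys <- sort(unique(.canonical_keys(mat)))
  reps <- .decode_segments(keys, n)
  paths <- lapply(seq_len(nrow(reps)), function(i) path_spec(reps[i, ]))
  list(paths = paths, count = length(paths), n = n, convention = convention)
}
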