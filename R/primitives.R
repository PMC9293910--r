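# Motion primitives: the 16 elementary segments from which every path is
# chained. Four unit cardinal segments, four sqrt(2) diagonal segments, and
# eight quarter-circle arcs of radius 1 (start tangent N/E/S/W crossed with
# clockwise/counter-clockwise turn).

.heading_vectors <- list(
  N  = c(0, 1),  E  = c(1, 0),  S  = c(0, -1), W  = c(-1, 0),
  NE = c(1, 1),  SE = c(1, -1), SW = c(-1, -1), NW = c(-1, 1)
)

# rotate a 2-vector by +90 (ccw) or -90 (cw) degrees
.rot90 <- function(v, sign) {
  if (sign > 0) c(-v[2], v[1]) else c(v[2], -v[1])
}

.build_primitive_table <- function() {
  card <- c("N", "E", "S", "W")
  diag <- c("NE", "SE", "SW", "NW")
  rows <- vector("list", 16)
  for (i in seq_along(card)) {
    v <- .heading_vectors[[card[i]]]
    rows[[i]] <- list(id = i - 1L, kind = "cardinal", heading = card[i],
                      turn = NA_character_, length = 1,
                      dx = v[1], dy = v[2], cx = NA_real_, cy = NA_real_,
                      end_heading = card[i])
  }
  for (i in seq_along(diag)) {
    v <- .heading_vectors[[diag[i]]]
    rows[[4 + i]] <- list(id = 3L + i, kind = "diagonal", heading = diag[i],
                          turn = NA_character_, length = sqrt(2),
                          dx = v[1], dy = v[2], cx = NA_real_, cy = NA_real_,
                          end_heading = diag[i])
  }
  k <- 8L
  for (h in card) {
    for (turn in c("CW", "CCW")) {
      hv <- .heading_vectors[[h]]
      s <- if (turn == "CW") -1 else 1
      # circle center sits one radius to the side of the start tangent
      ctr <- .rot90(hv, s)
      disp <- ctr + .rot90(-ctr, s)
      ev <- .rot90(hv, s)                       # end tangent
      end_heading <- card[vapply(card, function(d)
        isTRUE(all.equal(.heading_vectors[[d]], ev)), logical(1))]
      rows[[k + 1L]] <- list(id = k, kind = "arc", heading = h, turn = turn,
                             length = pi / 2, dx = disp[1], dy = disp[2],
                             cx = ctr[1], cy = ctr[2], end_heading = end_heading)
      k <- k + 1L
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

.primitive_table <- .build_primitive_table()

.opposite_heading <- c(N = "S", E = "W", S = "N", W = "E",
                       NE = "SW", SE = "NW", SW = "NE", NW = "SE")

# id of the primitive that traverses `id` in reverse (retrace table)
.build_retrace_table <- function() {
  tb <- .primitive_table
  out <- integer(16)
  for (i in seq_len(16)) {
    r <- tb[i, ]
    if (r$kind %in% c("cardinal", "diagonal")) {
      opp <- .opposite_heading[[r$heading]]
      out[i] <- tb$id[tb$kind == r$kind & tb$heading == opp]
    } else {
      opp <- .opposite_heading[[r$end_heading]]
      flip <- if (r$turn == "CW") "CCW" else "CW"
      out[i] <- tb$id[tb$kind == "arc" & tb$heading == opp &
                        !is.na(tb$turn) & tb$turn == flip]
    }
  }
  out
}

.retrace_table <- .build_retrace_table()

#' List the sixteen motion primitives
#'
#' Returns the table of elementary movement segments used to build paths:
#' four unit-length cardinal segments, four diagonal segments of length
#' `sqrt(2)`, and eight 90-degree arc segments of radius 1 (length `pi/2`),
#' parameterised by start tangent and turn direction.
#'
#' @return A data frame with one row per primitive and columns `id` (0-15),
#'   `kind` (`"cardinal"`, `"diagonal"`, `"arc"`), `heading` (start tangent),
#'   `turn` (`"CW"`/`"CCW"` for arcs, `NA` otherwise), `length` (arc length in
#'   arena units), `dx`, `dy` (end-minus-start displacement), and
#'   `end_heading` (tangent direction at the end of the segment).
#' @examples
#' prims <- list_primitives()
#' nrow(prims)  # 16
#' @export
list_primitives <- function() {
  .primitive_table[, c("id", "kind", "heading", "turn", "length",
                       "dx", "dy", "end_heading")]
}

#' Reversal (retrace) of a primitive
#'
#' For each primitive id, the id of the primitive whose geometry is the same
#' segment traversed in the opposite direction. Applying it twice is the
#' identity.
#'
#' @param id Integer vector of primitive ids (0-15).
#' @return Integer vector of retraced primitive ids.
#' @export
retrace_primitive <- function(id) {
  stopifnot(all(id %in% 0:15))
  .retrace_table[id + 1L]
}

# Render one primitive from `start` with `k` equal arc-length sub-steps.
# Returns a k x 2 matrix of the points after the start (start excluded).
.render_primitive <- function(id, start, k) {
  r <- .primitive_table[id + 1L, ]
  if (r$kind %in% c("cardinal", "diagonal")) {
    t <- seq_len(k) / k
    cbind(start[1] + t * r$dx, start[2] + t * r$dy)
  } else {
    ctr <- start + c(r$cx, r$cy)
    v <- start - ctr
    s <- if (r$turn == "CW") -1 else 1
    ang <- s * (pi / 2) * seq_len(k) / k
    cbind(ctr[1] + cos(ang) * v[1] - sin(ang) * v[2],
          ctr[2] + sin(ang) * v[1] + cos(ang) * v[2])
  }
}
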