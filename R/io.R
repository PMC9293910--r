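# Readers and writers for the artifact's plain-text formats. All formats
# round-trip losslessly at full double precision; malformed input is
# reported with the offending field and line.

#' Write / read a rendered trajectory as CSV
#'
#' Schema: header `frame,x,y`, one row per frame, frame indices consecutive
#' from 0, "." decimal, UTF-8.
#'
#' @param traj An `effcomm_trajectory`.
#' @param path File path.
#' @return `read_trajectory_csv()` returns an `effcomm_trajectory` (without
#'   a source spec); `write_trajectory_csv()` returns `path` invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "effcomm_trajectory"))
  f <- traj$frames
  lines <- c("frame,x,y",
             sprintf("%d,%s,%s", f$frame,
                     formatC(f$x, digits = 17, format = "g"),
                     formatC(f$y, digits = 17, format = "g")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param frames_per_primitive Frames-per-primitive annotation to attach to
#'   the read trajectory (default 3).
#' @export
read_trajectory_csv <- function(path, frames_per_primitive = 3L) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric", "numeric"))
  if (!identical(names(df), c("frame", "x", "y"))) {
    stop("trajectory CSV must have columns frame,x,y: ", path)
  }
  bad <- which(df$frame != seq_len(nrow(df)) - 1L)
  if (length(bad) > 0) {
    stop(sprintf("trajectory CSV %s: non-consecutive frame index at line %d",
                 path, bad[1] + 1L))
  }
  if (anyNA(df$x) || anyNA(df$y)) {
    stop("trajectory CSV ", path, ": missing coordinates")
  }
  same <- which(diff(df$x) == 0 & diff(df$y) == 0)
  if (length(same) > 0) {
    stop(sprintf("trajectory CSV %s: consecutive frames coincide at line %d",
                 path, same[1] + 2L))
  }
  structure(list(frames = df, frames_per_primitive = as.integer(frames_per_primitive),
                 source = NULL),
            class = "effcomm_trajectory")
}

#' Write / read a path specification as JSON
#'
#' Schema: `{"origin": [x, y], "segments": [ids], "frames_per_primitive": k,
#' "scale": s}`.
#'
#' @param spec An [path_spec()] object.
#' @param path File path.
#' @param frames_per_primitive Annotation stored alongside the spec.
#' @return `read_path_spec()` returns a list with `spec` and
#'   `frames_per_primitive`.
#' @export
write_path_spec <- function(spec, path, frames_per_primitive = 3L) {
  stopifnot(inherits(spec, "effcomm_path"))
  jsonlite::write_json(
    list(origin = spec$origin, segments = spec$segments,
         frames_per_primitive = as.integer(frames_per_primitive),
         scale = spec$scale),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_path_spec
#' @export
read_path_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("origin", "segments")) {
    if (is.null(obj[[f]])) stop("path-spec JSON ", path, ": missing field ", f)
  }
  list(spec = path_spec(obj$segments, origin = obj$origin,
                        scale = if (is.null(obj$scale)) 1 else obj$scale),
       frames_per_primitive = if (is.null(obj$frames_per_primitive)) 3L
       else as.integer(obj$frames_per_primitive))
}

#' Write / read a world as JSON
#'
#' Schema: `{"bounds": [[xmin,ymin],[xmax,ymax]], "obstacles": [...],
#' "goal_spacing": g, "grid_resolution": h}`; each obstacle is either
#' `{"type":"polygon","vertices":[[x,y],...]}` or
#' `{"type":"band","polyline":[[x,y],...],"margin":m,"width":w}`.
#'
#' @param world An [build_world()] object.
#' @param path File path.
#' @export
write_world <- function(world, path) {
  stopifnot(inherits(world, "effcomm_world"))
  obs <- lapply(world$obstacles, function(ob) {
    if (ob$type == "polygon") {
      list(type = "polygon", vertices = unname(apply(ob$vertices, 1, c,
                                                     simplify = FALSE)))
    } else {
      list(type = "band",
           polyline = unname(apply(ob$polyline, 1, c, simplify = FALSE)),
           margin = ob$margin, width = ob$width)
    }
  })
  jsonlite::write_json(
    list(bounds = list(world$bounds[1:2], world$bounds[3:4]),
         obstacles = obs, goal_spacing = world$goal_spacing,
         grid_resolution = world$grid_resolution),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_world
#' @export
read_world <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("bounds", "goal_spacing", "grid_resolution")) {
    if (is.null(obj[[f]])) stop("world JSON ", path, ": missing field ", f)
  }
  b <- obj$bounds
  bounds <- if (is.matrix(b)) c(b[1, ], b[2, ]) else c(b[[1]], b[[2]])
  obstacles <- list()
  if (length(obj$obstacles) > 0) {
    raw <- if (is.data.frame(obj$obstacles)) {
      lapply(seq_len(nrow(obj$obstacles)), function(i) as.list(obj$obstacles[i, ]))
    } else obj$obstacles
    obstacles <- lapply(raw, function(ob) {
      type <- unlist(ob$type)
      if (identical(type, "polygon")) {
        v <- ob$vertices
        if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
        if (is.list(v[[1]])) v <- v[[1]]
        list(type = "polygon", vertices = matrix(unlist(v), ncol = 2,
                                                 byrow = !is.matrix(v)))
      } else if (identical(type, "band")) {
        p <- ob$polyline
        if (is.list(p) && !is.data.frame(p)) p <- p[[1]]
        if (is.list(p)) p <- do.call(rbind, lapply(p, unlist))
        list(type = "band", polyline = p,
             margin = unlist(ob$margin), width = unlist(ob$width))
      } else stop("world JSON ", path, ": unknown obstacle type ", type)
    })
  }
  build_world(bounds, obstacles = obstacles, goal_spacing = obj$goal_spacing,
              grid_resolution = obj$grid_resolution)
}

#' Write / read a judgment table as CSV
#'
#' Schema: header `participant,path_id,condition,rating`; ratings must be
#' integers in 1-7.
#'
#' @param judgments A judgment table (see [simulate_judgments()]).
#' @param path File path.
#' @export
write_judgments_csv <- function(judgments, path) {
  stopifnot(all(c("participant", "path_id", "condition", "rating") %in%
                  names(judgments)))
  utils::write.csv(judgments[, c("participant", "path_id", "condition",
                                 "rating")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_judgments_csv
#' @export
read_judgments_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "character", "integer"))
  if (!identical(names(df), c("participant", "path_id", "condition", "rating"))) {
    stop("judgments CSV must have columns participant,path_id,condition,rating: ",
         path)
  }
  bad <- which(is.na(df$rating) | df$rating < 1L | df$rating > 7L)
  if (length(bad) > 0) {
    stop(sprintf("judgments CSV %s: rating outside 1-7 at line %d",
                 path, bad[1] + 1L))
  }
  df$condition[df$condition == ""] <- NA_character_
  df
}

#' Write / read an analysis report as JSON
#'
#' @param report A named list of results (correlations, permutation results,
#'   per-class discrepancies, seeds, ...).
#' @param path File path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
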