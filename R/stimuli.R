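# Stimulus-set builders for the three point-display studies:
# study 1: 23 four-primitive paths spanning the eight movement classes;
# study 2: 7 basic two-primitive movements x {0, 1, 2} repetitions, equated
#          for total distance traveled;
# study 3: 12 paths from study 1, each shown unbordered and bordered by
#          obstacle "lakes" that make the movement consistent with efficient
#          world-directed travel.

.new_stimulus_set <- function(study, seed, items, paths, worlds = NULL) {
  structure(list(study = study, seed = seed, items = items, paths = paths,
                 worlds = worlds),
            class = "effcomm_stimulus_set")
}

#' @export
print.effcomm_stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus set %s: %d items%s>\n", x$study, nrow(x$items),
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}

#' Build the first stimulus set (rarity gradient across movement classes)
#'
#' Selects the two unique maximally efficient canonical paths (movement class
#' A: the straight cardinal and the straight diagonal chain) plus three
#' random canonical paths from each of the remaining seven classes, for a
#' total of 23 four-primitive paths.
#'
#' @param seed Integer RNG seed; the same seed always returns the same set.
#' @return An `effcomm_stimulus_set` with `items` (data frame `path_id`,
#'   `class`, `condition`, `rarity`) and `paths` (named list of
#'   `effcomm_path`).
#' @export
build_study1_set <- function(seed = 1L) {
  sp <- .canonical_space4()
  items <- list()
  paths <- list()
  withr::with_seed(as.integer(seed), {
    for (cl in LETTERS[1:8]) {
      idx <- which(sp$class == cl)
      take <- if (cl == "A") 2L else 3L
      if (length(idx) < take) {
        stop("movement class ", cl, " has fewer than ", take,
             " members; classifier inconsistency")
      }
      pick <- if (cl == "A") idx else idx[sample.int(length(idx), take)]
      for (k in seq_along(pick)) {
        pid <- sprintf("s1-%s%d", cl, k)
        paths[[pid]] <- sp$paths[[pick[k]]]
        items[[pid]] <- data.frame(path_id = pid, class = cl,
                                   condition = NA_character_,
                                   rarity = sp$rarity[pick[k]])
      }
    }
  })
  items <- do.call(rbind, items)
  rownames(items) <- NULL
  stopifnot(nrow(items) == 23L, !anyDuplicated(
    vapply(paths, canonical_key, character(1))))
  .new_stimulus_set("study1", as.integer(seed), items, paths)
}

# the canonical two-primitive basic movements eligible for repetition
# stimuli: second primitive never the retrace of the first, and the basic
# path must not already be closed (otherwise the repetition manipulation
# could not add rarity)
.study2_basics <- function() {
  enum <- enumerate_path_space(2, convention = "no_retrace")
  enum$paths <- Filter(function(p) net_displacement(p) > 1e-9, enum$paths)
  rars <- vapply(enum$paths, rarity, numeric(1))
  ord <- order(rars, vapply(enum$paths, canonical_key, character(1)))
  enum$paths[ord]
}

#' Build the repetition stimulus set
#'
#' Seven basic two-primitive movements (the second primitive never retraces
#' the first; chosen deterministically to span the rarity range of the
#' canonical two-primitive space), each in three versions: the basic path
#' (0 repetitions), a one-repetition version in which the path retraces
#' itself back to its origin (then rotated 90 degrees counter-clockwise and
#' reflected over the x-axis, masking the manipulation), and a two-repetition
#' version with two full out-and-back cycles (rotated 180 degrees
#' counter-clockwise). Every path's scale is adjusted so all 21 trajectories
#' have the same total distance traveled (that of the longest unscaled item).
#'
#' @return An `effcomm_stimulus_set` with 21 items; `items$condition` holds
#'   the repetition count (`"0"`, `"1"`, `"2"`).
#' @export
build_study2_set <- function() {
  basics <- .study2_basics()
  pick <- basics[round(seq(1, length(basics), length.out = 7))]
  variants <- list()
  for (b in seq_along(pick)) {
    s <- pick[[b]]$segments
    rev <- retrace_primitive(rev(s))  # reversal of the basic path
    variants[[sprintf("s2-b%d-rep0", b)]] <-
      list(spec = pick[[b]], reps = 0L)
    variants[[sprintf("s2-b%d-rep1", b)]] <-
      list(spec = transform_path(path_spec(c(s, rev)), "rot90ccw_reflectx"),
           reps = 1L)
    variants[[sprintf("s2-b%d-rep2", b)]] <-
      list(spec = transform_path(path_spec(c(s, rev, s, rev)), "rot180ccw"),
           reps = 2L)
  }
  raw_len <- vapply(variants, function(v) path_length(v$spec), numeric(1))
  target <- max(raw_len)
  paths <- list()
  items <- list()
  for (pid in names(variants)) {
    v <- variants[[pid]]
    sc <- target / path_length(v$spec)
    paths[[pid]] <- path_spec(v$spec$segments, origin = v$spec$origin,
                              scale = sc)
    items[[pid]] <- data.frame(path_id = pid,
                               class = NA_character_,
                               condition = as.character(v$reps),
                               rarity = rarity(paths[[pid]]))
  }
  items <- do.call(rbind, items)
  rownames(items) <- NULL
  stopifnot(nrow(items) == 21L)
  .new_stimulus_set("study2", NULL, items, paths)
}

#' Build the bordered/unbordered stimulus set
#'
#' Selects 12 base paths from an existing study-1 set: one random path from
#' each of the eight a-priori movement classes, plus four additional paths
#' randomly drawn from those whose average communicativeness rating is at
#' least 4.25. Each base path is emitted twice, tagged `unbordered` and
#' `bordered`; for the bordered condition a world whose obstacle "lakes"
#' closely flank the trajectory is generated with [make_bordered_world()].
#'
#' @param study1_set A set from [build_study1_set()].
#' @param ratings A judgment table (see [simulate_judgments()]) covering the
#'   study-1 paths.
#' @param seed Integer RNG seed.
#' @param margin Corridor half-width passed to [make_bordered_world()].
#' @param frames_per_primitive Frames per primitive for the rendered
#'   trajectories the bordered worlds are built around.
#' @return An `effcomm_stimulus_set` with 24 items over 12 base paths, and
#'   `worlds`: a named list of bordered worlds keyed by base path id.
#' @export
build_study3_set <- function(study1_set, ratings, seed = 1L, margin = 0.4,
                             frames_per_primitive = 3L) {
  stopifnot(inherits(study1_set, "effcomm_stimulus_set"))
  means <- tapply(ratings$rating, ratings$path_id, mean)
  base <- character(0)
  withr::with_seed(as.integer(seed), {
    for (cl in LETTERS[1:8]) {
      ids <- study1_set$items$path_id[study1_set$items$class == cl]
      base <- c(base, ids[sample.int(length(ids), 1L)])
    }
    pool <- setdiff(study1_set$items$path_id, base)
    pool <- pool[!is.na(means[pool]) & means[pool] >= 4.25]
    if (length(pool) < 4L) {
      stop("only ", length(pool), " non-selected paths have a mean rating ",
           ">= 4.25; cannot draw the 4 additional high-communicativeness paths")
    }
    base <- c(base, pool[sample.int(length(pool), 4L)])
  })
  paths <- study1_set$paths[base]
  worlds <- lapply(paths, function(p) {
    make_bordered_world(compose_path(p, frames_per_primitive), margin = margin)
  })
  items <- do.call(rbind, lapply(base, function(pid) {
    row <- study1_set$items[study1_set$items$path_id == pid, ]
    data.frame(path_id = pid, class = row$class,
               condition = c("unbordered", "bordered"), rarity = row$rarity)
  }))
  rownames(items) <- NULL
  stopifnot(length(base) == 12L, nrow(items) == 24L)
  .new_stimulus_set("study3", as.integer(seed), items, paths, worlds)
}
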