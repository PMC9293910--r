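# Synthetic communicativeness judgments. Real observers rated each path on a
# 1-7 Likert scale; the generator emulates that design with a linear link on
# a standardized predictor (rarity or model score), Gaussian participant
# intercepts and trial noise, rounded and clamped to the scale. It is a
# stand-in with the statistical structure the analysis assumes, not a model
# of real raters.

#' Parameters of the synthetic rating link
#'
#' Ratings are generated as
#' `clamp(round(a + b * z(predictor) + u_p + eps), 1, 7)` with participant
#' intercepts `u_p ~ N(0, tau^2)` and trial noise `eps ~ N(0, sigma^2)`,
#' where `z()` standardizes the predictor over paths.
#'
#' @param intercept `a`, in Likert units (default 4, the scale midpoint).
#' @param slope `b`, Likert units per standardized predictor unit (default
#'   1.2).
#' @param participant_sd `tau >= 0` (default 0.5).
#' @param trial_sd `sigma >= 0` (default 1).
#' @param n_participants Number of simulated raters (default 30, the
#'   per-study sample size the design emulates).
#' @param seed Integer RNG seed.
#' @return A list of class `effcomm_linking`.
#' @export
linking_params <- function(intercept = 4, slope = 1.2, participant_sd = 0.5,
                           trial_sd = 1, n_participants = 30L, seed = 1L) {
  stopifnot(participant_sd >= 0, trial_sd >= 0, n_participants >= 1)
  structure(list(intercept = intercept, slope = slope,
                 participant_sd = participant_sd, trial_sd = trial_sd,
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed)),
            class = "effcomm_linking")
}

#' Simulate participant x path Likert judgments
#'
#' @param path_ids Character vector of path identifiers (non-empty).
#' @param predictor Numeric per-path predictor (rarity or model score), same
#'   length as `path_ids`.
#' @param params An [linking_params()] object.
#' @param condition Optional per-path condition tag (recycled `NA` if absent).
#' @return A judgment table: data frame with columns `participant`,
#'   `path_id`, `condition`, `rating` (integer 1-7), one row per
#'   participant x path; fully reproducible from `params$seed`.
#' @export
simulate_judgments <- function(path_ids, predictor, params = linking_params(),
                               condition = NULL) {
  if (length(path_ids) == 0L) stop("empty path list")
  stopifnot(length(predictor) == length(path_ids), !anyNA(predictor))
  if (is.null(condition)) condition <- rep(NA_character_, length(path_ids))
  stopifnot(length(condition) == length(path_ids))
  n_path <- length(path_ids)
  n_part <- params$n_participants
  z <- if (stats::sd(predictor) > 0) {
    (predictor - mean(predictor)) / stats::sd(predictor)
  } else {
    rep(0, n_path)
  }
  withr::with_seed(params$seed, {
    u <- stats::rnorm(n_part, 0, params$participant_sd)
    eps <- matrix(stats::rnorm(n_part * n_path, 0, params$trial_sd),
                  nrow = n_part)
  })
  latent <- params$intercept + params$slope * rep(z, each = n_part) +
    rep(u, times = n_path) + as.numeric(eps)
  rating <- pmin(7L, pmax(1L, as.integer(round(latent))))
  data.frame(
    participant = rep(sprintf("pp%02d", seq_len(n_part)), times = n_path),
    path_id = rep(path_ids, each = n_part),
    condition = rep(condition, each = n_part),
    rating = rating
  )
}

#' Per-path mean ratings of a judgment table
#'
#' @param judgments A judgment table (see [simulate_judgments()]).
#' @param by Optional additional grouping column name (e.g. `"condition"`).
#' @return Data frame `path_id` (and `by`, if given), `mean_rating`.
#' @export
path_means <- function(judgments, by = NULL) {
  if (is.null(by)) {
    agg <- stats::aggregate(rating ~ path_id, data = judgments, FUN = mean)
    names(agg)[2] <- "mean_rating"
  } else {
    f <- stats::as.formula(paste("rating ~ path_id +", by))
    agg <- stats::aggregate(f, data = judgments, FUN = mean)
    names(agg)[ncol(agg)] <- "mean_rating"
  }
  agg
}
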