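# The statistical surface: effect sizes with percentile-bootstrap confidence
# intervals, linear calibration of model scores to ratings, a permutation
# test for the correlation increase after excluding a path subset, and
# per-movement-class model-human discrepancies.

#' Pearson correlation with a percentile bootstrap confidence interval
#'
#' Resamples path-level pairs with replacement and takes percentile quantiles
#' of the recomputed correlation as the confidence bounds.
#'
#' @param x,y Numeric vectors (length >= 3, non-constant); typically a
#'   per-path predictor and per-path mean ratings.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `effcomm_cor`: `r`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`, `n`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 10000L, seed = 1L, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  boots <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    vapply(seq_len(n_boot), function(b) {
      i <- idx[, b]
      if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) NA_real_
      else stats::cor(x[i], y[i])
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(r = r, ci_low = qs[1], ci_high = qs[2],
                 n_boot = as.integer(n_boot), seed = as.integer(seed), n = n),
            class = "effcomm_cor")
}

#' @export
print.effcomm_cor <- function(x, ...) {
  cat(sprintf("r = %.3f, CI95 = [%.3f, %.3f] (n = %d, %d bootstrap resamples)\n",
              x$r, x$ci_low, x$ci_high, x$n, x$n_boot))
  invisible(x)
}

#' Linear calibration of model scores to mean ratings
#'
#' Ordinary least squares of per-path mean ratings on per-path model scores,
#' used to put model output on the Likert scale for model-human comparison.
#'
#' @param scores Per-path model scores (length >= 3, non-constant).
#' @param ratings Per-path mean ratings.
#' @return A list of class `effcomm_calibration`: `slope`, `intercept`,
#'   `fitted` (per path), `residuals`, and the inputs.
#' @export
calibrate_linear <- function(scores, ratings) {
  stopifnot(length(scores) == length(ratings), length(scores) >= 3)
  if (stats::sd(scores) == 0) stop("calibration undefined for constant scores")
  fit <- stats::lm(ratings ~ scores)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 scores = scores, ratings = ratings),
            class = "effcomm_calibration")
}

#' Permutation test for a correlation increase after excluding paths
#'
#' Tests whether excluding a named subset of paths increases the
#' scores-ratings correlation more than excluding a random subset of the
#' same size: the observed statistic is
#' `delta_r = r(remaining paths) - r(all paths)`; the null distribution is
#' built from random equal-size exclusions (exhaustively enumerated when the
#' number of subsets does not exceed `n_perm`, Monte Carlo otherwise), and
#' `p = (1 + #(delta_null >= delta_obs)) / (n_perm + 1)`.
#'
#' @param scores,ratings Per-path values, named by `ids` positionally.
#' @param ids Character path ids aligned with `scores`/`ratings`.
#' @param excluded_ids Subset of `ids` to exclude.
#' @param n_perm Number of null exclusions (default 10000).
#' @param seed Integer RNG seed.
#' @return A list of class `effcomm_perm`: `delta_r_observed`, `p_value`,
#'   `r_all`, `r_excluded`, `n_perm`, `seed`, `excluded_ids`, `exhaustive`.
#' @export
correlation_increase_permutation <- function(scores, ratings, ids,
                                             excluded_ids, n_perm = 10000L,
                                             seed = 1L) {
  stopifnot(length(scores) == length(ratings), length(scores) == length(ids))
  if (!all(excluded_ids %in% ids)) stop("excluded_ids must be a subset of ids")
  m <- length(excluded_ids)
  n <- length(ids)
  if (n - m < 3L) stop("exclusion leaves fewer than 3 paths")
  keep <- !(ids %in% excluded_ids)
  r_all <- stats::cor(scores, ratings)
  r_exc <- stats::cor(scores[keep], ratings[keep])
  delta_obs <- r_exc - r_all
  n_subsets <- choose(n, m)
  exhaustive <- is.finite(n_subsets) && n_subsets <= n_perm
  delta_null <- if (exhaustive) {
    combs <- utils::combn(n, m)
    apply(combs, 2, function(drop) {
      stats::cor(scores[-drop], ratings[-drop]) - r_all
    })
  } else {
    withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(b) {
        drop <- sample.int(n, m)
        stats::cor(scores[-drop], ratings[-drop]) - r_all
      }, numeric(1))
    })
  }
  n_used <- length(delta_null)
  p <- (1 + sum(delta_null >= delta_obs - 1e-12)) / (n_used + 1)
  structure(list(delta_r_observed = delta_obs, p_value = p,
                 r_all = r_all, r_excluded = r_exc,
                 n_perm = n_used, seed = as.integer(seed),
                 excluded_ids = excluded_ids, exhaustive = exhaustive),
            class = "effcomm_perm")
}

#' @export
print.effcomm_perm <- function(x, ...) {
  cat(sprintf(
    "delta r = %.3f (r %.3f -> %.3f), p = %.4g (%d %s exclusions of %d paths)\n",
    x$delta_r_observed, x$r_all, x$r_excluded, x$p_value, x$n_perm,
    if (x$exhaustive) "exhaustive" else "random", length(x$excluded_ids)))
  invisible(x)
}

#' Per-movement-class model-human discrepancy
#'
#' For each movement class, the mean of (calibrated model prediction - mean
#' rating) over the paths of that class. Positive values mean the model saw
#' the movement as more communicative than participants, negative values
#' that it saw it as less communicative.
#'
#' @param calibration An [calibrate_linear()] fit.
#' @param classes Per-path movement class labels, aligned with the
#'   calibration inputs.
#' @return Data frame `class`, `discrepancy`, `n_paths`; classes with no
#'   paths are omitted with a warning.
#' @export
class_discrepancy <- function(calibration, classes) {
  stopifnot(inherits(calibration, "effcomm_calibration"),
            length(classes) == length(calibration$fitted))
  resid <- calibration$fitted - calibration$ratings
  present <- sort(unique(classes))
  missing <- setdiff(LETTERS[1:8], present)
  if (length(missing) > 0 && all(present %in% LETTERS[1:8])) {
    warning("no paths in class(es): ", paste(missing, collapse = ", "))
  }
  out <- data.frame(
    class = present,
    discrepancy = vapply(present, function(cl) mean(resid[classes == cl]),
                         numeric(1)),
    n_paths = vapply(present, function(cl) sum(classes == cl), integer(1))
  )
  rownames(out) <- NULL
  out
}

#' Linear trend of ratings across repetition counts
#'
#' OLS slope of per-path mean ratings on the number of repetitions (0, 1, 2),
#' the simple-trend analogue of a repetition effect.
#'
#' @param mean_ratings Per-path mean ratings.
#' @param repetitions Integer repetition counts, same length.
#' @return List with `slope`, `intercept`, `n`.
#' @export
repetition_trend <- function(mean_ratings, repetitions) {
  stopifnot(length(mean_ratings) == length(repetitions))
  if (length(unique(repetitions)) < 2L) {
    stop("repetition trend requires at least 2 repetition levels")
  }
  fit <- stats::lm(mean_ratings ~ repetitions)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(mean_ratings))
}

#' Recover the linking slope from a judgment table
#'
#' Estimates the slope of mean ratings on the standardized predictor by OLS
#' over path means, with a percentile bootstrap confidence interval that
#' resamples both random factors of the crossed design - participants and
#' paths - so the interval reflects generalization over raters and stimuli
#' alike (the classic subjects-and-items argument).
#'
#' @param judgments A judgment table (see [simulate_judgments()]) with a
#'   complete participant x path design.
#' @param predictor Per-path predictor values, aligned with the unique path
#'   ids in first-appearance order of `judgments$path_id`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `slope`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
recover_linking_slope <- function(judgments, predictor, n_boot = 1000L,
                                  seed = 1L, conf = 0.95) {
  ids <- unique(judgments$path_id)
  parts <- unique(judgments$participant)
  stopifnot(length(predictor) == length(ids),
            nrow(judgments) == length(ids) * length(parts))
  z <- (predictor - mean(predictor)) / stats::sd(predictor)
  # ratings as participant x path matrix (simulate_judgments emits path-major)
  ord <- order(match(judgments$path_id, ids), match(judgments$participant, parts))
  rt <- matrix(judgments$rating[ord], nrow = length(parts))
  slope_of <- function(m, zz) {
    zc <- zz - mean(zz)
    sum(zc * (colMeans(m) - mean(colMeans(m)))) / sum(zc^2)
  }
  slope <- slope_of(rt, z)
  bs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      pi <- sample.int(nrow(rt), replace = TRUE)
      qi <- sample.int(ncol(rt), replace = TRUE)
      if (stats::sd(z[qi]) == 0) return(NA_real_)
      slope_of(rt[pi, qi, drop = FALSE], z[qi])
    }, numeric(1))
  })
  qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(slope = slope, ci_low = qs[1], ci_high = qs[2],
       n_boot = as.integer(n_boot), seed = as.integer(seed))
}
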