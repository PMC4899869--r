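#' Nearest-neighbour distance summary
#'
#' Container for the per-cell distances underlying one observed (or
#' re-sampled) analysis. The summary statistic is the median, chosen over
#' the mean so a handful of isolated cells cannot dominate the estimate.
#' The even-count median is the arithmetic mean of the two central order
#' statistics.
#'
#' @param distances numeric vector of per-source-point NN distances (pixels).
#' @param mode one of `"point_to_point"`, `"point_to_region"`, `"self"`.
#' @param n_target number of target points (or region pixels).
#' @return An object of class `nn_summary`.
#' @export
nn_summary <- function(distances,
                       mode = c("point_to_point", "point_to_region", "self"),
                       n_target = NA_integer_) {
  mode <- match.arg(mode)
  distances <- as.numeric(distances)
  if (!length(distances))
    stop_nncoloc("nncoloc_empty_source", "no distances: source set is empty")
  if (!all(is.finite(distances)) || any(distances < 0))
    stop_nncoloc("nncoloc_schema", "distances must be finite and >= 0")
  structure(list(distances = distances,
                 median_distance = stats::median(distances),
                 n_source = length(distances),
                 n_target = n_target, mode = mode),
            class = "nn_summary")
}

#' Monte-Carlo null distribution of the median NN distance
#'
#' Summary of `K` re-sampling rounds. The standard deviation uses the
#' population convention (divisor `K`); at the default `K = 100000` the
#' difference from the sample convention is below 1e-5 relative, but one
#' convention must be fixed for bit-reproducibility.
#'
#' @param sampled_medians numeric vector of per-round median NN distances.
#' @param seed the integer seed the rounds were drawn under.
#' @param mode analysis mode the rounds re-computed (see [nn_summary()]).
#' @return An object of class `mc_null`.
#' @export
mc_null <- function(sampled_medians, seed = NA_integer_, mode = NULL) {
  sampled_medians <- as.numeric(sampled_medians)
  if (length(sampled_medians) < 2L)
    stop_nncoloc("nncoloc_schema", "a Monte-Carlo null needs >= 2 rounds")
  structure(list(n_rounds = length(sampled_medians),
                 sampled_medians = sampled_medians,
                 mean_median = mean(sampled_medians),
                 sd_median = pop_sd(sampled_medians),
                 seed = seed, mode = mode),
            class = "mc_null")
}

as_xy <- function(points) {
  if (inherits(points, "point_set") || is.data.frame(points))
    list(x = points$x, y = points$y)
  else stop_nncoloc("nncoloc_schema", "expected a point_set")
}

# Region pixel centers in point coordinates (x = col - 1, y = row - 1).
region_centers <- function(region) {
  region <- as.matrix(region) != 0
  idx <- which(region, arr.ind = TRUE)
  list(x = as.numeric(idx[, 2] - 1L), y = as.numeric(idx[, 1] - 1L),
       n = nrow(idx))
}

#' Distance from each query cell to the nearest reference cell
#'
#' The observed statistic of the co-localization analysis: for every source
#' point (e.g. a CD45+ immune cell), the Euclidean distance to the closest
#' target point (e.g. a senescent cell), summarised by the median.
#'
#' @param source,target [point_set]s; both must be nonempty. An image with
#'   zero reference cells yields no score — it is an error, not distance Inf.
#' @return An [nn_summary] with `mode = "point_to_point"`.
#' @export
nn_distances <- function(source, target) {
  s <- as_xy(source); t <- as_xy(target)
  if (!length(s$x))
    stop_nncoloc("nncoloc_empty_source", "source point set is empty")
  if (!length(t$x))
    stop_nncoloc("nncoloc_empty_target", "target point set is empty")
  nn_summary(cpp_nn_mindist(s$x, s$y, t$x, t$y), "point_to_point",
             n_target = length(t$x))
}

#' Distance from each cell to its nearest neighbour of the same class
#'
#' The self-association control (e.g. CD45 to CD45): each point's distance
#' to the nearest OTHER point. Exclusion is by index, not coordinate
#' equality, so coincident duplicate detections are mutual neighbours at
#' distance zero rather than being dropped.
#'
#' @param points a [point_set] with at least 2 members.
#' @return An [nn_summary] with `mode = "self"`.
#' @export
nn_distances_self <- function(points) {
  p <- as_xy(points)
  if (length(p$x) < 2L)
    stop_nncoloc("nncoloc_too_few_points",
                 "self NN distances need >= 2 points")
  nn_summary(cpp_nn_self(p$x, p$y), "self", n_target = length(p$x))
}

#' Distance from each cell to the nearest pixel of a region
#'
#' The point-to-region control (e.g. immune cells vs the epithelial layer):
#' Euclidean distance to the nearest region pixel center; a point sitting on
#' a region pixel center is at distance 0.
#'
#' @param source a nonempty [point_set].
#' @param region logical matrix with at least one `TRUE` pixel.
#' @return An [nn_summary] with `mode = "point_to_region"`.
#' @export
distance_to_region <- function(source, region) {
  s <- as_xy(source)
  if (!length(s$x))
    stop_nncoloc("nncoloc_empty_source", "source point set is empty")
  rc <- region_centers(region)
  if (!rc$n)
    stop_nncoloc("nncoloc_empty_target", "region has no pixel")
  nn_summary(cpp_nn_mindist(s$x, s$y, rc$x, rc$y), "point_to_region",
             n_target = rc$n)
}

#' Monte-Carlo null by random re-placement within the valid region
#'
#' Draws `n_rounds` rounds; in each, `n_source` points are placed uniformly
#' over the valid region (uniform choice among valid pixels plus uniform
#' sub-pixel jitter in \[−0.5, +0.5\] per axis — exactly uniform over the
#' valid area) and the round's median NN distance is recorded. Only the
#' query class is re-placed; in `point_to_point` and `point_to_region` modes
#' the reference geometry stays fixed at its observed positions, so the null
#' is conditioned on it. In `self` mode the whole set is re-placed and the
#' self-excluded NN median recomputed. Bit-reproducible from `(seed, inputs)`.
#'
#' @param n_source number of query points per round.
#' @param target a [point_set] (point_to_point), logical region matrix
#'   (point_to_region), or `NULL` (self).
#' @param mask a [region_mask]; placement is over `mask$valid`.
#' @param n_rounds number of Monte-Carlo rounds (>= 2); default 100000.
#' @param seed integer seed for this null.
#' @param mode analysis mode, see [nn_summary()].
#' @return An [mc_null].
#' @export
sample_null <- function(n_source, target, mask, n_rounds = 100000L, seed,
                        mode = c("point_to_point", "point_to_region", "self")) {
  mode <- match.arg(mode)
  if (n_source < 1L)
    stop_nncoloc("nncoloc_empty_source", "n_source must be >= 1")
  if (mode == "self" && n_source < 2L)
    stop_nncoloc("nncoloc_too_few_points", "self mode needs n_source >= 2")
  if (n_rounds < 2L)
    stop_nncoloc("nncoloc_schema", "n_rounds must be >= 2")
  if (!inherits(mask, "region_mask"))
    stop_nncoloc("nncoloc_schema", "mask must be a region_mask")
  vc <- region_centers(mask$valid)
  if (mode == "point_to_point") {
    t <- as_xy(target)
    if (!length(t$x))
      stop_nncoloc("nncoloc_empty_target", "target point set is empty")
    tx <- t$x; ty <- t$y; cmode <- 0L
  } else if (mode == "point_to_region") {
    rc <- region_centers(target)
    if (!rc$n) stop_nncoloc("nncoloc_empty_target", "region has no pixel")
    tx <- rc$x; ty <- rc$y; cmode <- 0L
  } else {
    tx <- numeric(0); ty <- numeric(0); cmode <- 1L
  }
  meds <- with_seed(seed, cpp_mc_medians(as.integer(n_source), tx, ty,
                                         vc$x, vc$y,
                                         as.integer(n_rounds), cmode))
  mc_null(meds, seed = as.integer(seed), mode = mode)
}

#' Normalized association score
#'
#' The core statistic: `(null mean median − observed median) / null sd of
#' medians`. It measures how many null standard deviations the observed
#' median NN distance lies below (positive: the query class sits closer to
#' the reference than chance — association) or above (negative — repulsion)
#' the random expectation. The empirical percentile is the fraction of
#' sampled medians strictly greater than the observed median; ties count
#' against association. For a near-Gaussian null a score of 2 corresponds
#' to an observed median smaller than about 97.5% of the sampled medians.
#'
#' @param observed an [nn_summary].
#' @param null an [mc_null] computed in the same mode against the same
#'   reference geometry.
#' @param sample_id identifier recorded in the result.
#' @param config_echo named list echoed into the result (and its JSON).
#' @return An object of class `nn_assoc` with fields `observed`, `null`,
#'   `score`, `percentile`, `sample_id`, `config_echo`.
#' @export
association_score <- function(observed, null, sample_id = NA_character_,
                              config_echo = list()) {
  if (!inherits(observed, "nn_summary") || !inherits(null, "mc_null"))
    stop_nncoloc("nncoloc_schema",
                 "association_score() needs an nn_summary and an mc_null")
  if (!is.null(null$mode) && !identical(null$mode, observed$mode))
    stop_nncoloc("nncoloc_mode_mismatch",
                 sprintf("observed mode '%s' but null mode '%s'",
                         observed$mode, null$mode))
  if (null$sd_median <= 0)
    stop_nncoloc("nncoloc_degenerate_null",
                 "all sampled medians identical (sd = 0); score undefined")
  score <- (null$mean_median - observed$median_distance) / null$sd_median
  percentile <- sum(null$sampled_medians > observed$median_distance) /
    null$n_rounds
  structure(list(observed = observed, null = null, score = score,
                 percentile = percentile, sample_id = sample_id,
                 config_echo = config_echo),
            class = "nn_assoc")
}

#' Fit the co-localization analysis for one sample
#'
#' The one-call unit applied once per image: computes the observed median
#' NN distance of `source` against the reference (`target` points, a region,
#' or the source itself), builds the Monte-Carlo null by re-placing the
#' source class uniformly within `mask$valid`, and returns the normalized
#' association score with its empirical percentile.
#'
#' @param source a [point_set] of query cells (e.g. CD45+).
#' @param target a [point_set] of reference cells (`mode =
#'   "point_to_point"`), a logical region matrix or the name of one of
#'   `mask$excluded` (`mode = "point_to_region"`), or `NULL` (`mode =
#'   "self"`).
#' @param mask a [region_mask].
#' @param mode analysis mode; see [nn_summary()].
#' @param n_rounds Monte-Carlo rounds; default 100000.
#' @param seed integer seed (use [derive_seed()] for batch runs).
#' @param sample_id identifier; defaults to the source's sample id.
#' @return An `nn_assoc` object; see [association_score()]. Methods:
#'   `print`, `summary`, `coef`, `plot`, `simulate`.
#' @examples
#' mask <- region_mask(matrix(TRUE, 64, 64))
#' set.seed(1)
#' tgt <- point_set(runif(20, 0, 63), runif(20, 0, 63), provenance = "simulated")
#' src <- point_set(runif(50, 0, 63), runif(50, 0, 63), provenance = "simulated")
#' fit <- analyze_sample(src, tgt, mask, n_rounds = 500, seed = 7)
#' fit
#' @export
analyze_sample <- function(source, target = NULL, mask,
                           mode = c("point_to_point", "point_to_region",
                                    "self"),
                           n_rounds = 100000L, seed,
                           sample_id = NULL) {
  mode <- match.arg(mode)
  if (is.null(sample_id))
    sample_id <- if (!is.null(attr(source, "sample_id")))
      attr(source, "sample_id") else NA_character_
  if (mode == "point_to_region" && is.character(target)) {
    if (!target %in% names(mask$excluded))
      stop_nncoloc("nncoloc_schema",
                   sprintf("mask has no excluded region '%s'", target))
    target <- mask$excluded[[target]]
  }
  observed <- switch(mode,
    point_to_point = nn_distances(source, target),
    point_to_region = distance_to_region(source, target),
    self = nn_distances_self(source))
  null <- sample_null(observed$n_source, target, mask,
                      n_rounds = n_rounds, seed = seed, mode = mode)
  config_echo <- list(mode = mode, n_rounds = as.integer(n_rounds),
                      seed = as.integer(seed),
                      n_source = observed$n_source,
                      n_target = observed$n_target,
                      n_valid_px = sum(mask$valid))
  association_score(observed, null, sample_id = sample_id,
                    config_echo = config_echo)
}

#' @export
print.nn_assoc <- function(x, ...) {
  cat("Nearest-neighbour co-localization analysis\n")
  cat(sprintf("  sample: %s   mode: %s\n", x$sample_id, x$observed$mode))
  cat(sprintf("  observed median NN distance: %.4g px (n_source = %d)\n",
              x$observed$median_distance, x$observed$n_source))
  cat(sprintf("  null: mean %.4g, sd %.4g (K = %d rounds, seed %s)\n",
              x$null$mean_median, x$null$sd_median, x$null$n_rounds,
              x$null$seed))
  cat(sprintf("  association score: %.3f   empirical percentile: %.4f\n",
              x$score, x$percentile))
  invisible(x)
}

#' @export
summary.nn_assoc <- function(object, ...) {
  out <- list(sample_id = object$sample_id, mode = object$observed$mode,
              n_source = object$observed$n_source,
              n_target = object$observed$n_target,
              observed_median = object$observed$median_distance,
              null_mean = object$null$mean_median,
              null_sd = object$null$sd_median,
              n_rounds = object$null$n_rounds,
              score = object$score, percentile = object$percentile,
              call = if (object$score > 0 && object$percentile >= 0.975)
                "association" else if (object$score < 0 &&
                                       object$percentile <= 0.025)
                "repulsion" else "none")
  class(out) <- "summary.nn_assoc"
  out
}

#' @export
print.summary.nn_assoc <- function(x, ...) {
  cat(sprintf("sample %s (%s): score %.3f, percentile %.4f -> %s\n",
              x$sample_id, x$mode, x$score, x$percentile, x$call))
  cat(sprintf("  observed median %.4g px vs null %.4g +/- %.4g (K = %d)\n",
              x$observed_median, x$null_mean, x$null_sd, x$n_rounds))
  invisible(x)
}

#' @export
coef.nn_assoc <- function(object, ...) {
  c(score = object$score)
}

#' Plot the Monte-Carlo null with the observed median
#'
#' Histogram of the sampled medians; the observed median NN distance is the
#' vertical line. An observed line far left of the null mass indicates
#' association.
#'
#' @param x an `nn_assoc` object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.nn_assoc <- function(x, ...) {
  graphics::hist(x$null$sampled_medians, breaks = 50, col = "grey85",
                 border = NA,
                 main = sprintf("sample %s: score %.2f", x$sample_id, x$score),
                 xlab = "median NN distance (px)", ...)
  graphics::abline(v = x$observed$median_distance, col = "firebrick", lwd = 2)
  graphics::abline(v = x$null$mean_median, col = "grey40", lty = 2)
  graphics::legend("topright", legend = c("observed", "null mean"),
                   col = c("firebrick", "grey40"), lty = c(1, 2), lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Draw median NN distances from the fitted null
#'
#' Samples with replacement from the stored Monte-Carlo null distribution —
#' useful for envelope displays without re-running the placement loop.
#'
#' @param object an `nn_assoc` object.
#' @param nsim number of draws.
#' @param seed optional seed.
#' @param ... unused.
#' @export
simulate.nn_assoc <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() sample(object$null$sampled_medians, nsim, replace = TRUE)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Per-cell residual distances
#'
#' Each query cell's NN distance minus the null mean median: negative values
#' mark cells sitting closer to the reference class than the typical random
#' placement.
#'
#' @param object an `nn_assoc` object.
#' @param ... unused.
#' @export
residuals.nn_assoc <- function(object, ...) {
  object$observed$distances - object$null$mean_median
}
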