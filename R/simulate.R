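# Synthetic-data generators for the three data kinds the analyses consume:
# identification confusion matrices, per-participant GRT-wIND matrix lists,
# and Garner filtering trial tables with response times under the
# RT-distance hypothesis.

# Draw n percepts from a gaussian2d (own Cholesky; 2x2 case).
.draw_percepts <- function(dist, n) {
  sx <- sqrt(dist$var[1]); sy <- sqrt(dist$var[2])
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- dist$mean[1] + sx * z1
  y <- dist$mean[2] + sy * (dist$rho * z1 + sqrt(1 - dist$rho^2) * z2)
  cbind(x, y)
}

# Classify percepts with both bounds: returns response index 1..4 in
# canonical order (a1b1, a2b1, a1b2, a2b2).
.classify <- function(xy, bound_a, bound_b) {
  a2 <- xy[, 1] > bound_a$slope * xy[, 2] + bound_a$intercept
  b2 <- xy[, 2] > bound_b$slope * xy[, 1] + bound_b$intercept
  1L + a2 + 2L * b2
}

#' Simulate a 2x2 identification experiment
#'
#' For each stimulus, draws `n_per_stimulus` percepts from its perceptual
#' distribution, classifies each percept with the two decision bounds, and
#' tallies the resulting 4x4 confusion matrix.
#'
#' @param model a [grt_model()].
#' @param n_per_stimulus trials per stimulus.
#' @param seed optional integer seed; fixed seed gives an identical matrix.
#' @return a [grt_confusion_matrix()] with all row totals equal to
#'   `n_per_stimulus`. When `n_per_stimulus = 0` the raw zero count matrix
#'   is returned (plain matrix, attribute `empty = TRUE`) since an all-zero
#'   table is not a valid confusion matrix.
#' @examples
#' m <- grt_model(list(gaussian2d(c(0, 0)), gaussian2d(c(2, 0)),
#'                     gaussian2d(c(0, 2)), gaussian2d(c(2, 2))),
#'                linear_bound(0, 1, "A"), linear_bound(0, 1, "B"))
#' simulate_identification(m, 100, seed = 1)
#' @export
simulate_identification <- function(model, n_per_stimulus, seed = NULL) {
  stopifnot(inherits(model, "grt_model"), n_per_stimulus >= 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(0L, 4, 4)
  if (n_per_stimulus == 0)
    return(structure(counts, empty = TRUE))
  for (s in 1:4) {
    xy <- .draw_percepts(model$dists[[s]], n_per_stimulus)
    resp <- .classify(xy, model$bound_a, model$bound_b)
    counts[s, ] <- tabulate(resp, nbins = 4)
  }
  grt_confusion_matrix(counts)
}

#' Simulate a multi-participant GRT-wIND experiment
#'
#' Applies each participant's attention scaling and personal bounds to the
#' shared group distributions, then simulates an identification experiment
#' per participant. Per-participant seeds are derived deterministically
#' from the master seed.
#'
#' @param model a [wind_model()].
#' @param n_per_stimulus trials per stimulus per participant.
#' @param seed optional integer master seed.
#' @return a list of [grt_confusion_matrix()] objects, one per participant.
#' @export
simulate_wind <- function(model, n_per_stimulus, seed = NULL) {
  stopifnot(inherits(model, "wind_model"))
  K <- length(model$participants)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, K)
  lapply(seq_len(K), function(p)
    simulate_identification(.wind_participant_model(model, p),
                            n_per_stimulus, seed = seeds[p]))
}

#' Response-time model parameters for the Garner simulator
#'
#' Under the RT-distance hypothesis, percepts farther from the decision
#' bound yield faster responses. The simulator uses the strictly
#' decreasing form RT = (t0 + a exp(-b d)) * exp(e), d the perpendicular
#' distance from the percept to the relevant bound and e ~ Normal(0, sd^2)
#' (multiplicative lognormal noise).
#'
#' @param t0 base response time (same unit as the data, e.g. ms); > 0.
#' @param a scale of the distance-dependent component; >= 0.
#' @param b decay rate of the distance effect; > 0.
#' @param sd lognormal sigma of the trial noise; >= 0.
#' @return an object of class `rt_params`.
#' @export
rt_params <- function(t0 = 350, a = 300, b = 1, sd = 0.15) {
  stopifnot(t0 > 0, a >= 0, b > 0, sd >= 0)
  structure(list(t0 = t0, a = a, b = b, sd = sd), class = "rt_params")
}

#' Simulate a 2x2 Garner filtering task
#'
#' Baseline blocks fix the irrelevant dimension (two sub-blocks of
#' `n_baseline / 2` trials, one per irrelevant level, so baseline
#' statistics are level-balanced); the filtering block mixes all four
#' stimuli equally over `n_filtering` trials. Each trial draws a percept
#' from the stimulus distribution, responds by the single relevant bound,
#' and produces an RT from the RT-distance model in [rt_params()].
#' `context_slowdown` is added to the base time on filtering trials only,
#' emulating a pure context effect (slower filtering blocks without any
#' separability failure).
#'
#' @param model a [grt_model()]; the bound for the relevant dimension is
#'   used as the classification bound.
#' @param relevant which dimension is classified, `"A"` or `"B"`.
#' @param rt an [rt_params()] object.
#' @param n_baseline total baseline trials (split over the two sub-blocks).
#' @param n_filtering filtering trials.
#' @param context_slowdown additive filtering-only slowdown of the base
#'   time (same unit as `t0`).
#' @param seed optional integer seed.
#' @return a [garner_trials()] table.
#' @export
simulate_garner <- function(model, relevant = c("A", "B"), rt = rt_params(),
                            n_baseline, n_filtering, context_slowdown = 0,
                            seed = NULL) {
  relevant <- match.arg(relevant)
  stopifnot(inherits(model, "grt_model"), inherits(rt, "rt_params"),
            n_baseline >= 0, n_filtering >= 0)
  if (!is.null(seed)) set.seed(seed)
  bound <- if (relevant == "A") model$bound_a else model$bound_b
  own <- if (relevant == "A") .grt_levels_a else .grt_levels_b
  oth <- if (relevant == "A") .grt_levels_b else .grt_levels_a

  one_trial <- function(rel, irr, block) {
    stim <- which(own == rel & oth == irr)
    xy <- .draw_percepts(model$dists[[stim]], 1)
    if (relevant == "A") {
      resp <- 1L + (xy[1] > bound$slope * xy[2] + bound$intercept)
      d <- abs(xy[1] - bound$slope * xy[2] - bound$intercept) /
        sqrt(1 + bound$slope^2)
    } else {
      resp <- 1L + (xy[2] > bound$slope * xy[1] + bound$intercept)
      d <- abs(xy[2] - bound$slope * xy[1] - bound$intercept) /
        sqrt(1 + bound$slope^2)
    }
    t0 <- rt$t0 + if (block == 2) context_slowdown else 0
    time <- (t0 + rt$a * exp(-rt$b * d)) * exp(rnorm(1, 0, rt$sd))
    c(block, rel, irr, as.integer(resp == rel), time)
  }

  rows <- list()
  n_half <- floor(n_baseline / 2)
  for (irr in 1:2) for (i in seq_len(n_half))
    rows[[length(rows) + 1L]] <- one_trial(sample(1:2, 1), irr, 1L)
  for (i in seq_len(n_filtering))
    rows[[length(rows) + 1L]] <- one_trial(sample(1:2, 1), sample(1:2, 1), 2L)
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("block", "relevant", "irrelevant", "accuracy", "rt")
  garner_trials(df)
}
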