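#' Bivariate Gaussian perceptual distribution
#'
#' The perceptual representation of one stimulus: repeated presentations
#' evoke percepts scattered around a mean according to a two-dimensional
#' Gaussian. Dimension A runs along the horizontal (x) axis and dimension B
#' along the vertical (y) axis.
#'
#' @param mean numeric length-2 vector `(mu_x, mu_y)`.
#' @param var numeric length-2 vector of positive variances
#'   `(sigma_x^2, sigma_y^2)`.
#' @param rho correlation between the two dimensions, in (-1, 1). A nonzero
#'   value is a violation of perceptual independence for this stimulus.
#' @return an object of class `gaussian2d`.
#' @export
gaussian2d <- function(mean = c(0, 0), var = c(1, 1), rho = 0) {
  stopifnot(length(mean) == 2, length(var) == 2, length(rho) == 1)
  if (any(var <= 0)) stop("variances must be positive", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  structure(list(mean = as.numeric(mean), var = as.numeric(var),
                 rho = as.numeric(rho)), class = "gaussian2d")
}

#' Linear decision bound
#'
#' For `axis = "A"` the bound is the line x = slope*y + intercept and the
#' observer responds level 2 on A whenever the percept satisfies
#' x > slope*y + intercept; for `axis = "B"` it is y = slope*x + intercept
#' with the analogous rule. Decisional separability on an axis holds exactly
#' when that axis's slope is 0.
#'
#' @param slope bound slope (0 = decisionally separable).
#' @param intercept bound intercept.
#' @param axis `"A"` or `"B"`.
#' @return an object of class `linear_bound`.
#' @export
linear_bound <- function(slope = 0, intercept = 0, axis = c("A", "B")) {
  axis <- match.arg(axis)
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept),
                 axis = axis), class = "linear_bound")
}

#' Full GRT model of the 2x2 identification task
#'
#' Four perceptual distributions (one per stimulus, in the canonical order
#' A1B1, A2B1, A1B2, A2B2) plus one linear decision bound per dimension.
#' Larger x means level 2 of A; larger y means level 2 of B.
#'
#' @param dists list of four [gaussian2d()] distributions.
#' @param bound_a decision bound for dimension A (a [linear_bound()] with
#'   `axis = "A"`).
#' @param bound_b decision bound for dimension B.
#' @return an object of class `grt_model`.
#' @export
grt_model <- function(dists, bound_a = linear_bound(axis = "A"),
                      bound_b = linear_bound(0, 0, "B")) {
  if (length(dists) != 4L || !all(vapply(dists, inherits, TRUE, "gaussian2d")))
    stop("dists must be a list of exactly four gaussian2d objects",
         call. = FALSE)
  stopifnot(inherits(bound_a, "linear_bound"), inherits(bound_b, "linear_bound"))
  if (bound_a$axis != "A" || bound_b$axis != "B")
    stop("bound_a must have axis A and bound_b axis B", call. = FALSE)
  names(dists) <- .grt_order
  structure(list(dists = dists, bound_a = bound_a, bound_b = bound_b),
            class = "grt_model")
}

#' Response-region probabilities for one perceptual distribution
#'
#' Probability that a percept drawn from `dist` falls in each of the four
#' response regions cut out by the two bounds. With discriminants
#' u = x - m_A*y - b_A and v = y - m_B*x - b_B, the pair (u, v) is bivariate
#' normal and the four regions are its quadrants about the origin; the
#' probabilities are computed from the bivariate normal CDF.
#'
#' @param dist a [gaussian2d()].
#' @param bound_a,bound_b the two [linear_bound()]s.
#' @return numeric vector of four probabilities in response order
#'   a1b1, a2b1, a1b2, a2b2, summing to 1.
#' @examples
#' region_probabilities(gaussian2d(rho = 0.5), linear_bound(axis = "A"),
#'                      linear_bound(axis = "B"))
#' @export
region_probabilities <- function(dist, bound_a, bound_b) {
  stopifnot(inherits(dist, "gaussian2d"))
  p <- cpp_region_probs(dist$mean, dist$var, dist$rho,
                        bound_a$slope, bound_a$intercept,
                        bound_b$slope, bound_b$intercept)
  names(p) <- tolower(.grt_order)
  p
}

#' Predicted confusion matrix of a GRT model
#'
#' Row i is the vector of response probabilities for stimulus i; every row
#' sums to 1.
#'
#' @param model a [grt_model()].
#' @return a 4x4 row-stochastic matrix in the canonical order.
#' @export
predicted_matrix <- function(model) {
  stopifnot(inherits(model, "grt_model"))
  p <- t(vapply(model$dists, region_probabilities, numeric(4),
                bound_a = model$bound_a, bound_b = model$bound_b))
  dimnames(p) <- list(stimulus = .grt_order, response = tolower(.grt_order))
  p
}

#' Multinomial log-likelihood of a confusion matrix under a GRT model
#'
#' Computes sum over cells of r_ij * log(p_ij), with each predicted
#' probability floored at 1e-10 so the result is always finite.
#'
#' @param model a [grt_model()].
#' @param cm a [grt_confusion_matrix()].
#' @return the log-likelihood (a finite number, at most 0).
#' @export
grt_log_likelihood <- function(model, cm) {
  stopifnot(inherits(cm, "grt_cm"))
  p <- pmax(predicted_matrix(model), 1e-10)
  sum(unclass(cm) * log(p))
}

#' @export
print.grt_model <- function(x, ...) {
  cat("GRT model for the 2x2 identification task\n")
  for (i in seq_along(x$dists)) {
    d <- x$dists[[i]]
    cat(sprintf("  %s: mean (%.3f, %.3f)  var (%.3f, %.3f)  rho %.3f\n",
                .grt_order[i], d$mean[1], d$mean[2], d$var[1], d$var[2],
                d$rho))
  }
  cat(sprintf("  bound A: x = %.3f y + %.3f\n", x$bound_a$slope,
              x$bound_a$intercept))
  cat(sprintf("  bound B: y = %.3f x + %.3f\n", x$bound_b$slope,
              x$bound_b$intercept))
  invisible(x)
}
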