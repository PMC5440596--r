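# Model visualization: one equal-density ellipse per perceptual
# distribution, decision bounds, marginal density curves along both axes
# (solid vs dotted by the level of the opposite dimension), and an optional
# inset of observed vs predicted response proportions.

.ellipse_xy <- function(dist, level = 1) {
  # contour at `level` standard deviations
  s <- c(sqrt(dist$var[1]), sqrt(dist$var[2]))
  cv <- matrix(c(dist$var[1], dist$rho * s[1] * s[2],
                 dist$rho * s[1] * s[2], dist$var[2]), 2)
  ch <- chol(cv)
  th <- seq(0, 2 * pi, length.out = 120)
  circ <- cbind(cos(th), sin(th)) * level
  sweep(circ %*% ch, 2, dist$mean, `+`)
}

#' Plot a GRT model
#'
#' Draws the four perceptual distributions as 1-SD ellipses (plus sign at
#' each mean), the two decision bounds, and the marginal densities of each
#' dimension along the axes — solid where the opposite dimension is at
#' level 1, dotted at level 2, so non-overlapping line styles signal a
#' failure of perceptual separability. When an observed confusion matrix
#' is supplied, a bottom-left inset plots observed against predicted
#' response proportions with the identity diagonal.
#'
#' @param model a [grt_model()].
#' @param observed optional [grt_confusion_matrix()] for the inset.
#' @param main plot title.
#' @param contour_sd radius of the equal-density contour, in SD units.
#' @return invisibly, the predicted matrix (when `observed` is given) or
#'   `NULL`.
#' @export
plot_grt_model <- function(model, observed = NULL, main = "GRT model",
                           contour_sd = 1) {
  stopifnot(inherits(model, "grt_model"))
  ells <- lapply(model$dists, .ellipse_xy, level = contour_sd)
  xr <- range(vapply(ells, function(e) range(e[, 1]), numeric(2)))
  yr <- range(vapply(ells, function(e) range(e[, 2]), numeric(2)))
  pad <- 0.35 * c(diff(xr), diff(yr))
  xr <- xr + c(-pad[1], pad[1] * 0.3)
  yr <- yr + c(-pad[2], pad[2] * 0.3)
  op <- graphics::par(mar = c(2, 2, 2.5, 1))
  on.exit(graphics::par(op))
  plot(NA, xlim = xr, ylim = yr, xlab = "", ylab = "", axes = FALSE,
       main = main, asp = NA)
  graphics::box()
  cols <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a")
  for (i in 1:4) {
    graphics::lines(ells[[i]], col = cols[i], lwd = 2)
    graphics::points(model$dists[[i]]$mean[1], model$dists[[i]]$mean[2],
                     pch = 3, col = cols[i], lwd = 2)
  }
  # decision bounds across the full panel
  ya <- seq(yr[1], yr[2], length.out = 2)
  graphics::lines(model$bound_a$slope * ya + model$bound_a$intercept, ya,
                  lty = 1, lwd = 1.5, col = "grey30")
  xb <- seq(xr[1], xr[2], length.out = 2)
  graphics::lines(xb, model$bound_b$slope * xb + model$bound_b$intercept,
                  lty = 1, lwd = 1.5, col = "grey30")
  # marginal densities: dimension A along the bottom edge, B along the left
  gx <- seq(xr[1], xr[2], length.out = 200)
  gy <- seq(yr[1], yr[2], length.out = 200)
  hx <- 0.28 * pad[1]; hy <- 0.28 * pad[2]
  for (i in 1:4) {
    d <- model$dists[[i]]
    dens_x <- dnorm(gx, d$mean[1], sqrt(d$var[1]))
    dens_y <- dnorm(gy, d$mean[2], sqrt(d$var[2]))
    lty_x <- if (.grt_levels_b[i] == 1) 1 else 3
    lty_y <- if (.grt_levels_a[i] == 1) 1 else 3
    graphics::lines(gx, yr[1] + dens_x / max(dens_x) * hy * 2,
                    lty = lty_x, col = cols[i])
    graphics::lines(xr[1] + dens_y / max(dens_y) * hx * 2, gy,
                    lty = lty_y, col = cols[i])
  }
  pred <- NULL
  if (!is.null(observed)) {
    stopifnot(inherits(observed, "grt_cm"))
    pred <- predicted_matrix(model)
    obs <- unclass(observed) / rowSums(observed)
    ofig <- graphics::par(fig = c(0.08, 0.38, 0.1, 0.4), new = TRUE,
                          mar = c(1.6, 1.6, 0.4, 0.2), mgp = c(0.6, 0.2, 0),
                          tcl = -0.15, cex.axis = 0.5, cex.lab = 0.6)
    plot(as.numeric(pred), as.numeric(obs), xlim = 0:1, ylim = 0:1,
         pch = 16, cex = 0.5, xlab = "predicted", ylab = "observed")
    graphics::abline(0, 1, col = "grey50")
    graphics::par(ofig)
  }
  invisible(pred)
}

#' Render a model plot to a file
#'
#' Thin wrapper around [plot_grt_model()] that opens a png, pdf or svg
#' device at `file`, draws the model, and closes the device.
#'
#' @inheritParams plot_grt_model
#' @param file output path.
#' @param format one of `"png"`, `"pdf"`, `"svg"`; defaults to the file
#'   extension.
#' @param width,height device size in inches.
#' @return `file`, invisibly.
#' @export
plot_model <- function(model, file, observed = NULL,
                       format = c("png", "pdf", "svg"),
                       main = "GRT model", contour_sd = 1,
                       width = 6, height = 6) {
  ext <- tolower(tools::file_ext(file))
  format <- if (missing(format) && ext %in% c("png", "pdf", "svg")) ext
            else match.arg(format)
  switch(format,
         png = grDevices::png(file, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(file, width = width, height = height),
         svg = grDevices::svg(file, width = width, height = height))
  on.exit(grDevices::dev.off())
  plot_grt_model(model, observed = observed, main = main,
                 contour_sd = contour_sd)
  invisible(file)
}

#' @export
plot.grt_model <- function(x, y = NULL, ...) plot_grt_model(x, observed = y, ...)

#' @export
plot.grt_hierarchy <- function(x, ...) {
  plot_grt_model(x$best$model, observed = x$cm,
                 main = paste("Best model:", x$best$label), ...)
}

#' @export
plot.wind_fit <- function(x, participant = 1, observed = NULL, ...) {
  plot_grt_model(.wind_participant_model(x$model, participant),
                 observed = observed,
                 main = sprintf("GRT-wIND fit, participant %d", participant),
                 ...)
}
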