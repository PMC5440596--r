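# Traditional model-based analysis: fit the 12-model GRT hierarchy to one
# confusion matrix by multi-start maximum likelihood and rank by AICc
# (small-sample correction over the 16 data cells of the design).
# All 12 models assume decisional separability and unit variances; the
# hierarchy crosses {PS both, PS(A) only, PS(B) only, neither} with
# {PI, single shared correlation (1_RHO), four free correlations}.

.pi_labels <- c(PI = "PI", single_rho = "1_RHO", free = "")

.model_label <- function(ps_a, ps_b, pi_mode) {
  parts <- c(.pi_labels[[pi_mode]],
             if (ps_a) "PS(A)", if (ps_b) "PS(B)", "DS")
  paste0("{", paste(parts[nzchar(parts)], collapse = ", "), "}")
}

#' Enumerate the 12 traditional GRT models
#'
#' The hierarchy crosses the perceptual-separability pattern (both
#' dimensions, A only, B only, neither) with the correlation structure
#' (perceptual independence, one shared correlation, four free
#' correlations). Decisional separability is assumed throughout, all
#' variances are fixed at 1, and the A1B1 mean is anchored at the origin;
#' `k` counts the free parameters that remain.
#'
#' @return a data frame with one row per model: `label`, `ps_a`, `ps_b`,
#'   `pi_mode`, `k`.
#' @examples
#' grt_hierarchy_models()
#' @export
grt_hierarchy_models <- function() {
  ps <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))
  pi_modes <- c("PI", "single_rho", "free")
  rows <- list()
  for (p in ps) for (pm in pi_modes) {
    means_k <- 6L - 2L * sum(p)
    corr_k <- c(PI = 0L, single_rho = 1L, free = 4L)[[pm]]
    rows[[length(rows) + 1L]] <- data.frame(
      label = .model_label(p[1], p[2], pm), ps_a = p[1], ps_b = p[2],
      pi_mode = pm, k = means_k + corr_k + 2L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Fit one traditional GRT model by multi-start maximum likelihood
#'
#' Maximizes the multinomial log-likelihood of the confusion matrix over
#' the model's free parameters. Each of the `n_starts` runs starts from the
#' canonical PS+PI+DS configuration (means on the unit grid, zero
#' correlations, bounds at 0.5) plus independent uniform perturbations on
#' `[-perturb, perturb]` per parameter; the best run is kept. Correlations
#' are constrained to (-0.99, 0.99) by a smooth tanh transform.
#'
#' @param spec one row of [grt_hierarchy_models()] (or a list with elements
#'   `ps_a`, `ps_b`, `pi_mode`).
#' @param cm a [grt_confusion_matrix()].
#' @param n_starts number of random restarts.
#' @param perturb half-width of the uniform start perturbation.
#' @param seed optional integer seed for the perturbations.
#' @param control list of control parameters passed through to
#'   [stats::optim()].
#' @return a list of class `grt_fit`: `spec`, `params` (named full
#'   parameter vector), `model` (the fitted [grt_model()]), `logL`, `aicc`,
#'   `k`, `converged`, `n_starts_used`.
#' @export
fit_grt_model <- function(spec, cm, n_starts = 10, perturb = 0.3,
                          seed = NULL, control = list()) {
  stopifnot(inherits(cm, "grt_cm"), n_starts >= 1, perturb >= 0)
  if (!is.null(seed)) set.seed(seed)
  spec <- as.list(spec)
  pm <- .wind_param_map(1L, ps_a = spec$ps_a, ps_b = spec$ps_b,
                        pi_mode = spec$pi_mode, fix_variances = TRUE,
                        fix_attention = TRUE)
  counts <- .counts_matrix(cm)
  fit <- .fit_mapped(counts, pm, n_starts, perturb, control)
  k <- pm$n_free
  # AICc sample size: the 2x2 design yields 16 data cells per participant,
  # which is what the small-sample correction has to guard against.
  N <- 16
  logL <- -fit$value
  aicc <- -2 * logL + 2 * k + 2 * k * (k + 1) / (N - k - 1)
  structure(list(spec = spec,
                 label = .model_label(spec$ps_a, spec$ps_b, spec$pi_mode),
                 params = fit$full, model = .full_to_grt_model(fit$full),
                 logL = logL, aicc = aicc, k = k,
                 converged = fit$converged,
                 n_starts_used = fit$n_starts_used),
            class = "grt_fit")
}

#' Fit the full 12-model hierarchy and select by AICc
#'
#' Fits every model in [grt_hierarchy_models()] with [fit_grt_model()],
#' ranks by the corrected Akaike information criterion
#' AICc = -2 logL + 2k + 2k(k+1)/(N - k - 1) with N the total trial count,
#' and reports Akaike weights w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2),
#' interpretable as the probability that a model is closest to the truth
#' among those tested. Ties break toward fewer parameters, then enumeration
#' order.
#'
#' @inheritParams fit_grt_model
#' @return an object of class `grt_hierarchy`: `fits` (list of `grt_fit`,
#'   ranked), `table` (ranked data frame with logL, AICc, weight), `best`
#'   (the winning fit) and `conclusions` (logical `ps_a`, `ps_b`,
#'   `pi_violated` read off the winning spec).
#' @examples
#' \donttest{
#' fit <- fit_grt_hierarchy(grt_face_example(), seed = 1)
#' summary(fit)
#' }
#' @export
fit_grt_hierarchy <- function(cm, n_starts = 10, perturb = 0.3, seed = NULL,
                              control = list()) {
  stopifnot(inherits(cm, "grt_cm"))
  if (!is.null(seed)) set.seed(seed)
  specs <- grt_hierarchy_models()
  fits <- lapply(seq_len(nrow(specs)), function(i)
    fit_grt_model(specs[i, ], cm, n_starts = n_starts, perturb = perturb,
                  seed = NULL, control = control))
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  k <- vapply(fits, `[[`, numeric(1), "k")
  ord <- order(aicc, k, seq_along(fits))
  fits <- fits[ord]
  aicc <- aicc[ord]
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "label"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    AICc = aicc, weight = w, stringsAsFactors = FALSE)
  best <- fits[[1]]
  structure(list(fits = fits, table = tab, best = best,
                 conclusions = list(ps_a = best$spec$ps_a,
                                    ps_b = best$spec$ps_b,
                                    pi_violated = best$spec$pi_mode != "PI"),
                 seed = seed, n_starts = n_starts, perturb = perturb,
                 cm = cm),
            class = "grt_hierarchy")
}

#' @export
print.grt_fit <- function(x, ...) {
  cat(sprintf("GRT model %s: logL = %.3f, AICc = %.3f, k = %d%s\n",
              x$label, x$logL, x$aicc, x$k,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.grt_hierarchy <- function(object, ...) {
  cat("Model-based analysis of the 2x2 identification task\n")
  cat(sprintf("(12-model hierarchy, %d starts, perturbation %.2f)\n\n",
              object$n_starts, object$perturb))
  tab <- object$table
  tab$logL <- sprintf("%.2f", tab$logL)
  tab$AICc <- sprintf("%.2f", tab$AICc)
  tab$weight <- sprintf("%.3f", tab$weight)
  print(tab, row.names = FALSE)
  cat(sprintf("\nBest model: %s\n", object$best$label))
  cc <- object$conclusions
  cat(sprintf("  PS of dimension A: %s\n",
              if (cc$ps_a) "assumed to hold" else "violated"))
  cat(sprintf("  PS of dimension B: %s\n",
              if (cc$ps_b) "assumed to hold" else "violated"))
  cat(sprintf("  PI: %s\n",
              if (cc$pi_violated) "violated" else "assumed to hold"))
  if (!all(vapply(object$fits, `[[`, TRUE, "converged")))
    cat("\nWarning: some member fits did not converge.\n")
  invisible(object)
}

#' @export
print.grt_hierarchy <- function(x, ...) summary(x, ...)
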