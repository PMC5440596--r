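# Summary-statistics analysis of the 2x2 Garner filtering task: Garner
# interference on response time and accuracy (baseline vs filtering), and
# the more diagnostic single-block tests — marginal response invariance
# (mRi) and marginal response-time invariance (mRTi) — computed on
# filtering blocks, where context effects cannot masquerade as
# separability failures.

.garner_code <- function(violated) if (violated) "NO" else "yes?"

#' Garner interference test on response times
#'
#' Welch two-sample t test comparing correct-trial response times between
#' filtering and baseline blocks. The verdict is directional: the test is
#' failed (`NO`) only when the difference is significant *and* filtering is
#' slower.
#'
#' @param trials a [garner_trials()] table.
#' @param alpha significance level.
#' @return a list with `statistic`, `p_value`, `code` (`"yes?"` or `"NO"`),
#'   `means` (baseline, filtering), `description`.
#' @export
garner_interference_rt <- function(trials, alpha = 0.05) {
  stopifnot(inherits(trials, "garner_trials"))
  rt_b <- trials$rt[trials$block == 1 & trials$accuracy == 1]
  rt_f <- trials$rt[trials$block == 2 & trials$accuracy == 1]
  if (length(rt_b) < 2 || length(rt_f) < 2)
    stop("each block type needs at least 2 correct trials (baseline ",
         length(rt_b), ", filtering ", length(rt_f), ")", call. = FALSE)
  tt <- t.test(rt_f, rt_b)
  violated <- tt$p.value < alpha && mean(rt_f) > mean(rt_b)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       code = .garner_code(violated),
       means = c(baseline = mean(rt_b), filtering = mean(rt_f)),
       description = "Garner interference, correct-trial RT (filtering vs baseline)")
}

#' Garner interference test on accuracy
#'
#' Pooled two-proportion z test comparing accuracy between filtering and
#' baseline blocks; failed (`NO`) only when filtering accuracy is
#' significantly *lower*. When either block's accuracy exceeds 0.95 the
#' result carries `ceiling_warning = TRUE`: near-ceiling accuracy leaves
#' too few errors for the proportion tests to be meaningful and they should
#' be ignored in favor of the RT tests.
#'
#' @inheritParams garner_interference_rt
#' @return a list as in [garner_interference_rt()], plus
#'   `ceiling_warning`.
#' @export
garner_interference_accuracy <- function(trials, alpha = 0.05) {
  stopifnot(inherits(trials, "garner_trials"))
  acc_b <- trials$accuracy[trials$block == 1]
  acc_f <- trials$accuracy[trials$block == 2]
  if (!length(acc_b) || !length(acc_f))
    stop("both block types must be present", call. = FALSE)
  p_b <- sanitize_proportion(mean(acc_b))
  p_f <- sanitize_proportion(mean(acc_f))
  n_b <- length(acc_b); n_f <- length(acc_f)
  pbar <- (p_b * n_b + p_f * n_f) / (n_b + n_f)
  z <- (p_f - p_b) / sqrt(pbar * (1 - pbar) * (1 / n_b + 1 / n_f))
  p <- 2 * pnorm(-abs(z))
  violated <- p < alpha && p_f < p_b
  list(statistic = z, p_value = p, code = .garner_code(violated),
       means = c(baseline = p_b, filtering = p_f),
       ceiling_warning = p_b > 0.95 || p_f > 0.95,
       description = "Garner interference, accuracy (filtering vs baseline)")
}

# Filtering-block subsets per (relevant level, irrelevant level); errors on
# empty cells.
.garner_cells <- function(trials, include_baseline = FALSE) {
  keep <- if (include_baseline) rep(TRUE, nrow(trials)) else trials$block == 2
  sub <- trials[keep, , drop = FALSE]
  cells <- lapply(1:2, function(rl) lapply(1:2, function(il)
    sub[sub$relevant == rl & sub$irrelevant == il, , drop = FALSE]))
  for (rl in 1:2) for (il in 1:2)
    if (!nrow(cells[[rl]][[il]]))
      stop("no filtering trials for relevant level ", rl,
           ", irrelevant level ", il, call. = FALSE)
  cells
}

#' Marginal response invariance tests for the Garner task
#'
#' For each level of the relevant dimension, a pooled two-proportion z test
#' comparing accuracy across the two levels of the irrelevant dimension,
#' using filtering blocks only (where all four stimuli are presented
#' together). Two-sided verdicts: invariance has no privileged direction.
#'
#' @inheritParams garner_interference_rt
#' @param include_baseline also pool baseline trials (not recommended).
#' @return a list of two test-result lists, one per relevant level.
#' @export
garner_mri <- function(trials, alpha = 0.05, include_baseline = FALSE) {
  stopifnot(inherits(trials, "garner_trials"))
  cells <- .garner_cells(trials, include_baseline)
  lapply(1:2, function(rl) {
    acc <- lapply(1:2, function(il) cells[[rl]][[il]]$accuracy)
    p1 <- sanitize_proportion(mean(acc[[1]]))
    p2 <- sanitize_proportion(mean(acc[[2]]))
    n1 <- length(acc[[1]]); n2 <- length(acc[[2]])
    pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    p <- 2 * pnorm(-abs(z))
    list(statistic = z, p_value = p, code = .garner_code(p < alpha),
         description = sprintf(
           "marginal response invariance, relevant level %d", rl))
  })
}

#' Marginal response-time invariance tests for the Garner task
#'
#' For each level of the relevant dimension, a two-sample
#' Kolmogorov-Smirnov test comparing the full distributions of
#' correct-trial response times across the two levels of the irrelevant
#' dimension, filtering blocks only. D is the exact supremum difference of
#' the empirical CDFs; the p value is the asymptotic two-sided one.
#'
#' @inheritParams garner_mri
#' @return a list of two test-result lists (`statistic` is D), one per
#'   relevant level.
#' @export
garner_mrti <- function(trials, alpha = 0.05, include_baseline = FALSE) {
  stopifnot(inherits(trials, "garner_trials"))
  cells <- .garner_cells(trials, include_baseline)
  lapply(1:2, function(rl) {
    rt <- lapply(1:2, function(il) {
      cell <- cells[[rl]][[il]]
      cell$rt[cell$accuracy == 1]
    })
    if (any(lengths(rt) < 2))
      stop("fewer than 2 correct trials in a compared cell (relevant level ",
           rl, ")", call. = FALSE)
    ks <- suppressWarnings(ks.test(rt[[1]], rt[[2]], exact = FALSE))
    list(statistic = unname(ks$statistic), p_value = ks$p.value,
         code = .garner_code(ks$p.value < alpha),
         description = sprintf(
           "marginal RT invariance (KS), relevant level %d", rl))
  })
}

#' Summary-statistics analysis of a 2x2 Garner filtering task
#'
#' Assembles the six separability tests — Garner interference on RT and
#' accuracy, and the per-level mRi and mRTi tests — into one report. All
#' tests passing (`yes?`) is consistent with the relevant dimension being
#' separable from the irrelevant one; any `NO` suggests it is not. A
#' significant interference effect alone can also reflect a pure context
#' effect, which is why the single-block mRi/mRTi tests are the more
#' diagnostic rows.
#'
#' @inheritParams garner_interference_rt
#' @return an object of class `garner_report` with elements `tests` (named
#'   list of the six results), `table` (data frame rendering), `overall`
#'   (TRUE when no test is failed) and `ceiling_warning`.
#' @export
garner_analysis <- function(trials, alpha = 0.05) {
  stopifnot(inherits(trials, "garner_trials"), alpha > 0, alpha < 1)
  gi_rt <- garner_interference_rt(trials, alpha)
  gi_acc <- garner_interference_accuracy(trials, alpha)
  mri <- garner_mri(trials, alpha)
  mrti <- garner_mrti(trials, alpha)
  tests <- list("GI(RT)" = gi_rt, "GI(accuracy)" = gi_acc,
                "mRi level 1" = mri[[1]], "mRi level 2" = mri[[2]],
                "mRTi level 1" = mrti[[1]], "mRTi level 2" = mrti[[2]])
  tab <- data.frame(
    test = names(tests),
    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    code = vapply(tests, `[[`, "", "code"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(tests = tests, table = tab,
                 overall = !any(tab$code == "NO"),
                 ceiling_warning = gi_acc$ceiling_warning,
                 alpha = alpha),
            class = "garner_report")
}

#' @export
summary.garner_report <- function(object, ...) {
  cat("Summary-statistics analysis of the 2x2 Garner filtering task",
      sprintf("(alpha = %g)\n\n", object$alpha))
  tab <- object$table[, c("test", "code")]
  names(tab) <- c("Test", "Passed?")
  print(tab, row.names = FALSE)
  cat(sprintf("\nOverall: %s\n", if (object$overall)
    "all tests passed; consistent with a separable relevant dimension"
    else "at least one test failed; the relevant dimension may not be separable"))
  if (object$ceiling_warning)
    cat("Warning: accuracy near ceiling; ignore the accuracy-based tests\n")
  invisible(object)
}

#' @export
print.garner_report <- function(x, ...) {
  cat("Summary-statistics analysis of the 2x2 Garner filtering task",
      sprintf("(alpha = %g)\n\n", x$alpha))
  for (t in x$tests)
    cat(sprintf("  %-55s stat = %8.3f, p = %.4g  [%s]\n", t$description,
                t$statistic, t$p_value, t$code))
  cat(sprintf("\nOverall separable-consistent: %s\n", x$overall))
  if (x$ceiling_warning)
    cat("Warning: accuracy near ceiling; ignore the accuracy-based tests\n")
  invisible(x)
}
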