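# Macro-analyses: summary-statistics tests that compare statistics linked to
# *different* stimuli — marginal response invariance, and equality of
# marginal d' and c across levels of the irrelevant dimension.

.conclusion_codes <- c("yes", "NO", "? yes", "? no", "?")

# Shared helper: a two-sided z test wrapped into the TestResult shape.
.test_result <- function(statistic, alpha, description) {
  p <- 2 * pnorm(-abs(statistic))
  list(statistic = statistic, p_value = p, passed = p >= alpha,
       description = description)
}

#' Marginal response proportion
#'
#' Proportion of responses to one stimulus whose component on a given
#' dimension is a given level, i.e. the sum of the two response columns that
#' share that component divided by the row total. Sanitized away from 0/1.
#'
#' @param cm a [grt_confusion_matrix()].
#' @param dim `"A"` or `"B"`.
#' @param stimulus stimulus row index (1-4, canonical order).
#' @param level response level on `dim` (1 or 2; default 2).
#' @return a single sanitized proportion, with the denominator attached as
#'   attribute `n`.
#' @examples
#' cm <- grt_face_example()
#' marginal_proportion(cm, "A", 1, level = 1)  # (140 + 34) / 250
#' @export
marginal_proportion <- function(cm, dim = c("A", "B"), stimulus, level = 2) {
  dim <- match.arg(dim)
  stopifnot(inherits(cm, "grt_cm"), stimulus %in% 1:4, level %in% 1:2)
  comp <- if (dim == "A") .grt_levels_a else .grt_levels_b
  n <- sum(cm[stimulus, ])
  p <- sum(cm[stimulus, comp == level]) / n
  p <- sanitize_proportion(p)
  attr(p, "n") <- n
  p
}

# Row indices of the stimulus pair that shares `level` on `dim` but differs
# on the other dimension.
.stim_pair_sharing <- function(dim, level) {
  if (dim == "A") which(.grt_levels_a == level) else which(.grt_levels_b == level)
}

#' Marginal response invariance test
#'
#' Two-proportion z test (pooled variance) comparing the proportion of
#' level-matching responses on `dim` between the two stimuli that share the
#' tested level of `dim` but differ on the other dimension. A failure is
#' evidence against perceptual and/or decisional separability of `dim`.
#'
#' @inheritParams marginal_proportion
#' @param level the level of `dim` under test.
#' @param alpha significance level.
#' @return a list with `statistic`, `p_value`, `passed`, `description`.
#' @export
mri_test <- function(cm, dim = c("A", "B"), level, alpha = 0.05) {
  dim <- match.arg(dim)
  rows <- .stim_pair_sharing(dim, level)
  p1 <- marginal_proportion(cm, dim, rows[1], level)
  p2 <- marginal_proportion(cm, dim, rows[2], level)
  n1 <- attr(p1, "n"); n2 <- attr(p2, "n")
  pbar <- (as.numeric(p1) * n1 + as.numeric(p2) * n2) / (n1 + n2)
  z <- (as.numeric(p1) - as.numeric(p2)) /
    sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  .test_result(z, alpha, sprintf(
    "marginal response invariance, dimension %s level %d (%s vs %s)",
    dim, level, .grt_order[rows[1]], .grt_order[rows[2]]))
}

#' Marginal signal-detection statistics
#'
#' With the irrelevant dimension fixed at `irrelevant_level`, treats the
#' level-2 stimulus on `dim` as signal: hit = marginal proportion of level-2
#' responses given the level-2 stimulus, false alarm = the same given the
#' level-1 stimulus. Returns d' = z(hit) - z(fa) and criterion
#' c = -(z(hit) + z(fa)) / 2, with Gourevitch-Galanter variances
#' var(d') = hit(1-hit) / (n_H phi(z(hit))^2) + fa(1-fa) / (n_F phi(z(fa))^2)
#' and var(c) = var(d') / 4.
#'
#' @inheritParams marginal_proportion
#' @param irrelevant_level level (1 or 2) at which the other dimension is
#'   fixed.
#' @return a list with `dprime`, `c`, `var_dprime`, `var_c`, `hit`, `fa`.
#' @export
marginal_sdt <- function(cm, dim = c("A", "B"), irrelevant_level) {
  dim <- match.arg(dim)
  rows <- .stim_pair_sharing(if (dim == "A") "B" else "A", irrelevant_level)
  own <- if (dim == "A") .grt_levels_a else .grt_levels_b
  hit_row <- rows[own[rows] == 2]
  fa_row <- rows[own[rows] == 1]
  hit <- marginal_proportion(cm, dim, hit_row, 2)
  fa <- marginal_proportion(cm, dim, fa_row, 2)
  .sdt_from_rates(as.numeric(hit), attr(hit, "n"), as.numeric(fa),
                  attr(fa, "n"))
}

.sdt_from_rates <- function(hit, n_h, fa, n_f) {
  zh <- qnorm(hit); zf <- qnorm(fa)
  vd <- hit * (1 - hit) / (n_h * dnorm(zh)^2) +
    fa * (1 - fa) / (n_f * dnorm(zf)^2)
  list(dprime = zh - zf, c = -(zh + zf) / 2, var_dprime = vd, var_c = vd / 4,
       hit = hit, fa = fa, n_hit = n_h, n_fa = n_f)
}

# Decision table mapping (d'eq, ceq, mri) to PS/DS codes, per dimension.
# Row 1 and 2 are forced by the worked face-identification example; the remaining rows
# follow the msda2-style logic that d' is criterion-free evidence about PS
# while c shifts have ambiguous attribution. Kept as a named constant so the
# mapping can be swapped.
.macro_decision <- function(dprime_eq, c_eq, mri_ok) {
  if (!dprime_eq) return(c(PS = "NO", DS = "?"))
  if (c_eq && mri_ok) return(c(PS = "yes", DS = "yes"))
  if (c_eq && !mri_ok) return(c(PS = "? yes", DS = "? yes"))
  if (!c_eq && mri_ok) return(c(PS = "? yes", DS = "?"))
  c(PS = "? yes", DS = "? no")
}

#' Macro-analysis of a 2x2 identification confusion matrix
#'
#' Runs, per dimension: both marginal response invariance tests, a two-sided
#' z test of equality of the two marginal d' values across levels of the
#' irrelevant dimension, and the analogous test for the criterion c; then
#' codes conclusions about perceptual separability (PS) and decisional
#' separability (DS) as one of `yes`, `NO`, `? yes`, `? no`, `?`.
#'
#' @param cm a [grt_confusion_matrix()].
#' @param alpha significance level for every test.
#' @return an object of class `grt_macro`; `summary()` prints the compact
#'   conclusions table, `print()` the full per-test detail, and
#'   `as.data.frame()` gives a machine-readable version.
#' @examples
#' summary(macro_analysis(grt_face_example()))
#' @export
macro_analysis <- function(cm, alpha = 0.05) {
  stopifnot(inherits(cm, "grt_cm"), alpha > 0, alpha < 1)
  dims <- c("A", "B")
  res <- lapply(dims, function(dim) {
    mri <- lapply(1:2, function(l) mri_test(cm, dim, l, alpha))
    sdt <- lapply(1:2, function(l) marginal_sdt(cm, dim, l))
    zd <- (sdt[[1]]$dprime - sdt[[2]]$dprime) /
      sqrt(sdt[[1]]$var_dprime + sdt[[2]]$var_dprime)
    zc <- (sdt[[1]]$c - sdt[[2]]$c) / sqrt(sdt[[1]]$var_c + sdt[[2]]$var_c)
    dprime_equal <- .test_result(zd, alpha, sprintf(
      "equal marginal d' across irrelevant levels, dimension %s", dim))
    c_equal <- .test_result(zc, alpha, sprintf(
      "equal marginal c across irrelevant levels, dimension %s", dim))
    codes <- .macro_decision(dprime_equal$passed, c_equal$passed,
                             mri[[1]]$passed && mri[[2]]$passed)
    list(dim = dim, mri = mri, sdt = sdt, dprime_equal = dprime_equal,
         c_equal = c_equal, PS = codes[["PS"]], DS = codes[["DS"]])
  })
  names(res) <- dims
  structure(list(dimensions = res, alpha = alpha, cm = cm),
            class = "grt_macro")
}

#' @export
as.data.frame.grt_macro <- function(x, ...) {
  do.call(rbind, lapply(x$dimensions, function(d) {
    data.frame(
      dimension = d$dim,
      MRI = if (d$mri[[1]]$passed && d$mri[[2]]$passed) "YES" else "NO",
      marginal_dprime = if (d$dprime_equal$passed) "YES" else "NO",
      marginal_c = if (d$c_equal$passed) "YES" else "NO",
      PS = d$PS, DS = d$DS, row.names = NULL)
  }))
}

#' @export
summary.grt_macro <- function(object, ...) {
  cat("Macro-analysis of the 2x2 identification task",
      sprintf("(alpha = %g)\n\n", object$alpha))
  df <- as.data.frame(object)
  names(df) <- c("Dimension", "MRI", "Marginal d'", "Marginal c", "PS", "DS")
  print(df, row.names = FALSE)
  invisible(object)
}

#' @export
print.grt_macro <- function(x, ...) {
  cat("Macro-analysis of the 2x2 identification task",
      sprintf("(alpha = %g)\n", x$alpha))
  for (d in x$dimensions) {
    cat(sprintf("\nDimension %s\n", d$dim))
    for (l in 1:2)
      cat(sprintf("  MRI level %d: z = %7.3f, p = %.4g  [%s]\n", l,
                  d$mri[[l]]$statistic, d$mri[[l]]$p_value,
                  if (d$mri[[l]]$passed) "pass" else "FAIL"))
    for (l in 1:2)
      cat(sprintf("  irrelevant level %d: d' = %.3f, c = %.3f\n", l,
                  d$sdt[[l]]$dprime, d$sdt[[l]]$c))
    cat(sprintf("  equal d': z = %7.3f, p = %.4g  [%s]\n",
                d$dprime_equal$statistic, d$dprime_equal$p_value,
                if (d$dprime_equal$passed) "pass" else "FAIL"))
    cat(sprintf("  equal c : z = %7.3f, p = %.4g  [%s]\n",
                d$c_equal$statistic, d$c_equal$p_value,
                if (d$c_equal$passed) "pass" else "FAIL"))
    cat(sprintf("  conclusions: PS %s, DS %s\n", d$PS, d$DS))
  }
  invisible(x)
}

#' The worked identification-experiment example table
#'
#' The simulated 2x2 face identification data (emotion x gender) used
#' throughout the documentation: four stimuli, 250 trials each.
#'
#' @return a [grt_confusion_matrix()].
#' @export
grt_face_example <- function() {
  grt_confusion_matrix(
    matrix(c(140, 36, 34, 40,
             89, 91, 4, 66,
             85, 5, 90, 70,
             20, 59, 8, 163), 4, 4, byrow = TRUE),
    labels = c("Happy/Male", "Sad/Male", "Happy/Female", "Sad/Female"))
}
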