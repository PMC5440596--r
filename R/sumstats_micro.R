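# Micro-analyses: summary-statistics tests that compare statistics linked to
# the *same* stimulus — sampling independence per response cell, and equality
# of conditional d'/c across conditioning response levels.

#' Sampling independence test for one cell of one stimulus
#'
#' Under perceptual independence (plus decisional separability), the joint
#' probability of a response equals the product of its marginal component
#' probabilities. Compares the observed cell proportion with the product of
#' the stimulus's marginal response proportions by a z test whose variance
#' uses the expected proportion.
#'
#' @param cm a [grt_confusion_matrix()].
#' @param stimulus stimulus row index (1-4).
#' @param response_cell response column index (1-4).
#' @param alpha significance level.
#' @return a test-result list (`statistic`, `p_value`, `passed`,
#'   `description`).
#' @examples
#' sampling_independence_test(grt_face_example(), 4, 4)
#' @export
sampling_independence_test <- function(cm, stimulus, response_cell,
                                       alpha = 0.05) {
  stopifnot(inherits(cm, "grt_cm"), stimulus %in% 1:4, response_cell %in% 1:4)
  n <- sum(cm[stimulus, ])
  p_obs <- cm[stimulus, response_cell] / n
  pa <- as.numeric(marginal_proportion(cm, "A", stimulus,
                                       .grt_levels_a[response_cell]))
  pb <- as.numeric(marginal_proportion(cm, "B", stimulus,
                                       .grt_levels_b[response_cell]))
  p_exp <- sanitize_proportion(pa * pb)
  z <- (p_obs - p_exp) / sqrt(p_exp * (1 - p_exp) / n)
  .test_result(z, alpha, sprintf(
    "sampling independence, stimulus %s response %s",
    .grt_order[stimulus], tolower(.grt_order[response_cell])))
}

#' Conditional signal-detection statistics
#'
#' For the stimulus pair differing on `dim` with the other dimension fixed
#' at `fixed_level`, restricts each row to the two response cells whose
#' other-dimension response component equals `conditioning_response_level`.
#' The conditional hit rate is the level-2 cell over the restricted total in
#' the level-2 stimulus row; the conditional false-alarm rate likewise from
#' the level-1 stimulus row. d', c and variances as in [marginal_sdt()] with
#' the restricted denominators.
#'
#' @inheritParams sampling_independence_test
#' @param dim dimension whose sensitivity is measured, `"A"` or `"B"`.
#' @param fixed_level level of the other dimension shared by the stimulus
#'   pair.
#' @param conditioning_response_level response level of the other dimension
#'   to condition on.
#' @return a list as from [marginal_sdt()].
#' @export
conditional_sdt <- function(cm, dim = c("A", "B"), fixed_level,
                            conditioning_response_level) {
  dim <- match.arg(dim)
  stopifnot(inherits(cm, "grt_cm"), fixed_level %in% 1:2,
            conditioning_response_level %in% 1:2)
  other <- if (dim == "A") "B" else "A"
  rows <- .stim_pair_sharing(other, fixed_level)
  own <- if (dim == "A") .grt_levels_a else .grt_levels_b
  oth <- if (dim == "A") .grt_levels_b else .grt_levels_a
  hit_row <- rows[own[rows] == 2]
  fa_row <- rows[own[rows] == 1]
  cols <- which(oth == conditioning_response_level)
  col2 <- cols[own[cols] == 2]
  col1 <- cols[own[cols] == 1]
  n_h <- cm[hit_row, col1] + cm[hit_row, col2]
  n_f <- cm[fa_row, col1] + cm[fa_row, col2]
  if (n_h == 0 || n_f == 0)
    stop("degenerate conditioning: zero denominator for dimension ", dim,
         ", fixed level ", fixed_level, ", conditioning response level ",
         conditioning_response_level, call. = FALSE)
  hit <- sanitize_proportion(cm[hit_row, col2] / n_h)
  fa <- sanitize_proportion(cm[fa_row, col2] / n_f)
  .sdt_from_rates(hit, n_h, fa, n_f)
}

# Conditional-equality z test (Gourevitch-Galanter form) for one dimension /
# fixed level, comparing statistics across the two conditioning response
# levels. Returns NULL when a conditioning denominator is empty (recorded as
# "?" upstream).
.conditional_equality <- function(cm, dim, fixed_level, alpha) {
  s <- tryCatch(lapply(1:2, function(l) conditional_sdt(cm, dim, fixed_level, l)),
                error = function(e) NULL)
  if (is.null(s)) return(NULL)
  zd <- (s[[1]]$dprime - s[[2]]$dprime) /
    sqrt(s[[1]]$var_dprime + s[[2]]$var_dprime)
  zc <- (s[[1]]$c - s[[2]]$c) / sqrt(s[[1]]$var_c + s[[2]]$var_c)
  list(
    dprime = .test_result(zd, alpha, sprintf(
      "equal conditional d', dimension %s, other fixed at %d", dim,
      fixed_level)),
    c = .test_result(zc, alpha, sprintf(
      "equal conditional c, dimension %s, other fixed at %d", dim,
      fixed_level)),
    sdt = s)
}

# DS code ladder used to degrade a verdict one step toward "? no" when only
# the conditional-c test fails.
.ds_ladder <- c("yes", "? yes", "?", "? no", "NO")
.degrade_ds <- function(code) {
  i <- match(code, .ds_ladder)
  .ds_ladder[min(i + 1L, 4L)]
}

# Micro conclusion table per stimulus (si = all four sampling-independence
# tests pass; cd = both conditional-d' equality tests involving the stimulus
# pass; cc = both conditional-c tests pass). Forced at the observed worked-example
# point; remainder reconstructed msda2-style. NA inputs (degenerate
# conditioning) yield "?".
.micro_decision <- function(si, cd, cc) {
  if (is.na(cd) || is.na(cc)) return(c(PI = "?", DS = "?"))
  out <- if (si && cd) c(PI = "yes", DS = "yes")
  else if (!si && cd) c(PI = "? no", DS = "?")
  else if (!si && !cd) c(PI = "? no", DS = "? no")
  else c(PI = "?", DS = "? no")
  if (!cc) out[["DS"]] <- .degrade_ds(out[["DS"]])
  c(PI = out[["PI"]], DS = out[["DS"]])
}

#' Micro-analysis of a 2x2 identification confusion matrix
#'
#' Runs, per stimulus, the four sampling-independence tests and, per
#' stimulus pair, the conditional d'/c equality tests; codes conclusions
#' about perceptual independence (PI) and decisional separability (DS) per
#' stimulus from the same five-value set as [macro_analysis()].
#'
#' @inheritParams macro_analysis
#' @return an object of class `grt_micro` with per-stimulus conclusions and
#'   an `overall` worst-case pair of codes.
#' @examples
#' summary(micro_analysis(grt_face_example()))
#' @export
micro_analysis <- function(cm, alpha = 0.05) {
  stopifnot(inherits(cm, "grt_cm"), alpha > 0, alpha < 1)
  si <- lapply(1:4, function(i)
    lapply(1:4, function(j) sampling_independence_test(cm, i, j, alpha)))
  # Conditional-equality tests keyed by (dim, fixed level of other dim).
  cond <- list(A = lapply(1:2, .conditional_equality, cm = cm, dim = "A",
                          alpha = alpha),
               B = lapply(1:2, .conditional_equality, cm = cm, dim = "B",
                          alpha = alpha))
  per_stim <- lapply(1:4, function(i) {
    la <- .grt_levels_a[i]; lb <- .grt_levels_b[i]
    tests <- list(cond$A[[lb]], cond$B[[la]])
    si_ok <- all(vapply(si[[i]], `[[`, TRUE, "passed"))
    cd <- if (any(vapply(tests, is.null, TRUE))) NA else
      all(vapply(tests, function(t) t$dprime$passed, TRUE))
    cc <- if (any(vapply(tests, is.null, TRUE))) NA else
      all(vapply(tests, function(t) t$c$passed, TRUE))
    codes <- .micro_decision(si_ok, cd, cc)
    list(stimulus = .grt_order[i], si = si[[i]], si_ok = si_ok,
         cond_dprime_equal = cd, cond_c_equal = cc,
         PI = codes[["PI"]], DS = codes[["DS"]])
  })
  names(per_stim) <- .grt_order
  worst <- function(codes) {
    severity <- c(yes = 1, "? yes" = 2, "?" = 3, "? no" = 4, NO = 5)
    codes[which.max(severity[codes])]
  }
  structure(list(stimuli = per_stim, conditional = cond, alpha = alpha,
                 overall = c(PI = unname(worst(vapply(per_stim, `[[`, "", "PI"))),
                             DS = unname(worst(vapply(per_stim, `[[`, "", "DS")))),
                 cm = cm),
            class = "grt_micro")
}

#' @export
as.data.frame.grt_micro <- function(x, ...) {
  do.call(rbind, lapply(x$stimuli, function(s) {
    data.frame(
      stimulus = s$stimulus,
      sampling_independence = if (s$si_ok) "YES" else "NO",
      equal_cond_dprime = if (is.na(s$cond_dprime_equal)) "?" else
        if (s$cond_dprime_equal) "YES" else "NO",
      equal_cond_c = if (is.na(s$cond_c_equal)) "?" else
        if (s$cond_c_equal) "YES" else "NO",
      PI = s$PI, DS = s$DS, row.names = NULL)
  }))
}

#' @export
summary.grt_micro <- function(object, ...) {
  cat("Micro-analysis of the 2x2 identification task",
      sprintf("(alpha = %g)\n\n", object$alpha))
  df <- as.data.frame(object)
  names(df) <- c("Stimulus", "Sampling Independence", "Equal Cond d'",
                 "Equal Cond c", "PI", "DS")
  print(df, row.names = FALSE)
  cat(sprintf("\nOverall: PI %s, DS %s\n", object$overall[["PI"]],
              object$overall[["DS"]]))
  invisible(object)
}

#' @export
print.grt_micro <- function(x, ...) {
  cat("Micro-analysis of the 2x2 identification task",
      sprintf("(alpha = %g)\n", x$alpha))
  for (s in x$stimuli) {
    cat(sprintf("\nStimulus %s\n", s$stimulus))
    for (t in s$si)
      cat(sprintf("  SI %-28s z = %7.3f, p = %.4g  [%s]\n",
                  sub(".*response ", "response ", t$description),
                  t$statistic, t$p_value, if (t$passed) "pass" else "FAIL"))
    cat(sprintf("  conclusions: PI %s, DS %s\n", s$PI, s$DS))
  }
  for (dim in c("A", "B")) for (l in 1:2) {
    ce <- x$conditional[[dim]][[l]]
    if (is.null(ce)) {
      cat(sprintf("\nConditional tests, dimension %s (other at %d): degenerate\n",
                  dim, l))
      next
    }
    cat(sprintf("\nConditional tests, dimension %s (other dimension at %d)\n",
                dim, l))
    cat(sprintf("  conditional d': %.3f vs %.3f; equal-d' z = %7.3f, p = %.4g  [%s]\n",
                ce$sdt[[1]]$dprime, ce$sdt[[2]]$dprime,
                ce$dprime$statistic, ce$dprime$p_value,
                if (ce$dprime$passed) "pass" else "FAIL"))
    cat(sprintf("  conditional c : %.3f vs %.3f; equal-c  z = %7.3f, p = %.4g  [%s]\n",
                ce$sdt[[1]]$c, ce$sdt[[2]]$c,
                ce$c$statistic, ce$c$p_value,
                if (ce$c$passed) "pass" else "FAIL"))
  }
  invisible(x)
}
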