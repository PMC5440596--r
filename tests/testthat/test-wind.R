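test_that("a neutral single participant reduces to the traditional model", {
  # kappa = 1, lambda = 0.5 doubles the unit group variances; the
  # equivalent traditional model carries the scaled variances explicitly
  group <- list(gaussian2d(c(0, 0), c(1, 1), 0.2),
                gaussian2d(c(1.5, 0), c(1, 1), -0.3),
                gaussian2d(c(0, 1.5), c(1, 1), 0),
                gaussian2d(c(1.5, 1.5), c(1, 1), 0.4))
  wm <- wind_model(group, list(wind_participant(1, 0.5,
                                                linear_bound(0.1, 0.7, "A"),
                                                linear_bound(-0.2, 0.8, "B"))))
  equiv <- grt_model(lapply(group, function(g)
    gaussian2d(g$mean, 2 * g$var, g$rho)),
    linear_bound(0.1, 0.7, "A"), linear_bound(-0.2, 0.8, "B"))
  cm <- simulate_identification(equiv, 500, seed = 14)
  expect_equal(wind_log_likelihood(wm, list(cm)),
               grt_log_likelihood(equiv, cm), tolerance = 1e-10)
})

test_that("the joint log-likelihood is additive over participants", {
  model <- wind_demo_model()
  data <- simulate_wind(model, 100, seed = 15)
  total <- wind_log_likelihood(model, data)
  per <- vapply(1:5, function(p) {
    sub <- wind_model(model$group, model$participants[p])
    wind_log_likelihood(sub, data[p])
  }, numeric(1))
  expect_equal(total, sum(per), tolerance = 1e-10)
})

test_that("the compiled objective matches the R-level likelihood", {
  model <- wind_demo_model()
  data <- simulate_wind(model, 100, seed = 16)
  full <- grtkit:::.wind_model_to_full(model)
  pm <- grtkit:::.wind_param_map(5)
  free <- grtkit:::.project_to_free(full, pm$map)
  nll <- grtkit:::cpp_wind_negll(free, pm$map, pm$fixed,
                                 grtkit:::.counts_matrix(data))
  expect_equal(-nll, wind_log_likelihood(model, data), tolerance = 1e-6)
})

test_that("single-start unperturbed wIND fits are deterministic", {
  data <- simulate_wind(wind_demo_model(), 80, seed = 17)
  f1 <- suppressWarnings(fit_grt_wind(data[1:2], n_reps = 1, perturb = 0,
                                      workers = 1, seed = 1))
  f2 <- suppressWarnings(fit_grt_wind(data[1:2], n_reps = 1, perturb = 0,
                                      workers = 1, seed = 77))
  expect_equal(f1$params, f2$params)
  expect_equal(f1$logL, f2$logL)
})

test_that("a single-participant fit warns but proceeds", {
  data <- simulate_wind(wind_demo_model(), 100, seed = 18)
  expect_warning(fit_grt_wind(data[1], n_reps = 1, perturb = 0, workers = 1),
                 "multiple participants")
})

test_that("simulate_wind with K = 1 matches the equivalent flat simulator", {
  group <- list(gaussian2d(c(0, 0), c(1, 1), 0),
                gaussian2d(c(2, 0), c(1, 1), 0),
                gaussian2d(c(0, 2), c(1, 1), 0),
                gaussian2d(c(2, 2), c(1, 1), 0))
  wm <- wind_model(group, list(wind_participant(2, 0.5,
                                                linear_bound(0, 1, "A"),
                                                linear_bound(0, 1, "B"))))
  # kappa = 2, lambda = 0.5 leaves unit variances; proportions must agree
  # with the analytic matrix of the equivalent traditional model
  sim <- simulate_wind(wm, 2e4, seed = 19)[[1]]
  equiv <- ps_pi_ds_model(d = 2)
  pm <- predicted_matrix(equiv)
  prop <- unclass(sim) / rowSums(sim)
  se <- sqrt(pm * (1 - pm) / 2e4)
  expect_true(all(abs(prop - pm) <= 3 * se + 1e-9))
})

test_that("starving dimension B of attention raises B errors", {
  group <- list(gaussian2d(c(0, 0), c(1, 1), 0),
                gaussian2d(c(2, 0), c(1, 1), 0),
                gaussian2d(c(0, 2), c(1, 1), 0),
                gaussian2d(c(2, 2), c(1, 1), 0))
  mk <- function(lambda) wind_model(group, list(
    wind_participant(1, lambda, linear_bound(0, 1, "A"),
                     linear_bound(0, 1, "B"))))
  err_b <- function(lambda) {
    cm <- simulate_wind(mk(lambda), 1e4, seed = 20)[[1]]
    # B-level errors: response B-component differs from stimulus B level
    lv <- c(1, 1, 2, 2)
    mismatch <- outer(lv, lv, `!=`)  # rows = stimulus, cols = response
    sum(unclass(cm)[mismatch]) / sum(cm)
  }
  expect_gt(err_b(0.99), err_b(0.5))
})

test_that("likelihood-ratio statistics are nonnegative and selectable", {
  data <- simulate_wind(wind_demo_model(), 150, seed = 22)
  fit <- fit_grt_wind(data, n_reps = 4, seed = 23, workers = 1)
  lrt <- wind_lr_tests(fit, data, tests = c("PS(A)", "DS(A)"), n_reps = 4,
                       seed = 24, workers = 1)
  expect_equal(nrow(lrt), 2)
  expect_equal(lrt$test, c("PS(A)", "DS(A)"))
  expect_true(all(lrt$chi2 >= 0))
  expect_equal(lrt$df, c(4, 5))
  expect_true(all(lrt$p_value >= 0 & lrt$p_value <= 1))
})

test_that("restriction maps drop the advertised number of parameters", {
  K <- 5
  full <- grtkit:::.wind_param_map(K)
  expect_equal(full$n_free, 16 + 6 * K)
  for (test in c("PS(A)", "PS(B)", "PI")) {
    pm <- grtkit:::.wind_restriction(test, K)
    expect_equal(full$n_free - pm$n_free, 4)
  }
  for (test in c("DS(A)", "DS(B)")) {
    pm <- grtkit:::.wind_restriction(test, K)
    expect_equal(full$n_free - pm$n_free, K)
  }
})

test_that("the fitted group space reproduces the generator's misalignment", {
  data <- simulate_wind(wind_demo_model(), 250, seed = 25)
  fit <- fit_grt_wind(data, n_reps = 10, seed = 26, workers = 1)
  expect_true(fit$converged)
  expect_gt(fit$r_squared, 0.9)
  lrt <- wind_lr_tests(fit, data, n_reps = 10, seed = 27, workers = 1)
  verdicts <- setNames(lrt$violated, lrt$test)
  expect_equal(unname(verdicts["PS(B)"]), "NO")
  expect_equal(unname(verdicts["PS(A)"]), "YES")
})
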