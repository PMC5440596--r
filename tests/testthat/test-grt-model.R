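test_that("region probabilities match the Gaussian orthant closed form", {
  ba <- linear_bound(0, 0, "A")
  bb <- linear_bound(0, 0, "B")
  # symmetric case
  expect_equal(unname(region_probabilities(gaussian2d(), ba, bb)),
               rep(0.25, 4))
  # P(a2b2) = 1/4 + arcsin(rho) / (2 pi) for a centered unit-variance
  # distribution and bounds through the origin
  for (rho in seq(-0.95, 0.95, by = 0.05)) {
    p <- region_probabilities(gaussian2d(rho = rho), ba, bb)
    expect_equal(unname(p[["a2b2"]]), 1 / 4 + asin(rho) / (2 * pi),
                 tolerance = 1e-6)
  }
  # far-field limit
  p <- region_probabilities(gaussian2d(c(10, 10)), ba, bb)
  expect_equal(unname(p[["a2b2"]]), 1, tolerance = 1e-6)
})

test_that("bivariate CDF agrees with an independent implementation", {
  set.seed(42)
  for (i in 1:200) {
    x <- rnorm(1, 0, 2); y <- rnorm(1, 0, 2); r <- runif(1, -0.99, 0.99)
    mine <- grtkit:::cpp_pbvnorm(x, y, r)
    ref <- mvtnorm::pmvnorm(upper = c(x, y),
                            corr = matrix(c(1, r, r, 1), 2),
                            algorithm = mvtnorm::TVPACK(1e-12))[1]
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("region probabilities are valid and flag degenerate bounds", {
  set.seed(7)
  for (i in 1:50) {
    d <- gaussian2d(rnorm(2), exp(rnorm(2, 0, 0.5)), runif(1, -0.9, 0.9))
    ba <- linear_bound(runif(1, -0.5, 0.5), rnorm(1), "A")
    bb <- linear_bound(runif(1, -0.5, 0.5), rnorm(1), "B")
    p <- region_probabilities(d, ba, bb)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-8)
  }
  # parallel discriminants: u and v perfectly anticorrelated
  expect_error(
    region_probabilities(gaussian2d(), linear_bound(1, 0, "A"),
                         linear_bound(1, 0, "B")),
    "degenerate")
})

test_that("predicted matrices are row-stochastic and respect symmetry", {
  sym <- grt_model(rep(list(gaussian2d()), 4),
                   linear_bound(0, 0, "A"), linear_bound(0, 0, "B"))
  expect_equal(unname(predicted_matrix(sym)), matrix(0.25, 4, 4))

  # PS+PI+DS grid model: swapping both A-levels and B-levels simultaneously
  # maps the matrix onto itself under the corresponding permutation
  m <- ps_pi_ds_model(d = 2)
  pm <- predicted_matrix(m)
  expect_equal(unname(rowSums(pm)), rep(1, 4), tolerance = 1e-8)
  perm <- c(4, 3, 2, 1)  # A1B1<->A2B2, A2B1<->A1B2
  expect_equal(unname(pm), unname(pm[perm, perm]), tolerance = 1e-10)
})

test_that("analytic region probabilities agree with Monte Carlo", {
  set.seed(101)
  model <- grt_model(list(gaussian2d(c(0, 0), c(1, 1), 0.3),
                          gaussian2d(c(1.5, 0.2), c(1.3, 0.8), -0.4),
                          gaussian2d(c(0.1, 1.8), c(0.9, 1.1), 0),
                          gaussian2d(c(1.7, 1.6), c(1, 1), 0.5)),
                     linear_bound(0.2, 0.8, "A"), linear_bound(-0.1, 0.9, "B"))
  pm <- predicted_matrix(model)
  n <- 2e5
  for (s in 1:4) {
    xy <- grtkit:::.draw_percepts(model$dists[[s]], n)
    resp <- grtkit:::.classify(xy, model$bound_a, model$bound_b)
    emp <- tabulate(resp, 4) / n
    se <- sqrt(pm[s, ] * (1 - pm[s, ]) / n)
    expect_true(all(abs(emp - pm[s, ]) <= 3 * se + 1e-9))
  }
})

test_that("log-likelihood matches direct summation and closed forms", {
  cm <- grt_face_example()
  uniform <- grt_model(rep(list(gaussian2d()), 4),
                       linear_bound(0, 0, "A"), linear_bound(0, 0, "B"))
  expect_equal(grt_log_likelihood(uniform, cm), 1000 * log(0.25),
               tolerance = 1e-10)

  set.seed(3)
  model <- ps_pi_ds_model(d = 1.5, rho = runif(4, -0.5, 0.5))
  counts <- grt_confusion_matrix(matrix(rpois(16, 40) + 1, 4, 4))
  p <- pmax(predicted_matrix(model), 1e-10)
  by_hand <- sum(sapply(1:4, function(i) sapply(1:4, function(j)
    counts[i, j] * log(p[i, j]))))
  expect_equal(grt_log_likelihood(model, counts), by_hand)
})

test_that("the predicted matrix is translation invariant", {
  set.seed(11)
  for (i in 1:10) {
    shift <- rnorm(2)
    m1 <- ps_pi_ds_model(d = 2, rho = runif(4, -0.6, 0.6))
    dists2 <- lapply(m1$dists, function(d)
      gaussian2d(d$mean + shift, d$var, d$rho))
    # intercepts shift consistently with the discriminant geometry
    m2 <- grt_model(dists2,
                    linear_bound(m1$bound_a$slope,
                                 m1$bound_a$intercept + shift[1] -
                                   m1$bound_a$slope * shift[2], "A"),
                    linear_bound(m1$bound_b$slope,
                                 m1$bound_b$intercept + shift[2] -
                                   m1$bound_b$slope * shift[1], "B"))
    expect_equal(predicted_matrix(m1), predicted_matrix(m2),
                 tolerance = 1e-9)
  }
})

test_that("raising the A bound weakly lowers every a2-response probability", {
  d <- gaussian2d(c(0.4, 0.2), c(1, 1.4), 0.3)
  bb <- linear_bound(0.1, 0.5, "B")
  bs <- seq(-2, 2, by = 0.25)
  probs <- t(vapply(bs, function(b)
    region_probabilities(d, linear_bound(0.2, b, "A"), bb), numeric(4)))
  a2 <- probs[, 2] + probs[, 4]
  expect_true(all(diff(a2) <= 1e-12))
})
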