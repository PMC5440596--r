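cm1 <- grt_face_example()

test_that("marginal proportions match hand arithmetic on the example table", {
  expect_equal(as.numeric(marginal_proportion(cm1, "A", 1, level = 1)),
               (140 + 34) / 250)
  expect_equal(as.numeric(marginal_proportion(cm1, "A", 3, level = 1)),
               (85 + 90) / 250)
  all_a1 <- grt_confusion_matrix(matrix(c(100, 0, 0, 0), 4, 4, byrow = TRUE))
  expect_equal(suppressWarnings(
    as.numeric(marginal_proportion(all_a1, "A", 1, level = 1))), 1 - 1e-10)
})

test_that("marginal response invariance tests match the pooled-z oracle", {
  # level 1 of A ("happy"): 0.696 vs 0.700
  t1 <- mri_test(cm1, "A", 1)
  pooled_z <- function(p1, p2, n1, n2) {
    pb <- (p1 * n1 + p2 * n2) / (n1 + n2)
    (p1 - p2) / sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
  }
  expect_equal(t1$statistic, pooled_z(0.696, 0.700, 250, 250))
  expect_equal(t1$statistic, -0.0974, tolerance = 1e-3)
  expect_true(t1$passed)

  # level 2 of A ("sad"): 0.628 vs 0.888 — a clear failure
  t2 <- mri_test(cm1, "A", 2)
  expect_equal(t2$statistic, pooled_z(157 / 250, 222 / 250, 250, 250))
  expect_equal(t2$statistic, -6.787, tolerance = 1e-3)
  expect_lt(t2$p_value, 1e-9)
  expect_false(t2$passed)

  # identical rows give z = 0, p = 1
  same <- grt_confusion_matrix(matrix(rep(c(60, 20, 10, 10), each = 4), 4, 4))
  t3 <- mri_test(same, "A", 1)
  expect_equal(t3$statistic, 0)
  expect_equal(t3$p_value, 1)
})

test_that("marginal d' and c match the normal-quantile oracle", {
  male <- marginal_sdt(cm1, "A", 1)
  expect_equal(male$dprime, qnorm(157 / 250) - qnorm(76 / 250))
  expect_equal(male$dprime, 0.84, tolerance = 0.005)
  female <- marginal_sdt(cm1, "A", 2)
  expect_equal(female$dprime, qnorm(222 / 250) - qnorm(75 / 250))
  expect_equal(female$dprime, 1.74, tolerance = 0.005)
  # Gourevitch-Galanter variance, written out
  gg <- function(h, nh, f, nf)
    h * (1 - h) / (nh * dnorm(qnorm(h))^2) +
    f * (1 - f) / (nf * dnorm(qnorm(f))^2)
  expect_equal(male$var_dprime, gg(157 / 250, 250, 76 / 250, 250))
  expect_equal(male$var_c, male$var_dprime / 4)
  # equal rates: d' = 0, c = -z(hit)
  flat <- grt_confusion_matrix(matrix(rep(c(30, 30, 20, 20), each = 4), 4, 4))
  s <- marginal_sdt(flat, "A", 1)
  expect_equal(s$dprime, 0)
  expect_equal(s$c, -qnorm(s$hit))
})

test_that("the example table yields the published macro conclusions", {
  rep <- macro_analysis(cm1)
  expect_equal(rep$dimensions$A$PS, "NO")
  expect_equal(rep$dimensions$A$DS, "?")
  expect_equal(rep$dimensions$B$PS, "yes")
  expect_equal(rep$dimensions$B$DS, "yes")
  df <- as.data.frame(rep)
  expect_equal(df$PS, c("NO", "yes"))
  expect_equal(df$DS, c("?", "yes"))
})

test_that("macro analysis is symmetric under relabeling the dimensions", {
  swapped <- swap_dimensions(cm1)
  r1 <- macro_analysis(cm1)
  r2 <- macro_analysis(swapped)
  for (lev in 1:2) {
    expect_equal(r2$dimensions$A$mri[[lev]]$statistic,
                 r1$dimensions$B$mri[[lev]]$statistic)
    expect_equal(r2$dimensions$B$mri[[lev]]$statistic,
                 r1$dimensions$A$mri[[lev]]$statistic)
  }
  expect_equal(r2$dimensions$A$PS, r1$dimensions$B$PS)
  expect_equal(r2$dimensions$B$PS, r1$dimensions$A$PS)
  expect_equal(r2$dimensions$A$DS, r1$dimensions$B$DS)
  expect_equal(r2$dimensions$B$DS, r1$dimensions$A$DS)
})

test_that("a separable, independent generator passes the macro analysis", {
  # expected counts at large n: every test statistic is essentially zero
  cm <- grt_confusion_matrix(round(1e5 * predicted_matrix(ps_pi_ds_model(d = 2))))
  rep <- macro_analysis(cm)
  expect_equal(rep$dimensions$A$PS, "yes")
  expect_equal(rep$dimensions$A$DS, "yes")
  expect_equal(rep$dimensions$B$PS, "yes")
  expect_equal(rep$dimensions$B$DS, "yes")
})

test_that("every reported p-value is in [0, 1] and passed matches alpha", {
  set.seed(5)
  for (i in 1:20) {
    cm <- simulate_identification(ps_pi_ds_model(d = runif(1, 0.5, 3)),
                                  200, seed = i)
    rep <- suppressWarnings(macro_analysis(cm, alpha = 0.1))
    for (d in rep$dimensions) {
      tests <- c(d$mri, list(d$dprime_equal, d$c_equal))
      for (t in tests) {
        expect_gte(t$p_value, 0)
        expect_lte(t$p_value, 1)
        expect_identical(t$passed, t$p_value >= 0.1)
      }
    }
  }
})
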