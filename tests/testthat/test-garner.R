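# A separable, context-free generator used throughout: orthogonal bounds,
# aligned marginals, RT depends only on bound distance.
sep_garner <- function(seed, n_baseline = 200, n_filtering = 200,
                       context_slowdown = 0, rt = rt_params()) {
  simulate_garner(ps_pi_ds_model(d = 2), relevant = "A", rt = rt,
                  n_baseline = n_baseline, n_filtering = n_filtering,
                  context_slowdown = context_slowdown, seed = seed)
}

test_that("identical RT samples give a null interference result", {
  rt <- rep(c(400, 450, 500, 550, 600), 4)
  trials <- garner_trials(data.frame(
    block = rep(1:2, each = 20),
    relevant = rep(1:2, 20),
    irrelevant = rep(rep(1:2, each = 10), 2),
    accuracy = 1, rt = rep(rt, 2)))
  gi <- garner_interference_rt(trials)
  expect_equal(gi$statistic, 0)
  expect_equal(gi$code, "yes?")
  acc <- garner_interference_accuracy(trials)
  expect_equal(acc$statistic, 0)
  expect_equal(acc$code, "yes?")
  expect_true(acc$ceiling_warning)  # all-correct toy data sit at ceiling
})

test_that("interference verdicts are directional", {
  # filtering 80 ms slower: violation
  slow <- sep_garner(seed = 41, context_slowdown = 80)
  expect_equal(garner_interference_rt(slow)$code, "NO")
  # filtering faster than baseline: significant but not in the violation
  # direction, so the test still passes
  fast <- sep_garner(seed = 42, context_slowdown = -80)
  gi <- garner_interference_rt(fast)
  expect_equal(gi$code, "yes?")
  expect_lt(gi$p_value, 0.05)
})

test_that("accuracy interference detects lower filtering accuracy", {
  set.seed(43)
  trials <- garner_trials(data.frame(
    block = rep(1:2, each = 400),
    relevant = rep(1:2, 400),
    irrelevant = rep(1:2, times = 400),
    accuracy = c(rbinom(400, 1, 0.90), rbinom(400, 1, 0.80)),
    rt = rlnorm(800, log(500), 0.2)))
  res <- garner_interference_accuracy(trials)
  expect_equal(res$code, "NO")
  expect_false(res$ceiling_warning)
})

test_that("near-ceiling accuracy raises the ceiling warning", {
  set.seed(44)
  trials <- garner_trials(data.frame(
    block = rep(1:2, each = 200),
    relevant = rep(1:2, 200),
    irrelevant = rep(rep(1:2, each = 2), 100),
    accuracy = c(rbinom(200, 1, 0.98), rbinom(200, 1, 0.97)),
    rt = rlnorm(400, log(450), 0.2)))
  expect_true(garner_interference_accuracy(trials)$ceiling_warning)
  expect_true(garner_analysis(trials)$ceiling_warning)
})

test_that("mRi detects irrelevant-level-dependent accuracy and is antisymmetric", {
  set.seed(45)
  n <- 200
  mk <- function(p_by_irr) garner_trials(data.frame(
    block = 2,
    relevant = rep(1:2, each = 2 * n),
    irrelevant = rep(c(1, 2, 1, 2), each = n),
    accuracy = rbinom(4 * n, 1, rep(p_by_irr, each = n)),
    rt = rlnorm(4 * n, log(500), 0.2)))
  trials <- mk(c(0.9, 0.75, 0.9, 0.75))
  res <- garner_mri(trials)
  expect_equal(res[[1]]$code, "NO")
  expect_equal(res[[2]]$code, "NO")
  # swapping the irrelevant labels flips the sign of the statistic
  swapped <- trials
  swapped$irrelevant <- 3 - swapped$irrelevant
  res2 <- garner_mri(garner_trials(as.data.frame(swapped)))
  expect_equal(res2[[1]]$statistic, -res[[1]]$statistic)
})

test_that("the KS statistic equals the brute-force ECDF supremum", {
  set.seed(46)
  for (i in 1:20) {
    n1 <- sample(20:60, 1); n2 <- sample(20:60, 1)
    trials <- garner_trials(data.frame(
      block = 2,
      relevant = 1,
      irrelevant = rep(1:2, c(n1, n2)),
      accuracy = 1,
      rt = c(rlnorm(n1, log(500), 0.3), rlnorm(n2, log(520), 0.3))))
    # add a token second relevant level so the cell grid is complete
    extra <- data.frame(block = 2, relevant = 2,
                        irrelevant = rep(1:2, each = 3), accuracy = 1,
                        rt = rlnorm(6, log(500), 0.3))
    trials <- garner_trials(rbind(as.data.frame(trials), extra))
    res <- garner_mrti(trials)
    x <- trials$rt[trials$relevant == 1 & trials$irrelevant == 1]
    y <- trials$rt[trials$relevant == 1 & trials$irrelevant == 2]
    expect_equal(res[[1]]$statistic, brute_force_ks_d(x, y))
  }
})

test_that("mRTi detects an irrelevant-level RT shift", {
  set.seed(47)
  n <- 150
  trials <- garner_trials(data.frame(
    block = 2,
    relevant = rep(1:2, each = 2 * n),
    irrelevant = rep(c(1, 2, 1, 2), each = n),
    accuracy = 1,
    rt = rlnorm(4 * n, log(500), 0.2) +
      rep(c(0, 100, 0, 100), each = n)))
  res <- garner_mrti(trials)
  expect_equal(res[[1]]$code, "NO")
  expect_equal(res[[2]]$code, "NO")
})

test_that("a separable context-free generator rarely fails any test", {
  # six tests per run at alpha = 0.05 (directional for the GI rows), so a
  # handful of false alarms over 15 runs is expected; many would be a bug
  n_no <- 0
  full_pass <- 0
  for (s in 1:15) {
    rep <- garner_analysis(sep_garner(seed = 4800 + s, n_baseline = 400,
                                      n_filtering = 400))
    n_no <- n_no + sum(rep$table$code == "NO")
    full_pass <- full_pass + rep$overall
  }
  expect_lte(n_no, 9)       # <= 10% of 90 verdicts
  expect_gte(full_pass, 8)  # most runs pass outright
})

test_that("a pure context effect fires GI but not the invariance tests", {
  # the paper's diagnosticity claim as a testable dissociation
  hits <- 0
  for (s in 1:40) {
    rep <- garner_analysis(sep_garner(seed = 400 + s, context_slowdown = 80))
    codes <- setNames(rep$table$code, rep$table$test)
    if (codes[["GI(RT)"]] == "NO" && codes[["mRTi level 1"]] == "yes?" &&
        codes[["mRTi level 2"]] == "yes?")
      hits <- hits + 1
  }
  expect_gte(hits, 36)  # >= 90% of seeds
})

test_that("degenerate Garner inputs raise informative errors", {
  base_only <- garner_trials(data.frame(
    block = 1, relevant = rep(1:2, 10), irrelevant = rep(1:2, each = 10),
    accuracy = 1, rt = rlnorm(20, log(500), 0.2)))
  expect_error(garner_mri(base_only), "no filtering trials")
  expect_error(garner_analysis(base_only), "correct trials|filtering")
})
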