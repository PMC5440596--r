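# Shared parameterization for maximum-likelihood fitting. Both the
# traditional 12-model hierarchy (K = 1) and GRT-wIND (K participants) are
# expressed over one full parameter vector of length 16 + 6K:
#
#   [1..6]   means a2b1.(x,y), a1b2.(x,y), a2b2.(x,y)   (a1b1 fixed at (0,0))
#   [7..12]  log variances of the same three stimuli    (a1b1 fixed at 1, 1)
#   [13..16] correlation transforms z, rho = 0.99 tanh z, stimuli in order
#   then per participant: log kappa, logit lambda, slope_a, intercept_a,
#                         slope_b, intercept_b
#
# Restricted models are encoded by an integer map (full[i] = free[map[i]]
# when map[i] > 0, else the fixed value), which also ties parameters by
# sharing a free index. Participant-level variances are sx2/(kappa*lambda)
# and sy2/(kappa*(1-lambda)); traditional models fix kappa = 2, lambda = 1/2
# so the effective variances are exactly the unit variances they assume.

.wind_npar <- function(K) 16L + 6L * K

.full_param_names <- function(K) {
  c("a2b1.x", "a2b1.y", "a1b2.x", "a1b2.y", "a2b2.x", "a2b2.y",
    "a2b1.lsx", "a2b1.lsy", "a1b2.lsx", "a1b2.lsy", "a2b2.lsx", "a2b2.lsy",
    "z.a1b1", "z.a2b1", "z.a1b2", "z.a2b2",
    unlist(lapply(seq_len(K), function(p)
      paste0("p", p, ".", c("logkappa", "logitlambda", "slope_a", "int_a",
                            "slope_b", "int_b")))))
}

# Canonical PS+PI+DS starting configuration on the full scale: grid means
# (0,0),(1,0),(0,1),(1,1), unit variances, zero correlations, mid bounds at
# 0.5, kappa/lambda at their neutral values.
.canonical_full <- function(K, traditional = FALSE) {
  full <- c(1, 0, 0, 1, 1, 1, rep(0, 6), rep(0, 4),
            rep(c(if (traditional) log(2) else 0, 0, 0, 0.5, 0, 0.5), K))
  names(full) <- .full_param_names(K)
  full
}

# Build map/fixed encoding a set of constraints over the full vector.
# Constraints: ps_a / ps_b tie means (and, when tie_variances, variances)
# across levels of the other dimension; pi_mode fixes or ties correlations;
# ds_a / ds_b fix bound slopes at 0; fix_variances and fix_attention freeze
# those blocks entirely (traditional models).
.wind_param_map <- function(K, ps_a = FALSE, ps_b = FALSE,
                            pi_mode = c("free", "single_rho", "PI"),
                            tie_variances = TRUE, fix_variances = FALSE,
                            fix_attention = FALSE, ds_a = FALSE,
                            ds_b = FALSE) {
  pi_mode <- match.arg(pi_mode)
  n <- .wind_npar(K)
  map <- integer(n)
  fixed <- numeric(n)
  canonical <- .canonical_full(K, traditional = fix_attention)
  tie <- rep(NA_integer_, n)  # index of the full-parameter this one copies
  free_mask <- rep(TRUE, n)

  fix <- function(i, value) {
    free_mask[i] <<- FALSE
    fixed[i] <<- value
    tie[i] <<- NA_integer_
  }
  tie_to <- function(i, j) {
    free_mask[i] <<- FALSE
    tie[i] <<- j
  }

  if (ps_a) {            # x marginals equal across B levels
    fix(3L, 0)           # a1b2.x = a1b1.x = 0
    tie_to(5L, 1L)       # a2b2.x = a2b1.x
    if (tie_variances && !fix_variances) {
      fix(9L, 0)         # a1b2.lsx = log 1
      tie_to(11L, 7L)    # a2b2.lsx = a2b1.lsx
    }
  }
  if (ps_b) {            # y marginals equal across A levels
    fix(2L, 0)           # a2b1.y = a1b1.y = 0
    tie_to(6L, 4L)       # a2b2.y = a1b2.y
    if (tie_variances && !fix_variances) {
      fix(8L, 0)         # a2b1.lsy = log 1
      tie_to(12L, 10L)   # a2b2.lsy = a1b2.lsy
    }
  }
  if (fix_variances) for (i in 7:12) fix(i, 0)
  if (pi_mode == "PI") for (i in 13:16) fix(i, 0)
  if (pi_mode == "single_rho") for (i in 14:16) tie_to(i, 13L)
  for (p in seq_len(K)) {
    base <- 16L + 6L * (p - 1L)
    if (fix_attention) {
      fix(base + 1L, log(2))
      fix(base + 2L, 0)
    }
    if (ds_a) fix(base + 3L, 0)
    if (ds_b) fix(base + 5L, 0)
  }
  # traditional models always assume DS
  if (fix_attention) for (p in seq_len(K)) {
    base <- 16L + 6L * (p - 1L)
    fix(base + 3L, 0)
    fix(base + 5L, 0)
  }

  map[free_mask] <- seq_len(sum(free_mask))
  for (i in which(!is.na(tie))) map[i] <- map[tie[i]]
  start <- canonical[free_mask]
  list(map = map, fixed = fixed, start = start, n_free = sum(free_mask),
       names = .full_param_names(K)[free_mask])
}

.build_full <- function(free, map, fixed) {
  full <- fixed
  full[map > 0] <- free[map[map > 0]]
  names(full) <- .full_param_names((length(map) - 16L) %/% 6L)
  full
}

# Project a full vector onto the free vector of a (possibly stricter) map,
# averaging tied entries; used to warm-start restricted fits.
.project_to_free <- function(full, map) {
  vapply(seq_len(max(map)), function(j) mean(full[map == j]), numeric(1))
}

# Flatten a list of confusion matrices into the K x 16 count matrix the C++
# objective consumes (row-major per stimulus).
.counts_matrix <- function(data) {
  if (inherits(data, "grt_cm")) data <- list(data)
  t(vapply(data, function(cm) as.numeric(t(unclass(cm))), numeric(16)))
}

# One multi-start BFGS run over a mapped objective. Starts are the supplied
# start vector plus independent uniform perturbations on [-perturb, perturb]
# per free parameter; initial points are drawn up front so the result does
# not depend on execution order or worker count.
.fit_mapped <- function(counts, pm, n_starts, perturb, control = list(),
                        start = NULL, workers = 1L) {
  if (is.null(start)) start <- pm$start
  inits <- lapply(seq_len(n_starts), function(s)
    start + runif(length(start), -perturb, perturb))
  run1 <- function(init) {
    tryCatch(
      optim(init, fn = cpp_wind_negll, gr = cpp_wind_negll_grad,
            map = pm$map, fixed = pm$fixed, counts = counts,
            method = "BFGS",
            control = modifyList(list(maxit = 1000, reltol = 1e-10), control)),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
  }
  fits <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(inits, run1, mc.cores = workers)
  } else {
    lapply(inits, run1)
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  # polish: restart BFGS from the best solution (a restart resets the
  # Hessian approximation and recovers from stalls on flat ridges)
  if (is.finite(best$value)) {
    for (round in 1:5) {
      again <- run1(best$par)
      if (!is.finite(again$value) || again$value > best$value - 1e-7) break
      best <- again
    }
  }
  conv <- vapply(fits, function(f) identical(f$convergence, 0L), logical(1))
  # A run that exhausts its iteration budget on a flat likelihood ridge is
  # still at a maximum for practical purposes; accept a near-zero gradient.
  if (!any(conv) && is.finite(best$value)) {
    g <- cpp_wind_negll_grad(best$par, pm$map, pm$fixed, counts)
    if (max(abs(g)) < 0.5) conv <- TRUE
  }
  list(par = best$par, value = best$value,
       full = .build_full(best$par, pm$map, pm$fixed),
       converged = any(conv), n_starts_used = n_starts,
       convergence_codes = vapply(fits, function(f)
         as.integer(f$convergence %||% 99L), integer(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reconstruct participant p's effective GRT model (attention-scaled
# variances, own bounds) from a full parameter vector.
.full_to_grt_model <- function(full, participant = 1L) {
  mx <- c(0, full[1], full[3], full[5])
  my <- c(0, full[2], full[4], full[6])
  sx2 <- c(1, exp(full[7]), exp(full[9]), exp(full[11]))
  sy2 <- c(1, exp(full[8]), exp(full[10]), exp(full[12]))
  rho <- 0.99 * tanh(full[13:16])
  base <- 16L + 6L * (participant - 1L)
  kappa <- exp(full[base + 1L])
  lambda <- plogis(full[base + 2L])
  ax <- 1 / (kappa * lambda)
  ay <- 1 / (kappa * (1 - lambda))
  dists <- lapply(1:4, function(s)
    gaussian2d(c(mx[s], my[s]), c(sx2[s] * ax, sy2[s] * ay), rho[s]))
  grt_model(dists,
            linear_bound(full[base + 3L], full[base + 4L], "A"),
            linear_bound(full[base + 5L], full[base + 6L], "B"))
}
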