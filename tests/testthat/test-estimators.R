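# The five causal estimators, heterogeneity and OR reporting.

test_that("Wald ratios follow the delta-method arithmetic", {
  h <- make_h(beta_exp = c(0.25, 0.5), beta_out = c(0.05, 0),
              se_exp = 0.01, se_out = 0.01)
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, c(0.2, 0))
  expect_equal(wr$se, c(0.04, 0.02))
  # zero exposure effect: excluded with a warning, not fatal
  h0 <- make_h(beta_exp = c(0.25, 0), beta_out = c(0.05, 0.01))
  expect_warning(wr0 <- wald_ratios(h0), "zero exposure effect")
  expect_equal(nrow(wr0), 1L)
})

test_that("IVW collapses to the Wald ratio for a single instrument", {
  h <- make_h(beta_exp = 0.25, beta_out = 0.05, se_exp = 0.01, se_out = 0.01)
  est <- mr_ivw(h)
  expect_identical(est$beta, 0.05 / 0.25)
  expect_identical(est$se, 0.01 / 0.25)
  expect_equal(est$n_snp, 1L)
  expect_true(is.na(est$q_stat))
})

test_that("IVW matches an independent weighted-least-squares solve on a 5-row fixture", {
  bx <- c(0.12, 0.09, 0.15, 0.11, 0.08)
  by <- c(0.030, 0.031, 0.044, 0.020, 0.029)
  sy <- c(0.010, 0.012, 0.009, 0.015, 0.011)
  h <- make_h(bx, by, se_exp = 0.01, se_out = sy)
  # oracle: weighted regression through the origin, weights 1/sy^2
  w <- 1 / sy^2
  beta_wls <- solve(t(bx) %*% (w * bx), t(bx) %*% (w * by))[1, 1]
  est_f <- mr_ivw(h, model = "fixed")
  expect_equal(est_f$beta, beta_wls, tolerance = 1e-12)
  expect_equal(est_f$se, sqrt(1 / sum((bx / sy)^2)), tolerance = 1e-12)
  # multiplicative random effects only rescales the standard error
  est_r <- mr_ivw(h)
  expect_equal(est_r$beta, beta_wls, tolerance = 1e-12)
  expect_equal(est_r$se,
               est_f$se * max(1, sqrt(est_r$q_stat / (5 - 1))),
               tolerance = 1e-12)
})

test_that("MR-Egger matches an independent normal-equations solve", {
  bx <- c(0.12, 0.09, 0.15, 0.11)
  by <- c(0.035, 0.020, 0.050, 0.033)
  sy <- c(0.010, 0.012, 0.009, 0.015)
  h <- make_h(bx, by, se_exp = 0.01, se_out = sy)
  w <- 1 / sy^2
  X <- unname(cbind(1, bx))
  coefs <- solve(t(X) %*% (w * X), t(X) %*% (w * by))
  est <- mr_egger(h)
  expect_equal(est$beta, coefs[2, 1], tolerance = 1e-12)
  expect_equal(est$egger_intercept, coefs[1, 1], tolerance = 1e-12)
  # classical WLS standard errors, inflated by max(1, sigma)
  res <- by - X %*% coefs
  sigma2 <- sum(w * res^2) / (4 - 2)
  se_cl <- sqrt(diag(solve(t(X) %*% (w * X))))
  expect_equal(est$se, unname(se_cl[2]) * max(1, sqrt(sigma2)),
               tolerance = 1e-12)
  expect_error(mr_egger(make_h(bx[1:2], by[1:2])), "at least 3")
})

test_that("Egger re-orients instruments so the exposure effects are non-negative", {
  bx <- c(0.12, -0.09, 0.15, -0.11)
  by <- c(0.035, -0.020, 0.050, -0.033)
  h1 <- make_h(bx, by, se_out = 0.01)
  h2 <- make_h(abs(bx), sign(bx) * by, se_out = 0.01)
  e1 <- mr_egger(h1); e2 <- mr_egger(h2)
  expect_equal(e1$beta, e2$beta)
  expect_equal(e1$egger_intercept, e2$egger_intercept)
})

test_that("the weighted median reduces to the ordinary median with equal weights", {
  h <- make_h(beta_exp = c(1, 1, 1), beta_out = c(1, 2, 9), se_out = 1)
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$beta, 2)
})

test_that("the weighted median returns the ratio holding dominant weight", {
  # weights via se: middle ratio gets ~0.9 of the inverse-variance mass
  h <- new_harmonized_set(data.frame(
    rsid = c("rs1", "rs2", "rs3"), beta_exp = 1, se_exp = 0.01,
    beta_out = c(0.1, 0.5, 3.0), se_out = c(0.3, 0.0707, 0.3)))
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.5, tolerance = 1e-6)
})

test_that("mode estimators return the common ratio for a point mass and ignore outliers", {
  h_same <- make_h(beta_exp = c(1, 1, 1, 1), beta_out = rep(0.7, 4))
  expect_equal(mr_mode(h_same, n_boot = 20, seed = 1)$beta, 0.7)
  expect_equal(mr_mode(h_same, weighted = TRUE, n_boot = 20, seed = 1)$beta, 0.7)

  h_out <- make_h(beta_exp = rep(1, 4), beta_out = c(0.3, 0.3, 0.3, 5.0),
                  se_out = 0.05)
  est <- mr_mode(h_out, n_boot = 20, seed = 1)
  # independent grid-search oracle over the smoothed density
  r <- c(0.3, 0.3, 0.3, 5.0)
  s <- min(sd(r), mad(r)); if (s <= 0) s <- sd(r)   # documented mad fallback
  bw <- 0.9 * s * 4^(-1 / 5)
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 512)
  dens <- sapply(grid, function(g) sum(dnorm(g, r, bw)) / 4)
  expect_equal(est$beta, grid[which.max(dens)], tolerance = 1e-12)
  expect_lt(abs(est$beta - 0.3), 0.05)
})

test_that("Cochran's Q is zero for homogeneous ratios and matches hand arithmetic", {
  h_same <- make_h(beta_exp = c(1, 2), beta_out = c(0.5, 1.0), se_out = 0.1)
  q <- cochran_q(h_same)
  expect_equal(q$q_stat, 0)
  expect_equal(q$q_pval, 1)

  h2 <- make_h(beta_exp = c(1, 1), beta_out = c(0.2, 0.6), se_out = c(0.1, 0.2))
  # hand computation: ratios .2/.6, weights 100/25
  w <- c(100, 25); r <- c(0.2, 0.6)
  b <- sum(w * r) / sum(w)
  expect_equal(cochran_q(h2)$q_stat, sum(w * (r - b)^2), tolerance = 1e-12)
  expect_equal(cochran_q(h2)$df, 1)
  expect_error(cochran_q(make_h(1, 0.5)), "at least 2")
})

test_that("Q follows its chi-square reference under a homogeneous null", {
  set.seed(21)
  m <- 10
  qs <- replicate(1000, {
    bx <- rnorm(m, 0.2, 0.02)
    by <- rnorm(m, 0.3 * bx, 0.05)
    cochran_q(make_h(bx, by, se_out = 0.05))$q_stat
  })
  # E[Q] = df; MC tolerance 3 * sd/sqrt(n)
  expect_lt(abs(mean(qs) - (m - 1)), 3 * sd(qs) / sqrt(1000))
})

test_that("odds-ratio transform keeps the geometric-mean structure of the CI", {
  o <- to_or(0, 0.5)
  expect_equal(o$or, 1)
  expect_equal(o$ci_low * o$ci_high, 1, tolerance = 1e-12)
  o2 <- to_or(-1.9805, 0.7617)
  expect_equal(sqrt(o2$ci_low * o2$ci_high), o2$or, tolerance = 1e-12)
  expect_error(to_or(1, 0), "se")
})

test_that("every estimator is invariant to instrument ordering", {
  set.seed(13)
  m <- 12
  bx <- rnorm(m, 0.2, 0.05)
  by <- rnorm(m, 0.4 * bx, 0.03)
  h1 <- make_h(bx, by, se_out = 0.03)
  perm <- sample(m)
  h2 <- new_harmonized_set(h1$rows[perm, , drop = FALSE])
  for (fn in list(function(h) mr_ivw(h),
                  function(h) mr_egger(h),
                  function(h) mr_weighted_median(h, n_boot = 50, seed = 4),
                  function(h) mr_mode(h, n_boot = 50, seed = 4),
                  function(h) mr_mode(h, weighted = TRUE, n_boot = 50, seed = 4))) {
    e1 <- fn(h1); e2 <- fn(h2)
    expect_identical(e1$beta, e2$beta)
    expect_identical(e1$se, e2$se)   # seeded, sort-before-resample bootstrap
  }
})

test_that("estimates are scale-equivariant in the exposure effects", {
  set.seed(14)
  m <- 10
  bx <- rnorm(m, 0.3, 0.05)
  by <- rnorm(m, 0.5 * bx, 0.02)
  h1 <- make_h(bx, by, se_out = 0.02)
  cc <- 2.5
  h2 <- make_h(cc * bx, by, se_out = 0.02)
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h1)$beta / cc, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$beta, mr_egger(h1)$beta / cc, tolerance = 1e-10)
  expect_equal(mr_weighted_median(h2, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(h1, n_boot = 10, seed = 1)$beta / cc,
               tolerance = 1e-10)
})

test_that("all five estimators recover the simulated effect with valid instruments", {
  # well-powered regime: balanced outcome, no pleiotropy, true effect 0.3
  n_rep <- 200
  betas <- matrix(NA_real_, n_rep, 5)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(m_snps = 20, h2_x = 0.1, theta_xd = 0.3,
                      n_cases = 50000, n_controls = 50000, seed = 3000 + i)
    tri <- simulate_triple(cfg)
    iv <- select_instruments(tri$exposure)
    h <- harmonize(tri$exposure, tri$outcome, iv)
    fit <- mr_fit(h, n_boot = 10, seed = 1)
    betas[i, ] <- fit$estimates$beta[match(
      c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode"),
      fit$estimates$method)]
  }
  for (j in 1:5) {
    mc_se <- sd(betas[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(betas[, j]) - 0.3), 2 * mc_se + 0.01)
  }
})

test_that("the weighted median resists directional pleiotropy better than IVW", {
  # majority-valid regime: 40% of instruments carry a +0.5 pleiotropic offset
  set.seed(77)
  n_rep <- 200
  err <- matrix(NA_real_, n_rep, 2)
  for (i in seq_len(n_rep)) {
    m <- 20
    bx <- rnorm(m, 0.25, 0.03)
    offset <- c(rep(0.5, 8), rep(0, 12)) * bx   # pleiotropy in outcome units
    by <- rnorm(m, 0.3 * bx + offset, 0.02)
    h <- make_h(bx, by, se_out = 0.02)
    err[i, ] <- c(abs(mr_weighted_median(h, n_boot = 10, seed = i)$beta - 0.3),
                  abs(mr_ivw(h)$beta - 0.3))
  }
  expect_lt(mean(err[, 1]), mean(err[, 2]))
})

test_that("mr_fit aggregates methods, skipping those below their instrument minimum", {
  h2 <- make_h(c(0.1, 0.2), c(0.03, 0.06), se_out = 0.01)
  warns <- character(0)
  fit <- withCallingHandlers(mr_fit(h2, n_boot = 10), warning = function(w) {
    warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  expect_length(warns, 4L)   # egger, median and both modes need 3 instruments
  expect_match(warns, "skipped", all = TRUE)
  expect_equal(fit$estimates$method, "ivw")
  h5 <- make_h(seq(0.1, 0.5, length.out = 5), seq(0.03, 0.15, length.out = 5),
               se_out = 0.01)
  fit5 <- mr_fit(h5, n_boot = 10)
  expect_equal(nrow(fit5$estimates), 5L)
  expect_named(coef(fit5), c("ivw", "egger", "weighted_median", "simple_mode",
                             "weighted_mode"))
  ci <- confint(fit5)
  expect_true(all(ci[, 1] < coef(fit5) & coef(fit5) < ci[, 2]))
  tab <- mr_table(fit5)
  expect_match(tab$`OR(95%CI)`[1], "^\\d+\\.\\d{3}\\(\\d+\\.\\d{3}-\\d+\\.\\d{3}\\)$")
})
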