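test_that("wald_ratio divides effects with delta-method SE", {
  w <- wald_ratio(0.1, 0.01, 0.02, 0.005)
  expect_equal(w$estimate, 0.2)
  expect_equal(w$se, 0.05)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.005)$estimate, 0)
  # sign symmetry
  wn <- wald_ratio(-0.1, 0.01, 0.02, 0.005)
  expect_equal(wn$estimate, -0.2)
  expect_equal(wn$se, w$se)
  # second-order SE adds the exposure term
  w2 <- wald_ratio(0.1, 0.01, 0.02, 0.005, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.005^2 / 0.1^2 + 0.02^2 * 0.01^2 / 0.1^4))
  expect_gt(w2$se, w$se)
  expect_error(wald_ratio(0, 0.01, 0.02, 0.005), "beta_exp")
})

test_that("mr_ivw matches the closed form and the regression oracle", {
  h <- make_hset(bx = c(0.1, 0.2, 0.3), sx = 0.01,
                 by = c(0.03, 0.04, 0.05), sy = 0.01)
  fit <- mr_ivw(h)
  expect_equal(fit$estimate, sum(h$beta_exposure * h$beta_outcome) /
                 sum(h$beta_exposure^2))
  expect_equal(fit$estimate, 0.1857, tolerance = 1e-3)
  expect_equal(fit$estimate, oracle_ivw(h$beta_exposure, h$beta_outcome,
                                        h$se_outcome))

  # identical Wald ratios: estimate = ratio, Q = 0
  h0 <- make_hset(bx = c(0.1, 0.2, 0.4), sx = 0.01,
                  by = c(0.02, 0.04, 0.08), sy = 0.01)
  f0 <- mr_ivw(h0)
  expect_equal(f0$estimate, 0.2)
  expect_equal(f0$q, 0, tolerance = 1e-24)

  # with 2 SNPs IVW equals the weight-averaged Wald ratio
  h2 <- make_hset(bx = c(0.1, 0.25), sx = 0.01, by = c(0.05, 0.02),
                  sy = c(0.01, 0.02))
  r <- h2$beta_outcome / h2$beta_exposure
  wr <- h2$beta_exposure^2 / h2$se_outcome^2
  expect_equal(mr_ivw(h2)$estimate, sum(wr * r) / sum(wr))
  expect_error(mr_ivw(make_hset(0.1, 0.01, 0.02, 0.01)), "at least 2")

  # oracle equivalence on random instances
  set.seed(12)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    hh <- make_hset(bx = rnorm(k, 0.1, 0.05), sx = runif(k, 0.005, 0.02),
                    by = rnorm(k, 0.02, 0.02), sy = runif(k, 0.005, 0.03))
    expect_equal(mr_ivw(hh)$estimate,
                 oracle_ivw(hh$beta_exposure, hh$beta_outcome, hh$se_outcome))
  }
})

test_that("mr_egger matches hand OLS and the weighted regression oracle", {
  h <- make_hset(bx = c(0.1, 0.2, 0.3), sx = 0.01,
                 by = c(0.03, 0.04, 0.05), sy = 0.01)
  fit <- mr_egger(h)
  expect_equal(fit$estimate, 0.1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.02, tolerance = 1e-10)

  # proportional effects: zero intercept, exact slope
  hp <- make_hset(bx = c(0.1, 0.2, 0.4), sx = 0.01,
                  by = 0.3 * c(0.1, 0.2, 0.4), sy = 0.01)
  fp <- mr_egger(hp)
  expect_equal(fp$estimate, 0.3, tolerance = 1e-12)
  expect_equal(fp$intercept, 0, tolerance = 1e-12)

  # oracle equivalence, including negative exposure effects (orientation)
  set.seed(13)
  for (i in 1:20) {
    k <- sample(4:12, 1)
    hh <- make_hset(bx = rnorm(k, 0, 0.2), sx = runif(k, 0.005, 0.02),
                    by = rnorm(k, 0, 0.05), sy = runif(k, 0.005, 0.03))
    hh <- hh[hh$beta_exposure != 0, ]
    ofit <- oracle_egger(hh$beta_exposure, hh$beta_outcome, hh$se_outcome)
    efit <- mr_egger(hh)
    expect_equal(efit$intercept, ofit[1])
    expect_equal(efit$estimate, ofit[2])
  }
  expect_error(mr_egger(make_hset(c(0.1, 0.2), 0.01, c(0.1, 0.1), 0.01)),
               "at least 3")
})

test_that("egger with intercept forced to zero reproduces IVW", {
  set.seed(14)
  k <- 8
  h <- make_hset(bx = abs(rnorm(k, 0.1, 0.05)), sx = 0.01,
                 by = rnorm(k, 0.02, 0.02), sy = runif(k, 0.01, 0.02))
  # constrained fit = weighted regression through the origin = IVW point
  fit0 <- lm(beta_outcome ~ 0 + beta_exposure, data = h,
             weights = 1 / h$se_outcome^2)
  expect_equal(mr_ivw(h)$estimate, unname(coef(fit0)[1]))
})

test_that("weighted median interpolates cumulative weights and bootstraps SE", {
  # equal weights, symmetric ratios: plain median
  h <- make_hset(bx = c(0.1, 0.1, 0.1), sx = 0.001,
                 by = c(0.01, 0.02, 0.03), sy = 0.01)
  fit <- mr_weighted_median(h, n_boot = 200, seed = 5)
  expect_equal(fit$estimate, 0.2, tolerance = 1e-10)

  # all ratios equal: that value, small bootstrap SE
  he <- make_hset(bx = c(0.1, 0.2, 0.3), sx = 0.001,
                  by = 0.25 * c(0.1, 0.2, 0.3), sy = 0.001)
  fe <- mr_weighted_median(he, n_boot = 200, seed = 5)
  expect_equal(fe$estimate, 0.25, tolerance = 1e-10)
  expect_lt(fe$se, 0.05)

  # spec worked example: ratios (0.1, 0.2, 0.9), weights (0.45, 0.45, 0.10)
  est <- stonemr:::weighted_median_point(c(0.1, 0.2, 0.9), c(0.45, 0.45, 0.10))
  expect_gt(est, 0.1); expect_lt(est, 0.2)
  expect_equal(est, oracle_weighted_median(c(0.1, 0.2, 0.9),
                                           c(0.45, 0.45, 0.10)))

  # oracle equivalence on random instances; dominant-weight SNP wins
  set.seed(15)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    r <- rnorm(k); w <- runif(k)
    expect_equal(stonemr:::weighted_median_point(r, w),
                 oracle_weighted_median(r, w))
  }
  dom <- stonemr:::weighted_median_point(c(0.5, 1, 2), c(0.002, 0.996, 0.002))
  expect_equal(dom, 1, tolerance = 1e-2)

  # determinism under the same seed
  f1 <- mr_weighted_median(h, n_boot = 100, seed = 9)
  f2 <- mr_weighted_median(h, n_boot = 100, seed = 9)
  expect_identical(f1$se, f2$se)
  expect_error(mr_weighted_median(h[1:2, ]), "at least 3")
})

test_that("contamination mixture finds the supported mode with a ci_set", {
  # all SNPs valid, tight around 0.2
  h <- make_hset(bx = rep(0.2, 6), sx = 0.001,
                 by = rep(0.04, 6) + c(-2, -1, 0, 0, 1, 2) * 1e-4, sy = 0.005)
  fit <- mr_conmix(h, psi = 0.1)
  expect_equal(fit$estimate, 0.2, tolerance = 0.01)
  expect_equal(nrow(fit$ci_set), 1L)
  expect_true(fit$ci_set[1, "lower"] <= fit$estimate &&
                fit$estimate <= fit$ci_set[1, "upper"])

  # symmetric contamination: estimate sits at the better-supported mode
  # and equals the brute-force grid scan
  bx <- rep(0.2, 10)
  by <- c(rep(0.04, 6), rep(0.16, 4)) # ratios 0.2 (x6) and 0.8 (x4)
  hc <- make_hset(bx = bx, sx = 0.001, by = by, sy = 0.004)
  fitc <- mr_conmix(hc, psi = 0.5)
  ratios <- by / bx
  ses <- hc$se_outcome / abs(bx)
  grid <- seq(-0.5, 1.5, length.out = 2001)
  expect_equal(fitc$estimate, oracle_conmix(ratios, ses, 0.5, grid),
               tolerance = 0.01)  # grids differ; same mode
  expect_equal(fitc$estimate, 0.2, tolerance = 0.01)

  # ci_set always contains the estimate (random property)
  set.seed(16)
  for (i in 1:10) {
    k <- sample(4:10, 1)
    hh <- make_hset(bx = rnorm(k, 0.2, 0.02), sx = 0.01,
                    by = rnorm(k, 0.05, 0.03), sy = runif(k, 0.01, 0.03))
    ff <- mr_conmix(hh)
    inside <- any(ff$ci_set[, "lower"] <= ff$estimate &
                    ff$estimate <= ff$ci_set[, "upper"])
    expect_true(inside)
  }
  expect_error(mr_conmix(h, psi = -1), "psi")
  expect_error(mr_conmix(h[1:2, ]), "at least 3")
})

test_that("estimators are invariant to SNP order and joint allele flips", {
  set.seed(17)
  k <- 9
  h <- make_hset(bx = rnorm(k, 0.1, 0.05), sx = 0.01,
                 by = rnorm(k, 0.02, 0.02), sy = runif(k, 0.01, 0.02))
  perm <- sample(k)
  hp <- h[perm, ]
  expect_equal(mr_ivw(hp)$estimate, mr_ivw(h)$estimate)
  expect_equal(mr_egger(hp)$estimate, mr_egger(h)$estimate)

  flip <- h
  j <- c(2, 5)
  flip$beta_exposure[j] <- -flip$beta_exposure[j]
  flip$beta_outcome[j] <- -flip$beta_outcome[j]
  expect_equal(mr_ivw(flip)$estimate, mr_ivw(h)$estimate)
  expect_equal(mr_egger(flip)$estimate, mr_egger(h)$estimate)
  expect_equal(mr_conmix(flip, psi = 0.3)$estimate,
               mr_conmix(h, psi = 0.3)$estimate)
})
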