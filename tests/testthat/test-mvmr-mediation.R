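mv_set_from <- function(bx1, bx2, by, sy = 0.01) {
  k <- length(bx1)
  data.frame(variant_id = sprintf("s%02d", 1:k),
             beta_exp1 = bx1, se_exp1 = 0.01,
             beta_exp2 = bx2, se_exp2 = 0.01,
             beta_outcome = by, se_outcome = sy,
             stringsAsFactors = FALSE)
}

test_that("mvmr_fit solves exact linear constructions", {
  # orthogonal exposure vectors, exact by = 0.2 bx1 + 0.5 bx2: zero residual Q
  bx1 <- c(0.1, 0.2, 0.0, 0.0, 0.3, 0.0)
  bx2 <- c(0.0, 0.0, 0.2, 0.1, 0.0, 0.25)
  by <- 0.2 * bx1 + 0.5 * bx2
  mv <- mvmr_fit(mv_set_from(bx1, bx2, by), exposures = c("exp1", "exp2"))
  expect_equal(mv$estimates$direct_estimate, c(0.2, 0.5), tolerance = 1e-10)
  expect_equal(mv$q, 0, tolerance = 1e-18)
  expect_equal(mv$n_snp, 6L)

  # all-zero co-exposure column: first estimate equals univariable IVW
  set.seed(41)
  bx1 <- rnorm(8, 0.15, 0.05)
  by <- 0.3 * bx1 + rnorm(8, 0, 0.01)
  expect_message(
    mv0 <- mvmr_fit(mv_set_from(bx1, rep(0, 8), by),
                    exposures = c("exp1", "exp2")),
    "all-zero")
  h <- make_hset(bx = bx1, sx = 0.01, by = by, sy = 0.01)
  expect_equal(mv0$estimates$direct_estimate[1], mr_ivw(h)$estimate)
  expect_true(is.na(mv0$estimates$direct_estimate[2]))

  # genuine collinearity names the offending exposures
  expect_error(mvmr_fit(mv_set_from(bx1, 2 * bx1, by),
                        exposures = c("exp1", "exp2")), "collinear")
  expect_error(mvmr_fit(mv_set_from(bx1[1:2], rnorm(2), by[1:2]),
                        exposures = c("exp1", "exp2")), "more SNPs")
})

test_that("mvmr_fit recovers direct effects on simulated data", {
  reps <- 25
  ests <- vapply(seq_len(reps), function(r) {
    cfg <- simulation_config(m_snps = 250, m_instruments = 100,
                             m_instruments_mediator = 100,
                             theta_direct = 0.1, a_path = 0.5, b_path = 0.2,
                             seed = 3000 + r)
    sim <- simulate_sumstats(cfg)
    mv <- harmonize_mv(list(exposure = sim$exposure, mediator = sim$mediator),
                       sim$outcome)
    instr <- unique(c(sim$truth$valid_instrument_ids,
                      sim$truth$mediator_instrument_ids))
    fit <- mvmr_fit(mv[mv$variant_id %in% instr, ],
                    exposures = c("exposure", "mediator"))
    fit$estimates$direct_estimate
  }, numeric(2))
  mc <- function(x) 3 * sd(x) / sqrt(reps)
  expect_lt(abs(mean(ests[1, ]) - 0.1), mc(ests[1, ]) + 0.01)
  expect_lt(abs(mean(ests[2, ]) - 0.2), mc(ests[2, ]) + 0.01)
})

test_that("mediate multiplies paths with delta-method uncertainty", {
  # B = 0: no indirect effect, zero proportion
  m0 <- mediate(total = c(0.3, 0.05), a_path = c(0.5, 0.02), b_path = c(0, 0.01))
  expect_equal(m0$indirect$estimate, 0)
  expect_equal(m0$proportion_mediated$estimate, 0)

  # full mediation: c = A x B exactly
  mf <- mediate(total = c(0.1, 0.01), a_path = c(0.5, 0.01),
                b_path = c(0.2, 0.01))
  expect_equal(mf$proportion_mediated$estimate, 1)
  expect_equal(mf$direct_product$estimate, 0)

  # printed-values arithmetic: A = 0.12, B = ln(1.48), c = ln(1.33)
  mp <- mediate(total = c(log(1.33), 0.05), a_path = c(0.12, 0.02),
                b_path = c(log(1.48), 0.09))
  expect_equal(mp$indirect$estimate, 0.12 * log(1.48))
  expect_equal(mp$proportion_mediated$estimate, 0.165, tolerance = 1e-2)

  # delta-method variances against the analytic formulas
  a <- c(0.4, 0.03); b <- c(0.25, 0.05); ct <- c(0.3, 0.04)
  mm <- mediate(ct, a, b)
  expect_equal(mm$indirect$se,
               sqrt(a[1]^2 * b[2]^2 + b[1]^2 * a[2]^2))
  ind <- a[1] * b[1]
  expect_equal(mm$proportion_mediated$se,
               sqrt((a[1]^2 * b[2]^2 + b[1]^2 * a[2]^2) / ct[1]^2 +
                      ind^2 * ct[2]^2 / ct[1]^4))
  # exact arithmetic identities
  expect_equal(mm$proportion_mediated$estimate * mm$total$estimate,
               mm$indirect$estimate)

  # zero-SE inputs give zero-variance outputs
  mz <- mediate(c(0.2, 0), c(0.5, 0), c(0.2, 0))
  expect_equal(mz$indirect$se, 0)
  expect_equal(mz$proportion_mediated$se, 0)
  expect_equal(mz$proportion_mediated$estimate, 0.5)

  expect_warning(mediate(c(0, 0.01), a, b), "undefined")
})

test_that("mediation is invariant to rescaling the mediator's units", {
  a <- c(0.4, 0.03); b <- c(0.25, 0.05); ct <- c(0.3, 0.04)
  base <- mediate(ct, a, b)
  for (s in c(0.1, 2, 12.5)) {
    scaled <- mediate(ct, c(a[1] * s, a[2] * s), c(b[1] / s, b[2] / s))
    expect_equal(scaled$indirect$estimate, base$indirect$estimate)
    expect_equal(scaled$indirect$se, base$indirect$se, tolerance = 1e-12)
    expect_equal(scaled$proportion_mediated$estimate,
                 base$proportion_mediated$estimate)
  }
})

test_that("proportion-mediated recovery with CI coverage on simulated data", {
  # stated world: c' = 0.17, A = 0.3, B = 0.1 -> proportion 0.15
  reps <- 40
  res <- vapply(seq_len(reps), function(r) {
    cfg <- simulation_config(m_snps = 250, m_instruments = 100,
                             m_instruments_mediator = 100,
                             theta_direct = 0.17, a_path = 0.3, b_path = 0.1,
                             seed = 6000 + r)
    sim <- simulate_sumstats(cfg)
    h_xy <- harmonize(sim$exposure, sim$outcome)
    h_xm <- harmonize(sim$exposure, sim$mediator)
    instr <- sim$truth$valid_instrument_ids
    total <- mr_ivw(h_xy[h_xy$variant_id %in% instr, ])
    a_fit <- mr_ivw(h_xm[h_xm$variant_id %in% instr, ])
    mv <- harmonize_mv(list(exposure = sim$exposure, mediator = sim$mediator),
                       sim$outcome)
    all_instr <- c(instr, sim$truth$mediator_instrument_ids)
    b_fit <- mvmr_fit(mv[mv$variant_id %in% all_instr, ],
                      exposures = c("exposure", "mediator"))
    med <- mediate(total, a_fit,
                   b_fit$estimates[b_fit$estimates$exposure == "mediator", ])
    p <- med$proportion_mediated
    c(est = p$estimate, covered = p$ci_lower <= 0.15 && 0.15 <= p$ci_upper)
  }, numeric(2))
  truth_p <- 0.3 * 0.1 / (0.17 + 0.03)
  expect_equal(truth_p, 0.15)
  expect_lt(abs(mean(res["est", ]) - 0.15), 3 * sd(res["est", ]) / sqrt(reps) + 0.01)
  expect_gt(mean(res["covered", ]), 0.8)   # ~95% nominal, small-sample slack
})
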