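test_that("EGFR recovery fitting recovers the turnover rate", {
  tt <- seq(0, 72, by = 12)
  truth <- 1.5 / 24  # per hour
  ts <- time_series(tt, 1 - exp(-truth * tt))
  fit <- fit_egfr_recovery(ts)
  expect_lt(abs(fit$estimates$kout_EGFR_per_day - 1.5), 1e-5)

  # half-recovery closed form: at t = ln2/k the signal is exactly 0.5
  t_half <- log(2) / truth
  expect_equal(1 - exp(-fit$estimates$kout_EGFR_per_hour * t_half), 0.5,
               tolerance = 1e-5)
  # long-time plateau
  expect_equal(1 - exp(-truth * 1e5), 1)

  flat <- fit_egfr_recovery(time_series(tt, rep(0, length(tt))))
  expect_false(flat$converged)
})

test_that("four-parameter logistic fitting round-trips and flags degeneracy", {
  conc <- c(0.5, 1.5, 5, 15, 50, 150, 500)
  for (truth in list(c(bottom = 0, top = 1, EC50 = 14.49, hill = 1),
                     c(bottom = 0.1, top = 0.9, EC50 = 30, hill = 1.8))) {
    y <- truth[["bottom"]] + (truth[["top"]] - truth[["bottom"]]) /
      (1 + (conc / truth[["EC50"]])^truth[["hill"]])  # decreasing curve
    fit <- fit_4pl(conc, y)
    expect_lt(abs(fit$estimates$EC50 - truth[["EC50"]]) / truth[["EC50"]],
              1e-3)
    expect_lt(abs(fit$estimates$hill - truth[["hill"]]), 1e-2)
    # response at the EC50 equals the midpoint of the asymptotes
    mid <- fit$estimates$bottom +
      (fit$estimates$top - fit$estimates$bottom) / 2
    obs_mid <- truth[["bottom"]] + (truth[["top"]] - truth[["bottom"]]) / 2
    expect_equal(mid, obs_mid, tolerance = 1e-3)
  }
  expect_warning(f0 <- fit_4pl(conc, rep(0.4, 7)), "non-identifiable")
  expect_false(f0$converged)
})

test_that("EGFR-proliferation exponent fitting matches the closed form", {
  kng <- 0.0203
  tt <- c(24, 48, 72, 96, 120)
  # predictor (ODE integration) vs closed-form oracle at several gammas
  for (g in c(0.25, 0.5, 2)) {
    oracle <- tgi_egfr_closed_form(tt, kng, 0.0967, g)
    fit <- fit_gamma_egfr(time_series(tt, oracle), egfr_level = 0.0967,
                          kng = kng)
    expect_lt(abs(fit$estimates$gamma_EGFR - g) / g, 0.01)
  }
  # gamma = 0 gives identically zero inhibition
  expect_equal(tgi_egfr_closed_form(tt, kng, 0.0967, 0), rep(0, 5))
  expect_error(fit_gamma_egfr(time_series(tt, rep(10, 5)), 1, kng),
               "non-identifiable")
})

test_that("folate cytotoxicity mini-model fits and has the algebraic steady state", {
  pem_conc <- molar_to_mass(300, drug_pem(), to = "mg/L")  # 0.1282 mg/L
  # slow enzyme turnover keeps the transient informative, so all three
  # free parameters are identifiable from the five-point TGI course
  fixed <- list(kng = 0.0203, kout_enzyme = 0.05, kout_folate = 0.04,
                EC50_pem = 0.47315, EC50_folate = 1, k1 = 0.01 / 24,
                k2 = 0.08 / 24)
  truth <- list(Emax_pem = 15, gamma_enzyme = 1, Emax_folate = 40)
  tt <- c(24, 48, 72, 96, 120)
  gen <- simulate_folate_mini(tt, c(truth, fixed,
                                    list(Cpem = pem_conc,
                                         drop_control_k1 = FALSE)))
  fit <- fit_folate_cytotoxicity(time_series(tt, gen$TGIPct), pem_conc,
                                 fixed = fixed)
  for (nm in names(truth))
    expect_lt(abs(fit$estimates[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)

  # null effect: Emax_pem = 0 leaves folate at baseline and TGI at zero
  # (k1 = 0 so the natural damage cycle does not masquerade as drug effect)
  fixed0 <- fixed; fixed0$k1 <- 0
  null <- simulate_folate_mini(tt, c(list(Emax_pem = 0, gamma_enzyme = 1,
                                          Emax_folate = 40), fixed0,
                                     list(Cpem = pem_conc,
                                          drop_control_k1 = FALSE)))
  expect_true(all(abs(null$TGIPct) < 1e-8))
  expect_true(all(abs(null$Folate - 1) < 1e-8))

  # steady state under constant exposure: Enzyme_ss = 1/(1 + Emax C/(EC50+C)),
  # Folate_ss = Enzyme_ss^gamma
  long <- simulate_folate_mini(3000, c(truth, fixed,
                                       list(Cpem = pem_conc,
                                            drop_control_k1 = FALSE)))
  ss <- 1 / (1 + truth$Emax_pem * pem_conc / (fixed$EC50_pem + pem_conc))
  expect_equal(long$Enzyme, ss, tolerance = 1e-6)
  expect_equal(long$Folate, ss^truth$gamma_enzyme, tolerance = 1e-6)
})

test_that("apoptosis power-law fitting recovers the exponent", {
  deficit <- c(0.1, 0.2, 0.3, 0.45, 0.6, 0.75, 0.85, 0.95)
  truth_g <- 0.6; truth_a <- 2.5
  fit <- fit_gamma_bim(deficit, truth_a * deficit^truth_g)
  expect_equal(fit$estimates$gamma_bim, truth_g, tolerance = 1e-10)
  expect_equal(fit$estimates$gain, truth_a, tolerance = 1e-10)

  # flat response corresponds to a zero exponent
  flat <- fit_gamma_bim(deficit, rep(3, 8))
  expect_equal(flat$estimates$gamma_bim, 0, tolerance = 1e-10)

  # noisy recovery: 10% log-normal at n = 8 within 15%
  set.seed(4)
  noisy <- truth_a * deficit^truth_g *
    exp(rnorm(8, 0, sqrt(log(1 + 0.1^2))))
  nf <- fit_gamma_bim(deficit, noisy)
  expect_lt(abs(nf$estimates$gamma_bim - truth_g) / truth_g, 0.15)

  expect_warning(fit_gamma_bim(c(deficit, 0), c(truth_a * deficit^truth_g, 1)),
                 "excluded")
})

test_that("control-growth fitting recovers the Simeoni parameters", {
  p <- default_params()
  days <- seq(0, 21, by = 3)
  tr <- simulate_regimen(build_regimen("control"), p, t_end = 21 * 24,
                         dt_out = 12)
  vols <- approx(tr$time_h, tr$X_total, xout = days * 24)$y
  fit <- fit_simeoni_control(time_series(days * 24, vols), p)
  expect_lt(abs(fit$estimates$lambda0 - 0.1032) / 0.1032, 0.01)
  expect_lt(abs(fit$estimates$lambda1 - 51.08) / 51.08, 0.01)
})

test_that("exponential-phase log-slope matches the linear-system oracle", {
  p <- default_params()
  tr <- simulate_regimen(build_regimen("control"), p, t_end = 4 * 24,
                         dt_out = 12)
  slope <- coef(lm(log(tr$X_total) ~ tr$time_h))[2] * 24
  oracle_v <- control_linear_oracle(c(0, 4) * 24, p$tgi$V0,
                                    p$tgi$lambda0 / 24, p$tgi$k1 / 24,
                                    p$tgi$k2 / 24)
  oracle_slope <- diff(log(oracle_v)) / 4
  expect_lt(abs(slope - oracle_slope) / oracle_slope, 0.01)
  # and it sits between the damage-corrected and the raw exponential rate
  expect_gt(slope, p$tgi$lambda0 - p$tgi$k1 - 1e-6)
  expect_lt(slope, p$tgi$lambda0 + 1e-6)
})

test_that("two-compartment PK fitting round-trips and matches NCA", {
  truth <- list(ka = 2, V1 = 0.5, k12 = 0.3, k21 = 0.8, kel = 0.6)
  tt <- c(0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24)
  conc <- pk_conc_2cmt(tt, dose = 10, route = "ip", ka = truth$ka,
                       V1 = truth$V1, k12 = truth$k12, k21 = truth$k21,
                       kel = truth$kel)
  fit <- fit_two_compartment(time_series(tt, conc), dose = 10, route = "ip")
  for (nm in names(truth))
    expect_lt(abs(fit$estimates[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)

  # iv bolus with k12 = 0 is mono-exponential with slope kel
  civ <- pk_conc_2cmt(tt, dose = 10, route = "iv", ka = 1, V1 = 0.5,
                      k12 = 1e-9, k21 = 1, kel = 0.6)
  expect_equal(civ, 10 / 0.5 * exp(-0.6 * tt), tolerance = 1e-6)

  # fitted parameters reproduce the NCA AUCinf on a dense profile
  dense <- pk_conc_2cmt(seq(0.05, 48, by = 0.05), dose = 10, route = "ip",
                        ka = truth$ka, V1 = truth$V1, k12 = truth$k12,
                        k21 = truth$k21, kel = truth$kel)
  n <- nca(time_series(seq(0.05, 48, by = 0.05), dense), dose = 10)
  cl <- fit$estimates$V1 * fit$estimates$kel
  expect_lt(abs(n$AUCinf - 10 / cl) / (10 / cl), 0.02)
})

test_that("non-compartmental analysis matches analytic exposures", {
  tt <- seq(0, 30, by = 0.05)
  k <- 0.4; c0 <- 8
  n <- nca(time_series(tt, c0 * exp(-k * tt)), dose = 1)
  expect_lt(abs(n$AUCinf - c0 / k) / (c0 / k), 0.01)
  expect_lt(abs(n$t_half - log(2) / k) / (log(2) / k), 0.01)
  expect_error(nca(time_series(1, 5)), "3 points")

  # two-compartment closed form: AUCinf = dose / (V1 kel)
  conc <- pk_conc_2cmt(seq(0.02, 60, by = 0.02), dose = 5, route = "ip",
                       ka = 3, V1 = 0.2, k12 = 0.4, k21 = 0.9, kel = 0.7)
  n2 <- nca(time_series(seq(0.02, 60, by = 0.02), conc), dose = 5)
  expect_lt(abs(n2$AUCinf - 5 / (0.2 * 0.7)) / (5 / (0.2 * 0.7)), 0.01)

  # AUClast invariant to interpolated points on log-linear segments
  sparse_t <- c(0.25, 0.5, 1, 2, 4, 8, 12)
  sparse <- c0 * exp(-k * sparse_t)
  mid_t <- sort(c(sparse_t, sqrt(sparse_t[-1] * sparse_t[-7])))
  a1 <- nca(time_series(sparse_t, c0 * exp(-k * sparse_t)))$AUClast
  a2 <- nca(time_series(mid_t, c0 * exp(-k * mid_t)))$AUClast
  expect_lt(abs(a1 - a2) / a1, 0.001)
})

test_that("the DDI rule applies the closed bioequivalence window", {
  tt <- seq(0.1, 24, by = 0.1)
  base <- nca(time_series(tt, 5 * exp(-0.3 * tt)), dose = 1)
  expect_true(ddi_assessment(base, base)$no_ddi)
  expect_equal(unname(ddi_assessment(base, base)$ratios["AUCinf"]), 1)

  up <- nca(time_series(tt, 1.31 * 5 * exp(-0.3 * tt)), dose = 1)
  res <- ddi_assessment(up, base)
  expect_false(res$no_ddi)
  expect_equal(unname(res$ratios[["AUClast"]]), 1.31, tolerance = 1e-9)

  edge <- nca(time_series(tt, 1.25 * 5 * exp(-0.3 * tt)), dose = 1)
  expect_true(ddi_assessment(edge, base)$no_ddi)  # boundary is inside
})

test_that("optimiser multi-start never returns a worse fit than the best start", {
  # quadratic residual with a unique optimum: all starts converge there
  resid <- function(th) c(th[["a"]] - 3, th[["b"]] - 0.5)
  fit <- multistart_fit(resid, c(a = 1, b = 1))
  expect_lt(fit$objective, 1e-12)
  expect_true(fit$converged)
})
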