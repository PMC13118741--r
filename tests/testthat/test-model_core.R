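test_that("plasma concentrations follow the compartment/volume definitions", {
  p <- default_params()
  y <- initial_state(200)
  expect_equal(unname(plasma_concentrations(y, p$pem_pk, p$osi_pk)),
               c(0, 0))
  y["Xpem_1"] <- 1
  cc <- plasma_concentrations(y, pem_pk_params(V1 = 0.1), p$osi_pk)
  expect_equal(unname(cc["Cpem"]), 10)  # 1 mg/kg over 0.1 L/kg
  y["Xosi_1"] <- 2
  cc <- plasma_concentrations(y, p$pem_pk, p$osi_pk)
  expect_equal(unname(cc["Cosi"]),
               2 / (p$osi_pk$V1 / p$osi_pk$Fa) * 1000)
  y["Xpem_1"] <- NaN
  expect_error(plasma_concentrations(y, p$pem_pk, p$osi_pk), "Xpem_1")
})

test_that("instant absorption limit reproduces the analytic bolus Cmax", {
  # ka -> infinity: the first output instant after the dose sees dose/V1
  p <- default_params(pem_pk = pem_pk_params(ka = 5000))
  reg <- build_regimen("PEM", n_cycles = 1)
  reg <- truncate_regimen(reg, 1)  # single dose at t = 0
  tr <- simulate_regimen(reg, p, t_end = 2, dt_out = 0.01)
  cmax <- max(tr$Cpem)
  expect_lt(abs(cmax - 35 / p$pem_pk$V1) / (35 / p$pem_pk$V1), 0.02)
})

test_that("drug-free baseline is a fixed point of the turnover modules", {
  pvec <- param_vector(default_params())
  y <- initial_state(200)
  d <- rhs(0, y, pvec)[[1]]
  expect_equal(unname(d[c("Enzyme", "Folate", "EGFR")]), c(0, 0, 0))
  # and stays stationary over 1000 h of integration; the natural damage
  # cycle is switched off so no feedback acts on EGFR synthesis
  p_nodmg <- default_params(tgi = tgi_params(k1 = 1e-12))
  tr <- simulate_regimen(build_regimen("control"), p_nodmg,
                         t_end = 1000, dt_out = 50)
  expect_lt(max(abs(tr$Enzyme - 1)), 1e-6)
  expect_lt(max(abs(tr$Folate - 1)), 1e-6)
  expect_lt(max(abs(tr$EGFR - 1)), 1e-6)
})

test_that("half-maximal inhibitor concentration gives a half-maximal loss term", {
  p <- default_params(egfr = egfr_pd_params(gamma_osi = 1))
  pvec <- param_vector(p)
  y <- initial_state(200)
  # hold Xosi_1 so that Cosi equals EC50
  y["Xosi_1"] <- p$egfr$EC50_osi / 1000 * (p$osi_pk$V1 / p$osi_pk$Fa)
  d <- rhs(0, y, pvec)[[1]]
  kout_h <- p$egfr$kout_EGFR / 24
  expect_equal(unname(d[["EGFR"]]),
               kout_h - kout_h * (1 + p$egfr$Imax_osi / 2),
               tolerance = 1e-10)
})

test_that("EGFR at baseline leaves the damaged-cell transit unamplified", {
  pvec <- param_vector(default_params())
  y <- initial_state(200)
  y["X2"] <- 50
  d <- rhs(0, y, pvec)[[1]]
  k2_h <- pvec[["k2"]]
  # X2 -> X3 flux must be exactly k2 * X2 (bim multiplier 1)
  expect_equal(unname(d[["X3"]]), k2_h * 50, tolerance = 1e-12)
})

test_that("compiled and reference right-hand sides agree", {
  pvec <- param_vector(default_params())
  set.seed(99)
  for (i in 1:20) {
    y <- initial_state(200)
    y[1:6] <- runif(6, 0, 5)
    y["Enzyme"] <- runif(1, 0, 1.2); y["Folate"] <- runif(1, 0, 1.2)
    y["EGFR"] <- runif(1, 0, 2.5)
    y["X1"] <- runif(1, 10, 500); y["X2"] <- runif(1, 0, 200)
    y["X3"] <- runif(1, 0, 100); y["X4"] <- runif(1, 0, 100)
    reg <- build_regimen("concurrent", n_cycles = 1)
    r_r <- rhs(0, y, pvec)[[1]]
    # evaluate the compiled side through a zero-length integration step
    tr <- deSolve::ode(y, c(0, 1e-6), func = "pemosi_derivs",
                       initfunc = "pemosi_init", dllname = "pemosi",
                       parms = pvec, nout = 1)
    d_c <- (tr[2, 1 + seq_along(y)] - y) / 1e-6
    expect_equal(unname(d_c), unname(r_r), tolerance = 1e-4)
  }
  # full-trajectory agreement (flux symmetry and all terms, by construction)
  reg <- build_regimen("concurrent", n_cycles = 1)
  t1 <- simulate_regimen(reg, default_params(), t_end = 168,
                         use_compiled = TRUE)
  t2 <- simulate_regimen(reg, default_params(), t_end = 168,
                         use_compiled = FALSE)
  expect_equal(t1$X_total, t2$X_total, tolerance = 1e-6)
})

test_that("regimen construction matches the xenograft dosing design", {
  r <- build_regimen("sequential", interval_h = 48, n_cycles = 1)
  osi <- r[r$drug == "OSI", ]
  expect_equal(min(osi$time_h), 48)
  pem <- r[r$drug == "PEM", ]
  expect_equal(pem$time_h, c(0, 4, 8, 24, 28, 32))
  expect_true(all(pem$amount_mg_per_kg == 35))

  rc <- build_regimen("concurrent", n_cycles = 1)
  expect_equal(min(rc$time_h[rc$drug == "OSI"]), 0)

  expect_equal(nrow(build_regimen("control")), 0)
  expect_error(build_regimen("tid"))

  r3 <- build_regimen("sequential", interval_h = 48, n_cycles = 3)
  expect_false(is.unsorted(r3$time_h))
  # second cycle repeats the pattern one week later
  expect_true(all((r3$time_h[r3$drug == "PEM"] %% 168) %in%
                    c(0, 4, 8, 24, 28, 32)))
})

test_that("drug-free growth matches the linear four-compartment oracle", {
  p <- default_params()
  t_days <- c(1, 2, 3, 4, 5)  # exponential regime, X well below lambda1/lambda0
  tr <- simulate_regimen(build_regimen("control"), p, t_end = 5 * 24,
                         dt_out = 24)
  oracle <- control_linear_oracle(t_days * 24, p$tgi$V0,
                                  p$tgi$lambda0 / 24, p$tgi$k1 / 24,
                                  p$tgi$k2 / 24)
  sim <- tr$X_total[match(t_days * 24, tr$time_h)]
  expect_lt(max(abs(sim / oracle - 1)), 0.01)
})

test_that("mass balance holds along treated trajectories", {
  p <- default_params()
  for (strategy in c("control", "sequential", "concurrent")) {
    reg <- if (strategy == "sequential")
      build_regimen("sequential", interval_h = 48) else build_regimen(strategy)
    tr <- simulate_regimen(reg, p)
    resid <- abs(tr$X_total + tr$CumDead - p$tgi$V0 - tr$CumGrowth) /
      pmax(tr$X_total, 1e-6)
    expect_lt(max(resid), 1e-4)
    expect_true(all(diff(tr$CumDead) >= -1e-9))  # cumulative dead monotone
    expect_true(all(tr[STATE_NAMES] >= -1e-9 * max(tr$X_total)))
  }
})

test_that("null drug effects reduce treated trajectories to control", {
  p <- default_params(folate = folate_pd_params(Emax_pem = 1e-12),
                      egfr = egfr_pd_params(Imax_osi = 0))
  # Emax_pem = 0 is excluded by the Hill driver only through its gain; use
  # an exact zero via modify? constructor requires >= 0; use 0 directly:
  p$folate$Emax_pem <- 0
  reg <- build_regimen("concurrent")
  treated <- simulate_regimen(reg, p)
  ctrl <- simulate_regimen(build_regimen("control"), p,
                           t_end = max(treated$time_h))
  idx <- match(ctrl$time_h, treated$time_h)
  # event restarts change the step sequence, so agreement is to solver
  # tolerance rather than bit-for-bit
  expect_equal(treated$X_total[idx], ctrl$X_total, tolerance = 1e-6)
  expect_equal(treated$EGFR[idx], ctrl$EGFR, tolerance = 1e-6)
})

test_that("derived metrics implement the damaged/proliferating fractions and TGI", {
  p <- default_params()
  tr <- simulate_regimen(build_regimen("control"), p, t_end = 48)
  m <- derived_metrics(tr, tr)
  expect_true(all(abs(m$TGIPct) < 1e-12))  # identical arms

  y <- tr[1, ]
  expect_equal(y$DamagedPct, 0)
  expect_equal(y$X1Pct, 100)

  fake <- tr
  fake$X1 <- fake$X2 <- fake$X3 <- fake$X4 <- 25
  fake$X_total <- 100
  fake$DamagedPct <- (75 / 100) * 100
  expect_equal(fake$DamagedPct[1], 75)

  bad <- tr[-1, ]
  expect_error(derived_metrics(tr, bad), "grid")
})
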