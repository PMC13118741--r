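#' Tagged time series
#'
#' Light container for calibration inputs: times in hours, values in the
#' unit named by `unit`, optional per-point SDs.
#'
#' @param times h
#' @param values measurements
#' @param unit unit tag (e.g. `"normalized"`, `"TGI%"`, `"mg/L"`, `"mm3"`)
#' @param sd optional per-point SD
#' @return a `pemosi_ts`
#' @export
time_series <- function(times, values, unit = "", sd = NULL) {
  stopifnot(length(times) == length(values), all(is.finite(values)),
            !is.unsorted(times))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit, sd = sd),
            class = "pemosi_ts")
}

fit_result <- function(estimates, objective, converged = TRUE,
                       n_iter = NA_integer_, se = NULL) {
  structure(list(estimates = estimates, se = se, objective = objective,
                 converged = converged, n_iter = n_iter),
            class = "pemosi_fit")
}

#' @export
print.pemosi_fit <- function(x, ...) {
  cat("pemosi fit (", if (x$converged) "converged" else "NOT converged",
      "), RSS = ", format(x$objective, digits = 6), "\n", sep = "")
  print(unlist(x$estimates))
  invisible(x)
}

## Bounded multi-start Levenberg-Marquardt on log-parameters.
## residual_fn(theta) takes the natural-scale named parameter vector.
multistart_fit <- function(residual_fn, start, lower = NULL, upper = NULL,
                           scales = c(0.2, 0.5, 1, 2, 5)) {
  start <- unlist(start)
  best <- NULL
  for (s in scales) {
    th0 <- log(start * s)
    res <- try(minpack.lm::nls.lm(
      par = th0,
      fn = function(lth) residual_fn(stats::setNames(exp(lth), names(start))),
      lower = if (is.null(lower)) rep(-Inf, length(th0)) else log(lower),
      upper = if (is.null(upper)) rep(Inf, length(th0)) else log(upper),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  est <- stats::setNames(exp(best$par), names(start))
  se <- tryCatch({
    cv <- vcov(best)
    sqrt(diag(cv)) * est  # delta method from log scale
  }, error = function(e) NULL)
  fit_result(as.list(est), objective = best$deviance,
             converged = best$info %in% 1:4, n_iter = best$niter, se = se)
}

#' Fit the EGFR turnover rate from a signal-recovery time course
#'
#' After washout of an irreversible inhibitor the normalised EGFR signal
#' recovers from 0 by resynthesis only, following
#' `EGFR(t) = 1 - exp(-kout * t)`.
#'
#' @param data a [time_series()] of normalised EGFR signal, first point at
#'   t = 0 h, plateau 1
#' @return `pemosi_fit` with `kout_EGFR_per_day` (and per hour)
#' @export
fit_egfr_recovery <- function(data) {
  stopifnot(inherits(data, "pemosi_ts"))
  if (all(data$values == 0))
    return(fit_result(list(kout_EGFR_per_day = NA_real_), NA_real_,
                      converged = FALSE))
  rss <- function(logk) {
    k <- exp(logk)
    sum((data$values - (1 - exp(-k * data$times)))^2)
  }
  opt <- stats::optimize(rss, interval = log(c(1e-5, 10)), tol = 1e-12)
  k_h <- exp(opt$minimum)
  fit_result(list(kout_EGFR_per_day = k_h * 24, kout_EGFR_per_hour = k_h),
             objective = opt$objective)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' `y = bottom + (top - bottom) / (1 + (EC50 / x)^hill)`; EC50 is reported
#' in the units of `conc`.
#'
#' @param conc concentration series (must span the EC50; at least 5 levels)
#' @param response response series
#' @return `pemosi_fit` with `bottom`, `top`, `EC50`, `hill`
#' @export
fit_4pl <- function(conc, response) {
  stopifnot(length(conc) == length(response), length(unique(conc)) >= 5,
            all(conc > 0))
  if (diff(range(response)) < 1e-12 * max(abs(response), 1)) {
    warning("constant response: EC50 non-identifiable")
    return(fit_result(list(bottom = response[1], top = response[1],
                           EC50 = NA_real_, hill = NA_real_),
                      objective = 0, converged = FALSE))
  }
  lo <- min(response); hi <- max(response)
  increasing <- stats::cor(log(conc), response) > 0
  model <- function(th) {
    # high-concentration asymptote th["asym_hi"], response at conc -> 0 is
    # asym_hi -/+ span depending on direction
    th[["asym_lo"]] + (th[["asym_hi"]] - th[["asym_lo"]]) /
      (1 + (th[["EC50"]] / conc)^th[["hill"]])
  }
  best <- NULL
  for (ec_start in exp(seq(log(min(conc)), log(max(conc)),
                           length.out = 5))) {
    th0 <- c(asym_lo = if (increasing) lo else hi,
             asym_hi = if (increasing) hi else lo,
             EC50 = ec_start, hill = 1)
    res <- try(minpack.lm::nls.lm(
      par = th0, fn = function(th) response - model(th),
      lower = c(-Inf, -Inf, min(conc) / 1e3, 0.05),
      upper = c(Inf, Inf, max(conc) * 1e3, 20),
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("4PL fit failed from all starts")
  th <- best$par
  est <- list(bottom = min(th[["asym_lo"]], th[["asym_hi"]]),
              top = max(th[["asym_lo"]], th[["asym_hi"]]),
              EC50 = th[["EC50"]], hill = th[["hill"]])
  fit_result(est, best$deviance, best$info %in% 1:4, best$niter)
}

#' Fit the EGFR-to-proliferation exponent from an in vitro TGI time course
#'
#' Exposure to a fixed inhibitor concentration holds the EGFR signal at a
#' constant fraction of baseline; treated cells grow as
#' `dX1/dt = kng * X1 * EGFR^gamma` against untreated `dX2/dt = kng * X2`,
#' and `TGI% = (1 - X1/X2) * 100`. The predictor integrates the two ODEs.
#'
#' @param tgi a [time_series()] of TGI% values (times in h)
#' @param egfr_level fixed EGFR fraction of baseline, in (0, 1)
#' @param kng in vitro exponential growth rate (1/h)
#' @return `pemosi_fit` with `gamma_EGFR`
#' @export
fit_gamma_egfr <- function(tgi, egfr_level, kng) {
  stopifnot(inherits(tgi, "pemosi_ts"), egfr_level > 0, kng > 0)
  if (egfr_level >= 1) stop("egfr_level must be < 1: gamma non-identifiable")
  predict_tgi <- function(gamma) {
    de <- function(t, y, p) list(c(kng * y[1] * egfr_level^gamma, kng * y[2]))
    out <- deSolve::ode(c(1, 1), sort(unique(c(0, tgi$times))), de, NULL,
                        rtol = 1e-10, atol = 1e-12)
    keep <- match(tgi$times, out[, 1])
    (1 - out[keep, 2] / out[keep, 3]) * 100
  }
  rss <- function(loggamma) sum((tgi$values - predict_tgi(exp(loggamma)))^2)
  opt <- stats::optimize(rss, interval = log(c(1e-4, 50)))
  fit_result(list(gamma_EGFR = exp(opt$minimum)), objective = opt$objective)
}

## In vitro folate-cytotoxicity mini-model: treated cells X1-X4 under a
## constant PEM concentration, untreated control X5, with the folate
## cascade driving the X1 -> X2 damage transition. All rates per hour.
folate_mini_rhs <- function(t, y, p) {
  stim <- 1 + p$Emax_pem * p$Cpem / (p$EC50_pem + p$Cpem)
  dEnz <- p$kout_enzyme - p$kout_enzyme * y[["Enzyme"]] * stim
  dFol <- max(0, y[["Enzyme"]])^p$gamma_enzyme * p$kout_folate -
    p$kout_folate * y[["Folate"]]
  D <- max(0, 1 - y[["Folate"]])
  kill <- p$k1 * (1 + p$Emax_folate * D / (p$EC50_folate + D))
  ctrl_loss <- if (p$drop_control_k1) 0 else p$k1
  list(c(Enzyme = dEnz, Folate = dFol,
         X1 = p$kng * y[["X1"]] - kill * y[["X1"]],
         X2 = kill * y[["X1"]] - p$k2 * y[["X2"]],
         X3 = p$k2 * y[["X2"]] - p$k2 * y[["X3"]],
         X4 = p$k2 * y[["X3"]] - p$k2 * y[["X4"]],
         X5 = p$kng * y[["X5"]] - ctrl_loss * y[["X5"]]))
}

simulate_folate_mini <- function(times, pars) {
  y0 <- c(Enzyme = 1, Folate = 1, X1 = 1, X2 = 0, X3 = 0, X4 = 0, X5 = 1)
  out <- deSolve::ode(y0, sort(unique(c(0, times))), folate_mini_rhs, pars,
                      rtol = 1e-9, atol = 1e-11)
  out <- as.data.frame(out)
  keep <- match(times, out$time)
  tot <- out$X1 + out$X2 + out$X3 + out$X4
  data.frame(time = times, TGIPct = (1 - tot[keep] / out$X5[keep]) * 100,
             Enzyme = out$Enzyme[keep], Folate = out$Folate[keep])
}

#' Fit the folate-cytotoxicity block from an in vitro TGI time course
#'
#' Fits (`Emax_pem`, `gamma_enzyme`, `Emax_folate`) of the five-compartment
#' mini-model (treated X1-X4 against control X5) to TGI% measured under a
#' constant pemetrexed exposure. The remaining rates are supplied as fixed.
#' By default the control compartment carries the same natural loss `-k1*X5`
#' as the treated proliferating pool; `drop_control_k1 = TRUE` removes it.
#'
#' @param tgi a [time_series()] of TGI% (times in h)
#' @param pem_conc constant medium exposure expressed on the plasma potency
#'   scale (mg/L)
#' @param fixed named list with `kng`, `kout_enzyme`, `kout_folate`,
#'   `EC50_pem`, `EC50_folate`, `k1`, `k2` (all per hour)
#' @param free named list of start values for the free parameters (defaults
#'   `Emax_pem = 2`, `gamma_enzyme = 1`, `Emax_folate = 20`); fix a
#'   parameter by omitting it from `free` and adding it to `fixed`
#' @param drop_control_k1 drop the control loss term
#' @return `pemosi_fit`
#' @export
fit_folate_cytotoxicity <- function(tgi, pem_conc, fixed,
                                    free = list(Emax_pem = 2,
                                                gamma_enzyme = 1,
                                                Emax_folate = 20),
                                    drop_control_k1 = FALSE) {
  stopifnot(inherits(tgi, "pemosi_ts"), pem_conc > 0)
  need <- c("kng", "kout_enzyme", "kout_folate", "EC50_pem", "EC50_folate",
            "k1", "k2")
  missing_fixed <- setdiff(setdiff(need, names(free)), names(fixed))
  if (length(missing_fixed))
    stop("missing fixed parameters: ", paste(missing_fixed, collapse = ", "))
  if (length(tgi$times) < length(free))
    stop("fewer time points than free parameters")
  resid <- function(th) {
    pars <- c(as.list(th), fixed, list(Cpem = pem_conc,
                                       drop_control_k1 = drop_control_k1))
    tgi$values - simulate_folate_mini(tgi$times, pars)$TGIPct
  }
  multistart_fit(resid, free, lower = rep(1e-6, length(free)),
                 upper = rep(1e4, length(free)))
}

#' Fit the apoptosis exponent from EGFR-deficit vs apoptosis-marker data
#'
#' Fits the power law `clparp = a * deficit^gamma` by log-log linear
#' regression; non-positive points are excluded with a warning.
#'
#' @param egfr_deficit EGFR deficit `1 - EGFR`, in (0, 1]
#' @param clparp apoptosis marker (cleaved PARP) levels
#' @return `pemosi_fit` with `gain` and `gamma_bim`
#' @export
fit_gamma_bim <- function(egfr_deficit, clparp) {
  stopifnot(length(egfr_deficit) == length(clparp))
  ok <- egfr_deficit > 0 & clparp > 0
  if (any(!ok)) warning(sum(!ok), " non-positive point(s) excluded")
  if (sum(ok) < 2) stop("not enough positive points for a power-law fit")
  fit <- stats::lm(log(clparp[ok]) ~ log(egfr_deficit[ok]))
  se <- suppressWarnings(summary(fit)$coefficients[, 2])
  fit_result(list(gain = exp(unname(stats::coef(fit)[1])),
                  gamma_bim = unname(stats::coef(fit)[2])),
             objective = sum(stats::residuals(fit)^2), se = se)
}

#' Fit unperturbed Simeoni growth parameters from control tumour volumes
#'
#' Simulates the drug-free four-compartment model (with the natural
#' k1/k2 damage cycle fixed) and fits the exponential and linear growth
#' rates to observed volumes.
#'
#' @param volumes a [time_series()] of tumour volumes (mm3, times in h)
#' @param params a `pemosi_params` supplying V0, psi, k1 and k2
#' @param start optional start values (`lambda0` 1/day, `lambda1` mm3/day)
#' @return `pemosi_fit` with `lambda0` (1/day) and `lambda1` (mm3/day)
#' @export
fit_simeoni_control <- function(volumes, params = default_params(),
                                start = list(lambda0 = 0.1, lambda1 = 50)) {
  stopifnot(inherits(volumes, "pemosi_ts"), length(volumes$times) >= 5)
  ctrl <- build_regimen("control")
  predict_v <- function(th) {
    p <- params
    p$tgi$lambda0 <- th[["lambda0"]]; p$tgi$lambda1 <- th[["lambda1"]]
    traj <- simulate_regimen(ctrl, p, t_end = max(volumes$times),
                             dt_out = max(volumes$times) / 50)
    stats::approx(traj$time_h, traj$X_total, xout = volumes$times)$y
  }
  resid <- function(th) volumes$values - predict_v(th)
  multistart_fit(resid, start, lower = c(1e-4, 1e-2),
                 upper = c(10, 1e4), scales = c(0.5, 1, 2))
}

## Analytic two-compartment concentration profile with first-order
## absorption (route "ip"/"oral", full dose absorbed) or iv bolus.
## Returns amount_X1(t) / V1.
pk_conc_2cmt <- function(times, dose, route, ka, V1, k12, k21, kel) {
  if (route == "iv") {
    A <- matrix(c(-(k12 + kel), k21, k12, -k21), 2, 2, byrow = TRUE)
    y0 <- c(dose, 0); idx <- 1
  } else {
    A <- matrix(c(-ka, 0, 0,
                  ka, -(k12 + kel), k21,
                  0, k12, -k21), 3, 3, byrow = TRUE)
    y0 <- c(dose, 0, 0); idx <- 2
  }
  E <- eigen(A)
  co <- solve(E$vectors, y0)
  x1 <- vapply(times, function(t)
    Re(sum(E$vectors[idx, ] * co * exp(E$values * t))), numeric(1))
  pmax(x1, 0) / V1
}

#' Fit a two-compartment PK model to a concentration-time profile
#'
#' Least squares on log concentrations (equivalent to 1/y^2 weighting).
#' For extravascular routes the full dose is treated as absorbed, so the
#' fitted `V1` is the apparent central volume (V/F) and `ka` the apparent
#' absorption rate. For `route = "iv"` no absorption parameters are fitted.
#'
#' @param conc a [time_series()] of plasma concentrations
#' @param dose administered dose (mg/kg)
#' @param route `"iv"`, `"ip"` or `"oral"`
#' @return `pemosi_fit` with `ka` (unless iv), `V1`, `k12`, `k21`, `kel`
#' @export
fit_two_compartment <- function(conc, dose, route = c("ip", "oral", "iv")) {
  route <- match.arg(route)
  stopifnot(inherits(conc, "pemosi_ts"), length(conc$times) >= 6, dose > 0)
  pos <- conc$values > 0
  if (sum(pos) < 6) stop("need at least 6 positive concentrations")
  ts <- conc$times[pos]; cs <- conc$values[pos]
  if (diff(range(log(cs))) < 0.1) stop("flat profile: non-identifiable")
  ## heuristics: terminal slope and back-extrapolated volume
  nt <- length(ts)
  tail_i <- max(1, nt - 2):nt
  lz <- max(1e-4, -unname(stats::coef(stats::lm(log(cs[tail_i]) ~ ts[tail_i]))[2]))
  v0 <- dose / max(cs)
  start <- c(ka = 5 * lz, V1 = v0, k12 = lz / 2, k21 = lz, kel = 2 * lz)
  if (route == "iv") start <- start[-1]
  resid <- function(th) {
    pr <- pk_conc_2cmt(ts, dose, route,
                       ka = if (route == "iv") 1 else th[["ka"]],
                       V1 = th[["V1"]], k12 = th[["k12"]],
                       k21 = th[["k21"]], kel = th[["kel"]])
    log(cs) - log(pmax(pr, 1e-300))
  }
  multistart_fit(resid, start, lower = rep(1e-6, length(start)),
                 upper = rep(1e4, length(start)))
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Linear-up/log-down trapezoidal AUC to the last positive concentration;
#' the terminal slope `lambda_z` is estimated by log-linear regression on
#' the terminal points (3 up to 8, chosen by adjusted R-squared);
#' `AUCinf = AUClast + Clast / lambda_z`, `t_half = ln 2 / lambda_z`.
#'
#' @param conc a [time_series()] of plasma concentrations
#' @param dose administered dose (used only for reporting)
#' @return an `nca_result`: `Cmax`, `Tmax`, `AUClast`, `AUCinf`, `t_half`,
#'   `lambda_z` (AUCinf and t_half are NA, with a warning, when no positive
#'   terminal slope exists)
#' @export
nca <- function(conc, dose = NA) {
  stopifnot(inherits(conc, "pemosi_ts"))
  t <- conc$times; y <- conc$values
  if (length(t) < 3) stop("NCA needs at least 3 points")
  auc <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    if (dt == 0) next
    if (y[i + 1] < y[i] && y[i + 1] > 0 && y[i] > 0) {
      auc <- auc + dt * (y[i] - y[i + 1]) / log(y[i] / y[i + 1])
    } else {
      auc <- auc + dt * (y[i] + y[i + 1]) / 2
    }
  }
  imax <- which.max(y)
  ## terminal slope after Tmax
  cand <- which(t > t[imax] & y > 0)
  lz <- NA_real_; best_r2 <- -Inf
  if (length(cand) >= 3) {
    for (n in 3:min(8, length(cand))) {
      idx <- utils::tail(cand, n)
      f <- stats::lm(log(y[idx]) ~ t[idx])
      sl <- -unname(stats::coef(f)[2])
      ly <- log(y[idx])
      r2 <- 1 - sum(stats::residuals(f)^2) / sum((ly - mean(ly))^2)
      adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
      if (sl > 0 && adj > best_r2) { best_r2 <- adj; lz <- sl }
    }
  }
  clast <- y[max(which(y > 0))]
  if (is.na(lz) || lz <= 0) {
    warning("non-positive terminal slope: AUCinf undefined")
    aucinf <- NA_real_; thalf <- NA_real_; lz <- NA_real_
  } else {
    aucinf <- auc + clast / lz
    thalf <- log(2) / lz
  }
  structure(list(Cmax = max(y), Tmax = t[imax], AUClast = auc,
                 AUCinf = aucinf, t_half = thalf, lambda_z = lz,
                 dose = dose),
            class = "nca_result")
}

#' Drug-drug interaction assessment by the bioequivalence window
#'
#' Ratios combination/monotherapy for Cmax and AUC; the interaction is
#' called absent when every ratio lies in the closed interval
#' \[0.8, 1.25\].
#'
#' @param combo,mono `nca_result` objects for the combination and
#'   monotherapy arms
#' @return list with `ratios` (named vector) and `no_ddi` flag
#' @export
ddi_assessment <- function(combo, mono) {
  stopifnot(inherits(combo, "nca_result"), inherits(mono, "nca_result"))
  pars <- c("Cmax", "AUClast", "AUCinf")
  ratios <- vapply(pars, function(p) {
    m <- mono[[p]]; cb <- combo[[p]]
    if (is.na(m) || is.na(cb)) return(NA_real_)
    if (m == 0) stop("zero denominator for ", p)
    cb / m
  }, numeric(1))
  ok <- ratios[!is.na(ratios)]
  eps <- 1e-9  # boundary-inclusive up to floating error
  list(ratios = ratios, no_ddi = all(ok >= 0.8 - eps & ok <= 1.25 + eps))
}
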