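STATE_NAMES <- c("Xpem_a", "Xpem_1", "Xpem_2", "Xosi_a", "Xosi_1", "Xosi_2",
                 "Enzyme", "Folate", "EGFR", "X1", "X2", "X3", "X4",
                 "CumDead", "CumGrowth")

#' Initial system state
#'
#' Drug-free homeostatic baseline: normalised enzyme, folate and EGFR at 1,
#' all tumour volume in the proliferating compartment.
#'
#' @param V0 initial tumour volume (mm3)
#' @return named numeric state vector
#' @export
initial_state <- function(V0 = 200) {
  y <- stats::setNames(numeric(length(STATE_NAMES)), STATE_NAMES)
  y["Enzyme"] <- 1; y["Folate"] <- 1; y["EGFR"] <- 1
  y["X1"] <- V0
  y
}

#' Plasma concentrations from a system state
#'
#' PEM: `Xpem_1 / V1_pem` in mg/L. OSI: `Xosi_1 / (V1_osi / Fa_osi)` in
#' ug/L (the oral parameters are on a V/F basis), matching the scales on
#' which the plasma potencies are expressed.
#'
#' @param state named state vector (or a trajectory row)
#' @param pem,osi PK parameter blocks
#' @return named vector `c(Cpem = mg/L, Cosi = ug/L)`
#' @export
plasma_concentrations <- function(state, pem, osi) {
  bad <- !is.finite(unlist(state[c("Xpem_1", "Xosi_1")]))
  if (any(bad))
    stop("non-finite state component: ",
         paste(c("Xpem_1", "Xosi_1")[bad], collapse = ", "))
  c(Cpem = max(0, state[["Xpem_1"]]) / pem$V1,
    Cosi = max(0, state[["Xosi_1"]]) / (osi$V1 / osi$Fa) * 1000)
}

safe_pow <- function(x, g) ifelse(x > 0, x^g, ifelse(g == 0, 1, 0))

simeoni_switch_r <- function(r, psi) {
  if (r <= 0) return(1)
  if (r <= 1) (1 + r^psi)^(1 / psi) else r * (1 + r^(-psi))^(1 / psi)
}

#' Model right-hand side (reference R implementation)
#'
#' Plain-R mirror of the compiled derivative function used by
#' [simulate_regimen()]; exposed for transparency and for regression tests
#' against the compiled code. Hill drivers clip negative states to zero;
#' raw states are left untouched.
#'
#' @param t time (h)
#' @param y named state vector
#' @param pvec parameter vector from [param_vector()]
#' @return `list(dy)` in deSolve convention
#' @export
rhs <- function(t, y, pvec) {
  p <- as.list(pvec)
  pos <- function(x) max(0, x)
  Cpem <- pos(y[["Xpem_1"]]) / p$V1_pem
  Cosi <- pos(y[["Xosi_1"]]) / (p$V1_osi / p$Fa_osi) * 1000

  dy <- stats::setNames(numeric(length(STATE_NAMES)), STATE_NAMES)
  dy["Xpem_a"] <- -p$ka_pem * y[["Xpem_a"]]
  dy["Xpem_1"] <- p$ka_pem * y[["Xpem_a"]] - p$k12_pem * y[["Xpem_1"]] +
    p$k21_pem * y[["Xpem_2"]] - p$kel_pem * y[["Xpem_1"]]
  dy["Xpem_2"] <- p$k12_pem * y[["Xpem_1"]] - p$k21_pem * y[["Xpem_2"]]

  dy["Xosi_a"] <- -p$Fa_osi * p$ka_osi * y[["Xosi_a"]]
  dy["Xosi_1"] <- p$Fa_osi * p$ka_osi * y[["Xosi_a"]] -
    p$k12_osi * y[["Xosi_1"]] + p$k21_osi * y[["Xosi_2"]] -
    p$kel_osi * y[["Xosi_1"]]
  dy["Xosi_2"] <- p$k12_osi * y[["Xosi_1"]] - p$k21_osi * y[["Xosi_2"]]

  stim_pem <- 1 + p$Emax_pem * Cpem / (p$EC50_pem + Cpem)
  dy["Enzyme"] <- p$kout_enzyme - p$kout_enzyme * y[["Enzyme"]] * stim_pem
  dy["Folate"] <- safe_pow(pos(y[["Enzyme"]]), p$gamma_enzyme) *
    p$kout_folate - p$kout_folate * y[["Folate"]]

  X1 <- pos(y[["X1"]]); X2 <- pos(y[["X2"]])
  X3 <- pos(y[["X3"]]); X4 <- pos(y[["X4"]])
  X <- X1 + X2 + X3 + X4
  damaged <- if (X > 0) (X2 + X3 + X4) / X else 0
  cg <- safe_pow(Cosi, p$gamma_osi)
  stim_osi <- 1 + p$Imax_osi * cg / (p$EC50_osi^p$gamma_osi + cg)
  dy["EGFR"] <- p$kout_EGFR *
    (1 + p$k_feedback * safe_pow(damaged, p$gamma_feedback)) -
    p$kout_EGFR * y[["EGFR"]] * stim_osi

  EGFR <- pos(y[["EGFR"]])
  growth <- p$lambda0 * X1 * safe_pow(EGFR, p$gamma_EGFR) /
    simeoni_switch_r(p$lambda0 / p$lambda1 * X, p$psi)
  D <- pos(1 - y[["Folate"]])
  dg <- safe_pow(D, p$gamma_folate)
  kill_amp <- 1 + p$Emax_folate * dg / (p$EC50_folate^p$gamma_folate + dg)
  egfr_gate <- if (EGFR < 1) safe_pow(EGFR, p$gamma_G1) else 1
  flux12 <- p$k1 * X1 * kill_amp * egfr_gate
  bim <- 1 + p$kbim * safe_pow(pos(1 - EGFR), p$gamma_bim)
  k2b <- p$k2 * bim

  dy["X1"] <- growth - flux12
  dy["X2"] <- flux12 - k2b * X2
  dy["X3"] <- k2b * X2 - k2b * X3
  dy["X4"] <- k2b * X3 - k2b * X4
  dy["CumDead"] <- k2b * X4
  dy["CumGrowth"] <- growth
  list(dy)
}

regimen_events <- function(regimen, F_pem = 1) {
  if (nrow(regimen) == 0) return(NULL)
  data.frame(
    var = ifelse(regimen$drug == "PEM", "Xpem_a", "Xosi_a"),
    time = regimen$time_h,
    value = regimen$amount_mg_per_kg * ifelse(regimen$drug == "PEM", F_pem, 1),
    method = "add")
}

#' Simulate a dosing regimen
#'
#' Integrates the full PK/PD system with a stiff solver (default `lsoda`
#' with rtol 1e-6, atol 1e-9). Dose events are instantaneous additions to
#' the relevant absorption compartment. The output grid is augmented with
#' all event times so that the trajectory captures every dose.
#'
#' @param regimen a `pemosi_regimen`
#' @param params a `pemosi_params` set
#' @param t_end end of simulation (h)
#' @param dt_out output resolution (h)
#' @param use_compiled use the compiled right-hand side (default) or the R
#'   reference implementation
#' @param rtol,atol solver tolerances
#' @return a `pemosi_trajectory`: data frame with `time_h`, all states and
#'   the derived series `Cpem` (mg/L), `Cosi` (ug/L), `X_total` (mm3),
#'   `DamagedPct` and `X1Pct` (percent), `TotalDead` (mm3)
#' @export
simulate_regimen <- function(regimen, params, t_end = 21 * 24, dt_out = 2,
                             use_compiled = TRUE, rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(regimen, "pemosi_regimen"),
            inherits(params, "pemosi_params"))
  if (nrow(regimen) > 0 && any(regimen$time_h > t_end))
    stop("regimen contains events after t_end")
  pvec <- param_vector(params)
  y0 <- initial_state(params$tgi$V0)
  times <- sort(unique(c(seq(0, t_end, by = dt_out), t_end,
                         regimen$time_h)))
  ev <- regimen_events(regimen, F_pem = params$pem_pk$F)
  args <- list(y = y0, times = times, parms = pvec,
               rtol = rtol, atol = atol)
  if (!is.null(ev)) args$events <- list(data = ev)
  if (use_compiled) {
    args$func <- "pemosi_derivs"; args$initfunc <- "pemosi_init"
    args$dllname <- "pemosi"; args$nout <- 1; args$outnames <- "Xtot"
  } else {
    args$func <- rhs
  }
  out <- try(do.call(deSolve::ode, args), silent = TRUE)
  if (inherits(out, "try-error") || any(!is.finite(out)))
    stop("ODE solver failure for strategy '",
         attr(regimen, "strategy"), "': ", paste(out, collapse = " "))
  traj <- as.data.frame(out)
  names(traj)[1] <- "time_h"
  traj$Cpem <- pmax(0, traj$Xpem_1) / params$pem_pk$V1
  traj$Cosi <- pmax(0, traj$Xosi_1) / (params$osi_pk$V1 / params$osi_pk$Fa) * 1000
  traj$X_total <- traj$X1 + traj$X2 + traj$X3 + traj$X4
  traj$DamagedPct <- ifelse(traj$X_total > 0,
                            (traj$X2 + traj$X3 + traj$X4) / traj$X_total * 100, 0)
  traj$X1Pct <- ifelse(traj$X_total > 0, traj$X1 / traj$X_total * 100, 100)
  traj$TotalDead <- traj$CumDead
  traj$Xtot <- NULL
  structure(traj, regimen = regimen, V0 = params$tgi$V0,
            class = c("pemosi_trajectory", "data.frame"))
}

#' Derived efficacy metrics relative to a paired control trajectory
#'
#' Adds the real-time tumour growth inhibition
#' `TGIPct = (1 - X_treated / X_control) * 100` to the treated trajectory's
#' damaged-fraction and dead-volume series. Both trajectories must share a
#' time grid.
#'
#' @param traj treated `pemosi_trajectory`
#' @param control_traj control trajectory on the same grid
#' @return data frame `time_h`, `X_total`, `DamagedPct`, `X1Pct`,
#'   `TotalDead`, `TGIPct`
#' @export
derived_metrics <- function(traj, control_traj) {
  if (nrow(traj) != nrow(control_traj) ||
      max(abs(traj$time_h - control_traj$time_h)) > 1e-8)
    stop("treated and control trajectories are on different time grids")
  data.frame(time_h = traj$time_h, X_total = traj$X_total,
             DamagedPct = traj$DamagedPct, X1Pct = traj$X1Pct,
             TotalDead = traj$TotalDead,
             TGIPct = (1 - traj$X_total / control_traj$X_total) * 100)
}

#' Export a trajectory to CSV
#' @param traj a `pemosi_trajectory` (or the output of [derived_metrics()])
#' @param path output file
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
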