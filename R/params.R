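#' @useDynLib pemosi
NULL

HOURS_PER_DAY <- 24

#' Pemetrexed two-compartment PK parameters
#'
#' All rates are first order per hour; volumes are apparent central volumes
#' per kg body weight. Pemetrexed is dosed intraperitoneally, for which the
#' bioavailability is fixed at 1.
#'
#' @param ka first-order absorption rate from the injection site (1/h)
#' @param V1 central volume of distribution (L/kg)
#' @param k12,k21 central-peripheral distribution rates (1/h)
#' @param kel elimination rate from the central compartment (1/h)
#' @param F bioavailability fraction (1 for i.p.)
#' @return an object of class `pem_pk_params`
#' @export
pem_pk_params <- function(ka = 6, V1 = 0.15, k12 = 0.05, k21 = 3.0,
                          kel = 1.25, F = 1) {
  p <- list(ka = ka, V1 = V1, k12 = k12, k21 = k21, kel = kel, F = F)
  stopifnot(all(unlist(p[c("ka", "V1", "k12", "k21", "kel")]) > 0),
            F > 0, F <= 1)
  structure(p, class = "pem_pk_params")
}

#' Osimertinib two-compartment PK parameters
#'
#' Oral dosing; `V1` is the apparent central volume on a V/F basis, so the
#' plasma concentration is `Xosi_1 / (V1 / Fa)`, mirroring the convention in
#' which the oral parameters are estimated.
#'
#' @param ka absorption rate (1/h)
#' @param Fa oral bioavailability fraction
#' @param V1 apparent central volume, V/F basis (L/kg)
#' @param k12,k21,kel distribution and elimination rates (1/h)
#' @return an object of class `osi_pk_params`
#' @export
osi_pk_params <- function(ka = 0.8, Fa = 0.6, V1 = 4.0, k12 = 0.1,
                          k21 = 0.3, kel = 0.18) {
  p <- list(ka = ka, Fa = Fa, V1 = V1, k12 = k12, k21 = k21, kel = kel)
  stopifnot(all(unlist(p[c("ka", "V1", "k12", "k21", "kel")]) > 0),
            Fa > 0, Fa <= 1)
  structure(p, class = "osi_pk_params")
}

#' Folate-module pharmacodynamic parameters
#'
#' Indirect-response turnover of normalised folate-metabolising enzyme and
#' folate levels. Pemetrexed stimulates the loss of active enzyme with an
#' Emax model on the plasma concentration (mg/L); folate synthesis follows
#' the enzyme level raised to a transduction exponent.
#'
#' @param kout_enzyme enzyme turnover (1/day)
#' @param kout_folate folate turnover (1/day)
#' @param Emax_pem maximal stimulation of enzyme loss (dimensionless)
#' @param EC50_pem pemetrexed potency on the plasma scale (mg/L)
#' @param gamma_enzyme enzyme-to-folate transduction exponent
#' @return an object of class `folate_pd_params`
#' @export
folate_pd_params <- function(kout_enzyme = 4.8, kout_folate = 3.0,
                             Emax_pem = 15, EC50_pem = 0.47315,
                             gamma_enzyme = 1) {
  stopifnot(kout_enzyme > 0, kout_folate > 0, Emax_pem >= 0, EC50_pem > 0)
  structure(list(kout_enzyme = kout_enzyme, kout_folate = kout_folate,
                 Emax_pem = Emax_pem, EC50_pem = EC50_pem,
                 gamma_enzyme = gamma_enzyme),
            class = "folate_pd_params")
}

#' EGFR-module pharmacodynamic parameters
#'
#' Turnover of normalised EGFR signal. Osimertinib stimulates EGFR
#' inactivation with a sigmoid Imax model on the plasma concentration
#' (ug/L); damaged tumour cells stimulate EGFR synthesis (compensatory
#' rebound) through the damaged-volume fraction in \[0, 1\].
#'
#' The default `Imax_osi` is fixed by the steady state of the turnover
#' equation: an EGFR level of 0.0967 under 30 nM osimertinib with a medium
#' EC50 of 14.49 nM and unit Hill slope requires
#' `Imax = (1/0.0967 - 1) * (14.49 + 30) / 30`.
#'
#' @param kout_EGFR EGFR turnover (1/day)
#' @param Imax_osi maximal stimulation of EGFR inactivation
#' @param EC50_osi osimertinib potency, plasma scale (ug/L)
#' @param gamma_osi Hill coefficient on the osimertinib effect
#' @param k_feedback damage-driven synthesis gain (on the fraction scale)
#' @param gamma_feedback feedback exponent
#' @return an object of class `egfr_pd_params`
#' @export
egfr_pd_params <- function(kout_EGFR = 1.5,
                           Imax_osi = (1 / 0.0967 - 1) * (14.49 + 30) / 30,
                           EC50_osi = 48.86, gamma_osi = 1,
                           k_feedback = 1, gamma_feedback = 1) {
  stopifnot(kout_EGFR > 0, Imax_osi >= 0, EC50_osi > 0, gamma_osi > 0,
            k_feedback >= 0)
  structure(list(kout_EGFR = kout_EGFR, Imax_osi = Imax_osi,
                 EC50_osi = EC50_osi, gamma_osi = gamma_osi,
                 k_feedback = k_feedback, gamma_feedback = gamma_feedback),
            class = "egfr_pd_params")
}

#' Tumour growth inhibition parameters (extended Simeoni model)
#'
#' Four tumour compartments: proliferating cells X1 and a three-stage chain
#' of damaged cells X2-X4. Growth switches from exponential (`lambda0`) to
#' linear (`lambda1`) with exponent `psi`; EGFR signal gates both
#' proliferation (`gamma_EGFR`) and the X1 to X2 damage transition
#' (`gamma_G1`, the G1-arrest antagonism). Folate deficit below baseline
#' amplifies the damage transition; EGFR deficit below baseline (a Bim
#' surrogate) amplifies transit and death of damaged cells.
#'
#' @param lambda0 exponential growth rate (1/day)
#' @param lambda1 linear growth rate (mm3/day)
#' @param psi Simeoni switching exponent
#' @param k1 natural proliferating-to-damaged transition rate (1/day)
#' @param k2 damaged-cell transit/death rate (1/day)
#' @param Emax_folate maximal folate-driven kill amplification
#' @param EC50_folate potency on the folate-deficit (1 - folate) scale
#' @param gamma_folate Hill exponent on the folate deficit
#' @param gamma_EGFR EGFR-to-proliferation exponent
#' @param gamma_G1 EGFR-to-damage-transition gating exponent
#' @param kbim apoptosis amplification gain (wild-type Bim)
#' @param gamma_bim apoptosis exponent on the EGFR deficit
#' @param V0 initial tumour volume (mm3)
#' @return an object of class `tgi_params`
#' @export
tgi_params <- function(lambda0 = 0.1032, lambda1 = 51.08, psi = 20,
                       k1 = 0.01, k2 = 0.08, Emax_folate = 200,
                       EC50_folate = 1, gamma_folate = 2,
                       gamma_EGFR = 0.2, gamma_G1 = 1,
                       kbim = 211, gamma_bim = 9.5, V0 = 200) {
  stopifnot(lambda0 > 0, lambda1 > 0, k1 > 0, k2 > 0, psi > 0,
            Emax_folate >= 0, kbim >= 0,
            EC50_folate > 0, EC50_folate <= 1, V0 > 0)
  structure(list(lambda0 = lambda0, lambda1 = lambda1, psi = psi, k1 = k1,
                 k2 = k2, Emax_folate = Emax_folate,
                 EC50_folate = EC50_folate, gamma_folate = gamma_folate,
                 gamma_EGFR = gamma_EGFR, gamma_G1 = gamma_G1,
                 kbim = kbim, gamma_bim = gamma_bim, V0 = V0),
            class = "tgi_params")
}

#' Assemble the full model parameter set
#'
#' Bundles the PK and PD parameter blocks; any block can be overridden.
#' Rates declared per day (`lambda0`, `lambda1`, `k1`, `k2`, `kout_*`) are
#' converted to per hour internally by [param_vector()].
#'
#' @param pem_pk,osi_pk,folate,egfr,tgi parameter blocks; defaults are the
#'   package's calibrated typical-mouse values
#' @return an object of class `pemosi_params`
#' @export
default_params <- function(pem_pk = pem_pk_params(), osi_pk = osi_pk_params(),
                           folate = folate_pd_params(), egfr = egfr_pd_params(),
                           tgi = tgi_params()) {
  stopifnot(inherits(pem_pk, "pem_pk_params"), inherits(osi_pk, "osi_pk_params"),
            inherits(folate, "folate_pd_params"), inherits(egfr, "egfr_pd_params"),
            inherits(tgi, "tgi_params"))
  structure(list(pem_pk = pem_pk, osi_pk = osi_pk, folate = folate,
                 egfr = egfr, tgi = tgi),
            class = "pemosi_params")
}

#' Flatten a parameter set to the internal solver vector
#'
#' Converts all per-day rates to per-hour and returns the 35-element named
#' numeric vector consumed by the compiled right-hand side.
#'
#' @param params a `pemosi_params` object
#' @return named numeric vector (rates per hour)
#' @export
param_vector <- function(params) {
  stopifnot(inherits(params, "pemosi_params"))
  pk1 <- params$pem_pk; pk2 <- params$osi_pk
  fo <- params$folate; eg <- params$egfr; tg <- params$tgi
  h <- HOURS_PER_DAY
  c(ka_pem = pk1$ka, V1_pem = pk1$V1, k12_pem = pk1$k12, k21_pem = pk1$k21,
    kel_pem = pk1$kel, F_pem = pk1$F,
    ka_osi = pk2$ka, Fa_osi = pk2$Fa, V1_osi = pk2$V1, k12_osi = pk2$k12,
    k21_osi = pk2$k21, kel_osi = pk2$kel,
    kout_enzyme = fo$kout_enzyme / h, kout_folate = fo$kout_folate / h,
    Emax_pem = fo$Emax_pem, EC50_pem = fo$EC50_pem,
    gamma_enzyme = fo$gamma_enzyme,
    kout_EGFR = eg$kout_EGFR / h, Imax_osi = eg$Imax_osi,
    EC50_osi = eg$EC50_osi, gamma_osi = eg$gamma_osi,
    k_feedback = eg$k_feedback, gamma_feedback = eg$gamma_feedback,
    lambda0 = tg$lambda0 / h, lambda1 = tg$lambda1 / h, psi = tg$psi,
    k1 = tg$k1 / h, k2 = tg$k2 / h, Emax_folate = tg$Emax_folate,
    EC50_folate = tg$EC50_folate, gamma_folate = tg$gamma_folate,
    gamma_EGFR = tg$gamma_EGFR, gamma_G1 = tg$gamma_G1,
    kbim = tg$kbim, gamma_bim = tg$gamma_bim)
}

#' Apply multiplicative modifications to a parameter set
#'
#' @param params a `pemosi_params` object
#' @param modifications named numeric vector of multipliers; names must match
#'   fields of the PD/TGI blocks (e.g. `c(EC50_osi = 5, Imax_osi = 0.2)`)
#' @return modified `pemosi_params`
#' @export
modify_params <- function(params, modifications) {
  stopifnot(inherits(params, "pemosi_params"))
  if (length(modifications) == 0) return(params)
  stopifnot(!is.null(names(modifications)), all(modifications > 0))
  for (nm in names(modifications)) {
    hit <- FALSE
    for (block in names(params)) {
      if (nm %in% names(params[[block]])) {
        params[[block]][[nm]] <- params[[block]][[nm]] * modifications[[nm]]
        hit <- TRUE
      }
    }
    if (!hit) stop("unknown parameter in modifications: ", nm)
  }
  params
}
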