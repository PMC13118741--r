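#' Measurement-noise model for synthetic data
#'
#' @param kind `"none"`, `"additive_gaussian"`, `"proportional"` or
#'   `"lognormal"`
#' @param magnitude SD (additive, in data units) or CV (proportional,
#'   log-normal)
#' @return a `noise_model`
#' @export
noise_model <- function(kind = c("none", "additive_gaussian", "proportional",
                                 "lognormal"),
                        magnitude = 0) {
  kind <- match.arg(kind)
  stopifnot(magnitude >= 0)
  structure(list(kind = kind, magnitude = magnitude), class = "noise_model")
}

apply_noise <- function(values, noise) {
  stopifnot(inherits(noise, "noise_model"))
  n <- length(values); m <- noise$magnitude
  switch(noise$kind,
         none = values,
         additive_gaussian = values + stats::rnorm(n, 0, m),
         proportional = values * (1 + stats::rnorm(n, 0, m)),
         lognormal = values * exp(stats::rnorm(n, 0, sqrt(log(1 + m^2)))))
}

#' Generate tumour-volume measurement curves with known ground truth
#'
#' Simulates the full model under a regimen and emulates a caliper study:
#' measurements every third day by default, one noisy replicate per animal
#' (log-normal, CV 20% by default).
#'
#' @param params a `pemosi_params`
#' @param regimen a `pemosi_regimen`
#' @param sample_days measurement days
#' @param noise a [noise_model()]; default log-normal CV 20%
#' @param n_animals animals per group
#' @param seed integer seed
#' @return list with `animals` (list of [time_series()], mm3), `truth_curve`
#'   (noise-free time series) and `ground_truth`
#' @export
gen_tumor_curves <- function(params, regimen, sample_days = seq(0, 21, by = 3),
                             noise = noise_model("lognormal", 0.20),
                             n_animals = 5, seed = 1) {
  stopifnot(all(sample_days >= 0))
  set.seed(seed)
  t_end <- max(sample_days) * 24
  traj <- simulate_regimen(regimen, params, t_end = max(t_end, 24),
                           dt_out = 6)
  v <- stats::approx(traj$time_h, traj$X_total, xout = sample_days * 24)$y
  animals <- lapply(seq_len(n_animals), function(i)
    time_series(sample_days * 24, apply_noise(v, noise), unit = "mm3"))
  list(animals = animals,
       truth_curve = time_series(sample_days * 24, v, unit = "mm3"),
       ground_truth = list(params = params,
                           strategy = attr(regimen, "strategy"),
                           noise = unclass(noise), n_animals = n_animals,
                           seed = seed))
}

#' Generate plasma concentration-time profiles with known ground truth
#'
#' Two-compartment profile after a single dose, sampled at the given times
#' with proportional error (default CV 15%). `sparse_groups > 1` emulates a
#' rotating sparse-sampling design: animals are split into subgroups that
#' cover alternating time points, and the pooled mean curve is returned
#' alongside the individual samples.
#'
#' @param pk a `pem_pk_params` or `osi_pk_params` block
#' @param dose mg/kg
#' @param route `"ip"`, `"oral"` or `"iv"`
#' @param times sampling times (h)
#' @param noise a [noise_model()]; default proportional CV 15%
#' @param n_animals animals
#' @param sparse_groups number of rotating subgroups (1 = dense sampling)
#' @param seed integer seed
#' @return list with `mean_curve` ([time_series()]), `animals`, and
#'   `ground_truth` (true parameters and the noise-free curve). PEM
#'   concentrations are mg/L; OSI concentrations are ug/L.
#' @export
gen_pk_profiles <- function(pk, dose, route = "ip",
                            times = c(0.083, 0.25, 0.5, 1, 2, 4, 8, 12, 24),
                            noise = noise_model("proportional", 0.15),
                            n_animals = 5, sparse_groups = 1, seed = 1) {
  set.seed(seed)
  osi_like <- inherits(pk, "osi_pk_params")
  if (osi_like) {
    conc <- pk_conc_2cmt(times, dose, route, ka = pk$Fa * pk$ka,
                         V1 = pk$V1 / pk$Fa, k12 = pk$k12, k21 = pk$k21,
                         kel = pk$kel) * 1000  # ug/L
  } else {
    conc <- pk_conc_2cmt(times, dose * pk$F, route, ka = pk$ka, V1 = pk$V1,
                         k12 = pk$k12, k21 = pk$k21, kel = pk$kel)  # mg/L
  }
  grp <- rep(seq_len(sparse_groups), length.out = length(times))
  animals <- lapply(seq_len(n_animals), function(i) {
    idx <- if (sparse_groups > 1)
      which(grp == ((i - 1) %% sparse_groups) + 1) else seq_along(times)
    time_series(times[idx], pmax(0, apply_noise(conc[idx], noise)),
                unit = if (osi_like) "ug/L" else "mg/L")
  })
  ## pooled mean curve across animals covering each time point
  pool_t <- sort(unique(unlist(lapply(animals, `[[`, "times"))))
  pool_v <- vapply(pool_t, function(tt) {
    vals <- unlist(lapply(animals, function(a) a$values[a$times == tt]))
    mean(vals)
  }, numeric(1))
  list(mean_curve = time_series(pool_t, pool_v,
                                unit = if (osi_like) "ug/L" else "mg/L"),
       animals = animals,
       ground_truth = list(pk = unclass(pk), dose = dose, route = route,
                           true_curve = time_series(times, conc),
                           noise = unclass(noise), seed = seed))
}

#' Generate EGFR-recovery and dose-response calibration inputs
#'
#' Produces (a) a signal-recovery time course `1 - exp(-kout t)` on the
#' standard 0-72 h washout grid and (b) a four-parameter logistic
#' dose-response table, each with optional noise (default additive 5% of
#' baseline, a typical densitometry CV).
#'
#' @param kout EGFR turnover (1/day)
#' @param ec50 dose-response EC50 (nM)
#' @param hill Hill slope
#' @param recovery_times_h recovery sampling grid (h)
#' @param conc_nM dose-response concentration series (nM)
#' @param top,bottom dose-response asymptotes (response falls from `top` at
#'   zero drug to `bottom` at saturating drug)
#' @param noise a [noise_model()]
#' @param seed integer seed
#' @return list with `recovery` ([time_series()]), `dose_response` (data
#'   frame `conc_nM`, `response`) and `ground_truth`
#' @export
gen_recovery_and_doseresponse <- function(kout = 1.5, ec50 = 14.49, hill = 1,
                                          recovery_times_h = seq(0, 72, by = 12),
                                          conc_nM = c(1, 3, 10, 30, 100, 300,
                                                      1000) / 3.3,
                                          top = 1, bottom = 0,
                                          noise = noise_model("additive_gaussian",
                                                              0.05),
                                          seed = 1) {
  stopifnot(kout > 0, ec50 > 0, all(recovery_times_h >= 0), all(conc_nM > 0))
  set.seed(seed)
  rec_true <- 1 - exp(-kout / 24 * recovery_times_h)
  dr_true <- bottom + (top - bottom) / (1 + (conc_nM / ec50)^hill)
  list(recovery = time_series(recovery_times_h, apply_noise(rec_true, noise),
                              unit = "normalized"),
       dose_response = data.frame(conc_nM = conc_nM,
                                  response = apply_noise(dr_true, noise)),
       ground_truth = list(kout_per_day = kout, ec50_nM = ec50, hill = hill,
                           top = top, bottom = bottom,
                           recovery_true = rec_true, dr_true = dr_true,
                           noise = unclass(noise), seed = seed))
}
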