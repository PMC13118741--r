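## canonical unit per configurable parameter field
UNIT_REGISTRY <- list(
  pem_pk = c(ka = "1/h", V1 = "L/kg", k12 = "1/h", k21 = "1/h", kel = "1/h",
             F = "dimensionless"),
  osi_pk = c(ka = "1/h", Fa = "dimensionless", V1 = "L/kg", k12 = "1/h",
             k21 = "1/h", kel = "1/h"),
  folate = c(kout_enzyme = "1/day", kout_folate = "1/day",
             Emax_pem = "dimensionless", EC50_pem = "mg/L",
             gamma_enzyme = "dimensionless"),
  egfr = c(kout_EGFR = "1/day", Imax_osi = "dimensionless",
           EC50_osi = "ug/L", gamma_osi = "dimensionless",
           k_feedback = "dimensionless", gamma_feedback = "dimensionless"),
  tgi = c(lambda0 = "1/day", lambda1 = "mm3/day", psi = "dimensionless",
          k1 = "1/day", k2 = "1/day", Emax_folate = "dimensionless",
          EC50_folate = "dimensionless", gamma_folate = "dimensionless",
          gamma_EGFR = "dimensionless", gamma_G1 = "dimensionless",
          kbim = "dimensionless", gamma_bim = "dimensionless", V0 = "mm3"))

convert_unit <- function(value, from, to) {
  if (from == to) return(value)
  conv <- list("1/day->1/h" = 1 / 24, "1/h->1/day" = 24,
               "mm3/day->mm3/h" = 1 / 24, "mm3/h->mm3/day" = 24,
               "mg/L->ug/L" = 1000, "ug/L->mg/L" = 1 / 1000)
  key <- paste0(from, "->", to)
  if (is.null(conv[[key]])) stop("cannot convert ", from, " to ", to)
  value * conv[[key]]
}

parse_entry <- function(entry, field, canonical) {
  if (is.numeric(entry)) return(list(value = entry, problems = character(0)))
  if (is.list(entry) && !is.null(entry$value)) {
    if (is.null(entry$unit))
      return(list(value = NA_real_,
                  problems = paste0(field, ": unit missing")))
    v <- try(convert_unit(entry$value, entry$unit, canonical), silent = TRUE)
    if (inherits(v, "try-error"))
      return(list(value = NA_real_,
                  problems = paste0(field, ": malformed unit '", entry$unit,
                                    "' (expected ", canonical, ")")))
    return(list(value = v, problems = character(0)))
  }
  list(value = NA_real_, problems = paste0(field, ": unreadable entry"))
}

#' Load a run configuration from YAML or JSON
#'
#' The file may contain any subset of the parameter blocks `pem_pk`,
#' `osi_pk`, `folate`, `egfr`, `tgi` (entries either plain numbers, taken
#' in the field's canonical unit, or `{value:, unit:}` pairs that are
#' converted: 1/day vs 1/h, mg/L vs ug/L, mm3/day vs mm3/h), a `regimen`
#' block (`strategy`, `interval_h`, `pem_dose`, `osi_dose`, `n_cycles`,
#' `cycle_length_days`), plus `seed`, `stages`, `out_dir`, `t_end_h`,
#' `rtol`, `atol`. Unspecified parameters fall back to the package
#' defaults. All validation problems are reported together.
#'
#' @param path YAML (or JSON) configuration file
#' @return a `pemosi_config`: list with `params`, `regimen`, `stages`,
#'   `seed`, `out_dir`, `t_end_h`, `rtol`, `atol`, `config_md5`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
  else yaml::read_yaml(path)
  problems <- character(0)
  known_top <- c(names(UNIT_REGISTRY), "regimen", "seed", "stages",
                 "out_dir", "t_end_h", "rtol", "atol")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    problems <- c(problems, paste0("unknown top-level key(s): ",
                                   paste(unknown, collapse = ", ")))
  params <- default_params()
  for (block in names(UNIT_REGISTRY)) {
    if (is.null(cfg[[block]])) next
    reg <- UNIT_REGISTRY[[block]]
    bad <- setdiff(names(cfg[[block]]), names(reg))
    if (length(bad))
      problems <- c(problems, paste0(block, ": unknown key(s) ",
                                     paste(bad, collapse = ", ")))
    for (field in intersect(names(cfg[[block]]), names(reg))) {
      pe <- parse_entry(cfg[[block]][[field]], paste0(block, "$", field),
                        reg[[field]])
      problems <- c(problems, pe$problems)
      if (!is.na(pe$value)) {
        if (grepl("^1/", reg[[field]]) && pe$value <= 0)
          problems <- c(problems,
                        paste0(block, "$", field, ": rate must be positive"))
        else params[[block]][[field]] <- pe$value
      }
    }
  }
  if (length(problems))
    stop("configuration problems:\n  ", paste(problems, collapse = "\n  "))
  reg_cfg <- cfg$regimen
  regimen <- if (is.null(reg_cfg)) build_regimen("control")
  else do.call(build_regimen, reg_cfg)
  structure(list(params = params, regimen = regimen,
                 stages = if (is.null(cfg$stages)) "simulate" else
                   unlist(cfg$stages),
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
                 out_dir = if (is.null(cfg$out_dir)) "pemosi_out" else
                   cfg$out_dir,
                 t_end_h = if (is.null(cfg$t_end_h)) 21 * 24 else cfg$t_end_h,
                 rtol = if (is.null(cfg$rtol)) 1e-6 else cfg$rtol,
                 atol = if (is.null(cfg$atol)) 1e-9 else cfg$atol,
                 config_md5 = unname(tools::md5sum(path))),
            class = "pemosi_config")
}

#' Run the pipeline stages described by a configuration
#'
#' Executes the selected stages in calibration order — `synth` (generate
#' synthetic calibration inputs), `fit` (round-trip calibration on those
#' inputs), `simulate` (trajectory under the configured regimen),
#' `intervals` (interval comparison), `population` (Monte Carlo ORR) — and
#' writes CSV/JSON artifacts plus a manifest carrying the master seed and
#' the configuration hash. A stage failure aborts downstream stages; the
#' partial manifest is still written.
#'
#' @param config a `pemosi_config` from [load_config()]
#' @return (invisibly) the manifest list
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pemosi_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, config_md5 = config$config_md5,
                   started = format(Sys.time()), outputs = list(),
                   status = "ok")
  emit <- function(name, path) {
    manifest$outputs[[name]] <<- path
  }
  stage_order <- c("synth", "fit", "simulate", "intervals", "population")
  stages <- intersect(stage_order, config$stages)
  unknown <- setdiff(config$stages, stage_order)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  for (stage in stages) {
    res <- tryCatch({
      switch(stage,
        synth = {
          gen <- gen_recovery_and_doseresponse(seed = config$seed)
          path <- file.path(config$out_dir, "synthetic_recovery.csv")
          utils::write.csv(data.frame(time_h = gen$recovery$times,
                                      value = gen$recovery$values),
                           path, row.names = FALSE)
          emit("synthetic_recovery", path)
          path2 <- file.path(config$out_dir, "synthetic_dose_response.csv")
          utils::write.csv(gen$dose_response, path2, row.names = FALSE)
          emit("synthetic_dose_response", path2)
          gt <- file.path(config$out_dir, "synthetic_ground_truth.json")
          jsonlite::write_json(gen$ground_truth, gt, auto_unbox = TRUE,
                               digits = NA)
          emit("synthetic_ground_truth", gt)
        },
        fit = {
          gen <- gen_recovery_and_doseresponse(noise = noise_model("none"),
                                               seed = config$seed)
          f1 <- fit_egfr_recovery(gen$recovery)
          f2 <- fit_4pl(gen$dose_response$conc_nM, gen$dose_response$response)
          path <- file.path(config$out_dir, "fit_results.json")
          jsonlite::write_json(
            list(egfr_recovery = f1$estimates, dose_response = f2$estimates,
                 seed = config$seed), path, auto_unbox = TRUE, digits = NA)
          emit("fit_results", path)
        },
        simulate = {
          traj <- simulate_regimen(config$regimen, config$params,
                                   t_end = config$t_end_h,
                                   rtol = config$rtol, atol = config$atol)
          path <- file.path(config$out_dir, "trajectory.csv")
          write_trajectory_csv(traj, path)
          emit("trajectory", path)
        },
        intervals = {
          cmp <- compare_intervals(config$params, t_end = config$t_end_h)
          path <- file.path(config$out_dir, "interval_comparison.csv")
          utils::write.csv(cmp$summary, path, row.names = FALSE)
          emit("interval_comparison", path)
        },
        population = {
          spec <- population_spec(n_subjects = 200, seed = config$seed)
          pop <- run_population(spec, config$params)
          path <- file.path(config$out_dir, "orr_curve.csv")
          utils::write.csv(pop$orr, path, row.names = FALSE)
          emit("orr_curve", path)
          path2 <- file.path(config$out_dir, "orr_summary.json")
          jsonlite::write_json(
            list(time_averaged_orr = as.list(pop$time_averaged_orr),
                 n_subjects = spec$n_subjects, n_failed = pop$n_failed,
                 seed = config$seed),
            path2, auto_unbox = TRUE, digits = NA)
          emit("orr_summary", path2)
        })
      TRUE
    }, error = function(e) {
      manifest$status <<- paste0("failed at stage '", stage, "': ",
                                 conditionMessage(e))
      FALSE
    })
    if (!isTRUE(res)) break
  }
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (manifest$status != "ok") stop(manifest$status)
  invisible(manifest)
}
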