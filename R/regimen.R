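#' Build a dosing regimen from a strategy descriptor
#'
#' Mirrors the xenograft study design: pemetrexed (PEM) 35 mg/kg i.p. three
#' times daily at a 4 h interval on the first two days of each cycle (six
#' doses, giving roughly 48 h of continuous exposure given the ~35 min
#' terminal half-life), osimertinib (OSI) 1 mg/kg orally once daily from its
#' start time to the end of the cycle, over three 7-day cycles. Under the
#' sequential strategy the first OSI dose of each cycle is delayed by
#' `interval_h` after the cycle's first PEM dose; concurrent means zero
#' delay.
#'
#' @param strategy one of `"control"`, `"PEM"`, `"OSI"`, `"concurrent"`,
#'   `"sequential"`
#' @param interval_h OSI start delay after the first PEM dose of each cycle
#'   (h); only used for `"sequential"`
#' @param pem_dose,osi_dose dose amounts (mg/kg)
#' @param n_cycles number of treatment cycles
#' @param cycle_length_days cycle length (days)
#' @return an object of class `pemosi_regimen`: a data frame of dose events
#'   (`time_h`, `drug`, `amount_mg_per_kg`) with strategy metadata
#' @export
build_regimen <- function(strategy = c("control", "PEM", "OSI", "concurrent",
                                       "sequential"),
                          interval_h = 48, pem_dose = 35, osi_dose = 1,
                          n_cycles = 3, cycle_length_days = 7) {
  strategy <- match.arg(strategy)
  stopifnot(interval_h >= 0, pem_dose >= 0, osi_dose >= 0, n_cycles >= 1)
  if (strategy == "concurrent") interval_h <- 0
  cyc_h <- cycle_length_days * 24
  events <- data.frame(time_h = numeric(0), drug = character(0),
                       amount_mg_per_kg = numeric(0))
  pem_offsets <- c(0, 4, 8, 24, 28, 32)
  for (c_i in seq_len(n_cycles)) {
    t0 <- (c_i - 1) * cyc_h
    if (strategy %in% c("PEM", "concurrent", "sequential")) {
      events <- rbind(events, data.frame(
        time_h = t0 + pem_offsets, drug = "PEM",
        amount_mg_per_kg = pem_dose))
    }
    if (strategy %in% c("OSI", "concurrent", "sequential")) {
      osi_start <- if (strategy == "sequential") interval_h else 0
      osi_times <- seq(osi_start, cyc_h - 1e-9, by = 24)
      events <- rbind(events, data.frame(
        time_h = t0 + osi_times, drug = "OSI",
        amount_mg_per_kg = osi_dose))
    }
  }
  events <- events[order(events$time_h, events$drug), , drop = FALSE]
  rownames(events) <- NULL
  structure(events,
            strategy = strategy, interval_h = interval_h,
            n_cycles = n_cycles, cycle_length_days = cycle_length_days,
            class = c("pemosi_regimen", "data.frame"))
}

#' Drop dose events after a time horizon
#' @param regimen a `pemosi_regimen`
#' @param t_end horizon (h)
#' @return truncated `pemosi_regimen`
#' @export
truncate_regimen <- function(regimen, t_end) {
  at <- attributes(regimen)
  out <- as.data.frame(regimen)[regimen$time_h <= t_end, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, strategy = at$strategy, interval_h = at$interval_h,
            n_cycles = at$n_cycles, cycle_length_days = at$cycle_length_days,
            class = c("pemosi_regimen", "data.frame"))
}

#' Read a regimen from a CSV of dose events
#'
#' Expects columns `time_h`, `drug` (`PEM`/`OSI`), `amount_mg_per_kg`.
#' @param path CSV file path
#' @return `pemosi_regimen`
#' @export
read_regimen_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("time_h", "drug", "amount_mg_per_kg")
  if (!all(need %in% names(ev)))
    stop("regimen CSV must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(ev$drug %in% c("PEM", "OSI")), all(ev$time_h >= 0),
            all(ev$amount_mg_per_kg >= 0))
  ev <- ev[order(ev$time_h, ev$drug), need]
  rownames(ev) <- NULL
  structure(ev, strategy = "custom", class = c("pemosi_regimen", "data.frame"))
}

#' Write a regimen to CSV
#' @param regimen a `pemosi_regimen`
#' @param path output file
#' @export
write_regimen_csv <- function(regimen, path) {
  utils::write.csv(as.data.frame(regimen), path, row.names = FALSE)
  invisible(path)
}
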