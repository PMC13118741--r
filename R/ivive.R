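#' Drug identity for unit conversions
#'
#' Molecular weights are data, not constants: the defaults are pemetrexed
#' free acid 427.4 g/mol and osimertinib free base 499.6 g/mol (the free
#' acid reproduces the 300 nM = 0.1282 ug/mL conversion used for the in
#' vitro exposures).
#'
#' @param name drug label
#' @param molecular_weight g/mol
#' @return a `drug_identity`
#' @export
drug_identity <- function(name, molecular_weight) {
  stopifnot(molecular_weight > 0)
  structure(list(name = name, molecular_weight = molecular_weight),
            class = "drug_identity")
}

#' @rdname drug_identity
#' @export
drug_pem <- function() drug_identity("pemetrexed", 427.4)

#' @rdname drug_identity
#' @export
drug_osi <- function() drug_identity("osimertinib", 499.6)

#' Protein-binding context for free-fraction correction
#'
#' @param fu_plasma unbound fraction in plasma (0 < fu <= 1)
#' @param protein_ratio plasma-to-medium protein concentration ratio
#'   (default 10: medium with 10% serum, serum and plasma assumed to carry
#'   the same protein concentration)
#' @return a `binding_context`
#' @export
binding_context <- function(fu_plasma = 0.0535, protein_ratio = 10) {
  if (fu_plasma <= 0) stop("fu_plasma must be positive")
  stopifnot(fu_plasma <= 1, protein_ratio > 0)
  structure(list(fu_plasma = fu_plasma, protein_ratio = protein_ratio),
            class = "binding_context")
}

#' Unbound fraction in culture medium from plasma binding
#'
#' Assuming a single binding site class and protein-proportional binding,
#' `fu_medium = 1 / (1 + (Pmedium/Pplasma) * (1 - fu_plasma) / fu_plasma)`.
#'
#' @param ctx a [binding_context()]
#' @return unbound fraction in medium, in (0, 1]
#' @export
fu_medium <- function(ctx) {
  stopifnot(inherits(ctx, "binding_context"))
  1 / (1 + (1 / ctx$protein_ratio) * (1 - ctx$fu_plasma) / ctx$fu_plasma)
}

#' Convert a molar concentration to mass units
#'
#' @param conc molar concentration (nM by default)
#' @param drug a [drug_identity()]
#' @param from input molar unit: `"nM"` or `"M"`
#' @param to output mass unit: `"ug/L"` (= ng/mL), `"mg/L"` (= ug/mL) or
#'   `"g/L"`
#' @return mass concentration in the requested unit
#' @export
molar_to_mass <- function(conc, drug, from = "nM", to = "ug/L") {
  stopifnot(all(conc >= 0), inherits(drug, "drug_identity"))
  molar <- switch(from, nM = conc * 1e-9, M = conc,
                  stop("unknown molar unit: ", from))
  g_per_L <- molar * drug$molecular_weight
  switch(to, "g/L" = g_per_L, "mg/L" = g_per_L * 1e3,
         "ug/L" = g_per_L * 1e6, stop("unknown mass unit: ", to))
}

#' Convert a mass concentration back to molar
#' @param conc mass concentration
#' @param drug a [drug_identity()]
#' @param from mass unit of `conc` (`"ug/L"`, `"mg/L"`, `"g/L"`)
#' @param to molar output unit (`"nM"` or `"M"`)
#' @return molar concentration
#' @export
mass_to_molar <- function(conc, drug, from = "ug/L", to = "nM") {
  stopifnot(all(conc >= 0), inherits(drug, "drug_identity"))
  g_per_L <- switch(from, "g/L" = conc, "mg/L" = conc * 1e-3,
                    "ug/L" = conc * 1e-6, stop("unknown mass unit: ", from))
  molar <- g_per_L / drug$molecular_weight
  switch(to, M = molar, nM = molar * 1e9, stop("unknown molar unit: ", to))
}

#' Free-fraction correction of an in vitro potency to the plasma scale
#'
#' Scales a culture-medium EC50 by `fu_medium / fu_plasma` (equal unbound
#' concentrations in medium and plasma at equal effect) and converts from
#' molar to mass units.
#'
#' @param ec50_medium in vitro EC50 (nM)
#' @param ctx a [binding_context()]
#' @param drug a [drug_identity()]
#' @param to output mass unit (default `"ug/L"`)
#' @return plasma-scale EC50 in mass units
#' @export
ec50_to_plasma <- function(ec50_medium, ctx, drug, to = "ug/L") {
  stopifnot(ec50_medium > 0)
  ec50_plasma_nM <- ec50_medium * fu_medium(ctx) / ctx$fu_plasma
  molar_to_mass(ec50_plasma_nM, drug, from = "nM", to = to)
}

#' Scale an in vivo exponential growth rate to in vitro culture
#'
#' Cell culture proliferates faster than the xenograft; the fixed empirical
#' ratio 4.736 converts the in vivo exponential rate to its in vitro
#' counterpart, returned both per day and per hour.
#'
#' @param lambda0_in_vivo in vivo exponential growth rate (1/day)
#' @param factor in vitro / in vivo ratio
#' @return list with `per_day` and `per_hour`
#' @export
scale_growth_rate <- function(lambda0_in_vivo, factor = 4.736) {
  stopifnot(lambda0_in_vivo > 0)
  per_day <- factor * lambda0_in_vivo
  list(per_day = per_day, per_hour = per_day / 24)
}
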