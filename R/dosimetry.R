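# RBE-weighted absorbed-dose coefficients from time-integrated activity,
# absorbed doses, therapeutic indices, multi-cycle dose ledgers and
# mass-dose extrapolation.
#
# Unit chain for a coefficient (Gy per administered kBq):
#   TIA [%IA.h/g per kBq admin]
#     x 10      -> Bq/g per kBq administered per %IA/g
#     x 3600    -> decays per gram per kBq administered
#     x E [MeV] x 1.602176634e-13 [J/MeV] -> J/g
#     x 1000    -> J/kg = Gy
#     x RBE     -> RBE-weighted Gy
# Organ masses cancel because dose is per gram of tissue throughout.

.MEV_TO_JOULE <- 1.602176634e-13

#' Dose model: RBE and energy per decay
#'
#' @param chain A [decay_chain()]; its branching-weighted alpha energy is
#'   the energy deposited per parent decay (local-absorption assumption).
#' @param rbe Relative biological effectiveness for alpha radiation
#'   (default 5).
#' @return An object of class `dose_model`.
#' @export
dose_model <- function(chain = ac225_chain(), rbe = 5) {
  if (!is.numeric(rbe) || rbe <= 0) stop("rbe must be > 0", call. = FALSE)
  e <- alpha_energy_per_decay(chain)
  if (e <= 0) stop("chain deposits no alpha energy", call. = FALSE)
  structure(list(rbe = rbe, energy_per_decay = e,
                 mev_to_joule = .MEV_TO_JOULE,
                 nuclide = chain$parent),
            class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  cat(sprintf("<dose_model> %s chain, E = %.3f MeV/decay, RBE = %g\n",
              x$nuclide$name, x$energy_per_decay, x$rbe))
  invisible(x)
}

.new_dose_coefficient <- function(tissue, value, rbe_weighted = TRUE,
                                  derivation = "integrated", audit = NULL) {
  if (value < 0) stop("coefficient must be >= 0", call. = FALSE)
  structure(list(tissue = tissue, value = value,
                 rbe_weighted = rbe_weighted, derivation = derivation,
                 audit = audit),
            class = "dose_coefficient")
}

#' Construct a dose coefficient directly
#'
#' For entering published coefficients (e.g. a dosimetry table) into the
#' dose-ledger operations.
#'
#' @param tissue Tissue label.
#' @param value Gy per administered kBq.
#' @param rbe_weighted Logical; whether the value is RBE-weighted.
#' @param derivation `"integrated"` or `"extrapolated"`.
#' @return A `dose_coefficient`.
#' @export
dose_coefficient_value <- function(tissue, value, rbe_weighted = TRUE,
                                   derivation = "integrated") {
  .new_dose_coefficient(tissue, value, rbe_weighted, derivation,
                        audit = "entered directly")
}

#' RBE-weighted dose coefficient from a TIA result
#'
#' @param tia A `tia_result` from [integrate_tac()], computed from a
#'   physical curve in %IA/g (which makes it per administered kBq).
#' @param model A [dose_model()].
#' @return A `dose_coefficient` (Gy/kBq administered) carrying a
#'   unit-dimension audit trail in `$audit`.
#' @export
#' @examples
#' md <- dose_model(rbe = 5)
#' tia <- structure(list(tissue = "x", tia = 1, tail_model = "none",
#'                       tail_fraction = 0), class = "tia_result")
#' dose_coefficient(tia, md)$value # ~7.9e-4 for E ~ 27.5 MeV
dose_coefficient <- function(tia, model) {
  stopifnot(inherits(tia, "tia_result"), inherits(model, "dose_model"))
  val <- tia$tia * 10 * 3600 * model$energy_per_decay *
    model$mev_to_joule * 1000 * model$rbe
  audit <- sprintf(
    "%.6g %%IA.h/g x 10 [Bq/g per %%IA/g per kBq] x 3600 [s/h] x %.4g MeV x %.10g J/MeV x 1000 [g/kg] x RBE %g = %.6g Gy/kBq",
    tia$tia, model$energy_per_decay, model$mev_to_joule, model$rbe, val)
  .new_dose_coefficient(tia$tissue, val, rbe_weighted = TRUE,
                        derivation = "integrated", audit = audit)
}

#' @export
print.dose_coefficient <- function(x, ...) {
  cat(sprintf("<dose_coefficient> %s: %.3f Gy/kBq (%s%s)\n", x$tissue,
              x$value, x$derivation,
              if (x$rbe_weighted) ", RBE-weighted" else ""))
  invisible(x)
}

.coeff_value <- function(coeff) {
  if (inherits(coeff, "dose_coefficient")) coeff$value else as.numeric(coeff)
}

#' Absorbed dose for an administered activity
#'
#' @param coeff A `dose_coefficient` (or bare Gy/kBq value).
#' @param administered_kbq Administered activity, kBq, `>= 0`.
#' @return Absorbed dose, Gy, full precision (round for display; the
#'   conventional display is 2 significant figures).
#' @export
#' @examples
#' absorbed_dose(5.670, 37) # 209.79 Gy, displays as 210
absorbed_dose <- function(coeff, administered_kbq) {
  if (any(administered_kbq < 0))
    stop("administered activity must be >= 0", call. = FALSE)
  .coeff_value(coeff) * administered_kbq
}

#' Cumulative dose over treatment cycles
#'
#' Sums per-cycle absorbed doses with no repair or fractionation
#' correction (doses add).
#'
#' @param cycles A list of cycles, each `list(coeff, kbq)` where `coeff`
#'   is a `dose_coefficient` or bare Gy/kBq value.
#' @return Total Gy.
#' @export
#' @examples
#' cumulative_dose(list(list(5.670, 37), list(5.670, 37))) # 419.58
cumulative_dose <- function(cycles) {
  if (!is.list(cycles) || length(cycles) == 0L)
    stop("need at least one cycle", call. = FALSE)
  sum(vapply(cycles, function(cy)
    absorbed_dose(cy[[1L]], cy[[2L]]), numeric(1L)))
}

#' Therapeutic index
#'
#' Ratio of tumor to normal-organ dose coefficients. The RBE cancels,
#' but both coefficients must share the same weighting status.
#'
#' @param tumor,organ `dose_coefficient`s.
#' @return Dimensionless full-precision quotient.
#' @export
therapeutic_index <- function(tumor, organ) {
  stopifnot(inherits(tumor, "dose_coefficient"),
            inherits(organ, "dose_coefficient"))
  if (tumor$rbe_weighted != organ$rbe_weighted)
    stop("mixed RBE-weighting status", call. = FALSE)
  if (organ$value <= 0) stop("organ coefficient must be > 0", call. = FALSE)
  tumor$value / organ$value
}

#' Extrapolate a coefficient to a different mass regimen
#'
#' Scales a reference coefficient by the ratio of 24-h uptakes, assuming
#' similar time-activity curve shapes between regimens (i.e. clearance
#' kinetics unaffected by receptor saturation).
#'
#' @param ref Reference `dose_coefficient`.
#' @param ref_uptake_24h 24-h uptake under the reference regimen, %IA/g,
#'   `> 0`.
#' @param new_uptake_24h 24-h uptake under the new regimen, %IA/g.
#' @return A `dose_coefficient` with `derivation = "extrapolated"`.
#' @export
#' @examples
#' k <- dose_coefficient_value("kidney", 0.095)
#' extrapolate_coefficient(k, 0.63, 0.47)$value # ~0.0709
extrapolate_coefficient <- function(ref, ref_uptake_24h, new_uptake_24h) {
  stopifnot(inherits(ref, "dose_coefficient"))
  if (ref_uptake_24h <= 0)
    stop("reference uptake must be > 0", call. = FALSE)
  if (new_uptake_24h < 0) stop("uptake must be >= 0", call. = FALSE)
  val <- ref$value * new_uptake_24h / ref_uptake_24h
  .new_dose_coefficient(
    ref$tissue, val, rbe_weighted = ref$rbe_weighted,
    derivation = "extrapolated",
    audit = sprintf("%.6g Gy/kBq x (%.4g / %.4g %%IA/g) = %.6g Gy/kBq",
                    ref$value, new_uptake_24h, ref_uptake_24h, val))
}

# ---- model front end --------------------------------------------------

#' Fit biodistribution-driven dosimetry
#'
#' The package's main fitting function: takes a serial biodistribution
#' table, builds per-tissue physical time-activity curves, integrates them
#' to time-integrated activities and converts those to RBE-weighted
#' absorbed-dose coefficients under the local alpha-absorption assumption.
#'
#' @param samples A `biodist` data.frame ([read_biodist()] schema) with
#'   serial data per tissue, normalised per administered activity (%IA/g).
#' @param chain A [decay_chain()] (default: shipped Ac-225 chain).
#' @param rbe Relative biological effectiveness (default 5).
#' @param tail_model Tail handling passed to [integrate_tac()].
#' @param tumor_tissue Label used as the numerator of therapeutic indices
#'   (default `"tumor"`).
#' @return An object of class `prit_dosimetry` with methods [coef()],
#'   [predict()], `print()`, `summary()`.
#' @export
#' @examples
#' bd <- biodist_table(rep("tumor", 3), c(2, 24, 72), c(5, 10, 8))
#' fit <- dosimetry(bd)
#' coef(fit)
dosimetry <- function(samples, chain = ac225_chain(), rbe = 5,
                      tail_model = c("physical-decay",
                                     "fitted-monoexponential", "none"),
                      tumor_tissue = "tumor") {
  tail_model <- match.arg(tail_model)
  model <- dose_model(chain, rbe)
  curves <- biodist_to_tac(samples, model$nuclide)
  tias <- lapply(curves, integrate_tac, nuclide = model$nuclide,
                 tail_model = tail_model)
  coeffs <- lapply(tias, dose_coefficient, model = model)
  structure(
    list(model = model, tail_model = tail_model, curves = curves,
         tia = tias, coefficients = coeffs, tumor_tissue = tumor_tissue,
         call = match.call()),
    class = "prit_dosimetry"
  )
}

#' @export
coef.prit_dosimetry <- function(object, ...) {
  vapply(object$coefficients, function(cf) cf$value, numeric(1L))
}

#' Predicted absorbed doses for an administered activity
#'
#' @param object A `prit_dosimetry` fit.
#' @param administered_kbq Administered activity per cycle, kBq.
#' @param cycles Number of identical cycles (doses add; default 1).
#' @param ... Unused.
#' @return Named vector of absorbed doses (Gy) per tissue.
#' @export
predict.prit_dosimetry <- function(object, administered_kbq, cycles = 1L,
                                   ...) {
  coef(object) * administered_kbq * cycles
}

#' @export
print.prit_dosimetry <- function(x, ...) {
  cat(sprintf("PRIT dosimetry fit (%s, RBE %g, tail: %s)\n",
              x$model$nuclide$name, x$model$rbe, x$tail_model))
  cat("Dose coefficients (Gy/kBq administered):\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
summary.prit_dosimetry <- function(object, ...) {
  cf <- coef(object)
  tt <- tia_table(object$tia)
  tt$coefficient_gy_per_kbq <- cf[tt$tissue]
  tumor <- object$tumor_tissue
  tt$therapeutic_index <- if (tumor %in% tt$tissue)
    cf[tumor] / tt$coefficient_gy_per_kbq else NA_real_
  structure(list(model = object$model, tail_model = object$tail_model,
                 table = tt, tumor_tissue = tumor),
            class = "summary.prit_dosimetry")
}

#' @export
print.summary.prit_dosimetry <- function(x, ...) {
  print(x$model)
  tab <- x$table
  tab$tia <- signif(tab$tia, 4)
  tab$tail_fraction <- round(tab$tail_fraction, 3)
  tab$coefficient_gy_per_kbq <- round(tab$coefficient_gy_per_kbq, 3)
  tab$therapeutic_index <- round(tab$therapeutic_index, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}
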