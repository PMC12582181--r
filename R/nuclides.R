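# Nuclear-physics constants and decay arithmetic for alpha-emitting chains.
#
# Dose is computed under the "local absorption" assumption: every daughter
# in the chain decays where the parent decayed, instantaneously on the
# dosimetric timescale (secular equilibrium), so the energy released per
# parent decay is the branching-weighted sum of the chain's mean alpha
# energies. Beta and gamma emissions are excluded from dose.

.HOURS_PER_UNIT <- c(h = 1, d = 24, s = 1 / 3600)

#' Convert a duration to hours
#'
#' Internal time unit is hours throughout the package; public interfaces
#' accept days, hours or seconds with an explicit unit tag.
#'
#' @param x Numeric duration.
#' @param unit One of `"h"`, `"d"`, `"s"`.
#' @return Duration in hours.
#' @export
#' @examples
#' as_hours(9.92, "d")
as_hours <- function(x, unit = c("h", "d", "s")) {
  unit <- match.arg(unit)
  x * .HOURS_PER_UNIT[[unit]]
}

#' Define a radionuclide
#'
#' @param name Text label, e.g. `"Ac-225"`.
#' @param half_life Physical half-life (in `unit`). Must be positive.
#' @param unit Unit of `half_life`: `"h"`, `"d"` or `"s"`.
#' @return An object of class `nuclide` with fields `name`, `half_life_h`
#'   and `decay_constant` (per hour, `log(2)/half_life_h`).
#' @export
#' @examples
#' ac <- nuclide("Ac-225", 9.92, "d")
#' ac$decay_constant
nuclide <- function(name, half_life, unit = c("h", "d", "s")) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life) || length(half_life) != 1L || half_life <= 0)
    stop("`half_life` must be a single positive number", call. = FALSE)
  hl_h <- as_hours(half_life, unit)
  structure(
    list(name = name, half_life_h = hl_h, decay_constant = log(2) / hl_h),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %g h (lambda = %.6g /h)\n",
              x$name, x$half_life_h, x$decay_constant))
  invisible(x)
}

#' Physical decay factor
#'
#' Fraction of activity remaining after `t` hours of physical decay,
#' `exp(-lambda * t)`.
#'
#' @param nuclide A [nuclide()].
#' @param t Time in hours, `t >= 0` (vectorised).
#' @return Dimensionless fraction in (0, 1].
#' @export
#' @examples
#' decay_factor(nuclide("Ac-225", 9.92, "d"), 24)
decay_factor <- function(nuclide, t) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  exp(-nuclide$decay_constant * t)
}

#' Define a decay chain
#'
#' A chain is the parent nuclide plus an ordered list of steps. Each step
#' carries the probability that one parent decay passes through it
#' (`branching_fraction`) and the intensity-weighted mean alpha energy it
#' emits (0 for beta/gamma steps). Alternative branches at the same chain
#' `position` must have fractions summing to 1.
#'
#' @param parent A [nuclide()].
#' @param steps A data.frame with columns `nuclide`, `position`,
#'   `branching_fraction`, `mean_alpha_energy_mev`.
#' @param terminal_stable Logical; the chain must terminate in a stable
#'   nuclide (asserted, not modelled).
#' @return An object of class `decay_chain`.
#' @export
decay_chain <- function(parent, steps, terminal_stable = TRUE) {
  stopifnot(inherits(parent, "nuclide"), is.data.frame(steps))
  req <- c("nuclide", "position", "branching_fraction", "mean_alpha_energy_mev")
  missing_cols <- setdiff(req, names(steps))
  if (length(missing_cols))
    stop("steps missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(steps) == 0L) stop("decay chain has no steps", call. = FALSE)
  if (any(steps$branching_fraction <= 0 | steps$branching_fraction > 1))
    stop("branching fractions must be in (0, 1]", call. = FALSE)
  if (any(steps$mean_alpha_energy_mev < 0))
    stop("mean alpha energies must be >= 0", call. = FALSE)
  if (!isTRUE(terminal_stable))
    stop("chain must terminate in a stable nuclide", call. = FALSE)
  # alternative branches at one position sum to 1
  bsum <- tapply(steps$branching_fraction, steps$position, sum)
  if (any(abs(bsum - 1) > 1e-9))
    stop("branching fractions at position(s) ",
         paste(names(bsum)[abs(bsum - 1) > 1e-9], collapse = ", "),
         " do not sum to 1", call. = FALSE)
  structure(list(parent = parent, steps = steps), class = "decay_chain")
}

#' @export
print.decay_chain <- function(x, ...) {
  cat(sprintf("<decay_chain> parent %s, %d steps, %.3f MeV alpha/decay\n",
              x$parent$name, nrow(x$steps), alpha_energy_per_decay(x)))
  invisible(x)
}

#' Read a decay chain from a JSON data file
#'
#' @param path Path to a JSON file with `parent` (name, half_life, unit)
#'   and `steps` entries mirroring [decay_chain()].
#' @return A `decay_chain`.
#' @export
read_decay_chain <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  parent <- nuclide(j$parent$name, j$parent$half_life, j$parent$unit)
  stable <- isTRUE(j$terminal$stable)
  decay_chain(parent, as.data.frame(j$steps), terminal_stable = stable)
}

#' The shipped actinium-225 decay chain
#'
#' Loads the packaged nuclear-data file (branching-weighted mean alpha
#' energies for Ac-225 -> Fr-221 -> At-217 -> Bi-213 -> {Po-213 | Tl-209}
#' -> Pb-209 -> Bi-209, stable). Total alpha energy is about 27.5 MeV per
#' parent decay.
#'
#' @return A `decay_chain`.
#' @export
#' @examples
#' alpha_energy_per_decay(ac225_chain())
ac225_chain <- function() {
  read_decay_chain(system.file("extdata", "ac225_chain.json",
                               package = "pritdose", mustWork = TRUE))
}

#' Alpha energy released per parent decay
#'
#' Branching-weighted sum of mean alpha energies over the chain, i.e. the
#' energy locally deposited per parent decay under secular equilibrium and
#' total local absorption of alpha emissions. Order-independent.
#'
#' @param chain A [decay_chain()].
#' @return MeV per parent decay.
#' @export
alpha_energy_per_decay <- function(chain) {
  stopifnot(inherits(chain, "decay_chain"))
  sum(chain$steps$branching_fraction * chain$steps$mean_alpha_energy_mev)
}
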