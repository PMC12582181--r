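# Receptor-saturation analysis of hapten mass-dose effects, and
# internalization-assay kinetics summaries.
#
# Fractional tumor uptake of the radiohapten falls with administered mass
# because the pretargeted antigen sites are saturable. A single-site
# Langmuir form with the administered amount as free-ligand proxy,
#
#   uptake(m) = 100 * bmax / (km + m)   [%IA/g],
#
# is the minimal model reproducing the observed low- and high-mass
# uptakes; bmax is the bindable capacity (nmol/g) and km the
# half-saturation administered amount (nmol).

#' Saturation model
#'
#' @param bmax Bindable capacity, nmol per g of tissue, `> 0`.
#' @param km Half-saturation administered amount, nmol, `> 0`.
#' @return An object of class `saturation_model`.
#' @export
saturation_model <- function(bmax, km) {
  if (bmax <= 0 || km <= 0) stop("bmax and km must be > 0", call. = FALSE)
  structure(list(bmax = bmax, km = km), class = "saturation_model")
}

#' @export
print.saturation_model <- function(x, ...) {
  cat(sprintf("<saturation_model> bmax = %.4g nmol/g, km = %.4g nmol\n",
              x$bmax, x$km))
  invisible(x)
}

#' Predicted fractional uptake at an administered mass
#'
#' `100 * bmax / (km + administered)` %IA/g: strictly decreasing in the
#' administered amount; the absolute bound amount per gram,
#' `uptake/100 * administered`, rises toward the asymptote `bmax`.
#'
#' @param model A `saturation_model` or `saturation_fit`.
#' @param administered_nmol Administered amount(s), nmol, `> 0`.
#' @return %IA/g (vectorised).
#' @export
#' @examples
#' m <- saturation_model(0.1037, 0.3894)
#' predicted_uptake(m, c(0.60, 26.9))
predicted_uptake <- function(model, administered_nmol) {
  if (inherits(model, "saturation_fit")) model <- model$model
  stopifnot(inherits(model, "saturation_model"))
  if (any(administered_nmol <= 0))
    stop("administered amount must be > 0", call. = FALSE)
  100 * model$bmax / (model$km + administered_nmol)
}

#' Calibrate the saturation model to observed uptakes
#'
#' Two observations give the exact algebraic solution; more than two are
#' fitted by least squares on log-uptake (multiplicative errors),
#' initialised from the extreme points.
#'
#' @param administered_nmol Administered amounts, nmol (distinct, `> 0`).
#' @param uptake Observed uptakes, %IA/g (`> 0`).
#' @return An object of class `saturation_fit` with elements `model`
#'   (a [saturation_model()]), `data`, `fitted`; methods `coef`,
#'   `predict`, `residuals`, `print`, `plot`.
#' @export
#' @examples
#' fit <- fit_saturation(c(0.60, 26.9), c(10.48, 0.38))
#' coef(fit)
fit_saturation <- function(administered_nmol, uptake) {
  m <- as.numeric(administered_nmol); u <- as.numeric(uptake)
  stopifnot(length(m) == length(u), length(m) >= 2L)
  if (any(m <= 0) || any(u <= 0))
    stop("amounts and uptakes must be > 0", call. = FALSE)
  if (length(unique(m)) < 2L)
    stop("need at least two distinct administered amounts", call. = FALSE)
  ord <- order(m)
  misfit <- any(diff(u[ord]) > 0)
  if (misfit)
    warning("uptake increases with administered mass; saturation model misfit")

  two_point <- function(m1, u1, m2, u2) {
    r <- u1 / u2                      # (km + m2) / (km + m1)
    km <- (m2 - r * m1) / (r - 1)
    bmax <- u1 * (km + m1) / 100
    if (!is.finite(km) || km <= 0 || bmax <= 0)
      stop("observations are inconsistent with a saturable model",
           call. = FALSE)
    c(bmax = bmax, km = km)
  }

  ls_fit <- function(init) {
    obj <- function(lp) {
      pred <- 100 * exp(lp[1L]) / (exp(lp[2L]) + m)
      sum((log(u) - log(pred))^2)
    }
    opt <- stats::optim(log(init), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    c(bmax = exp(opt$par[[1L]]), km = exp(opt$par[[2L]]))
  }
  # misfitting (non-decreasing) data have no two-point solution; fall back
  # to constrained least squares from a flat-curve start
  flat_init <- function() {
    km0 <- 10 * max(m)
    c(bmax = mean(u) / 100 * km0, km = km0)
  }
  if (length(m) == 2L) {
    p <- if (misfit) ls_fit(flat_init())
         else two_point(m[ord][1L], u[ord][1L], m[ord][2L], u[ord][2L])
  } else {
    init <- if (misfit) flat_init()
            else two_point(m[ord][1L], u[ord][1L],
                           m[ord][length(m)], u[ord][length(m)])
    p <- ls_fit(init)
  }

  model <- saturation_model(p[["bmax"]], p[["km"]])
  structure(
    list(model = model,
         data = data.frame(administered_nmol = m, uptake = u),
         fitted = predicted_uptake(model, m)),
    class = "saturation_fit"
  )
}

#' @export
coef.saturation_fit <- function(object, ...) {
  c(bmax = object$model$bmax, km = object$model$km)
}

#' @export
predict.saturation_fit <- function(object, administered_nmol = NULL, ...) {
  if (is.null(administered_nmol))
    administered_nmol <- object$data$administered_nmol
  predicted_uptake(object$model, administered_nmol)
}

#' @export
residuals.saturation_fit <- function(object, ...) {
  log(object$data$uptake) - log(object$fitted)
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("Saturable-uptake fit: uptake = 100 * bmax / (km + m)\n")
  print(x$model)
  cat(sprintf("  %d observations, max |log residual| = %.3g\n",
              nrow(x$data), max(abs(residuals(x)))))
  invisible(x)
}

#' @export
plot.saturation_fit <- function(x, ...) {
  d <- x$data
  grid <- exp(seq(log(min(d$administered_nmol) / 2),
                  log(max(d$administered_nmol) * 2), length.out = 200))
  graphics::plot(d$administered_nmol, d$uptake, log = "xy",
                 xlab = "administered amount (nmol)",
                 ylab = "uptake (%IA/g)", pch = 19, ...)
  graphics::lines(grid, predicted_uptake(x$model, grid))
  invisible(x)
}

# ---- internalization kinetics ----------------------------------------

#' Internalization assay series
#'
#' Membrane-bound and internalized activity per time point, in percent of
#' added activity per 10^6 cells (any common unit works; the summaries
#' are scale-invariant).
#'
#' @param time_h Assay times, hours, strictly increasing.
#' @param membrane Membrane-bound activity per time point, `>= 0`.
#' @param internalized Internalized activity per time point, `>= 0`.
#' @return A data.frame of class `internalization_series`.
#' @export
internalization_series <- function(time_h, membrane, internalized) {
  stopifnot(length(time_h) == length(membrane),
            length(time_h) == length(internalized))
  if (any(diff(time_h) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(membrane < 0) || any(internalized < 0))
    stop("activities must be >= 0", call. = FALSE)
  structure(data.frame(time_h = time_h, membrane = membrane,
                       internalized = internalized),
            class = c("internalization_series", "data.frame"))
}

#' Internalized fraction per time point
#'
#' `internalized / (membrane + internalized)` at each time. Time points
#' with zero total are undefined and returned as `NA` (flagged via the
#' `"undefined"` attribute), never as 0.
#'
#' @param series An [internalization_series()].
#' @return Numeric vector of fractions in \[0, 1\] (with possible `NA`s);
#'   attribute `"undefined"` holds the indices of zero-total points.
#' @export
#' @examples
#' s <- internalization_series(c(1, 24), c(9.1, 7.2), c(0.9, 2.8))
#' internalized_fraction(s)
internalized_fraction <- function(series) {
  total <- series$membrane + series$internalized
  f <- ifelse(total > 0, series$internalized / total, NA_real_)
  attr(f, "undefined") <- which(total <= 0)
  f
}

#' Overall internalized percentage by AUC
#'
#' 100 x trapezoidal AUC of the internalized channel over the AUC of the
#' total bound channel, on the observed span (no extrapolation).
#' Invariant to uniform rescaling of both channels.
#'
#' @param series An [internalization_series()] with `>= 2` points.
#' @return Percent, in \[0, 100\].
#' @export
auc_internalized_percent <- function(series) {
  if (nrow(series) < 2L)
    stop("need at least 2 time points", call. = FALSE)
  auc_i <- .trapz(series$time_h, series$internalized)
  auc_t <- .trapz(series$time_h, series$membrane + series$internalized)
  if (auc_t <= 0) stop("total-bound AUC is zero", call. = FALSE)
  100 * auc_i / auc_t
}
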