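# Time-integrated activity (TIA): turn serial %IA/g samples into the total
# number of decays per gram per administered kBq, MIRD-style.
#
# Integration runs on the *physical* (decay-inclusive) curve. A leading
# segment holds the first observed value constant back to t = 0; the tail
# beyond the last sample is either pure physical decay (A_last / lambda,
# the conservative default), a fitted monoexponential (A_last / lambda_eff
# with lambda_eff >= lambda estimated from the last points), or nothing.

#' Time-activity curve
#'
#' Per-tissue activity concentration over time. `decay_corrected = FALSE`
#' means the values include physical decay (what a gamma counter sees,
#' referenced to injection); integration requires this convention.
#'
#' @param tissue Tissue label.
#' @param time_h Sampling times, hours, strictly increasing, `>= 0`.
#' @param activity Activity concentration at each time, %IA/g, `>= 0`.
#' @param decay_corrected Logical flag; see Details.
#' @param provenance Free-text description of the data source.
#' @return An object of class `tac`.
#' @export
time_activity_curve <- function(tissue, time_h, activity,
                                decay_corrected = FALSE, provenance = "") {
  stopifnot(length(time_h) == length(activity), length(time_h) >= 1L)
  if (any(diff(time_h) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(time_h < 0) || any(activity < 0))
    stop("times and activities must be >= 0", call. = FALSE)
  structure(
    list(tissue = tissue, time_h = as.numeric(time_h),
         activity = as.numeric(activity),
         decay_corrected = isTRUE(decay_corrected),
         provenance = provenance),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s: %d points over [%g, %g] h (%s)\n", x$tissue,
              length(x$time_h), min(x$time_h), max(x$time_h),
              if (x$decay_corrected) "decay-corrected" else "physical"))
  invisible(x)
}

#' Remove decay correction from a curve
#'
#' Multiplies each decay-corrected activity by the physical decay factor
#' at its sampling time, producing the physical curve that integration
#' needs. Refuses curves that are already physical, so the decay
#' convention is always explicit.
#'
#' @param curve A decay-corrected [time_activity_curve()].
#' @param nuclide The [nuclide()] whose decay was corrected out.
#' @return A physical (`decay_corrected = FALSE`) `tac`.
#' @export
undecay_correct <- function(curve, nuclide) {
  stopifnot(inherits(curve, "tac"))
  if (!curve$decay_corrected)
    stop("curve is already physical (not decay-corrected)", call. = FALSE)
  out <- curve
  out$activity <- curve$activity * decay_factor(nuclide, curve$time_h)
  out$decay_corrected <- FALSE
  out
}

.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Integrate a time-activity curve
#'
#' Trapezoidal integration over the observed span, plus a leading segment
#' (first observed value held constant back to t = 0) and a tail beyond
#' the last sample:
#' \describe{
#'   \item{`physical-decay`}{`A_last / lambda` — no biological clearance
#'     assumed beyond the last sample (conservative default).}
#'   \item{`fitted-monoexponential`}{`A_last / lambda_eff`, with
#'     `lambda_eff` from a log-linear fit to the last `n_tail` points;
#'     must satisfy `lambda_eff >= lambda`, otherwise falls back to
#'     physical decay with a warning.}
#'   \item{`none`}{0.}
#' }
#'
#' @param curve A physical [time_activity_curve()] (use
#'   [undecay_correct()] first if needed).
#' @param nuclide The decaying [nuclide()].
#' @param tail_model One of `"physical-decay"`, `"fitted-monoexponential"`,
#'   `"none"`.
#' @param n_tail Number of trailing points used for the fitted tail
#'   (default 3, at least 2).
#' @return An object of class `tia_result` with fields `tissue`, `tia`
#'   (%IA·h/g), `tail_model`, `tail_fraction`.
#' @export
#' @examples
#' ac <- nuclide("Ac-225", 9.92, "d")
#' cv <- time_activity_curve("tumor", 0, 10)
#' integrate_tac(cv, ac)$tia # 10 / lambda
integrate_tac <- function(curve, nuclide,
                          tail_model = c("physical-decay",
                                         "fitted-monoexponential", "none"),
                          n_tail = 3L) {
  stopifnot(inherits(curve, "tac"), inherits(nuclide, "nuclide"))
  tail_model <- match.arg(tail_model)
  if (curve$decay_corrected)
    stop("curve is decay-corrected; apply undecay_correct() first",
         call. = FALSE)
  t <- curve$time_h; a <- curve$activity
  lambda <- nuclide$decay_constant
  lead <- t[1L] * a[1L]                      # hold first value back to 0
  body <- .trapz(t, a)
  a_last <- a[length(a)]

  used_model <- tail_model
  tail <- 0
  if (tail_model == "physical-decay") {
    tail <- a_last / lambda
  } else if (tail_model == "fitted-monoexponential") {
    if (length(t) < 2L)
      stop("fitted tail requires at least 2 points", call. = FALSE)
    k <- max(2L, min(as.integer(n_tail), length(t)))
    idx <- seq.int(length(t) - k + 1L, length(t))
    tt <- t[idx]; aa <- a[idx]
    if (any(aa <= 0)) {
      warning("non-positive activity in tail window; using physical-decay tail")
      used_model <- "physical-decay"
      tail <- a_last / lambda
    } else {
      lambda_eff <- -stats::coef(stats::lm(log(aa) ~ tt))[[2L]]
      if (lambda_eff < lambda * (1 - 1e-9)) {
        warning("fitted tail slower than physical decay (rising tail); ",
                "falling back to physical-decay")
        used_model <- "physical-decay"
        tail <- a_last / lambda
      } else {
        tail <- a_last / lambda_eff
      }
    }
  }

  tia <- lead + body + tail
  structure(
    list(tissue = curve$tissue, tia = tia, tail_model = used_model,
         tail_fraction = if (tia > 0) tail / tia else 0),
    class = "tia_result"
  )
}

#' @export
print.tia_result <- function(x, ...) {
  cat(sprintf("<tia> %s: %.4g %%IA.h/g (tail %s, %.1f%% of total)\n",
              x$tissue, x$tia, x$tail_model, 100 * x$tail_fraction))
  invisible(x)
}

#' Group a biodistribution table into per-tissue mean curves
#'
#' Averages `pia_g_mean` per (tissue, time) and builds one physical
#' [time_activity_curve()] per tissue, removing any decay correction
#' declared in the table.
#'
#' @param samples A `biodist` data.frame ([read_biodist()] schema).
#' @param nuclide The [nuclide()] used for un-decay-correction.
#' @return Named list of `tac` objects, one per tissue.
#' @export
biodist_to_tac <- function(samples, nuclide) {
  samples <- as.data.frame(samples)
  split_by <- split(samples, samples$tissue)
  lapply(split_by, function(d) {
    d <- d[order(d$time_h), ]
    agg <- stats::aggregate(pia_g_mean ~ time_h, data = d, FUN = mean)
    dc <- unique(d$decay_corrected)
    if (length(dc) != 1L)
      stop("mixed decay_corrected flags within tissue ", d$tissue[1L],
           call. = FALSE)
    cv <- time_activity_curve(d$tissue[1L], agg$time_h, agg$pia_g_mean,
                              decay_corrected = dc,
                              provenance = "biodist table")
    if (dc) cv <- undecay_correct(cv, nuclide)
    cv
  })
}

#' Export TIA results as a data.frame
#'
#' @param x A list of `tia_result` objects (e.g. per tissue).
#' @return data.frame with columns `tissue`, `tia`, `tail_model`,
#'   `tail_fraction`, suitable for `write.csv`.
#' @export
tia_table <- function(x) {
  if (inherits(x, "tia_result")) x <- list(x)
  do.call(rbind, lapply(x, function(r)
    data.frame(tissue = r$tissue, tia = r$tia, tail_model = r$tail_model,
               tail_fraction = r$tail_fraction, stringsAsFactors = FALSE)))
}
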