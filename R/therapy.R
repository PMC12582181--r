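# Tumor-response classification, size-based endpoint times, and native
# survival statistics: Kaplan-Meier product-limit estimation, median
# survival and the Mantel-Cox (log-rank) test.
#
# "Survival" here is time to a tumor-size endpoint (volume doubling, or a
# 10-mm diameter), with deaths from any other cause counted as events at
# the death time; animals that never reach the endpoint are right-censored
# at last follow-up.

#' Per-animal tumor measurement series
#'
#' @param animal_id Animal label.
#' @param day Measurement days, increasing; day 0 is treatment start.
#' @param value Measured sizes, `>= 0`.
#' @param type `"volume"` (mm^3) or `"diameter"` (mm).
#' @param group Optional group label.
#' @param baseline Baseline size; defaults to the day-0 measurement.
#' @return A data.frame of class `tumor_series` with attributes `type`,
#'   `baseline`, `animal_id`, `group`.
#' @export
tumor_series <- function(animal_id, day, value,
                         type = c("volume", "diameter"), group = NA_character_,
                         baseline = NULL) {
  type <- match.arg(type)
  stopifnot(length(day) == length(value), length(day) >= 1L)
  if (any(diff(day) <= 0)) stop("days must be increasing", call. = FALSE)
  if (any(value < 0)) stop("sizes must be >= 0", call. = FALSE)
  if (is.null(baseline)) {
    if (day[1L] != 0)
      stop("no day-0 measurement; supply `baseline` explicitly",
           call. = FALSE)
    baseline <- value[1L]
  }
  col <- if (type == "volume") "volume_mm3" else "diameter_mm"
  d <- data.frame(animal_id = animal_id, group = group, day = day)
  d[[col]] <- value
  structure(d, type = type, baseline = baseline, animal_id = animal_id,
            group = group, class = c("tumor_series", "data.frame"))
}

#' Classify tumor response
#'
#' Complete response iff the final recorded volume is at or below the
#' threshold (inclusive); judged on the final measurement, not the
#' any-time minimum, so regrowth after a transient dip is not a CR.
#'
#' @param series A volume-typed [tumor_series()].
#' @param threshold_mm3 CR threshold, mm^3 (default 4.2).
#' @return `"complete_response"` or `"no_complete_response"`.
#' @export
#' @examples
#' s <- tumor_series("a1", c(0, 30), c(100, 4.2))
#' classify_response(s)
classify_response <- function(series, threshold_mm3 = 4.2) {
  stopifnot(inherits(series, "tumor_series"))
  if (attr(series, "type") != "volume")
    stop("complete response is defined on volumes, not diameters",
         call. = FALSE)
  final <- series$volume_mm3[nrow(series)]
  if (final <= threshold_mm3) "complete_response" else "no_complete_response"
}

#' Endpoint time from a tumor series
#'
#' First day the size criterion holds: volume doubling relative to
#' baseline, or a diameter of `threshold_mm`. Crossings between
#' measurement days are located by linear interpolation (default) or, if
#' `interpolate = FALSE`, at the first measurement past the threshold.
#' If the criterion is never met the animal is censored at the last
#' observation day.
#'
#' @param series A [tumor_series()].
#' @param rule `"doubling"` (volume series) or `"diameter_10mm"`
#'   (diameter series).
#' @param threshold_mm Diameter threshold for `"diameter_10mm"`
#'   (default 10).
#' @param interpolate Linear interpolation between bracketing days?
#' @return `list(time, event)`: days, and whether the endpoint was
#'   reached (`FALSE` = censored).
#' @export
#' @examples
#' s <- tumor_series("a1", c(0, 7, 14), c(100, 150, 250))
#' endpoint_time(s, "doubling") # 10.5 d, event
endpoint_time <- function(series, rule = c("doubling", "diameter_10mm"),
                          threshold_mm = 10, interpolate = TRUE) {
  stopifnot(inherits(series, "tumor_series"))
  rule <- match.arg(rule)
  type <- attr(series, "type")
  if (rule == "doubling") {
    if (type != "volume")
      stop("doubling rule requires a volume series", call. = FALSE)
    y <- series$volume_mm3
    threshold <- 2 * attr(series, "baseline")
  } else {
    if (type != "diameter")
      stop("diameter rule requires a diameter series", call. = FALSE)
    y <- series$diameter_mm
    threshold <- threshold_mm
  }
  day <- series$day
  hit <- which(y >= threshold)
  if (!length(hit))
    return(list(time = day[length(day)], event = FALSE))
  i <- hit[1L]
  if (i == 1L || !interpolate || y[i] == threshold)
    return(list(time = day[i], event = TRUE))
  # linear interpolation between the bracketing measurements
  t_cross <- day[i - 1L] +
    (threshold - y[i - 1L]) / (y[i] - y[i - 1L]) * (day[i] - day[i - 1L])
  list(time = t_cross, event = TRUE)
}

#' Build survival records from tumor series
#'
#' @param series_list List of [tumor_series()].
#' @param rule Endpoint rule passed to [endpoint_time()].
#' @param deaths Optional named vector of death days (other causes);
#'   a death before the endpoint is an event at the death time.
#' @param ... Passed to [endpoint_time()].
#' @return data.frame with columns `animal_id`, `group`, `time_d`,
#'   `event`, `reason`.
#' @export
survival_records <- function(series_list, rule = "doubling", deaths = NULL,
                             ...) {
  do.call(rbind, lapply(series_list, function(s) {
    ep <- endpoint_time(s, rule, ...)
    time <- ep$time; event <- ep$event; reason <- if (event) rule else "censored"
    id <- attr(s, "animal_id")
    if (!is.null(deaths) && id %in% names(deaths) && deaths[[id]] <= time) {
      time <- deaths[[id]]; event <- TRUE; reason <- "death"
    }
    data.frame(animal_id = id, group = attr(s, "group"), time_d = time,
               event = event, reason = reason, stringsAsFactors = FALSE)
  }))
}

#' Kaplan-Meier product-limit estimate
#'
#' Native implementation: at each distinct event time, the survival
#' probability is multiplied by `1 - d/n`; censored times reduce the
#' risk set without producing a step. With no censoring the estimate
#' equals the empirical survival function.
#'
#' @param time Event/censoring times, `> 0`.
#' @param event Logical (or 0/1) event indicators.
#' @return An object of class `km_fit`: data.frame `$table` with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`; plus `$n` and
#'   `$max_time`.
#' @export
#' @examples
#' f <- km_fit(c(1, 1.5, 2), c(TRUE, FALSE, TRUE))
#' f$table
km_fit <- function(time, event) {
  event <- as.logical(event)
  stopifnot(length(time) == length(event))
  if (any(time <= 0)) stop("times must be > 0", call. = FALSE)
  if (anyNA(time) || anyNA(event)) stop("missing values", call. = FALSE)
  ut <- sort(unique(time))
  n <- length(time)
  at_risk <- vapply(ut, function(t) sum(time >= t), numeric(1L))
  d <- vapply(ut, function(t) sum(time == t & event), numeric(1L))
  cns <- vapply(ut, function(t) sum(time == t & !event), numeric(1L))
  surv <- cumprod(1 - d / at_risk)
  structure(
    list(table = data.frame(time = ut, n_risk = at_risk, n_event = d,
                            n_censor = cns, surv = surv),
         n = n, max_time = max(time)),
    class = "km_fit"
  )
}

#' Survival probability at given times
#'
#' @param object A `km_fit`.
#' @param times Times at which to evaluate the step function.
#' @param ... Unused.
#' @return S(t) at each time (1 before the first event).
#' @export
predict.km_fit <- function(object, times, ...) {
  tab <- object$table[object$table$n_event > 0, ]
  vapply(times, function(t) {
    i <- which(tab$time <= t)
    if (!length(i)) 1 else tab$surv[max(i)]
  }, numeric(1L))
}

#' @export
print.km_fit <- function(x, ...) {
  med <- median_survival(x)
  cat(sprintf("Kaplan-Meier fit: n = %d, %d events; median survival %s\n",
              x$n, sum(x$table$n_event),
              if (is.na(med)) sprintf("not reached (>%g d)", x$max_time)
              else sprintf("%g d", med)))
  invisible(x)
}

#' @export
summary.km_fit <- function(object, ...) {
  object$table
}

#' @export
plot.km_fit <- function(x, xlab = "time (d)", ylab = "S(t)", ...) {
  tab <- x$table[x$table$n_event > 0, ]
  graphics::plot(stats::stepfun(tab$time, c(1, tab$surv)),
                 do.points = FALSE, verticals = FALSE,
                 xlim = c(0, x$max_time), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Median survival time
#'
#' Smallest time with `S(t) <= 0.5`. If the curve never reaches 0.5 the
#' median is undefined: `NA` is returned with the last follow-up time as
#' attribute `"last_followup"` (report as "> last follow-up").
#'
#' @param fit A [km_fit()].
#' @return Days, or `NA` with attribute `"last_followup"`.
#' @export
median_survival <- function(fit) {
  stopifnot(inherits(fit, "km_fit"))
  tab <- fit$table
  i <- which(tab$surv <= 0.5)
  if (!length(i)) {
    out <- NA_real_
    attr(out, "last_followup") <- fit$max_time
    return(out)
  }
  tab$time[i[1L]]
}

#' Mantel-Cox (log-rank) test
#'
#' Native two-group log-rank test: at each distinct pooled event time a
#' 2x2 table contributes observed-minus-expected events and its
#' hypergeometric variance; the chi-square statistic (1 df) is
#' `(sum(O - E))^2 / sum(V)`. Symmetric under group swap.
#'
#' @param time Event/censoring times.
#' @param event Logical event indicators.
#' @param group Two-level group labels.
#' @return An object of classes `logrank_test` and `htest` with
#'   `statistic` (chi-square), `parameter` (df), `p.value`, and the
#'   per-group observed/expected counts in `$observed` / `$expected`.
#' @export
#' @examples
#' lr <- logrank_test(c(1, 2, 3, 10, 12, 14), rep(TRUE, 6),
#'                    rep(c("a", "b"), each = 3))
#' lr$p.value
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  group <- as.factor(group)
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (nlevels(group) != 2L)
    stop("log-rank test requires exactly 2 groups", call. = FALSE)
  if (any(table(group) == 0L)) stop("empty group", call. = FALSE)
  if (!any(event)) {
    warning("no events in either group; statistic undefined")
    out <- list(statistic = c(chisq = NA_real_), parameter = c(df = 1),
                p.value = NA_real_, method = "Mantel-Cox log-rank test",
                data.name = "survival records",
                observed = c(0, 0), expected = c(0, 0))
    class(out) <- c("logrank_test", "htest")
    return(out)
  }
  g1 <- levels(group)[1L]
  etimes <- sort(unique(time[event]))
  o_minus_e <- 0; v <- 0
  obs <- c(0, 0); expd <- c(0, 0)
  for (t in etimes) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & group == g1)
    d_j <- sum(time == t & event)
    d1_j <- sum(time == t & event & group == g1)
    e1_j <- d_j * n1_j / n_j
    o_minus_e <- o_minus_e + (d1_j - e1_j)
    if (n_j > 1L)
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    obs <- obs + c(d1_j, d_j - d1_j)
    expd <- expd + c(e1_j, d_j - e1_j)
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  out <- list(
    statistic = c(chisq = chisq), parameter = c(df = 1),
    p.value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    method = "Mantel-Cox log-rank test", data.name = "survival records",
    observed = stats::setNames(obs, levels(group)),
    expected = stats::setNames(expd, levels(group)))
  class(out) <- c("logrank_test", "htest")
  out
}
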