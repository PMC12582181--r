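# Ex vivo biodistribution data model: CSV reader/writer, unit conversion
# between %IA/g and pmol/g, and tissue uptake ratios.

.CORE_TISSUES <- c("tumor", "blood", "kidney", "liver", "spleen", "lung",
                   "heart", "muscle", "bone", "skin", "stomach",
                   "small intestine", "large intestine", "tail")

.BIODIST_COLS <- c("tissue", "time_h", "pia_g_mean", "pia_g_sd", "n",
                   "decay_corrected")

#' Administration record for a three-step PRIT regimen
#'
#' Captures the radiohapten injection (activity and molar amount) together
#' with the pretargeting schedule: bispecific antibody (BsAb) given first,
#' a clearing agent second, radiolabelled hapten last (time zero).
#'
#' @param activity_kbq Administered activity, kBq.
#' @param amount_nmol Administered hapten amount, nmol.
#' @param bsab_nmol BsAb amount, nmol (default 1.19).
#' @param bsab_time_h BsAb injection time, hours relative to hapten
#'   (default -28).
#' @param clearing_nmol Clearing-agent amount, nmol (default 2.76).
#' @param clearing_time_h Clearing-agent time, hours (default -4).
#' @param hapten_time_h Hapten time, hours (default 0).
#' @return An object of class `administration`; `specific_activity` is
#'   derived as `activity_kbq / amount_nmol` (kBq/nmol).
#' @export
#' @examples
#' administration(37, 0.60)$specific_activity
administration <- function(activity_kbq, amount_nmol,
                           bsab_nmol = 1.19, bsab_time_h = -28,
                           clearing_nmol = 2.76, clearing_time_h = -4,
                           hapten_time_h = 0) {
  if (activity_kbq < 0) stop("activity must be >= 0", call. = FALSE)
  if (amount_nmol <= 0) stop("amount must be > 0", call. = FALSE)
  if (!(bsab_time_h < clearing_time_h && clearing_time_h < hapten_time_h))
    stop("timing must satisfy bsab_time < clearing_time < hapten_time",
         call. = FALSE)
  structure(
    list(activity_kbq = activity_kbq, amount_nmol = amount_nmol,
         specific_activity = activity_kbq / amount_nmol,
         bsab_nmol = bsab_nmol, bsab_time_h = bsab_time_h,
         clearing_nmol = clearing_nmol, clearing_time_h = clearing_time_h,
         hapten_time_h = hapten_time_h),
    class = "administration"
  )
}

#' @export
print.administration <- function(x, ...) {
  cat(sprintf(
    "<administration> %g kBq / %g nmol (%.3g kBq/nmol); BsAb %g nmol @ %g h, CA %g nmol @ %g h, hapten @ %g h\n",
    x$activity_kbq, x$amount_nmol, x$specific_activity,
    x$bsab_nmol, x$bsab_time_h, x$clearing_nmol, x$clearing_time_h,
    x$hapten_time_h))
  invisible(x)
}

.validate_biodist <- function(df, file = "<data>") {
  missing_cols <- setdiff(.BIODIST_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad <- which(df$pia_g_mean < 0 | df$pia_g_sd < 0)
  if (length(bad))
    stop(sprintf("%s: negative uptake in row(s) %s", file,
                 paste(bad, collapse = ", ")), call. = FALSE)
  bad <- which(df$n < 1 | df$time_h < 0)
  if (length(bad))
    stop(sprintf("%s: invalid n or time in row(s) %s", file,
                 paste(bad, collapse = ", ")), call. = FALSE)
  df$decay_corrected <- as.logical(df$decay_corrected)
  if (anyNA(df$decay_corrected))
    stop(sprintf("%s: decay_corrected must be logical", file), call. = FALSE)
  unknown <- setdiff(unique(df$tissue), .CORE_TISSUES)
  if (length(unknown))
    warning("tissue label(s) outside the core vocabulary kept verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  class(df) <- c("biodist", "data.frame")
  df
}

#' Read a biodistribution CSV
#'
#' Expected schema (header required, UTF-8):
#' `tissue,time_h,pia_g_mean,pia_g_sd,n,decay_corrected`.
#' Uptake is percent injected activity per gram (%IA/g); `decay_corrected`
#' declares whether values were corrected back to injection time. Unknown
#' tissue labels are preserved verbatim with a warning.
#'
#' @param path CSV file path.
#' @return A data.frame of class `biodist`.
#' @export
read_biodist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .validate_biodist(df, file = path)
}

#' Write a biodistribution table as CSV
#'
#' @param x A `biodist` data.frame (schema of [read_biodist()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biodist <- function(x, path) {
  x <- .validate_biodist(as.data.frame(x))
  utils::write.csv(x[, .BIODIST_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Construct a biodistribution table in code
#'
#' Convenience constructor enforcing the [read_biodist()] schema.
#'
#' @param tissue,time_h,pia_g_mean,pia_g_sd,n,decay_corrected Column
#'   vectors (recycled by `data.frame`).
#' @return A data.frame of class `biodist`.
#' @export
biodist_table <- function(tissue, time_h, pia_g_mean, pia_g_sd = 0,
                          n = 1L, decay_corrected = FALSE) {
  .validate_biodist(data.frame(
    tissue = tissue, time_h = time_h, pia_g_mean = pia_g_mean,
    pia_g_sd = pia_g_sd, n = n, decay_corrected = decay_corrected,
    stringsAsFactors = FALSE))
}

#' Convert %IA/g to pmol/g
#'
#' The molar concentration corresponding to a fractional uptake, given the
#' administered molar amount: `uptake/100 * amount_nmol * 1000` pmol/g.
#' Linear in both arguments.
#'
#' @param uptake Uptake in %IA/g (vectorised, `>= 0`).
#' @param administered_nmol Administered amount, nmol (`> 0`).
#' @return pmol of compound per gram of tissue.
#' @export
#' @examples
#' pia_to_pmol(10.48, 0.60) # 62.88 pmol/g
pia_to_pmol <- function(uptake, administered_nmol) {
  if (any(uptake < 0)) stop("uptake must be >= 0", call. = FALSE)
  if (any(administered_nmol <= 0))
    stop("administered amount must be > 0", call. = FALSE)
  uptake / 100 * administered_nmol * 1000
}

#' Tissue-to-tissue uptake ratio
#'
#' Ratio of mean uptakes of two samples taken at the same time point
#' (e.g. tumor-to-blood). Computed from tissue means, full precision;
#' set `digits` to round for display.
#'
#' @param a,b Single rows of a `biodist` table (numerator, denominator).
#' @param digits Optional rounding for the returned value (default none).
#' @return Dimensionless ratio.
#' @export
#' @examples
#' bd <- biodist_table(c("tumor", "blood"), 24, c(10.48, 0.68))
#' uptake_ratio(bd[1, ], bd[2, ], digits = 1) # 15.4
uptake_ratio <- function(a, b, digits = NULL) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (a$time_h != b$time_h)
    stop("samples are from different time points (", a$time_h, " vs ",
         b$time_h, " h)", call. = FALSE)
  if (b$pia_g_mean <= 0)
    stop("denominator uptake must be > 0", call. = FALSE)
  r <- a$pia_g_mean / b$pia_g_mean
  if (!is.null(digits)) r <- round(r, digits)
  r
}
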