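#' Kovats retention index under a linear temperature programme
#'
#' Converts a GC retention time into a retention index on the n-alkane
#' scale using the van den Dool--Kratz (temperature-programmed) form:
#' linear interpolation between the bracketing calibration alkanes,
#' `KI = 100 n + 100 (rt - t_n) / (t_(n+1) - t_n)`. Every calibration
#' alkane therefore maps exactly onto 100 times its carbon number, and the
#' index is strictly increasing in retention time across the calibrated
#' range. The classical isothermal (logarithmic) Kovats formula is
#' available via `method = "isothermal"`.
#'
#' @param rt Retention time(s), same units as the calibration.
#' @param calibration A data frame with columns `carbon` (alkane carbon
#'   number, e.g. 8:20 for a C8--C20 standard) and `rt` (retention time),
#'   strictly increasing in both.
#' @param extrapolate If `FALSE` (default), retention times outside the
#'   calibrated range are an error; if `TRUE`, the nearest segment is
#'   extended linearly (isothermal method: log-linearly).
#' @param method `"programmed"` (van den Dool--Kratz, default) or
#'   `"isothermal"` (log interpolation).
#' @return Numeric retention index/indices.
#' @export
#' @examples
#' cal <- tibble::tibble(carbon = 8:20, rt = seq(2, 26, by = 2))
#' kovats_index(cal$rt[3], cal)          # exactly 1000
#' kovats_index(21.4, tibble::tibble(carbon = 14:15, rt = c(20, 22)))  # 1470
kovats_index <- function(rt, calibration, extrapolate = FALSE,
                         method = c("programmed", "isothermal")) {
  method <- match.arg(method)
  if (!all(c("carbon", "rt") %in% names(calibration))) {
    abort("`calibration` needs columns `carbon` and `rt`.")
  }
  cal <- dplyr::arrange(as_tibble(calibration), .data$carbon)
  if (nrow(cal) < 2) abort("Need at least two calibration alkanes.")
  if (any(diff(cal$rt) <= 0)) {
    abort("Calibration retention times must be strictly increasing in carbon number.")
  }
  out_of_range <- rt < cal$rt[1] | rt > cal$rt[nrow(cal)]
  if (any(out_of_range) && !extrapolate) {
    abort(paste0("Retention time outside the calibrated range [",
                 cal$rt[1], ", ", cal$rt[nrow(cal)],
                 "]; set `extrapolate = TRUE` to extend the end segments."))
  }
  # bracketing segment per rt; clamp to end segments when extrapolating
  seg <- findInterval(rt, cal$rt, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(cal) - 1L)
  n0 <- cal$carbon[seg]
  n1 <- cal$carbon[seg + 1L]
  t0 <- cal$rt[seg]
  t1 <- cal$rt[seg + 1L]
  frac <- switch(method,
    programmed = (rt - t0) / (t1 - t0),
    isothermal = (log(rt) - log(t0)) / (log(t1) - log(t0))
  )
  100 * (n0 + frac * (n1 - n0))
}
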