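#' Ventilated respiratory cycle model
#'
#' Describes one mechanically ventilated breathing cycle for the purpose of
#' acquisition planning. The trigger instant (t = 0) is modeled as the onset
#' of the end-expiration plateau, so a motion-free window of length
#' `plateau_ms - guard_ms` opens at the start of every cycle. Timing is kept
#' as exact reals; rounding happens only in display helpers.
#'
#' @param rate Ventilation rate in breaths per minute (> 0). Default 45, the
#'   standard rate for a ventilated adult rat.
#' @param ie_ratio Inspiration:expiration ratio as a length-2 positive numeric
#'   vector, default `c(1, 2)`.
#' @param plateau_ms Usable motion-free window length in ms, measured from the
#'   trigger point. Default `0.4 * period`: the end-expiration plateau
#'   occupies roughly 40% of a regular ventilated cycle (about 533 ms at
#'   45 bpm, consistent with observed 500-550 ms plateaus).
#' @param trigger_window_ms Prospective trigger window length in ms
#'   (default 10). A short window pinned to the plateau onset makes the
#'   inversion instant reproducible across repetitions.
#' @param readout_ms Duration of the echo-planar readout in ms (default 50).
#' @param guard_ms Safety margin subtracted from the end of each plateau
#'   (default 0).
#'
#' @return An object of class `respiration_model` with fields `rate`,
#'   `ie_ratio`, `period_ms`, `plateau_ms`, `trigger_window_ms`,
#'   `readout_ms`, `guard_ms`.
#' @examples
#' m <- respiration_model(rate = 45)
#' m$period_ms            # 1333.333...
#' m$plateau_ms           # 533.333...
#' @export
respiration_model <- function(rate = 45, ie_ratio = c(1, 2),
                              plateau_ms = NULL, trigger_window_ms = 10,
                              readout_ms = 50, guard_ms = 0) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number (breaths per minute)")
  if (length(ie_ratio) != 2L || any(!is.finite(ie_ratio)) || any(ie_ratio <= 0))
    stop("'ie_ratio' must be two positive numbers (inspiration, expiration)")
  period <- cycle_period(rate)
  if (is.null(plateau_ms)) plateau_ms <- 0.4 * period
  if (!is.finite(plateau_ms) || plateau_ms < 0)
    stop("'plateau_ms' must be a non-negative number")
  if (plateau_ms >= period)
    stop("'plateau_ms' must be shorter than the respiratory period (",
         format(period), " ms)")
  if (!is.finite(readout_ms) || readout_ms < 0)
    stop("'readout_ms' must be non-negative")
  if (!is.finite(guard_ms) || guard_ms < 0)
    stop("'guard_ms' must be non-negative")
  structure(list(rate = rate, ie_ratio = as.numeric(ie_ratio),
                 period_ms = period, plateau_ms = plateau_ms,
                 trigger_window_ms = trigger_window_ms,
                 readout_ms = readout_ms, guard_ms = guard_ms),
            class = "respiration_model")
}

#' @export
print.respiration_model <- function(x, ...) {
  cat("Respiration model:", x$rate, "bpm, I:E ",
      paste(x$ie_ratio, collapse = ":"), "\n")
  cat(sprintf("  period  %s ms (display %d ms)\n",
              format(x$period_ms), display_period_ms(x$rate)))
  cat(sprintf("  plateau %.1f ms (%.0f%% of cycle), guard %.1f ms\n",
              x$plateau_ms, 100 * x$plateau_ms / x$period_ms, x$guard_ms))
  cat(sprintf("  trigger window %.1f ms, readout %.1f ms\n",
              x$trigger_window_ms, x$readout_ms))
  invisible(x)
}

#' Respiratory cycle period
#'
#' Exact cycle period for a given ventilation rate. The value is kept as an
#' exact real (45 bpm gives 1333.333... ms); use [display_period_ms()] for
#' the integer-ms display form. Pre-rounding the period would misclassify
#' long inversion times several cycles after the trigger.
#'
#' @param rate Breaths per minute (> 0).
#' @return Period in ms, `60000 / rate`.
#' @examples
#' cycle_period(45)   # 1333.333
#' cycle_period(60)   # 1000
#' @export
cycle_period <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate <= 0))
    stop("'rate' must be positive (breaths per minute)")
  60000 / rate
}

#' @rdname cycle_period
#' @return `display_period_ms` returns the period floored to integer ms.
#' @export
display_period_ms <- function(rate) as.integer(floor(cycle_period(rate)))

#' @rdname cycle_period
#' @return `effective_tr_s` returns the respiratory-gated effective repetition
#'   time in seconds (one trigger per cycle), rounded to two decimals for
#'   display (1.33 s at 45 bpm).
#' @export
effective_tr_s <- function(rate) round(cycle_period(rate) / 1000, 2)

#' Motion-free windows of a respiration model
#'
#' Enumerates the end-expiration plateau windows, as half-open intervals
#' `[start, end)` in ms relative to the trigger, over a finite horizon.
#' Window k starts at `k * period` and extends for `plateau_ms - guard_ms`.
#'
#' @param model A [respiration_model()].
#' @param horizon_ms Positive horizon in ms; windows starting before it are
#'   returned.
#' @return A data frame with columns `k` (0-based cycle index), `start_ms`,
#'   `end_ms`. Windows may be empty (`end_ms == start_ms`) when the guard
#'   consumes the plateau.
#' @examples
#' m <- respiration_model(45)
#' motion_free_windows(m, 3000)
#' @export
motion_free_windows <- function(model, horizon_ms) {
  stopifnot(inherits(model, "respiration_model"))
  if (!is.numeric(horizon_ms) || length(horizon_ms) != 1L || horizon_ms <= 0)
    stop("'horizon_ms' must be a single positive number")
  P <- model$period_ms
  width <- max(model$plateau_ms - model$guard_ms, 0)
  k <- seq(0L, floor((horizon_ms - 1e-9) / P))
  data.frame(k = k, start_ms = k * P, end_ms = k * P + width)
}

#' Is an inversion time motion-free?
#'
#' An inversion time TI is motion-free when the delayed readout interval
#' `[TI, TI + readout_ms]` lies wholly inside one end-expiration window,
#' i.e. `(TI mod period) <= plateau_ms - guard_ms - readout_ms`. The
#' inversion pulse itself fires at t = 0, the onset of window 0.
#'
#' @param ti Inversion time(s) in ms (> 0); vectorized.
#' @param model A [respiration_model()].
#' @return Logical vector, one element per `ti`.
#' @examples
#' m <- respiration_model(45)
#' is_ti_motion_free(c(100, 700, 5500), m)   # TRUE FALSE TRUE
#' @export
is_ti_motion_free <- function(ti, model) {
  stopifnot(inherits(model, "respiration_model"))
  if (any(!is.finite(ti)) || any(ti <= 0))
    stop("'ti' must be positive inversion times in ms")
  limit <- model$plateau_ms - model$guard_ms - model$readout_ms
  (ti %% model$period_ms) <= limit + 1e-9
}
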