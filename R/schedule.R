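#' Inversion-time schedule
#'
#' A validated, strictly increasing list of inversion times together with the
#' readout duration and a record of how it was generated.
#'
#' @param tis_ms Strictly increasing positive inversion times in ms
#'   (length >= 2).
#' @param mode One of `"geometric"`, `"motion_free"`, `"explicit"`.
#' @param readout_ms Readout duration in ms (default 50).
#' @param provenance Free-text description of how the schedule was generated.
#' @return An object of class `ti_schedule`.
#' @export
ti_schedule <- function(tis_ms, mode = c("explicit", "geometric", "motion_free"),
                        readout_ms = 50, provenance = "") {
  mode <- match.arg(mode)
  tis_ms <- as.numeric(tis_ms)
  if (length(tis_ms) < 2L)
    stop("a schedule needs at least 2 inversion times")
  if (any(!is.finite(tis_ms)) || any(tis_ms <= 0))
    stop("all inversion times must be positive and finite")
  if (any(diff(tis_ms) <= 0))
    stop("inversion times must be strictly increasing")
  structure(list(tis_ms = tis_ms, mode = mode, readout_ms = readout_ms,
                 provenance = provenance),
            class = "ti_schedule")
}

#' @export
print.ti_schedule <- function(x, ...) {
  cat(sprintf("TI schedule (%s, %d TIs, readout %.0f ms)\n",
              x$mode, length(x$tis_ms), x$readout_ms))
  cat(" ", paste(format(round(x$tis_ms, 2)), collapse = " "), "\n")
  invisible(x)
}

#' Geometric inversion-time series
#'
#' The vendor-default TI placement: a geometric progression from `ti_min` to
#' `ti_max`, sampling the recovery curve densely at short delays. Used for
#' free-breathing acquisitions where motion-free instants cannot be
#' pre-computed.
#'
#' @param n Number of inversion times (>= 2).
#' @param ti_min,ti_max First and last inversion time in ms,
#'   `0 < ti_min < ti_max`.
#' @return A [ti_schedule()] with `TI_k = ti_min * r^(k-1)`,
#'   `r = (ti_max/ti_min)^(1/(n-1))`; the endpoints are hit exactly.
#' @examples
#' plan_geometric_tis(16, 100, 4500)
#' @export
plan_geometric_tis <- function(n, ti_min, ti_max) {
  check_ti_plan_args(n, ti_min, ti_max)
  r <- (ti_max / ti_min)^(1 / (n - 1))
  tis <- ti_min * r^(seq_len(n) - 1)
  tis[1] <- ti_min; tis[n] <- ti_max
  ti_schedule(tis, mode = "geometric",
              provenance = sprintf("geometric series n=%d, %g..%g ms, ratio %.6g",
                                   n, ti_min, ti_max, r))
}

#' Motion-free inversion-time planner
#'
#' Pre-computes a list of inversion times such that, for a regular ventilated
#' cycle, both the inversion pulse (at the trigger) and the delayed readout
#' fall inside end-expiration plateaus. Candidate targets are placed
#' log-uniformly across `[ti_min, ti_max]` (mirroring the dense-early
#' geometric coverage) and each target is snapped to the nearest valid
#' instant on a 10 ms grid, ties broken toward the earlier instant. The
#' result is deterministic for fixed inputs.
#'
#' @param model A [respiration_model()].
#' @param n Number of inversion times (>= 2).
#' @param ti_min,ti_max Range of admissible inversion times in ms.
#' @param granularity_ms Spacing of the candidate instant grid (default 10,
#'   the trigger-window scale); also the minimum separation of returned TIs.
#' @return A [ti_schedule()] whose every TI satisfies [is_ti_motion_free()].
#' @examples
#' m <- respiration_model(45)
#' sched <- plan_motion_free_tis(m, n = 14, ti_min = 100, ti_max = 5500)
#' all(is_ti_motion_free(sched$tis_ms, m))
#' @export
plan_motion_free_tis <- function(model, n, ti_min, ti_max,
                                 granularity_ms = 10) {
  stopifnot(inherits(model, "respiration_model"))
  check_ti_plan_args(n, ti_min, ti_max)
  g <- granularity_ms
  grid <- seq(ceiling(ti_min / g) * g, floor(ti_max / g) * g, by = g)
  grid <- grid[grid > 0]
  valid <- grid[is_ti_motion_free(grid, model)]
  if (length(valid) < n)
    stop(sprintf(paste0(
      "infeasible schedule: only %d motion-free instants at %g ms granularity ",
      "in [%g, %g] ms (plateau %.1f ms - guard %.1f ms - readout %.1f ms ",
      "leaves %.1f ms per cycle), but %d TIs requested"),
      length(valid), g, ti_min, ti_max, model$plateau_ms, model$guard_ms,
      model$readout_ms,
      model$plateau_ms - model$guard_ms - model$readout_ms, n))
  targets <- exp(seq(log(ti_min), log(ti_max), length.out = n))
  chosen <- numeric(n)
  remaining <- valid
  for (i in seq_len(n)) {
    d <- abs(remaining - targets[i])
    j <- which(d == min(d))[1]           # tie -> earlier instant
    chosen[i] <- remaining[j]
    remaining <- remaining[-j]
  }
  ti_schedule(sort(chosen), mode = "motion_free", readout_ms = model$readout_ms,
              provenance = sprintf(
                "motion-free plan n=%d, %g..%g ms at %g bpm (period %.4f ms)",
                n, ti_min, ti_max, model$rate, model$period_ms))
}

#' Validate a schedule against a respiration model
#'
#' Checks every inversion time of a schedule for motion-free readout and
#' reports the cycle offset of each. TIs are reported with 1-based indices.
#'
#' @param schedule A [ti_schedule()].
#' @param model A [respiration_model()].
#' @return A data frame (class `schedule_report`) with columns `index`,
#'   `ti_ms`, `cycle_offset_ms`, `pass`; attributes `n_pass` and `n_fail`
#'   carry the summary counts.
#' @export
validate_schedule <- function(schedule, model) {
  stopifnot(inherits(schedule, "ti_schedule"),
            inherits(model, "respiration_model"))
  tis <- schedule$tis_ms
  ok <- is_ti_motion_free(tis, model)
  rep <- data.frame(index = seq_along(tis), ti_ms = tis,
                    cycle_offset_ms = tis %% model$period_ms, pass = ok)
  attr(rep, "n_pass") <- sum(ok)
  attr(rep, "n_fail") <- sum(!ok)
  class(rep) <- c("schedule_report", "data.frame")
  rep
}

#' @export
print.schedule_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  cat(sprintf("-- %d pass, %d fail\n", attr(x, "n_pass"), attr(x, "n_fail")))
  invisible(x)
}

#' Read or write a schedule sidecar
#'
#' Schedules are stored as JSON sidecars with fields `tis_ms`, `mode`,
#' `readout_ms`, `provenance`, and optionally the respiration-model
#' parameters they were planned against.
#'
#' @param schedule A [ti_schedule()].
#' @param path File path for the JSON sidecar.
#' @param model Optional [respiration_model()] to embed.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` returns
#'   a [ti_schedule()].
#' @export
write_schedule <- function(schedule, path, model = NULL) {
  stopifnot(inherits(schedule, "ti_schedule"))
  out <- unclass(schedule)
  if (!is.null(model)) out$model <- unclass(model)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ti_schedule(as.numeric(j$tis_ms), mode = j$mode,
              readout_ms = if (!is.null(j$readout_ms)) as.numeric(j$readout_ms) else 50,
              provenance = if (!is.null(j$provenance)) j$provenance else "")
}

check_ti_plan_args <- function(n, ti_min, ti_max) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2")
  if (!is.finite(ti_min) || !is.finite(ti_max) || ti_min <= 0 ||
      ti_min >= ti_max)
    stop("need 0 < ti_min < ti_max")
  invisible(TRUE)
}
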