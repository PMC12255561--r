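#' Magnitude inversion-recovery signal model
#'
#' The FAIR signal at inversion time TI for equilibrium signal `s0`,
#' inversion efficiency `alpha` and longitudinal relaxation time `t1`:
#'
#'   S(TI) = | s0 * (1 - 2 * alpha * exp(-TI / t1)) |
#'
#' Magnitude images cannot carry polarity, so the model takes the absolute
#' value of the recovering magnetization; the null point sits at
#' `TI = t1 * log(2)` for full inversion.
#'
#' @param s0 Equilibrium signal (> 0), arbitrary units.
#' @param alpha Inversion efficiency in \[0, 1\].
#' @param t1 Longitudinal relaxation time in ms (> 0).
#' @param ti Inversion time(s) in ms (>= 0); vectorized.
#' @return Magnitude signal(s), same length as `ti`.
#' @examples
#' fair_signal(1000, 1, 1500, ti = 1500 * log(2))  # 0 at the null point
#' fair_signal(1000, 1, 1500, ti = 0)              # s0
#' @export
fair_signal <- function(s0, alpha, t1, ti) {
  stopifnot(s0 > 0, alpha >= 0, alpha <= 1, t1 > 0, all(ti >= 0))
  abs(s0 * (1 - 2 * alpha * exp(-ti / t1)))
}

#' Default fit bounds for the inversion-recovery fit
#'
#' `t1` spans 50-10000 ms (tissue through blood at high field with headroom),
#' `alpha` is confined to \[0, 1\], and `s0` to (0, 10 x max observed signal\].
#'
#' @param signals Observed signals; used only to scale the `s0` upper bound.
#' @return List with elements `t1`, `s0`, `alpha`, each `c(lower, upper)`.
#' @export
ir_fit_bounds <- function(signals) {
  smax <- max(signals, na.rm = TRUE)
  if (!is.finite(smax) || smax <= 0) smax <- 1
  list(t1 = c(50, 10000), s0 = c(1e-8, 10 * smax), alpha = c(0, 1))
}

#' Initial parameter guess from the signal null point
#'
#' For full inversion the signal crosses zero at `TI_null = t1 * log(2)`, so
#' the TI of the minimum observed magnitude anchors the `t1` start value.
#' `s0` starts at the maximum signal and `alpha` at 1. Degenerate (constant)
#' signals fall back to the geometric midpoint of the `t1` bounds.
#'
#' @param signals Observed magnitudes, one per TI.
#' @param tis_ms Inversion times in ms, ascending.
#' @param bounds Fit bounds as from [ir_fit_bounds()].
#' @return Numeric vector `c(s0, alpha, t1)` clamped to the bounds.
#' @export
ir_initial_guess <- function(signals, tis_ms, bounds = ir_fit_bounds(signals)) {
  stopifnot(length(signals) == length(tis_ms), length(signals) >= 3)
  clamp <- function(x, b) min(max(x, b[1]), b[2])
  if (diff(range(signals)) < .Machine$double.eps * max(abs(signals), 1)) {
    t1g <- sqrt(bounds$t1[1] * bounds$t1[2])
  } else {
    t1g <- tis_ms[which.min(signals)] / log(2)
  }
  c(s0 = clamp(max(signals), bounds$s0),
    alpha = clamp(1, bounds$alpha),
    t1 = clamp(t1g, bounds$t1))
}

# Sum-of-squares objective and its gradient for the magnitude model.
# p = (s0, alpha, t1). The gradient uses the subgradient sign(u) at the
# null point, which is immaterial for L-BFGS-B in practice.
ir_sse <- function(p, tis, s) {
  r <- abs(p[1] * (1 - 2 * p[2] * exp(-tis / p[3]))) - s
  sum(r * r)
}

ir_sse_grad <- function(p, tis, s) {
  e <- exp(-tis / p[3])
  u <- 1 - 2 * p[2] * e
  su <- sign(u)
  r <- p[1] * abs(u) - s
  c(2 * sum(r * abs(u)),
    2 * sum(r * p[1] * su * (-2 * e)),
    2 * sum(r * p[1] * su * (-2 * p[2] * e * tis / p[3]^2)))
}

#' Bounded three-parameter inversion-recovery fit for one voxel
#'
#' Minimizes the sum of squared differences between the magnitude model and
#' the observed per-TI signals under box constraints (L-BFGS-B with analytic
#' gradient), restarted from a small set of `t1` start values around the
#' null-point guess, plus one start seeded from a coarse closed-form-`s0`
#' grid (covering low inversion efficiencies, where the null-point anchor
#' misleads), to avoid local minima of the folded model. Non-converged
#' fits are returned flagged, with `NA` parameters, never as silent zeros.
#'
#' @param signals Observed magnitudes (>= 3 finite values).
#' @param tis_ms Inversion times in ms, same length.
#' @param bounds Fit bounds, see [ir_fit_bounds()].
#' @param initial Optional start `c(s0, alpha, t1)`; default from
#'   [ir_initial_guess()].
#' @param t1_start_factors Multipliers applied to the `t1` start for the
#'   multi-start (default `c(1, 0.3, 0.7, 1.6, 3.5)`).
#' @return List with `params` (named `s0`, `alpha`, `t1`), `residuals`
#'   (model - data, ascending-TI order), `mse` (= SSE / n), `converged`.
#' @examples
#' tis <- plan_geometric_tis(14, 100, 5500)$tis_ms
#' s <- fair_signal(1000, 1, 1500, tis)
#' fit_ir_voxel(s, tis)$params
#' @export
fit_ir_voxel <- function(signals, tis_ms, bounds = ir_fit_bounds(signals),
                         initial = NULL,
                         t1_start_factors = c(1, 0.3, 0.7, 1.6, 3.5)) {
  keep <- is.finite(signals) & is.finite(tis_ms)
  s <- signals[keep]; tis <- tis_ms[keep]
  if (length(s) < 3)
    stop("at least 3 finite (signal, TI) points are required")
  if (is.null(initial)) initial <- ir_initial_guess(s, tis, bounds)
  lower <- c(bounds$s0[1], bounds$alpha[1], bounds$t1[1])
  upper <- c(bounds$s0[2], bounds$alpha[2], bounds$t1[2])
  clamp <- function(x) pmin(pmax(x, lower), upper)
  # the null-point anchor misleads when alpha is low (no zero crossing), so
  # add one start from a coarse closed-form-s0 grid over (t1, alpha)
  starts <- lapply(t1_start_factors, function(f)
    clamp(c(initial[1], initial[2], initial[3] * f)))
  starts <- c(starts, list(ir_coarse_start(s, tis, bounds)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, ir_sse, ir_sse_grad, tis = tis, s = s,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(parscale = c(max(upper[1] / 10, 1), 1, 1000),
                                  factr = 1e4, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(list(params = c(s0 = NA_real_, alpha = NA_real_, t1 = NA_real_),
                residuals = rep(NA_real_, length(signals)),
                mse = NA_real_, converged = FALSE))
  p <- unname(best$par)
  res <- rep(NA_real_, length(signals))
  res[keep] <- abs(p[1] * (1 - 2 * p[2] * exp(-tis / p[3]))) - s
  list(params = c(s0 = p[1], alpha = p[2], t1 = p[3]),
       residuals = res,
       mse = best$value / length(s),
       converged = TRUE)
}

# best node of a small (t1, alpha) grid with the conditionally optimal s0
# in closed form; used as one multistart seed of fit_ir_voxel
ir_coarse_start <- function(s, tis, bounds) {
  t1s <- exp(seq(log(bounds$t1[1]), log(bounds$t1[2]), length.out = 12))
  alphas <- seq(max(bounds$alpha[1], 0.4), bounds$alpha[2], length.out = 4)
  grid <- expand.grid(t1 = t1s, alpha = alphas)
  G <- abs(1 - 2 * grid$alpha * exp(-t(outer(tis, grid$t1, `/`))))
  gsq <- rowSums(G * G)
  num <- as.numeric(G %*% s)
  s0 <- pmin(pmax(num / pmax(gsq, 1e-12), bounds$s0[1]), bounds$s0[2])
  sse <- sum(s * s) - 2 * s0 * num + s0^2 * gsq
  i <- which.min(sse)
  c(s0[i], grid$alpha[i], grid$t1[i])
}

#' Brute-force grid reference fit
#'
#' Exhaustive reference for the bounded fit: `t1` on a regular grid (default
#' 10 ms steps across the bounds), `alpha` on a 0.01 grid, and for each grid
#' node the conditionally optimal `s0` in closed form (the model is linear in
#' `s0` for fixed `alpha`, `t1`), clamped to its bounds. Used as an
#' independent check that the iterative fit reaches the global basin; it is
#' far too slow to be the production fitter.
#'
#' @param signals Observed magnitudes.
#' @param tis_ms Inversion times in ms.
#' @param bounds Fit bounds, see [ir_fit_bounds()].
#' @param t1_step,alpha_step Grid steps (ms and dimensionless).
#' @param design Optional precomputed design from [ir_grid_design()], reused
#'   across voxels sharing `tis_ms` and grids.
#' @return List with `params`, `mse` (SSE / n) and `sse` at the best node.
#' @export
ir_grid_fit <- function(signals, tis_ms, bounds = ir_fit_bounds(signals),
                        t1_step = 10, alpha_step = 0.01, design = NULL) {
  keep <- is.finite(signals)
  s <- signals[keep]
  if (is.null(design))
    design <- ir_grid_design(tis_ms[keep], bounds, t1_step, alpha_step)
  num <- as.numeric(design$G %*% s)
  s0 <- pmin(pmax(num / design$gsq, bounds$s0[1]), bounds$s0[2])
  sse <- sum(s * s) - 2 * s0 * num + s0^2 * design$gsq
  i <- which.min(sse)
  list(params = c(s0 = s0[i], alpha = design$alpha[i], t1 = design$t1[i]),
       mse = sse[i] / length(s), sse = sse[i])
}

#' @rdname ir_grid_fit
#' @export
ir_grid_design <- function(tis_ms, bounds, t1_step = 10, alpha_step = 0.01) {
  t1s <- seq(bounds$t1[1], bounds$t1[2], by = t1_step)
  alphas <- seq(bounds$alpha[1], bounds$alpha[2], by = alpha_step)
  grid <- expand.grid(t1 = t1s, alpha = alphas)
  G <- abs(1 - 2 * grid$alpha * exp(-t(outer(tis_ms, grid$t1, `/`))))
  list(G = G, gsq = rowSums(G * G), t1 = grid$t1, alpha = grid$alpha)
}

#' Paired FAIR image series
#'
#' Container for one multi-TI FAIR acquisition: a label (slice-selective
#' inversion) stack and a control (global inversion) stack, each
#' `n_TI x rows x cols`, sharing an ascending TI list, plus an optional
#' fit mask.
#'
#' @param label_stack,control_stack Numeric arrays `n_TI x rows x cols` of
#'   non-negative magnitudes.
#' @param tis_ms Ascending inversion times, length `n_TI`.
#' @param mask Optional logical `rows x cols` matrix of voxels to fit;
#'   default: voxels whose mean control signal exceeds 5% of the stack
#'   maximum.
#' @return An object of class `fair_series`.
#' @export
fair_series <- function(label_stack, control_stack, tis_ms, mask = NULL) {
  if (!identical(dim(label_stack), dim(control_stack)))
    stop("label and control stacks must share dimensions")
  d <- dim(label_stack)
  if (length(d) != 3L)
    stop("stacks must be 3D arrays (n_TI x rows x cols)")
  if (d[1] != length(tis_ms))
    stop(sprintf("stack has %d frames but %d TIs given", d[1], length(tis_ms)))
  if (length(tis_ms) < 3)
    stop("at least 3 TIs are required for fitting")
  if (any(diff(tis_ms) <= 0)) stop("'tis_ms' must be strictly increasing")
  if (any(!is.finite(label_stack)) || any(!is.finite(control_stack)))
    stop("stacks must be finite")
  if (min(label_stack) < 0 || min(control_stack) < 0)
    stop("magnitude stacks must be non-negative")
  if (is.null(mask)) {
    mean_ctrl <- apply(control_stack, c(2, 3), mean)
    mask <- mean_ctrl > 0.05 * max(control_stack)
  }
  if (!identical(dim(mask), d[2:3]))
    stop("mask must match the image grid")
  structure(list(label_stack = label_stack, control_stack = control_stack,
                 tis_ms = as.numeric(tis_ms), mask = mask),
            class = "fair_series")
}

#' @export
print.fair_series <- function(x, ...) {
  d <- dim(x$label_stack)
  cat(sprintf("FAIR series: %d TIs (%g..%g ms), grid %dx%d, %d masked voxels\n",
              d[1], min(x$tis_ms), max(x$tis_ms), d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Per-voxel T1 fit of one inversion mode
#'
#' Applies [fit_ir_voxel()] to every masked voxel of the selected stack,
#' optionally excluding flagged inversion times, and assembles T1, S0, alpha
#' and MSE maps. The MSE of each voxel is `SSE / n` with `n` the number of
#' TIs actually used (after exclusion). Residuals are stored per TI in
#' ascending-TI order for downstream quality control; excluded TIs carry
#' `NA` residuals. Non-fitted and non-converged voxels hold `NA` in every
#' map.
#'
#' @param series A [fair_series()].
#' @param mode `"label"` (slice-selective inversion) or `"control"` (global
#'   inversion).
#' @param exclude_tis Optional integer vector of 1-based TI indices to drop
#'   from the fit.
#' @param bounds Optional fit bounds applied to every voxel; default scales
#'   from each voxel's own signals.
#' @return An object of class `t1_fit` with fields `t1_map`, `s0_map`,
#'   `alpha_map`, `mse_map`, `converged_mask`, `n_points_map`, `residuals`
#'   (array `n_TI x rows x cols`), `mode`, `tis_ms`, `excluded_tis`, `mask`.
#' @export
fit_series <- function(series, mode = c("label", "control"),
                       exclude_tis = NULL, bounds = NULL) {
  stopifnot(inherits(series, "fair_series"))
  mode <- match.arg(mode)
  stack <- if (mode == "label") series$label_stack else series$control_stack
  mask <- series$mask
  if (!any(mask)) stop("the fit mask is empty")
  n_ti <- length(series$tis_ms)
  use <- setdiff(seq_len(n_ti), exclude_tis)
  if (!is.null(exclude_tis) &&
      (any(exclude_tis < 1) || any(exclude_tis > n_ti)))
    stop("'exclude_tis' must be 1-based indices into the TI list")
  if (length(use) < 3)
    stop(sprintf("excluding %d of %d TIs leaves fewer than 3 points",
                 length(exclude_tis), n_ti))
  tis <- series$tis_ms[use]
  d <- dim(stack)[2:3]
  na_map <- matrix(NA_real_, d[1], d[2])
  t1_map <- s0_map <- alpha_map <- mse_map <- na_map
  conv <- matrix(FALSE, d[1], d[2])
  n_map <- matrix(NA_integer_, d[1], d[2])
  residuals <- array(NA_real_, dim = c(n_ti, d[1], d[2]))
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(bounds)) {
    stack_bounds <- ir_fit_bounds(as.numeric(stack[use, , , drop = FALSE]))
  } else stack_bounds <- bounds
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]
    sig <- stack[use, i, j]
    fit <- fit_ir_voxel(sig, tis, bounds = stack_bounds)
    if (fit$converged) {
      t1_map[i, j] <- fit$params["t1"]
      s0_map[i, j] <- fit$params["s0"]
      alpha_map[i, j] <- fit$params["alpha"]
      mse_map[i, j] <- fit$mse
      residuals[use, i, j] <- fit$residuals
      conv[i, j] <- TRUE
      n_map[i, j] <- length(use)
    }
  }
  structure(list(t1_map = t1_map, s0_map = s0_map, alpha_map = alpha_map,
                 mse_map = mse_map, converged_mask = conv,
                 n_points_map = n_map, residuals = residuals, mode = mode,
                 tis_ms = series$tis_ms, excluded_tis = sort(exclude_tis),
                 mask = mask),
            class = "t1_fit")
}

#' @export
print.t1_fit <- function(x, ...) {
  cat(sprintf("T1 fit (%s inversion): %d voxels, %d TIs%s\n",
              x$mode, sum(x$converged_mask), length(x$tis_ms),
              if (length(x$excluded_tis))
                paste0(", excluded TI ", paste(x$excluded_tis, collapse = ","))
              else ""))
  cat(sprintf("  median T1 %.0f ms, median MSE %.4g\n",
              stats::median(x$t1_map, na.rm = TRUE),
              stats::median(x$mse_map, na.rm = TRUE)))
  invisible(x)
}
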