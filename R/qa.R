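#' Flag corrupted inversion times from fit residuals
#'
#' Scores every inversion time by how strongly its residuals stand out from
#' each voxel's own residual scale: for TI k the score is the median over
#' masked voxels of `|r_k| / scale_v`, where `scale_v` is the voxel's robust
#' residual scale (1.4826 x MAD across its TIs, falling back to the RMSE when
#' the MAD is zero). A respiration-corrupted TI deviates coherently across
#' the liver, so its median score rises far above the ~0.7 expected for
#' well-behaved residuals; TIs scoring above `threshold_z` are flagged.
#'
#' Two refinements make the detection robust when several TIs are corrupted:
#' the per-voxel scale uses the MAD rather than the RMSE (the RMSE is itself
#' dominated by the outliers, capping every score near `sqrt(n/2)`), and
#' flagging is iterative when the series is supplied — the least-squares fit
#' partially absorbs a second corrupted point into the parameters, so after
#' each flag a deterministic subsample of voxels is refit without the
#' flagged TIs, residuals are re-predicted at every TI, and the remaining
#' TIs are re-scored. Iteration stops when no score exceeds the threshold or
#' when flagging more TIs would leave fewer than 4 points.
#'
#' @param fit A [fit_series()] result (residuals in ascending-TI order).
#' @param threshold_z Flagging threshold (default 3).
#' @param series The [fair_series()] behind `fit`; enables the iterative
#'   refit (recommended). `NULL` gives the single-pass score.
#' @param subsample Number of masked voxels used in refit iterations
#'   (default 400, taken at a deterministic stride).
#' @return A data frame (class `ti_flags`) with columns `index` (1-based),
#'   `ti_ms`, `score`, `flagged`; for flagged TIs the score is the one at
#'   which they were flagged. `attr(, "threshold_z")` records the threshold.
#'   Excluded TIs carry `NA` scores.
#' @export
flag_corrupted_tis <- function(fit, threshold_z = 3, series = NULL,
                               subsample = 400) {
  stopifnot(inherits(fit, "t1_fit"))
  n_ti <- length(fit$tis_ms)
  if (n_ti - length(fit$excluded_tis) < 4)
    stop("need at least 4 fitted TIs to distinguish an outlier from the trend")
  mask <- fit$converged_mask
  if (!any(mask)) stop("no converged voxels to score")
  R <- matrix(fit$residuals, n_ti, length(mask))[, as.vector(mask),
                                                 drop = FALSE]
  floor_fit <- 1e-7 * as.vector(fit$s0_map)[as.vector(mask)]
  floor_fit[!is.finite(floor_fit)] <- 0
  score <- score_ti_residuals(R, floor_v = floor_fit)
  flagged <- integer(0)
  if (!is.null(series)) {
    stopifnot(inherits(series, "fair_series"))
    stack <- if (fit$mode == "label") series$label_stack
             else series$control_stack
    vox <- which(as.vector(mask))
    if (length(vox) > subsample)
      vox <- vox[seq(1, length(vox), length.out = subsample)]
    sig <- matrix(stack, n_ti, length(mask))[, vox, drop = FALSE]
    bounds <- ir_fit_bounds(sig)
    excluded <- fit$excluded_tis
    repeat {
      cand <- setdiff(which(!is.na(score) & score > threshold_z),
                      c(flagged, excluded))
      if (length(cand) == 0) break
      if (n_ti - length(c(flagged, excluded)) - 1 < 4) break
      top <- cand[which.max(score[cand])]
      flagged <- c(flagged, top)
      retained <- setdiff(seq_len(n_ti), c(flagged, excluded))
      Rnew <- apply(sig, 2, function(s) {
        f <- fit_ir_voxel(s[retained], fit$tis_ms[retained], bounds = bounds)
        if (!f$converged) return(rep(NA_real_, n_ti))
        p <- f$params
        abs(p["s0"] * (1 - 2 * p["alpha"] * exp(-fit$tis_ms / p["t1"]))) - s
      })
      new_score <- score_ti_residuals(Rnew, scale_tis = retained,
                                      floor_v = 1e-7 * apply(sig, 2, max))
      keep_old <- c(flagged, excluded)
      new_score[keep_old] <- score[keep_old]
      score <- new_score
    }
  } else {
    flagged <- which(!is.na(score) & score > threshold_z)
  }
  out <- data.frame(index = seq_len(n_ti), ti_ms = fit$tis_ms, score = score,
                    flagged = seq_len(n_ti) %in% flagged)
  attr(out, "threshold_z") <- threshold_z
  class(out) <- c("ti_flags", "data.frame")
  out
}

# median over voxels (columns) of |r_k| / robust per-voxel scale; the scale
# is computed from the rows in scale_tis (all rows by default) and floored
# at a small fraction of the voxel's signal amplitude so that pure numerical
# noise in near-perfect fits never scores as an outlier
score_ti_residuals <- function(R, scale_tis = NULL, floor_v = 0) {
  if (is.null(scale_tis)) scale_tis <- seq_len(nrow(R))
  scale_v <- apply(R[scale_tis, , drop = FALSE], 2, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) return(NA_real_)
    s <- stats::mad(r)
    if (s == 0) s <- sqrt(mean(r^2))
    s
  })
  scale_v <- pmax(scale_v, floor_v)
  vapply(seq_len(nrow(R)), function(k) {
    rk <- abs(R[k, ])
    ok <- is.finite(rk) & is.finite(scale_v) & scale_v > 0
    if (!any(ok)) return(if (all(is.na(R[k, ]))) NA_real_ else 0)
    stats::median(rk[ok] / scale_v[ok])
  }, numeric(1))
}

#' @export
print.ti_flags <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 3)
  f <- x$index[x$flagged]
  cat(if (length(f)) paste("-- flagged TI:", paste(f, collapse = ", "))
      else "-- no TI flagged", "\n")
  invisible(x)
}

#' Exclude flagged inversion times and refit
#'
#' Refits both inversion modes without the flagged TIs and quantifies the
#' improvement. For comparability, the "before" MSE is recomputed over the
#' retained points with the original parameters, so by construction the
#' refit can only decrease it (least squares on a subset). Data exclusion
#' mainly restores accuracy; the perfusion histogram spread changes little.
#'
#' @param series A [fair_series()].
#' @param flagged Integer vector of 1-based TI indices to exclude, or a
#'   `ti_flags` object.
#' @param fit_label_before,fit_control_before Optional pre-computed full-TI
#'   fits; computed when missing.
#' @param config A [quant_config()] for the perfusion maps.
#' @return List with `fit_label`, `fit_control` (refits), `perfusion_before`,
#'   `perfusion_after`, and `summary`: a data frame per mode with the median
#'   masked-voxel MSE before (all points and retained points, original
#'   parameters) and after the refit, plus perfusion FWHM before/after.
#' @export
exclude_and_refit <- function(series, flagged, fit_label_before = NULL,
                              fit_control_before = NULL,
                              config = quant_config()) {
  stopifnot(inherits(series, "fair_series"))
  if (inherits(flagged, "ti_flags")) flagged <- flagged$index[flagged$flagged]
  flagged <- sort(unique(as.integer(flagged)))
  n_ti <- length(series$tis_ms)
  if (length(flagged) && (min(flagged) < 1 || max(flagged) > n_ti))
    stop("'flagged' must be 1-based TI indices")
  if (n_ti - length(flagged) < 3)
    stop("excluding the flagged TIs leaves fewer than 3 points per voxel")
  if (is.null(fit_label_before)) fit_label_before <- fit_series(series, "label")
  if (is.null(fit_control_before))
    fit_control_before <- fit_series(series, "control")
  fit_l <- fit_series(series, "label", exclude_tis = flagged)
  fit_c <- fit_series(series, "control", exclude_tis = flagged)
  perf_before <- perfusion_map(fit_label_before, fit_control_before, config)
  perf_after <- perfusion_map(fit_l, fit_c, config)

  retained <- setdiff(seq_len(n_ti), flagged)
  retained_mse <- function(fit) {
    R <- matrix(fit$residuals, n_ti, length(fit$converged_mask))
    colMeans(R[retained, , drop = FALSE]^2)
  }
  summarize <- function(before, after) {
    mask_v <- as.vector(before$converged_mask & after$converged_mask)
    data.frame(
      median_mse_before = stats::median(before$mse_map[mask_v], na.rm = TRUE),
      median_mse_before_retained =
        stats::median(retained_mse(before)[mask_v], na.rm = TRUE),
      median_mse_after = stats::median(after$mse_map[mask_v], na.rm = TRUE))
  }
  summ <- rbind(cbind(mode = "label",
                      summarize(fit_label_before, fit_l)),
                cbind(mode = "control",
                      summarize(fit_control_before, fit_c)))
  pv_b <- perf_before$values[is.finite(perf_before$values)]
  pv_a <- perf_after$values[is.finite(perf_after$values)]
  attr(summ, "perfusion_fwhm_before") <- as.numeric(histogram_fwhm(pv_b))
  attr(summ, "perfusion_fwhm_after") <- as.numeric(histogram_fwhm(pv_a))
  list(fit_label = fit_l, fit_control = fit_c,
       perfusion_before = perf_before, perfusion_after = perf_after,
       summary = summ, excluded_tis = flagged)
}

# gradient magnitude by central differences (replicated borders)
gradient_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  gy <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  sqrt(gx^2 + gy^2)
}

#' Edge-overlay motion inspection
#'
#' Computes gradient-magnitude edges of a reference TI frame (thresholded at
#' a percentile) for visual overlay on every other frame, and estimates the
#' in-plane displacement of each frame against the reference by
#' integer-shift cross-correlation of the gradient maps.
#'
#' @param series A [fair_series()].
#' @param reference_ti_index 1-based index of the reference frame
#'   (default 1).
#' @param mode Which stack to inspect (default `"label"`, the stack motion
#'   corrupts most).
#' @param edge_percentile Percentile of the non-zero gradient magnitude used
#'   as the edge threshold (default 0.9).
#' @param max_shift Largest displacement searched, in pixels (default 8).
#' @return An object of class `edge_overlay`: list with `reference_edges`
#'   (logical matrix), `displacement` (data frame `ti_index`, `drow`, `dcol`,
#'   `magnitude_px`), and `flat` (TRUE when the reference frame had no
#'   edges, in which case displacements are `NA`).
#' @export
edge_overlay <- function(series, reference_ti_index = 1,
                         mode = c("label", "control"),
                         edge_percentile = 0.9, max_shift = 8) {
  stopifnot(inherits(series, "fair_series"))
  mode <- match.arg(mode)
  stack <- if (mode == "label") series$label_stack else series$control_stack
  n_ti <- dim(stack)[1]
  if (reference_ti_index < 1 || reference_ti_index > n_ti)
    stop("'reference_ti_index' is outside the TI list")
  ref <- stack[reference_ti_index, , ]
  gref <- gradient_magnitude(ref)
  pos <- gref[gref > 0]
  flat <- length(pos) == 0
  edges <- if (flat) matrix(FALSE, nrow(ref), ncol(ref))
           else gref > stats::quantile(pos, edge_percentile)
  disp <- data.frame(ti_index = seq_len(n_ti), drow = NA_integer_,
                     dcol = NA_integer_, magnitude_px = NA_real_)
  if (!flat) {
    shifts <- expand.grid(drow = -max_shift:max_shift,
                          dcol = -max_shift:max_shift)
    for (k in seq_len(n_ti)) {
      gk <- gradient_magnitude(stack[k, , ])
      best <- -Inf; bi <- 1L
      for (i in seq_len(nrow(shifts))) {
        sc <- sum(gref * shift_frame(gk, -shifts$drow[i], -shifts$dcol[i]))
        if (sc > best) { best <- sc; bi <- i }
      }
      disp$drow[k] <- shifts$drow[bi]
      disp$dcol[k] <- shifts$dcol[bi]
      disp$magnitude_px[k] <- sqrt(shifts$drow[bi]^2 + shifts$dcol[bi]^2)
    }
  }
  structure(list(reference_edges = edges, displacement = disp, flat = flat,
                 mode = mode, reference_ti_index = reference_ti_index),
            class = "edge_overlay")
}

# rank-based AUC separating two samples (probability a draw from x exceeds
# a draw from y, ties counted half)
rank_auc <- function(x, y) {
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (as.numeric(length(x)) * length(y))
}

robust_outlier_fraction <- function(values, z = 3) {
  v <- values[is.finite(values)]
  if (!length(v)) return(NA_real_)
  s <- stats::mad(v)
  if (s == 0) return(0)
  mean(v > stats::median(v) + z * s)
}

#' Assemble a quality-assurance report
#'
#' Aggregates the residual-based quality metrics of one FAIR acquisition:
#' per-mode MSE histograms and per-TI corruption scores, per-ROI mean fit
#' error, the fraction of voxels with outlying MSE, the fraction of negative
#' perfusion values, and the per-TI edge-overlay displacement estimates.
#' The report is a plain nested list and serializes losslessly to JSON.
#'
#' @param series A [fair_series()].
#' @param fit_label,fit_control Fits of the two inversion modes.
#' @param perfusion A [perfusion_map()].
#' @param masks Optional integer ROI label matrix for per-ROI mean MSE.
#' @param roi_names Optional names for the mask labels (see [roi_stats()]).
#' @param threshold_z Per-TI flagging threshold (default 3).
#' @param reference_ti_index Reference frame for the edge overlay.
#' @return An object of class `qa_report` (a nested list).
#' @export
qa_report <- function(series, fit_label, fit_control, perfusion,
                      masks = NULL, roi_names = NULL, threshold_z = 3,
                      reference_ti_index = 1) {
  stopifnot(inherits(series, "fair_series"), inherits(fit_label, "t1_fit"),
            inherits(fit_control, "t1_fit"),
            inherits(perfusion, "perfusion_map"))
  mode_block <- function(fit) {
    mse <- fit$mse_map[fit$converged_mask]
    fw <- histogram_fwhm(mse)
    h <- attr(fw, "histogram")
    fl <- flag_corrupted_tis(fit, threshold_z, series = series)
    list(mse_median = stats::median(mse),
         mse_fwhm = as.numeric(fw),
         mse_histogram = list(mids = h$mids, counts = h$counts),
         per_ti_scores = fl$score,
         flagged_tis = fl$index[fl$flagged],
         flagged_voxel_fraction = robust_outlier_fraction(mse, threshold_z))
  }
  roi_mse <- function(fit) {
    if (is.null(masks)) return(NULL)
    st <- roi_stats(fit$mse_map, masks, roi_names)
    stats::setNames(as.list(st$mean), st$roi)
  }
  eo <- edge_overlay(series, reference_ti_index)
  pv <- perfusion$values[is.finite(perfusion$values)]
  rep <- list(
    n_ti = length(series$tis_ms),
    tis_ms = series$tis_ms,
    threshold_z = threshold_z,
    modes = list(label = mode_block(fit_label),
                 control = mode_block(fit_control)),
    roi_mean_mse = list(label = roi_mse(fit_label),
                        control = roi_mse(fit_control)),
    negative_perfusion_fraction = mean(pv < 0),
    edge_displacement = list(ti_index = eo$displacement$ti_index,
                             drow = eo$displacement$drow,
                             dcol = eo$displacement$dcol,
                             magnitude_px = eo$displacement$magnitude_px))
  class(rep) <- "qa_report"
  rep
}

#' @export
print.qa_report <- function(x, ...) {
  cat("QA report:", x$n_ti, "TIs\n")
  for (m in names(x$modes)) {
    b <- x$modes[[m]]
    cat(sprintf("  %s: median MSE %.4g, flagged TI [%s], outlier fraction %.3f\n",
                m, b$mse_median,
                paste(b$flagged_tis, collapse = ", "),
                b$flagged_voxel_fraction))
  }
  cat(sprintf("  negative perfusion fraction %.3f, max edge displacement %.1f px\n",
              x$negative_perfusion_fraction,
              max(x$edge_displacement$magnitude_px, na.rm = TRUE)))
  invisible(x)
}

#' Serialize / restore a QA report
#'
#' @param report A [qa_report()].
#' @param path JSON file path.
#' @return `write_qa_report` returns `path` invisibly; `read_qa_report`
#'   returns the restored `qa_report`.
#' @export
write_qa_report <- function(report, path) {
  stopifnot(inherits(report, "qa_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_qa_report
#' @export
read_qa_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "qa_report"
  rep
}
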