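#' Perfusion quantification configuration
#'
#' Constants of the FAIR perfusion equation. With selective and global T1
#' maps (ms), perfusion is
#'
#'   f = unit_factor * lambda * (T1_global / T1_blood) *
#'       (1 / T1_selective - 1 / T1_global)
#'
#' in ml/100 g tissue/min. The `unit_factor` of 6e6 converts
#' ml g^-1 ms^-1 to ml/100 g/min (x 60000 ms -> min, x 100 g -> 100 g); it is
#' exposed so alternative unit conventions stay auditable.
#'
#' @param lambda_ml_per_g Blood-tissue partition coefficient in ml/g
#'   (default 0.95, liver).
#' @param t1_blood_ms Blood T1 in ms (default 2430, appropriate at 9.4 T).
#' @param unit_factor Unit conversion factor (default 6e6).
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(lambda_ml_per_g = 0.95, t1_blood_ms = 2430,
                         unit_factor = 6e6) {
  if (any(c(lambda_ml_per_g, t1_blood_ms, unit_factor) <= 0))
    stop("all quantification constants must be positive")
  structure(list(lambda_ml_per_g = lambda_ml_per_g,
                 t1_blood_ms = t1_blood_ms, unit_factor = unit_factor),
            class = "quant_config")
}

#' Perfusion map from paired T1 maps
#'
#' Computes voxel-wise perfusion from the selective- and global-inversion T1
#' maps. Voxels missing in either input are missing in the output. Negative
#' values — the signature of poor fits — are retained, never clipped; they
#' feed the quality report.
#'
#' @param t1_selective,t1_global T1 maps in ms: numeric matrices or
#'   [fit_series()] results (`t1_fit` objects), congruent grids.
#' @param config A [quant_config()].
#' @return An object of class `perfusion_map` with fields `values`
#'   (ml/100 g tissue/min), `config`, and `source` (modes of the inputs when
#'   fits were supplied).
#' @examples
#' perfusion_map(matrix(950, 2, 2), matrix(1000, 2, 2))$values[1, 1]  # ~123.5
#' @export
perfusion_map <- function(t1_selective, t1_global, config = quant_config()) {
  src <- c(selective = "matrix", global = "matrix")
  if (inherits(t1_selective, "t1_fit")) {
    src["selective"] <- t1_selective$mode; t1_selective <- t1_selective$t1_map
  }
  if (inherits(t1_global, "t1_fit")) {
    src["global"] <- t1_global$mode; t1_global <- t1_global$t1_map
  }
  if (!identical(dim(t1_selective), dim(t1_global)))
    stop("selective and global T1 maps must share dimensions")
  stopifnot(inherits(config, "quant_config"))
  bad <- which(t1_selective <= 0 | t1_global <= 0)
  f <- config$unit_factor * config$lambda_ml_per_g *
    (t1_global / config$t1_blood_ms) * (1 / t1_selective - 1 / t1_global)
  f[bad] <- NA_real_
  structure(list(values = f, config = config, source = src),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "Perfusion map: %d voxels, median %.1f ml/100g/min, %.1f%% negative\n",
    length(v), stats::median(v), 100 * mean(v < 0)))
  invisible(x)
}

#' Selective T1 implied by a perfusion value
#'
#' Algebraic inverse of the perfusion equation: given true perfusion and the
#' global T1, returns the selective T1 that [perfusion_map()] would convert
#' back to exactly that perfusion. Used by the phantom generator to plant
#' ground truth.
#'
#' @param f Perfusion in ml/100 g tissue/min (>= 0); vectorized.
#' @param t1_global Global-inversion T1 in ms (> 0).
#' @param config A [quant_config()].
#' @return Selective T1 in ms.
#' @export
t1sel_from_perfusion <- function(f, t1_global, config = quant_config()) {
  if (any(f < 0, na.rm = TRUE)) stop("perfusion must be non-negative")
  if (any(t1_global <= 0, na.rm = TRUE)) stop("'t1_global' must be positive")
  inv <- 1 / t1_global +
    f * config$t1_blood_ms / (config$unit_factor * config$lambda_ml_per_g *
                                t1_global)
  if (any(inv <= 0, na.rm = TRUE))
    stop("parameters imply a non-positive selective T1")
  1 / inv
}

#' ROI statistics of a perfusion map
#'
#' Per-region mean, sample standard deviation (n - 1), coefficient of
#' variation (sigma / mu x 100%), median, voxel count, histogram and FWHM.
#' The CV is undefined (NA, with a flag) for regions whose mean is zero;
#' empty regions yield all-missing rows.
#'
#' @param map A [perfusion_map()] or a numeric matrix.
#' @param masks Integer label matrix on the same grid (0 = outside all ROIs),
#'   or a logical matrix for a single ROI.
#' @param roi_names Optional character vector naming the labels, either
#'   unnamed (label 1 = first name, ...) or named by label value.
#' @return A data frame (class `roi_stats`) with one row per ROI: `roi`,
#'   `n`, `mean`, `sd`, `cv_pct`, `median`, `fwhm`, `cv_defined`; the
#'   per-ROI histograms are kept in `attr(, "histograms")`.
#' @export
roi_stats <- function(map, masks, roi_names = NULL) {
  values <- if (inherits(map, "perfusion_map")) map$values else map
  if (is.logical(masks)) masks <- masks * 1L
  if (!identical(dim(values), dim(masks)))
    stop("ROI masks must match the map grid")
  labels <- sort(unique(masks[masks != 0]))
  nm <- as.character(labels)
  if (!is.null(roi_names)) {
    if (!is.null(names(roi_names))) {
      hit <- match(nm, names(roi_names))
      nm[!is.na(hit)] <- roi_names[hit[!is.na(hit)]]
    } else {
      nm <- roi_names[seq_along(labels)]
    }
  }
  hists <- vector("list", length(labels))
  names(hists) <- nm
  rows <- lapply(seq_along(labels), function(i) {
    v <- values[masks == labels[i]]
    v <- v[is.finite(v)]
    if (length(v) == 0)
      return(data.frame(roi = nm[i], n = 0L, mean = NA_real_, sd = NA_real_,
                        cv_pct = NA_real_, median = NA_real_, fwhm = NA_real_,
                        cv_defined = FALSE))
    mu <- mean(v); sdv <- stats::sd(v)
    cv_ok <- mu != 0
    fw <- if (length(unique(v)) >= 2) {
      h <- histogram_fwhm(v)
      hists[[i]] <<- attr(h, "histogram")
      as.numeric(h)
    } else NA_real_
    data.frame(roi = nm[i], n = length(v), mean = mu, sd = sdv,
               cv_pct = if (cv_ok) sdv / mu * 100 else NA_real_,
               median = stats::median(v), fwhm = fw, cv_defined = cv_ok)
  })
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- hists
  class(out) <- c("roi_stats", "data.frame")
  out
}

#' Histogram FWHM of a value distribution
#'
#' Full width at half maximum of the tallest peak of the binned distribution,
#' with linear interpolation of the half-maximum crossings on either flank.
#' Bin width defaults to the Freedman-Diaconis rule. For a large Gaussian
#' sample the result approaches `2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param values Numeric vector (>= 2 distinct values for a meaningful
#'   width).
#' @param bin_width Optional bin width; default Freedman-Diaconis.
#' @return The FWHM as a single number; the underlying histogram (list with
#'   `mids`, `counts`, `breaks`) is attached as `attr(, "histogram")`. When
#'   all values are identical the bin width is returned with
#'   `attr(, "degenerate") = TRUE`.
#' @export
histogram_fwhm <- function(values, bin_width = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("no finite values")
  if (is.null(bin_width)) {
    iqr <- stats::IQR(values)
    bin_width <- if (iqr > 0) 2 * iqr / length(values)^(1 / 3) else 1
  }
  if (length(unique(values)) < 2) {
    out <- bin_width
    attr(out, "degenerate") <- TRUE
    attr(out, "histogram") <- list(mids = mean(values),
                                   counts = length(values),
                                   breaks = mean(values) +
                                     c(-0.5, 0.5) * bin_width)
    return(out)
  }
  breaks <- seq(min(values) - bin_width, max(values) + bin_width,
                by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  counts <- h$counts; mids <- h$mids
  pk <- which.max(counts)
  half <- counts[pk] / 2
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(pk)) else pk:length(counts)
    below <- which(counts[idx] < half)
    if (length(below) == 0) return(mids[idx[length(idx)]])
    b <- idx[below[1]]                 # first bin below half, walking outward
    a <- if (side == "left") b + 1 else b - 1   # last bin at/above half
    # linear interpolation between bin centers a and b
    mids[a] + (half - counts[a]) / (counts[b] - counts[a]) * (mids[b] - mids[a])
  }
  out <- cross("right") - cross("left")
  attr(out, "histogram") <- list(mids = mids, counts = counts,
                                 breaks = h$breaks)
  out
}

#' Count histogram peaks
#'
#' Local maxima of a binned distribution that rise above a fraction of the
#' tallest peak and are separated from it by a valley dropping below half the
#' smaller peak. Used to classify perfusion histograms as monophasic or
#' biphasic (tissue vs. vessel peaks).
#'
#' @param values Numeric vector.
#' @param bin_width Optional bin width; default Freedman-Diaconis.
#' @param min_height Minimum peak height as a fraction of the tallest peak
#'   (default 0.1).
#' @return Integer: the number of detected peaks.
#' @export
histogram_peaks <- function(values, bin_width = NULL, min_height = 0.1) {
  fw <- histogram_fwhm(values, bin_width)
  h <- attr(fw, "histogram")
  counts <- h$counts
  if (length(counts) < 3) return(1L)
  is_max <- vapply(seq_along(counts), function(i) {
    l <- if (i > 1) counts[i - 1] else -Inf
    r <- if (i < length(counts)) counts[i + 1] else -Inf
    counts[i] > l && counts[i] >= r
  }, logical(1))
  cand <- which(is_max & counts >= min_height * max(counts))
  if (length(cand) <= 1) return(length(cand))
  # merge candidates not separated by a deep enough valley
  keep <- cand[1]
  for (i in cand[-1]) {
    prev <- keep[length(keep)]
    valley <- min(counts[prev:i])
    if (valley < 0.5 * min(counts[prev], counts[i])) {
      keep <- c(keep, i)
    } else if (counts[i] > counts[prev]) {
      keep[length(keep)] <- i
    }
  }
  length(keep)
}

#' Vessel mask from a perfusion map
#'
#' Flags voxels whose perfusion exceeds `median + k_mad * MAD` of the valid
#' voxels and keeps only those forming 4-connected clusters of at least
#' `min_cluster` voxels — a reproducible surrogate for the visual exclusion
#' of vessel-like high-perfusion clusters.
#'
#' @param map A [perfusion_map()] or numeric matrix.
#' @param k_mad Threshold in robust standard deviations above the median
#'   (default 5).
#' @param min_cluster Minimum cluster size in voxels (default 4).
#' @return Logical matrix marking vessel voxels.
#' @export
vessel_mask <- function(map, k_mad = 5, min_cluster = 4) {
  values <- if (inherits(map, "perfusion_map")) map$values else map
  v <- values[is.finite(values)]
  if (length(v) < 1) stop("the map has no valid voxel")
  thr <- stats::median(v) + k_mad * stats::mad(v)
  high <- is.finite(values) & values > thr
  if (!any(high)) return(high)
  lab <- EBImage::bwlabel(high * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_cluster)
  high & matrix(as.integer(lab) %in% keep, nrow(values), ncol(values))
}
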