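#' Write a FAIR series to NIfTI stacks plus a JSON sidecar
#'
#' Stacks are written as `rows x cols x n_TI` NIfTI volumes; the sidecar is
#' the single source of truth for the inversion times (the NIfTI headers
#' carry geometry only).
#'
#' @param series A [fair_series()].
#' @param label_path,control_path Output NIfTI paths (`.nii` / `.nii.gz`).
#' @param sidecar_path Output JSON sidecar path.
#' @param mask_path Optional NIfTI path for the fit mask.
#' @return Invisibly, the sidecar path.
#' @export
write_fair_series <- function(series, label_path, control_path, sidecar_path,
                              mask_path = NULL) {
  stopifnot(inherits(series, "fair_series"))
  RNifti::writeNifti(aperm(series$label_stack, c(2, 3, 1)), label_path)
  RNifti::writeNifti(aperm(series$control_stack, c(2, 3, 1)), control_path)
  if (!is.null(mask_path))
    RNifti::writeNifti(series$mask * 1, mask_path)
  sidecar <- list(tis_ms = series$tis_ms,
                  n_ti = length(series$tis_ms),
                  stacks = list(label = basename(label_path),
                                control = basename(control_path)))
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar_path)
}

#' Read a FAIR series from NIfTI stacks plus a JSON sidecar
#'
#' Validates shapes against the sidecar TI count and reorders frames to
#' ascending TI when the sidecar lists them in another order (the applied
#' permutation is reported as a message).
#'
#' @param label_path,control_path NIfTI stack paths.
#' @param sidecar_path JSON sidecar with `tis_ms`.
#' @param mask_path Optional NIfTI mask path (non-zero = fit).
#' @return A [fair_series()].
#' @export
read_fair_series <- function(label_path, control_path, sidecar_path,
                             mask_path = NULL) {
  for (p in c(label_path, control_path, sidecar_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sidecar$tis_ms)) stop("sidecar lacks 'tis_ms': ", sidecar_path)
  tis <- as.numeric(sidecar$tis_ms)
  lab <- as.array(RNifti::readNifti(label_path))
  ctl <- as.array(RNifti::readNifti(control_path))
  if (length(dim(lab)) != 3 || length(dim(ctl)) != 3)
    stop("stacks must be 3D (rows x cols x n_TI)")
  if (dim(lab)[3] != length(tis) || dim(ctl)[3] != length(tis))
    stop(sprintf("sidecar lists %d TIs but stacks have %d / %d frames",
                 length(tis), dim(lab)[3], dim(ctl)[3]))
  ord <- order(tis)
  if (any(ord != seq_along(tis))) {
    message("reordering frames to ascending TI; permutation: ",
            paste(ord, collapse = " "))
    tis <- tis[ord]
    lab <- lab[, , ord, drop = FALSE]
    ctl <- ctl[, , ord, drop = FALSE]
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) stop("input file not found: ", mask_path)
    mask <- as.array(RNifti::readNifti(mask_path)) != 0
    dim(mask) <- dim(lab)[1:2]
  }
  fair_series(aperm(lab, c(3, 1, 2)), aperm(ctl, c(3, 1, 2)), tis,
              mask = mask)
}

#' Write / read a scalar map as NIfTI
#'
#' @param values Numeric matrix (NA allowed; stored as NaN).
#' @param path NIfTI path.
#' @return `write_map` returns `path` invisibly; `read_map` returns a numeric
#'   matrix with NaN mapped back to NA.
#' @export
write_map <- function(values, path) {
  if (inherits(values, "perfusion_map")) values <- values$values
  RNifti::writeNifti(values, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  m <- as.array(RNifti::readNifti(path))
  dim(m) <- dim(m)[1:2]
  m[is.nan(m)] <- NA_real_
  m
}

#' Write integer ROI labels with a JSON name table
#'
#' @param labels Integer label matrix.
#' @param path NIfTI path for the labels.
#' @param names_path JSON path for the label -> name table.
#' @param name_table Named integer vector (names are ROI names, values the
#'   label codes), e.g. [phantom_labels()].
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path, names_path = NULL,
                         name_table = NULL) {
  RNifti::writeNifti(labels * 1, path)
  if (!is.null(names_path) && !is.null(name_table))
    jsonlite::write_json(as.list(name_table), names_path, auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, names_path = NULL) {
  m <- as.array(RNifti::readNifti(path))
  dim(m) <- dim(m)[1:2]
  storage.mode(m) <- "integer"
  if (!is.null(names_path)) {
    nt <- jsonlite::read_json(names_path, simplifyVector = TRUE)
    attr(m, "name_table") <- unlist(nt)
  }
  m
}

#' Write ROI statistics as CSV
#'
#' One row per ROI: name, n, mean, sd, cv, median, fwhm.
#'
#' @param stats A [roi_stats()] result.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_roi_stats <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}
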