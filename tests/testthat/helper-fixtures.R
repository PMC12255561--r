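# Shared fixtures. Everything is generated in code; no data files.

default_model <- function() respiration_model(rate = 45)

# 14 motion-free TIs under the default ventilated model
mv_schedule <- function() {
  plan_motion_free_tis(default_model(), n = 14, ti_min = 100, ti_max = 5500)
}

# the vendor-default 16-TI geometric series used under free breathing
nmv_schedule <- function() plan_geometric_tis(16, 100, 4500)

# a small phantom for fast tests; the acceptance suite uses the full 96x96
small_spec <- function(...) phantom_spec(grid = c(48, 48), ...)

# thin a series' fit mask to every stride-th voxel (fit speed in unit tests)
thin_mask <- function(series, stride = 3) {
  idx <- which(series$mask)
  keep <- idx[seq(1, length(idx), by = stride)]
  m <- series$mask & FALSE
  m[keep] <- TRUE
  series$mask <- m
  series
}

# brute-force check that a TI's delayed readout fits inside one enumerated
# motion-free window (interval containment, independent of the modular test)
ti_in_windows_oracle <- function(ti, model) {
  w <- motion_free_windows(model, horizon_ms = ti + model$readout_ms + 1)
  any(ti >= w$start_ms - 1e-9 & ti + model$readout_ms <= w$end_ms + 1e-9)
}
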