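test_that("phantom geometry contains every region with sane proportions", {
  truth <- build_phantom(phantom_spec())
  codes <- phantom_labels()
  counts <- table(factor(truth$labels[truth$labels > 0], levels = codes))
  expect_true(all(counts > 0))
  liver <- truth$labels %in% c(codes[1:5], codes["vessel"])
  # the liver occupies a plausible fraction of a 96x96 slice
  expect_gt(mean(liver), 0.10)
  expect_lt(mean(liver), 0.50)
  # lobes map covers liver voxels incl. vessels; vessels sit inside lobes
  expect_true(all(truth$lobes[truth$labels == codes["vessel"]] > 0))
  expect_true(all(truth$labels[truth$labels == codes["muscle"]] == 6L))
})

test_that("vessel fractions are planted per lobe as specified", {
  truth <- build_phantom(phantom_spec())
  codes <- phantom_labels()
  vf <- truth$spec$vessel_fraction
  for (s in 1:5) {
    lobe <- truth$lobes == s
    frac <- sum(lobe & truth$labels == codes["vessel"]) / sum(lobe)
    expect_lt(abs(frac - unname(vf[names(codes)[s]])), 0.005)
  }
  # LLL is the vessel-rich lobe
  lll_frac <- sum(truth$lobes == 4 & truth$labels == 7L) / sum(truth$lobes == 4)
  expect_gt(lll_frac, 0.25)
})

test_that("ground truth is self-consistent through the perfusion equation", {
  truth <- build_phantom(phantom_spec())
  f <- perfusion_map(truth$t1_selective, truth$t1_global, truth$config)$values
  valid <- truth$labels > 0
  expect_equal(f[valid], truth$perfusion[valid], tolerance = 1e-10)
  # selective T1 is strictly below global T1 wherever perfusion > 0
  pos <- valid & truth$perfusion > 0
  expect_true(all(truth$t1_selective[pos] < truth$t1_global[pos]))
})

test_that("noiseless simulation reproduces the analytic signal exactly", {
  spec <- small_spec(noise = list(model = "gaussian", sigma = 0))
  truth <- build_phantom(spec)
  sched <- mv_schedule()
  ser <- simulate_series(truth, sched)
  i <- which(truth$labels == 1L)[1]
  ri <- ((i - 1) %% nrow(truth$labels)) + 1
  ci <- ((i - 1) %/% nrow(truth$labels)) + 1
  expect_equal(ser$label_stack[, ri, ci],
               fair_signal(truth$s0_map[ri, ci], truth$alpha,
                           truth$t1_selective[ri, ci], sched$tis_ms))
  expect_equal(ser$control_stack[, ri, ci],
               fair_signal(truth$s0_map[ri, ci], truth$alpha,
                           truth$t1_global[ri, ci], sched$tis_ms))
  # background stays zero, mask equals the labeled region
  bg <- truth$labels == 0L
  expect_true(all(apply(ser$label_stack, 1, function(f) all(f[bg] == 0))))
  expect_identical(ser$mask, truth$labels > 0)
})

test_that("simulation is bit-identical for a fixed seed", {
  truth <- build_phantom(small_spec())
  sched <- mv_schedule()
  a <- simulate_series(truth, sched, seed = 123)
  b <- simulate_series(truth, sched, seed = 123)
  d <- simulate_series(truth, sched, seed = 124)
  expect_identical(a$label_stack, b$label_stack)
  expect_identical(a$control_stack, b$control_stack)
  expect_false(identical(a$label_stack, d$label_stack))
})

test_that("noise models behave as documented near the null point", {
  truth <- build_phantom(small_spec())
  sched <- ti_schedule(c(100, round(1200 * log(2)), 4000))
  g <- simulate_series(truth, sched,
                       noise = list(model = "gaussian", sigma = 0.05),
                       seed = 5)
  r <- simulate_series(truth, sched,
                       noise = list(model = "rician", sigma = 0.05),
                       seed = 5)
  expect_gte(min(g$label_stack), 0)      # gaussian clipped at zero
  fg <- truth$labels > 0
  rician_min <- min(apply(r$control_stack, 1, function(f) min(f[fg])))
  expect_gt(rician_min, 0)               # rician floor > 0
  # near the control null point the rician mean sits above the true signal
  null_ctrl <- r$control_stack[2, , ][truth$labels == 1L]
  true_ctrl <- fair_signal(1000, 1, 1200, sched$tis_ms[2])
  expect_gt(mean(null_ctrl), true_ctrl)
})

test_that("through-plane mismatch attenuates only the targeted TI and mode", {
  spec <- small_spec(noise = list(model = "gaussian", sigma = 0))
  truth <- build_phantom(spec)
  sched <- nmv_schedule()
  ev <- corruption_event(12, "through_plane_mismatch", magnitude = 0.5)
  expect_identical(ev$mode, "label")
  clean <- simulate_series(truth, sched, corruptions = list())
  corr <- simulate_series(truth, sched, corruptions = list(ev))
  # control stack untouched
  expect_identical(corr$control_stack, clean$control_stack)
  # label frames differ only at TI 12
  same <- vapply(seq_along(sched$tis_ms), function(k)
    identical(corr$label_stack[k, , ], clean$label_stack[k, , ]),
    logical(1))
  expect_identical(which(!same), 12L)
  # inside the cranial region the effective alpha is halved
  reg <- fairasl:::resolve_region("cranial", truth)
  i <- which(truth$labels == 1L & reg & truth$lobes > 0)[1]
  ri <- ((i - 1) %% nrow(truth$labels)) + 1
  ci <- ((i - 1) %/% nrow(truth$labels)) + 1
  expect_equal(corr$label_stack[12, ri, ci],
               fair_signal(truth$s0_map[ri, ci], 0.5,
                           truth$t1_selective[ri, ci], sched$tis_ms[12]))
})

test_that("in-plane shift translates the frame with zero fill", {
  spec <- small_spec(noise = list(model = "gaussian", sigma = 0))
  truth <- build_phantom(spec)
  sched <- nmv_schedule()
  ev <- corruption_event(12, "in_plane_shift", shift = c(0L, 6L))
  corr <- simulate_series(truth, sched, corruptions = list(ev))
  clean <- simulate_series(truth, sched, corruptions = list())
  expect_identical(corr$label_stack[12, , 7:48],
                   clean$label_stack[12, , 1:42])
  expect_true(all(corr$label_stack[12, , 1:6] == 0))
  # both stacks move (mode "both")
  expect_identical(corr$control_stack[12, , 7:48],
                   clean$control_stack[12, , 1:42])
  # oversized shift is rejected
  big <- corruption_event(12, "in_plane_shift", shift = c(0L, 20L))
  expect_error(simulate_series(truth, sched, corruptions = list(big)),
               "quarter")
})

test_that("corruption events referencing absent TIs are rejected", {
  truth <- build_phantom(small_spec())
  sched <- ti_schedule(c(100, 500, 2000))
  ev <- corruption_event(9, "through_plane_mismatch")
  expect_error(simulate_series(truth, sched, corruptions = list(ev)),
               "schedule has 3")
})

test_that("corruption presets encode the documented scenarios", {
  p <- corruption_preset("fig3-corrupt")
  expect_length(p, 2)
  expect_identical(vapply(p, `[[`, integer(1), "ti_index"), c(9L, 12L))
  expect_true(all(vapply(p, `[[`, character(1), "kind") ==
                    "through_plane_mismatch"))
  s <- corruption_preset("shift6")
  expect_identical(s[[1]]$shift, c(0L, 6L))
  expect_identical(s[[1]]$mode, "both")
})
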