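# Shared fixtures for this file: one clean and one corrupted acquisition of
# the small phantom under the 16-TI geometric schedule.
qa_fix <- local({
  sched <- nmv_schedule()
  clean_spec <- small_spec()
  corr_spec <- small_spec(corruptions = corruption_preset("fig3-corrupt"))
  clean <- thin_mask(simulate_series(build_phantom(clean_spec), sched,
                                     seed = 7))
  corr <- thin_mask(simulate_series(build_phantom(corr_spec), sched,
                                    seed = 7))
  list(sched = sched,
       clean = clean, corr = corr,
       fit_clean = fit_series(clean, "label"),
       fit_corr = fit_series(corr, "label"))
})

test_that("clean acquisitions are not flagged", {
  fl <- flag_corrupted_tis(qa_fix$fit_clean, series = qa_fix$clean)
  expect_s3_class(fl, "ti_flags")
  expect_false(any(fl$flagged))
  # well-behaved residual scores sit near the Gaussian median of ~0.67
  expect_lt(max(fl$score, na.rm = TRUE), 1.5)
  expect_gt(min(fl$score, na.rm = TRUE), 0.3)
})

test_that("both corrupted TIs are flagged, and only those", {
  fl <- flag_corrupted_tis(qa_fix$fit_corr, series = qa_fix$corr)
  expect_identical(fl$index[fl$flagged], c(9L, 12L))
  expect_true(all(fl$score[c(9, 12)] > 3))
  expect_true(all(fl$score[-c(9, 12)] < 3))
  expect_identical(attr(fl, "threshold_z"), 3)
})

test_that("corrupted-TI scores dominate clean scores with perfect ranking", {
  fl <- flag_corrupted_tis(qa_fix$fit_corr, series = qa_fix$corr)
  auc <- fairasl:::rank_auc(fl$score[c(9, 12)], fl$score[-c(9, 12)])
  expect_equal(auc, 1)
})

test_that("rank_auc matches hand-checkable cases", {
  expect_equal(fairasl:::rank_auc(c(5, 6), c(1, 2)), 1)
  expect_equal(fairasl:::rank_auc(c(1, 2), c(5, 6)), 0)
  expect_equal(fairasl:::rank_auc(c(1, 2), c(1, 2)), 0.5)
})

test_that("noiseless near-perfect fits never score as outliers", {
  # without a scale floor, numerical noise in exact fits would explode the
  # normalized scores
  spec <- small_spec(noise = list(model = "gaussian", sigma = 0))
  ser <- thin_mask(simulate_series(build_phantom(spec), mv_schedule()),
                   stride = 6)
  fit <- fit_series(ser, "label")
  fl <- flag_corrupted_tis(fit, series = ser)
  expect_false(any(fl$flagged))
})

test_that("flagging requires enough TIs and converged voxels", {
  tis <- c(100, 600, 2000)
  st <- array(rep(fair_signal(1000, 1, 1200, tis), 4), dim = c(3, 2, 2))
  ser <- fair_series(st, st, tis, mask = matrix(TRUE, 2, 2))
  fit <- fit_series(ser, "label")
  expect_error(flag_corrupted_tis(fit), "at least 4")
})

test_that("exclude_and_refit improves the retained-point error", {
  res <- exclude_and_refit(qa_fix$corr, c(9L, 12L),
                           fit_label_before = qa_fix$fit_corr)
  expect_identical(res$excluded_tis, c(9L, 12L))
  s <- res$summary
  # refitting without the corrupted points can only reduce the retained MSE
  expect_true(all(s$median_mse_after <= s$median_mse_before_retained + 1e-9))
  # and the overall error collapses once the corrupted TIs are dropped
  lab <- s[s$mode == "label", ]
  expect_lt(lab$median_mse_after, lab$median_mse_before / 2)
  # excluded TIs recorded on the refits
  expect_identical(res$fit_label$excluded_tis, c(9L, 12L))
  expect_true(all(is.na(res$fit_label$residuals[c(9, 12), , ])))
  # ti_flags objects are accepted directly
  fl <- flag_corrupted_tis(qa_fix$fit_corr, series = qa_fix$corr)
  res2 <- exclude_and_refit(qa_fix$corr, fl,
                            fit_label_before = qa_fix$fit_corr,
                            fit_control_before = res$fit_control)
  expect_identical(res2$excluded_tis, c(9L, 12L))
})

test_that("exclusion refit restores perfusion accuracy", {
  truth <- build_phantom(small_spec(corruptions = corruption_preset("fig3-corrupt")))
  res <- exclude_and_refit(qa_fix$corr, c(9L, 12L),
                           fit_label_before = qa_fix$fit_corr)
  mask <- qa_fix$corr$mask & truth$lobes > 0 & truth$labels != 7L
  err <- function(pm) {
    v <- pm$values[mask] - truth$perfusion[mask]
    stats::median(abs(v), na.rm = TRUE)
  }
  expect_lt(err(res$perfusion_after), err(res$perfusion_before))
})

test_that("exclude_and_refit rejects exclusions leaving too few points", {
  expect_error(exclude_and_refit(qa_fix$corr, 1:14), "fewer than 3")
  expect_error(exclude_and_refit(qa_fix$corr, 99), "1-based")
})

test_that("edge overlay recovers a planted in-plane shift", {
  spec <- small_spec(corruptions = corruption_preset("shift6"))
  ser <- simulate_series(build_phantom(spec), nmv_schedule(), seed = 7)
  eo <- edge_overlay(ser)
  expect_false(eo$flat)
  expect_true(any(eo$reference_edges))
  d <- eo$displacement
  expect_identical(d$dcol[12], 6L)
  expect_identical(d$drow[12], 0L)
  expect_equal(d$magnitude_px[12], 6)
  # uncorrupted frames register at zero displacement, except possibly frames
  # near the inversion null where the gradient field is too weak to register
  expect_gte(sum(d$magnitude_px[-12] == 0), 13)
})

test_that("edge overlay flags a featureless reference frame", {
  st <- array(5, dim = c(4, 8, 8))
  ser <- fair_series(st, st, c(100, 400, 900, 2500),
                     mask = matrix(TRUE, 8, 8))
  eo <- edge_overlay(ser)
  expect_true(eo$flat)
  expect_true(all(is.na(eo$displacement$magnitude_px)))
})

test_that("robust_outlier_fraction behaves on known mixtures", {
  set.seed(8)
  v <- rnorm(5000)
  base <- fairasl:::robust_outlier_fraction(v)
  expect_lt(base, 0.01)
  expect_gt(fairasl:::robust_outlier_fraction(c(v, rep(50, 500))), 0.08)
  expect_equal(fairasl:::robust_outlier_fraction(rep(3, 10)), 0)
})

test_that("qa_report aggregates the metrics and round-trips through JSON", {
  fit_c <- fit_series(qa_fix$corr, "control")
  perf <- perfusion_map(qa_fix$fit_corr, fit_c)
  truth <- build_phantom(small_spec())
  rep <- qa_report(qa_fix$corr, qa_fix$fit_corr, fit_c, perf,
                   masks = truth$labels,
                   roi_names = names(phantom_labels()))
  expect_s3_class(rep, "qa_report")
  expect_identical(rep$n_ti, 16L)
  expect_identical(rep$modes$label$flagged_tis, c(9L, 12L))
  expect_true(is.finite(rep$modes$control$mse_median))
  expect_true(rep$negative_perfusion_fraction >= 0 &&
                rep$negative_perfusion_fraction <= 1)
  expect_named(rep$roi_mean_mse$label)

  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_qa_report(rep, tmp)
  back <- read_qa_report(tmp)
  expect_equal(back$modes$label$per_ti_scores, rep$modes$label$per_ti_scores)
  expect_equal(back$tis_ms, rep$tis_ms)
  expect_equal(back$modes$label$mse_median, rep$modes$label$mse_median)
  expect_equal(unlist(back$edge_displacement$magnitude_px),
               rep$edge_displacement$magnitude_px)
})

test_that("flags vanish as the corruption amplitude goes to zero", {
  sched <- nmv_schedule()
  score_at <- function(mag) {
    ev <- if (mag > 0)
      list(corruption_event(12, "through_plane_mismatch", magnitude = mag))
    else list()
    spec <- small_spec(corruptions = ev)
    ser <- thin_mask(simulate_series(build_phantom(spec), sched, seed = 7),
                     stride = 4)
    fit <- fit_series(ser, "label")
    fl <- flag_corrupted_tis(fit)
    list(score = fl$score[12], flagged = any(fl$flagged))
  }
  s0 <- score_at(0)
  s2 <- score_at(0.2)
  s5 <- score_at(0.5)
  expect_false(s0$flagged)
  expect_true(s5$flagged)
  # per-TI score grows monotonically with the injected amplitude
  expect_gt(s2$score, s0$score)
  expect_gt(s5$score, s2$score)
})

test_that("a single corrupted TI attains the top score in >= 18/20 phantoms", {
  sched <- nmv_schedule()
  set.seed(99)
  hits <- 0L
  for (i in 1:20) {
    ti <- sample(5:15, 1)
    mag <- runif(1, 0.3, 0.7)
    ev <- corruption_event(ti, "through_plane_mismatch", magnitude = mag)
    spec <- small_spec(corruptions = list(ev), seed = i)
    ser <- thin_mask(simulate_series(build_phantom(spec), sched), stride = 4)
    fit <- fit_series(ser, "label")
    fl <- flag_corrupted_tis(fit)
    if (which.max(fl$score) == ti) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("exclusion restores accuracy without inflating the histogram spread", {
  res <- exclude_and_refit(qa_fix$corr, c(9L, 12L),
                           fit_label_before = qa_fix$fit_corr)
  fw_b <- attr(res$summary, "perfusion_fwhm_before")
  fw_a <- attr(res$summary, "perfusion_fwhm_after")
  expect_true(is.finite(fw_b) && is.finite(fw_a))
  expect_lt(abs(fw_a - fw_b) / fw_b, 0.25)
})

test_that("corrupted acquisitions have right-shifted MSE relative to clean", {
  mse_c <- median(qa_fix$fit_corr$mse_map, na.rm = TRUE)
  mse_0 <- median(qa_fix$fit_clean$mse_map, na.rm = TRUE)
  expect_gt(mse_c, 2 * mse_0)
})

test_that("clean low-noise acquisitions have almost no negative perfusion", {
  spec <- small_spec(noise = list(model = "gaussian", sigma = 0.01))
  ser <- thin_mask(simulate_series(build_phantom(spec), mv_schedule(),
                                   seed = 2))
  perf <- perfusion_map(fit_series(ser, "label"), fit_series(ser, "control"))
  v <- perf$values[is.finite(perf$values)]
  expect_lt(mean(v < 0), 0.01)
})
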