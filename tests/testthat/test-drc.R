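test_that("pointwise toxicity effect", {
  nc <- c(1, 2, 3, 4)
  s <- make_set(list(nc, nc * 1.5, c(1, 2, 0, 0)), nc)
  # identical to NC at every grid hour
  for (t in 0:3) expect_equal(toxicity_effect_point(s, t, 1), 0)
  expect_equal(toxicity_effect_point(s, 2, 2), 50)
  expect_equal(toxicity_effect_point(s, 3, 3), -100)   # total kill
  expect_error(toxicity_effect_point(s, 2.5, 1), "grid")
  s0 <- make_set(list(c(1, 1)), c(1, 0))
  expect_error(toxicity_effect_point(s0, 1, 1), "0 at t")
  # invariance to common positive rescaling of both curves
  s2 <- make_set(list(7 * c(1, 2, 0.5, 3)), 7 * nc)
  s1 <- make_set(list(c(1, 2, 0.5, 3)), nc)
  for (t in 0:3) {
    expect_equal(toxicity_effect_point(s2, t, 1),
                 toxicity_effect_point(s1, t, 1))
  }
})

test_that("AUC toxicity effect matches closed-form integrals", {
  nc <- c(1, 2, 3, 4)
  s <- make_set(list(nc, nc * 2), nc)
  expect_equal(toxicity_effect_auc(s, 3, 1), 0)
  expect_equal(toxicity_effect_auc(s, 3, 2), 100)  # AUC linearity
  # linear curves: trapezoid is exact, compare with the analytic ratio
  a1 <- 2; b1 <- 0.5; a2 <- 1; b2 <- 0.25
  tr <- a1 + b1 * (0:10); ncl <- a2 + b2 * (0:10)
  sl <- make_set(list(tr), ncl)
  for (t in c(1, 4, 10)) {
    int_tr <- a1 * t + b1 * t^2 / 2
    int_nc <- a2 * t + b2 * t^2 / 2
    expect_equal(toxicity_effect_auc(sl, t, 1),
                 100 * (int_tr - int_nc) / int_nc, tolerance = 1e-12)
  }
  # one-step degenerate trapezoid: point and AUC agree for curves
  # launched from zero
  sz <- make_set(list(c(0, 3)), c(0, 2))
  expect_equal(toxicity_effect_auc(sz, 1, 1),
               toxicity_effect_point(sz, 1, 1))
})

test_that("drc_at_time produces rank-ordered 11-value profiles", {
  s <- make_default_set()
  p <- drc_at_time(s, 72)
  expect_length(p$te, 11)
  expect_equal(p$variant, "point")
  # Hill-kill generator: toxicity weakens monotonically with dilution
  expect_true(all(diff(p$te) >= -1e-9))
  expect_true(all(p$te <= 1e-9))
  pa <- drc_at_time(s, 72, variant = "auc")
  expect_length(pa$te, 11)
  # all-identical curves give the zero vector
  nc <- rep(2, 5)
  sid <- make_set(rep(list(nc), 3), nc)
  expect_equal(drc_at_time(sid, 4)$te, rep(0, 3))
})

test_that("sr_time_profile localizes the informative window", {
  # clusters identical before the onset hour, divergent after
  cfg <- preset_config("window")
  cfg$counts <- c(8L, 8L)
  ds <- generate_dataset(cfg, seed = 61)
  times <- c(6, 12, 24, 48, 60, 72)
  prof <- sr_time_profile(ds$sets, times, reps = 20, seed = 3)
  expect_equal(prof$time_h, times)
  expect_true(all(prof$mean_sr >= 0 & prof$mean_sr <= 1))
  early <- mean(prof$mean_sr[prof$time_h < 36])
  late <- mean(prof$mean_sr[prof$time_h > 36])
  expect_gt(late, early + 0.1)  # clearly elevated after divergence onset
  # single time point gives a single row
  expect_equal(nrow(sr_time_profile(ds$sets, 48, reps = 5, seed = 3)), 1)
})

test_that("select_time_interval picks the longest qualifying run", {
  prof <- data.frame(time_h = 1:72, mean_sr = c(rep(0.5, 29), rep(0.9, 43)))
  iv <- select_time_interval(prof, threshold = 0.8)
  expect_equal(iv$start, 30)
  expect_equal(iv$end, 72)
  # constant-high profile: the full window qualifies
  ivc <- select_time_interval(data.frame(time_h = 1:72,
                                         mean_sr = rep(0.9, 72)),
                              threshold = 0.8)
  expect_equal(c(ivc$start, ivc$end), c(1, 72))
  # nothing qualifies: empty-selection signal
  expect_null(select_time_interval(prof, threshold = 0.95))
  # default threshold is the profile mean
  iv2 <- select_time_interval(prof)
  expect_equal(iv2$threshold, mean(prof$mean_sr))
})

test_that("restrict_tcrc truncates all curves consistently", {
  s <- make_default_set()
  full <- restrict_tcrc(s, list(start = 0, end = 72))
  expect_equal(full$curves[[1]]$nci, s$curves[[1]]$nci)
  r <- restrict_tcrc(s, list(start = 30, end = 72))
  expect_length(r$curves[[1]]$nci, 43)
  expect_length(r$negative_control$nci, 43)
  expect_equal(r$curves[[3]]$times[1], 30)
  expect_error(restrict_tcrc(s, list(start = -5, end = 72)), "outside")
  # wavelet block arithmetic still applies to the shorter curves
  ci <- concatenate_tcrc(r, n = 11, include_nc = TRUE)
  expect_length(ci$values, 12 * 43)
  d <- dwt_decompose(ci$values, 5)
  expect_equal(d$block_lengths, dwt_block_lengths(12 * 43, 5))
})
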