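test_that("compute_cell_index matches the max-ratio definition", {
  # no cells: impedance equals background at every frequency
  expect_equal(compute_cell_index(c(2, 5, 9), c(2, 5, 9)), 0)
  expect_equal(compute_cell_index(3, 2), 0.5)
  # brute-force oracle over all frequencies
  r_b <- c(2, 4, 10)
  r_cell <- c(1.5, 2.0, 1.2) * r_b
  expect_equal(compute_cell_index(r_cell, r_b),
               max(vapply(1:3, function(k) r_cell[k] / r_b[k] - 1,
                          numeric(1))))
  expect_equal(compute_cell_index(r_cell, r_b), 1.0)
})

test_that("compute_cell_index guards and invariances", {
  expect_error(compute_cell_index(numeric(0), numeric(0)), "empty")
  expect_error(compute_cell_index(c(1, 2), c(1, 0)), "> 0")
  expect_error(compute_cell_index(c(1, 2), 1), "equal length")
  # permutation invariance
  set.seed(4)
  for (i in 1:20) {
    r_b <- runif(5, 1, 10); r_cell <- runif(5, 0.5, 30)
    p <- sample(5)
    expect_equal(compute_cell_index(r_cell, r_b),
                 compute_cell_index(r_cell[p], r_b[p]))
  }
  expect_gte(compute_cell_index(runif(4, 0.01, 1), runif(4, 1, 10)), -1)
})

test_that("normalize_ci divides by the pre-treatment value", {
  s <- cell_index_series(c(-1, 0, 1, 2), c(3, 3, 3, 3))
  expect_equal(normalize_ci(s)$nci, rep(1, 4))
  s2 <- cell_index_series(c(0, 5), c(2, 4))
  expect_equal(normalize_ci(s2)$nci, c(1, 2))
  expect_error(normalize_ci(cell_index_series(c(0, 1), c(0, 1))), "> 0")
  # scale invariance
  set.seed(5)
  tt <- c(-2, 0, 1, 3, 7)
  v <- runif(5, 0.5, 4)
  for (c0 in c(0.1, 2, 117)) {
    expect_equal(normalize_ci(cell_index_series(tt, v * c0))$nci,
                 normalize_ci(cell_index_series(tt, v))$nci)
  }
})

test_that("resample_uniform is exact on knots and on cubics", {
  # identity on an already-hourly grid
  set.seed(6)
  v <- cumsum(rnorm(11))
  out <- resample_uniform(0:10, v)
  expect_equal(out$times, 0:10)
  expect_equal(out$nci, v, tolerance = 0)
  # a cubic is reproduced exactly (not-a-knot end condition)
  p <- function(t) 0.1 * t^3 - t^2 + t + 1
  tt <- c(0, 0.7, 1.9, 3.2, 4.4, 6.1, 7.5, 9.3, 10)
  out <- resample_uniform(tt, p(tt), t_start = 0, t_end = 10)
  expect_equal(out$nci, p(0:10), tolerance = 1e-9)
})

test_that("resample_uniform guards", {
  expect_error(resample_uniform(c(0, 1, 2), c(1, 1, 1)), "4 distinct")
  expect_error(resample_uniform(c(0.5, 1, 2, 3.5), c(1, 1, 1, 1),
                                t_start = 0, t_end = 3), "span")
})

test_that("preprocess_well yields a 73-sample 0-72 h TCRC", {
  tt <- sort(c(-2, 0, runif(120, 0.01, 74.9), 75))
  v <- 2 * (1 + 0.05 * tt + 0.001 * tt^2)
  cv <- preprocess_well(cell_index_series(tt, v), 10, "x")
  expect_length(cv$nci, 73)
  expect_equal(cv$times, 0:72)
  expect_equal(cv$nci[1], 1)  # NCI anchored at treatment
})

test_that("tcrc_set validates its invariants", {
  tt <- 0:5
  mk <- function(conc) tcrc(tt, rep(1, 6), conc)
  nc <- tcrc(tt, rep(1, 6), "negative_control")
  good <- lapply(c(9, 3, 1), mk)
  expect_s3_class(tcrc_set("c", good, nc, n_curves = 3), "tcrc_set")
  expect_error(tcrc_set("c", lapply(c(1, 3, 9), mk), nc, n_curves = 3),
               "decreasing")
  expect_error(tcrc_set("c", good, mk(5), n_curves = 3), "negative_control")
  bad_grid <- tcrc(1:6, rep(1, 6), 0.1)
  expect_error(tcrc_set("c", list(mk(9), mk(3), bad_grid), nc, n_curves = 3),
               "time grid")
  expect_error(tcrc(c(0, 2, 4), c(1, 1, 1), 1), "1 h")
})

test_that("raw reader round-trips generator output", {
  cfg <- preset_config("separable")
  cfg$counts <- c(2L, rep(1L, 6))
  ds <- generate_dataset(cfg, seed = 9)
  td <- withr::local_tempdir()
  dp <- file.path(td, "data.csv"); pp <- file.path(td, "platemap.csv")
  write_raw_dataset(ds, dp, pp)
  back <- read_rtca(dp, pp)
  expect_length(back, length(ds$sets))
  s0 <- ds$sets[[1]]; s1 <- back[[1]]
  expect_equal(s1$chemical_id, s0$chemical_id)
  expect_equal(s1$label, s0$label)
  # reader re-normalizes at t = 0, so compare on that scale
  expect_equal(s1$curves[[1]]$nci,
               s0$curves[[1]]$nci / s0$curves[[1]]$nci[1],
               tolerance = 1e-10)
  # tcrc_set serialization round-trips exactly
  sp <- file.path(td, "sets.csv")
  write_tcrc_sets(ds$sets, sp)
  back2 <- read_tcrc_sets(sp)
  expect_equal(back2[[1]]$curves[[5]]$nci, ds$sets[[1]]$curves[[5]]$nci,
               tolerance = 1e-12)
  expect_equal(back2[[2]]$negative_control$nci,
               ds$sets[[2]]$negative_control$nci, tolerance = 1e-12)
})
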