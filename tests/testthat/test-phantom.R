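test_that("label map ground truth is exact voxel arithmetic and tracks the request", {
  sp <- small_spec()
  voxvol <- sp$fov[1] / sp$matrix_size[1] * sp$fov[2] / sp$matrix_size[2] *
    sp$slice_thickness
  for (week in c(1, 4, 8)) {
    lm_ <- build_label_map(sp, week)
    n_tumor <- sum(lm_$labels == lm_$classes[["tumor"]])
    expect_identical(lm_$ground_truth_tumor_volume, n_tumor * voxvol)
    expect_lt(abs(lm_$ground_truth_tumor_volume - tumor_volume_at_week(sp, week)),
              voxvol)
  }
  # week-1 default request of 0.5 mm3 discretizes to within one voxel volume
  lm1 <- build_label_map(sp, 1)
  expect_lt(abs(lm1$ground_truth_tumor_volume - 0.5), voxvol)
})

test_that("default growth rate puts week-8 volume at 38 mm3", {
  sp <- phantom_spec()
  expect_equal(sp$growth_rate, log(38 / 0.5) / 7)
  expect_equal(tumor_volume_at_week(sp, 8), 38, tolerance = 1e-12)
})

test_that("an impossible tumor volume names the week and volumes", {
  sp <- small_spec()
  expect_error(build_label_map(sp, 20), "week 20.*exceeds available brain")
})

test_that("labels use only declared classes and the tumor is carved from brain", {
  sp <- small_spec()
  lm_ <- build_label_map(sp, 5)
  expect_true(all(lm_$labels %in% lm_$classes))
  # rebuilding with a negligible tumor shows the blob replaced brain voxels:
  # every tumor voxel of the week-5 map is brain in the week-1 map or tumor
  lm1 <- build_label_map(sp, 1)
  replaced <- lm1$labels[lm_$labels == lm_$classes[["tumor"]]]
  expect_true(all(replaced %in% lm_$classes[c("brain", "tumor")]))
})

test_that("rendered intensities follow the decay law and the seed contract", {
  s <- small_session(week = 3, seed = 42)
  idx <- which(s$label_map$labels == s$label_map$classes[["tumor"]],
               arr.ind = TRUE)[1, ]
  for (e in c(1, 5, 10))
    expect_equal(s$stack$intensities[idx[1], idx[2], idx[3], e],
                 100 * exp(-default_te[e] / 68), tolerance = 1e-12)
  # background voxels are zero without noise
  bg <- which(s$label_map$labels == 0, arr.ind = TRUE)[1, ]
  expect_identical(s$stack$intensities[bg[1], bg[2], bg[3], 1], 0)

  sp_n <- small_spec(noise_sd = 1)
  lm_ <- build_label_map(sp_n, 3)
  a <- render_echo_stack(lm_, sp_n, seed = 7)
  b <- render_echo_stack(lm_, sp_n, seed = 7)
  c_ <- render_echo_stack(lm_, sp_n, seed = 8)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c_$intensities))
})

test_that("simulate_flux follows the power law exactly at zero scatter", {
  expect_equal(simulate_flux(1, 5.81, 1.04, 0, seed = 1), 10^5.81)
  expect_equal(simulate_flux(10, 5.81, 1.04, 0, seed = 1), 10^6.85)
  v <- c(0.7, 2, 9, 31)
  fl <- simulate_flux(v, 5.81, 1.04, 0, seed = 1)
  expect_equal(log10(fl), 5.81 + 1.04 * log10(v), tolerance = 1e-12)
  expect_error(simulate_flux(0), "positive")
  expect_error(simulate_flux(-3), "positive")
  expect_identical(simulate_flux(c(1, 4), log_resid_sd = 0.1, seed = 5),
                   simulate_flux(c(1, 4), log_resid_sd = 0.1, seed = 5))
})

test_that("simulated survival cohorts hit the requested median and censoring rules", {
  tab <- simulate_survival_cohort(c(g = 44), n_per_group = 10000,
                                  censor_day = 1e9, seed = 3)
  expect_equal(median(tab$day), 44, tolerance = 0.01)
  expect_true(all(tab$event == 1))

  tab0 <- simulate_survival_cohort(c(g = 44), 10, censor_day = 0, seed = 3)
  expect_true(all(tab0$event == 0))
  expect_true(all(tab0$day == 0))

  t1 <- simulate_survival_cohort(c(a = 40, b = 60), 12, seed = 9)
  t2 <- simulate_survival_cohort(c(a = 40, b = 60), 12, seed = 9)
  expect_identical(t1, t2)
  # censored records are exactly those at the censor day
  t3 <- simulate_survival_cohort(c(a = 100), 200, censor_day = 139, seed = 1)
  expect_true(all(t3$day[t3$event == 0] == 139))
  expect_true(all(t3$day[t3$event == 1] <= 139))
})

test_that("phantom randomness leaves the caller's RNG untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_flux(3, log_resid_sd = 0.2, seed = 99))
  invisible(simulate_survival_cohort(c(a = 10), 5, seed = 99))
  expect_identical(.Random.seed, before)
})
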