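test_that("the decay fitter recovers noiseless exponentials to 1e-6 relative", {
  cases <- list(c(s0 = 100, t2 = 47), c(s0 = 100, t2 = 68),
                c(s0 = 250, t2 = 125), c(s0 = 15, t2 = 20))
  for (cs in cases) {
    f <- fit_pixel_decay(cs["s0"] * exp(-default_te / cs["t2"]), default_te)
    expect_true(f$defined)
    expect_equal(f$s0, unname(cs["s0"]), tolerance = 1e-6)
    expect_equal(f$t2_ms, unname(cs["t2"]), tolerance = 1e-6)
    expect_lt(f$sse, 1e-10)
  }
})

test_that("the fitter matches the two-point closed form on every echo pair", {
  # exponential through S(12.5) = 80 and S(162.5) = 20: T2 = 150 / ln 4
  t2_ref <- t2_two_point(12.5, 162.5, 80, 20)
  expect_equal(t2_ref, 150 / log(4))
  s0_ref <- 80 / exp(-12.5 / t2_ref)
  f <- fit_pixel_decay(s0_ref * exp(-default_te / t2_ref), default_te)
  expect_equal(f$t2_ms, t2_ref, tolerance = 1e-6)
  # every echo pair of the fitted curve reproduces the same decay time
  s_hat <- f$s0 * exp(-default_te / f$t2_ms)
  for (i in 1:5) for (j in 6:10)
    expect_equal(t2_two_point(default_te[i], default_te[j], s_hat[i], s_hat[j]),
                 f$t2_ms, tolerance = 1e-6)
})

test_that("degenerate pixels are flagged undefined, never errors", {
  expect_false(fit_pixel_decay(rep(50, 10), default_te)$defined)   # no decay
  expect_false(fit_pixel_decay(rep(0, 10), default_te)$defined)    # no signal
  expect_false(fit_pixel_decay(rep(-5, 10), default_te)$defined)
  expect_error(fit_pixel_decay(c(3, 2), c(10, 20)), "3 echoes")
})

test_that("scale equivariance: a common intensity factor moves s0 only", {
  s <- 100 * exp(-default_te / 68) + c(0.5, -0.3, 0.2, 0, -0.1, 0.3, -0.2, 0.1, 0, -0.4)
  f1 <- fit_pixel_decay(s, default_te)
  f2 <- fit_pixel_decay(7.5 * s, default_te)
  expect_equal(f2$s0 / f1$s0, 7.5, tolerance = 1e-5)
  expect_equal(f2$t2_ms, f1$t2_ms, tolerance = 1e-5)
})

test_that("T2 mapping on a noiseless phantom recovers per-tissue T2 exactly", {
  s <- small_session(week = 4)
  tm <- compute_t2_map(s$stack)
  lab <- s$label_map$labels
  truth <- c(brain = 47, csf = 125, tumor = 68)
  for (nm in names(truth)) {
    vals <- tm$t2_ms[lab == s$label_map$classes[[nm]]]
    expect_true(all(is.finite(vals)))
    expect_equal(median(vals), unname(truth[nm]), tolerance = 1e-6)
  }
  # background carries the undefined flag, not a silent zero
  expect_true(all(is.na(tm$t2_ms[lab == 0])))
  expect_true(all(!tm$defined[lab == 0]))
})

test_that("per-tissue median T2 stays within 2% of truth at 1% intensity noise", {
  s <- small_session(week = 5, noise_sd = 1, seed = 21)
  tm <- compute_t2_map(s$stack)
  lab <- s$label_map$labels
  truth <- c(brain = 47, csf = 125, tumor = 68)
  for (nm in names(truth)) {
    vals <- tm$t2_ms[lab == s$label_map$classes[[nm]] & tm$defined]
    expect_gt(length(vals), 0)
    expect_lt(abs(median(vals) - truth[nm]) / truth[nm], 0.02)
  }
})

test_that("a mask restricts the map to the masked pixel", {
  s <- small_session(week = 3)
  d <- dim(s$stack$intensities)[1:3]
  mask <- array(FALSE, d)
  idx <- which(s$label_map$labels == 3, arr.ind = TRUE)[1, ]
  mask[idx[1], idx[2], idx[3]] <- TRUE
  tm <- compute_t2_map(s$stack, mask = mask)
  expect_identical(sum(tm$defined), 1L)
  expect_equal(tm$t2_ms[idx[1], idx[2], idx[3]], 68, tolerance = 1e-6)
})

test_that("the display clamp is rendering-only and never alters stored values", {
  s <- small_session(week = 3)
  tm <- compute_t2_map(s$stack, display_clamp_ms = 120)
  csf_vals <- tm$t2_ms[s$label_map$labels == 2]
  expect_true(all(csf_vals > 120))  # CSF T2 of 125 ms survives above the clamp
})

test_that("T2 averaging picks exact echoes and averages pixel-wise", {
  s <- small_session(week = 4)
  avg <- compute_t2_average(s$stack)
  expect_identical(dim(avg$pixels), dim(s$stack$intensities)[1:3])
  idx <- which(s$label_map$labels == 3, arr.ind = TRUE)[1, ]
  expected <- 100 * mean(exp(-c(45.8, 62.5, 79.2) / 68))
  expect_equal(avg$pixels[idx[1], idx[2], idx[3]], expected, tolerance = 1e-12)
  expect_equal(expected, 40.69, tolerance = 1e-3)

  # hand-built stack: a pixel valued (60, 50, 40) across selected echoes
  arr <- array(0, dim = c(2, 2, 1, 3))
  arr[1, 1, 1, ] <- c(60, 50, 40)
  st <- echo_stack(arr, c(45.8, 62.5, 79.2), fov = c(20, 20),
                   slice_thickness = 0.8)
  expect_equal(compute_t2_average(st, c(45.8, 62.5, 79.2))$pixels[1, 1, 1], 50)
  # identity: averaging identical echoes returns the image
  arr2 <- array(rep(matrix(1:4, 2), 3), dim = c(2, 2, 1, 3))
  st2 <- echo_stack(arr2, c(45.8, 62.5, 79.2), fov = c(20, 20),
                    slice_thickness = 0.8)
  expect_equal(compute_t2_average(st2)$pixels[, , 1], matrix(1:4, 2))
  expect_error(compute_t2_average(st, te_subset_ms = 99),
               "not in stack.*45.8")
})
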