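test_that("the product-limit curve matches hand arithmetic and the median rule", {
  k <- km_curve(c(10, 20, 30), c(1, 1, 1))
  expect_equal(k$surv, c(2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(k$median, 20)

  # all censored: survival stays at 1, median undefined
  kc <- km_curve(c(10, 20, 30), c(0, 0, 0))
  expect_true(all(kc$surv == 1))
  expect_true(is.na(kc$median))
  expect_identical(kc$n_events, 0L)

  # single event defines the median at that time
  expect_equal(km_curve(15, 1)$median, 15)

  # exact 0.5 plateau: first time S <= 0.5 is the median
  k4 <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(k4$median, 2)
})

test_that("without censoring KM equals the empirical survival function", {
  set.seed(31)
  t_ <- sort(sample(1:200, 40, replace = FALSE))
  k <- km_curve(t_, rep(1, 40))
  emp <- vapply(k$time, function(x) mean(t_ > x), numeric(1))
  expect_equal(k$surv, emp, tolerance = 1e-12)
})

test_that("the median ignores censoring that occurs after the median time", {
  t_ <- c(10, 20, 30, 40, 50)
  base <- km_curve(t_, rep(1, 5))
  cens <- km_curve(t_, c(1, 1, 1, 0, 0))  # censor strictly after the median
  expect_equal(base$median, cens$median)
})

test_that("log-rank matches brute-force risk-set tabulation and is symmetric", {
  ta <- c(1, 2, 3); tb <- c(10, 20, 30)
  ea <- eb <- c(1, 1, 1)
  lr <- logrank(ta, ea, tb, eb)
  ref <- logrank_bruteforce(ta, ea, tb, eb)
  expect_equal(lr$chisq, ref$chisq, tolerance = 1e-9)
  expect_equal(lr$p, ref$p, tolerance = 1e-9)

  set.seed(12)
  tc <- rexp(12, 1/40); td <- rexp(15, 1/60)
  ec <- rbinom(12, 1, 0.8); ed <- rbinom(15, 1, 0.8)
  ec[1] <- 1; ed[1] <- 1
  lr2 <- logrank(tc, ec, td, ed)
  ref2 <- logrank_bruteforce(tc, ec, td, ed)
  expect_equal(lr2$chisq, ref2$chisq, tolerance = 1e-9)
  swap <- logrank(td, ed, tc, ec)
  expect_equal(lr2$chisq, swap$chisq, tolerance = 1e-12)

  same <- logrank(tc, ec, tc, ec)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  expect_warning(z <- logrank(c(5, 6), c(0, 0), tb, eb), "zero events")
  expect_true(is.na(z$chisq))
})

test_that("Mann-Whitney exact p matches full enumeration for small samples", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(unname(r$U), 0)
  expect_equal(r$p, 2/6, tolerance = 1e-12)

  set.seed(44)
  for (i in 1:5) {
    a <- sample(seq(1, 200, by = 3), sample(2:4, 1))
    b <- sample(seq(2, 200, by = 3), sample(2:4, 1))
    got <- mann_whitney(a, b)
    expect_equal(got$p, mann_whitney_enum(a, b), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }

  # identical multisets: the exact two-sided p is 1
  expect_equal(mann_whitney(c(3, 7, 9), c(3, 7, 9))$p, 1, tolerance = 1e-12)

  # extreme separation attains the smallest two-sided p for those sizes
  ext <- mann_whitney(1:4, 101:104)
  expect_equal(ext$p, 2 / choose(8, 4), tolerance = 1e-12)
})

test_that("percent enhancement reproduces printed medians and sign rules", {
  cases <- rbind(c(66, 44, 50), c(73, 59, 24), c(66, 50, 32),
                 c(73, 63, 16), c(50, 44, 14), c(63, 59, 7))
  for (i in seq_len(nrow(cases)))
    expect_identical(percent_enhancement(cases[i, 1], cases[i, 2]),
                     cases[i, 3])
  expect_identical(percent_enhancement(44, 44), 0)
  expect_true(is.na(percent_enhancement(NA, 44)))
  # anti-symmetry of sign
  expect_gt(percent_enhancement(60, 50), 0)
  expect_lt(percent_enhancement(50, 60), 0)
})

test_that("simulated medians 44 vs 66 yield about 50% enhancement at n = 10000", {
  tab <- simulate_survival_cohort(c(control = 44, treated = 66),
                                  n_per_group = 10000, censor_day = 1e9,
                                  seed = 6)
  rep_ <- survival_report(tab, "control")
  expect_lte(abs(rep_$tests$pct_enhancement - 50), 2)
  expect_equal(rep_$groups$control$median, 44, tolerance = 0.02)
  expect_equal(rep_$groups$treated$median, 66, tolerance = 0.02)
})

test_that("the survival report assembles per-group tests against the control", {
  tab <- simulate_survival_cohort(c(sham = 44, rt = 50, rt_dec_abc = 66),
                                  n_per_group = 8, seed = 13)
  rep_ <- survival_report(tab, "sham")
  expect_setequal(rep_$tests$group, c("rt", "rt_dec_abc"))
  expect_true(all(c("logrank_p", "mw_p", "pct_enhancement") %in%
                  names(rep_$tests)))
  expect_identical(length(rep_$groups), 3L)
  expect_error(survival_report(tab, "nope"), "not present")
})
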