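test_that("wCV matches direct arithmetic and handles zeros by policy", {
  same <- paired_samples(1:5, c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(wcv(same), 0)
  one <- paired_samples("s", 3, 1)
  expect_equal(wcv(one), sqrt(0.5))
  # a single-sided zero is a finite term of value 2 and is retained
  expect_equal(wcv(paired_samples("s", 0, 4)), sqrt(2))
  withzero <- paired_samples(1:3, c(3, 0, 0), c(1, 0, 4))
  expect_equal(wcv(withzero), sqrt(mean(c(0.5, 2))))
  expect_error(wcv(withzero, zero_policy = "error"), "a = b = 0")
  allzero <- paired_samples(1:2, c(0, 0), c(0, 0))
  expect_error(wcv(allzero), "no usable pairs")
  expect_error(paired_samples(1, -1, 2), "non-negative")
})

test_that("RC is 1.96 * sqrt(2) * wCV, exactly", {
  expect_equal(rc(0) , 0)
  expect_error(rc(-0.1), "non-negative")
  for (w in c(0.01, 0.119, 0.124, 0.5)) expect_equal(rc(w) / w, 1.96 * sqrt(2))
})

test_that("wCV is invariant to global rescaling and to swapping the scans", {
  for (s in 1:5) {
    p <- rand_pairs(30, seed = s)
    w <- wcv(p)
    for (c in c(0.01, 3, 1e4)) {
      ps <- p; ps$a <- ps$a * c; ps$b <- ps$b * c
      expect_equal(wcv(ps), w)
    }
    sw <- p; sw$a <- p$b; sw$b <- p$a
    expect_equal(wcv(sw), w)
    # appending a perfectly repeatable pair never increases wCV
    aug <- rbind(p, paired_samples("extra", 7.7, 7.7))
    expect_lte(wcv(aug), w)
  }
})

test_that("bootstrap CIs are seed-reproducible and degenerate correctly", {
  p <- rand_pairs(16, seed = 2)
  ci1 <- bootstrap_ci(p, "wcv", n_boot = 500, seed = 31)
  ci2 <- bootstrap_ci(p, "wcv", n_boot = 500, seed = 31)
  expect_identical(ci1, ci2)
  expect_false(identical(ci1, bootstrap_ci(p, "wcv", n_boot = 500, seed = 32)))
  expect_true(ci1[1] <= wcv(p) && wcv(p) <= ci1[2])
  # rc interval is the wcv interval scaled
  expect_equal(bootstrap_ci(p, "rc", n_boot = 500, seed = 31), rc(ci1))
  same <- paired_samples(1:6, rep(2, 6), rep(2, 6))
  expect_equal(bootstrap_ci(same, "wcv", n_boot = 100, seed = 1), c(0, 0))
  expect_error(bootstrap_ci(paired_samples("s", 3, 1), "wcv"), "at least 2")
})

test_that("repeatability() bundles consistent point and interval estimates", {
  p <- rand_pairs(18, seed = 4)
  p$a[17:18] <- 0; p$b[17:18] <- 0
  est <- repeatability(p, n_boot = 300, seed = 9)
  expect_equal(est$rc / est$wcv, 1.96 * sqrt(2))
  expect_identical(est$n_subjects, 16L)
  expect_identical(est$n_excluded_zero_pairs, 2L)
  expect_lte(est$rc_ci_low, est$rc)
  expect_gte(est$rc_ci_high, est$rc)
})

test_that("Bland-Altman matches closed forms and flips sign under pair swap", {
  same <- paired_samples(1:4, 1:4, 1:4)
  ba0 <- bland_altman(same)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_low, 0); expect_equal(ba0$loa_high, 0)
  two <- paired_samples(1:2, c(10, 20), c(12, 22))
  ba <- bland_altman(two)
  expect_equal(ba$bias, 2); expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(2, 2))
  for (s in 1:3) {
    p <- rand_pairs(20, seed = s)
    sw <- p; sw$a <- p$b; sw$b <- p$a
    expect_equal(bland_altman(sw)$bias, -bland_altman(p)$bias)
  }
  expect_equal(bland_altman(two, sign = "a_minus_b")$bias, -2)
  expect_error(bland_altman(paired_samples("s", 1, 2)), "at least 2")
})

test_that("ICC variants behave definitionally and match an aov()-based oracle", {
  set.seed(8)
  x <- rnorm(20, 10, 4)
  # duplicated column: perfect agreement
  expect_equal(icc(cbind(x, x))$value, 1)
  # constant offset: consistency 1, agreement < 1
  off <- cbind(x, x + 2)
  expect_lt(icc(off, "agreement")$value, 1)
  expect_equal(icc(off, "consistency")$value, 1)
  expect_error(icc(cbind(rep(3, 5), rep(3, 5))), "undefined")
  # oracle: mean squares from aov() on the long layout
  M <- cbind(x, x + rnorm(20, 0, 1.5))
  long <- data.frame(y = c(M), subj = factor(rep(1:20, 2)),
                     rater = factor(rep(1:2, each = 20)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  n <- 20; k <- 2
  oracle <- (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
  expect_equal(icc(M, "agreement")$value, oracle)
})

test_that("Pearson correlation handles log-log and degenerate designs", {
  x <- c(1, 2, 3, 4, 5)
  r <- correlation_r2(x, 2 * x + 1)
  expect_equal(r$r2, 1)
  y <- c(1, -2, 0, 2, -1) # orthogonal to centered x
  expect_equal(correlation_r2(x, y + 5)$r2, 0)
  # log-log drops non-positive pairs before transforming
  lx <- c(0, 10, 100, 1000, 10000); ly <- c(5, 1, 2, 4, 8)
  rl <- correlation_r2(lx, ly, log_log = TRUE)
  expect_identical(rl$n, 4L)
  expect_error(correlation_r2(1:2, 1:2), "at least 3")
})

test_that("the SUVmax profile strata follow the start/step rule and noise structure", {
  set.seed(21)
  # two noise strata: low-avidity lesions repeat worse
  n <- 200
  smax <- c(runif(n, 2, 5), runif(n, 25, 35))
  wtrue <- rep(c(0.30, 0.05), each = n)
  tv <- runif(2 * n, 1, 10)
  a <- tv * (1 + rnorm(2 * n, 0, wtrue)); b <- tv * (1 + rnorm(2 * n, 0, wtrue))
  p <- paired_samples(seq_along(a), pmax(a, 0.01), pmax(b, 0.01))
  prof <- rc_suvmax_profile(p, smax, start = 1, step = 5, mode = "above")
  expect_equal(prof$threshold[1:4], c(1, 6, 11, 16))
  # discarding low-SUVmax lesions improves (lowers) RC
  expect_lt(prof$rc[prof$threshold == 16], prof$rc[prof$threshold == 1])
  # single-stratum input: only one populated row
  p1 <- p[1:50, ]
  prof1 <- rc_suvmax_profile(p1, rep(12, 50), start = 1, step = 5, mode = "above")
  expect_identical(sum(prof1$n > 0), sum(prof1$threshold <= 12))
  expect_true(all(prof1$n[prof1$threshold <= 12] == 50))
  # below mode includes only lesions under the threshold
  profb <- rc_suvmax_profile(p, smax, start = 1, step = 5, mode = "below")
  expect_identical(profb$n[profb$threshold == 6], sum(smax < 6))
  expect_true(profb$low_n[profb$threshold == 1])
  expect_error(rc_suvmax_profile(p[0, ], numeric(0)), "empty")
})
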