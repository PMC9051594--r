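test_that("phantom generation is deterministic and honors zero retest", {
  sp <- mini_phantom_spec(
    lesions = list(lesion_spec(c(90, 90, 40), "uniform_sphere", 8, 18)),
    retest = list(), seed = 42)
  p1 <- generate_phantom_pair(sp)
  p2 <- generate_phantom_pair(sp)
  expect_identical(p1$scan1$values, p2$scan1$values)
  expect_identical(p1$scan2$values, p2$scan2$values)
  # all retest parameters zero: the two scans are bit-identical
  expect_identical(p1$scan1$values, p1$scan2$values)
  expect_identical(p1$truth1$labels, p1$truth2$labels)
})

test_that("ground-truth masks are exactly the voxel centers inside each sphere", {
  sp <- mini_phantom_spec(
    lesions = list(lesion_spec(c(90, 90, 40), "uniform_sphere", 8.6, 18),
                   lesion_spec(c(30, 90, 150), "uniform_sphere", 5.1, 12)),
    seed = 2)
  pp <- generate_phantom_pair(sp)
  ax <- lapply(1:3, function(a) sp$origin_mm[a] + (seq_len(sp$grid_dim[a]) - 1) * sp$spacing_mm[a])
  for (j in 1:2) {
    l <- sp$lesions[[j]]
    d2 <- outer(outer((ax[[1]] - l$center_mm[1])^2, (ax[[2]] - l$center_mm[2])^2, "+"),
                (ax[[3]] - l$center_mm[3])^2, "+")
    expect_identical(which(pp$truth1$labels == j), which(d2 <= l$size_mm^2))
  }
})

test_that("overlapping specifications are rejected", {
  sp <- mini_phantom_spec(
    lesions = list(lesion_spec(c(90, 90, 40), "uniform_sphere", 8, 18),
                   lesion_spec(c(94, 90, 40), "uniform_sphere", 8, 12)),
    seed = 1)
  expect_error(generate_phantom_pair(sp), "overlap")
  spl <- mini_phantom_spec(
    lesions = list(lesion_spec(c(48, 40, 150), "uniform_sphere", 8, 18)),
    seed = 1)
  expect_error(generate_phantom_pair(spl), "liver")
  expect_error(phantom_spec(lesions = list(lesion_spec(c(1, 1, 1), "uniform_sphere", 8, 18))),
               "beyond the grid")
})

test_that("injected per-lesion amplitude CV is recovered from measured SUVmax pairs", {
  # 18 well-separated lesions; amplitude jitter only
  ctrs <- as.matrix(expand.grid(x = c(25, 64, 103), y = c(25, 103), z = c(30, 75, 115)))
  lesions <- apply(ctrs, 1, function(cc)
    lesion_spec(cc, "uniform_sphere", 7, 20), simplify = FALSE)
  sp <- phantom_spec(grid_dim = c(64L, 64L, 96L), spacing_mm = c(2, 2, 2),
                     background_suv = 0.5,
                     liver = list(center_mm = c(64, 64, 160),
                                  semiaxes_mm = c(20, 16, 14),
                                  mean_suv = 5, sd_suv = 0.5),
                     lesions = lesions,
                     retest = list(lesion_amp_cv = 0.10), seed = 9,
                     patient_id = "amp")
  pp <- generate_phantom_pair(sp)
  s1 <- segment_whole_body(pp$scan1, pp$liver_mask)
  s2 <- segment_whole_body(pp$scan2, pp$liver_mask)
  mt <- match_lesions(s1, s2)
  expect_identical(nrow(mt$pairs), length(lesions))
  t1 <- lesion_table(pp$scan1, s1); t2 <- lesion_table(pp$scan2, s2)
  p <- paired_samples(mt$pairs$lesion_a,
                      t1$suv_max[match(mt$pairs$lesion_a, t1$lesion_id)],
                      t2$suv_max[match(mt$pairs$lesion_b, t2$lesion_id)])
  # Monte-Carlo tolerance ~ 3 * w / sqrt(2 n)
  expect_lt(abs(wcv(p) - 0.10), 3 * 0.10 / sqrt(2 * length(lesions)) + 0.01)
})

test_that("paired cohorts honor their spec and recover the generating wCV", {
  co0 <- simulate_pair_cohort(cohort_spec(50, true_wcv = 0, seed = 3))
  expect_identical(co0$a, co0$b)
  coz <- simulate_pair_cohort(cohort_spec(18, true_wcv = 0.1, n_zero_subjects = 2, seed = 3))
  expect_identical(nrow(coz), 18L)
  expect_identical(sum(coz$a == 0 & coz$b == 0), 2L)
  co1 <- simulate_pair_cohort(cohort_spec(200, true_wcv = 0.1, seed = 3))
  expect_identical(co1, simulate_pair_cohort(cohort_spec(200, true_wcv = 0.1, seed = 3)))
  # estimator recovery at n = 5000: within 3 Monte-Carlo SEs for small,
  # medium and large generating CVs, under both error laws
  for (w in c(0.05, 0.127, 0.277)) {
    for (mdl in c("multiplicative_normal", "multiplicative_lognormal")) {
      co <- simulate_pair_cohort(cohort_spec(5000, true_wcv = w, error_model = mdl,
                                             seed = 17))
      est <- wcv(co)
      se <- w / sqrt(2 * 5000)
      expect_lt(abs(est - w), 3 * se)
    }
  }
})

test_that("error-scale calibration matches the estimator's population value", {
  # the calibrated scale differs from the nominal CV at second order
  s <- calibrate_error_scale(0.277, "multiplicative_lognormal")
  expect_gt(s, 0.277)
  expect_equal(calibrate_error_scale(0, "multiplicative_normal"), 0)
  # very large simulation as an independent check of the calibration target
  set.seed(1)
  e <- matrix(rnorm(2e6, 0, calibrate_error_scale(0.2, "multiplicative_normal")), ncol = 2)
  term <- (e[, 1] - e[, 2])^2 / (2 * (1 + rowMeans(e))^2)
  expect_equal(sqrt(mean(term)), 0.2, tolerance = 0.003)
})

test_that("the 18-patient study fixture has the study's shape", {
  fx <- generate_study_fixture(seed = 101)
  expect_length(fx$patients, 18L)
  nles <- vapply(fx$patients, `[[`, integer(1), "n_lesions")
  expect_identical(sum(nles == 0L), 2L)
  expect_identical(sum(nles), 96L)
  # injected within-subject CV is exact in the finite cohort
  tm <- do.call(rbind, lapply(fx$patients, function(p)
    data.frame(s = p$patient_id, a = p$true_mtv["a"], b = p$true_mtv["b"])))
  expect_equal(wcv(paired_samples(tm$s, tm$a, tm$b)), 0.127, tolerance = 1e-10)
  # per-patient totals span the cohort's range, including large-burden patients
  tot <- vapply(fx$patients, function(p) unname(p$true_mtv["a"]), numeric(1))
  expect_gt(max(tot), 600); expect_lt(min(tot[tot > 0]), 5)
  # deterministic under the seed
  fx2 <- generate_study_fixture(seed = 101)
  expect_identical(fx, fx2)
  p5a <- materialize_patient(fx, 5); p5b <- materialize_patient(fx2, 5)
  expect_identical(p5a$scan1$values, p5b$scan1$values)
  expect_identical(p5a$scan2$values, p5b$scan2$values)
})
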