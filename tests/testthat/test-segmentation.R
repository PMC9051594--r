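test_that("liver threshold follows the sink-effect correction", {
  expect_equal(liver_threshold(list(mean = 4.3, sd = 0))$threshold, 4.3)
  expect_equal(liver_threshold(list(mean = 4.3, sd = 0.7))$threshold, 5.0)
  expect_equal(liver_threshold(list(mean = 2.15, sd = 0.43))$threshold, 5.16)
  expect_error(liver_threshold(list(mean = 0, sd = 0.5)), "degenerate")
  expect_error(liver_threshold(list(mean = 5, sd = -0.1)), "non-negative")
  # strictly decreasing in liver mean for fixed sd > 0: a lowered (sink-
  # suppressed) liver uptake must raise the threshold
  means <- seq(2, 8, by = 0.25)
  thr <- vapply(means, function(m) liver_threshold(list(mean = m, sd = 0.6))$threshold,
                numeric(1))
  expect_true(all(diff(thr) < 0))
})

test_that("SUVpeak equals the sphere mean, with exact degenerate cases", {
  v <- mk_volume(c(15, 15, 15), spacing = c(2, 2, 2), value = 7.2)
  expect_equal(suv_peak(v, c(8, 8, 8)), 7.2)
  # single hot voxel of 100 on zero background: the 1.0 mL sphere at 2 mm
  # isotropic holds 123 voxel centers
  v2 <- mk_volume(c(21, 21, 21), spacing = c(2, 2, 2), value = 0)
  v2$values[11, 11, 11] <- 100
  expect_equal(suv_peak(v2, c(11, 11, 11), 1.0), 100 / 123)
  # sphere smaller than one voxel degenerates to the voxel's own SUV
  expect_equal(suv_peak(v2, c(11, 11, 11), 0.001), 100)
  expect_error(suv_peak(v2, c(0, 1, 1)), "outside")
})

test_that("candidate detection finds one seed per connected component", {
  liver <- mk_liver_ref(threshold = 5.0)
  v <- mk_volume(c(48, 48, 48), spacing = c(2, 2, 2), value = 0.2,
                 spheres = list(list(center = c(20, 20, 20), radius = 8, value = 8),
                                list(center = c(70, 20, 20), radius = 8, value = 8),
                                list(center = c(20, 70, 70), radius = 8, value = 8),
                                list(center = c(70, 70, 70), radius = 8, value = 3)))
  seeds <- detect_candidates(v, liver)
  expect_identical(nrow(seeds), 3L)
  # seed voxels carry the component maximum
  expect_true(all(v$values[seeds] == 8))
  # all-background volume yields an empty list
  expect_identical(nrow(detect_candidates(mk_volume(value = 0.2), liver)), 0L)
})

test_that("components touching under 26-connectivity merge into one seed", {
  liver <- mk_liver_ref(threshold = 5.0)
  arr <- array(0, c(20, 20, 20))
  arr[5:8, 5:8, 5:8] <- 8       # block A
  arr[9:12, 9:12, 9:12] <- 7    # block B, corner-touching A
  v <- suv_volume(arr, c(2, 2, 2))
  # a tiny SUVpeak sphere makes the candidate set the raw threshold set,
  # isolating the connectivity semantics
  s26 <- detect_candidates(v, liver, connectivity = 26L, sphere_volume_ml = 1e-3)
  s6 <- detect_candidates(v, liver, connectivity = 6L, sphere_volume_ml = 1e-3)
  expect_identical(nrow(s26), 1L)
  expect_identical(nrow(s6), 2L)
})

test_that("50% isocontour delineation matches closed-form regions", {
  # uniform sphere on zero background: the mask is the whole sphere
  v <- mk_volume(c(32, 32, 32), spacing = c(2, 2, 2), value = 0,
                 spheres = list(list(center = c(32, 32, 32), radius = 10, value = 10)))
  inside <- which(v$values == 10)
  seed <- arrayInd(inside[1], dim(v$values))[1, ]
  les <- delineate_lesion(v, seed)
  expect_setequal(les$lin, inside)
  # every mask voxel at or above half the mask maximum (the 50% invariant)
  expect_true(min(v$values[les$lin]) >= 0.5 * max(v$values[les$lin]))
  # core 10 inside shell 4: shell is below half-max, mask is the core only
  v2 <- mk_volume(c(32, 32, 32), spacing = c(2, 2, 2), value = 0,
                  spheres = list(list(center = c(32, 32, 32), radius = 14, value = 4),
                                 list(center = c(32, 32, 32), radius = 7, value = 10)))
  core <- which(v2$values == 10)
  les2 <- delineate_lesion(v2, arrayInd(core[1], dim(v2$values))[1, ])
  expect_setequal(les2$lin, core)
  expect_error(delineate_lesion(v, c(1, 1, 1)), "positive")
})

test_that("Gaussian lesion 50% isocontour matches the analytic FWHM ball", {
  # peak 8, sigma 4 mm, 1 mm voxels, generic (non-lattice-aligned) center
  sp <- phantom_spec(grid_dim = c(40L, 40L, 40L), spacing_mm = c(1, 1, 1),
                     background_suv = 0,
                     liver = list(center_mm = c(7, 7, 7), semiaxes_mm = c(4, 3, 3),
                                  mean_suv = 5, sd_suv = 0),
                     lesions = list(lesion_spec(c(25.3, 24.7, 26.1), "gaussian", 4, 8)),
                     seed = 1)
  pp <- generate_phantom_pair(sp)
  seed <- arrayInd(which.max(pp$scan1$values), dim(pp$scan1$values))[1, ]
  les <- delineate_lesion(pp$scan1, seed)
  m <- compute_lesion_metrics(pp$scan1, les)
  analytic_ml <- 4 / 3 * pi * (4 * sqrt(2 * log(2)))^3 / 1000
  expect_equal(m$mtv_ml, analytic_ml, tolerance = 0.05)
  expect_gt(m$suv_mean, 4); expect_lt(m$suv_mean, 8)
  # oracle equivalence: enumeration of grid voxels where the analytic
  # Gaussian reaches half the observed grid maximum
  ax <- lapply(1:3, function(a) 0.5 + (0:39))
  d2 <- outer(outer((ax[[1]] - 25.3)^2, (ax[[2]] - 24.7)^2, "+"),
              (ax[[3]] - 26.1)^2, "+")
  g <- 8 * exp(-d2 / (2 * 16))
  expect_identical(length(les$lin), sum(g >= 0.5 * max(g)))
})

test_that("whole-body segmentation reproduces noiseless ground truth exactly", {
  pp <- generate_phantom_pair(mini_phantom_spec(
    lesions = list(lesion_spec(c(90, 90, 40), "uniform_sphere", 9, 20),
                   lesion_spec(c(30, 90, 40), "uniform_sphere", 6, 15),
                   lesion_spec(c(90, 90, 150), "uniform_sphere", 7, 12)),
    seed = 11))
  seg <- segment_whole_body(pp$scan1, pp$liver_mask)
  expect_length(seg$lesions, 3L)
  got <- sort(unlist(lapply(seg$lesions, `[[`, "lin")))
  expect_identical(got, sort(which(pp$truth1$labels > 0L)))
  lt <- lesion_table(pp$scan1, seg)
  expect_identical(sum(lt$mtv_ml), sum(pp$truth1$labels > 0L) * voxel_volume_ml(pp$scan1))
  # per-run invariants: 50% rule, pairwise disjoint, connected
  for (l in seg$lesions)
    expect_gte(min(pp$scan1$values[l$lin]), 0.5 * max(pp$scan1$values[l$lin]))
  all_lin <- unlist(lapply(seg$lesions, `[[`, "lin"))
  expect_identical(anyDuplicated(all_lin), 0L)
})

test_that("a zero-lesion phantom yields an empty segmentation and zero totals", {
  pp <- generate_phantom_pair(mini_phantom_spec(lesions = list(), seed = 3))
  seg <- segment_whole_body(pp$scan1, pp$liver_mask)
  expect_length(seg$lesions, 0L)
  tot <- aggregate_total(lesion_table(pp$scan1, seg), "Z1", "scan1")
  expect_identical(tot$mtv_total, 0)
  expect_identical(tot$n_lesions, 0L)
})

test_that("segmentation output does not depend on the lesion spec order", {
  les <- list(lesion_spec(c(90, 90, 40), "uniform_sphere", 9, 20),
              lesion_spec(c(30, 90, 40), "uniform_sphere", 6, 15),
              lesion_spec(c(90, 90, 150), "uniform_sphere", 7, 12))
  s1 <- segment_whole_body(generate_phantom_pair(mini_phantom_spec(les, seed = 2))$scan1,
                           generate_phantom_pair(mini_phantom_spec(les, seed = 2))$liver_mask)
  rev_pp <- generate_phantom_pair(mini_phantom_spec(rev(les), seed = 2))
  s2 <- segment_whole_body(rev_pp$scan1, rev_pp$liver_mask)
  expect_identical(sort(unlist(lapply(s1$lesions, `[[`, "lin"))),
                   sort(unlist(lapply(s2$lesions, `[[`, "lin"))))
})

test_that("physiologic hot spots are removed by edits, whole-lesion only", {
  bladder <- lesion_spec(c(90, 30, 150), "uniform_sphere", 10, 25,
                         region_tag = "physiologic")
  pp <- generate_phantom_pair(mini_phantom_spec(
    lesions = list(lesion_spec(c(90, 90, 40), "uniform_sphere", 9, 20)),
    physiologic = list(bladder), seed = 4))
  seg0 <- segment_whole_body(pp$scan1, pp$liver_mask)
  expect_length(seg0$lesions, 2L)    # tumor + bladder
  edits <- list(exclude_points = list(c(45L, 15L, 75L)))
  seg <- segment_whole_body(pp$scan1, pp$liver_mask, edits = edits)
  expect_length(seg$lesions, 1L)
  expect_identical(sort(seg$lesions[[1]]$lin), sort(which(pp$truth1$labels > 0L)))
})

test_that("edits exclude whole lesions by id, include by seed, and are idempotent", {
  pp <- generate_phantom_pair(mini_phantom_spec(
    lesions = list(lesion_spec(c(90, 90, 40), "uniform_sphere", 9, 20),
                   lesion_spec(c(30, 90, 40), "uniform_sphere", 6, 15),
                   lesion_spec(c(90, 90, 150), "uniform_sphere", 7, 12)),
    seed = 11))
  seg <- segment_whole_body(pp$scan1, pp$liver_mask)
  ids <- vapply(seg$lesions, `[[`, integer(1), "lesion_id")
  drop_id <- ids[2]
  e1 <- apply_edits(seg, list(exclude = drop_id), pp$scan1)
  expect_length(e1$lesions, 2L)
  expect_identical(vapply(e1$lesions, `[[`, integer(1), "lesion_id"),
                   setdiff(ids, drop_id))
  expect_error(apply_edits(seg, list(exclude = 99L), pp$scan1), "unknown lesion id")
  # include a missed lesion: remove one, then re-include by seed
  seed_vox <- seg$lesions[[2]]$seed_index
  e2 <- apply_edits(e1, list(include = list(seed_vox)), pp$scan1)
  expect_length(e2$lesions, 3L)
  new <- e2$lesions[[3]]
  expect_gte(min(pp$scan1$values[new$lin]), 0.5 * max(pp$scan1$values[new$lin]))
  # idempotency: the same edit list twice gives the identical result
  edits <- list(exclude = drop_id, include = list(seed_vox))
  once <- apply_edits(seg, edits, pp$scan1)
  twice <- apply_edits(once, edits, pp$scan1)
  expect_identical(lapply(twice$lesions, `[[`, "lin"),
                   lapply(once$lesions, `[[`, "lin"))
})

test_that("lesion matching pairs mutual nearest centroids and surfaces splits", {
  les <- list(lesion_spec(c(90, 90, 40), "uniform_sphere", 9, 20),
              lesion_spec(c(30, 90, 40), "uniform_sphere", 6, 15))
  pp <- generate_phantom_pair(mini_phantom_spec(les, seed = 6))
  seg <- segment_whole_body(pp$scan1, pp$liver_mask)
  # identical segmentations: everything pairs, nothing conflicts
  m0 <- match_lesions(seg, seg)
  expect_identical(nrow(m0$pairs), 2L)
  expect_length(m0$conflicts, 0L)
  expect_length(m0$unmatched_scan1, 0L)
  # small shift well inside the cap still pairs
  pp2 <- generate_phantom_pair(mini_phantom_spec(les, retest = list(shift_mm = c(1, 0, 0)),
                                                 seed = 6))
  seg2 <- segment_whole_body(pp2$scan2, pp2$liver_mask)
  m1 <- match_lesions(seg, seg2, max_centroid_distance_mm = 10)
  expect_identical(nrow(m1$pairs), 2L)
  # split case: one big lesion on scan 1, three nearby fragments on scan 2
  ppA <- generate_phantom_pair(mini_phantom_spec(
    list(lesion_spec(c(90, 90, 100), "uniform_sphere", 10, 20)), seed = 7))
  ppB <- generate_phantom_pair(mini_phantom_spec(
    list(lesion_spec(c(82, 90, 100), "uniform_sphere", 4, 20),
         lesion_spec(c(98, 90, 100), "uniform_sphere", 4, 20),
         lesion_spec(c(90, 90, 110), "uniform_sphere", 4, 20)), seed = 7))
  sA <- segment_whole_body(ppA$scan1, ppA$liver_mask)
  sB <- segment_whole_body(ppB$scan1, ppB$liver_mask)
  ms <- match_lesions(sA, sB, max_centroid_distance_mm = 15)
  expect_gt(length(ms$conflicts), 0L)
  expect_identical(nrow(ms$pairs), 0L)
})
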