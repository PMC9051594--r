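# Small in-code fixtures shared across test files.

# uniform-background volume with optional spherical inserts
mk_volume <- function(dims = c(32, 32, 32), spacing = c(2, 2, 2), value = 0,
                      spheres = list()) {
  arr <- array(value, dim = dims)
  origin <- spacing / 2
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
  for (s in spheres) {
    d2 <- outer(outer((ax[[1]] - s$center[1])^2, (ax[[2]] - s$center[2])^2, "+"),
                (ax[[3]] - s$center[3])^2, "+")
    arr[d2 <= s$radius^2] <- s$value
  }
  suv_volume(arr, spacing, origin, patient_id = "test", scan_id = "scan1")
}

# liver reference with a given threshold, bypassing a rendered liver
mk_liver_ref <- function(threshold = 5.0) {
  liver_threshold(list(mean = threshold, sd = 0),
                  normal_liver_constant = threshold)
}

# an all-in-one small phantom spec: liver + two well-separated lesions
mini_phantom_spec <- function(lesions, physiologic = list(), retest = list(),
                              seed = 1L, patient_id = "mini") {
  phantom_spec(grid_dim = c(64L, 64L, 96L), spacing_mm = c(2, 2, 2),
               background_suv = 0.5,
               liver = list(center_mm = c(40, 40, 150),
                            semiaxes_mm = c(20, 16, 14),
                            mean_suv = 5.0, sd_suv = 0.5),
               lesions = lesions, physiologic = physiologic,
               retest = retest, seed = seed, patient_id = patient_id)
}

# three-patient mini study cohort (one patient with no disease),
# bladder hot spot excluded by both readers' edits
mini_cohort <- function(seed = 5L, vol_scale = 1.15) {
  bladder <- lesion_spec(c(90, 30, 150), "uniform_sphere", 10, 25,
                         region_tag = "physiologic")
  bladder_vox <- c(45L, 15L, 75L)   # (90,30,150) on the 2 mm grid, origin 1
  edits <- list(exclude_points = list(bladder_vox))
  mk_patient <- function(pid, lesions, sd) {
    list(patient_id = pid,
         spec = mini_phantom_spec(lesions, physiologic = list(bladder),
                                  retest = list(vol_scale = vol_scale,
                                                lesion_amp_cv = 0.05),
                                  seed = sd, patient_id = pid),
         edits = list(R1 = edits, R2 = edits))
  }
  structure(list(patients = list(
    mk_patient("M01", list(
      lesion_spec(c(90, 90, 40), "uniform_sphere", 9, 20, "skeletal"),
      lesion_spec(c(30, 90, 40), "uniform_sphere", 6, 15, "nodal")), seed),
    mk_patient("M02", list(
      lesion_spec(c(90, 90, 150), "uniform_sphere", 12, 25, "skeletal"),
      lesion_spec(c(30, 90, 150), "uniform_sphere", 7, 18, "nodal"),
      lesion_spec(c(90, 90, 40), "uniform_sphere", 5.5, 30, "prostate")), seed + 1L),
    mk_patient("M03", list(), seed + 2L)),
    seed = seed), class = "study_fixture")
}

# random paired cohort for property loops
rand_pairs <- function(n, seed, wcv = 0.15) {
  co <- simulate_pair_cohort(cohort_spec(n, true_wcv = wcv, seed = seed))
  co[setdiff(names(co), "true_value")]
}
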