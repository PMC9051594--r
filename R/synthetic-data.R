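# Synthetic paired test-retest data with known ground truth:
# (a) whole-body SUV phantoms -- low background, a liver reference ellipsoid
#     with Gaussian texture, focal lesions, optional physiologic hot spots --
#     re-rendered under a retest perturbation model, and
# (b) tabular paired cohorts with a known true within-subject CV.

#' Lesion specification for phantoms
#'
#' @param center_mm Physical center (mm).
#' @param shape `"uniform_sphere"` (constant SUV inside a radius) or
#'   `"gaussian"` (isotropic Gaussian profile).
#' @param size_mm Radius in mm (uniform sphere) or sigma in mm (Gaussian).
#' @param peak_suv Peak SUV (> 0).
#' @param region_tag Free-text anatomic tag (e.g. `"skeletal"`, `"nodal"`,
#'   `"prostate"`), used by the stratified subgroup mode.
#' @return A list of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, shape = c("uniform_sphere", "gaussian"),
                        size_mm, peak_suv, region_tag = "nodal") {
  shape <- match.arg(shape)
  if (size_mm <= 0) stop("size_mm must be positive")
  if (peak_suv <= 0) stop("peak_suv must be positive")
  structure(list(center_mm = as.numeric(center_mm), shape = shape,
                 size_mm = size_mm, peak_suv = peak_suv,
                 region_tag = region_tag),
            class = "lesion_spec")
}

#' Phantom specification
#'
#' Generative description of one paired test-retest phantom. Defaults: a
#' 128 x 128 x 256 grid at 2 mm isotropic (large enough for a liver
#' ellipsoid plus well-separated lesions, small enough to render in
#' seconds), background 0.5 SUV, liver mean 5.0 / sd 0.5 (placing the
#' liver-referenced candidate threshold near 4.7, above background and below
#' typical lesion peaks).
#'
#' The retest model perturbs the two scans around the specified lesions:
#' \describe{
#'   \item{`lesion_amp_cv`}{per-lesion multiplicative amplitude jitter,
#'     `1 + N(0, cv)` (clamped at 2.5 cv), drawn independently for each of
#'     the two scans -- `cv` is the per-scan amplitude CV, so the
#'     between-scan SUVmax wCV of the rendered pair equals `cv`;}
#'   \item{`vol_cv`}{per-scan multiplicative lesion-volume jitter (mean-one
#'     log-normal), likewise drawn independently per scan, driving
#'     volumetric repeatability; `vol_mode` `"lesion"` draws independently
#'     per lesion, `"patient"` draws one multiplier per scan shared by all
#'     lesions (coherent scan-level variation);}
#'   \item{`vol_scale`}{optional fixed scan2/scan1 volume multiplier(s)
#'     overriding the `vol_cv` draw -- used by calibrated fixtures that
#'     inject an exact CV;}
#'   \item{`global_scale_sd`}{one global uptake scale `1 + N(0, sd)` applied
#'     to the whole second scan (note the liver-referenced threshold is
#'     invariant to it by construction);}
#'   \item{`voxel_noise_sd`}{additive Gaussian voxel noise (SUV) on the
#'     second scan, clamped at zero;}
#'   \item{`shift_mm`}{subvoxel translation applied to the second scan's
#'     lesion centers.}
#' }
#' With all retest parameters zero the two scans are bit-identical.
#'
#' @param grid_dim Integer length-3 grid size.
#' @param spacing_mm Voxel spacing (mm).
#' @param background_suv Background SUV.
#' @param liver List: `center_mm`, `semiaxes_mm`, `mean_suv`, `sd_suv`.
#' @param lesions List of [lesion_spec()] (tumor; enters the ground truth).
#' @param physiologic List of [lesion_spec()] rendered as normal physiologic
#'   uptake (e.g. bladder): present in the image, absent from the truth.
#' @param retest List of retest parameters, see above.
#' @param seed Integer seed; all generation is deterministic under it.
#' @param patient_id Identifier carried into the volumes.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(128L, 128L, 256L),
                         spacing_mm = c(2, 2, 2),
                         background_suv = 0.5,
                         liver = list(center_mm = c(165, 110, 340),
                                      semiaxes_mm = c(55, 40, 32),
                                      mean_suv = 5.0, sd_suv = 0.5),
                         lesions = list(),
                         physiologic = list(),
                         retest = list(),
                         seed = 1L,
                         patient_id = "phantom") {
  retest <- utils::modifyList(list(global_scale_sd = 0, lesion_amp_cv = 0,
                                   vol_cv = 0, vol_mode = "lesion",
                                   vol_scale = NULL, voxel_noise_sd = 0,
                                   shift_mm = c(0, 0, 0)),
                              retest)
  stopifnot(retest$global_scale_sd >= 0, retest$lesion_amp_cv >= 0,
            retest$vol_cv >= 0, retest$voxel_noise_sd >= 0,
            retest$vol_mode %in% c("lesion", "patient"))
  origin <- spacing_mm / 2
  hi <- origin + (grid_dim - 1) * spacing_mm
  for (l in lesions) {
    ext <- if (l$shape == "uniform_sphere") l$size_mm else l$size_mm * sqrt(2 * log(2))
    if (any(l$center_mm - ext < origin) || any(l$center_mm + ext > hi))
      stop("lesion extends beyond the grid")
  }
  structure(list(grid_dim = as.integer(grid_dim),
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = origin,
                 background_suv = background_suv,
                 liver = liver, lesions = lesions, physiologic = physiologic,
                 retest = retest, seed = as.integer(seed),
                 patient_id = patient_id),
            class = "phantom_spec")
}

# coordinate vector of voxel centers along one axis
.axis_mm <- function(spec, ax)
  spec$origin_mm[ax] + (seq_len(spec$grid_dim[ax]) - 1) * spec$spacing_mm[ax]

# indices of the bounding box [lo, hi] (mm) on the grid
.box <- function(spec, lo, hi) {
  lapply(1:3, function(ax) {
    x <- .axis_mm(spec, ax)
    which(x >= lo[ax] & x <= hi[ax])
  })
}

# squared distance field (mm^2) from `center` over a box; returns list(box, d2)
.dist2_box <- function(spec, center, extent_mm) {
  bx <- .box(spec, center - extent_mm, center + extent_mm)
  if (any(vapply(bx, length, integer(1)) == 0L)) return(NULL)
  dx2 <- (.axis_mm(spec, 1)[bx[[1]]] - center[1])^2
  dy2 <- (.axis_mm(spec, 2)[bx[[2]]] - center[2])^2
  dz2 <- (.axis_mm(spec, 3)[bx[[3]]] - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  list(box = bx, d2 = d2)
}

.liver_inside <- function(spec) {
  lv <- spec$liver
  bx <- .box(spec, lv$center_mm - lv$semiaxes_mm, lv$center_mm + lv$semiaxes_mm)
  ex2 <- (.axis_mm(spec, 1)[bx[[1]]] - lv$center_mm[1])^2 / lv$semiaxes_mm[1]^2
  ey2 <- (.axis_mm(spec, 2)[bx[[2]]] - lv$center_mm[2])^2 / lv$semiaxes_mm[2]^2
  ez2 <- (.axis_mm(spec, 3)[bx[[3]]] - lv$center_mm[3])^2 / lv$semiaxes_mm[3]^2
  list(box = bx, inside = outer(outer(ex2, ey2, "+"), ez2, "+") <= 1)
}

.render_scan <- function(spec, radius_scale, amp, global, noise, shift,
                         liver_texture, scan_id) {
  arr <- array(spec$background_suv * global, dim = spec$grid_dim)
  li <- .liver_inside(spec)
  sub <- arr[li$box[[1]], li$box[[2]], li$box[[3]]]
  sub[li$inside] <- pmax(0, (spec$liver$mean_suv + spec$liver$sd_suv * liver_texture) * global)
  arr[li$box[[1]], li$box[[2]], li$box[[3]]] <- sub
  all_les <- c(spec$lesions, spec$physiologic)
  n_tumor <- length(spec$lesions)
  for (j in seq_along(all_les)) {
    l <- all_les[[j]]
    tumor <- j <= n_tumor
    sc <- if (tumor) radius_scale[j] else 1
    am <- if (tumor) amp[j] else 1
    ctr <- l$center_mm + if (tumor) shift else 0
    if (l$shape == "uniform_sphere") {
      r <- l$size_mm * sc
      db <- .dist2_box(spec, ctr, rep(r, 3))
      if (is.null(db)) next
      sub <- arr[db$box[[1]], db$box[[2]], db$box[[3]]]
      sel <- db$d2 <= r^2
      sub[sel] <- pmax(sub[sel], l$peak_suv * am * global)
    } else {
      s <- l$size_mm * sc
      ext <- 4 * s
      db <- .dist2_box(spec, ctr, rep(ext, 3))
      if (is.null(db)) next
      sub <- arr[db$box[[1]], db$box[[2]], db$box[[3]]]
      contrib <- l$peak_suv * am * global * exp(-db$d2 / (2 * s^2))
      sub <- pmax(sub, contrib)
    }
    arr[db$box[[1]], db$box[[2]], db$box[[3]]] <- sub
  }
  if (noise > 0)
    arr <- pmax(arr + array(stats::rnorm(length(arr), 0, noise), dim = dim(arr)), 0)
  suv_volume(arr, spec$spacing_mm, spec$origin_mm,
             patient_id = spec$patient_id, scan_id = scan_id)
}

.truth_labels <- function(spec, radius_scale, shift) {
  lab <- array(0L, dim = spec$grid_dim)
  for (j in seq_along(spec$lesions)) {
    l <- spec$lesions[[j]]
    r <- if (l$shape == "uniform_sphere") l$size_mm * radius_scale[j]
         else l$size_mm * radius_scale[j] * sqrt(2 * log(2))
    db <- .dist2_box(spec, l$center_mm + shift, rep(r, 3))
    if (is.null(db)) next
    sub <- lab[db$box[[1]], db$box[[2]], db$box[[3]]]
    sel <- db$d2 <= r^2
    if (any(sub[sel] != 0L)) stop("overlapping lesion specifications")
    sub[sel] <- j
    lab[db$box[[1]], db$box[[2]], db$box[[3]]] <- sub
  }
  voi_mask(lab, spec$spacing_mm, spec$origin_mm)
}

#' Generate a paired test-retest phantom
#'
#' Renders the two scans of one test-retest acquisition from the phantom
#' specification, drawing each scan's amplitude and volume perturbations
#' independently per the retest model (see [phantom_spec()]). Ground-truth
#' lesion label masks are returned for both scans (the truth of a Gaussian
#' lesion is its analytic half-maximum ball, the target of 50% isocontour
#' delineation).
#' Deterministic under `spec$seed`: the same spec yields bit-identical
#' output on every call.
#'
#' @param spec A [phantom_spec()].
#' @return List: `scan1`, `scan2` ([suv_volume()]), `liver_mask`, `truth1`,
#'   `truth2` ([voi_mask()]), `draws` (the realized retest multipliers).
#' @export
generate_phantom_pair <- function(spec) {
  .with_seed(spec$seed, {
    li <- .liver_inside(spec)
    texture <- stats::rnorm(sum(li$inside))
    L <- length(spec$lesions)
    rt <- spec$retest
    draw_amp <- function()
      if (L) pmax(0.05, pmin(pmax(1 + stats::rnorm(L, 0, rt$lesion_amp_cv),
                                  1 - 2.5 * rt$lesion_amp_cv),
                             1 + 2.5 * rt$lesion_amp_cv)) else numeric(0)
    amp1 <- draw_amp(); amp2 <- draw_amp()
    draw_vol <- function() {
      if (rt$vol_cv > 0 && L) {
        s <- sqrt(log(1 + rt$vol_cv^2))
        nd <- if (rt$vol_mode == "patient") 1L else L
        rep_len(exp(stats::rnorm(nd, -s^2 / 2, s)), L)
      } else rep(1, L)
    }
    if (!is.null(rt$vol_scale)) {
      m1 <- rep(1, L); m2 <- rep_len(rt$vol_scale, L)
    } else {
      m1 <- draw_vol(); m2 <- draw_vol()
    }
    g <- if (rt$global_scale_sd > 0) max(0.2, 1 + stats::rnorm(1, 0, rt$global_scale_sd)) else 1
    truth1 <- .truth_labels(spec, m1^(1 / 3), c(0, 0, 0))
    truth2 <- .truth_labels(spec, m2^(1 / 3), rt$shift_mm)
    lab <- array(0L, dim = spec$grid_dim)
    sub <- lab[li$box[[1]], li$box[[2]], li$box[[3]]]
    sub[li$inside] <- 1L
    lab[li$box[[1]], li$box[[2]], li$box[[3]]] <- sub
    liver_mask <- voi_mask(lab, spec$spacing_mm, spec$origin_mm)
    if (any(truth1$labels > 0L & liver_mask$labels > 0L) ||
        any(truth2$labels > 0L & liver_mask$labels > 0L))
      stop("lesion specification overlaps the liver reference VOI")
    scan1 <- .render_scan(spec, m1^(1 / 3), amp1, 1, 0, c(0, 0, 0),
                          texture, "scan1")
    scan2 <- .render_scan(spec, m2^(1 / 3), amp2, g, rt$voxel_noise_sd,
                          rt$shift_mm, texture, "scan2")
    list(scan1 = scan1, scan2 = scan2, liver_mask = liver_mask,
         truth1 = truth1, truth2 = truth2,
         draws = list(amp1 = amp1, amp2 = amp2, vol1 = m1, vol2 = m2,
                      global = g))
  })
}

# ---- tabular paired cohorts ----

#' Cohort specification for tabular paired simulation
#'
#' Describes a cohort of subjects with log-normal true burden values and a
#' paired test-retest error model with known true within-subject CV.
#' `true_wcv` is defined as the population within-subject coefficient of
#' variation in the relative paired-difference sense (the quantity the wCV
#' estimator targets); by default the error-law scale parameter is
#' calibrated numerically so that this population value equals `true_wcv`
#' exactly rather than only to first order (see [calibrate_error_scale()]).
#'
#' @param n_subjects Total subjects, including zero-burden ones.
#' @param median_ml Median of the log-normal true values (default 30, the
#'   scale of whole-body tumor volumes in advanced disease).
#' @param log_sd SD of the log true values (default 1.5: cohort values span
#'   roughly 2-650 mL).
#' @param true_wcv True within-subject CV as a fraction.
#' @param error_model `"multiplicative_normal"` (`value = T * (1 + e)`,
#'   `e ~ N(0, s)`, negative draws resampled) or
#'   `"multiplicative_lognormal"` (mean-one log-normal multiplier; never
#'   negative, preferred at large CV).
#' @param n_zero_subjects Subjects appended with (0, 0) on both scans
#'   (no detectable disease on either visit).
#' @param seed Integer seed.
#' @param calibrate Calibrate the error scale to `true_wcv` (default TRUE).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, median_ml = 30, log_sd = 1.5, true_wcv,
                        error_model = c("multiplicative_normal",
                                        "multiplicative_lognormal"),
                        n_zero_subjects = 0L, seed = 1L, calibrate = TRUE) {
  error_model <- match.arg(error_model)
  if (true_wcv < 0) stop("true_wcv must be non-negative")
  if (n_zero_subjects > n_subjects)
    stop("n_zero_subjects cannot exceed n_subjects")
  structure(list(n_subjects = as.integer(n_subjects), median_ml = median_ml,
                 log_sd = log_sd, true_wcv = true_wcv,
                 error_model = error_model,
                 n_zero_subjects = as.integer(n_zero_subjects),
                 seed = as.integer(seed), calibrate = calibrate),
            class = "cohort_spec")
}

#' Calibrate the retest error scale to a target within-subject CV
#'
#' The wCV estimator averages terms `(a - b)^2 / (2 * mean(a, b)^2)`; under
#' either multiplicative error law the population value of that average is
#' not exactly the nominal scale parameter (they diverge at second order in
#' the CV -- noticeably so above ~20%). This solves for the scale parameter
#' whose population wCV equals the target, by numeric integration of the
#' paired-term expectation over the error law and root finding.
#'
#' @param true_wcv Target within-subject CV (fraction).
#' @param error_model As in [cohort_spec()].
#' @return The calibrated scale: the normal sd `s`, or the log-normal
#'   log-scale sigma.
#' @export
calibrate_error_scale <- function(true_wcv,
                                  error_model = c("multiplicative_normal",
                                                  "multiplicative_lognormal")) {
  error_model <- match.arg(error_model)
  if (true_wcv == 0) return(0)
  estimand <- function(s) {
    if (error_model == "multiplicative_normal") {
      # (a-b)^2/(2*mean^2) = d^2 / (2 (1+z)^2), d ~ N(0, 2 s^2) indep of
      # z = (e1+e2)/2 ~ N(0, s^2/2); integrate over the effective support
      sz <- s / sqrt(2)
      up <- 8 * sz
      C <- stats::integrate(function(z) stats::dnorm(z, 0, sz) / (1 + z)^2,
                            lower = max(-0.99, -up), upper = up,
                            rel.tol = 1e-10)$value
      s^2 * C
    } else {
      # term = 2 tanh(u)^2 with u = (eta1 - eta2)/2 ~ N(0, s^2/2)
      su <- s / sqrt(2)
      stats::integrate(function(u) stats::dnorm(u, 0, su) * 2 * tanh(u)^2,
                       lower = -8 * su, upper = 8 * su, rel.tol = 1e-10)$value
    }
  }
  upper <- if (error_model == "multiplicative_normal") 0.6 else 2
  stats::uniroot(function(s) estimand(s) - true_wcv^2,
                 interval = c(1e-9, upper), tol = 1e-10)$root
}

#' Simulate a tabular paired test-retest cohort
#'
#' Draws true subject values from the log-normal, applies two independent
#' multiplicative retest errors per subject, and appends the requested
#' number of zero-burden subjects. Deterministic under `spec$seed`. With
#' `true_wcv = 0` the two scans are identical.
#'
#' @param spec A [cohort_spec()].
#' @return A [paired_samples()] data frame with an extra `true_value`
#'   column.
#' @export
simulate_pair_cohort <- function(spec) {
  .with_seed(spec$seed, {
    nd <- spec$n_subjects - spec$n_zero_subjects
    tv <- exp(stats::rnorm(nd, log(spec$median_ml), spec$log_sd))
    s <- if (spec$calibrate) calibrate_error_scale(spec$true_wcv, spec$error_model)
         else spec$true_wcv
    if (spec$error_model == "multiplicative_normal") {
      e <- matrix(stats::rnorm(2 * nd, 0, s), ncol = 2)
      while (any(bad <- (1 + e) <= 0))
        e[bad] <- stats::rnorm(sum(bad), 0, s)
      a <- tv * (1 + e[, 1]); b <- tv * (1 + e[, 2])
    } else {
      mlt <- matrix(exp(stats::rnorm(2 * nd, -s^2 / 2, s)), ncol = 2)
      a <- tv * mlt[, 1]; b <- tv * mlt[, 2]
    }
    out <- paired_samples(subject_id = sprintf("S%03d", seq_len(spec$n_subjects)),
                          a = c(a, rep(0, spec$n_zero_subjects)),
                          b = c(b, rep(0, spec$n_zero_subjects)),
                          metric_name = "mtv_total")
    out$true_value <- c(tv, rep(0, spec$n_zero_subjects))
    out
  })
}

# ---- the 18-patient study fixture ----

# lesions per patient; zero-burden patients 1 and 10; 96 lesions in total
.fixture_lesion_counts <- c(0L, 2L, 11L, 7L, 3L, 2L, 6L, 9L, 13L, 0L,
                            3L, 6L, 12L, 5L, 1L, 8L, 5L, 3L)

# candidate lesion sites (mm): a lattice with >= 90 mm clearance between
# neighbouring sites, pruned of sites too close to the liver ellipsoid
.fixture_sites <- function(liver_center = c(165, 110, 340)) {
  g <- as.matrix(expand.grid(x = c(60, 196), y = c(60, 196),
                             z = c(54, 156, 258, 360, 462)))
  d <- sqrt(rowSums((g - matrix(liver_center, nrow(g), 3, byrow = TRUE))^2))
  g[d >= 104, , drop = FALSE]
}

# split a patient total volume into n lesion volumes in [vmin, vmax]
.split_volumes <- function(total, n, vmin = 0.8, vmax = 250) {
  if (n == 1L) return(min(total, vmax))
  w <- exp(stats::rnorm(n, 0, 1))
  v <- vmin + (total - vmin * n) * w / sum(w)
  for (it in 1:20) {
    over <- v > vmax
    if (!any(over)) break
    excess <- sum(v[over] - vmax)
    v[over] <- vmax
    room <- !over
    v[room] <- v[room] + excess * v[room] / sum(v[room])
  }
  v
}

#' Generate the 18-patient paired-phantom study fixture
#'
#' Builds a full synthetic study emulating an 18-patient test-retest cohort:
#' 2 patients with no disease, 96 tumor lesions in total across the others,
#' per-patient total volumes spanning roughly 2-650 mL (taken from the
#' bundled example cohort, see [testretest_cohort()]), a liver reference
#' ellipsoid and a physiologic bladder hot spot per patient, and per-reader
#' edit lists that remove the bladder (exercising the manual-edit step).
#'
#' The retest perturbation jitters each lesion's volume with the requested
#' CV, coherently within a patient (scan-level effects such as uptake-time
#' differences move all of a patient's lesions together), so the injected
#' lesion-level CV carries through to the per-patient total unattenuated.
#' The per-patient relative deviations are drawn at random and then
#' standardized to the target second moment, so the injected within-subject
#' CV is exact in the finite cohort rather than only in expectation --
#' end-to-end checks then isolate pipeline error from cohort sampling error.
#' Per-lesion amplitude jitter and a global uptake scale perturb the SUV
#' side.
#'
#' Phantom volumes are not materialized here (they would hold gigabytes);
#' each patient carries its [phantom_spec()] and is rendered on demand by
#' [materialize_patient()].
#'
#' @param seed Master seed; every per-patient seed derives from it.
#' @param lesion_vol_cv Injected lesion-volume CV between scans (default
#'   0.127).
#' @param lesion_amp_cv Per-lesion amplitude jitter CV (default 0.10).
#' @param global_scale_sd Global uptake scale sd (default 0.03).
#' @param exact_injection Standardize the drawn deviations to the target
#'   second moment (default TRUE).
#' @return A list of class `study_fixture`: `patients` (each with
#'   `patient_id`, `spec`, `edits`, `true_mtv`, `n_lesions`, `delta`),
#'   `seed`, `params`.
#' @export
generate_study_fixture <- function(seed = 101L, lesion_vol_cv = 0.127,
                                   lesion_amp_cv = 0.10,
                                   global_scale_sd = 0.03,
                                   exact_injection = TRUE) {
  cohort <- testretest_cohort()
  counts <- .fixture_lesion_counts
  stopifnot(nrow(cohort) == length(counts))
  targets <- cohort$r1_scan1
  .with_seed(seed, {
    diseased <- which(counts > 0L)
    delta <- stats::rnorm(length(diseased), 0, lesion_vol_cv / sqrt(2))
    delta <- pmin(pmax(delta, -0.3), 0.3)
    if (exact_injection && lesion_vol_cv > 0)
      delta <- pmin(pmax(delta * lesion_vol_cv / sqrt(mean(2 * delta^2)),
                         -0.32), 0.32)
    sites <- .fixture_sites()
    liver_center <- c(165, 110, 340)
    site_order <- order(-sqrt(rowSums((sites - matrix(liver_center, nrow(sites), 3,
                                                      byrow = TRUE))^2)))
    bladder_mm <- c(128, 128, 120)
    patients <- vector("list", length(counts))
    for (p in seq_along(counts)) {
      n <- counts[p]
      dlt <- if (n > 0L) delta[match(p, diseased)] else 0
      pseed <- sample.int(2^30, 1L)
      lesions <- list()
      if (n > 0L) {
        v <- .split_volumes(targets[p], n)
        v1 <- v * (1 - dlt)                      # scan-1 ground truth volumes
        r1 <- (3 * v1 * 1000 / (4 * pi))^(1 / 3) # mm
        ord <- order(-v1)
        jit <- matrix(stats::runif(3 * n, -6, 6), ncol = 3)
        peaks <- stats::runif(n, 15, 35)
        tags <- sample(c("skeletal", "nodal", "prostate"), n, replace = TRUE,
                       prob = c(0.5, 0.35, 0.15))
        ctrs <- sites[site_order[seq_len(n)], , drop = FALSE] + jit
        lesions <- lapply(seq_len(n), function(q) {
          j <- ord[q]                            # largest lesion, farthest site
          lesion_spec(center_mm = ctrs[q, ], shape = "uniform_sphere",
                      size_mm = r1[j], peak_suv = peaks[j], region_tag = tags[j])
        })
      }
      bladder <- lesion_spec(center_mm = bladder_mm, shape = "uniform_sphere",
                             size_mm = 15, peak_suv = 30,
                             region_tag = "physiologic")
      spec <- phantom_spec(lesions = lesions, physiologic = list(bladder),
                           retest = list(vol_scale = if (n > 0L) (1 + dlt) / (1 - dlt) else 1,
                                         lesion_amp_cv = lesion_amp_cv,
                                         global_scale_sd = global_scale_sd),
                           seed = pseed,
                           patient_id = cohort$patient_id[p])
      bladder_vox <- as.integer(round((bladder_mm - spec$origin_mm) / spec$spacing_mm) + 1L)
      edits <- list(exclude_points = list(bladder_vox))
      patients[[p]] <- list(patient_id = cohort$patient_id[p],
                            spec = spec,
                            edits = list(R1 = edits, R2 = edits),
                            true_mtv = c(a = targets[p] * (1 - dlt),
                                         b = targets[p] * (1 + dlt)),
                            n_lesions = n, delta = dlt)
    }
    structure(list(patients = patients, seed = seed,
                   params = list(lesion_vol_cv = lesion_vol_cv,
                                 lesion_amp_cv = lesion_amp_cv,
                                 global_scale_sd = global_scale_sd,
                                 exact_injection = exact_injection)),
              class = "study_fixture")
  })
}

#' Render one fixture patient's phantom pair
#'
#' @param fixture A [generate_study_fixture()] result.
#' @param i Patient index.
#' @return The [generate_phantom_pair()] output for that patient.
#' @export
materialize_patient <- function(fixture, i) {
  generate_phantom_pair(fixture$patients[[i]]$spec)
}
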