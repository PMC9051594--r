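# Per-lesion volumetric/uptake metrics and their per-patient aggregates:
# molecular tumor volume (MTV), PSMA total lesion uptake (PSMA-TL = MTV x
# SUVmean, the PSMA analogue of total lesion glycolysis) and the PSMA total
# lesion quotient (PSMA-TLQ = MTV / SUVmean).

#' Per-lesion metrics
#'
#' Computes, for one delineated lesion: MTV (voxel count times voxel volume,
#' in mL), SUVmax, SUVpeak (sphere mean at the lesion's hottest location,
#' see [suv_peak()]; on a plateau of tied maxima the position maximizing the
#' sphere mean is taken), SUVmean, PSMA-TL (`mtv * suv_mean`), PSMA-TLQ
#' (`mtv / suv_mean`) and the unweighted centroid in mm. Note the exact
#' identity `psma_tl * psma_tlq = mtv^2`.
#'
#' @param volume An [suv_volume()].
#' @param lesion A `lesion_mask` (see [delineate_lesion()]).
#' @param peak_sphere_ml SUVpeak sphere volume in mL (default 1.0).
#' @return One-row data frame with columns `lesion_id`, `n_voxels`, `mtv_ml`,
#'   `suv_max`, `suv_peak`, `suv_mean`, `psma_tl`, `psma_tlq`,
#'   `centroid_x_mm`, `centroid_y_mm`, `centroid_z_mm`.
#' @export
compute_lesion_metrics <- function(volume, lesion, peak_sphere_ml = 1.0) {
  if (length(lesion$lin) == 0L) stop("empty lesion mask")
  v <- volume$values[lesion$lin]
  if (any(v <= 0)) stop("lesion mask contains non-positive SUV voxels")
  m <- mean(v)
  if (m <= 0) stop("lesion SUVmean is zero; PSMA-TLQ undefined")
  mtv <- length(v) * voxel_volume_ml(volume)
  cen <- .lesion_centroid(lesion, volume$spacing, volume$origin)
  # SUVpeak at the hottest location; on a plateau of tied maxima the sphere
  # position maximizing the sphere mean is used
  dm <- dim(volume$values)
  plateau <- lesion$lin[v == max(v)]
  pk <- max(.peak_values(volume$values, dm, plateau,
                         .sphere_offsets(volume$spacing, peak_sphere_ml)))
  data.frame(lesion_id = lesion$lesion_id,
             n_voxels = length(v),
             mtv_ml = mtv,
             suv_max = max(v),
             suv_peak = pk,
             suv_mean = m,
             psma_tl = mtv * m,
             psma_tlq = mtv / m,
             centroid_x_mm = cen[1], centroid_y_mm = cen[2], centroid_z_mm = cen[3])
}

#' Lesion table for a whole segmentation
#'
#' @param volume An [suv_volume()].
#' @param segmentation A `patient_segmentation`.
#' @param peak_sphere_ml SUVpeak sphere volume in mL.
#' @return Data frame with one row per lesion (columns of
#'   [compute_lesion_metrics()] plus `patient_id` and `scan_id`); zero rows
#'   for an empty segmentation.
#' @export
lesion_table <- function(volume, segmentation, peak_sphere_ml = 1.0) {
  rows <- lapply(segmentation$lesions, compute_lesion_metrics,
                 volume = volume, peak_sphere_ml = peak_sphere_ml)
  if (!length(rows)) {
    out <- data.frame(lesion_id = integer(0), n_voxels = integer(0),
                      mtv_ml = numeric(0), suv_max = numeric(0),
                      suv_peak = numeric(0), suv_mean = numeric(0),
                      psma_tl = numeric(0), psma_tlq = numeric(0),
                      centroid_x_mm = numeric(0), centroid_y_mm = numeric(0),
                      centroid_z_mm = numeric(0))
  } else {
    out <- do.call(rbind, rows)
  }
  cbind(data.frame(patient_id = rep(segmentation$patient_id, nrow(out)),
                   scan_id = rep(segmentation$scan_id, nrow(out))),
        out)
}

# run code with a private RNG stream, restoring the caller's stream after
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random lesion subgroup
#'
#' Selects up to `cap` lesions per patient for the subgroup analysis. When
#' more than `cap` lesions are available, a uniform random sample without
#' replacement is drawn, deterministic under `seed`. Selection is
#' unstratified by default; with `stratify_by` (e.g. a region tag per
#' lesion), the sample is spread across strata round-robin, emulating a
#' reader spreading picks over anatomic regions.
#'
#' @param lesions Data frame of lesions (rows are lesions).
#' @param cap Maximum subgroup size (default 10; must be >= 1).
#' @param seed Integer seed for the random draw.
#' @param stratify_by Optional factor of length `nrow(lesions)`.
#' @return The selected rows of `lesions`.
#' @export
select_subgroup <- function(lesions, cap = 10L, seed = 1L, stratify_by = NULL) {
  if (cap < 1L) stop("cap must be at least 1")
  n <- nrow(lesions)
  if (n <= cap) return(lesions)
  idx <- .with_seed(seed, {
    if (is.null(stratify_by)) {
      sample.int(n, cap)
    } else {
      strata <- split(seq_len(n), stratify_by)
      strata <- lapply(strata, function(s) sample(s))
      picked <- integer(0); r <- 1L
      while (length(picked) < cap) {
        for (s in strata) {
          if (length(picked) >= cap) break
          if (length(s) >= r) picked <- c(picked, s[r])
        }
        r <- r + 1L
      }
      picked
    }
  })
  lesions[sort(idx), , drop = FALSE]
}

#' Subgroup aggregates
#'
#' Aggregates a subgroup of lesions into per-patient metrics: sums of MTV,
#' PSMA-TL and PSMA-TLQ, the mean lesion MTV, and unweighted means of
#' SUVmax / SUVpeak / SUVmean over the member lesions.
#'
#' @param lesions Data frame with at least `mtv_ml`, `suv_max`, `suv_peak`,
#'   `suv_mean`, `psma_tl`, `psma_tlq` (one row per lesion; >= 1 row).
#' @return One-row data frame: `n_lesions`, `mtv_subgroup`,
#'   `subgroup_mtv_mean`, `psma_tl_subgroup`, `psma_tlq_subgroup`,
#'   `mean_suv_max`, `mean_suv_peak`, `mean_suv_mean`.
#' @export
aggregate_subgroup <- function(lesions) {
  if (nrow(lesions) == 0L) stop("cannot aggregate an empty lesion set")
  data.frame(n_lesions = nrow(lesions),
             mtv_subgroup = sum(lesions$mtv_ml),
             subgroup_mtv_mean = mean(lesions$mtv_ml),
             psma_tl_subgroup = sum(lesions$psma_tl),
             psma_tlq_subgroup = sum(lesions$psma_tlq),
             mean_suv_max = mean(lesions$suv_max),
             mean_suv_peak = mean(lesions$suv_peak),
             mean_suv_mean = mean(lesions$suv_mean))
}

#' Per-patient totals
#'
#' Whole-body totals over all segmented lesions of one patient and scan:
#' MTV_total (sum of lesion MTVs, equivalently the voxel count of the union
#' mask times the voxel volume), the mean component-lesion MTV, summed
#' PSMA-TL and PSMA-TLQ, and unweighted means of SUVmax / SUVmean over the
#' component lesions. A patient with no segmented disease yields all-zero
#' totals with `n_lesions = 0`.
#'
#' @param lesions Data frame of the patient's lesions (may have zero rows).
#' @param patient_id,scan_id,reader_id Identifiers copied into the output.
#' @return One-row data frame: identifiers, `mtv_total`, `total_mtv_mean`,
#'   `psma_tl_total`, `psma_tlq_total`, `total_mean_suv_max`,
#'   `total_mean_suv_mean`, `n_lesions`.
#' @export
aggregate_total <- function(lesions, patient_id = NA_character_,
                            scan_id = NA_character_, reader_id = NA_character_) {
  n <- nrow(lesions)
  data.frame(patient_id = patient_id, scan_id = scan_id, reader_id = reader_id,
             mtv_total = if (n) sum(lesions$mtv_ml) else 0,
             total_mtv_mean = if (n) mean(lesions$mtv_ml) else 0,
             psma_tl_total = if (n) sum(lesions$psma_tl) else 0,
             psma_tlq_total = if (n) sum(lesions$psma_tlq) else 0,
             total_mean_suv_max = if (n) mean(lesions$suv_max) else 0,
             total_mean_suv_mean = if (n) mean(lesions$suv_mean) else 0,
             n_lesions = n)
}
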