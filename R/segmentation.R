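# Whole-body semiautomatic tumor segmentation: liver-referenced SUVpeak
# threshold, candidate focus detection, 50% isocontour delineation, manual
# whole-lesion edits, and cross-scan lesion matching.

# ---- grid helpers (linear indices are R column-major: i fastest) ----

.conn_offsets <- function(connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nrm <- rowSums(abs(g))
  g <- g[nrm > 0, , drop = FALSE]
  if (connectivity == 6L)  g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (connectivity == 18L) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  g
}

.lin <- function(ijk, dm) {
  ijk[, 1] + (ijk[, 2] - 1L) * dm[1] + (ijk[, 3] - 1L) * dm[1] * dm[2]
}

.ijk <- function(lin, dm) arrayInd(lin, dm)

# neighbours of a set of linear indices; returns linear indices (in-bounds only)
.neighbours <- function(lin, dm, offsets) {
  ijk <- .ijk(lin, dm)
  out <- vector("list", nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    ii <- ijk[, 1] + offsets[o, 1]
    jj <- ijk[, 2] + offsets[o, 2]
    kk <- ijk[, 3] + offsets[o, 3]
    ok <- ii >= 1L & ii <= dm[1] & jj >= 1L & jj <= dm[2] & kk >= 1L & kk <= dm[3]
    out[[o]] <- ii[ok] + (jj[ok] - 1L) * dm[1] + (kk[ok] - 1L) * dm[1] * dm[2]
  }
  unlist(out, use.names = FALSE)
}

# connected-component labels for a sparse voxel set, via igraph
.label_components <- function(lin, dm, connectivity = 26L) {
  n <- length(lin)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  offsets <- .conn_offsets(connectivity)
  # half the offsets suffice for an undirected edge list
  keep <- offsets[, 3] > 0 |
    (offsets[, 3] == 0 & offsets[, 2] > 0) |
    (offsets[, 3] == 0 & offsets[, 2] == 0 & offsets[, 1] > 0)
  offsets <- offsets[keep, , drop = FALSE]
  ijk <- .ijk(lin, dm)
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(offsets))) {
    ii <- ijk[, 1] + offsets[o, 1]
    jj <- ijk[, 2] + offsets[o, 2]
    kk <- ijk[, 3] + offsets[o, 3]
    ok <- ii >= 1L & ii <= dm[1] & jj >= 1L & jj <= dm[2] & kk >= 1L & kk <= dm[3]
    nb <- ii[ok] + (jj[ok] - 1L) * dm[1] + (kk[ok] - 1L) * dm[1] * dm[2]
    m <- match(nb, lin)
    hit <- !is.na(m)
    from <- c(from, which(ok)[hit])
    to <- c(to, m[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  as.integer(igraph::components(g)$membership)
}

# grow the connected region >= threshold containing start (linear index),
# optionally restricted to an allowed set (logical vector over the grid)
.region_grow <- function(vals, dm, start, threshold, connectivity = 26L,
                         allowed = NULL) {
  offsets <- .conn_offsets(connectivity)
  n <- prod(dm)
  inregion <- logical(length = 0)
  visited <- raw(n)
  accept <- function(lin) {
    ok <- vals[lin] >= threshold
    if (!is.null(allowed)) ok <- ok & allowed[lin]
    ok
  }
  if (!accept(start)) return(integer(0))
  visited[start] <- as.raw(1)
  frontier <- start
  region <- start
  while (length(frontier)) {
    nb <- unique(.neighbours(frontier, dm, offsets))
    nb <- nb[visited[nb] == as.raw(0)]
    visited[nb] <- as.raw(1)
    nb <- nb[accept(nb)]
    region <- c(region, nb)
    frontier <- nb
  }
  sort(region)
}

# strict ascent from seed to the connected regional maximum;
# ties broken by the smallest linear (column-major) index
.hill_climb <- function(vals, dm, start, connectivity = 26L) {
  offsets <- .conn_offsets(connectivity)
  cur <- start
  repeat {
    nb <- .neighbours(cur, dm, offsets)
    if (!length(nb)) return(cur)
    best <- max(vals[nb])
    if (best <= vals[cur]) return(cur)
    cand <- nb[vals[nb] == best]
    cur <- min(cand)
  }
}

# ---- liver reference threshold ----

#' Liver-referenced candidate threshold
#'
#' Computes the SUVpeak threshold used to pick candidate tumor foci from the
#' liver reference VOI statistics:
#' `threshold = constant / liver_mean * (liver_mean + liver_sd)`.
#' The leading factor is a corrective coefficient for the tumor sink effect:
#' a high tumor burden sequesters tracer and lowers liver uptake, and dividing
#' the nominal normal-liver SUVmean (default 4.3) by the observed liver mean
#' raises the threshold back to where it would sit in a normal liver. When
#' the observed liver mean equals the constant the correction is the identity
#' and the threshold reduces to `liver_mean + liver_sd`.
#'
#' @param liver A [voi_stats()] for the liver VOI (or any list with `mean`
#'   and `sd`).
#' @param normal_liver_constant Nominal normal-liver SUVmean (default 4.3).
#' @return A list of class `liver_reference`: `liver_mean`, `liver_sd`,
#'   `normal_liver_constant`, `threshold`.
#' @export
liver_threshold <- function(liver, normal_liver_constant = 4.3) {
  if (!is.finite(liver$mean) || liver$mean <= 0)
    stop("degenerate liver VOI: liver mean SUV must be positive")
  if (liver$sd < 0) stop("liver SUV sd must be non-negative")
  thr <- normal_liver_constant / liver$mean * (liver$mean + liver$sd)
  structure(list(liver_mean = liver$mean, liver_sd = liver$sd,
                 normal_liver_constant = normal_liver_constant,
                 threshold = thr),
            class = "liver_reference")
}

#' @export
print.liver_reference <- function(x, ...) {
  cat(sprintf("<liver_reference> mean %.3f, sd %.3f, constant %.2f -> threshold %.3f SUV\n",
              x$liver_mean, x$liver_sd, x$normal_liver_constant, x$threshold))
  invisible(x)
}

# ---- SUVpeak ----

# integer voxel offsets whose centers lie inside a sphere of the given
# volume, for the given spacing
.sphere_offsets <- function(spacing, sphere_volume_ml) {
  r <- (3 * sphere_volume_ml * 1000 / (4 * pi))^(1 / 3)  # mm
  nmax <- floor(r / spacing)
  g <- as.matrix(expand.grid(di = -nmax[1]:nmax[1],
                             dj = -nmax[2]:nmax[2],
                             dk = -nmax[3]:nmax[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  g[d2 <= r^2, , drop = FALSE]
}

#' SUVpeak at a voxel
#'
#' Mean SUV over all voxels whose centers lie within a sphere of the stated
#' volume (default 1.0 mL, the common EANM-style convention; radius about
#' 6.2 mm) centered on the given voxel center. A sphere smaller than one
#' voxel degenerates to the voxel's own SUV. At the grid boundary only
#' in-grid voxel centers contribute.
#'
#' @param volume An [suv_volume()].
#' @param index Integer length-3 voxel index `(i, j, k)` (1-based).
#' @param sphere_volume_ml Sphere volume in mL (default 1.0).
#' @return SUVpeak as a scalar.
#' @export
suv_peak <- function(volume, index, sphere_volume_ml = 1.0) {
  dm <- dim(volume$values)
  if (any(index < 1L) || any(index > dm))
    stop("index outside grid")
  if (sphere_volume_ml <= 0) stop("sphere_volume_ml must be positive")
  offs <- .sphere_offsets(volume$spacing, sphere_volume_ml)
  ii <- index[1] + offs[, 1]; jj <- index[2] + offs[, 2]; kk <- index[3] + offs[, 3]
  ok <- ii >= 1L & ii <= dm[1] & jj >= 1L & jj <= dm[2] & kk >= 1L & kk <= dm[3]
  mean(volume$values[cbind(ii[ok], jj[ok], kk[ok])])
}

# SUVpeak for a set of voxels (linear indices), vectorized over the set
.peak_values <- function(vals, dm, lin, offs) {
  ijk <- .ijk(lin, dm)
  acc <- numeric(length(lin))
  cnt <- numeric(length(lin))
  for (o in seq_len(nrow(offs))) {
    ii <- ijk[, 1] + offs[o, 1]
    jj <- ijk[, 2] + offs[o, 2]
    kk <- ijk[, 3] + offs[o, 3]
    ok <- ii >= 1L & ii <= dm[1] & jj >= 1L & jj <= dm[2] & kk >= 1L & kk <= dm[3]
    l2 <- ii[ok] + (jj[ok] - 1L) * dm[1] + (kk[ok] - 1L) * dm[1] * dm[2]
    acc[ok] <- acc[ok] + vals[l2]
    cnt[ok] <- cnt[ok] + 1
  }
  acc / cnt
}

# ---- candidate detection ----

#' Detect candidate tumor foci
#'
#' Finds all voxels whose SUVpeak reaches the liver-referenced threshold and
#' returns one seed per connected component of that set: the component's
#' maximum-SUV voxel (ties broken by the smallest column-major index).
#' Components are returned in order of descending seed SUV.
#'
#' SUVpeak is only evaluated where it can possibly reach the threshold
#' (the sphere-dilation of the set of voxels with SUV at or above the
#' threshold), which makes detection exact and fast on whole-body grids.
#'
#' @param volume An [suv_volume()].
#' @param liver A [liver_threshold()] result.
#' @param body_mask Optional [voi_mask()]; when given, only voxels with a
#'   positive label are searched.
#' @param connectivity Component connectivity: 6, 18 or 26 (default).
#' @param sphere_volume_ml SUVpeak sphere volume (mL).
#' @return Integer matrix of seed indices (one row per candidate, columns
#'   `i, j, k`), ordered by descending seed SUV; zero rows when nothing
#'   reaches the threshold.
#' @export
detect_candidates <- function(volume, liver, body_mask = NULL,
                              connectivity = 26L, sphere_volume_ml = 1.0) {
  vals <- volume$values
  dm <- dim(vals)
  thr <- liver$threshold
  hot <- which(vals >= thr)
  if (!is.null(body_mask)) {
    .check_aligned(volume, body_mask)
    hot <- hot[body_mask$labels[hot] > 0L]
  }
  if (!length(hot)) return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "k"))))
  offs <- .sphere_offsets(volume$spacing, sphere_volume_ml)
  # superset: anywhere within sphere reach of a hot voxel
  ijk <- .ijk(hot, dm)
  sup <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    ii <- ijk[, 1] + offs[o, 1]
    jj <- ijk[, 2] + offs[o, 2]
    kk <- ijk[, 3] + offs[o, 3]
    ok <- ii >= 1L & ii <= dm[1] & jj >= 1L & jj <= dm[2] & kk >= 1L & kk <= dm[3]
    sup[[o]] <- ii[ok] + (jj[ok] - 1L) * dm[1] + (kk[ok] - 1L) * dm[1] * dm[2]
  }
  sup <- unique(unlist(sup, use.names = FALSE))
  pk <- .peak_values(vals, dm, sup, offs)
  cand <- sup[pk >= thr]
  if (!is.null(body_mask)) cand <- cand[body_mask$labels[cand] > 0L]
  if (!length(cand)) return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "k"))))
  cand <- sort(cand)
  memb <- .label_components(cand, dm, connectivity)
  seeds <- vapply(split(cand, memb), function(lin) {
    mx <- max(vals[lin])
    min(lin[vals[lin] == mx])
  }, numeric(1))
  seeds <- as.integer(seeds[order(vals[seeds], seeds, decreasing = c(TRUE, FALSE), method = "radix")])
  out <- .ijk(seeds, dm)
  colnames(out) <- c("i", "j", "k")
  out
}

# ---- lesion delineation ----

#' Delineate one lesion by 50% isocontour
#'
#' From a seed voxel, ascends to the connected regional SUV maximum (strict
#' hill climb, so the contour does not depend on which component voxel was
#' flagged), then grows the connected set of voxels with SUV at or above 50%
#' of that local maximum. If growth reaches a yet-higher voxel (two peaks
#' joined above the half-max level), the local maximum and threshold are
#' raised and the region regrown until stable.
#'
#' @param volume An [suv_volume()].
#' @param seed Integer length-3 voxel index.
#' @param connectivity 6, 18 or 26 (default).
#' @param climb If `FALSE`, the 50% cut is taken from the seed voxel's own
#'   SUV instead of the regional maximum.
#' @return A list of class `lesion_mask`: `lesion_id` (NA until assigned),
#'   `voxels` (n x 3 index matrix), `lin` (linear indices), `seed_index`
#'   (the local-maximum voxel), `connectivity`.
#' @export
delineate_lesion <- function(volume, seed, connectivity = 26L, climb = TRUE) {
  vals <- volume$values
  dm <- dim(vals)
  if (any(seed < 1L) || any(seed > dm)) stop("seed outside grid")
  slin <- seed[1] + (seed[2] - 1L) * dm[1] + (seed[3] - 1L) * dm[1] * dm[2]
  if (vals[slin] <= 0) stop("seed SUV must be positive")
  m <- if (climb) .hill_climb(vals, dm, slin, connectivity) else slin
  repeat {
    thr <- 0.5 * vals[m]
    region <- .region_grow(vals, dm, m, thr, connectivity)
    mx <- max(vals[region])
    if (mx <= vals[m]) break
    cand <- region[vals[region] == mx]
    m <- min(cand)
  }
  .new_lesion_mask(region, m, dm, connectivity)
}

.new_lesion_mask <- function(lin, seed_lin, dm, connectivity, lesion_id = NA_integer_) {
  lin <- unname(as.integer(lin))
  vox <- .ijk(lin, dm)
  colnames(vox) <- c("i", "j", "k")
  structure(list(lesion_id = lesion_id,
                 voxels = vox,
                 lin = lin,
                 seed_index = as.integer(.ijk(seed_lin, dm)),
                 connectivity = as.integer(connectivity)),
            class = "lesion_mask")
}

.lesion_centroid <- function(lesion, spacing, origin) {
  origin + (colMeans(lesion$voxels) - 1) * spacing
}

# ---- whole-body segmentation ----

#' Whole-body semiautomatic tumor segmentation
#'
#' Composition of the full segmentation chain for one scan: liver VOI
#' statistics, liver-referenced threshold, SUVpeak candidate detection,
#' per-candidate 50% isocontour delineation, and whole-lesion manual edits.
#' Candidates are processed in order of descending SUVmax; voxels claimed by
#' an earlier lesion are not re-claimed, and a delineation left empty (or
#' whose local maximum is already claimed) is dropped. Candidates whose seed
#' lies inside the liver reference VOI are excluded: the reference organ is
#' by definition not tumor (other physiologic uptake is removed via `edits`).
#'
#' @param volume An [suv_volume()].
#' @param liver_mask [voi_mask()] for the liver reference VOI.
#' @param edits Optional edit list, see [apply_edits()].
#' @param normal_liver_constant Nominal normal-liver SUVmean (default 4.3).
#' @param connectivity 6, 18 or 26 (default).
#' @param sphere_volume_ml SUVpeak sphere volume in mL (default 1.0).
#' @param liver_label Label of the liver VOI in `liver_mask` (default 1).
#' @param body_mask Optional search region, see [detect_candidates()].
#' @param climb Passed to [delineate_lesion()].
#' @return A list of class `patient_segmentation`: `patient_id`, `scan_id`,
#'   `dim`, `spacing`, `origin`, `lesions` (list of `lesion_mask`),
#'   `liver_reference`, `edits_applied`.
#' @export
segment_whole_body <- function(volume, liver_mask, edits = NULL,
                               normal_liver_constant = 4.3,
                               connectivity = 26L, sphere_volume_ml = 1.0,
                               liver_label = 1L, body_mask = NULL,
                               climb = TRUE) {
  vals <- volume$values
  dm <- dim(vals)
  lstats <- voi_stats(volume, liver_mask, liver_label)
  ref <- liver_threshold(lstats, normal_liver_constant)
  seeds <- detect_candidates(volume, ref, body_mask = body_mask,
                             connectivity = connectivity,
                             sphere_volume_ml = sphere_volume_ml)
  claimed <- raw(prod(dm))
  lesions <- list()
  for (s in seq_len(nrow(seeds))) {
    seed <- seeds[s, ]
    slin <- seed[1] + (seed[2] - 1L) * dm[1] + (seed[3] - 1L) * dm[1] * dm[2]
    if (liver_mask$labels[slin] == liver_label) next
    if (claimed[slin] != as.raw(0)) next
    les <- delineate_lesion(volume, seed, connectivity, climb = climb)
    mlin <- les$seed_index[1] + (les$seed_index[2] - 1L) * dm[1] +
      (les$seed_index[3] - 1L) * dm[1] * dm[2]
    if (claimed[mlin] != as.raw(0)) next
    if (liver_mask$labels[mlin] == liver_label) next
    free <- les$lin[claimed[les$lin] == as.raw(0)]
    if (!length(free)) next
    if (length(free) < length(les$lin)) {
      # keep the connected piece containing the local maximum
      keep <- logical(prod(dm)); keep[free] <- TRUE
      free <- .region_grow(vals, dm, mlin, 0.5 * vals[mlin], connectivity,
                           allowed = keep)
      if (!length(free)) next
    }
    claimed[free] <- as.raw(1)
    lesions[[length(lesions) + 1L]] <-
      .new_lesion_mask(free, mlin, dm, connectivity,
                       lesion_id = length(lesions) + 1L)
  }
  seg <- structure(list(patient_id = volume$patient_id,
                        scan_id = volume$scan_id,
                        dim = dm,
                        spacing = volume$spacing,
                        origin = volume$origin,
                        lesions = lesions,
                        liver_reference = ref,
                        edits_applied = list()),
                   class = "patient_segmentation")
  if (!is.null(edits)) seg <- apply_edits(seg, edits, volume)
  seg
}

#' @export
print.patient_segmentation <- function(x, ...) {
  cat(sprintf("<patient_segmentation> %s / %s: %d lesion(s), liver threshold %.3f SUV, %d edit(s)\n",
              x$patient_id, x$scan_id, length(x$lesions),
              x$liver_reference$threshold, length(x$edits_applied)))
  invisible(x)
}

# ---- manual edits ----

#' Apply whole-lesion manual edits
#'
#' Emulates the manual correction step of semiautomatic segmentation:
#' erroneously included sites of physiologic uptake are removed whole, and
#' missed lesions are added by delineating from a supplied seed. Contours are
#' never partially modified -- edits act at whole-lesion granularity only.
#' Applying the same edit list twice yields the identical segmentation.
#'
#' The edit list has elements:
#' \describe{
#'   \item{`exclude`}{integer lesion ids to remove (error if an id was never
#'     present).}
#'   \item{`exclude_points`}{list of voxel indices; the lesion containing each
#'     point is removed (a point in no lesion is a no-op, so exclusion by
#'     location is idempotent).}
#'   \item{`include`}{list of voxel indices; each is delineated with
#'     [delineate_lesion()] and appended under a fresh id (a seed inside an
#'     existing lesion is a no-op).}
#' }
#' Edit lists can also be read from JSON files of the form
#' `{"exclude": [...], "exclude_points": [[i,j,k], ...], "include": [{"seed": [i,j,k]}, ...]}`
#' via [read_edits()].
#'
#' @param segmentation A `patient_segmentation`.
#' @param edits Edit list as described above.
#' @param volume The [suv_volume()] the segmentation was computed on
#'   (required for `include` edits).
#' @return The edited `patient_segmentation`; remaining lesion ids are stable.
#' @export
apply_edits <- function(segmentation, edits, volume = NULL) {
  seg <- segmentation
  ids <- vapply(seg$lesions, function(l) l$lesion_id, integer(1))
  seen_excluded <- unlist(lapply(seg$edits_applied, function(e)
    if (identical(e$op, "exclude")) e$lesion_id else NULL))
  for (id in edits[["exclude"]] %||% integer(0)) {
    if (id %in% ids) {
      seg$lesions <- seg$lesions[ids != id]
      ids <- ids[ids != id]
      seg$edits_applied <- c(seg$edits_applied,
                             list(list(op = "exclude", lesion_id = id)))
    } else if (!id %in% seen_excluded) {
      stop(sprintf("edit refers to unknown lesion id %d", id))
    }
  }
  dm <- seg$dim
  for (pt in edits[["exclude_points"]] %||% list()) {
    pt <- as.integer(pt)
    plin <- pt[1] + (pt[2] - 1L) * dm[1] + (pt[3] - 1L) * dm[1] * dm[2]
    hit <- vapply(seg$lesions, function(l) plin %in% l$lin, logical(1))
    if (any(hit)) {
      rid <- ids[hit][1]
      seg$lesions <- seg$lesions[ids != rid]
      ids <- ids[ids != rid]
      seg$edits_applied <- c(seg$edits_applied,
                             list(list(op = "exclude_point", point = pt,
                                       lesion_id = rid)))
    }
  }
  for (inc in edits[["include"]] %||% list()) {
    pt <- as.integer(if (is.list(inc)) inc$seed else inc)
    plin <- pt[1] + (pt[2] - 1L) * dm[1] + (pt[3] - 1L) * dm[1] * dm[2]
    inside <- any(vapply(seg$lesions, function(l) plin %in% l$lin, logical(1)))
    if (inside) next
    if (is.null(volume))
      stop("`volume` is required for include edits")
    les <- delineate_lesion(volume, pt, seg$lesions[[1]]$connectivity %||% 26L)
    les$lesion_id <- if (length(ids)) max(ids) + 1L else 1L
    seg$lesions <- c(seg$lesions, list(les))
    ids <- c(ids, les$lesion_id)
    seg$edits_applied <- c(seg$edits_applied,
                           list(list(op = "include", seed = pt,
                                     lesion_id = les$lesion_id)))
  }
  seg
}

#' Read an edit list from JSON
#'
#' @param path JSON file with optional fields `exclude`, `exclude_points`,
#'   `include` (see [apply_edits()]).
#' @return An edit list.
#' @export
read_edits <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  e <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(exclude = as.integer(unlist(e$exclude)),
       exclude_points = lapply(e$exclude_points %||% list(), function(p) as.integer(unlist(p))),
       include = lapply(e$include %||% list(), function(p)
         if (is.list(p) && !is.null(p$seed)) as.integer(unlist(p$seed)) else as.integer(unlist(p))))
}

#' Segmentation as a label image
#'
#' @param segmentation A `patient_segmentation`.
#' @return A [voi_mask()] with each voxel carrying its lesion id (0 outside).
#' @export
segmentation_to_labels <- function(segmentation) {
  lab <- array(0L, dim = segmentation$dim)
  for (l in segmentation$lesions) lab[l$lin] <- l$lesion_id
  voi_mask(lab, segmentation$spacing, segmentation$origin)
}

# ---- cross-scan lesion matching ----

#' Match lesions across two scans
#'
#' Pairs lesions between the segmentations of a test and a retest scan by
#' mutual nearest centroids within a distance cap. One-to-many groups (a
#' lesion that is the nearest neighbour of several lesions on the other scan,
#' e.g. a metastasis segmented as one focus on one scan and several on the
#' other) are reported in `conflicts` and excluded from the pair list rather
#' than silently merged -- such splits need a human decision.
#'
#' @param segA,segB `patient_segmentation` objects on comparable frames.
#' @param max_centroid_distance_mm Pairing cap in mm (default 15).
#' @return A list of class `lesion_pairing`: `pairs` (data frame with
#'   `lesion_a`, `lesion_b`, `distance_mm`), `unmatched_scan1`,
#'   `unmatched_scan2`, `conflicts` (list of one-to-many groups).
#' @export
match_lesions <- function(segA, segB, max_centroid_distance_mm = 15) {
  idA <- vapply(segA$lesions, function(l) l$lesion_id, integer(1))
  idB <- vapply(segB$lesions, function(l) l$lesion_id, integer(1))
  empty <- function(u1, u2, conflicts = list())
    structure(list(pairs = data.frame(lesion_a = integer(0), lesion_b = integer(0),
                                      distance_mm = numeric(0)),
                   unmatched_scan1 = u1, unmatched_scan2 = u2,
                   conflicts = conflicts),
              class = "lesion_pairing")
  if (!length(idA) || !length(idB)) return(empty(idA, idB))
  cA <- t(vapply(segA$lesions, .lesion_centroid, numeric(3),
                 spacing = segA$spacing, origin = segA$origin))
  cB <- t(vapply(segB$lesions, .lesion_centroid, numeric(3),
                 spacing = segB$spacing, origin = segB$origin))
  D <- outer(seq_along(idA), seq_along(idB),
             Vectorize(function(a, b) sqrt(sum((cA[a, ] - cB[b, ])^2))))
  nnA <- apply(D, 1, which.min)           # nearest B for each A
  nnB <- apply(D, 2, which.min)           # nearest A for each B
  okA <- D[cbind(seq_along(idA), nnA)] <= max_centroid_distance_mm
  okB <- D[cbind(nnB, seq_along(idB))] <= max_centroid_distance_mm
  conflicts <- list()
  confA <- rep(FALSE, length(idA)); confB <- rep(FALSE, length(idB))
  for (b in seq_along(idB)) {
    claimers <- which(nnA == b & okA)
    if (length(claimers) > 1) {
      conflicts <- c(conflicts, list(list(scan1 = idA[claimers], scan2 = idB[b])))
      confA[claimers] <- TRUE; confB[b] <- TRUE
    }
  }
  for (a in seq_along(idA)) {
    claimers <- which(nnB == a & okB)
    if (length(claimers) > 1) {
      conflicts <- c(conflicts, list(list(scan1 = idA[a], scan2 = idB[claimers])))
      confB[claimers] <- TRUE; confA[a] <- TRUE
    }
  }
  pa <- integer(0); pb <- integer(0); pd <- numeric(0)
  for (a in seq_along(idA)) {
    if (confA[a] || !okA[a]) next
    b <- nnA[a]
    if (confB[b]) next
    if (nnB[b] == a) { pa <- c(pa, idA[a]); pb <- c(pb, idB[b]); pd <- c(pd, D[a, b]) }
  }
  structure(list(pairs = data.frame(lesion_a = pa, lesion_b = pb, distance_mm = pd),
                 unmatched_scan1 = setdiff(idA[!confA], pa),
                 unmatched_scan2 = setdiff(idB[!confB], pb),
                 conflicts = conflicts),
            class = "lesion_pairing")
}
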