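# Orchestration of the full repeatability study over a paired cohort:
# segment both scans of every patient (per reader), compute per-lesion /
# subgroup / total metrics, assemble paired samples, run the repeatability
# statistics, and export study tables.

.total_metrics <- c("mtv_total", "total_mtv_mean", "psma_tl_total",
                    "psma_tlq_total", "total_mean_suv_max", "total_mean_suv_mean")
.lesion_metrics_cols <- c("mtv_ml", "psma_tl", "psma_tlq",
                          "suv_max", "suv_peak", "suv_mean")
.subgroup_metrics <- c("mtv_subgroup", "subgroup_mtv_mean", "psma_tl_subgroup",
                       "psma_tlq_subgroup", "mean_suv_max", "mean_suv_peak",
                       "mean_suv_mean")

# joint bootstrap of the reader-mean wCV/RC: resamples subjects once and
# recomputes every reader's wCV on the same resample
.boot_mean_wcv <- function(pair_list, n_boot, seed, level) {
  usable <- Reduce(intersect, lapply(pair_list, function(p)
    p$subject_id[(p$a + p$b) > 0]))
  if (length(usable) < 2L) return(c(NA_real_, NA_real_))
  tm <- vapply(pair_list, function(p) {
    p <- p[match(usable, p$subject_id), ]
    (p$a - p$b)^2 / (2 * ((p$a + p$b) / 2)^2)
  }, numeric(length(usable)))
  tm <- matrix(tm, nrow = length(usable))
  n <- nrow(tm)
  est <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      mean(sqrt(colMeans(tm[idx, , drop = FALSE])))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  stats::quantile(est, c(alpha, 1 - alpha), names = FALSE, type = 7)
}

.seg_for_patient <- function(entry, params) {
  if (!is.null(entry$spec)) {
    pair <- generate_phantom_pair(entry$spec)
  } else {
    pair <- list(scan1 = read_suv_volume(entry$scan1),
                 scan2 = read_suv_volume(entry$scan2),
                 liver_mask = read_voi_mask(entry$liver))
  }
  segs <- lapply(c(pair["scan1"], pair["scan2"]), function(vol)
    segment_whole_body(vol, pair$liver_mask,
                       normal_liver_constant = params$normal_liver_constant,
                       connectivity = params$connectivity,
                       sphere_volume_ml = params$peak_sphere_ml))
  list(pair = pair, segs = segs)
}

#' Run the full repeatability study
#'
#' Executes the whole analysis over a paired cohort: whole-body
#' segmentation of both scans of every patient, per-reader manual edits,
#' per-lesion metrics, cross-scan lesion matching, random lesion subgroups,
#' per-patient totals, and the repeatability statistics (wCV, RC, bootstrap
#' CIs, Bland-Altman, ICC), including the reader-swap design when two
#' readers are present. Readers share the algorithmic contours (contours
#' are never hand-adjusted) and differ only by their edit lists and
#' subgroup-selection seeds.
#'
#' The cohort is a [generate_study_fixture()] result, or any list with a
#' `patients` element whose entries carry either a `spec`
#' ([phantom_spec()]) or file paths `scan1`, `scan2`, `liver` (NIfTI), plus
#' optional per-reader `edits`. A patient whose scans fail to process is
#' recorded in `failures` and the run continues.
#'
#' @param cohort Study cohort, see above.
#' @param readers Reader tags (default `c("R1", "R2")`); the first reader's
#'   segmentations feed the per-lesion and subgroup analyses.
#' @param subgroup_cap Max lesions per patient in the subgroup analysis
#'   (default 10).
#' @param subgroup_seed Base seed for the per-patient random subgroup draws.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param stats_seed Seed for all bootstrap resampling.
#' @param zero_policy See [wcv()].
#' @param level CI level (default 0.95).
#' @param normal_liver_constant,connectivity,peak_sphere_ml Segmentation
#'   parameters, see [segment_whole_body()].
#' @param match_cap_mm Lesion-matching distance cap in mm (default 15).
#' @param verbose Print per-patient progress.
#' @return A list of class `repeatability_report`: `totals` (long),
#'   `totals_wide` (one row per patient, one MTV_total column per
#'   reader/scan), `lesion_pairs_n`, `pairs` (every paired sample used),
#'   `stats` (per-lesion / subgroup / total / swap tables), `bland_altman`,
#'   `icc`, `failures`, `provenance`.
#' @export
run_repeatability_study <- function(cohort,
                                    readers = c("R1", "R2"),
                                    subgroup_cap = 10L, subgroup_seed = 7L,
                                    n_boot = 1000L, stats_seed = 17L,
                                    zero_policy = "exclude_both_zero",
                                    level = 0.95,
                                    normal_liver_constant = 4.3,
                                    connectivity = 26L,
                                    peak_sphere_ml = 1.0,
                                    match_cap_mm = 15,
                                    verbose = FALSE) {
  params <- list(normal_liver_constant = normal_liver_constant,
                 connectivity = connectivity, peak_sphere_ml = peak_sphere_ml)
  r1 <- readers[1]
  totals <- list(); lesion_rows <- list(); subgroup_rows <- list()
  failures <- list(); n_matched_lesions <- 0L
  for (pi in seq_along(cohort$patients)) {
    entry <- cohort$patients[[pi]]
    pid <- entry$patient_id %||% sprintf("patient%02d", pi)
    res <- tryCatch({
      base <- .seg_for_patient(entry, params)
      per_reader <- list()
      for (r in readers) {
        ed <- entry$edits[[r]]
        segs <- lapply(1:2, function(s) {
          vol <- base$pair[[c("scan1", "scan2")[s]]]
          if (is.null(ed)) base$segs[[s]] else apply_edits(base$segs[[s]], ed, vol)
        })
        lts <- lapply(1:2, function(s)
          lesion_table(base$pair[[c("scan1", "scan2")[s]]], segs[[s]],
                       peak_sphere_ml = peak_sphere_ml))
        per_reader[[r]] <- list(segs = segs, lts = lts)
      }
      # totals for every reader and scan
      tot <- do.call(rbind, lapply(readers, function(r)
        do.call(rbind, lapply(1:2, function(s)
          aggregate_total(per_reader[[r]]$lts[[s]], patient_id = pid,
                          scan_id = c("scan1", "scan2")[s], reader_id = r)))))
      # per-lesion pairs, first reader
      pr <- per_reader[[r1]]
      mt <- match_lesions(pr$segs[[1]], pr$segs[[2]], match_cap_mm)
      lr <- NULL
      if (nrow(mt$pairs)) {
        i1 <- match(mt$pairs$lesion_a, pr$lts[[1]]$lesion_id)
        i2 <- match(mt$pairs$lesion_b, pr$lts[[2]]$lesion_id)
        lr <- list(scan1 = pr$lts[[1]][i1, , drop = FALSE],
                   scan2 = pr$lts[[2]][i2, , drop = FALSE],
                   patient_id = pid)
      }
      # subgroup: up to `cap` matched lesions, aggregated per scan
      sg <- NULL
      if (!is.null(lr)) {
        pick <- select_subgroup(data.frame(row = seq_len(nrow(lr$scan1))),
                                cap = subgroup_cap,
                                seed = subgroup_seed + pi)$row
        agg1 <- aggregate_subgroup(lr$scan1[pick, , drop = FALSE])
        agg2 <- aggregate_subgroup(lr$scan2[pick, , drop = FALSE])
        sg <- list(scan1 = agg1, scan2 = agg2, patient_id = pid)
      }
      list(tot = tot, lr = lr, sg = sg)
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        list(patient_id = pid, message = conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    totals[[pid]] <- res$tot
    if (!is.null(res$lr)) {
      lesion_rows[[pid]] <- res$lr
      n_matched_lesions <- n_matched_lesions + nrow(res$lr$scan1)
    }
    if (!is.null(res$sg)) subgroup_rows[[pid]] <- res$sg
    if (verbose) message(sprintf("processed %s (%d lesion pairs)", pid,
                                 if (is.null(res$lr)) 0L else nrow(res$lr$scan1)))
  }
  totals <- do.call(rbind, totals)
  rownames(totals) <- NULL

  pairs <- list()
  add_pairs <- function(analysis, metric, reader_tag, subject_id, a, b) {
    df <- paired_samples(subject_id, a, b, metric_name = metric,
                         reader_tag = reader_tag)
    df$analysis <- analysis
    pairs[[length(pairs) + 1L]] <<- df
  }
  # per-lesion
  for (m in .lesion_metrics_cols) {
    a <- unlist(lapply(lesion_rows, function(x) x$scan1[[m]]))
    b <- unlist(lapply(lesion_rows, function(x) x$scan2[[m]]))
    ids <- unlist(lapply(lesion_rows, function(x)
      paste0(x$patient_id, ":", x$scan1$lesion_id)))
    if (length(a)) add_pairs("lesion", m, r1, ids, a, b)
  }
  # subgroup
  for (m in .subgroup_metrics) {
    a <- vapply(subgroup_rows, function(x) x$scan1[[m]], numeric(1))
    b <- vapply(subgroup_rows, function(x) x$scan2[[m]], numeric(1))
    ids <- vapply(subgroup_rows, function(x) x$patient_id, character(1))
    if (length(a)) add_pairs("subgroup", m, r1, ids, a, b)
  }
  # totals per reader, and reader-swap when 2+ readers
  for (m in .total_metrics) {
    for (r in readers) {
      t1 <- totals[totals$reader_id == r & totals$scan_id == "scan1", ]
      t2 <- totals[totals$reader_id == r & totals$scan_id == "scan2", ]
      t2 <- t2[match(t1$patient_id, t2$patient_id), ]
      add_pairs("total", m, r, t1$patient_id, t1[[m]], t2[[m]])
    }
    if (length(readers) >= 2L) {
      for (rr in list(c(1L, 2L), c(2L, 1L))) {
        t1 <- totals[totals$reader_id == readers[rr[1]] & totals$scan_id == "scan1", ]
        t2 <- totals[totals$reader_id == readers[rr[2]] & totals$scan_id == "scan2", ]
        t2 <- t2[match(t1$patient_id, t2$patient_id), ]
        add_pairs("total_swap", m, paste(readers[rr], collapse = ","),
                  t1$patient_id, t1[[m]], t2[[m]])
      }
    }
  }
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL

  est_table <- function(analysis, metrics, tag = NULL) {
    do.call(rbind, lapply(metrics, function(m) {
      sub <- pairs[pairs$analysis == analysis & pairs$metric_name == m, ]
      if (!is.null(tag)) sub <- sub[sub$reader_tag == tag, ]
      if (!nrow(sub) || all(sub$a + sub$b == 0))
        return(data.frame(metric = m, reader_tag = tag %||% NA, wcv = NA, rc = NA,
                          rc_ci_low = NA, rc_ci_high = NA, n = 0L,
                          n_excluded_zero_pairs = NA, estimable = FALSE))
      est <- repeatability(sub, n_boot = n_boot, seed = stats_seed,
                           level = level, zero_policy = zero_policy)
      data.frame(metric = m, reader_tag = tag %||% sub$reader_tag[1],
                 wcv = est$wcv, rc = est$rc,
                 rc_ci_low = est$rc_ci_low, rc_ci_high = est$rc_ci_high,
                 n = est$n_subjects,
                 n_excluded_zero_pairs = est$n_excluded_zero_pairs,
                 estimable = TRUE)
    }))
  }
  stats <- list(per_lesion = est_table("lesion", .lesion_metrics_cols),
                subgroup = est_table("subgroup", .subgroup_metrics))
  # totals: one row per metric with per-reader and mean columns
  stats$total <- do.call(rbind, lapply(.total_metrics, function(m) {
    per <- lapply(readers, function(r)
      pairs[pairs$analysis == "total" & pairs$metric_name == m &
              pairs$reader_tag == r, ])
    ws <- vapply(per, function(p) wcv(p, zero_policy), numeric(1))
    ci <- .boot_mean_wcv(per, n_boot, stats_seed, level)
    data.frame(metric = m,
               t(stats::setNames(ws, paste0("wcv_", readers))),
               mean_wcv = mean(ws),
               t(stats::setNames(rc(ws), paste0("rc_", readers))),
               mean_rc = rc(mean(ws)),
               mean_rc_ci_low = rc(ci[1]), mean_rc_ci_high = rc(ci[2]))
  }))
  if (length(readers) >= 2L) {
    swaps <- c(paste(readers[1:2], collapse = ","),
               paste(readers[2:1], collapse = ","))
    stats$reader_swap <- do.call(rbind, lapply(.total_metrics, function(m) {
      per <- lapply(swaps, function(tg)
        pairs[pairs$analysis == "total_swap" & pairs$metric_name == m &
                pairs$reader_tag == tg, ])
      ws <- vapply(per, function(p) wcv(p, zero_policy), numeric(1))
      ci <- .boot_mean_wcv(per, n_boot, stats_seed, level)
      data.frame(metric = m,
                 t(stats::setNames(rc(ws), paste0("rc_", gsub(",", "_", swaps)))),
                 mean_rc = rc(mean(ws)),
                 mean_rc_ci_low = rc(ci[1]), mean_rc_ci_high = rc(ci[2]))
    }))
  }

  # agreement on MTV_total
  ba <- list()
  mk_mean_pairs <- function(metric) {
    per <- lapply(readers, function(r)
      pairs[pairs$analysis == "total" & pairs$metric_name == metric &
              pairs$reader_tag == r, ])
    base <- per[[1]]
    a <- rowMeans(vapply(per, function(p) p$a[match(base$subject_id, p$subject_id)],
                         numeric(nrow(base))))
    b <- rowMeans(vapply(per, function(p) p$b[match(base$subject_id, p$subject_id)],
                         numeric(nrow(base))))
    paired_samples(base$subject_id, a, b, metric_name = metric,
                   reader_tag = "mean")
  }
  ba$mtv_total <- bland_altman(mk_mean_pairs("mtv_total"))
  ba$total_mean_suv_max <- bland_altman(mk_mean_pairs("total_mean_suv_max"))
  iccs <- list()
  get_tot <- function(r, s) {
    t <- totals[totals$reader_id == r & totals$scan_id == s, ]
    t$mtv_total[match(unique(totals$patient_id), t$patient_id)]
  }
  for (r in readers)
    iccs[[paste0(r, "_scan1_vs_scan2")]] <-
      icc(cbind(get_tot(r, "scan1"), get_tot(r, "scan2")))
  if (length(readers) >= 2L) {
    for (s in c("scan1", "scan2"))
      iccs[[paste0(s, "_", readers[1], "_vs_", readers[2])]] <-
        icc(cbind(get_tot(readers[1], s), get_tot(readers[2], s)))
  }

  # one MTV_total column per reader/scan combination
  totals_wide <- Reduce(function(x, y) merge(x, y, by = "patient_id", sort = FALSE),
    lapply(split(totals, list(totals$reader_id, totals$scan_id)), function(t) {
      nm <- paste0(tolower(t$reader_id[1]), "_", t$scan_id[1])
      stats::setNames(t[, c("patient_id", "mtv_total")], c("patient_id", nm))
    }))

  structure(list(totals = totals, totals_wide = totals_wide,
                 lesion_pairs_n = n_matched_lesions,
                 pairs = pairs, stats = stats,
                 bland_altman = ba, icc = iccs, failures = failures,
                 provenance = list(readers = readers,
                                   subgroup_cap = subgroup_cap,
                                   subgroup_seed = subgroup_seed,
                                   n_boot = n_boot, stats_seed = stats_seed,
                                   zero_policy = zero_policy, level = level,
                                   segmentation = params,
                                   match_cap_mm = match_cap_mm,
                                   package_version = as.character(utils::packageVersion("psmarepeat")))),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("<repeatability_report> %d patients, %d matched lesion pairs, %d failure(s)\n",
              length(unique(x$totals$patient_id)), x$lesion_pairs_n,
              length(x$failures)))
  mt <- x$stats$total[x$stats$total$metric == "mtv_total", ]
  cat(sprintf("  MTV_total: mean wCV %.1f%%, mean RC %.1f%% (CI %.1f-%.1f%%)\n",
              100 * mt$mean_wcv, 100 * mt$mean_rc,
              100 * mt$mean_rc_ci_low, 100 * mt$mean_rc_ci_high))
  invisible(x)
}

#' Export study tables
#'
#' Writes the report as study-shaped tables: per-patient MTV_total (one
#' column per reader and scan), per-lesion / subgroup / total / reader-swap
#' repeatability (wCV and RC as percents, 1 decimal -- rounding happens only
#' at export), agreement (Bland-Altman, ICC), and a full-precision JSON
#' report.
#'
#' @param report A [run_repeatability_study()] result.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (tables + JSON) or `"json"` (JSON only).
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(report, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  pct <- function(x) round(100 * x, 1)
  if (format == "csv") {
    w <- function(df, name) {
      p <- file.path(dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      paths <<- c(paths, p)
    }
    tw <- report$totals_wide
    tw[-1] <- lapply(tw[-1], round, 2)
    w(tw, "totals_per_patient.csv")
    fmt_est <- function(df)
      data.frame(metric = df$metric, wcv_pct = pct(df$wcv), rc_pct = pct(df$rc),
                 rc_ci_low_pct = pct(df$rc_ci_low),
                 rc_ci_high_pct = pct(df$rc_ci_high), n = df$n)
    w(fmt_est(report$stats$per_lesion), "repeatability_per_lesion.csv")
    w(fmt_est(report$stats$subgroup), "repeatability_subgroup.csv")
    tt <- report$stats$total
    num <- vapply(tt, is.numeric, logical(1))
    tt[num] <- lapply(tt[num], pct)
    w(tt, "repeatability_total.csv")
    if (!is.null(report$stats$reader_swap)) {
      ts <- report$stats$reader_swap
      num <- vapply(ts, is.numeric, logical(1))
      ts[num] <- lapply(ts[num], pct)
      w(ts, "repeatability_reader_swap.csv")
    }
    agr <- do.call(rbind, lapply(names(report$bland_altman), function(m) {
      b <- report$bland_altman[[m]]
      data.frame(metric = m, bias = round(b$bias, 2),
                 bias_ci_low = round(b$bias_ci_low, 2),
                 bias_ci_high = round(b$bias_ci_high, 2),
                 loa_low = round(b$loa_low, 2), loa_high = round(b$loa_high, 2),
                 n = b$n)
    }))
    w(agr, "bland_altman.csv")
    iccdf <- do.call(rbind, lapply(names(report$icc), function(nm) {
      i <- report$icc[[nm]]
      data.frame(design = nm, icc = round(i$value, 3), variant = i$variant,
                 p = signif(i$p, 3))
    }))
    w(iccdf, "icc.csv")
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(stats = report$stats,
         bland_altman = lapply(report$bland_altman, unclass),
         icc = lapply(report$icc, unclass),
         lesion_pairs_n = report$lesion_pairs_n,
         failures = report$failures,
         provenance = report$provenance),
    jp, auto_unbox = TRUE, digits = NA, force = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}
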