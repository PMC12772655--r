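#' Pooled material statistics per scanner
#'
#' @param roi_meas ROI measurement table from the measure stage.
#' @return data frame: scanner, material, pooled mean, SE, ROI count.
#' @export
material_stats_table <- function(roi_meas) {
  out <- list()
  for (sc in unique(roi_meas$scanner)) {
    sub <- roi_meas[roi_meas$scanner == sc, ]
    for (mat in unique(sub$material)) {
      row <- pool_material_stats(sub, mat)
      out[[length(out) + 1]] <- cbind(data.frame(scanner = sc), row)
    }
  }
  do.call(rbind, out)
}

#' Image-noise summary
#'
#' Mean and SD of the parenchyma ROI standard deviations, pooled over all
#' parenchyma ROIs and repetitions, per scanner and dose.
#'
#' @param roi_meas ROI measurement table.
#' @return data frame: scanner, dose_mGy, mean_noise, sd_noise, n.
#' @export
summarize_noise <- function(roi_meas) {
  par <- roi_meas[roi_meas$roi_kind == "parenchyma", ]
  agg <- aggregate(sd ~ scanner + dose_mGy, data = par,
                   FUN = function(v) c(mean(v), sd(v), length(v)))
  out <- data.frame(scanner = agg$scanner, dose_mGy = agg$dose_mGy,
                    mean_noise = agg$sd[, 1], sd_noise = agg$sd[, 2],
                    n = agg$sd[, 3])
  out[order(out$scanner, -out$dose_mGy), ]
}

#' Per-dose noise reduction of one scanner relative to another
#'
#' @param noise_summary a [summarize_noise()] table.
#' @param reference,comparison scanner labels.
#' @return data frame: dose_mGy, reference/comparison mean noise, percent
#'   reduction (one decimal in reports).
#' @export
noise_reduction_table <- function(noise_summary, reference = "EIDCT",
                                  comparison = "PCCT") {
  ref <- noise_summary[noise_summary$scanner == reference, ]
  cmp <- noise_summary[noise_summary$scanner == comparison, ]
  m <- merge(ref[, c("dose_mGy", "mean_noise")],
             cmp[, c("dose_mGy", "mean_noise")], by = "dose_mGy",
             suffixes = c("_ref", "_cmp"))
  m$reduction_pct <- percent_change(m$mean_noise_ref, m$mean_noise_cmp,
                                    "reduction")
  m[order(-m$dose_mGy), ]
}

#' Per-instance contrast-to-noise ratios
#'
#' Pairs every lesion ROI with its adjacent parenchyma ROI (same lesion,
#' slice, scanner, dose, repetition) and applies the CNR formula.
#'
#' @param roi_meas ROI measurement table.
#' @return data frame with one CNR per lesion ROI instance.
#' @export
cnr_table <- function(roi_meas) {
  les <- roi_meas[roi_meas$roi_kind == "lesion", ]
  bg <- roi_meas[roi_meas$roi_kind == "parenchyma", ]
  key <- function(d) paste(d$lesion_id, d$slice, d$scanner, d$dose_mGy,
                           d$repetition)
  bg_mean <- setNames(bg$mean, key(bg))
  les$bg_mean <- bg_mean[key(les)]
  les$cnr <- (les$mean - les$bg_mean) / les$sd
  les[, c("lesion_id", "material", "slice", "scanner", "dose_mGy",
          "repetition", "mean", "sd", "bg_mean", "cnr")]
}

#' CNR summary per lesion type and overall
#'
#' Mean absolute CNR per (scanner, dose, lesion type), plus an overall
#' per-(scanner, dose) value: the mean over the six per-lesion CNR means
#' (each lesion first averaged across slices and repetitions).
#'
#' @param cnr a [cnr_table()] result.
#' @return list with `by_type` and `overall` data frames.
#' @export
cnr_summary <- function(cnr) {
  cnr$abs_cnr <- abs(cnr$cnr)
  by_type <- aggregate(abs_cnr ~ scanner + dose_mGy + material, data = cnr,
                       FUN = mean)
  names(by_type)[names(by_type) == "material"] <- "lesion_type"
  per_lesion <- aggregate(abs_cnr ~ scanner + dose_mGy + lesion_id,
                          data = cnr, FUN = mean)
  overall <- aggregate(abs_cnr ~ scanner + dose_mGy, data = per_lesion,
                       FUN = mean)
  list(by_type = by_type[order(by_type$scanner, -by_type$dose_mGy), ],
       overall = overall[order(overall$scanner, -overall$dose_mGy), ])
}

#' Coefficient-of-variation table
#'
#' For each scanner and material, the absolute CoV of the per-dose pooled
#' HU means (HU stability across the dose range).
#'
#' @param roi_meas ROI measurement table.
#' @return data frame: scanner, material, cov, unstable flag.
#' @export
cov_table <- function(roi_meas) {
  out <- list()
  for (sc in unique(roi_meas$scanner)) {
    for (mat in unique(roi_meas$material)) {
      sub <- roi_meas[roi_meas$scanner == sc & roi_meas$material == mat, ]
      per_dose <- aggregate(mean ~ dose_mGy, data = sub, FUN = mean)
      cv <- if (nrow(per_dose) > 1)
        coefficient_of_variation(per_dose$mean) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        scanner = sc, material = mat, cov = as.numeric(cv),
        unstable = isTRUE(attr(cv, "unstable")), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Statistical comparisons of a study
#'
#' Per dose: normality-gated paired comparison of parenchyma noise between
#' scanners (paired by ROI position, slice and repetition); per lesion
#' type and dose: gated paired comparison of absolute CNR; per scanner and
#' material: one-way ANOVA of ROI HU means across doses.
#'
#' @param roi_meas ROI measurement table.
#' @param cnr a [cnr_table()] result.
#' @param alpha significance level.
#' @param reference,comparison scanner labels.
#' @return data frame, one row per test.
#' @export
study_stats <- function(roi_meas, cnr, alpha = 0.05, reference = "EIDCT",
                        comparison = "PCCT") {
  res <- list()
  par <- roi_meas[roi_meas$roi_kind == "parenchyma", ]
  key <- function(d) paste(d$lesion_id, d$slice, d$repetition)
  for (dose in sort(unique(par$dose_mGy), decreasing = TRUE)) {
    a <- par[par$dose_mGy == dose & par$scanner == reference, ]
    b <- par[par$dose_mGy == dose & par$scanner == comparison, ]
    b <- b[match(key(a), key(b)), ]
    r <- paired_compare(a$sd, b$sd, alpha = alpha,
                        comparison = sprintf("noise_%s_vs_%s_%.1fmGy",
                                             reference, comparison, dose))
    r$metric <- "noise"; r$dose_mGy <- dose
    res[[length(res) + 1]] <- r
  }
  ckey <- function(d) paste(d$lesion_id, d$slice, d$repetition)
  for (lt in unique(cnr$material)) {
    for (dose in sort(unique(cnr$dose_mGy), decreasing = TRUE)) {
      a <- cnr[cnr$material == lt & cnr$dose_mGy == dose &
                 cnr$scanner == reference, ]
      b <- cnr[cnr$material == lt & cnr$dose_mGy == dose &
                 cnr$scanner == comparison, ]
      b <- b[match(ckey(a), ckey(b)), ]
      r <- paired_compare(abs(a$cnr), abs(b$cnr), alpha = alpha,
                          comparison = sprintf("cnr_%s_%.1fmGy", lt, dose))
      r$metric <- "cnr"; r$dose_mGy <- dose
      res[[length(res) + 1]] <- r
    }
  }
  for (sc in unique(roi_meas$scanner)) {
    for (mat in unique(roi_meas$material)) {
      sub <- roi_meas[roi_meas$scanner == sc & roi_meas$material == mat, ]
      groups <- split(sub$mean, sub$dose_mGy)
      if (length(groups) >= 3) {
        r <- one_way_anova(groups, alpha = alpha,
                           comparison = sprintf("hu_across_doses_%s_%s",
                                                sc, mat))
        r$metric <- "hu_vs_dose"; r$dose_mGy <- NA_real_
        res[[length(res) + 1]] <- r
      }
    }
  }
  do.call(rbind, lapply(res, function(r) {
    r$n_zero_dropped <- NULL
    r
  }))
}

#' Run the full phantom study
#'
#' Orchestrates generate -> measure -> radiomics -> cluster -> stats in
#' memory, deterministically under the configuration's base seed, and
#' optionally writes the tidy result tables to CSV/JSON.
#'
#' @param config a [study_config()].
#' @param stages subset of `c("measure", "radiomics", "cluster", "stats")`
#'   (generation is implicit; later stages require earlier ones).
#' @param outdir optional output directory for CSV/JSON artifacts.
#' @param verbose print per-stage progress to stderr.
#' @return list of class `study_report`: `manifest`, `roi_measurements`,
#'   `material_stats`, `noise`, `noise_reduction`, `cnr`, `cnr_summary`,
#'   `cov`, `features`, `pca`, `cluster_report`, `stats`, `config`.
#' @export
run_study <- function(config = study_config(),
                      stages = c("measure", "radiomics", "cluster", "stats"),
                      outdir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  grid <- study_grid(config$scanners, config$doses, config$repetitions,
                     config$lesions, config$base_seed)
  specs <- phantom_specs(lesion_specs()[lesion_specs()$lesion_id %in%
                                          config$lesions, ])
  models <- config_noise_models(config)
  report <- list(manifest = grid, config = config)

  roi_rows <- list()
  feat_rows <- list()
  shape_cache <- list()
  for (spec in specs) {
    pid <- spec$phantom_id
    for (sc_i in seq_along(config$scanners)) {
      sc <- config$scanners[sc_i]
      say("rasterizing phantom %d / %s", pid, sc)
      truth <- rasterize_phantom(spec, config$materials, sc,
                                 spacing = config$spacing,
                                 texture = config$texture,
                                 seed = condition_seed(config$base_seed,
                                                       phantom_id = pid))
      rois <- place_rois(truth$mask, spec)
      dims <- dim(truth$volume$data)
      roi_idx <- lapply(seq_len(nrow(rois)), function(i)
        roi_voxel_indices(rois[i, ], dims, config$spacing))
      lesion_masks <- lapply(spec$lesions$lesion_id, function(id)
        truth$mask$data == 10L + id)
      names(lesion_masks) <- spec$lesions$lesion_id
      for (id in spec$lesions$lesion_id) {
        ck <- paste0("l", id)
        if ("radiomics" %in% stages && is.null(shape_cache[[ck]]))
          shape_cache[[ck]] <- shape_features(lesion_masks[[as.character(id)]],
                                              config$spacing)
      }
      for (d_i in seq_along(config$doses)) {
        for (rep_i in seq_len(config$repetitions)) {
          seed <- condition_seed(config$base_seed, sc_i, d_i, rep_i, pid)
          vol <- simulate_scan(truth$volume, truth$mask, models[[sc]], sc,
                               config$doses[d_i], rep_i, seed, rois = rois,
                               corr_mm = config$noise_corr_mm)
          if ("measure" %in% stages)
            roi_rows[[length(roi_rows) + 1]] <-
              measure_rois(vol, rois, index_cache = roi_idx)
          if ("radiomics" %in% stages) {
            for (id in spec$lesions$lesion_id) {
              fv <- extract_all(vol, lesion_masks[[as.character(id)]],
                                bin_width = config$bin_width,
                                shape = shape_cache[[paste0("l", id)]])
              les <- spec$lesions[spec$lesions$lesion_id == id, ]
              feat_rows[[length(feat_rows) + 1]] <- cbind(
                data.frame(lesion_id = id, lesion_type = les$lesion_type,
                           size_class = les$size_class, scanner = sc,
                           dose_mGy = config$doses[d_i],
                           repetition = rep_i, stringsAsFactors = FALSE),
                as.data.frame(as.list(fv)))
            }
          }
        }
        say("  %s dose %.1f mGy done (%.1f s)", sc, config$doses[d_i],
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
      }
    }
  }

  if ("measure" %in% stages) {
    roi_meas <- do.call(rbind, roi_rows)
    rownames(roi_meas) <- NULL
    report$roi_measurements <- roi_meas
    report$material_stats <- material_stats_table(roi_meas)
    report$noise <- summarize_noise(roi_meas)
    report$noise_reduction <- noise_reduction_table(report$noise)
    report$cnr <- cnr_table(roi_meas)
    report$cnr_summary <- cnr_summary(report$cnr)
    report$cov <- cov_table(roi_meas)
  }
  if ("radiomics" %in% stages) {
    features <- do.call(rbind, feat_rows)
    rownames(features) <- NULL
    report$features <- features
  }
  if ("cluster" %in% stages && !is.null(report$features)) {
    meta_cols <- c("lesion_id", "lesion_type", "size_class", "scanner",
                   "dose_mGy", "repetition")
    X <- report$features[, setdiff(names(report$features), meta_cols)]
    space <- fit_pca(X, variance_threshold = config$variance_threshold)
    pts <- project_pca(X, space)
    report$pca <- space
    report$pca_points <- cbind(report$features[, meta_cols],
                               as.data.frame(pts))
    per_scanner <- lapply(config$scanners, function(sc) {
      sel <- report$features$scanner == sc
      labs <- report$features$lesion_type[sel]
      wc <- within_cluster_distance(pts[sel, , drop = FALSE], labs)
      list(within = wc,
           separability = if (length(unique(labs)) >= 2)
             separability(pts[sel, , drop = FALSE], labs) else NA_real_)
    })
    names(per_scanner) <- config$scanners
    report$cluster_report <- list(
      m = space$m, var_frac = space$var_frac,
      purity = cluster_purity(pts, report$features$lesion_type),
      per_scanner = per_scanner)
  }
  if ("stats" %in% stages && !is.null(report$roi_measurements) &&
      length(config$scanners) == 2) {
    report$stats <- study_stats(report$roi_measurements, report$cnr,
                                alpha = config$alpha,
                                reference = config$scanners[1],
                                comparison = config$scanners[2])
  }
  class(report) <- "study_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write study report tables to disk
#'
#' Tidy CSV tables plus a JSON cluster report, as produced by
#' [run_study()].
#'
#' @param report a `study_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) if (!is.null(x))
    write.csv(x, file.path(outdir, f), row.names = FALSE)
  wr(report$manifest, "manifest.csv")
  wr(report$roi_measurements, "roi_measurements.csv")
  wr(report$material_stats, "material_stats.csv")
  wr(report$noise, "noise.csv")
  wr(report$noise_reduction, "noise_reduction.csv")
  wr(report$cnr, "cnr.csv")
  if (!is.null(report$cnr_summary)) {
    wr(report$cnr_summary$by_type, "cnr_by_type.csv")
    wr(report$cnr_summary$overall, "cnr_overall.csv")
  }
  wr(report$cov, "cov.csv")
  wr(report$features, "features.csv")
  wr(report$pca_points, "pca_points.csv")
  wr(report$stats, "stats.csv")
  if (!is.null(report$cluster_report)) {
    cr <- report$cluster_report
    json <- list(m = cr$m, explained_variance = cr$var_frac,
                 purity = cr$purity,
                 per_scanner = lapply(cr$per_scanner, function(s)
                   list(within = s$within, separability = s$separability)))
    jsonlite::write_json(json, file.path(outdir, "cluster_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(outdir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$manifest))
    cat(sprintf("  %d lesion-measurement instances\n", nrow(x$manifest)))
  if (!is.null(x$noise)) {
    cat("  parenchyma noise (mean HU):\n")
    print(x$noise, row.names = FALSE)
  }
  if (!is.null(x$cluster_report))
    cat(sprintf("  PCA: m = %d components; purity %.2f\n",
                x$cluster_report$m, x$cluster_report$purity))
  invisible(x)
}
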