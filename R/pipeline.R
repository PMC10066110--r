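#' Study configuration
#'
#' Bundles everything one full synthetic study needs: the cohort, the
#' segmentation band, measurement options, classification thresholds,
#' rater jitter, output directory and master seed. Serializes losslessly
#' to YAML or JSON via [write_config()] / [read_config()].
#'
#' @param cohort a [cohort_spec()].
#' @param segmentation a [segmentation_params()].
#' @param thresholds a [criteria_thresholds()].
#' @param jitter a [rater_jitter()].
#' @param width_mode `"outermost"` or `"first_crossing"` caliper mode.
#' @param outdir output directory or `NULL` (no files written).
#' @param seed master seed.
#' @param log_level `"debug"`, `"info"`, or `"warning"`.
#' @return A `study_config` object.
#' @export
study_config <- function(cohort = cohort_spec(),
                         segmentation = segmentation_params(),
                         thresholds = criteria_thresholds(),
                         jitter = rater_jitter(),
                         width_mode = "outermost",
                         outdir = NULL, seed = 1L,
                         log_level = c("info", "debug", "warning")) {
  structure(list(cohort = cohort, segmentation = segmentation,
                 thresholds = thresholds, jitter = jitter,
                 width_mode = width_mode, outdir = outdir,
                 seed = as.integer(seed), log_level = match.arg(log_level)),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path file ending in `.yaml`, `.yml`, or `.json`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  plain <- rapply(unclass(config), identity, how = "list")
  plain$cohort$targets <- NULL # re-derived on read; not a free parameter
  plain$cohort$n <- as.list(config$cohort$n) # keep group names in YAML/JSON
  if (grepl("\\.json$", tolower(path)))
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname study_config
#' @export
read_config <- function(path) {
  plain <- if (grepl("\\.json$", tolower(path)))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  co <- plain$cohort
  study_config(
    cohort = cohort_spec(n = unlist(co$n), rho = co$rho,
                         spacing_mm = unlist(co$spacing_mm),
                         blur_sigma_mm = co$blur_sigma_mm,
                         noise_sd_hu = co$noise_sd_hu,
                         length_median_mm = co$length_median_mm,
                         length_sdlog = co$length_sdlog,
                         length_range_mm = unlist(co$length_range_mm),
                         exit_median_mm = co$exit_median_mm,
                         exit_sdlog = co$exit_sdlog,
                         exit_range_mm = unlist(co$exit_range_mm),
                         seed = co$seed),
    segmentation = segmentation_params(plain$segmentation$hu_lower,
                                       plain$segmentation$hu_upper,
                                       plain$segmentation$connectivity),
    thresholds = do.call(criteria_thresholds, plain$thresholds),
    jitter = do.call(rater_jitter, plain$jitter),
    width_mode = plain$width_mode,
    outdir = if (length(plain$outdir)) plain$outdir else NULL,
    seed = plain$seed, log_level = plain$log_level)
}

log_msg <- function(config, level, fmt, ...) {
  lv <- c(debug = 1L, info = 2L, warning = 3L)
  if (lv[[level]] >= lv[[config$log_level]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Segment a VA with the rater's re-click protocol
#'
#' Runs [isolate_va()] at the given seed; if the seed click misses the
#' lumen, re-clicks closer to `reference_seed`, then just inside the
#' operculum aperture where the duct is widest (a duct can be sub-voxel
#' mid-course yet clearly visible at its flaring end). Returns `NULL` when
#' the duct is nowhere identifiable at the image resolution.
#'
#' @param image a [voxel_image()].
#' @param params a [segmentation_params()].
#' @param landmarks a (possibly rater-perturbed) landmark set.
#' @param reference_seed the unperturbed seed point to fall back toward.
#' @return A binary [label_map()], or `NULL`.
#' @export
segment_ear <- function(image, params, landmarks,
                        reference_seed = landmarks$seed) {
  oper <- landmarks$operculum
  candidates <- c(
    lapply(c(1, 0.5, 0.25, 0),
           function(s) reference_seed + s * (landmarks$seed - reference_seed)),
    lapply(c(0.6, 1.2, 2), function(d) oper$point - d * unitize(oper$normal)))
  for (seed_try in candidates) {
    seg <- tryCatch(isolate_va(image, params, seed_try,
                               landmarks$vestibule_exit, landmarks$operculum),
                    vamorph_seed_error = function(e) NULL,
                    vamorph_domain_error = function(e) NULL)
    if (!is.null(seg)) return(seg)
  }
  NULL
}

# segment + centerline + measure one rasterized ear for one rater
measure_ear <- function(rast, config, ear_id, rater_id, rater_seed) {
  lm <- perturb_for_rater(rast$ground_truth$landmarks, config$jitter, rater_seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_vamorph("stage '%s' failed for %s: %s", name, ear_id,
                   conditionMessage(e), class = "vamorph_pipeline_error"))
  }
  va <- stage("segment",
              segment_ear(rast$image, config$segmentation, lm,
                          reference_seed = rast$ground_truth$landmarks$seed))
  if (is.null(va) || sum(va$data) < 4L) {
    # duct below the resolution limit everywhere: recorded as not
    # identifiable (zero widths / volume), as clinical tables do
    return(data.frame(ear_id = ear_id, rater_id = rater_id,
                      midpoint_mm = 0, operculum_mm = 0,
                      voxel_volume_mm3 = 0, mesh_volume_mm3 = 0,
                      flags = "not_identifiable", stringsAsFactors = FALSE))
  }
  cl <- stage("centerline", skeleton_centerline(va, lm$vestibule_exit$point,
                                                lm$operculum$point))
  stage("measure", measure_record(va, cl, ear_id = ear_id, rater_id = rater_id,
                                  measurement = lm$measurement,
                                  operculum_plane = lm$operculum,
                                  mode = config$width_mode))
}

#' Run the full synthetic study
#'
#' Generate the cohort, rasterize each ear, measure it under two
#' independently perturbed raters, classify, and assemble the statistical
#' blocks the published analysis reports: descriptive five-number
#' summaries per group, Kruskal-Wallis with Dunn post hoc and
#' Hodges-Lehmann differences for the significant control contrasts,
#' per-group Spearman correlations of volume against both diameters,
#' inter-rater ICC(2,1) per measurement type, ROC (EVAS vs control, VA
#' volume) with the Youden cutoff and exact binomial CIs, and the
#' Cincinnati-vs-volumetric concordance table. Deterministic in the
#' master seed; statistics other than the ICC use rater 1's measurements.
#'
#' @param config a [study_config()].
#' @return A `study_result` list; see Details in the package vignette.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  config$cohort$seed <- config$seed
  manifest <- sample_cohort(config$cohort)
  specs <- attr(manifest, "specs")
  log_msg(config, "info", "cohort of %d ears (%s)", nrow(manifest),
          paste(sprintf("%s=%d", names(config$cohort$n), config$cohort$n),
                collapse = ", "))
  recs <- vector("list", 2L * nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rast <- rasterize_phantom(specs[[i]])
    for (r in 1:2) {
      rec <- measure_ear(rast, config, manifest$ear_id[i], sprintf("r%d", r),
                         rater_seed = derive_seed(config$seed, 10L * i + r))
      recs[[2L * (i - 1L) + r]] <- rec
    }
    log_msg(config, "debug", "measured %s (%s)", manifest$ear_id[i],
            manifest$group[i])
  }
  meas <- do.call(rbind, recs)
  meas <- merge(meas, manifest[, c("ear_id", "group", "truth_volume_mm3",
                                   "truth_midpoint_mm", "truth_operculum_mm")],
                by = "ear_id", sort = FALSE)
  meas <- meas[order(meas$ear_id, meas$rater_id), ]
  rownames(meas) <- NULL
  cin <- classify_cincinnati(meas$midpoint_mm, meas$operculum_mm, config$thresholds)
  meas$cincinnati <- cin$enlarged
  meas$cincinnati_trigger <- cin$trigger
  meas$valvassori <- classify_valvassori(meas$midpoint_mm, config$thresholds)
  meas$volumetric <- classify_volumetric(meas$mesh_volume_mm3, config$thresholds)

  r1 <- meas[meas$rater_id == "r1", ]
  groups_present <- intersect(c("control", "CH", "IPI", "IPII", "EVAS"),
                              unique(r1$group))
  by_group <- function(col) split(r1[[col]], factor(r1$group, groups_present))

  descriptive <- do.call(rbind, lapply(groups_present, function(g) {
    gg <- r1[r1$group == g, ]
    cbind(data.frame(group = g,
                     measure = c("operculum_mm", "midpoint_mm", "mesh_volume_mm3"),
                     n = nrow(gg)),
          rbind(five_number_summary(gg$operculum_mm),
                five_number_summary(gg$midpoint_mm),
                five_number_summary(gg$mesh_volume_mm3)))
  }))

  vol_groups <- by_group("mesh_volume_mm3")
  group_tests <- NULL
  if (length(vol_groups) >= 2L) {
    kw <- kruskal_wallis(vol_groups)
    dunn <- dunn_posthoc(vol_groups)
    hl <- NULL
    sig <- dunn[dunn$p_adjusted < 0.05 &
                  (dunn$group1 == "control" | dunn$group2 == "control"), ]
    if (nrow(sig)) {
      hl <- do.call(rbind, lapply(seq_len(nrow(sig)), function(k) {
        g_other <- if (sig$group1[k] == "control") sig$group2[k] else sig$group1[k]
        h <- hodges_lehmann(vol_groups[["control"]], vol_groups[[g_other]])
        data.frame(pair = sprintf("%s-control", g_other),
                   median_difference = h$estimate,
                   ci_lower = h$ci_lower, ci_upper = h$ci_upper)
      }))
    }
    group_tests <- list(kruskal_wallis = kw, dunn = dunn, hodges_lehmann = hl)
  }

  correlations <- do.call(rbind, lapply(groups_present, function(g) {
    gg <- r1[r1$group == g, ]
    if (nrow(gg) < 3L) return(NULL)
    do.call(rbind, lapply(c(midpoint = "midpoint_mm", operculum = "operculum_mm"),
      function(col) {
        sp <- tryCatch(spearman(gg[[col]], gg$mesh_volume_mm3),
                       error = function(e) NULL)
        if (is.null(sp)) return(NULL)
        data.frame(group = g, diameter = sub("_mm$", "", col),
                   rho = sp$rho, p_value = sp$p_value, n = sp$n)
      }))
  }))

  r2 <- meas[meas$rater_id == "r2", ]
  reliability <- do.call(rbind, lapply(
    c(volume = "mesh_volume_mm3", midpoint = "midpoint_mm",
      operculum = "operculum_mm"),
    function(col) {
      icc <- tryCatch(icc_agreement(cbind(r1[[col]], r2[[col]])),
                      error = function(e) NA_real_)
      data.frame(measure = sub("_mm.*$", "", col), icc = icc)
    }))
  reliability$measure <- c("volume", "midpoint", "operculum")

  roc_block <- list(computable = FALSE)
  if (all(c("control", "EVAS") %in% groups_present)) {
    sel <- r1$group %in% c("control", "EVAS")
    roc <- roc_youden(r1$mesh_volume_mm3[sel], r1$group[sel] == "EVAS")
    n_pos <- sum(r1$group[sel] == "EVAS"); n_neg <- sum(sel) - n_pos
    roc_block <- list(
      computable = TRUE, cutoff = roc$cutoff, auc = roc$auc,
      sensitivity = roc$sensitivity, specificity = roc$specificity,
      youden_j = roc$youden_j,
      sensitivity_ci = binomial_ci(round(roc$sensitivity * n_pos), n_pos),
      specificity_ci = binomial_ci(round(roc$specificity * n_neg), n_neg))
  }

  concordance <- as.data.frame(table(cincinnati = r1$cincinnati,
                                     volumetric = r1$volumetric))

  result <- structure(list(config = config, manifest = manifest,
                           measurements = meas, descriptive = descriptive,
                           group_tests = group_tests,
                           correlations = correlations,
                           reliability = reliability, roc = roc_block,
                           concordance = concordance),
                      class = "study_result")
  if (!is.null(config$outdir)) write_study_result(result, config$outdir)
  log_msg(config, "info", "classified enlarged: cincinnati %d, valvassori %d, volumetric %d of %d ears",
          sum(r1$cincinnati), sum(r1$valvassori), sum(r1$volumetric), nrow(r1))
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d ears x 2 raters\n", nrow(x$manifest)))
  if (!is.null(x$group_tests))
    cat(sprintf("  Kruskal-Wallis H = %.2f, p = %.3g\n",
                x$group_tests$kruskal_wallis$statistic,
                x$group_tests$kruskal_wallis$p_value))
  if (isTRUE(x$roc$computable))
    cat(sprintf("  ROC volume cutoff %.2f mm^3: sens %.2f, spec %.2f\n",
                x$roc$cutoff, x$roc$sensitivity, x$roc$specificity))
  print(x$reliability, row.names = FALSE)
  invisible(x)
}

write_study_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(outdir, name), row.names = FALSE)
  wr(result$manifest, "manifest.csv")
  wr(result$measurements, "measurements.csv")
  wr(result$descriptive, "descriptive.csv")
  if (!is.null(result$group_tests)) {
    wr(result$group_tests$dunn, "dunn.csv")
    wr(result$group_tests$hodges_lehmann, "hodges_lehmann.csv")
  }
  wr(result$correlations, "correlations.csv")
  wr(result$reliability, "reliability.csv")
  wr(result$concordance, "concordance.csv")
  summary_json <- list(
    kruskal_wallis = result$group_tests$kruskal_wallis,
    roc = result$roc)
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Replicate the inter-rater reliability experiment
#'
#' For each replicate, a fresh cohort is generated and measured under two
#' independently perturbed raters; ICC(2,1) is computed per measurement
#' type, and the summary reports the fraction of replicates in which the
#' volume ICC exceeds both diameter ICCs, with its exact binomial CI.
#'
#' @param config a [study_config()]; its cohort sizes set the per-replicate
#'   cohort.
#' @param replicates number of replicate cohorts (>= 1).
#' @return List: `per_replicate` (data.frame with one row per replicate),
#'   `fraction_volume_highest`, `fraction_ci`.
#' @export
rater_experiment <- function(config = study_config(), replicates = 20L) {
  stopifnot(inherits(config, "study_config"), replicates >= 1L)
  rows <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    co <- config$cohort
    co$seed <- derive_seed(config$seed, 9000L + rep_i)
    manifest <- sample_cohort(co)
    specs <- attr(manifest, "specs")
    cols <- c("mesh_volume_mm3", "midpoint_mm", "operculum_mm")
    m1 <- m2 <- matrix(NA_real_, nrow(manifest), 3L,
                       dimnames = list(NULL, cols))
    flagged <- FALSE
    for (i in seq_len(nrow(manifest))) {
      rast <- rasterize_phantom(specs[[i]])
      for (r in 1:2) {
        rec <- measure_ear(rast, config, manifest$ear_id[i], sprintf("r%d", r),
                           rater_seed = derive_seed(co$seed, 10L * i + r))
        if (r == 1L) m1[i, ] <- unlist(rec[cols]) else m2[i, ] <- unlist(rec[cols])
      }
    }
    iccs <- vapply(1:3, function(j) {
      tryCatch(icc_agreement(cbind(m1[, j], m2[, j])), error = function(e) {
        flagged <<- TRUE; NA_real_
      })
    }, numeric(1))
    rows[[rep_i]] <- data.frame(replicate = rep_i, icc_volume = iccs[1],
                                icc_midpoint = iccs[2], icc_operculum = iccs[3],
                                degenerate = flagged)
    log_msg(config, "info", "replicate %d: ICC vol %.3f mid %.3f oper %.3f",
            rep_i, iccs[1], iccs[2], iccs[3])
  }
  per <- do.call(rbind, rows)
  ok <- !per$degenerate & !is.na(per$icc_volume)
  wins <- per$icc_volume[ok] > pmax(per$icc_midpoint[ok], per$icc_operculum[ok])
  if (length(wins) == 0L)
    return(list(per_replicate = per, fraction_volume_highest = NA_real_,
                fraction_ci = c(lower = NA_real_, upper = NA_real_)))
  list(per_replicate = per, fraction_volume_highest = mean(wins),
       fraction_ci = binomial_ci(sum(wins), length(wins)))
}
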