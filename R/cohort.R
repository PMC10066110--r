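#' Published group-wise diameter distribution targets
#'
#' Five-number summaries (mm) of the VA operculum and midpoint diameters
#' for the control group and the four inner-ear-malformation groups
#' (cochlear hypoplasia CH, incomplete partition types I/II, EVAS), used as
#' calibration targets for [cohort_spec()]. Zero minima are floored at
#' 0.05 mm when used as sampling bounds (a bony VA of strictly zero caliber
#' is not representable by a positive-radius tube).
#'
#' @return A data.frame with columns `group`, `site`, `min`, `q25`,
#'   `median`, `q75`, `max`.
#' @export
diameter_targets <- function() {
  tab <- rbind(
    c("control", "operculum", 0.2, 0.7, 0.9, 1.0, 1.4),
    c("control", "midpoint",  0.2, 0.5, 0.6, 0.7, 1.1),
    c("CH",      "operculum", 0.0, 0.6, 1.1, 3.6, 7.0),
    c("CH",      "midpoint",  0.0, 0.2, 0.8, 2.3, 3.4),
    c("IPI",     "operculum", 0.0, 0.6, 1.4, 2.7, 3.3),
    c("IPI",     "midpoint",  0.0, 0.9, 1.6, 2.0, 2.2),
    c("IPII",    "operculum", 2.2, 3.0, 3.4, 4.1, 4.8),
    c("IPII",    "midpoint",  1.2, 1.7, 2.1, 2.3, 3.1),
    c("EVAS",    "operculum", 1.9, 2.1, 3.4, 4.1, 5.4),
    c("EVAS",    "midpoint",  1.0, 1.4, 2.2, 2.9, 3.8))
  out <- data.frame(group = tab[, 1], site = tab[, 2],
                    apply(tab[, 3:7], 2L, as.double))
  names(out)[3:7] <- c("min", "q25", "median", "q75", "max")
  out
}

#' Cohort specification for synthetic study simulation
#'
#' Per-group sample sizes default to the study composition (42 controls,
#' 18 CH, 12 IPI, 11 IPII, 15 EVAS). Diameters are drawn from truncated
#' log-normal distributions whose location is solved so the *truncated*
#' median equals the published group median, whose log-scale comes from the
#' published interquartile ratio, and whose support is the published
#' min/max range. The three radii of an ear share a latent log-factor
#' (`rho`): an enlarged duct tends to be enlarged along its whole course.
#' Course length and the exit radius are not reported by diameter tables;
#' their defaults (length median 10 mm; exit diameter median 0.5 mm,
#' reflecting the uniformly narrow isthmus at the vestibule) are package
#' choices documented in the methods vignette.
#'
#' @param n named integer vector of group sizes.
#' @param rho latent-factor correlation between an ear's radii, in [0, 1).
#' @param spacing_mm,blur_sigma_mm,noise_sd_hu imaging parameters passed to
#'   every [phantom_spec()].
#' @param length_median_mm,length_sdlog,length_range_mm course-length
#'   distribution (log-normal, truncated).
#' @param exit_median_mm,exit_sdlog,exit_range_mm exit-diameter
#'   distribution (log-normal, truncated).
#' @param seed master seed; everything downstream is deterministic in it.
#' @return A `cohort_spec` object (calibration targets stored alongside).
#' @export
cohort_spec <- function(n = c(control = 42L, CH = 18L, IPI = 12L, IPII = 11L,
                              EVAS = 15L),
                        rho = 0.7,
                        spacing_mm = c(0.3, 0.3, 0.625),
                        blur_sigma_mm = 0.3, noise_sd_hu = 40,
                        length_median_mm = 10, length_sdlog = 0.08,
                        length_range_mm = c(8, 13),
                        exit_median_mm = 0.5, exit_sdlog = 0.25,
                        exit_range_mm = c(0.2, 1.2),
                        seed = 1L) {
  if (any(n < 0L)) stop_vamorph("group sizes must be >= 0", class = "vamorph_parameter_error")
  if (is.null(names(n)) || !all(names(n) %in% c("control", "CH", "IPI", "IPII", "EVAS")))
    stop_vamorph("n must be named with groups control/CH/IPI/IPII/EVAS",
                 class = "vamorph_parameter_error")
  structure(list(n = n, rho = rho, targets = diameter_targets(),
                 spacing_mm = spacing_mm, blur_sigma_mm = blur_sigma_mm,
                 noise_sd_hu = noise_sd_hu,
                 length_median_mm = length_median_mm, length_sdlog = length_sdlog,
                 length_range_mm = length_range_mm,
                 exit_median_mm = exit_median_mm, exit_sdlog = exit_sdlog,
                 exit_range_mm = exit_range_mm, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n =", paste(sprintf("%s:%d", names(x$n), x$n), collapse = " "),
      sprintf("| seed %d\n", x$seed))
  invisible(x)
}

# Truncated log-normal: solve the log-location so the truncated median hits
# `med`, then map correlated uniforms through the truncated quantile.
tlnorm_mu <- function(med, sdlog, lo, hi) {
  stopifnot(lo < med, med < hi)
  trunc_median <- function(mu) { # strictly increasing in mu
    a <- stats::plnorm(lo, mu, sdlog); b <- stats::plnorm(hi, mu, sdlog)
    p <- min(max((a + b) / 2, 1e-12), 1 - 1e-12)
    min(max(stats::qlnorm(p, mu, sdlog), lo), hi)
  }
  f <- function(mu) trunc_median(mu) - med
  iv <- log(med) + c(-3, 3) * sdlog
  for (i in 1:30) { if (f(iv[1]) < 0) break; iv[1] <- iv[1] - sdlog }
  for (i in 1:30) { if (f(iv[2]) > 0) break; iv[2] <- iv[2] + sdlog }
  stats::uniroot(f, iv, tol = 1e-10)$root
}

tlnorm_quantile <- function(u, mu, sdlog, lo, hi) {
  a <- stats::plnorm(lo, mu, sdlog); b <- stats::plnorm(hi, mu, sdlog)
  stats::qlnorm(a + u * (b - a), mu, sdlog)
}

# per-group, per-site sampling parameters derived from the targets
cohort_site_params <- function(spec, group, site) {
  tg <- spec$targets
  row <- tg[tg$group == group & tg$site == site, ]
  lo <- max(row$min, 0.05); hi <- row$max
  sdlog <- max((log(row$q75) - log(max(row$q25, 0.05))) / (2 * stats::qnorm(0.75)), 0.05)
  list(mu = tlnorm_mu(row$median, sdlog, lo, hi), sdlog = sdlog, lo = lo, hi = hi)
}

#' Sample a synthetic cohort
#'
#' Deterministic in the master seed. Each ear receives a [phantom_spec()]
#' (with its own derived seed) and the corresponding analytic ground truth;
#' the archetype tag records the dominant drawn shape.
#'
#' @param cohort a [cohort_spec()].
#' @return A data.frame manifest (one row per ear: id, group, seed, truth
#'   volume and diameters, drawn geometry) with the list of `phantom_spec`
#'   objects attached as attribute `"specs"`.
#' @export
sample_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  groups <- names(cohort$n)
  rows <- list(); specs <- list(); ear <- 0L
  for (g in groups) {
    ng <- cohort$n[[g]]
    if (ng == 0L) next
    pm <- cohort_site_params(cohort, g, "midpoint")
    po <- cohort_site_params(cohort, g, "operculum")
    draws <- withr::with_seed(derive_seed(cohort$seed, 300L + match(g, groups)), {
      zc <- rnorm(ng); ze <- rnorm(ng); zm <- rnorm(ng); zo <- rnorm(ng)
      zl <- rnorm(ng)
      mix <- function(z) stats::pnorm(cohort$rho * zc + sqrt(1 - cohort$rho^2) * z)
      d_exit <- tlnorm_quantile(mix(ze), log(cohort$exit_median_mm),
                                cohort$exit_sdlog,
                                cohort$exit_range_mm[1], cohort$exit_range_mm[2])
      d_mid <- tlnorm_quantile(mix(zm), pm$mu, pm$sdlog, pm$lo, pm$hi)
      d_oper <- tlnorm_quantile(mix(zo), po$mu, po$sdlog, po$lo, po$hi)
      L <- tlnorm_quantile(stats::pnorm(zl), log(cohort$length_median_mm),
                           cohort$length_sdlog,
                           cohort$length_range_mm[1], cohort$length_range_mm[2])
      list(d_exit = d_exit, d_mid = d_mid, d_oper = d_oper, L = L)
    })
    for (i in seq_len(ng)) {
      ear <- ear + 1L
      r <- c(draws$d_exit[i], draws$d_mid[i], draws$d_oper[i]) / 2
      tag <- if (r[2] > max(r[1], r[3])) "central_dilatation"
             else if (r[3] > r[1]) "funnel" else "uniform"
      prof <- new_radius_profile(tag, r[1], r[2], r[3])
      sp <- phantom_spec(prof, length_mm = draws$L[i],
                         bend_radius_mm = max(15, 4 * max(r)),
                         spacing_mm = cohort$spacing_mm,
                         blur_sigma_mm = cohort$blur_sigma_mm,
                         noise_sd_hu = cohort$noise_sd_hu,
                         seed = derive_seed(cohort$seed, 7000L + ear))
      gt <- ground_truth(sp, phantom_frame(sp))
      specs[[ear]] <- sp
      rows[[ear]] <- data.frame(
        ear_id = sprintf("ear%03d", ear), group = g, archetype = tag,
        seed = sp$seed, length_mm = draws$L[i],
        r_exit_mm = r[1], r_mid_mm = r[2], r_oper_mm = r[3],
        truth_volume_mm3 = gt$volume_mm3,
        truth_midpoint_mm = gt$midpoint_diameter_mm,
        truth_operculum_mm = gt$operculum_diameter_mm,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ear_id = character(), group = character())
  attr(manifest, "specs") <- specs
  manifest
}

# internal constructor bypassing archetype-consistency validation: cohort
# tags describe the dominant drawn shape, radii are whatever was drawn.
new_radius_profile <- function(tag, r_exit, r_mid, r_oper) {
  structure(list(archetype = tag, r_exit = r_exit, r_mid = r_mid,
                 r_oper = r_oper, fn = profile_fn(c(r_exit, r_mid, r_oper))),
            class = "radius_profile")
}
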