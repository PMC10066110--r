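#' Synthetic temporal-bone phantom specification
#'
#' Describes one synthetic ear: a vestibular aqueduct modeled as a tube of
#' varying radius along a planar circular-arc course running from the
#' vestibule exit to the operculum, embedded in uniformly dense bone, with
#' an ellipsoidal vestibule attached tangentially at the exit plane. The
#' course plane is tilted only slightly from the axial plane so that
#' axial-slice caliper widths approximate true diameters, as in clinical
#' practice. HU levels are phantom design parameters: the defaults place
#' the clinical segmentation threshold (700 HU) at the fluid/bone
#' half-maximum so that fixed-threshold segmentation recovers the true
#' lumen boundary rather than an HU-dependent offset of it.
#'
#' @param profile a [build_radius_profile()] object.
#' @param length_mm VA course length L in mm (> 0).
#' @param bend_radius_mm radius of the circular-arc course (must exceed the
#'   largest profile radius; default 15).
#' @param tilt_deg tilt of the course plane from the axial plane, degrees
#'   (|tilt| <= 20 keeps axial widths within ~6% of true diameters).
#' @param vestibule_semiaxes_mm ellipsoid semi-axes; the first is aligned
#'   with the course tangent at the exit. `NULL` drops the vestibule.
#' @param hu_bone,hu_fluid HU of otic capsule bone and of the fluid lumen.
#' @param blur_sigma_mm Gaussian partial-volume blur (mm; 0 disables).
#' @param noise_sd_hu additive Gaussian noise after blur (HU; 0 disables).
#' @param spacing_mm per-axis voxel spacing (mm, each within 0.1 to 1).
#' @param extent_mm optional physical image extent (length 3, mm). Default
#'   auto-fits the anatomy with a margin; an explicit extent too small for
#'   the tube raises a domain error.
#' @param with_cochlea add a decorative cochlear spiral (visual realism
#'   only; never part of the VA truth).
#' @param seed integer seed controlling the noise draw.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(profile, length_mm = 10, bend_radius_mm = 15,
                         tilt_deg = 10,
                         vestibule_semiaxes_mm = c(2.5, 1.5, 1.5),
                         hu_bone = 1370, hu_fluid = 30,
                         blur_sigma_mm = 0.3, noise_sd_hu = 40,
                         spacing_mm = c(0.3, 0.3, 0.625),
                         extent_mm = NULL, with_cochlea = FALSE, seed = 1L) {
  stopifnot(inherits(profile, "radius_profile"))
  if (length_mm <= 0) stop_vamorph("length_mm must be > 0", class = "vamorph_parameter_error")
  rmax <- max(profile$r_exit, profile$r_mid, profile$r_oper)
  if (bend_radius_mm <= rmax)
    stop_vamorph("bend radius (%.3g) must exceed the maximum tube radius (%.3g)",
                 bend_radius_mm, rmax, class = "vamorph_parameter_error")
  spacing_mm <- as.double(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm < 0.1 - 1e-12) || any(spacing_mm > 1 + 1e-12))
    stop_vamorph("spacing components must lie within [0.1, 1] mm",
                 class = "vamorph_parameter_error")
  if (hu_fluid >= hu_bone)
    stop_vamorph("hu_fluid must be below hu_bone", class = "vamorph_parameter_error")
  structure(list(profile = profile, length_mm = length_mm,
                 bend_radius_mm = bend_radius_mm, tilt_deg = tilt_deg,
                 vestibule_semiaxes_mm = vestibule_semiaxes_mm,
                 hu_bone = hu_bone, hu_fluid = hu_fluid,
                 blur_sigma_mm = blur_sigma_mm, noise_sd_hu = noise_sd_hu,
                 spacing_mm = spacing_mm, extent_mm = extent_mm,
                 with_cochlea = isTRUE(with_cochlea), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s VA, L=%.3g mm, bend R=%.3g mm, spacing %s mm, seed %d\n",
              x$profile$archetype, x$length_mm, x$bend_radius_mm,
              paste(format(x$spacing_mm, digits = 3), collapse = "x"), x$seed))
  invisible(x)
}

# Arc-course frame shared by rasterization and ground truth. The course lies
# in the plane spanned by u (in the axial plane) and v (tilted by tilt_deg);
# theta = 0 is the vestibule exit.
phantom_frame <- function(spec) {
  tau <- spec$tilt_deg * pi / 180
  u <- c(1, 0, 0)
  v <- c(0, cos(tau), sin(tau))
  np <- c(0, -sin(tau), cos(tau))
  dtheta <- spec$length_mm / spec$bend_radius_mm
  exit_pt <- c(0, 0, 0)
  center <- exit_pt - spec$bend_radius_mm * u
  arc_point <- function(s) {
    th <- s * dtheta
    center + spec$bend_radius_mm * (cos(th) * u + sin(th) * v)
  }
  arc_tangent <- function(s) {
    th <- s * dtheta
    -sin(th) * u + cos(th) * v
  }
  t0 <- arc_tangent(0)
  vest_center <- if (is.null(spec$vestibule_semiaxes_mm)) NULL else
    exit_pt - spec$vestibule_semiaxes_mm[1] * t0
  list(u = u, v = v, np = np, dtheta = dtheta, center = center,
       exit = exit_pt, arc_point = arc_point, arc_tangent = arc_tangent,
       t0 = t0, vest_center = vest_center)
}

# Membership tests, vectorized over an n x 3 matrix of world points.
phantom_membership <- function(spec, fr, P) {
  q <- sweep(P, 2L, fr$center, `-`)
  qu <- q %*% fr$u; qv <- q %*% fr$v; w <- q %*% fr$np
  phi <- atan2(qv, qu)
  in_ang <- phi >= 0 & phi <= fr$dtheta
  s <- pmin(pmax(phi / fr$dtheta, 0), 1)
  rho <- sqrt(qu^2 + qv^2)
  dist_axis <- sqrt((rho - spec$bend_radius_mm)^2 + w^2)
  rs <- profile_radius(spec$profile, as.vector(s))
  va <- as.vector(in_ang & dist_axis <= rs)
  lum <- va
  if (!is.null(fr$vest_center)) {
    a <- spec$vestibule_semiaxes_mm
    b1 <- fr$t0
    b2 <- unitize(pracma_nullvec(b1))
    b3 <- c(b1[2] * b2[3] - b1[3] * b2[2],
            b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    qq <- sweep(P, 2L, fr$vest_center, `-`)
    e <- (qq %*% b1 / a[1])^2 + (qq %*% b2 / a[2])^2 + (qq %*% b3 / a[3])^2
    lum <- lum | as.vector(e <= 1)
  }
  if (spec$with_cochlea) lum <- lum | cochlea_membership(spec, fr, P)
  list(lumen = lum, va = va)
}

# any unit vector orthogonal to b1
pracma_nullvec <- function(b1) {
  cand <- if (abs(b1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  cand - sum(cand * b1) * b1
}

# Decorative 1.5-turn spiral near the vestibule; visual realism only.
cochlea_membership <- function(spec, fr, P) {
  if (is.null(fr$vest_center)) return(rep(FALSE, nrow(P)))
  tseq <- seq(0, 1.5 * 2 * pi, length.out = 120L)
  rad <- 2.2 - 1.2 * tseq / max(tseq)
  ctr <- fr$vest_center - 4 * fr$t0
  pts <- cbind(ctr[1] + rad * cos(tseq), ctr[2] + rad * sin(tseq),
               ctr[3] + 0.4 * tseq / max(tseq))
  tube_r <- 0.5
  inside <- rep(FALSE, nrow(P))
  chunk <- 20000L
  for (i0 in seq(1L, nrow(P), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(P))
    d2 <- outer(rowSums(P[i0:i1, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * P[i0:i1, , drop = FALSE] %*% t(pts)
    inside[i0:i1] <- apply(d2, 1L, min) <= tube_r^2
  }
  inside
}

#' Rasterize a phantom to a CT volume with analytic ground truth
#'
#' Voxel HU is `bone + (fluid - bone) * coverage`, where coverage is the
#' fraction of the voxel inside the lumen, estimated by 3^3 supersampling
#' for voxels on the lumen boundary (exact 0/1 elsewhere); Gaussian blur and
#' seeded Gaussian noise are then applied as configured. The truth-lumen
#' label marks voxels with VA-only coverage > 0.5, restricted to the VA
#' segment between the vestibule-exit plane and the operculum end cap.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` ([voxel_image()]), `truth`
#'   ([label_map()] of the VA lumen), and `ground_truth` (analytic volume,
#'   true diameters, world landmarks).
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  fr <- phantom_frame(spec)
  h <- spec$spacing_mm
  rmax <- max(spec$profile$r_exit, spec$profile$r_mid, spec$profile$r_oper)

  ss <- t(vapply(seq(0, 1, length.out = 65L), fr$arc_point, numeric(3)))
  lo <- apply(ss, 2L, min) - rmax
  hi <- apply(ss, 2L, max) + rmax
  if (!is.null(fr$vest_center)) {
    a <- max(spec$vestibule_semiaxes_mm)
    lo <- pmin(lo, fr$vest_center - a); hi <- pmax(hi, fr$vest_center + a)
  }
  margin <- 3 * spec$blur_sigma_mm + 2 * max(h) + 0.6
  if (is.null(spec$extent_mm)) {
    lo <- lo - margin; hi <- hi + margin
  } else {
    ctr <- (lo + hi) / 2
    lo2 <- ctr - spec$extent_mm / 2; hi2 <- ctr + spec$extent_mm / 2
    if (any(lo < lo2 - 1e-9) || any(hi > hi2 + 1e-9))
      stop_vamorph("VA tube escapes the requested image extent",
                   class = "vamorph_domain_error")
    lo <- lo2; hi <- hi2
  }
  dm <- pmax(ceiling((hi - lo) / h) + 1L, 2L)
  origin <- lo

  dims <- as.integer(dm)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  P <- cbind(origin[1] + (idx[, 1] - 1) * h[1],
             origin[2] + (idx[, 2] - 1) * h[2],
             origin[3] + (idx[, 3] - 1) * h[3])

  mem <- phantom_membership(spec, fr, P)
  lum <- array(mem$lumen, dim = dims)
  va <- array(mem$va, dim = dims)

  cov_l <- supersampled_coverage(spec, fr, P, lum, dims, h, field = "lumen")
  cov_v <- supersampled_coverage(spec, fr, P, va, dims, h, field = "va")

  hu <- spec$hu_bone + (spec$hu_fluid - spec$hu_bone) * cov_l
  if (spec$blur_sigma_mm > 0)
    hu <- gauss_blur_cpp(hu, dims, spec$blur_sigma_mm / h)
  if (spec$noise_sd_hu > 0)
    hu <- hu + withr::with_seed(derive_seed(spec$seed, 101L),
                                rnorm(length(hu), 0, spec$noise_sd_hu))
  img <- voxel_image(array(hu, dim = dims), spacing = h, origin = origin)
  truth <- label_map(array(as.integer(cov_v > 0.5), dim = dims),
                     spacing = h, origin = origin)

  gt <- ground_truth(spec, fr)
  list(image = img, truth = truth, ground_truth = gt)
}

# coverage: exact 0/1 at interior/exterior voxels, 3^3 supersampling where a
# 6-neighbor differs in membership.
supersampled_coverage <- function(spec, fr, P, member_arr, dims, h, field) {
  cov <- as.double(member_arr)
  bnd <- boundary_voxels(member_arr, dims)
  if (!any(bnd)) return(cov)
  Pb <- P[bnd, , drop = FALSE]
  off <- as.matrix(expand.grid(x = c(-1, 0, 1) / 3, y = c(-1, 0, 1) / 3,
                               z = c(-1, 0, 1) / 3))
  acc <- numeric(nrow(Pb))
  for (k in seq_len(nrow(off))) {
    Pk <- sweep(Pb, 2L, off[k, ] * h, `+`)
    m <- phantom_membership(spec, fr, Pk)
    acc <- acc + if (field == "va") m$va else m$lumen
  }
  cov[bnd] <- acc / nrow(off)
  cov
}

boundary_voxels <- function(member_arr, dims) {
  m <- member_arr
  differs <- array(FALSE, dim = dims)
  shift_neq <- function(ax, dir) {
    n <- dims[ax]
    idx_a <- if (dir > 0) 1:(n - 1) else 2:n
    idx_b <- if (dir > 0) 2:n else 1:(n - 1)
    d <- array(FALSE, dim = dims)
    if (ax == 1) d[idx_a, , ] <- m[idx_a, , ] != m[idx_b, , ]
    if (ax == 2) d[, idx_a, ] <- m[, idx_a, ] != m[, idx_b, ]
    if (ax == 3) d[, , idx_a] <- m[, , idx_a] != m[, , idx_b]
    d
  }
  for (ax in 1:3) for (dir in c(-1, 1)) differs <- differs | shift_neq(ax, dir)
  as.vector(differs)
}

ground_truth <- function(spec, fr) {
  mid <- fr$arc_point(0.5)
  oper <- fr$arc_point(1)
  t_end <- fr$arc_tangent(1)
  list(
    volume_mm3 = analytic_tube_volume(spec$profile, spec$length_mm),
    midpoint_diameter_mm = 2 * profile_radius(spec$profile, 0.5),
    operculum_diameter_mm = 2 * profile_radius(spec$profile, 1),
    landmarks = list(
      seed = mid,
      midpoint = mid,
      # plane normals point away from the VA (the kept side)
      vestibule_exit = list(point = fr$exit, normal = -fr$t0),
      operculum = list(point = oper, normal = t_end)
    )
  )
}

#' Write / read a ground-truth + landmark JSON sidecar
#'
#' @param gt a `ground_truth` list as produced by [rasterize_phantom()].
#' @param path JSON file path.
#' @return `path` (write) or the ground-truth list (read).
#' @export
write_landmarks <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("seed", "midpoint")) gt$landmarks[[nm]] <- as.double(gt$landmarks[[nm]])
  for (nm in c("vestibule_exit", "operculum")) {
    gt$landmarks[[nm]]$point <- as.double(gt$landmarks[[nm]]$point)
    gt$landmarks[[nm]]$normal <- as.double(gt$landmarks[[nm]]$normal)
  }
  gt
}

#' Simulate rater-specific landmark perturbation
#'
#' Models an independent blinded rater re-doing the manual interactions:
#' every point landmark is displaced uniformly within a sphere, and each 2D
#' caliper measurement receives a measurement-line angle offset (uniform)
#' and an axial slice-index offset (uniform on `{-1, 0, +1}` scaled by
#' `slice`). Draws are independent per rater via the seed.
#'
#' @param landmarks the `landmarks` element of a ground-truth list.
#' @param jitter a [rater_jitter()] parameter set.
#' @param seed integer seed for this rater's draws.
#' @return Landmarks with perturbed points plus a `measurement` element
#'   holding per-site `angle_deg` and `slice_offset`.
#' @export
perturb_for_rater <- function(landmarks, jitter = rater_jitter(), seed = 1L) {
  stopifnot(jitter$point_mm >= 0, jitter$angle_deg >= 0, jitter$slice >= 0)
  withr::with_seed(derive_seed(seed, 202L), {
    disp <- function() {
      if (jitter$point_mm == 0) return(c(0, 0, 0))
      v <- rnorm(3); v <- v / max(vnorm(v), 1e-12)
      v * jitter$point_mm * runif(1)^(1 / 3)
    }
    out <- landmarks
    out$seed <- landmarks$seed + disp()
    out$midpoint <- landmarks$midpoint + disp()
    out$vestibule_exit$point <- landmarks$vestibule_exit$point + disp()
    out$operculum$point <- landmarks$operculum$point + disp()
    slice_draw <- function() if (jitter$slice == 0) 0L else
      as.integer(sample(c(-1L, 0L, 1L), 1L)) * as.integer(jitter$slice)
    out$measurement <- list(
      midpoint = list(angle_deg = runif(1, -jitter$angle_deg, jitter$angle_deg),
                      slice_offset = slice_draw()),
      operculum = list(angle_deg = runif(1, -jitter$angle_deg, jitter$angle_deg),
                       slice_offset = slice_draw())
    )
    out
  })
}

#' @param point_mm sphere radius for point-landmark displacement (mm).
#' @param angle_deg half-range of the measurement-line angle jitter (deg).
#' @param slice axial slice-index jitter amplitude (0 disables).
#' @rdname perturb_for_rater
#' @export
rater_jitter <- function(point_mm = 0.3, angle_deg = 10, slice = 1L) {
  list(point_mm = point_mm, angle_deg = angle_deg, slice = as.integer(slice))
}
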