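#' Voxel-counting volume of a binary mask
#'
#' @param mask a binary [label_map()] (or 0/1 array with `spacing`).
#' @param spacing per-axis spacing in mm (taken from the mask if omitted).
#' @return Foreground voxel count times the voxel volume, mm^3.
#' @export
voxel_volume <- function(mask, spacing = NULL) {
  if (inherits(mask, "label_map")) {
    spacing <- spacing %||% mask$spacing
    mask <- mask$data
  }
  if (is.null(spacing)) stop_vamorph("spacing required", class = "vamorph_parameter_error")
  sum(mask != 0) * prod(spacing)
}

#' Extract the 0.5-level surface of a binary mask
#'
#' Marching tetrahedra over the (zero-padded) binary field produce a
#' watertight, outward-oriented triangle mesh in world mm. The pad
#' guarantees closure even when foreground touches the lattice boundary.
#'
#' @param mask a binary [label_map()].
#' @param iso iso level (default 0.5, the midpoint of a binary field).
#' @return A [trimesh()].
#' @export
extract_surface <- function(mask, iso = 0.5) {
  stopifnot(inherits(mask, "label_map"))
  if (sum(mask$data != 0L) == 0L)
    stop_vamorph("cannot extract a surface from an empty mask",
                 class = "vamorph_geometry_error")
  dm <- dim(mask$data)
  padded <- array(0, dim = dm + 2L)
  padded[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- as.double(mask$data != 0L)
  res <- march_tets_cpp(as.double(padded), as.integer(dm + 2L), iso,
                        mask$spacing, mask$origin - mask$spacing)
  trimesh(res$vertices, res$faces)
}

#' Centerline of a tubular mask between two endpoints
#'
#' The mask's chamfer distance transform defines a medialness field; the
#' centerline is the minimum-cost (medialness-weighted geodesic) voxel path
#' between the foreground voxels nearest each endpoint, smoothed by a
#' 3-point moving average and parameterized by cumulative arc length.
#'
#' @param mask a binary [label_map()].
#' @param endpoint_a,endpoint_b world points (mm) at/adjacent to the mask
#'   (typically the vestibule-exit and operculum landmarks).
#' @return A `centerline`: list with `points` (n x 3 world mm), `arclen`
#'   (cumulative, mm), `length_mm`.
#' @export
skeleton_centerline <- function(mask, endpoint_a, endpoint_b) {
  stopifnot(inherits(mask, "label_map"))
  dm <- dim(mask$data)
  fg <- which(mask$data != 0L)
  if (length(fg) < 2L)
    stop_vamorph("mask too small for a centerline", class = "vamorph_centerline_error")
  fgi <- arrayInd(fg, dm)
  W <- index_to_world(mask, fgi)
  near <- function(p) {
    d2 <- (W[, 1] - p[1])^2 + (W[, 2] - p[2])^2 + (W[, 3] - p[3])^2
    fg[which.min(d2)]
  }
  ia <- near(as.double(endpoint_a)); ib <- near(as.double(endpoint_b))
  m01 <- as.integer(mask$data != 0L)
  dt <- chamfer_dt_cpp(m01, as.integer(dm), mask$spacing)
  path <- medial_path_cpp(m01, as.integer(dm), mask$spacing, dt,
                          as.integer(ia), as.integer(ib))
  if (length(path) == 0L)
    stop_vamorph("endpoints are not connected within the mask",
                 class = "vamorph_centerline_error")
  pts <- index_to_world(mask, arrayInd(path, dm))
  if (nrow(pts) >= 3L) {
    sm <- pts
    n <- nrow(pts)
    sm[2:(n - 1L), ] <- (pts[1:(n - 2L), ] + pts[2:(n - 1L), ] + pts[3:n, ]) / 3
    pts <- sm
  }
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arclen <- c(0, cumsum(seg))
  structure(list(points = pts, arclen = arclen, length_mm = arclen[length(arclen)]),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.2f mm\n",
              nrow(x$points), x$length_mm))
  invisible(x)
}

# interpolated point at arc position l (mm); tangent from a central
# difference over a +/- 0.5 mm window (robust to voxel-path jaggedness)
centerline_at <- function(cl, l) {
  l <- min(max(l, 0), cl$length_mm)
  i <- findInterval(l, cl$arclen, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(cl$points) - 1L)
  t0 <- cl$arclen[i]; t1 <- cl$arclen[i + 1L]
  w <- if (t1 > t0) (l - t0) / (t1 - t0) else 0
  p <- (1 - w) * cl$points[i, ] + w * cl$points[i + 1L, ]
  interp <- function(a) {
    a <- min(max(a, 0), cl$length_mm)
    j <- min(max(findInterval(a, cl$arclen, rightmost.closed = TRUE), 1L),
             nrow(cl$points) - 1L)
    s0 <- cl$arclen[j]; s1 <- cl$arclen[j + 1L]
    ww <- if (s1 > s0) (a - s0) / (s1 - s0) else 0
    (1 - ww) * cl$points[j, ] + ww * cl$points[j + 1L, ]
  }
  tg <- interp(l + 0.5) - interp(l - 0.5)
  if (vnorm(tg) < 1e-9) tg <- cl$points[i + 1L, ] - cl$points[i, ]
  list(point = p, tangent = unitize(tg))
}

# direction of the final `span` mm of the centerline: principal axis of the
# trailing points, signed toward the endpoint (stabilizes the direction at
# an endpoint against voxel-path jaggedness)
terminal_tangent <- function(cl, span = 1.5) {
  n <- nrow(cl$points)
  sel <- cl$arclen >= cl$length_mm - span
  if (sum(sel) < 3L) sel[max(1L, n - 2L):n] <- TRUE
  pts <- cl$points[sel, , drop = FALSE]
  ctr <- colMeans(pts)
  ev <- eigen(crossprod(sweep(pts, 2L, ctr)), symmetric = TRUE)$vectors[, 1L]
  chord <- cl$points[n, ] - pts[1L, ]
  if (sum(ev * chord) < 0) ev <- -ev
  unitize(ev)
}

#' Caliper width on an axial slice
#'
#' Reproduces the clinical 2D caliper: on the axial slice through the
#' measurement point, the binary field is sampled by interpolation along
#' the in-slice line through the point perpendicular to the in-slice
#' projection of the course tangent; the width is the distance between the
#' outermost 0.5 crossings (a `first_crossing` mode measures the run
#' containing the point instead). Sampling step is min in-plane spacing / 4.
#'
#' @param mask binary [label_map()].
#' @param at world measurement point (mm).
#' @param tangent local course direction (unit vector not required).
#' @param angle_deg extra in-plane rotation of the measurement line
#'   (rater jitter; 0 = exactly perpendicular).
#' @param slice_offset axial slice-index offset (rater jitter).
#' @param mode `"outermost"` (default) or `"first_crossing"`.
#' @param max_extent_mm half-length of the sampled line.
#' @param reflect_plane optional [cut_plane()] across which the field is
#'   mirrored while sampling: used at an anatomical cut (the operculum end
#'   cap) so that the zeros beyond the cut do not erode the interpolated
#'   boundary of a structure measured at its own truncation.
#' @return Width in mm (0 when the point lies outside the mask).
#' @export
axial_width <- function(mask, at, tangent, angle_deg = 0, slice_offset = 0L,
                        mode = c("outermost", "first_crossing"),
                        max_extent_mm = 10, reflect_plane = NULL) {
  stopifnot(inherits(mask, "label_map"))
  mode <- match.arg(mode)
  at <- as.double(at); tangent <- as.double(tangent)
  t2 <- tangent[1:2]
  if (vnorm(t2) < 1e-3)
    stop_vamorph("course tangent is perpendicular to the axial plane; width undefined",
                 class = "vamorph_direction_error")
  t2 <- t2 / vnorm(t2)
  d <- c(-t2[2], t2[1])
  if (angle_deg != 0) {
    a <- angle_deg * pi / 180
    d <- c(cos(a) * d[1] - sin(a) * d[2], sin(a) * d[1] + cos(a) * d[2])
  }
  dm <- dim(mask$data)
  k <- as.integer(round((at[3] - mask$origin[3]) / mask$spacing[3])) + 1L +
    as.integer(slice_offset)
  if (k < 1L || k > dm[3]) return(0)
  step <- min(mask$spacing[1:2]) / 4
  lam <- seq(-max_extent_mm, max_extent_mm, by = step)
  xs <- at[1] + lam * d[1]
  ys <- at[2] + lam * d[2]
  v <- bilinear_slice(mask, k, xs, ys, reflect_plane)
  if (all(is.na(v)) || max(v, na.rm = TRUE) < 0.5) return(0)
  v[is.na(v)] <- 0
  i0 <- which.min(abs(lam))
  if (v[i0] < 0.5) return(0)
  above <- v >= 0.5
  if (mode == "first_crossing") {
    lo <- i0; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- i0; while (hi < length(v) && above[hi + 1L]) hi <- hi + 1L
  } else {
    lo <- which(above)[1L]
    hi <- tail(which(above), 1L)
  }
  cross_lo <- if (lo == 1L) lam[1L] else {
    w <- (0.5 - v[lo - 1L]) / (v[lo] - v[lo - 1L]); lam[lo - 1L] + w * step
  }
  cross_hi <- if (hi == length(v)) lam[length(v)] else {
    w <- (0.5 - v[hi + 1L]) / (v[hi] - v[hi + 1L]); lam[hi + 1L] - w * step
  }
  cross_hi - cross_lo
}

# bilinear interpolation of the binary field within axial slice k; with a
# reflect_plane, corner voxels beyond the plane take the value of the voxel
# nearest their mirror image instead (mirror boundary at an anatomical cut)
bilinear_slice <- function(mask, k, xs, ys, reflect_plane = NULL) {
  dm <- dim(mask$data)
  fx <- (xs - mask$origin[1]) / mask$spacing[1] + 1
  fy <- (ys - mask$origin[2]) / mask$spacing[2] + 1
  x0 <- floor(fx); y0 <- floor(fy)
  wx <- fx - x0; wy <- fy - y0
  ok <- x0 >= 1 & x0 + 1 <= dm[1] & y0 >= 1 & y0 + 1 <= dm[2]
  out <- rep(NA_real_, length(xs))
  if (!any(ok)) return(out)
  x0k <- x0[ok]; y0k <- y0[ok]; wxk <- wx[ok]; wyk <- wy[ok]
  corner <- function(dx, dy) {
    xi <- x0k + dx; yi <- y0k + dy
    if (is.null(reflect_plane))
      return(as.double(mask$data[cbind(xi, yi, rep(k, length(xi)))] != 0L))
    W <- index_to_world(mask, cbind(xi, yi, k))
    sd <- (W[, 1] - reflect_plane$point[1]) * reflect_plane$normal[1] +
          (W[, 2] - reflect_plane$point[2]) * reflect_plane$normal[2] +
          (W[, 3] - reflect_plane$point[3]) * reflect_plane$normal[3]
    refl <- sd > 0
    if (any(refl)) {
      Wr <- W[refl, , drop = FALSE] -
        2 * sd[refl] %o% reflect_plane$normal
      ir <- nearest_voxel(mask, Wr)
      xi[refl] <- ir[, 1]; yi <- replace(yi, refl, ir[, 2])
      kk <- rep(k, length(xi)); kk[refl] <- ir[, 3]
      return(as.double(mask$data[cbind(xi, yi, kk)] != 0L))
    }
    as.double(mask$data[cbind(xi, yi, rep(k, length(xi)))] != 0L)
  }
  v00 <- corner(0L, 0L); v10 <- corner(1L, 0L)
  v01 <- corner(0L, 1L); v11 <- corner(1L, 1L)
  out[ok] <- (1 - wxk) * (1 - wyk) * v00 + wxk * (1 - wyk) * v10 +
             (1 - wxk) * wyk * v01 + wxk * wyk * v11
  out
}

#' Full morphometry of one segmented VA
#'
#' Midpoint diameter is the axial caliper width at the centerline's
#' half-arc-length point. The operculum diameter is measured at the
#' aperture itself: the caliper line sits 0.6 in-plane voxels inside the
#' duct end (at the very end the line would lie on the digitized cap
#' boundary), and the binary field is mirrored across the operculum plane
#' while sampling so that the emptiness beyond the anatomical cut does not
#' erode the interpolated aperture boundary. The measurement direction
#' comes from the operculum landmark plane normal when provided, else
#' from the trailing centerline direction. Volume is
#' reported both as voxel count and as the enclosed volume of the
#' watertight surface mesh (the headline figure). A record is flagged
#' `under_resolved` when the two volumes disagree by more than 15% or the
#' midpoint width is below two in-plane voxels — partial-volume territory.
#'
#' @param va_mask binary [label_map()] of the VA.
#' @param centerline a [skeleton_centerline()] result.
#' @param ear_id,rater_id identifiers carried into the record.
#' @param measurement optional per-site jitter list (from
#'   [perturb_for_rater()]).
#' @param operculum_plane the operculum landmark plane (`list(point=,
#'   normal=)` or [cut_plane()]); when given, its normal defines both the
#'   mirror plane and the course direction at the aperture, which is far
#'   more stable than the discrete centerline's terminal direction. When
#'   `NULL`, both are estimated from the trailing centerline.
#' @param mode width mode passed to [axial_width()].
#' @param oper_search_mm cap on the aperture pull-back distance (mm).
#' @return A one-row data.frame: `ear_id`, `rater_id`, `midpoint_mm`,
#'   `operculum_mm`, `voxel_volume_mm3`, `mesh_volume_mm3`, `flags`.
#' @export
measure_record <- function(va_mask, centerline, ear_id = "ear", rater_id = "r1",
                           measurement = NULL, operculum_plane = NULL,
                           mode = "outermost", oper_search_mm = 1.2) {
  stopifnot(inherits(va_mask, "label_map"), inherits(centerline, "centerline"))
  jmid <- measurement$midpoint %||% list(angle_deg = 0, slice_offset = 0L)
  joper <- measurement$operculum %||% list(angle_deg = 0, slice_offset = 0L)
  midpt <- centerline_at(centerline, centerline$length_mm / 2)
  w_mid <- axial_width(va_mask, midpt$point, midpt$tangent,
                       angle_deg = jmid$angle_deg,
                       slice_offset = jmid$slice_offset, mode = mode)
  if (!is.null(operculum_plane)) {
    cap <- if (inherits(operculum_plane, "cut_plane")) operculum_plane
           else cut_plane(operculum_plane$point, operculum_plane$normal)
    t_end <- cap$normal
  } else {
    t_end <- terminal_tangent(centerline)
    cap <- cut_plane(centerline$points[nrow(centerline$points), ], t_end)
  }
  delta <- min(0.6 * max(va_mask$spacing[1:2]), oper_search_mm)
  w_oper <- axial_width(va_mask,
                        centerline_at(centerline, centerline$length_mm - delta)$point,
                        t_end, angle_deg = joper$angle_deg,
                        slice_offset = joper$slice_offset, mode = mode,
                        reflect_plane = cap)
  vv <- voxel_volume(va_mask)
  mv <- mesh_volume(extract_surface(va_mask))
  flags <- character(0)
  if (mv > 0 && abs(vv - mv) / mv > 0.15) flags <- c(flags, "volume_mismatch")
  if (w_mid < 2 * max(va_mask$spacing[1:2])) flags <- c(flags, "under_resolved")
  data.frame(ear_id = ear_id, rater_id = rater_id,
             midpoint_mm = w_mid, operculum_mm = w_oper,
             voxel_volume_mm3 = vv, mesh_volume_mm3 = mv,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
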