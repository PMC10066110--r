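#' Segmentation parameters
#'
#' The clinical protocol segments the fluid-filled inner-ear lumina from
#' dense temporal bone by a fixed Hounsfield band; the default band is
#' -1024 to 700 HU, inclusive at both ends. Foreground connectivity
#' defaults to the 26-neighborhood (thin anisotropically sampled ducts
#' fragment under 6-connectivity).
#'
#' @param hu_lower,hu_upper HU band (lower < upper).
#' @param connectivity 6, 18, or 26.
#' @param roi optional world-mm ROI box `list(lo = c(x,y,z), hi = c(x,y,z))`;
#'   thresholding outside the box yields background.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(hu_lower = -1024, hu_upper = 700,
                                connectivity = 26L, roi = NULL) {
  if (!is.finite(hu_lower) || !is.finite(hu_upper) || hu_lower >= hu_upper)
    stop_vamorph("require hu_lower < hu_upper", class = "vamorph_parameter_error")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_vamorph("connectivity must be 6, 18 or 26", class = "vamorph_parameter_error")
  structure(list(hu_lower = hu_lower, hu_upper = hu_upper,
                 connectivity = as.integer(connectivity), roi = roi),
            class = "segmentation_params")
}

#' Threshold an image to a binary mask
#'
#' A voxel is foreground iff `hu_lower <= HU <= hu_upper` (inclusive both
#' ends) and, when an ROI is given, its center lies inside the ROI box.
#'
#' @param image a [voxel_image()].
#' @param params a [segmentation_params()].
#' @return A binary [label_map()] on the image grid.
#' @export
threshold_mask <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "voxel_image"), inherits(params, "segmentation_params"))
  m <- image$data >= params$hu_lower & image$data <= params$hu_upper
  if (!is.null(params$roi)) {
    dm <- dim(image$data)
    idx <- arrayInd(seq_len(prod(dm)), dm)
    P <- index_to_world(image, idx)
    inroi <- P[, 1] >= params$roi$lo[1] & P[, 1] <= params$roi$hi[1] &
             P[, 2] >= params$roi$lo[2] & P[, 2] <= params$roi$hi[2] &
             P[, 3] >= params$roi$lo[3] & P[, 3] <= params$roi$hi[3]
    m <- m & array(inroi, dim = dm)
  }
  label_map(array(as.integer(m), dim = dim(image$data)),
            spacing = image$spacing, origin = image$origin)
}

#' Label connected components of a binary mask
#'
#' Components are labeled 1..C in order of decreasing voxel count
#' (background 0).
#'
#' @param mask a binary [label_map()].
#' @param connectivity 6, 18 or 26.
#' @return A [label_map()] with attribute `"counts"` (voxels per label).
#' @export
connected_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "label_map"))
  dm <- dim(mask$data)
  lab <- cc_label_cpp(as.integer(mask$data != 0L), as.integer(dm),
                      as.integer(connectivity))
  out <- label_map(array(lab, dim = dm), spacing = mask$spacing,
                   origin = mask$origin)
  nc <- attr(lab, "n_components")
  counts <- if (nc > 0) tabulate(lab[lab > 0L], nbins = nc) else integer(0)
  attr(out, "counts") <- counts
  out
}

#' Select the component containing a seed point
#'
#' The component containing the voxel nearest the world-mm seed is
#' returned as a binary mask. Ties in voxel proximity resolve to the
#' lowest linear index (documented tie-break, via coordinate rounding).
#' A seed whose nearest voxel is background raises a seed-miss error that
#' reports the distance to the nearest foreground voxel.
#'
#' @param labels a labeled [label_map()] from [connected_components()].
#' @param seed world point (mm), inside the image bounds.
#' @return A binary [label_map()].
#' @export
select_seeded_component <- function(labels, seed) {
  stopifnot(inherits(labels, "label_map"))
  if (!in_bounds(labels, seed))
    stop_vamorph("seed point lies outside the image bounds",
                 class = "vamorph_domain_error")
  idx <- nearest_voxel(labels, seed)
  lab <- labels$data[idx[1, 1], idx[1, 2], idx[1, 3]]
  if (lab == 0L) {
    fg <- which(labels$data > 0L)
    if (length(fg) == 0L)
      stop_vamorph("seed misses: mask has no foreground", class = "vamorph_seed_error")
    fgi <- arrayInd(fg, dim(labels$data))
    W <- index_to_world(labels, fgi)
    dmin <- sqrt(min(colSums((t(W) - as.double(seed))^2)))
    stop_vamorph("seed voxel is background; nearest foreground voxel is %.3f mm away",
                 dmin, class = "vamorph_seed_error")
  }
  label_map(array(as.integer(labels$data == lab), dim = dim(labels$data)),
            spacing = labels$spacing, origin = labels$origin)
}

#' Cutting planes
#'
#' A plane is a world point plus unit normal; [clip_by_planes()] keeps the
#' voxels whose centers have signed distance `<= 0` to every plane, i.e.
#' the side the normal points *away* from.
#'
#' @param point world point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @return A `cut_plane` object.
#' @export
cut_plane <- function(point, normal) {
  structure(list(point = as.double(point), normal = unitize(as.double(normal))),
            class = "cut_plane")
}

#' @param mask a binary [label_map()].
#' @param planes list of [cut_plane()]s (empty list leaves the mask as is).
#' @rdname cut_plane
#' @export
clip_by_planes <- function(mask, planes) {
  stopifnot(inherits(mask, "label_map"))
  if (length(planes) == 0L) return(mask)
  dm <- dim(mask$data)
  keep <- mask$data != 0L
  fg <- which(keep)
  if (length(fg)) {
    W <- index_to_world(mask, arrayInd(fg, dm))
    ok <- rep(TRUE, length(fg))
    for (pl in planes) {
      stopifnot(inherits(pl, "cut_plane"))
      sd <- (W[, 1] - pl$point[1]) * pl$normal[1] +
            (W[, 2] - pl$point[2]) * pl$normal[2] +
            (W[, 3] - pl$point[3]) * pl$normal[3]
      ok <- ok & sd <= 0
    }
    keep[fg[!ok]] <- FALSE
  }
  label_map(array(as.integer(keep), dim = dm), spacing = mask$spacing,
            origin = mask$origin)
}

#' Isolate the vestibular aqueduct from a CT volume
#'
#' The semi-automatic protocol made explicit: HU-band thresholding,
#' connected components, selection of the component containing the seed,
#' then clipping at the vestibule-exit plane and operculum end plane (plane
#' normals pointing away from the VA). The published method does not state
#' how the VA was separated from the vestibule; the exit plane here is a
#' declared, reproducible reconstruction of that manual step.
#'
#' @param image a [voxel_image()].
#' @param params a [segmentation_params()].
#' @param seed world seed point inside the VA lumen.
#' @param vestibule_exit,operculum `list(point=, normal=)` landmark planes
#'   (as stored in the phantom sidecar), or [cut_plane()] objects.
#' @return A binary [label_map()] of the VA.
#' @export
isolate_va <- function(image, params = segmentation_params(), seed,
                       vestibule_exit, operculum) {
  as_plane <- function(x) if (inherits(x, "cut_plane")) x else cut_plane(x$point, x$normal)
  for (p in list(seed, as_plane(vestibule_exit)$point, as_plane(operculum)$point))
    if (!in_bounds(image, p))
      stop_vamorph("landmark outside image bounds", class = "vamorph_domain_error")
  mask <- threshold_mask(image, params)
  labs <- connected_components(mask, params$connectivity)
  comp <- select_seeded_component(labs, seed)
  va <- clip_by_planes(comp, list(as_plane(vestibule_exit), as_plane(operculum)))
  if (sum(va$data) == 0L)
    stop_vamorph("segmentation produced an empty VA mask",
                 class = "vamorph_segmentation_error")
  va
}
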