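# Shared fixture builders; everything generated in code at test time.

# a noise-free, blur-free phantom at isotropic spacing for geometry checks
clean_phantom_spec <- function(archetype = "uniform", radii = c(1.5, 1.5, 1.5),
                               length_mm = 10, spacing = 0.2, tilt_deg = 10,
                               vestibule = c(2.5, 1.5, 1.5), seed = 1L, ...) {
  phantom_spec(vamorph:::new_radius_profile(archetype, radii[1], radii[2], radii[3]),
               length_mm = length_mm, blur_sigma_mm = 0, noise_sd_hu = 0,
               spacing_mm = rep(spacing, 3), tilt_deg = tilt_deg,
               vestibule_semiaxes_mm = vestibule, seed = seed, ...)
}

# rasterize + segment + centerline in one go
measure_clean_phantom <- function(spec) {
  r <- rasterize_phantom(spec)
  lm <- r$ground_truth$landmarks
  va <- isolate_va(r$image, segmentation_params(), lm$seed,
                   lm$vestibule_exit, lm$operculum)
  cl <- skeleton_centerline(va, lm$vestibule_exit$point, lm$operculum$point)
  list(rast = r, va = va, cl = cl,
       rec = measure_record(va, cl, operculum_plane = lm$operculum))
}

# axis-aligned solid cylinder mask (axis along x) on an isotropic grid;
# `offset` shifts the axis off the lattice (generic position)
cylinder_mask <- function(radius = 1.5, length_mm = 10, h = 0.2, margin = 1,
                          offset = c(0, 0)) {
  ext <- c(length_mm + 2 * margin, 2 * (radius + margin), 2 * (radius + margin))
  dm <- ceiling(ext / h) + 1L
  idx <- arrayInd(seq_len(prod(dm)), dm)
  x <- (idx[, 1] - 1) * h; y <- (idx[, 2] - 1) * h; z <- (idx[, 3] - 1) * h
  cy <- ext[2] / 2 + offset[1]; cz <- ext[3] / 2 + offset[2]
  inside <- x >= margin & x <= margin + length_mm &
    (y - cy)^2 + (z - cz)^2 <= radius^2
  out <- label_map(array(as.integer(inside), dim = dm), spacing = rep(h, 3))
  attr(out, "axis_center") <- c(cy, cz)
  out
}

# independent permutation enumerator (distinct from the package's),
# used by the exhaustive statistical oracles
perm_list <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in perm_list(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

quiet_config <- function(...) study_config(..., log_level = "warning")
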