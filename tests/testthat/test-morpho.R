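test_that("voxel volume is count times voxel size", {
  m <- label_map(array(0L, dim = c(10, 10, 10)), spacing = c(0.2, 0.2, 0.2))
  expect_equal(voxel_volume(m), 0)
  m$data[1:10, 1:10, 1:10] <- 1L
  expect_equal(voxel_volume(m), 1000 * 0.008)
  expect_equal(voxel_volume(m$data, spacing = c(0.1, 0.2, 0.5)), 1000 * 0.01)
})

test_that("surface extraction yields closed, oriented, consistent meshes", {
  one <- label_map(array(0L, dim = c(3, 3, 3)), spacing = c(0.5, 0.5, 0.5))
  one$data[2, 2, 2] <- 1L
  mesh <- extract_surface(one)
  expect_true(is_watertight(mesh))
  expect_equal(euler_characteristic(mesh), 2L)
  v <- mesh_volume(mesh)
  expect_gt(v, 0)
  expect_lte(v, 0.5^3)

  ball <- cylinder_mask(radius = 1.2, length_mm = 2.4, h = 0.2)
  bm <- extract_surface(ball)
  expect_true(is_watertight(bm))
  expect_equal(euler_characteristic(bm), 2L)

  two <- label_map(array(0L, dim = c(7, 3, 3)), spacing = c(1, 1, 1))
  two$data[2, 2, 2] <- 1L; two$data[6, 2, 2] <- 1L
  shells <- extract_surface(two)
  expect_true(is_watertight(shells))
  expect_equal(euler_characteristic(shells), 4L) # two genus-0 shells

  expect_error(extract_surface(label_map(array(0L, dim = c(2, 2, 2)),
                                         spacing = c(1, 1, 1))),
               class = "vamorph_geometry_error")
})

test_that("mesh volume matches closed forms and is translation invariant", {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f12 <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
               c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
               c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  expect_equal(mesh_volume(trimesh(v, f12)), 1)
  expect_equal(mesh_volume(trimesh(sweep(v, 2L, c(10, -40, 7), `+`), f12)), 1,
               tolerance = 1e-12)
  expect_error(mesh_volume(trimesh(v, f12[1:11, ])),
               class = "vamorph_geometry_error")

  cyl <- cylinder_mask(radius = 1.5, length_mm = 10, h = 0.2)
  expect_equal(mesh_volume(extract_surface(cyl)), pi * 1.5^2 * 10,
               tolerance = 0.02)
  expect_equal(voxel_volume(cyl), pi * 1.5^2 * 10, tolerance = 0.03)
})

test_that("mesh and voxel volumes agree on well-resolved masks", {
  for (radius in c(0.8, 1.5)) {
    m <- cylinder_mask(radius = radius, length_mm = 6, h = 0.2)
    vv <- voxel_volume(m); mv <- mesh_volume(extract_surface(m))
    expect_lt(abs(vv - mv) / mv, 0.15)
  }
})

test_that("centerline arc length tracks the course length", {
  straight <- cylinder_mask(radius = 0.8, length_mm = 10, h = 0.2, margin = 1)
  ctr <- dim(straight$data)[2:3] / 2 * 0.2
  a <- c(1, ctr); b <- c(11, ctr)
  cl <- skeleton_centerline(straight, a, b)
  expect_equal(cl$length_mm, 10, tolerance = 0.05 * 10)

  arc <- clean_phantom_spec("uniform", c(0.8, 0.8, 0.8), length_mm = 10,
                            bend_radius_mm = 8)
  r <- rasterize_phantom(arc)
  lm <- r$ground_truth$landmarks
  va <- isolate_va(r$image, segmentation_params(), lm$seed,
                   lm$vestibule_exit, lm$operculum)
  cl2 <- skeleton_centerline(va, lm$vestibule_exit$point, lm$operculum$point)
  expect_equal(cl2$length_mm, 10, tolerance = 0.07 * 10)

  rev <- skeleton_centerline(va, lm$operculum$point, lm$vestibule_exit$point)
  expect_equal(rev$points, cl2$points[nrow(cl2$points):1, ], tolerance = 1e-12)

  disconnected <- label_map(array(0L, dim = c(9, 3, 3)), spacing = c(1, 1, 1))
  disconnected$data[1, 2, 2] <- 1L; disconnected$data[9, 2, 2] <- 1L
  expect_error(skeleton_centerline(disconnected, c(0, 1, 1), c(8, 1, 1)),
               class = "vamorph_centerline_error")
})

test_that("axial caliper width behaves per the measurement convention", {
  # generic sub-voxel position: a grid-aligned axis is the worst case for
  # midpoint-crossing digitization, not the typical one
  cyl <- cylinder_mask(radius = 1.5, length_mm = 10, h = 0.2,
                       offset = c(0.07, 0.03))
  ax <- attr(cyl, "axis_center")
  ctr <- c(6, ax[1], ax[2])
  w <- axial_width(cyl, ctr, tangent = c(1, 0, 0))
  expect_equal(w, 3, tolerance = 0.1 / 3) # within half the in-plane spacing

  expect_equal(axial_width(cyl, c(ctr[1], ctr[2] + 2.5, ctr[3]), c(1, 0, 0)), 0)
  expect_error(axial_width(cyl, ctr, tangent = c(0, 0, 1)),
               class = "vamorph_direction_error")

  # tube at 20 degrees obliquity: perpendicular width stays near 2r and below
  # the ellipse major-axis bound 2r/cos(20 deg) = 3.19
  ob <- clean_phantom_spec("uniform", c(1.5, 1.5, 1.5), tilt_deg = 20,
                           bend_radius_mm = 40)
  m <- measure_clean_phantom(ob)
  expect_lte(m$rec$midpoint_mm, 3.19)
  expect_equal(m$rec$midpoint_mm, 3, tolerance = 0.07)
})

test_that("width is robust to sub-voxel in-plane translation", {
  h <- 0.2
  ref <- NULL
  for (frac in c(0, 0.3, 0.55, 0.8)) {
    ext <- c(6, 5, 3); dm <- ceiling(ext / h) + 1L
    idx <- arrayInd(seq_len(prod(dm)), dm)
    y0 <- 2.5 + frac * h
    inside <- (idx[, 2] - 1) * h >= y0 - 1 & (idx[, 2] - 1) * h <= y0 + 1 &
      abs((idx[, 3] - 1) * h - 1.4) <= 0.41
    m <- label_map(array(as.integer(inside), dim = dm), spacing = rep(h, 3))
    w <- axial_width(m, c(3, y0, 1.4), tangent = c(1, 0, 0))
    if (is.null(ref)) ref <- w
    expect_equal(w, ref, tolerance = (h / 2) / ref)
  }
})

test_that("measured diameters recover the analytic truth across shapes", {
  shapes <- list(list("uniform", c(1.5, 1.5, 1.5)),
                 list("central_dilatation", c(0.4, 1.6, 0.5)),
                 list("funnel", c(0.25, 0.5, 1.0)),
                 list("funnel", c(0.25, 0.8, 1.7)),
                 list("funnel", c(1.0, 1.6, 2.1)))
  for (sh in shapes) {
    m <- measure_clean_phantom(clean_phantom_spec(sh[[1]], sh[[2]]))
    tm <- 2 * sh[[2]][2]; to <- 2 * sh[[2]][3]
    expect_lte(abs(m$rec$midpoint_mm - tm), 0.1 + 0.05 * tm,
               label = sprintf("%s midpoint", paste(sh[[2]], collapse = "/")))
    expect_lte(abs(m$rec$operculum_mm - to), 0.1 + 0.05 * to,
               label = sprintf("%s operculum", paste(sh[[2]], collapse = "/")))
  }
})

test_that("central-dilatation morphometry matches its construction", {
  m <- measure_clean_phantom(clean_phantom_spec("central_dilatation",
                                                c(0.4, 1.6, 0.5)))
  expect_equal(m$rec$midpoint_mm, 3.2, tolerance = 0.2 / 3.2)
  expect_equal(m$rec$operculum_mm, 1.0, tolerance = 0.2 / 1.0)
  expect_equal(m$rec$mesh_volume_mm3, m$rast$ground_truth$volume_mm3,
               tolerance = 0.05)
  expect_equal(m$rec$flags, "")
})

test_that("under-resolved ducts are flagged rather than silently returned", {
  m <- measure_clean_phantom(clean_phantom_spec("uniform", c(0.3, 0.3, 0.3),
                                                spacing = 0.4))
  expect_true(nzchar(m$rec$flags))
})
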