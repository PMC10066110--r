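hu_cube <- function(vals, spacing = c(1, 1, 1)) {
  voxel_image(array(vals, dim = c(length(vals), 1, 1)), spacing = spacing)
}

test_that("threshold band is inclusive at both ends and monotone", {
  img <- hu_cube(c(-2000, -1024, 30, 700, 700.5, 1800))
  m <- threshold_mask(img)
  expect_equal(as.vector(m$data), c(0L, 1L, 1L, 1L, 0L, 0L))
  wide <- threshold_mask(img, segmentation_params(-2048, 800))
  expect_true(all(wide$data >= m$data))
})

test_that("connected components order labels by size and honour connectivity", {
  a <- array(0L, dim = c(7, 7, 3))
  a[1:2, 1:2, 1] <- 1L        # 4 voxels
  a[5:7, 5:7, 1:3] <- 1L      # 27 voxels
  m <- label_map(a, spacing = c(1, 1, 1))
  lab <- connected_components(m)
  expect_equal(attr(lab, "counts"), c(27L, 4L))
  expect_equal(lab$data[6, 6, 2], 1L)
  expect_equal(lab$data[1, 1, 1], 2L)

  empty <- connected_components(label_map(array(0L, dim = c(3, 3, 3)),
                                          spacing = c(1, 1, 1)))
  expect_length(attr(empty, "counts"), 0L)

  diag2 <- array(0L, dim = c(3, 3, 3))
  diag2[1, 1, 1] <- 1L; diag2[2, 2, 2] <- 1L
  dm <- label_map(diag2, spacing = c(1, 1, 1))
  expect_length(attr(connected_components(dm, 26L), "counts"), 1L)
  expect_length(attr(connected_components(dm, 6L), "counts"), 2L)
})

test_that("seeded selection picks the right component with documented tie-break", {
  a <- array(0L, dim = c(9, 3, 3))
  a[1:3, 1, 1] <- 1L
  a[7:9, 3, 3] <- 1L
  m <- label_map(a, spacing = c(1, 1, 1))
  lab <- connected_components(m)
  sel <- select_seeded_component(lab, c(7, 2, 2))
  expect_equal(which(sel$data != 0L), which(a != 0L & seq_along(a) > 27))
  err <- tryCatch(select_seeded_component(lab, c(4, 0, 0)),
                  vamorph_seed_error = identity)
  expect_s3_class(err, "vamorph_seed_error")
  expect_match(conditionMessage(err), "mm away")
  expect_error(select_seeded_component(lab, c(90, 0, 0)),
               class = "vamorph_domain_error")
})

test_that("plane clipping partitions a mask and halves a cylinder", {
  cyl <- cylinder_mask(radius = 1.5, length_mm = 10, h = 0.2)
  expect_identical(clip_by_planes(cyl, list())$data, cyl$data)

  ctr <- colMeans(index_to_world(cyl, arrayInd(which(cyl$data != 0L),
                                               dim(cyl$data))))
  ctr[1] <- ctr[1] + 0.01 # off-lattice so no voxel center sits on the plane
  p1 <- cut_plane(ctr, c(1, 0, 0))
  p2 <- cut_plane(ctr, c(-1, 0, 0))
  a <- clip_by_planes(cyl, list(p1))
  b <- clip_by_planes(cyl, list(p2))
  expect_equal(sum(a$data) + sum(b$data), sum(cyl$data))
  expect_equal(sum(a$data & b$data), 0)
  # half cylinder within one slice's worth of voxels
  slice_voxels <- sum(cyl$data[abs((seq_len(dim(cyl$data)[1]) - 1) * 0.2 - ctr[1]) < 0.1, , ])
  expect_lte(abs(sum(a$data) - sum(cyl$data) / 2), slice_voxels + 1)
  # clipping with more planes never grows the mask
  expect_lte(sum(clip_by_planes(cyl, list(p1, cut_plane(ctr, c(0, 1, 0))))$data),
             sum(a$data))
})

test_that("isolate_va recovers the phantom lumen and excludes the vestibule", {
  sp <- clean_phantom_spec("uniform", c(0.8, 0.8, 0.8))
  r <- rasterize_phantom(sp)
  lm <- r$ground_truth$landmarks
  va <- isolate_va(r$image, segmentation_params(), lm$seed,
                   lm$vestibule_exit, lm$operculum)
  expect_equal(voxel_volume(va), r$ground_truth$volume_mm3, tolerance = 0.05)

  # all kept voxels on the VA side of the exit plane (signed distance <= 0)
  W <- index_to_world(va, arrayInd(which(va$data != 0L), dim(va$data)))
  sd <- sweep(W, 2L, lm$vestibule_exit$point) %*% lm$vestibule_exit$normal
  expect_true(all(sd <= 1e-9))

  # seeding inside the vestibule still segments, and clipping removes it
  vest_seed <- lm$vestibule_exit$point + 1.2 * lm$vestibule_exit$normal
  va2 <- isolate_va(r$image, segmentation_params(), vest_seed,
                    lm$vestibule_exit, lm$operculum)
  expect_identical(va2$data, va$data)
})

test_that("isolate_va is idempotent on its own output", {
  sp <- clean_phantom_spec("funnel", c(0.4, 0.8, 1.2))
  r <- rasterize_phantom(sp)
  lm <- r$ground_truth$landmarks
  va <- isolate_va(r$image, segmentation_params(), lm$seed,
                   lm$vestibule_exit, lm$operculum)
  as_img <- voxel_image(array(ifelse(va$data != 0L, 30, 1370), dim(va$data)),
                        spacing = va$spacing, origin = va$origin)
  va2 <- isolate_va(as_img, segmentation_params(), lm$seed,
                    lm$vestibule_exit, lm$operculum)
  expect_identical(va2$data, va$data)
})

test_that("defaults match the clinical protocol and failures are explicit", {
  p <- segmentation_params()
  expect_equal(p$hu_lower, -1024)
  expect_equal(p$hu_upper, 700)
  expect_equal(p$connectivity, 26L)
  expect_error(segmentation_params(700, -1024), class = "vamorph_parameter_error")

  sp <- clean_phantom_spec()
  r <- rasterize_phantom(sp)
  lm <- r$ground_truth$landmarks
  expect_error(
    isolate_va(r$image, segmentation_params(2000, 3000), lm$seed,
               lm$vestibule_exit, lm$operculum),
    class = "vamorph_seed_error")
})
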