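test_that("rasterization digitizes a known solid accurately", {
  sp <- clean_phantom_spec("uniform", c(1.5, 1.5, 1.5), spacing = 0.2)
  r <- rasterize_phantom(sp)
  vol <- sum(r$truth$data) * prod(sp$spacing_mm)
  expect_equal(vol, pi * 1.5^2 * 10, tolerance = 0.03)
  expect_equal(r$ground_truth$volume_mm3, pi * 1.5^2 * 10, tolerance = 1e-6)
  expect_equal(r$ground_truth$midpoint_diameter_mm, 3)
  expect_equal(r$ground_truth$operculum_diameter_mm, 3)
})

test_that("truth-lumen voxels fall inside the clinical threshold band", {
  # HU defaults place 700 HU at the fluid/bone half-maximum, so VA-lumen
  # voxels (coverage > 0.5) are strictly below it before noise
  sp <- clean_phantom_spec("funnel", c(0.3, 0.6, 1.0))
  r <- rasterize_phantom(sp)
  expect_true(all(r$image$data[r$truth$data == 1L] < 700))
  expect_true(all(r$image$data <= sp$hu_bone + 1e-9))
  expect_true(all(r$image$data >= sp$hu_fluid - 1e-9))
})

test_that("identical specs and seeds give bit-identical noisy images", {
  sp <- phantom_spec(build_radius_profile("uniform", 1, 1, 1),
                     spacing_mm = c(0.3, 0.3, 0.625), blur_sigma_mm = 0.3,
                     noise_sd_hu = 40, seed = 77L)
  a <- rasterize_phantom(sp)
  b <- rasterize_phantom(sp)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$data, b$truth$data)
  sp2 <- phantom_spec(build_radius_profile("uniform", 1, 1, 1),
                      spacing_mm = c(0.3, 0.3, 0.625), blur_sigma_mm = 0.3,
                      noise_sd_hu = 40, seed = 78L)
  expect_false(identical(rasterize_phantom(sp2)$image$data, a$image$data))
})

test_that("truth volume converges to the analytic volume as spacing halves", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    sp <- clean_phantom_spec("funnel", c(0.4, 0.7, 1.1), length_mm = 6,
                             spacing = h, vestibule = NULL)
    r <- rasterize_phantom(sp)
    abs(sum(r$truth$data) * h^3 - r$ground_truth$volume_mm3) /
      r$ground_truth$volume_mm3
  }, numeric(1))
  expect_lt(errs[2], errs[1] * 1.1)
  expect_lt(errs[3], errs[2] * 1.1)
  expect_lt(errs[3], 0.02)
})

test_that("truth-lumen count is self-consistent across archetypes at 0.2 mm", {
  shapes <- list(uniform = c(0.8, 0.8, 0.8),
                 central_dilatation = c(0.4, 1.6, 0.5),
                 funnel = c(0.3, 0.6, 1.2))
  for (nm in names(shapes)) {
    sp <- clean_phantom_spec(nm, shapes[[nm]])
    r <- rasterize_phantom(sp)
    vol <- sum(r$truth$data) * prod(sp$spacing_mm)
    expect_equal(vol, r$ground_truth$volume_mm3, tolerance = 0.05,
                 label = sprintf("%s truth volume", nm))
  }
})

test_that("a tube escaping a requested extent raises a domain error", {
  expect_error(
    rasterize_phantom(clean_phantom_spec(extent_mm = c(4, 4, 4))),
    class = "vamorph_domain_error")
})

test_that("rater perturbation respects its bounds and determinism", {
  sp <- clean_phantom_spec()
  lm <- rasterize_phantom(sp)$ground_truth$landmarks
  same <- perturb_for_rater(lm, rater_jitter(0, 0, 0L), seed = 3L)
  expect_equal(same$seed, lm$seed)
  expect_equal(same$operculum$point, lm$operculum$point)
  expect_equal(same$measurement$midpoint$angle_deg, 0)

  for (s in 1:20) {
    p <- perturb_for_rater(lm, rater_jitter(0.3, 10, 1L), seed = s)
    expect_lte(sqrt(sum((p$seed - lm$seed)^2)), 0.3)
    expect_lte(abs(p$measurement$operculum$angle_deg), 10)
    expect_true(p$measurement$midpoint$slice_offset %in% -1:1)
  }
  a <- perturb_for_rater(lm, rater_jitter(), seed = 5L)
  b <- perturb_for_rater(lm, rater_jitter(), seed = 5L)
  c2 <- perturb_for_rater(lm, rater_jitter(), seed = 6L)
  expect_identical(a, b)
  expect_false(identical(a$seed, c2$seed))
})

test_that("cohort sampling is deterministic and honours group sizes", {
  co <- cohort_spec(n = c(control = 4L, CH = 0L, IPI = 2L, IPII = 0L, EVAS = 3L),
                    seed = 9L)
  m1 <- sample_cohort(co)
  m2 <- sample_cohort(co)
  expect_identical(m1, m2)
  expect_equal(as.vector(table(factor(m1$group, c("control", "IPI", "EVAS")))),
               c(4L, 2L, 3L))
  expect_false("CH" %in% m1$group)
  # truncation: draws stay within the published per-group ranges
  tg <- diameter_targets()
  for (g in unique(m1$group)) {
    row <- tg[tg$group == g & tg$site == "operculum", ]
    expect_true(all(m1$truth_operculum_mm[m1$group == g] <= row$max + 1e-9))
    expect_true(all(m1$truth_operculum_mm[m1$group == g] >=
                      max(row$min, 0.05) - 1e-9))
  }
})

test_that("the calibrated truncated distributions hit the published medians", {
  co <- cohort_spec()
  tg <- diameter_targets()
  for (i in seq_len(nrow(tg))) {
    pp <- vamorph:::cohort_site_params(co, tg$group[i], tg$site[i])
    med <- vamorph:::tlnorm_quantile(0.5, pp$mu, pp$sdlog, pp$lo, pp$hi)
    expect_equal(med, tg$median[i], tolerance = 1e-6,
                 label = sprintf("%s %s median", tg$group[i], tg$site[i]))
  }
})
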