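test_that("degenerate and analytic leaf shapes give exact pixel counts", {
  sp0 <- scene_spec(leaf_shape = list(type = "ellipse",
                                      center_px = c(240, 240),
                                      semi_axes_px = c(0, 0),
                                      rotation_deg = 0))
  expect_identical(render_scene(sp0)$truth$leaf_area_px, 0L)

  spr <- scene_spec(leaf_shape = list(type = "rectangle",
                                      center_px = c(240, 240),
                                      semi_axes_px = c(20, 25)))
  expect_identical(render_scene(spr)$truth$leaf_area_px, 2000L)
})

test_that("ellipse pixel count matches a brute-force rasterization oracle", {
  sp <- scene_spec(leaf_shape = list(type = "ellipse",
                                     center_px = c(200, 260),
                                     semi_axes_px = c(60, 30),
                                     rotation_deg = 0))
  got <- render_scene(sp)$truth$leaf_area_px
  brute <- 0L
  for (i in seq_len(480)) for (j in seq_len(480)) {
    dy <- i - 0.5 - 200; dx <- j - 0.5 - 260
    if ((dy / 60)^2 + (dx / 30)^2 <= 1) brute <- brute + 1L
  }
  expect_identical(got, brute)
})

test_that("rendered physical area tracks the analytic shape area", {
  for (sp in scene_battery(6)) {
    tr <- render_scene(sp)$truth
    expect_gte(tr$leaf_area_px, 1000)
    sa <- sp$leaf_shape$semi_axes_px
    analytic_px <- switch(sp$leaf_shape$type,
      rectangle = 4 * sa[1] * sa[2],
      ellipse = pi * sa[1] * sa[2],
      superellipse = {
        p <- sp$leaf_shape$exponent
        4 * sa[1] * sa[2] * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)
      })
    analytic_cm2 <- analytic_px * sp$board_square_size_cm^2 /
      sp$board_square_size_px^2
    expect_lt(abs(tr$leaf_area_cm2 - analytic_cm2) / analytic_cm2, 0.02)
    # internal consistency of the ground-truth record
    expect_equal(tr$leaf_area_cm2,
                 tr$leaf_area_px * tr$board_square_size_cm^2 /
                   tr$square_pixel_area)
    expect_identical(tr$leaf_area_px, sum(tr$leaf_mask))
  }
})

test_that("rendering is bit-identical under the same seed and differs across seeds", {
  a <- render_scene(scene_spec(seed = 7))
  b <- render_scene(scene_spec(seed = 7))
  c <- render_scene(scene_spec(seed = 8))
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$image, c$image))
})

test_that("a leaf reaching the image border is rejected", {
  sp <- scene_spec(leaf_shape = list(type = "ellipse",
                                     center_px = c(240, 240),
                                     semi_axes_px = c(300, 100),
                                     rotation_deg = 0))
  expect_error(render_scene(sp), "extends beyond")
})

test_that("noiseless sample at a bump center returns the clipped amplitude", {
  surf <- list(list(center = c(25, 130, 300), amplitude = 10.4, width = 0.5))
  sp <- sim_spec(1, "growing", surface = surf, noise_sd_gkg = 0, seed = 1)
  x <- matrix(c(25, 130, 300), 1)
  expect_equal(eval_surface(sp, x), 10.4)
  # amplitude outside the stage range is clipped on simulation output
  surf2 <- list(list(center = c(25, 130, 300), amplitude = 14, width = 0.5))
  sp2 <- sim_spec(2000, "growing", surface = surf2, noise_sd_gkg = 0,
                  seed = 2)
  d <- simulate_dataset(sp2)
  expect_true(all(d$nitrogen_gkg <= 11 & d$nitrogen_gkg >= 9))
})

test_that("simulation is deterministic and respects the stage ranges", {
  a <- simulate_dataset(sim_spec(50, "mature", seed = 3))
  b <- simulate_dataset(sim_spec(50, "mature", seed = 3))
  expect_identical(a, b)
  expect_true(all(a$nitrogen_gkg >= 15 & a$nitrogen_gkg <= 19))
  g <- simulate_dataset(sim_spec(50, "growing", seed = 3))
  expect_true(all(g$nitrogen_gkg >= 9 & g$nitrogen_gkg <= 11))
  expect_false(identical(g$nitrogen_gkg,
                         simulate_dataset(sim_spec(50, "growing",
                                                   seed = 4))$nitrogen_gkg))
})

test_that("generator noise matches its nominal SD at large n", {
  sp <- sim_spec(10000, "growing", noise_sd_gkg = 0.2, seed = 11)
  d <- simulate_dataset(sp)
  resid <- attr(d, "nitrogen_preclip") - attr(d, "nitrogen_surface")
  expect_gte(sd(resid), 0.19)
  expect_lte(sd(resid), 0.21)
})

test_that("an empty bump set is rejected", {
  expect_error(sim_spec(10, "growing", surface = list()), "bump")
})

test_that("scene files round-trip through PNG and JSON sidecar", {
  sc <- render_scene(scene_spec(seed = 21))
  stem <- file.path(withr::local_tempdir(), "scene")
  write_scene(sc, stem)
  img <- read_image(paste0(stem, ".png"))
  expect_identical(img, sc$image)
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(side$leaf_area_px, sc$truth$leaf_area_px)
  expect_equal(side$leaf_area_cm2, sc$truth$leaf_area_cm2)
})
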