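test_that("factor levels map to scene optics as declared", {
  sc <- generate_scene("aligned", "transmission", shape = c(16, 16), seed = 1,
                       transmission_level = 0.33)
  ctrl <- generate_scene("aligned", "transmission", shape = c(16, 16), seed = 1)
  # absorber level is the Beer-Lambert outcome: 33% of control transmissivity
  expect_equal(sc$maps$transmissivity, 0.33 * ctrl$maps$transmissivity / 1.0)
  expect_error(generate_scene("aligned", "transmission", shape = c(16, 16),
                              seed = 1, collagen_density = 2.2),
               "collagen_density")
  expect_error(generate_scene("aligned", "transmission", shape = c(16, 16),
                              seed = 1, transmission_level = 0.5),
               "transmission_level")
})

test_that("degenerate concentration and determinism contracts hold", {
  sc <- generate_scene("aligned", "transmission", shape = c(16, 16), seed = 2,
                       kappa = 1e6, mu_deg = 35)
  expect_true(all(sc$maps$fiber_axis_deg == 35))
  a <- generate_scene("aligned", "transmission", shape = c(16, 16), seed = 3)
  b <- generate_scene("aligned", "transmission", shape = c(16, 16), seed = 3)
  d <- generate_scene("aligned", "transmission", shape = c(16, 16), seed = 4)
  expect_identical(a$maps, b$maps)
  expect_false(identical(a$maps$fiber_axis_deg, d$maps$fiber_axis_deg))
})

test_that("noise-free render is exact Malus sampling", {
  # unpolarized uniform scene: every analyzer sees S0/2
  sc <- generate_scene("aligned", "transmission", shape = c(8, 8), seed = 1,
                       retardance_rad = 0, depol_linear = 0,
                       base_intensity = 1, transmission_level = 1,
                       control_transmissivity = 1)
  m <- render_mosaic(sc, noise = FALSE)
  expect_equal(m$pixels, matrix(0.5, 8, 8))

  # closed-form Malus values for S0 = 1, DoLP = 0.5, AoP = 30 deg
  s1 <- 0.5 * cos(deg2rad(60)); s2 <- 0.5 * sin(deg2rad(60))
  io <- 0.5 * (1 + s1); i45 <- 0.5 * (1 + s2)
  i90 <- 0.5 * (1 - s1); i135 <- 0.5 * (1 - s2)
  expect_equal(round(c(io, i45, i90, i135), 6),
               c(0.625, 0.716506, 0.375, 0.283494))
})

test_that("vectorized scene rendering matches element-wise Mueller propagation", {
  for (mode in c("transmission", "reflectance")) {
    sc <- generate_scene("disorganized", mode, shape = c(8, 8), seed = 5)
    s <- scene_stokes(sc, "left")
    for (px in list(c(1, 1), c(3, 6), c(8, 8))) {
      ch <- pixel_chain(sc, px[1], px[2], "left")
      ref <- unclass(propagate(ch$input_state, ch))
      got <- c(s$S0[px[1], px[2]], s$S1[px[1], px[2]],
               s$S2[px[1], px[2]], s$S3[px[1], px[2]])
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("switching input handedness shifts the recovered AoP map by 90 deg", {
  sc <- uniform_scene(shape = c(32, 32))
  ar <- pipeline_stokes(sc, "right")$AoP
  al <- pipeline_stokes(sc, "left")$AoP
  expect_true(all(abs(aop_circular_difference(ar, al) - 90) < 1e-9))
})

test_that("rendered mosaics are deterministic per seed and noise is seeded", {
  sc <- generate_scene("aligned", "transmission", shape = c(16, 16), seed = 1)
  m1 <- render_mosaic(sc, noise = TRUE, seed = 8)
  m2 <- render_mosaic(sc, noise = TRUE, seed = 8)
  m3 <- render_mosaic(sc, noise = TRUE, seed = 9)
  expect_identical(m1$pixels, m2$pixels)
  expect_false(identical(m1$pixels, m3$pixels))
  expect_error(render_mosaic(sc, noise = TRUE), "seed")
  expect_error(render_mosaic(sc, input_handedness = "up"), "right")
})

test_that("stronger depolarization strictly lowers recovered AVG DoLP", {
  d_levels <- c(0.9, 0.7, 0.5, 0.3)
  avg <- vapply(d_levels, function(d) {
    sc <- generate_scene("aligned", "transmission", shape = c(32, 32),
                         seed = 2, depol_linear = d)
    avg_dolp(pipeline_stokes(sc, method = "superpixel"))
  }, numeric(1))
  expect_true(all(diff(avg) < 0))
})

test_that("aligned scenes beat disorganized in AVG DoLP and lose in STD AoP", {
  sa <- pipeline_stokes(generate_scene("aligned", "transmission",
                                       shape = c(32, 32), seed = 6))
  sd_ <- pipeline_stokes(generate_scene("disorganized", "transmission",
                                        shape = c(32, 32), seed = 6))
  expect_gt(avg_dolp(sa), avg_dolp(sd_))
  expect_gt(std_aop(sd_), std_aop(sa))
})

test_that("axial von Mises sampler hits its degenerate and uniform limits", {
  a <- with(list(), {set.seed(1); rvonmises_axial(50, 15, 1e6)})
  expect_true(all(a == 15))
  # kappa = 0: chi-square GOF against uniform on 18 bins
  set.seed(11)
  x <- rvonmises_axial(5000, 0, 0)
  expect_true(all(x >= -90 & x < 90))
  counts <- table(cut(x, breaks = seq(-90, 90, by = 10)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
  # concentrated draws cluster around mu
  set.seed(12)
  y <- rvonmises_axial(2000, 30, 8)
  expect_lt(aop_circular_difference(axial_mean(y), 30), 2)
})

test_that("fiber textures are reproducible and respect their orientation law", {
  t1 <- generate_fiber_texture(kappa = 2, mu_deg = 10, n_fibers = 50,
                               shape = c(64, 64), seed = 3)
  t2 <- generate_fiber_texture(kappa = 2, mu_deg = 10, n_fibers = 50,
                               shape = c(64, 64), seed = 3)
  expect_identical(unclass(t1), unclass(t2))
  tall <- generate_fiber_texture(kappa = 1e6, mu_deg = 40, n_fibers = 30,
                                 shape = c(64, 64), seed = 4)
  expect_true(all(attr(tall, "angles_deg") == 40))
  set.seed(13)
  t0 <- generate_fiber_texture(kappa = 0, mu_deg = 0, n_fibers = 5000,
                               shape = c(64, 64), seed = 5)
  counts <- table(cut(attr(t0, "angles_deg"), breaks = seq(-90, 90, by = 10)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})
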