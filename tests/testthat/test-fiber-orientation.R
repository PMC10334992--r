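test_that("CED filter identity and constant-image behaviour", {
  img <- generate_fiber_texture(kappa = 2, mu_deg = 0, n_fibers = 40,
                                shape = c(64, 64), seed = 1)
  expect_identical(ced_filter(img, n_iter = 0), img)
  const <- matrix(0.4, 64, 64)
  expect_equal(ced_filter(const, n_iter = 10), const, tolerance = 1e-12)
  expect_error(ced_filter(img, step = 0.3), "0.25")
})

test_that("CED smooths while preserving the dominant fiber orientation", {
  img <- generate_fiber_texture(kappa = 1e6, mu_deg = 30, n_fibers = 60,
                                shape = c(96, 96), seed = 5)
  f <- ced_filter(img, n_iter = 20)
  expect_lt(stats::var(as.vector(f)), stats::var(as.vector(img)))
  d0 <- orientation_distribution_fft(img)
  d1 <- orientation_distribution_fft(f)
  peak0 <- d0$angles_deg[which.max(d0$weights)]
  peak1 <- d1$angles_deg[which.max(d1$weights)]
  bw <- 180 / d1$n_bins
  expect_lte(aop_circular_difference(peak1, 30), bw)
  expect_lte(aop_circular_difference(peak1, peak0), bw)
})

test_that("FFT orientation distribution localizes stripes and is normalized", {
  # analytic stripe pattern oriented at 30 degrees (y-up convention)
  h <- 128; w <- 128; th <- deg2rad(30)
  x <- matrix(1:w, h, w, byrow = TRUE); y <- matrix(-(1:h), h, w)
  img <- 0.5 + 0.5 * cos(2 * pi * 0.15 * (-sin(th) * x + cos(th) * y))
  d <- orientation_distribution_fft(img)
  expect_equal(sum(d$weights), 1, tolerance = 1e-9)
  expect_true(all(d$weights >= 0))
  peak <- d$angles_deg[which.max(d$weights)]
  expect_lte(aop_circular_difference(peak, 30), 180 / d$n_bins)
  expect_error(orientation_distribution_fft(matrix(0.3, 128, 128)),
               "degenerate")
  expect_error(orientation_distribution_fft(img[1:32, 1:32]), "64")
})

test_that("white-noise images give a near-flat orientation distribution", {
  # noise has no edge discontinuity to suppress, so no window is applied
  ratios <- vapply(1:10, function(s) {
    img <- with_seed_local(s, matrix(stats::runif(256 * 256), 256, 256))
    d <- orientation_distribution_fft(img, n_bins = 90, window = "none")
    max(d$weights) / min(d$weights)
  }, numeric(1))
  expect_lt(mean(ratios), 1.5)
})

test_that("orientation distribution shifts with the texture's mean axis", {
  peak_of <- function(mu) {
    img <- generate_fiber_texture(kappa = 1e6, mu_deg = mu, n_fibers = 80,
                                  shape = c(128, 128), seed = 9)
    d <- orientation_distribution_fft(img)
    d$angles_deg[which.max(d$weights)]
  }
  bw <- 2  # 90 bins over 180 degrees
  p0 <- peak_of(0); p15 <- peak_of(15); p60 <- peak_of(60)
  expect_lte(aop_circular_difference(p15, p0 + 15), bw)
  expect_lte(aop_circular_difference(p60, p0 + 60), bw)
})

test_that("von Mises fit recovers parameters from exact tabulated densities", {
  th <- -90 + (1:90 - 0.5) * 2
  w <- exp(2 * cos(2 * deg2rad(th - 10)))
  dist <- structure(list(angles_deg = th, weights = w / sum(w), n_bins = 90,
                         radial_band = c(0.1, 0.8)),
                    class = "orientation_distribution")
  f <- fit_von_mises(dist)
  expect_true(f$converged)
  expect_gte(f$k, 1.9); expect_lte(f$k, 2.1)
  expect_gte(f$mu_deg, 9); expect_lte(f$mu_deg, 11)

  # flat distribution: isotropy
  flat <- structure(list(angles_deg = th, weights = rep(1 / 90, 90),
                         n_bins = 90, radial_band = c(0.1, 0.8)),
                    class = "orientation_distribution")
  f0 <- fit_von_mises(flat)
  expect_lt(f0$k, 0.05)
  # uniform axial SD limit: 180/sqrt(12) deg, within 2%
  expect_lt(abs(f0$sigma_deg - 51.96) / 51.96, 0.02)
})

test_that("sigma decreases as k increases and tracks the circular SD when tight", {
  ks <- c(0, 0.5, 1, 2, 4, 10, 40)
  sig <- vapply(ks, qpli:::vm_window_sd_deg, numeric(1))
  expect_true(all(diff(sig) < 0))
  expect_true(all(sig > 0 & sig <= 51.97))
  # convergence to the axial circular SD at high concentration
  circ40 <- 0.5 * sqrt(-2 * log(besselI(40, 1, TRUE) / besselI(40, 0, TRUE))) * 180 / pi
  expect_lt(abs(sig[length(sig)] - circ40) / circ40, 0.01)
})

test_that("texture-to-fit chain discriminates aligned from disorganized", {
  for (s in 1:5) {
    ta <- generate_fiber_texture(kappa = 2, mu_deg = 0, n_fibers = 300,
                                 shape = c(128, 128), seed = s)
    td <- generate_fiber_texture(kappa = 0.05, mu_deg = 0, n_fibers = 300,
                                 shape = c(128, 128), seed = s + 100)
    fa <- fit_von_mises(orientation_distribution_fft(ta))
    fd <- fit_von_mises(orientation_distribution_fft(td))
    expect_gt(fa$k, fd$k)
    expect_gt(fd$sigma_deg, fa$sigma_deg)
  }
})

test_that("fiber_metrics averages the per-slice fits", {
  slices <- lapply(1:3, function(s) {
    generate_fiber_texture(kappa = 4, mu_deg = 20, n_fibers = 200,
                           shape = c(96, 96), seed = s)
  })
  fm <- fiber_metrics(slices, ced = FALSE)
  expect_equal(nrow(fm$per_slice), 3)
  expect_equal(fm$mean_k, mean(fm$per_slice$k))
  expect_equal(fm$mean_sigma_deg, mean(fm$per_slice$sigma_deg))
})
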