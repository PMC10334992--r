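test_that("standard element matrices act correctly on known states", {
  # full depolarizer erases all polarization
  d <- make_element("depolarizer", depol_linear = 0, depol_circular = 0)
  expect_equal(drop(d$matrix %*% c(1, 0.3, 0.4, 0.5)), c(1, 0, 0, 0))

  # mirror flips helicity: only S3 changes sign on a circular-pure state
  m <- make_element("mirror")
  expect_equal(drop(m$matrix %*% c(1, 0, 0, 1)), c(1, 0, 0, -1))

  # quarter-wave retarder at 20 deg on right circular light:
  # closed-form column entries (-sin 2t sin d, cos 2t sin d, cos d)
  r <- make_element("retarder", fast_axis_deg = 20, retardance_rad = pi / 2)
  out <- drop(r$matrix %*% c(1, 0, 0, 1))
  expect_equal(out, c(1, -sin(deg2rad(40)), cos(deg2rad(40)), 0),
               tolerance = 1e-12)
  expect_equal(round(out, 4), c(1, -0.6428, 0.7660, 0))
})

test_that("element parameter validation names the offending field", {
  expect_error(make_element("retarder", retardance_rad = 7), "retardance_rad")
  expect_error(make_element("depolarizer", depol_linear = 1.2), "depol_linear")
  expect_error(make_element("attenuator", transmissivity = -0.1),
               "transmissivity")
})

test_that("propagate composes chains in optical order", {
  idch <- mode_chain("transmission",
                     list(make_element("attenuator", transmissivity = 1)))
  s <- stokes_vector(1, 0.2, 0, 0)
  expect_equal(unclass(propagate(s, idch)), c(1, 0.2, 0, 0))

  ret <- make_element("retarder", fast_axis_deg = 20, retardance_rad = pi / 2)
  t_out <- propagate(circular_state("right"),
                     mode_chain("transmission", list(ret)))
  expect_equal(aop(t_out), 65, tolerance = 1e-10)  # fast axis + 45 for sin d > 0

  r_out <- propagate(circular_state("right"),
                     mode_chain("reflectance", list(make_element("mirror"), ret)))
  expect_equal(aop(r_out), -25, tolerance = 1e-10)
  expect_equal(aop_circular_difference(aop(t_out), aop(r_out)), 90,
               tolerance = 1e-10)
})

test_that("propagate rejects non-physical input", {
  expect_error(propagate(stokes_vector(1, 1, 1, 1), list(make_element("mirror"))),
               "not physical")
})

test_that("axial circular difference follows the 180-degree metric", {
  expect_equal(aop_circular_difference(65, -25), 90)
  expect_equal(aop_circular_difference(10, 10), 0)
  expect_equal(aop_circular_difference(89, -89), 2)
  # brute-force oracle over branch shifts on random pairs
  set.seed(42)
  for (i in 1:200) {
    a <- runif(1, -360, 360); b <- runif(1, -360, 360)
    brute <- min(abs(a - b + 180 * (-4:4)))
    expect_equal(aop_circular_difference(a, b), brute, tolerance = 1e-9)
  }
})

test_that("retarder preserves degree of polarization; mirror is an involution", {
  expect_equal(make_element("mirror")$matrix %*% make_element("mirror")$matrix,
               diag(4))
  set.seed(7)
  for (i in 1:200) {
    s <- random_physical_state()
    r <- make_element("retarder", fast_axis_deg = runif(1, 0, 180),
                      retardance_rad = runif(1, 0, 2 * pi - 1e-9))
    out <- unclass(propagate(s, list(r)))
    sv <- unclass(s)
    expect_equal(out[1], sv[1], tolerance = 1e-12)
    expect_equal(sqrt(sum(out[2:4]^2)) / out[1],
                 sqrt(sum(sv[2:4]^2)) / sv[1], tolerance = 1e-12)
  }
})

test_that("mirror prepension shifts AoP by exactly 90 degrees for any retarder", {
  # sweep fast axis over [0, 180); retardance in (0, pi)
  for (theta in seq(0, 179, by = 7.3)) {
    for (delta in c(0.3, pi / 2, 2.8)) {
      ret <- make_element("retarder", fast_axis_deg = theta,
                          retardance_rad = delta)
      a_t <- aop(propagate(circular_state("right"),
                           mode_chain("transmission", list(ret))))
      a_r <- aop(propagate(circular_state("right"),
                           mode_chain("reflectance",
                                      list(make_element("mirror"), ret))))
      expect_equal(aop_circular_difference(a_t, a_r), 90, tolerance = 1e-9)
      # switching handedness is the same 90-degree shift
      a_l <- aop(propagate(circular_state("left"),
                           mode_chain("transmission", list(ret))))
      expect_equal(aop_circular_difference(a_t, a_l), 90, tolerance = 1e-9)
    }
  }
})

test_that("chain serialization round-trips through a config list", {
  ch <- mode_chain("reflectance", list(
    make_element("mirror"),
    make_element("retarder", fast_axis_deg = 12, retardance_rad = 1.1),
    make_element("depolarizer", depol_linear = 0.4, depol_circular = 0.3)
  ), circular_state("left"))
  ch2 <- chain_from_config(chain_to_config(ch))
  expect_equal(ch2$mode, "reflectance")
  expect_equal(unclass(ch2$input_state), unclass(ch$input_state))
  for (i in seq_along(ch$elements)) {
    expect_equal(ch2$elements[[i]]$matrix, ch$elements[[i]]$matrix)
  }
})

test_that("chain mode constraints are enforced", {
  ret <- make_element("retarder", fast_axis_deg = 0, retardance_rad = 1)
  expect_error(mode_chain("reflectance", list(ret)), "mirror")
  expect_error(mode_chain("transmission",
                          list(make_element("mirror"), ret)), "mirror")
  expect_error(mode_chain("transmission", list()), "non-empty")
})
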