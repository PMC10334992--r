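#' Generate a collagen-phantom-like scene for the forward simulator
#'
#' Builds per-pixel optical-property maps emulating the collagen gel phantoms
#' used to characterize division-of-focal-plane Stokes polarimetry: an
#' `aligned` phantom has a concentrated axial fiber-orientation field, a
#' `disorganized` phantom a near-uniform one. Factor levels map to optics as:
#'
#' * collagen density (mg/mL) sets per-pixel retardance
#'   `retardance_rad = c_ret * density * thickness_factor` (more birefringent
#'   material in the optical path), plus a mild extra depolarization
#'   (more scatterers);
#' * riboflavin-mediated crosslinking (mM) scales retardance by
#'   `1 + 0.2 * mM`;
#' * absorber density is expressed as its Beer-Lambert outcome: the
#'   `transmission_level` fraction (1.0, 0.67 or 0.33 of control
#'   transmission) multiplies the control transmissivity directly;
#' * reflectance mode multiplies the linear/circular depolarization retention
#'   by `depol_reflectance` (backscattered photons undergo many more
#'   depolarizing scattering events than ballistic transmitted photons).
#'
#' Sub-resolution fibril dispersion additionally depolarizes: a pixel
#' containing fibrils with axial von Mises orientation scatter of
#' concentration `kappa` retains only the fraction
#' \eqn{R_2(\kappa) = I_1(\kappa)/I_0(\kappa)} of its linear polarization
#' (incoherent orientation mixture), which is folded into `depol_linear`.
#' This is what makes disorganized phantoms darker in DoLP, not only noisier
#' in AoP.
#'
#' Random fields (fiber axis, retardance jitter) are drawn at superpixel
#' (half) resolution and replicated 2x2, modelling a fibril correlation
#' length at the analyzer-superpixel pitch.
#'
#' @param alignment `"aligned"` (concentrated orientations) or
#'   `"disorganized"` (near-uniform orientations).
#' @param mode Imaging mode, `"transmission"` or `"reflectance"`.
#' @param shape Image size `c(height, width)` in mosaic pixels; both even.
#' @param seed Integer seed; scenes are deterministic given the seed.
#' @param collagen_density Final gel concentration in mg/mL; one of
#'   1.5 (control), 3.0, 4.5.
#' @param riboflavin Crosslinker concentration in mM; one of 0, 0.5, 1.0.
#' @param transmission_level Fraction of control transmission after absorber
#'   addition; one of 1.0, 0.67, 0.33.
#' @param mu_deg Mean fiber axis in degrees.
#' @param kappa Axial von Mises concentration of the fiber field; defaults to
#'   4 for aligned and 0.05 for disorganized scenes. `kappa >= 1e6` is the
#'   degenerate perfectly-aligned limit.
#' @param retardance_rad Optional override: a constant per-pixel retardance
#'   (radians) used verbatim instead of the density mapping (no jitter);
#'   useful for controlled single-retarder experiments.
#' @param depol_linear Optional override: constant linear retention factor in
#'   `[0,1]` used verbatim (fibril-dispersion and mode factors skipped).
#' @param c_ret Retardance per unit density (rad per mg/mL), default 0.7.
#' @param thickness_factor Relative sample thickness, default 1.
#' @param control_transmissivity Transmissivity of a control (absorber-free)
#'   phantom, default 0.9.
#' @param base_intensity Source intensity at the sample in full-scale units,
#'   default 0.8 (keeps the brightest analyzer pixel below saturation).
#' @param depol_transmission Mode retention factor for transmission, 0.98.
#' @param depol_reflectance Extra retention factor applied in reflectance
#'   mode, default 0.36 (uniform scaling of DoLP relative to transmission).
#' @param retardance_jitter Relative SD of multiplicative per-superpixel
#'   retardance variation, default 0.05.
#' @return A `phantom_scene`: per-pixel maps `fiber_axis_deg`,
#'   `retardance_rad`, `depol_linear`, `depol_circular`, `transmissivity`,
#'   `base_intensity` plus the factor levels and mode.
#' @examples
#' sc <- generate_scene("aligned", "transmission", shape = c(32, 32), seed = 1)
#' range(sc$maps$fiber_axis_deg)
#' @export
generate_scene <- function(alignment = c("aligned", "disorganized"),
                           mode = c("transmission", "reflectance"),
                           shape = c(64, 64), seed,
                           collagen_density = 1.5,
                           riboflavin = 0,
                           transmission_level = 1.0,
                           mu_deg = 0, kappa = NULL,
                           retardance_rad = NULL,
                           depol_linear = NULL,
                           c_ret = 0.7, thickness_factor = 1,
                           control_transmissivity = 0.9,
                           base_intensity = 0.8,
                           depol_transmission = 0.98,
                           depol_reflectance = 0.36,
                           retardance_jitter = 0.05) {
  alignment <- match.arg(alignment)
  mode <- match.arg(mode)
  if (missing(seed)) stop("`seed` is required for scene generation", call. = FALSE)
  if (length(shape) != 2L || any(shape %% 2 != 0) || any(shape < 2)) {
    stop("`shape` must be two even positive integers (height, width)", call. = FALSE)
  }
  check_level <- function(x, name, levels) {
    if (!isTRUE(any(abs(x - levels) < 1e-9))) {
      stop(sprintf("unknown %s level %s; must be one of {%s}",
                   name, format(x), paste(levels, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_level(collagen_density, "collagen_density", c(1.5, 3.0, 4.5))
  check_level(riboflavin, "riboflavin", c(0, 0.5, 1.0))
  check_level(transmission_level, "transmission_level", c(1.0, 0.67, 0.33))

  h <- shape[1]; w <- shape[2]
  hh <- h %/% 2L; ww <- w %/% 2L
  if (is.null(kappa)) kappa <- if (alignment == "aligned") 4 else 0.05

  maps <- with_seed(seed, {
    axis_sp <- matrix(rvonmises_axial(hh * ww, mu_deg, kappa), hh, ww)
    if (is.null(retardance_rad)) {
      delta0 <- c_ret * collagen_density * thickness_factor * (1 + 0.2 * riboflavin)
      jitter <- matrix(pmax(1 + retardance_jitter * stats::rnorm(hh * ww), 0), hh, ww)
      ret_sp <- delta0 * jitter
    } else {
      stopifnot_scalar_in(retardance_rad, "retardance_rad", 0, 2 * pi - 1e-12)
      ret_sp <- matrix(retardance_rad, hh, ww)
    }
    list(axis = axis_sp, ret = ret_sp)
  })
  # retardance must stay in the retarder's valid range
  maps$ret <- pmin(maps$ret, 2 * pi - 1e-9)

  if (is.null(depol_linear)) {
    d_fibril <- bessel_ratio(kappa)          # sub-resolution orientation mixture
    d_density <- 1 - 0.03 * (collagen_density - 1.5)
    d_mode <- if (mode == "reflectance") depol_transmission * depol_reflectance
              else depol_transmission
    d_lin <- d_mode * d_fibril * d_density
  } else {
    stopifnot_scalar_in(depol_linear, "depol_linear", 0, 1)
    d_lin <- depol_linear
  }

  up <- function(m) m[rep(seq_len(hh), each = 2L), rep(seq_len(ww), each = 2L)]
  structure(list(
    height = h, width = w,
    maps = list(
      fiber_axis_deg = up(maps$axis),
      retardance_rad = up(maps$ret),
      depol_linear   = matrix(d_lin, h, w),
      depol_circular = matrix(d_lin, h, w),
      transmissivity = matrix(transmission_level * control_transmissivity, h, w),
      base_intensity = matrix(base_intensity, h, w)
    ),
    alignment = alignment, mode = mode, seed = seed,
    kappa = kappa, mu_deg = mu_deg,
    factors = list(collagen_density = collagen_density,
                   riboflavin = riboflavin,
                   transmission_level = transmission_level)
  ), class = "phantom_scene")
}

# I1/I0 Bessel ratio = mean resultant length of a von Mises distribution;
# exponentially scaled to stay finite for very large kappa.
bessel_ratio <- function(kappa) {
  if (kappa <= 0) return(0)
  # large-argument asymptotics: besselI under/overflows beyond ~1e4
  if (kappa > 1e4) return(1 - 1 / (2 * kappa) - 1 / (8 * kappa^2))
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Sample axial (180-degree-periodic) von Mises orientations
#'
#' Draws fiber orientations from the semicircular von Mises density
#' \eqn{p(\theta) \propto \exp(\kappa \cos 2(\theta - \mu))} on
#' \eqn{[-90, 90)} degrees, via the doubled-angle circular von Mises and the
#' Best-Fisher rejection sampler.
#'
#' @param n Number of draws.
#' @param mu_deg Mean axis in degrees.
#' @param kappa Concentration; 0 gives the uniform axial distribution,
#'   `kappa >= 1e6` the degenerate point mass at `mu_deg`.
#' @return Numeric vector of angles in `[-90, 90)`.
#' @export
rvonmises_axial <- function(n, mu_deg = 0, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0) {
    stop("`kappa` must be a single non-negative number", call. = FALSE)
  }
  if (kappa >= 1e6) return(rep(wrap_axial(mu_deg), n))
  if (kappa < 1e-8) return(stats::runif(n, -90, 90))
  phi <- rvonmises_circular(n, kappa)     # VM(0, kappa) on (-pi, pi]
  wrap_axial(mu_deg + rad2deg(phi) / 2)
}

# Best & Fisher (1979) rejection sampler for the circular von Mises VM(0, kappa)
rvonmises_circular <- function(n, kappa) {
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.5 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  out[seq_len(n)]
}

#' Sensor model parameters for the DoFP polarization camera
#'
#' @param layout 2x2 integer matrix (row-major from the sensor's top-left)
#'   giving the analyzer angles of one superpixel; must be a permutation of
#'   0, 45, 90, 135.
#' @param gain Full-scale signal in photoelectron-equivalents used by the
#'   Poisson shot-noise model.
#' @param read_noise_sd Gaussian read noise SD as a fraction of full scale.
#' @param bit_depth Output bit depth for digitized frames.
#' @return A `sensor_params` list.
#' @export
sensor_params <- function(layout = matrix(c(90, 45, 135, 0), 2, 2, byrow = TRUE),
                          gain = 1000, read_noise_sd = 0.005,
                          bit_depth = 16L) {
  layout <- matrix(as.integer(layout), 2, 2)
  if (!setequal(as.vector(layout), c(0L, 45L, 90L, 135L))) {
    stop("`layout` must be a 2x2 permutation of analyzer angles 0, 45, 90, 135",
         call. = FALSE)
  }
  if (gain <= 0) stop("`gain` must be positive", call. = FALSE)
  if (read_noise_sd < 0) stop("`read_noise_sd` must be >= 0", call. = FALSE)
  structure(list(layout = layout, gain = gain, read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth)),
            class = "sensor_params")
}

#' Per-pixel output Stokes maps of a scene (before the analyzer)
#'
#' Propagates the circular illumination state through each pixel's optical
#' chain in closed form. The chain is, in optical order: (reflectance only)
#' helicity-flipping mirror; linear retarder with the pixel's fiber axis and
#' retardance; diagonal depolarizer; neutral attenuator times source
#' intensity. Identical to building the per-pixel [mode_chain()] and calling
#' [propagate()], but vectorized over the image.
#'
#' @param scene A `phantom_scene`.
#' @param input_handedness `"right"` or `"left"` circular illumination.
#' @return List of matrices `S0`, `S1`, `S2`, `S3`.
#' @export
scene_stokes <- function(scene, input_handedness = c("right", "left")) {
  input_handedness <- match.arg(input_handedness)
  m <- scene$maps
  s3_in <- if (input_handedness == "right") 1 else -1
  if (scene$mode == "reflectance") s3_in <- -s3_in     # helicity flip
  th2 <- deg2rad(2 * m$fiber_axis_deg)
  sd <- sin(m$retardance_rad); cd <- cos(m$retardance_rad)
  amp <- m$transmissivity * m$base_intensity
  list(
    S0 = amp,
    S1 = amp * m$depol_linear * (-sin(th2) * sd * s3_in),
    S2 = amp * m$depol_linear * ( cos(th2) * sd * s3_in),
    S3 = amp * m$depol_circular * cd * s3_in
  )
}

#' The Mueller chain of a single scene pixel
#'
#' Convenience accessor used for cross-checking the vectorized renderer
#' against element-by-element propagation.
#'
#' @param scene A `phantom_scene`.
#' @param i,j Pixel row and column (1-based).
#' @param input_handedness `"right"` or `"left"`.
#' @return A [mode_chain()].
#' @export
pixel_chain <- function(scene, i, j, input_handedness = c("right", "left")) {
  input_handedness <- match.arg(input_handedness)
  m <- scene$maps
  els <- list()
  if (scene$mode == "reflectance") els <- c(els, list(make_element("mirror")))
  els <- c(els, list(
    make_element("retarder", fast_axis_deg = m$fiber_axis_deg[i, j],
                 retardance_rad = m$retardance_rad[i, j]),
    make_element("depolarizer", depol_linear = m$depol_linear[i, j],
                 depol_circular = m$depol_circular[i, j]),
    make_element("attenuator", transmissivity = m$transmissivity[i, j])
  ))
  mode_chain(scene$mode, els,
             circular_state(input_handedness, intensity = m$base_intensity[i, j]))
}

#' Render a raw DoFP mosaic from a phantom scene
#'
#' Each sensor pixel sees the scene pixel behind it through one of four
#' linear analyzers arranged in repeating 2x2 superpixels. The detected
#' intensity at analyzer angle \eqn{\theta} follows Malus sampling of the
#' pixel's output Stokes state:
#' \eqn{I(\theta) = \tfrac12 (S_0 + S_1 \cos 2\theta + S_2 \sin 2\theta)}.
#'
#' With `noise = TRUE` the intensity (full-scale units) is converted to
#' photoelectron-equivalents via `sensor$gain`, Poisson shot noise and
#' Gaussian read noise are added, and the frame is digitized to
#' `sensor$bit_depth` bits with clipping. With `noise = FALSE` the exact
#' Malus intensities are returned unquantized.
#'
#' @param scene A `phantom_scene`.
#' @param sensor A [sensor_params()] object.
#' @param input_handedness `"right"` or `"left"` circular illumination.
#' @param noise Logical; add Poisson-Gaussian sensor noise and digitize.
#' @param seed Integer seed; required when `noise = TRUE`.
#' @return A `mosaic_image`: matrix `pixels` plus `layout` and provenance
#'   metadata (`mode`, `handedness`, `seed`, scene factors).
#' @export
render_mosaic <- function(scene, sensor = sensor_params(),
                          input_handedness = c("right", "left"),
                          noise = TRUE, seed = NULL) {
  if (!inherits(scene, "phantom_scene")) stop("`scene` must be a phantom_scene", call. = FALSE)
  if (is.character(input_handedness)) {
    if (!all(input_handedness %in% c("right", "left"))) {
      stop("`input_handedness` must be \"right\" or \"left\"", call. = FALSE)
    }
  }
  input_handedness <- match.arg(input_handedness)
  s <- scene_stokes(scene, input_handedness)
  h <- scene$height; w <- scene$width
  ang <- sensor$layout[cbind(rep(((seq_len(h) - 1L) %% 2L) + 1L, times = w),
                             rep(((seq_len(w) - 1L) %% 2L) + 1L, each = h))]
  ang <- matrix(deg2rad(ang), h, w)
  intens <- 0.5 * (s$S0 + s$S1 * cos(2 * ang) + s$S2 * sin(2 * ang))
  if (noise) {
    if (is.null(seed)) stop("`seed` is required when noise = TRUE", call. = FALSE)
    full <- 2^sensor$bit_depth - 1
    intens <- with_seed(seed, {
      e <- stats::rpois(length(intens), pmax(intens, 0) * sensor$gain) +
        stats::rnorm(length(intens), 0, sensor$read_noise_sd * sensor$gain)
      matrix(e / sensor$gain, h, w)
    })
    intens <- round(pmin(pmax(intens, 0), 1) * full) / full
  }
  mosaic_image(intens, sensor$layout,
               meta = list(mode = scene$mode, handedness = input_handedness,
                           seed = if (noise) seed else NA_integer_,
                           scene_seed = scene$seed,
                           alignment = scene$alignment,
                           factors = scene$factors))
}

#' Raw DoFP mosaic frames
#'
#' @param pixels Non-negative numeric matrix with even dimensions.
#' @param layout 2x2 analyzer-angle matrix (see [sensor_params()]).
#' @param meta Optional provenance metadata list.
#' @return A `mosaic_image`.
#' @export
mosaic_image <- function(pixels, layout, meta = list()) {
  if (!is.matrix(pixels) || any(dim(pixels) %% 2 != 0)) {
    stop("mosaic dimensions must be even in both axes", call. = FALSE)
  }
  if (any(pixels < 0)) stop("mosaic values must be >= 0", call. = FALSE)
  layout <- matrix(as.integer(layout), 2, 2)
  if (!setequal(as.vector(layout), c(0L, 45L, 90L, 135L))) {
    stop("`layout` must be a permutation of 0, 45, 90, 135", call. = FALSE)
  }
  structure(list(pixels = pixels, layout = layout, meta = meta),
            class = "mosaic_image")
}

#' Render a synthetic fiber-texture image
#'
#' Draws `n_fibers` straight line segments whose orientations are i.i.d.
#' axial von Mises draws, rendered with a Gaussian cross-section profile
#' (anti-aliased), plus additive Gaussian background noise. Emulates the
#' fibrous texture of structural imaging slices used for orientation
#' analysis.
#'
#' Orientation convention: degrees counterclockwise from the horizontal with
#' the y axis pointing up (row index increasing downward).
#'
#' @param kappa Axial von Mises concentration (>= 0).
#' @param mu_deg Mean fiber axis in degrees.
#' @param n_fibers Number of segments (>= 1).
#' @param shape Image size `c(height, width)`.
#' @param fiber_width Gaussian half-width of the fiber profile in pixels.
#' @param seed Integer seed.
#' @param fiber_length Segment length in pixels; default 60% of the shorter
#'   image side.
#' @param noise_sd Additive Gaussian background noise SD (image units).
#' @return Numeric matrix in approximately `[0, 1]`, with attribute
#'   `angles_deg` carrying the drawn orientations (ground truth for tests).
#' @export
generate_fiber_texture <- function(kappa, mu_deg = 0, n_fibers = 400,
                                   shape = c(128, 128), fiber_width = 1.5,
                                   seed, fiber_length = NULL,
                                   noise_sd = 0.02) {
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (n_fibers < 1) stop("`n_fibers` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  h <- shape[1]; w <- shape[2]
  if (is.null(fiber_length)) fiber_length <- 0.6 * min(h, w)
  with_seed(seed, {
    ang <- rvonmises_axial(n_fibers, mu_deg, kappa)
    cx <- stats::runif(n_fibers, 1, w)
    cy <- stats::runif(n_fibers, 1, h)
    img <- matrix(0, h, w)
    margin <- ceiling(3 * fiber_width)
    for (f in seq_len(n_fibers)) {
      th <- deg2rad(ang[f])
      dx <- cos(th); dy <- -sin(th)       # y up == row index down
      half <- fiber_length / 2
      x0 <- cx[f] - half * dx; x1 <- cx[f] + half * dx
      y0 <- cy[f] - half * dy; y1 <- cy[f] + half * dy
      cmin <- max(1L, floor(min(x0, x1)) - margin)
      cmax <- min(w, ceiling(max(x0, x1)) + margin)
      rmin <- max(1L, floor(min(y0, y1)) - margin)
      rmax <- min(h, ceiling(max(y0, y1)) + margin)
      if (cmin > cmax || rmin > rmax) next
      cols <- cmin:cmax; rows <- rmin:rmax
      px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
      py <- matrix(rows, length(rows), length(cols))
      t_par <- (px - cx[f]) * dx + (py - cy[f]) * dy
      t_par <- pmin(pmax(t_par, -half), half)
      qx <- cx[f] + t_par * dx; qy <- cy[f] + t_par * dy
      d2 <- (px - qx)^2 + (py - qy)^2
      img[rows, cols] <- img[rows, cols] + exp(-d2 / (2 * fiber_width^2))
    }
    img <- img / max(max(img), 1e-12)
    img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    img <- pmin(pmax(img, 0), 1)
    attr(img, "angles_deg") <- ang
    img
  })
}
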