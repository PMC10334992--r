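#' Stokes vectors
#'
#' Construct a full four-component Stokes vector \eqn{(S_0, S_1, S_2, S_3)}.
#' \eqn{S_0} is the total intensity (arbitrary units), \eqn{S_1} the
#' 0/90 degree linear component, \eqn{S_2} the +/-45 degree linear component
#' and \eqn{S_3} the circular component (positive = right-handed).
#'
#' A physical state satisfies \eqn{\sqrt{S_1^2+S_2^2+S_3^2} \le S_0} and
#' \eqn{S_0 \ge 0}.
#'
#' @param s0,s1,s2,s3 Stokes components.
#' @return A numeric vector of class `stokes_vector`.
#' @examples
#' stokes_vector(1, 0, 0, 1)   # right-handed circular
#' @export
stokes_vector <- function(s0, s1 = 0, s2 = 0, s3 = 0) {
  v <- c(s0, s1, s2, s3)
  if (!is.numeric(v) || length(v) != 4L || any(!is.finite(v))) {
    stop("Stokes components must be four finite numbers", call. = FALSE)
  }
  structure(v, class = "stokes_vector")
}

#' Right- and left-handed circular input states
#'
#' Unit-intensity circular polarization states used as illumination in the
#' forward model. Right-handed corresponds to \eqn{S_3 = +1}.
#'
#' @param handedness `"right"` or `"left"`.
#' @param intensity Total intensity \eqn{S_0}.
#' @return A `stokes_vector`.
#' @export
circular_state <- function(handedness = c("right", "left"), intensity = 1) {
  handedness <- match.arg(handedness)
  stokes_vector(intensity, 0, 0, if (handedness == "right") intensity else -intensity)
}

#' Test physicality of a Stokes vector
#'
#' @param s A `stokes_vector` or numeric vector of length 4.
#' @param tol Relative tolerance on the polarization inequality.
#' @return `TRUE` if \eqn{S_0 \ge 0} and
#'   \eqn{\sqrt{S_1^2+S_2^2+S_3^2} \le S_0 (1 + tol)}.
#' @export
is_physical <- function(s, tol = 1e-9) {
  s <- unclass(s)
  s[1] >= 0 && sqrt(sum(s[2:4]^2)) <= s[1] * (1 + tol) + tol * max(abs(s))
}

#' Degree and angle of linear polarization of a Stokes state
#'
#' `dolp()` returns \eqn{\sqrt{S_1^2+S_2^2}/S_0}; `aop()` returns
#' \eqn{\tfrac12 \mathrm{atan2}(S_2, S_1)} in degrees, wrapped to
#' \eqn{[-90, 90)}. Both accept a length-4 Stokes vector.
#'
#' @param s A `stokes_vector`.
#' @return A scalar.
#' @export
dolp <- function(s) {
  s <- unclass(s)
  sqrt(s[2]^2 + s[3]^2) / s[1]
}

#' @rdname dolp
#' @export
aop <- function(s) {
  s <- unclass(s)
  wrap_axial(rad2deg(0.5 * atan2(s[3], s[2])))
}

element_kinds <- c("retarder", "polarizer", "depolarizer", "attenuator", "mirror")

#' Construct a Mueller optical element
#'
#' Builds the standard 4x4 Mueller matrix for one of five element kinds:
#'
#' * `retarder`: linear retarder with fast axis `fast_axis_deg` (degrees,
#'   counterclockwise from the camera horizontal) and retardance
#'   `retardance_rad` (radians, in `[0, 2*pi)`). Preserves total intensity
#'   and degree of polarization.
#' * `polarizer`: ideal linear polarizer at `axis_deg`.
#' * `depolarizer`: diagonal depolarizer `diag(1, d_lin, d_lin, d_circ)` with
#'   separate linear (`depol_linear`) and circular (`depol_circular`)
#'   retention factors in `[0, 1]`.
#' * `attenuator`: neutral attenuator, `transmissivity` times the identity.
#' * `mirror`: helicity-flipping reflection, `diag(1, 1, -1, -1)`; circularly
#'   polarized light reverses handedness on reflection. Composing the mirror
#'   with itself gives the identity.
#'
#' @param kind One of `"retarder"`, `"polarizer"`, `"depolarizer"`,
#'   `"attenuator"`, `"mirror"`.
#' @param fast_axis_deg,retardance_rad Retarder parameters.
#' @param axis_deg Polarizer transmission axis (degrees).
#' @param depol_linear,depol_circular Depolarizer retention factors in `[0,1]`
#'   (1 = no depolarization, 0 = complete).
#' @param transmissivity Attenuator transmission in `[0,1]`.
#' @return A `mueller_element`: list with `matrix` (4x4), `kind`, `params`.
#' @examples
#' make_element("retarder", fast_axis_deg = 20, retardance_rad = pi / 2)
#' make_element("mirror")
#' @export
make_element <- function(kind = element_kinds,
                         fast_axis_deg = 0, retardance_rad = 0,
                         axis_deg = 0,
                         depol_linear = 1, depol_circular = depol_linear,
                         transmissivity = 1) {
  kind <- match.arg(kind)
  m <- switch(kind,
    retarder = {
      if (!is.finite(retardance_rad) || retardance_rad < 0 || retardance_rad >= 2 * pi) {
        stop("`retardance_rad` must lie in [0, 2*pi)", call. = FALSE)
      }
      retarder_matrix(fast_axis_deg, retardance_rad)
    },
    polarizer = {
      th <- deg2rad(axis_deg)
      c2 <- cos(2 * th); s2 <- sin(2 * th)
      0.5 * matrix(c(
        1, c2, s2, 0,
        c2, c2^2, c2 * s2, 0,
        s2, c2 * s2, s2^2, 0,
        0, 0, 0, 0), 4, 4, byrow = TRUE)
    },
    depolarizer = {
      stopifnot_scalar_in(depol_linear, "depol_linear", 0, 1)
      stopifnot_scalar_in(depol_circular, "depol_circular", 0, 1)
      diag(c(1, depol_linear, depol_linear, depol_circular))
    },
    attenuator = {
      stopifnot_scalar_in(transmissivity, "transmissivity", 0, 1)
      transmissivity * diag(4)
    },
    mirror = diag(c(1, 1, -1, -1))
  )
  params <- switch(kind,
    retarder = list(fast_axis_deg = fast_axis_deg, retardance_rad = retardance_rad),
    polarizer = list(axis_deg = axis_deg),
    depolarizer = list(depol_linear = depol_linear, depol_circular = depol_circular),
    attenuator = list(transmissivity = transmissivity),
    mirror = list()
  )
  structure(list(matrix = m, kind = kind, params = params),
            class = "mueller_element")
}

# Linear retarder Mueller matrix, fast axis theta (deg), retardance delta (rad)
retarder_matrix <- function(fast_axis_deg, retardance_rad) {
  th <- deg2rad(fast_axis_deg)
  c2 <- cos(2 * th); s2 <- sin(2 * th)
  cd <- cos(retardance_rad); sd <- sin(retardance_rad)
  matrix(c(
    1, 0, 0, 0,
    0, c2^2 + s2^2 * cd, c2 * s2 * (1 - cd), -s2 * sd,
    0, c2 * s2 * (1 - cd), s2^2 + c2^2 * cd, c2 * sd,
    0, s2 * sd, -c2 * sd, cd), 4, 4, byrow = TRUE)
}

#' @export
print.mueller_element <- function(x, ...) {
  cat("<mueller_element>", x$kind, "\n")
  if (length(x$params)) {
    cat(paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "), "\n")
  }
  print(round(x$matrix, 6))
  invisible(x)
}

#' Optical mode chains
#'
#' A `mode_chain` bundles an ordered list of [make_element()] elements (in
#' optical order, i.e. the first element acts first), the imaging mode, and
#' the illumination Stokes state. A reflectance chain must contain exactly
#' one mirror element (the helicity-flipping reflection off the sample);
#' a transmission chain must contain none.
#'
#' @param mode `"transmission"` or `"reflectance"`.
#' @param elements List of `mueller_element` objects in optical order.
#' @param input_state Illumination `stokes_vector`; defaults to unit
#'   right-handed circular, matching a right-handed circular polarizing film
#'   in front of the source.
#' @return A `mode_chain`.
#' @examples
#' ch <- mode_chain("reflectance", list(
#'   make_element("mirror"),
#'   make_element("retarder", fast_axis_deg = 20, retardance_rad = pi / 2)
#' ))
#' propagate(circular_state("right"), ch)
#' @export
mode_chain <- function(mode = c("transmission", "reflectance"), elements,
                       input_state = circular_state("right")) {
  mode <- match.arg(mode)
  if (!is.list(elements) || length(elements) == 0L) {
    stop("`elements` must be a non-empty list of mueller_element objects",
         call. = FALSE)
  }
  if (!all(vapply(elements, inherits, logical(1), "mueller_element"))) {
    stop("all elements must be created with make_element()", call. = FALSE)
  }
  n_mirror <- sum(vapply(elements, function(e) e$kind == "mirror", logical(1)))
  if (mode == "reflectance" && n_mirror != 1L) {
    stop("a reflectance chain must contain exactly one mirror element",
         call. = FALSE)
  }
  if (mode == "transmission" && n_mirror != 0L) {
    stop("a transmission chain must not contain a mirror element",
         call. = FALSE)
  }
  structure(list(mode = mode, elements = elements, input_state = input_state),
            class = "mode_chain")
}

#' Propagate a Stokes state through an element chain
#'
#' Applies the chain's Mueller matrices in optical order:
#' \eqn{s' = M_n \cdots M_1 s}.
#'
#' @param state Input `stokes_vector` (must be physical).
#' @param chain A `mode_chain`, or a list of `mueller_element`s.
#' @return The output `stokes_vector`.
#' @export
propagate <- function(state, chain) {
  elements <- if (inherits(chain, "mode_chain")) chain$elements else chain
  if (!is_physical(state)) {
    stop("input state is not physical: sqrt(S1^2+S2^2+S3^2) > S0 or S0 < 0",
         call. = FALSE)
  }
  s <- unclass(state)
  for (e in elements) s <- drop(e$matrix %*% s)
  stokes_vector(s[1], s[2], s[3], s[4])
}

#' Axial (180-degree-periodic) circular difference between two angles
#'
#' The angle of polarization is an axial quantity: values 180 degrees apart
#' are the same axis. The axial difference between two angles is
#' \eqn{\min(|\Delta| \bmod 180, 180 - |\Delta| \bmod 180)}, in `[0, 90]`.
#' This is the metric used to quantify the ~90 degree AoP shift between
#' transmission and reflectance modes and between input handedness states.
#'
#' @param a_deg,b_deg Angles in degrees.
#' @return Axial difference in degrees, in `[0, 90]`. Vectorized.
#' @examples
#' aop_circular_difference(65, -25)   # 90
#' aop_circular_difference(89, -89)   # 2
#' @export
aop_circular_difference <- function(a_deg, b_deg) {
  if (any(!is.finite(a_deg)) || any(!is.finite(b_deg))) {
    stop("angles must be finite", call. = FALSE)
  }
  d <- abs(a_deg - b_deg) %% 180
  pmin(d, 180 - d)
}

#' Serialize / deserialize element chains
#'
#' `chain_to_config()` turns a `mode_chain` into a plain list (suitable for
#' `yaml::write_yaml()`); `chain_from_config()` rebuilds the chain. Elements
#' are listed in optical order with named parameters.
#'
#' @param chain A `mode_chain`.
#' @param config A list as produced by `chain_to_config()` (or read from
#'   YAML/JSON) with fields `mode`, `input_handedness`, `elements`.
#' @return A list, or a `mode_chain`.
#' @export
chain_to_config <- function(chain) {
  stopifnot(inherits(chain, "mode_chain"))
  s <- unclass(chain$input_state)
  list(
    mode = chain$mode,
    input_handedness = if (s[4] >= 0) "right" else "left",
    elements = lapply(chain$elements, function(e) c(list(kind = e$kind), e$params))
  )
}

#' @rdname chain_to_config
#' @export
chain_from_config <- function(config) {
  if (!all(c("mode", "elements") %in% names(config))) {
    stop("chain config needs `mode` and `elements`", call. = FALSE)
  }
  elements <- lapply(config$elements, function(e) {
    do.call(make_element, e)
  })
  handed <- config$input_handedness %||% "right"
  mode_chain(config$mode, elements, circular_state(handed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
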