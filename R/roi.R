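#' Axial circular mean of angles in degrees
#'
#' Mean axis of 180-degree-periodic data via the doubled-angle resultant:
#' \eqn{\bar\theta = \tfrac12 \mathrm{atan2}(\overline{\sin 2\theta},
#' \overline{\cos 2\theta})}, in `[-90, 90)`.
#'
#' @param a_deg Angles in degrees.
#' @param w Optional non-negative weights.
#' @return Mean axis in degrees, or `NA` if the resultant vanishes.
#' @export
axial_mean <- function(a_deg, w = NULL) {
  t2 <- deg2rad(2 * a_deg)
  if (is.null(w)) w <- rep(1, length(a_deg))
  w <- w / sum(w)
  C <- sum(w * cos(t2)); S <- sum(w * sin(t2))
  if (sqrt(C^2 + S^2) < 1e-12) return(NA_real_)
  wrap_axial(rad2deg(0.5 * atan2(S, C)))
}

#' ROI outcome: average degree of linear polarization (AVG DoLP)
#'
#' Arithmetic mean of DoLP over the masked pixels — the ROI-level measure of
#' collagen fiber alignment strength.
#'
#' @param stokes A `stokes_image`.
#' @param mask Logical matrix the same shape as the image; defaults to the
#'   image's own `valid_mask`. Pixels flagged invalid are always excluded.
#' @return Scalar in `[0, 1]`.
#' @export
avg_dolp <- function(stokes, mask = NULL) {
  sel <- roi_selection(stokes, mask)
  mean(stokes$DoLP[sel])
}

#' ROI outcome: standard deviation of the angle of polarization (STD AoP)
#'
#' Dispersion of the axial AoP values in an ROI — the measure of collagen
#' fiber orientation spread. Two estimators:
#'
#' * `"recentred"` (default): find the axial circular mean axis via the
#'   doubled-angle resultant, map every AoP into the 180-degree window
#'   centred on that axis, and return the population (divide-by-n) standard
#'   deviation of the recentred values. Equals the naive SD for concentrated
#'   data but is safe at the +/-90 branch cut.
#' * `"circular"`: the axial circular SD
#'   \eqn{\sigma = \tfrac12\sqrt{-2 \ln R_2}} (in degrees), where \eqn{R_2}
#'   is the doubled-angle mean resultant length.
#'
#' If the resultant vanishes (perfectly balanced axes) the recentred
#' estimator falls back to a window centred at 0 degrees, with a warning.
#'
#' @param stokes A `stokes_image`.
#' @param mask Logical ROI mask (default: the valid mask).
#' @param estimator `"recentred"` or `"circular"`.
#' @return Dispersion in degrees (recentred: in `[0, 90]`).
#' @export
std_aop <- function(stokes, mask = NULL, estimator = c("recentred", "circular")) {
  sel <- roi_selection(stokes, mask)
  std_aop_values(stokes$AoP[sel], estimator)
}

#' @rdname std_aop
#' @param a_deg Raw AoP values in degrees (for use outside image containers).
#' @export
std_aop_values <- function(a_deg, estimator = c("recentred", "circular")) {
  estimator <- match.arg(estimator)
  if (length(a_deg) == 0L) stop("no AoP values supplied", call. = FALSE)
  t2 <- deg2rad(2 * a_deg)
  C <- mean(cos(t2)); S <- mean(sin(t2))
  R2 <- sqrt(C^2 + S^2)
  if (estimator == "circular") {
    if (R2 < .Machine$double.eps) return(Inf)
    return(rad2deg(0.5 * sqrt(-2 * log(R2))))
  }
  if (R2 < 1e-12) {
    warning("zero axial resultant; recentring window centred at 0 degrees")
    axis <- 0
  } else {
    axis <- wrap_axial(rad2deg(0.5 * atan2(S, C)))
  }
  d <- wrap_axial(a_deg - axis)
  sqrt(mean(d^2) - mean(d)^2)
}

roi_selection <- function(stokes, mask) {
  if (!inherits(stokes, "stokes_image")) stop("`stokes` must be a stokes_image", call. = FALSE)
  if (is.null(mask)) {
    sel <- stokes$valid_mask
  } else {
    if (!identical(dim(mask), dim(stokes$S0))) {
      stop("ROI mask shape does not match the image", call. = FALSE)
    }
    sel <- (mask > 0) & stokes$valid_mask
  }
  if (!any(sel)) stop("ROI mask selects no valid pixels", call. = FALSE)
  sel
}

#' Rectangular ROI mask helper
#'
#' @param shape `c(height, width)` of the target image.
#' @param margin Number of pixels excluded on every side.
#' @return Logical matrix.
#' @export
roi_rect <- function(shape, margin = 2L) {
  h <- shape[1]; w <- shape[2]
  if (2 * margin >= min(h, w)) stop("margin leaves an empty ROI", call. = FALSE)
  m <- matrix(FALSE, h, w)
  m[(margin + 1L):(h - margin), (margin + 1L):(w - margin)] <- TRUE
  m
}

#' ROI outcome table
#'
#' Computes AVG DoLP and STD AoP for each ROI mask.
#'
#' @param stokes A `stokes_image`.
#' @param masks Named list of logical ROI masks; default one full-frame ROI.
#' @param estimator Passed to [std_aop()].
#' @return `data.frame` with columns `roi_id`, `n_pixels`, `avg_dolp`,
#'   `std_aop_deg`.
#' @export
roi_outcomes <- function(stokes, masks = NULL,
                         estimator = c("recentred", "circular")) {
  estimator <- match.arg(estimator)
  if (is.null(masks)) masks <- list(full = NULL)
  if (is.null(names(masks))) names(masks) <- paste0("roi", seq_along(masks))
  rows <- lapply(names(masks), function(id) {
    sel <- roi_selection(stokes, masks[[id]])
    data.frame(roi_id = id, n_pixels = sum(sel),
               avg_dolp = mean(stokes$DoLP[sel]),
               std_aop_deg = std_aop_values(stokes$AoP[sel], estimator))
  })
  do.call(rbind, rows)
}

#' Render a DoLP or AoP map to RGB
#'
#' DoLP maps use a sequential (viridis) lookup table saturating at
#' `scale_max`: rescaling the lookup table (for example to `[0, 0.25]` in
#' reflectance mode instead of `[0, 1]`) makes a uniformly scaled-down DoLP
#' image render identically to its transmission counterpart. AoP maps use a
#' cyclic hue map with period 180 degrees, so -90 and +90 degrees (the same
#' physical axis) render identically.
#'
#' @param map2d Numeric matrix (DoLP in `[0,1]` or AoP in degrees).
#' @param kind `"dolp"` or `"aop"`.
#' @param scale_max Saturation point of the DoLP lookup table, in `(0, 1]`.
#' @return `height x width x 3` RGB array in `[0, 1]`.
#' @export
render_map <- function(map2d, kind = c("dolp", "aop"), scale_max = 1) {
  kind <- match.arg(kind)
  h <- nrow(map2d); w <- ncol(map2d)
  if (kind == "dolp") {
    if (!is.numeric(scale_max) || length(scale_max) != 1L ||
        scale_max <= 0 || scale_max > 1) {
      stop("`scale_max` must be in (0, 1]", call. = FALSE)
    }
    v <- pmin(pmax(map2d / scale_max, 0), 1)
    pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))) / 255
    idx <- 1L + as.integer(round(v * 255))
    rgb <- pal[idx, , drop = FALSE]
  } else {
    hue <- pos_mod(map2d + 90, 180) / 180
    cols <- grDevices::hsv(pmin(hue, 1 - 1e-12), 1, 1)
    rgb <- t(grDevices::col2rgb(cols)) / 255
  }
  array(rgb, dim = c(h, w, 3L))
}
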