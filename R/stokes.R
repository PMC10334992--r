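#' Demosaic a DoFP mosaic into four analyzer channel images
#'
#' Splits the raw superpixel-tiled frame into its 0/45/90/135-degree
#' analyzer channels. Two resolution modes:
#'
#' * `"superpixel"`: direct extraction — each channel is the quarter-
#'   resolution subgrid of pixels carrying that analyzer.
#' * `"bilinear"` (default, matching common DoFP practice): each channel is
#'   returned at full mosaic resolution, with the missing pixels filled by
#'   bilinear interpolation from that channel's own subgrid; borders are
#'   handled by edge replication. Bilinear interpolation improves the
#'   effective spatial resolution of the reconstruction.
#'
#' @param mosaic A [mosaic_image()].
#' @param method `"bilinear"` or `"superpixel"`.
#' @return A `channel_stack`: matrices `I0`, `I45`, `I90`, `I135` sharing one
#'   shape, plus `resolution_mode`.
#' @export
demosaic <- function(mosaic, method = c("bilinear", "superpixel")) {
  method <- match.arg(method)
  if (!inherits(mosaic, "mosaic_image")) stop("`mosaic` must be a mosaic_image", call. = FALSE)
  px <- mosaic$pixels
  if (any(dim(px) %% 2 != 0)) stop("mosaic dimensions must be even", call. = FALSE)
  h <- nrow(px); w <- ncol(px)
  chans <- lapply(c(0L, 45L, 90L, 135L), function(a) {
    pos <- which(mosaic$layout == a, arr.ind = TRUE)[1, ]
    sub <- px[seq(pos[1], h, by = 2L), seq(pos[2], w, by = 2L), drop = FALSE]
    if (method == "superpixel") sub
    else bilinear_upsample(sub, pos[1], pos[2], h, w)
  })
  structure(list(I0 = chans[[1]], I45 = chans[[2]], I90 = chans[[3]],
                 I135 = chans[[4]],
                 resolution_mode = if (method == "superpixel") "superpixel"
                                   else "interpolated"),
            class = "channel_stack")
}

# Bilinear upsampling of a channel subgrid (known at rows r0, r0+2, ... and
# cols c0, c0+2, ...) to the full h x w grid. Missing interior samples have
# both neighbours known (spacing 2), so separable interpolation reduces to
# neighbour averaging; borders replicate the nearest known sample.
bilinear_upsample <- function(sub, r0, c0, h, w) {
  full <- matrix(NA_real_, h, w)
  kr <- seq(r0, h, by = 2L); kc <- seq(c0, w, by = 2L)
  full[kr, kc] <- sub
  fill_1d <- function(m, known, n, byrow) {
    miss <- setdiff(seq_len(n), known)
    for (j in miss) {
      lo <- if (j - 1L >= min(known)) j - 1L else j + 1L
      hi <- if (j + 1L <= max(known)) j + 1L else j - 1L
      if (byrow) m[j, ] <- (m[lo, ] + m[hi, ]) / 2
      else m[, j] <- (m[, lo] + m[, hi]) / 2
    }
    m
  }
  full <- fill_1d(full, kc, w, byrow = FALSE)   # along columns, known rows
  full <- fill_1d(full, kr, h, byrow = TRUE)    # then along rows, all columns
  full
}

#' Compute Stokes, DoLP and AoP images from analyzer channels
#'
#' The linear-analyzer Stokes reconstruction:
#' \deqn{S_0 = (I_0 + I_{45} + I_{90} + I_{135})/2, \quad
#'       S_1 = I_0 - I_{90}, \quad S_2 = I_{45} - I_{135},}
#' using all four channels for \eqn{S_0} (redundancy-averaged). Derived maps:
#' \eqn{DoLP = \sqrt{S_1^2 + S_2^2}/S_0} (clipped to `[0, 1]`) and
#' \eqn{AoP = \tfrac12 \mathrm{atan2}(S_2, S_1)} in degrees on
#' \eqn{[-90, 90)}. Pixels whose \eqn{S_0} falls below
#' `s0_floor_frac * max(S_0)` are flagged invalid in `valid_mask` (their
#' DoLP/AoP are set to 0, never NaN). The sensor is linear-only: \eqn{S_3}
#' is not observable and not estimated.
#'
#' @param channels A `channel_stack` from [demosaic()].
#' @param s0_floor_frac Fraction of the maximum \eqn{S_0} below which pixels
#'   are masked invalid; default `1e-3`.
#' @return A `stokes_image`: matrices `S0`, `S1`, `S2`, `DoLP`, `AoP`,
#'   logical `valid_mask`, and `resolution_mode`.
#' @examples
#' m <- mosaic_image(matrix(0.5, 4, 4), matrix(c(90, 45, 135, 0), 2, 2))
#' st <- compute_stokes(demosaic(m, "superpixel"))
#' st$DoLP
#' @export
compute_stokes <- function(channels, s0_floor_frac = 1e-3) {
  if (!inherits(channels, "channel_stack")) {
    stop("`channels` must be a channel_stack", call. = FALSE)
  }
  s0 <- (channels$I0 + channels$I45 + channels$I90 + channels$I135) / 2
  s1 <- channels$I0 - channels$I90
  s2 <- channels$I45 - channels$I135
  valid <- s0 > s0_floor_frac * max(s0)
  lin <- sqrt(s1^2 + s2^2)
  dolp <- matrix(0, nrow(s0), ncol(s0))
  dolp[valid] <- pmin(lin[valid] / s0[valid], 1)
  aop <- matrix(0, nrow(s0), ncol(s0))
  aop[valid] <- wrap_axial(rad2deg(0.5 * atan2(s2[valid], s1[valid])))
  structure(list(S0 = s0, S1 = s1, S2 = s2, DoLP = dolp, AoP = aop,
                 valid_mask = valid,
                 resolution_mode = channels$resolution_mode),
            class = "stokes_image")
}

#' @export
print.stokes_image <- function(x, ...) {
  cat(sprintf("<stokes_image> %d x %d (%s), %.1f%% valid\n",
              nrow(x$S0), ncol(x$S0), x$resolution_mode,
              100 * mean(x$valid_mask)))
  cat(sprintf("  DoLP mean %.4f | AoP axial mean %.2f deg\n",
              mean(x$DoLP[x$valid_mask]),
              axial_mean(x$AoP[x$valid_mask])))
  invisible(x)
}
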