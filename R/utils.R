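#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a local RNG seed, restoring any pre-existing global
# RNG state afterwards. All stochastic operations in the package route
# through this so there is no hidden global random state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# x mod m with the result always in [0, m)
pos_mod <- function(x, m) {
  r <- x %% m
  r[r >= m] <- 0
  r
}

# Map angles in degrees to the axial half-open window [-90, 90)
wrap_axial <- function(a_deg) {
  pos_mod(a_deg + 90, 180) - 90
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Separable Gaussian smoothing of a matrix with replicate (Neumann) border
# padding. Kernel truncated at 3*sigma. sigma = 0 returns the input.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  m <- conv_sep_1d(m, k, along = "rows")
  conv_sep_1d(m, k, along = "cols")
}

# 1-D convolution along rows or columns with replicate padding
conv_sep_1d <- function(m, k, along = c("rows", "cols")) {
  along <- match.arg(along)
  half <- (length(k) - 1L) / 2L
  if (along == "cols") m <- t(m)
  n <- nrow(m)
  idx <- pmin(pmax(seq_len(n + 2L * half) - half, 1L), n)
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  if (along == "cols") t(out) else out
}

# Central difference along rows (y) / columns (x) with replicate borders,
# so border derivatives are one-sided halves (Neumann-compatible).
diff_central <- function(m, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (along == "cols") return(t(diff_central(t(m), "rows")))
  n <- nrow(m)
  up <- m[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]
  dn <- m[pmin(seq_len(n) + 1L, n), , drop = FALSE]
  (dn - up) / 2
}

stopifnot_scalar_in <- function(x, name, lo, hi) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
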