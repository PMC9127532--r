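#' Synthetic tumor-phantom specification
#'
#' Describes a two-level synthetic test image: a bright object silhouette on
#' a darker background, optionally degraded by additive Gaussian noise. Three
#' silhouette families emulate the object shapes that motivate wormhole-based
#' clustering:
#'
#' * `"disc"` - a plain disc of radius `size/4`.
#' * `"bottleneck"` - two lobes joined by a narrow neck whose half-width
#'   follows a hyperbolic-style profile `w(y) = neck_width/2 + k * y^2`,
#'   truncated at the lobe radius; `neck_gap > 0` removes that many central
#'   rows of the neck, leaving two disjoint lobes separated by a gap.
#' * `"dualtail"` - a disc with two long tapering tails extending from
#'   opposite sides; tail half-width shrinks as
#'   `(rd/2) * (1 - u/tail_length)^tail_taper` with distance `u` from the
#'   disc, so the rasterized tail width is non-increasing along the tail.
#'
#' @param shape `"disc"`, `"bottleneck"` or `"dualtail"`.
#' @param size square image side in pixels, `>= 16`.
#' @param object_gray,background_gray intensities with
#'   `0 <= background_gray < object_gray <= 255`.
#' @param noise_sd standard deviation of the additive zero-mean Gaussian
#'   noise (intensity units, `>= 0`).
#' @param neck_width bottleneck only: width in pixels of the neck at its
#'   narrowest row.
#' @param neck_gap bottleneck only: number of central neck rows removed.
#' @param tail_length dualtail only: tail length in pixels.
#' @param tail_taper dualtail only: taper exponent (1 = linear).
#' @param seed integer RNG seed for the noise.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c("disc", "bottleneck", "dualtail"),
                         size = 64L, object_gray = 200L, background_gray = 50L,
                         noise_sd = 0, neck_width = 3, neck_gap = 0,
                         tail_length = 15, tail_taper = 1, seed = 1L) {
  shape <- match.arg(shape)
  if (!is.numeric(size) || size < 16) stop("`size` must be >= 16", call. = FALSE)
  if (background_gray < 0 || object_gray > 255 || background_gray >= object_gray)
    stop("need 0 <= background_gray < object_gray <= 255", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (neck_width < 1) stop("`neck_width` must be >= 1", call. = FALSE)
  if (neck_gap < 0) stop("`neck_gap` must be >= 0", call. = FALSE)
  if (tail_length < 1) stop("`tail_length` must be >= 1", call. = FALSE)
  if (tail_taper <= 0) stop("`tail_taper` must be positive", call. = FALSE)
  structure(list(shape = shape, size = as.integer(size),
                 object_gray = as.integer(object_gray),
                 background_gray = as.integer(background_gray),
                 noise_sd = as.numeric(noise_sd),
                 neck_width = as.numeric(neck_width),
                 neck_gap = as.numeric(neck_gap),
                 tail_length = as.numeric(tail_length),
                 tail_taper = as.numeric(tail_taper),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_mask <- function(spec) {
  s <- spec$size
  cy <- (s - 1) / 2; cx <- (s - 1) / 2
  rows <- matrix(0:(s - 1), s, s)          # row index per cell
  cols <- matrix(0:(s - 1), s, s, byrow = TRUE)
  if (spec$shape == "disc") {
    rad <- s / 4
    return((rows - cy)^2 + (cols - cx)^2 <= rad^2)
  }
  if (spec$shape == "bottleneck") {
    lobe_r <- round(s / 5)
    d <- cy - lobe_r - 2                   # lobe centers at rows cy +/- d
    lobes <- ((rows - (cy - d))^2 + (cols - cx)^2 <= lobe_r^2) |
             ((rows - (cy + d))^2 + (cols - cx)^2 <= lobe_r^2)
    y <- rows - cy
    kk <- (lobe_r - spec$neck_width / 2) / d^2
    # widen in whole-column steps so the rasterized neck is exactly
    # neck_width pixels wide at its narrowest row
    hw <- spec$neck_width / 2 + floor(pmin(kk * y^2, lobe_r - spec$neck_width / 2))
    neck <- abs(y) <= d & cols >= cx - hw & cols < cx + hw
    if (spec$neck_gap > 0) {
      gap <- rows >= cy - spec$neck_gap / 2 & rows < cy + spec$neck_gap / 2
      neck <- neck & !gap
    }
    return(lobes | neck)
  }
  # dualtail
  rd <- round(s / 6)
  disc <- (rows - cy)^2 + (cols - cx)^2 <= rd^2
  u <- abs(cols - cx) - rd                 # distance beyond the disc edge
  hw <- pmax((rd / 2) * pmax(1 - u / spec$tail_length, 0)^spec$tail_taper, 0.51)
  tails <- u > 0 & u <= spec$tail_length & abs(rows - cy) <= hw
  disc | tails
}

#' Generate a synthetic phantom image with ground truth
#'
#' Renders the silhouette of a [phantom_spec()] at `object_gray` on a
#' `background_gray` background, adds zero-mean Gaussian noise of standard
#' deviation `noise_sd`, rounds, and clips to `[0, 255]`. The returned mask is
#' the exact noiseless silhouette and does not depend on `noise_sd`. The
#' result is deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (a [gray_image()]), `mask` (logical matrix),
#'   and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- phantom_mask(spec)
  base <- ifelse(mask, spec$object_gray, spec$background_gray)
  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    base <- base + stats::rnorm(length(base), 0, spec$noise_sd)
  }
  vals <- matrix(pmin(pmax(round(base), 0), 255), spec$size, spec$size)
  list(image = gray_image(vals), mask = mask, spec = spec)
}

#' Fixed battery of test phantoms
#'
#' A reproducible suite of ten 64x64 phantoms: one disc, two bottlenecks
#' (neck widths 2 and 5) and two dualtails (tail lengths 10 and 20), each
#' rendered noiseless and with noise standard deviation 10.
#'
#' @param seed integer seed from which each phantom's noise seed is derived.
#' @return A list of ten items, each a list with `image`, `mask`, `spec`, and
#'   `name`.
#' @export
phantom_suite <- function(seed = 1L) {
  shapes <- list(
    list(name = "disc",        spec = function(sd, k) phantom_spec("disc", 64, noise_sd = sd, seed = k)),
    list(name = "bottleneck2", spec = function(sd, k) phantom_spec("bottleneck", 64, noise_sd = sd, neck_width = 2, seed = k)),
    list(name = "bottleneck5", spec = function(sd, k) phantom_spec("bottleneck", 64, noise_sd = sd, neck_width = 5, seed = k)),
    list(name = "dualtail10",  spec = function(sd, k) phantom_spec("dualtail", 64, noise_sd = sd, tail_length = 10, seed = k)),
    list(name = "dualtail20",  spec = function(sd, k) phantom_spec("dualtail", 64, noise_sd = sd, tail_length = 20, seed = k))
  )
  out <- list()
  i <- 0L
  for (sd in c(0, 10)) {
    for (sh in shapes) {
      i <- i + 1L
      ph <- make_phantom(sh$spec(sd, seed + i))
      ph$name <- sprintf("%s_sd%g", sh$name, sd)
      out[[i]] <- ph
    }
  }
  out
}
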