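#' QPSO parameters
#'
#' Parameters of the quantum-behaved particle swarm: the contraction-expansion
#' coefficient `alpha` scales the update step, `L` is the characteristic
#' length of the delta potential well (pixels), `swarm_size` the number of
#' particles, and `max_iter` the number of sweeps over the swarm (so the
#' position-update budget is `max_iter * swarm_size`).
#'
#' Defaults: `alpha = 0.75` held constant over iterations, and
#' `L = 0.1 * max(height, width)` when `L` is `NULL` at segmentation time.
#'
#' @param alpha positive contraction-expansion coefficient.
#' @param L positive potential-well length in pixels, or `NULL` to derive it
#'   from the image size.
#' @param swarm_size integer number of particles, `>= 2`.
#' @param max_iter integer number of sweeps, `>= 1`.
#' @return A list of class `"qpso_params"`.
#' @export
qpso_params <- function(alpha = 0.75, L = NULL, swarm_size = 100L, max_iter = 200L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  if (!is.null(L) && (!is.numeric(L) || length(L) != 1L || is.na(L) || L <= 0))
    stop("`L` must be a single positive number or NULL", call. = FALSE)
  if (!is.numeric(swarm_size) || swarm_size < 2)
    stop("`swarm_size` must be >= 2", call. = FALSE)
  if (!is.numeric(max_iter) || max_iter < 1)
    stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(alpha = as.numeric(alpha),
                 L = if (is.null(L)) NULL else as.numeric(L),
                 swarm_size = as.integer(swarm_size),
                 max_iter = as.integer(max_iter)),
            class = "qpso_params")
}

#' Delta-potential-well probability density
#'
#' The Laplace-shaped sampling density of a quantum particle bound in a delta
#' potential well centered on its attractor: `Q(y) = (1/L) exp(-2|y|/L)`,
#' where `y` is the signed offset from the attractor and `L` the
#' characteristic length of the well.
#'
#' @param y signed pixel offset(s) from the attractor.
#' @param L positive characteristic length.
#' @return Density value(s), same length as `y`.
#' @export
delta_well_density <- function(y, L) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L <= 0)
    stop("`L` must be a single positive number", call. = FALSE)
  (1 / L) * exp(-2 * abs(y) / L)
}

#' Monte Carlo position sampling from the delta well
#'
#' Inverts the delta-well density via a uniform draw: the sampled position is
#' `p + sign * (L/2) * log(1/u)`. With `sign` a fair coin and `u ~ U(0, 1]`,
#' the draws are distributed with density [delta_well_density()] about `p`.
#'
#' @param p attractor coordinate(s).
#' @param L positive characteristic length.
#' @param u uniform draw(s) in `(0, 1]`.
#' @param sign `+1` or `-1` (vectorized).
#' @return Sampled coordinate(s).
#' @export
sample_well_position <- function(p, L, u, sign = 1) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L <= 0)
    stop("`L` must be a single positive number", call. = FALSE)
  if (any(u <= 0) || any(u > 1))
    stop("`u` must lie in (0, 1]", call. = FALSE)
  p + sign * (L / 2) * log(1 / u)
}

#' Local attractor of a particle
#'
#' The stochastic convex combination of the personal best and global best
#' positions: `(phi1 * p_id + phi2 * p_gd) / (phi1 + phi2)`. The result
#' always lies in the closed interval spanned by the two endpoints.
#'
#' @param p_id personal-best coordinate.
#' @param p_gd global-best coordinate.
#' @param phi1,phi2 non-negative weights (uniform draws in the algorithm),
#'   with `phi1 + phi2 > 0`.
#' @return Attractor coordinate.
#' @export
local_attractor <- function(p_id, p_gd, phi1, phi2) {
  if (any(phi1 + phi2 <= 0) || any(phi1 < 0) || any(phi2 < 0))
    stop("`phi1 + phi2` must be positive with non-negative weights", call. = FALSE)
  (phi1 * p_id + phi2 * p_gd) / (phi1 + phi2)
}

#' Mean best position of the swarm
#'
#' Coordinate-wise arithmetic mean of all personal-best positions.
#'
#' @param personal_bests numeric matrix with one row per particle, or a
#'   numeric vector for one-dimensional problems.
#' @return Numeric vector, the mean best position.
#' @export
mean_best <- function(personal_bests) {
  if (is.matrix(personal_bests)) {
    if (nrow(personal_bests) == 0L) stop("`personal_bests` must be non-empty", call. = FALSE)
    return(colMeans(personal_bests))
  }
  if (length(personal_bests) == 0L) stop("`personal_bests` must be non-empty", call. = FALSE)
  mean(personal_bests)
}

#' QPSO position update
#'
#' The iterative update of quantum-behaved PSO, applied per coordinate axis:
#' if `mu > 0.5` the new position is `p - alpha * |mbest - x_t| * log(1/mu)`,
#' otherwise `p + alpha * |mbest - x_t| * log(1/mu)`. At `mu = 1` the update
#' collapses exactly onto the attractor `p`.
#'
#' @param x_t current coordinate(s).
#' @param p attractor coordinate(s) from [local_attractor()].
#' @param mbest mean best coordinate(s) from [mean_best()].
#' @param alpha positive contraction-expansion coefficient.
#' @param mu uniform draw(s) in `(0, 1]`.
#' @return Updated coordinate(s).
#' @export
qpso_update <- function(x_t, p, mbest, alpha, mu) {
  if (!is.numeric(alpha) || any(alpha <= 0))
    stop("`alpha` must be positive", call. = FALSE)
  if (any(mu <= 0) || any(mu > 1))
    stop("`mu` must lie in (0, 1]", call. = FALSE)
  step <- alpha * abs(mbest - x_t) * log(1 / mu)
  ifelse(mu > 0.5, p - step, p + step)
}

#' Segment an image with the QPSO baseline
#'
#' Runs the shared particle-swarm clustering loop with the wormhole branch
#' disabled: meetings between two clustered (seed) particles fall through to
#' the plain QPSO position update. Equivalent to [qwpso_segment()] with
#' `wormhole_enabled = FALSE`; the outputs are bitwise identical for matched
#' seeds.
#'
#' @param image a [gray_image()].
#' @param qp [qpso_params()].
#' @param cp [cluster_params()].
#' @param seed integer RNG seed; the run is deterministic given the seed.
#' @param polarity `"bright-object"` (default) or `"dark-object"`.
#' @return A `segmentation_result`; see [qwpso_segment()].
#' @export
qpso_segment <- function(image, qp = qpso_params(), cp = cluster_params(),
                         seed = 1L, polarity = "bright-object") {
  cfg <- qwpso_config(qpso = qp, cluster = cp, wormhole = wormhole_params(),
                      polarity = polarity, seed = seed,
                      wormhole_enabled = FALSE)
  res <- qwpso_segment(image, cfg)
  res$method <- "qpso"
  res
}
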