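#' Maximum admissible angular separation (degrees)
#'
#' The angular separation between two disc-embedded clusters is restricted to
#' `(0, 57.32]` degrees (57.32 ~ 360/(2*pi)). Relative to the full 0-360
#' degree range effectively explored by the unconstrained QPSO sampling law,
#' this window occupies `100 * 57.32 / 360` percent; see
#' [angular_range_ratio()].
#'
#' @return The numeric constant 57.32.
#' @export
delta_theta_max <- function() 57.32

#' @rdname delta_theta_max
#' @return `angular_range_ratio()`: the percentage `100 * 57.32 / 360`.
#' @export
angular_range_ratio <- function() 100 * delta_theta_max() / 360

#' Wormhole geometry parameters
#'
#' Parameters of the hyperbolic-disc wormhole measure. A cluster is embedded
#' at radial coordinate `r` (scaled so the disc radius `R = disc_radius`
#' corresponds to an image corner) and angular coordinate `theta`. The number
#' of nodes a disc of radius `R` supports scales as `N = c * exp(R/2)`, with
#' `c = avg_degree_c` controlling the average degree; node angles are uniform
#' and radial density falls off as [node_radial_density()]. Two clusters are
#' linked when the connection probability of their path length reaches
#' `connect_prob_min`.
#'
#' @param zeta positive distance coefficient of the path measure.
#' @param disc_radius positive hyperbolic disc radius `R`.
#' @param avg_degree_c positive disc constant `c` in `N = c * exp(R/2)`.
#' @param delta_theta_policy `"measured"` (compute the angular separation per
#'   cluster pair from the disc embedding) or `"fixed"` (use
#'   `delta_theta_fixed` throughout).
#' @param delta_theta_fixed angular separation in degrees used under the
#'   `"fixed"` policy; must lie in `(0, 57.32)`.
#' @param connect_prob_min connection-probability threshold in `(0, 1]`.
#' @return A list of class `"wormhole_params"`.
#' @export
wormhole_params <- function(zeta = 1, disc_radius = 10, avg_degree_c = 1,
                            delta_theta_policy = c("measured", "fixed"),
                            delta_theta_fixed = 0.6,
                            connect_prob_min = 0.5) {
  delta_theta_policy <- match.arg(delta_theta_policy)
  if (!is.numeric(zeta) || length(zeta) != 1L || is.na(zeta) || zeta <= 0)
    stop("`zeta` must be a single positive number", call. = FALSE)
  if (!is.numeric(disc_radius) || disc_radius <= 0)
    stop("`disc_radius` must be positive", call. = FALSE)
  if (!is.numeric(avg_degree_c) || avg_degree_c <= 0)
    stop("`avg_degree_c` must be positive", call. = FALSE)
  if (identical(delta_theta_policy, "fixed") &&
      (delta_theta_fixed <= 0 || delta_theta_fixed >= delta_theta_max()))
    stop("`delta_theta_fixed` must lie in (0, 57.32)", call. = FALSE)
  if (!is.numeric(connect_prob_min) || connect_prob_min <= 0 || connect_prob_min > 1)
    stop("`connect_prob_min` must lie in (0, 1]", call. = FALSE)
  structure(list(zeta = as.numeric(zeta),
                 disc_radius = as.numeric(disc_radius),
                 avg_degree_c = as.numeric(avg_degree_c),
                 delta_theta_policy = delta_theta_policy,
                 delta_theta_fixed = as.numeric(delta_theta_fixed),
                 connect_prob_min = as.numeric(connect_prob_min)),
            class = "wormhole_params")
}

#' Hyperbolic wormhole path length
#'
#' The wormhole measure of the hyperbolic path between two embedded nodes at
#' radial coordinates `r` and `r_prime` with angular separation `delta_theta`
#' (degrees): `x = r + r_prime + (2/zeta) * log(delta_theta / 2)`. Symmetric
#' in `(r, r_prime)` and strictly increasing in `delta_theta`.
#'
#' @param r,r_prime radial coordinates (non-negative).
#' @param delta_theta angular separation in degrees, `> 0`.
#' @param zeta positive distance coefficient.
#' @return Path length(s).
#' @export
hyperbolic_path_length <- function(r, r_prime, delta_theta, zeta) {
  if (any(delta_theta <= 0))
    stop("`delta_theta` must be positive", call. = FALSE)
  if (!is.numeric(zeta) || any(zeta <= 0))
    stop("`zeta` must be positive", call. = FALSE)
  r + r_prime + (2 / zeta) * log(delta_theta / 2)
}

#' Radial node density of the wormhole disc
#'
#' The approximate node density at radial coordinate `r` of the hyperbolic
#' disc: `rho(r) = exp(-zeta * r / 2)`, strictly decreasing in `r`.
#'
#' @param r radial coordinate(s).
#' @param zeta positive distance coefficient.
#' @return Density value(s).
#' @export
node_radial_density <- function(r, zeta) {
  if (!is.numeric(zeta) || any(zeta <= 0))
    stop("`zeta` must be positive", call. = FALSE)
  exp(-zeta * r / 2)
}

#' Wormhole connection probability
#'
#' The probability that two nodes at hyperbolic path length `x` are linked:
#' `P = exp(zeta * (x - R) / 2)`, clamped at 1 for `x > R` so the result is a
#' valid probability. Non-decreasing in `x`.
#'
#' @param x path length(s) from [hyperbolic_path_length()].
#' @param params a [wormhole_params()].
#' @return Probability value(s) in `[0, 1]`.
#' @export
connection_probability <- function(x, params = wormhole_params()) {
  pmin(1, exp(params$zeta * (x - params$disc_radius) / 2))
}

#' Wormhole particle position
#'
#' Position sampling under the wormhole path measure:
#' `p_id + sign * (2/zeta) * log(delta_theta / 2)`. The logarithm's argument
#' is bounded by the admissible angular range, so steps are bounded, unlike
#' the unbounded `log(1/u)` of [sample_well_position()].
#'
#' @param p_id attractor coordinate(s).
#' @param delta_theta angular separation in degrees, `> 0`.
#' @param zeta positive distance coefficient.
#' @param sign `+1` or `-1`.
#' @return Coordinate(s).
#' @export
wormhole_position <- function(p_id, delta_theta, zeta, sign = 1) {
  if (any(delta_theta <= 0))
    stop("`delta_theta` must be positive", call. = FALSE)
  if (!is.numeric(zeta) || any(zeta <= 0))
    stop("`zeta` must be positive", call. = FALSE)
  p_id + sign * (2 / zeta) * log(delta_theta / 2)
}

#' Wormhole position update
#'
#' The iterative update used when two seed clusters meet, applied per
#' coordinate axis. For `delta_theta > 2`:
#' `x(t+1) = p_t - (2/zeta) * |mbest - x_t| * log(delta_theta / 2)`;
#' for `delta_theta <= 2` the term is added instead. The signed logarithm is
#' kept literal (no absolute value), so both branches coincide with the
#' attractor exactly at `delta_theta = 2`.
#'
#' @param x_t current coordinate(s).
#' @param p_t attractor coordinate(s).
#' @param mbest mean best coordinate(s).
#' @param delta_theta angular separation in degrees, `> 0`.
#' @param zeta positive distance coefficient.
#' @return Updated coordinate(s).
#' @export
wormhole_update <- function(x_t, p_t, mbest, delta_theta, zeta) {
  if (any(delta_theta <= 0))
    stop("`delta_theta` must be positive", call. = FALSE)
  if (!is.numeric(zeta) || any(zeta <= 0))
    stop("`zeta` must be positive", call. = FALSE)
  term <- (2 / zeta) * abs(mbest - x_t) * log(delta_theta / 2)
  ifelse(delta_theta > 2, p_t - term, p_t + term)
}

# internal: embed a centroid (0-based row, col) of an h x w image
disc_embed_point <- function(centroid, h, w, disc_radius) {
  center <- c((h - 1) / 2, (w - 1) / 2)
  half_diag <- sqrt(sum(center^2))
  d <- centroid - center
  dist <- sqrt(sum(d^2))
  r <- if (half_diag > 0) dist / half_diag * disc_radius else 0
  # polar angle about the image center: 0 deg along +col, increasing toward +row
  theta <- if (dist == 0) 0 else (atan2(d[1], d[2]) * 180 / pi) %% 360
  structure(list(r = r, theta = theta), class = "disc_coords")
}

#' Embed a cluster in the hyperbolic disc
#'
#' Maps a cluster to disc coordinates: `r` is the Euclidean distance of the
#' cluster centroid from the image center, normalized by the center-to-corner
#' half-diagonal and scaled to `disc_radius`; `theta` is the polar angle of
#' the centroid about the image center in degrees in `[0, 360)` (0 along the
#' +column axis). A centroid at the image center maps to `r = 0`; a corner
#' pixel maps to `r = disc_radius`.
#'
#' @param cluster a [pixel_cluster()].
#' @param image the [gray_image()] the cluster lives in.
#' @param disc_radius the disc radius `R`.
#' @return A list of class `"disc_coords"` with fields `r` and `theta`.
#' @export
disc_embed <- function(cluster, image, disc_radius = 10) {
  disc_embed_point(cluster$centroid, nrow(image), ncol(image), disc_radius)
}

#' Angular separation of two embedded clusters
#'
#' The minimal absolute angular difference `|theta_a - theta_b|`, folded into
#' `[0, 180]` and clamped into the admissible range `[0.01, 57.32]` degrees.
#'
#' @param a,b `disc_coords` from [disc_embed()], or bare numeric angles in
#'   degrees.
#' @return Angular separation in degrees, always within `[0.01, 57.32]`.
#' @export
angular_separation <- function(a, b) {
  ta <- if (is.list(a)) a$theta else a
  tb <- if (is.list(b)) b$theta else b
  d <- abs(ta - tb) %% 360
  d <- ifelse(d > 180, 360 - d, d)
  pmin(pmax(d, 0.01), delta_theta_max())
}
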