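# Speed and direction marginals of a fitted displacement density: the two
# low-dimensional views of the 3-D movement-preference model.

# Fibonacci sphere: nearly equal-area direction set of size n.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) + 1) * i           # golden-angle azimuths
  cz <- 1 - 2 * i / n
  sz <- sqrt(pmax(0, 1 - cz^2))
  cbind(sz * cos(phi), sz * sin(phi), cz)
}

#' Speed marginal of a fitted displacement density
#'
#' The probability density of the per-frame displacement magnitude
#' \eqn{r = \lVert x \rVert} (cube-normalized, so \eqn{0 \le r \le
#' \sqrt 3}) under a fitted density. For each grid radius the density is
#' integrated over all directions via a near-equal-area spherical rule,
#' with directions leaving the cube clipped, then renormalized so the
#' trapezoid integral over the grid is exactly 1.
#'
#' @param f A `maxent_density`.
#' @param n_grid Number of speed grid points (default 200).
#' @param n_dir Spherical quadrature directions per radius (default 8192).
#' @return A `marginal_speed` tibble with columns `speed` (normalized
#'   displacement per frame) and `density`.
#' @export
speed_marginal <- function(f, n_grid = 200L, n_dir = 8192L) {
  r <- seq(0, sqrt(3), length.out = n_grid)
  U <- fibonacci_sphere(n_dir)
  dens <- vapply(r, function(ri) {
    pts <- U * ri
    inside <- abs(pts[, 1]) <= 1 & abs(pts[, 2]) <= 1 & abs(pts[, 3]) <= 1
    if (!any(inside)) return(0)
    fv <- density_eval(f, pts[inside, , drop = FALSE])
    ri^2 * (4 * pi / n_dir) * sum(fv)
  }, numeric(1))
  total <- pracma::trapz(r, dens)
  structure(tibble(speed = r, density = dens / total),
            class = c("marginal_speed", class(tibble())),
            k = f$k)
}

#' Direction marginal of a fitted displacement density on the sphere
#'
#' The probability density (per steradian) of the movement direction
#' \eqn{u = x / \lVert x \rVert} under a fitted density:
#' \eqn{q(u) \propto \int_0^{R(u)} f(r u)\, r^2\, dr}, where
#' \eqn{R(u) = 1 / \max_i |u_i|} is the distance to the cube boundary
#' along \eqn{u}. Directions are laid out on a Gauss-Legendre-in-latitude
#' by uniform-azimuth grid (antipodally symmetric, with exact area
#' weights); the radial integral uses Gauss-Legendre nodes. Normalized so
#' the weighted sum over the sphere is 1. Convention: +y is forward,
#' +z vertical.
#'
#' @param f A `maxent_density`.
#' @param n_grid Approximate number of direction pixels (default 2048,
#'   realized as an n x 2n latitude-azimuth grid).
#' @param n_radial Radial quadrature nodes per direction (default 32).
#' @return A `marginal_direction` tibble with columns `azimuth` (radians,
#'   measured in the horizontal plane from +x toward +y), `elevation`
#'   (radians from the horizontal), `weight` (pixel solid angle,
#'   steradians) and `density` (per steradian).
#' @export
direction_marginal <- function(f, n_grid = 2048L, n_radial = 32L) {
  n_el <- max(4L, floor(sqrt(n_grid / 2)))
  n_az <- 2L * n_el
  gl <- pracma::gaussLegendre(n_el, -1, 1)   # nodes in cos(colatitude)
  cz <- gl$x
  w_el <- gl$w
  az <- 2 * pi * (seq_len(n_az) - 0.5) / n_az
  grid <- expand.grid(iaz = seq_len(n_az), iel = seq_len(n_el))
  cu <- cz[grid$iel]
  su <- sqrt(pmax(0, 1 - cu^2))
  U <- cbind(su * cos(az[grid$iaz]), su * sin(az[grid$iaz]), cu)
  w <- w_el[grid$iel] * (2 * pi / n_az)

  Rmax <- 1 / pmax(abs(U[, 1]), abs(U[, 2]), abs(U[, 3]))
  glr <- pracma::gaussLegendre(n_radial, 0, 1)
  # radial nodes per direction: r = Rmax * t, dr = Rmax dt
  q_int <- numeric(nrow(U))
  for (j in seq_len(n_radial)) {
    r_j <- Rmax * glr$x[j]
    fv <- density_eval(f, U * r_j)
    q_int <- q_int + glr$w[j] * Rmax * r_j^2 * fv
  }
  total <- sum(w * q_int)
  structure(
    tibble(azimuth = az[grid$iaz],
           elevation = asin(cu),
           weight = w,
           density = q_int / total),
    class = c("marginal_direction", class(tibble())),
    k = f$k
  )
}

#' Cumulative distribution of a speed marginal
#'
#' Trapezoid-integrated CDF on the marginal's grid; used for
#' Kolmogorov-Smirnov comparisons against sampled speeds.
#'
#' @param marg A `marginal_speed` tibble.
#' @return A function mapping speed to cumulative probability.
#' @export
speed_cdf <- function(marg) {
  cum <- pracma::cumtrapz(marg$speed, marg$density)[, 1]
  cum <- cum / cum[length(cum)]
  stats::approxfun(marg$speed, cum, yleft = 0, yright = 1, rule = 2)
}

#' @export
autoplot.marginal_speed <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$speed, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "normalized speed (displacement per frame)",
                  y = "probability density",
                  title = "Speed marginal of fitted displacement density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.marginal_direction <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$azimuth, y = .data$elevation,
                               fill = .data$density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "density\n(per sr)") +
    ggplot2::labs(x = "azimuth (rad; pi/2 = forward)",
                  y = "elevation (rad)",
                  title = "Direction marginal of fitted displacement density") +
    ggplot2::theme_minimal()
}

#' Plot the speed marginal
#' @param f A `maxent_density`.
#' @param ... Passed to [speed_marginal()].
#' @return A ggplot object.
#' @export
plot_speed_marginal <- function(f, ...) autoplot(speed_marginal(f, ...))

#' Plot the direction marginal
#' @param f A `maxent_density`.
#' @param ... Passed to [direction_marginal()].
#' @return A ggplot object.
#' @export
plot_direction_marginal <- function(f, ...) autoplot(direction_marginal(f, ...))
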