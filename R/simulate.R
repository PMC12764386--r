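# Synthetic spatial study designs with known labels: a center ball with two
# linear response functions, a ring with two nonlinear functions, and a
# sun-and-moon pair of compact regions plus background with three nonlinear
# functions and configurable Gaussian response noise.

in_disc <- function(s, center, radius) {
  (s[, 1] - center[1])^2 + (s[, 2] - center[2])^2 <= radius^2
}

# Evaluate a per-cluster response map: f(x) or f(s, x) depending on arity.
# x rows are passed as vectors so defaults like f(x) = 3*x[1] + 2*x[2] work.
eval_response <- function(f, s, x) {
  n <- nrow(x)
  if (length(formals(f)) >= 2L) {
    vapply(seq_len(n), function(i) f(s[i, ], x[i, ]), numeric(1))
  } else {
    vapply(seq_len(n), function(i) f(x[i, ]), numeric(1))
  }
}

check_domain <- function(domain) {
  if (length(domain) != 2L || !all(is.finite(domain)) ||
      domain[2] <= domain[1]) {
    stop("'domain' must be a finite (lower, upper) interval", call. = FALSE)
  }
  domain
}

# Draw the common ingredients: s, x uniform on the domain rectangle, in a
# fixed order (s, then x, then noise) so datasets are bitwise reproducible.
draw_uniforms <- function(n, p, domain, noise_var, seed) {
  with_seed(seed, {
    s <- matrix(stats::runif(2 * n, domain[1], domain[2]), n, 2)
    x <- matrix(stats::runif(n * p, domain[1], domain[2]), n, p)
    eps <- if (noise_var > 0) stats::rnorm(n, 0, sqrt(noise_var)) else
      numeric(n)
    list(s = s, x = x, eps = eps)
  })
}

check_noise <- function(noise_var) {
  if (!is.numeric(noise_var) || length(noise_var) != 1L ||
      !is.finite(noise_var) || noise_var < 0) {
    stop("'noise_var' must be a single non-negative number", call. = FALSE)
  }
  noise_var
}

finish_sim <- function(draw, labels, functions, noise_var) {
  y <- numeric(length(labels))
  for (j in seq_along(functions)) {
    idx <- which(labels == j)
    if (length(idx) > 0L) {
      y[idx] <- eval_response(functions[[j]], draw$s[idx, , drop = FALSE],
                              draw$x[idx, , drop = FALSE])
    }
  }
  spatial_dataset(draw$s, draw$x, y + draw$eps, true_labels = labels)
}

#' Center-ball design with two linear response functions
#'
#' Locations and covariates are independent uniforms on the domain square;
#' the spatial domain splits into a central ball (cluster 1) and the
#' background (cluster 2), each with its own linear response map. By
#' construction there is essentially no marginal separation in `s`, `x` or
#' `y` alone — the clusters differ only in the functional relation between
#' covariates and response.
#'
#' @param n Number of observations.
#' @param noise_var Variance of additive zero-mean Gaussian response noise.
#' @param seed RNG seed; the same seed reproduces the dataset bitwise.
#' @param p Number of covariates.
#' @param domain (lower, upper) bounds of the square from which both `s` and
#'   `x` coordinates are drawn.
#' @param ball_center,ball_radius Geometry of the central ball; the ball must
#'   lie inside the domain.
#' @param f_ball,f_background Response maps, functions of a covariate vector
#'   `x` (or of `(s, x)`).
#' @return A [spatial_dataset()] with `true_labels` (1 = ball, 2 =
#'   background).
#' @export
simulate_linear_ball <- function(n = 800, noise_var = 0, seed = 1, p = 2,
                                 domain = c(0, 1),
                                 ball_center = c(0.5, 0.5), ball_radius = 0.25,
                                 f_ball = function(x) 3 * x[1] + 2 * x[2],
                                 f_background = function(x) -3 * x[1] - 2 * x[2]) {
  domain <- check_domain(domain)
  check_noise(noise_var)
  if (any(ball_center - ball_radius < domain[1]) ||
      any(ball_center + ball_radius > domain[2])) {
    stop("invalid geometry: the ball is not contained in the domain",
         call. = FALSE)
  }
  draw <- draw_uniforms(n, p, domain, noise_var, seed)
  labels <- ifelse(in_disc(draw$s, ball_center, ball_radius), 1L, 2L)
  finish_sim(draw, labels, list(f_ball, f_background), noise_var)
}

#' Ring design with two nonlinear response functions
#'
#' As [simulate_linear_ball()] but the first cluster is an annulus
#' (`inner_radius <= ||s - center|| <= outer_radius`) and the two response
#' maps are nonlinear, so no method relying on linear structure can separate
#' the clusters.
#'
#' @inheritParams simulate_linear_ball
#' @param ring_center Center of the annulus.
#' @param inner_radius,outer_radius Annulus radii, `inner_radius <
#'   outer_radius`.
#' @param f_ring,f_background Response maps for the ring (cluster 1) and the
#'   background (cluster 2).
#' @return A [spatial_dataset()] with `true_labels` (1 = ring, 2 =
#'   background).
#' @export
simulate_nonlinear_ring <- function(n = 800, noise_var = 0, seed = 1, p = 2,
                                    domain = c(0, 1),
                                    ring_center = c(0.5, 0.5),
                                    inner_radius = 0.25, outer_radius = 0.4,
                                    f_ring = function(x)
                                      5 * sin(2 * pi * x[1]) + 5 * cos(2 * pi * x[2]),
                                    f_background = function(x)
                                      5 * (x[1]^2 + x[2]^2)) {
  domain <- check_domain(domain)
  check_noise(noise_var)
  if (inner_radius >= outer_radius || inner_radius < 0) {
    stop("invalid geometry: need 0 <= inner_radius < outer_radius",
         call. = FALSE)
  }
  draw <- draw_uniforms(n, p, domain, noise_var, seed)
  d2 <- (draw$s[, 1] - ring_center[1])^2 + (draw$s[, 2] - ring_center[2])^2
  labels <- ifelse(d2 >= inner_radius^2 & d2 <= outer_radius^2, 1L, 2L)
  finish_sim(draw, labels, list(f_ring, f_background), noise_var)
}

#' Sun-and-moon design with three response functions and noise
#'
#' Two compact regions — the "sun" and the "moon", interpretable as two urban
#' centers inside a larger rural background — each carry a distinct nonlinear
#' response map, with the background as a third cluster. Additive zero-mean
#' Gaussian noise of variance `noise_var` is added to the response, making
#' this the design for studying robustness to noise and to an overspecified
#' number of clusters.
#'
#' The default response maps combine distinct mean levels with distinct
#' nonlinear shapes (an oscillatory sun, a shifted quadratic moon, a
#' negatively shifted interaction for the background), emulating systematic
#' urban/rural response-regime differences. Their scale is chosen so that the
#' separation between any two maps dominates response noise up to variance
#' of order 100, the noisiest regime this design is meant to probe: per-point
#' assignment by prediction error with the true maps still recovers the
#' clusters there, while substantially weaker separation would make recovery
#' impossible for any error-based rule.
#'
#' @inheritParams simulate_linear_ball
#' @param sun_center,sun_radius Geometry of the sun disc (cluster 1).
#' @param moon_center,moon_radius Geometry of the moon (cluster 2).
#' @param moon_shape `"disc"` (default) or `"crescent"`; a crescent is the
#'   moon disc minus a bite disc of the same radius offset by
#'   `crescent_offset` (points in the bite belong to the background).
#' @param crescent_offset Offset of the bite disc for `moon_shape =
#'   "crescent"`.
#' @param f_sun,f_moon,f_background Response maps for the three clusters.
#' @return A [spatial_dataset()] with `true_labels` (1 = sun, 2 = moon, 3 =
#'   background).
#' @export
simulate_sun_moon <- function(n = 900, noise_var = 0, seed = 1, p = 2,
                              domain = c(0, 1),
                              sun_center = c(0.3, 0.5), sun_radius = 0.15,
                              moon_center = c(0.7, 0.5), moon_radius = 0.15,
                              moon_shape = c("disc", "crescent"),
                              crescent_offset = c(0.07, 0),
                              f_sun = function(x)
                                60 * sin(2 * pi * x[1]) + 60 * cos(2 * pi * x[2]),
                              f_moon = function(x)
                                80 + 60 * (x[1]^2 + x[2]^2),
                              f_background = function(x)
                                -80 - 120 * x[1] * x[2]) {
  domain <- check_domain(domain)
  check_noise(noise_var)
  moon_shape <- match.arg(moon_shape)
  if (sqrt(sum((sun_center - moon_center)^2)) < sun_radius + moon_radius) {
    stop("invalid geometry: sun and moon regions overlap", call. = FALSE)
  }
  draw <- draw_uniforms(n, p, domain, noise_var, seed)
  in_sun <- in_disc(draw$s, sun_center, sun_radius)
  in_moon <- in_disc(draw$s, moon_center, moon_radius)
  if (moon_shape == "crescent") {
    bite <- in_disc(draw$s, moon_center + crescent_offset, moon_radius)
    in_moon <- in_moon & !bite
  }
  labels <- ifelse(in_sun, 1L, ifelse(in_moon, 2L, 3L))
  finish_sim(draw, labels, list(f_sun, f_moon, f_background), noise_var)
}

#' Run a simulation design by name
#'
#' Dispatches to [simulate_linear_ball()], [simulate_nonlinear_ring()] or
#' [simulate_sun_moon()].
#'
#' @param design One of `"linear_ball"`, `"nonlinear_ring"`, `"sun_moon"`.
#' @param ... Passed to the design's generator.
#' @return A [spatial_dataset()].
#' @export
simulate_design <- function(design = c("linear_ball", "nonlinear_ring",
                                       "sun_moon"), ...) {
  design <- match.arg(design)
  switch(design,
         linear_ball = simulate_linear_ball(...),
         nonlinear_ring = simulate_nonlinear_ring(...),
         sun_moon = simulate_sun_moon(...))
}
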