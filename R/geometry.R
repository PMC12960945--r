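#' Volume of a d-ball
#'
#' @param r Radius (vectorised, `>= 0`).
#' @param d Dimension, 1 (length), 2 (area) or 3 (volume).
#' @return `V_d * r^d`.
#' @export
ball_volume <- function(r, d) {
  if (!d %in% 1:3) stop("'d' must be 1, 2 or 3")
  unit_ball_volume(d) * r^d
}

#' Overlap volume of two d-balls
#'
#' d-volume of the intersection of a ball of radius `r1` with a ball of radius
#' `r2` whose centre lies at distance `dist`. In 1D this is the interval
#' overlap, in 2D the circle-circle lens area, in 3D the spherical-lens
#' volume. All arguments are vectorised and recycled.
#'
#' @param r1,r2 Radii (`>= 0`).
#' @param dist Centre separation (`>= 0`).
#' @param d Dimension (1, 2 or 3).
#' @return Overlap d-volume.
#' @export
ball_overlap_volume <- function(r1, r2, dist, d) {
  if (!d %in% 1:3) stop("'d' must be 1, 2 or 3")
  n <- max(length(r1), length(r2), length(dist))
  r1 <- rep_len(pmax(r1, 0), n)
  r2 <- rep_len(pmax(r2, 0), n)
  dist <- rep_len(dist, n)
  out <- numeric(n)
  disjoint <- dist >= r1 + r2
  contained <- dist <= abs(r1 - r2)  # smaller ball inside larger
  lens <- !disjoint & !contained
  if (any(contained)) {
    out[contained] <- ball_volume(pmin(r1[contained], r2[contained]), d)
  }
  if (any(lens)) {
    a <- r1[lens]; b <- r2[lens]; s <- dist[lens]
    out[lens] <- switch(d,
      # 1D: overlap of [-a, a] and [s - b, s + b]
      pmin(a, s + b) - pmax(-a, s - b),
      {
        # 2D circular lens
        ca <- pmin(pmax((s^2 + a^2 - b^2) / (2 * s * a), -1), 1)
        cb <- pmin(pmax((s^2 + b^2 - a^2) / (2 * s * b), -1), 1)
        tri <- (-s + a + b) * (s + a - b) * (s - a + b) * (s + a + b)
        a^2 * acos(ca) + b^2 * acos(cb) - 0.5 * sqrt(pmax(tri, 0))
      },
      {
        # 3D spherical lens
        pi * (a + b - s)^2 *
          (s^2 + 2 * s * b - 3 * b^2 + 2 * s * a + 6 * a * b - 3 * a^2) /
          (12 * s)
      })
  }
  pmax(out, 0)
}

#' Monte-Carlo overlap estimate
#'
#' Estimates the same quantity as [ball_overlap_volume()] by uniform sampling
#' inside the first ball and counting points that also fall in the second.
#' Used as an independent geometric oracle for the analytic lens formulas.
#'
#' @inheritParams ball_overlap_volume
#' @param n Number of sample points.
#' @return Estimated overlap volume (scalar arguments only).
#' @export
ball_overlap_volume_mc <- function(r1, r2, dist, d, n = 1e6) {
  stopifnot(length(r1) == 1L, length(r2) == 1L, length(dist) == 1L)
  if (r1 <= 0 || r2 <= 0) return(0)
  # uniform points in the r1-ball centred at the origin; second centre on axis 1
  u <- r1 * stats::runif(n)^(1 / d)
  x1 <- if (d == 1) {
    u * sign(stats::runif(n) - 0.5)
  } else if (d == 2) {
    phi <- stats::runif(n, 0, 2 * pi)
    u * cos(phi)
  } else {
    u * stats::runif(n, -1, 1)  # cosine of polar angle is uniform
  }
  perp2 <- u^2 - x1^2
  inside <- (x1 - dist)^2 + perp2 <= r2^2
  ball_volume(r1, d) * mean(inside)
}
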