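# Analytic contact backend: sphere primitive (patellar button) against a
# fitted polynomial surface (femoral implant). Contact iff the distance from
# the sphere center to the surface is smaller than the sphere radius.

#' Sphere primitive in the patella body frame
#' @param center length-3 local center (m).
#' @param radius sphere radius (m), > 0.
#' @export
sphere_primitive <- function(center = c(0, 0, 0), radius) {
  stopifnot(radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "pf_sphere")
}

# f, fx, fy, fxx, fxy, fyy of the fitted surface at scalar (x, y)
surface_eval2 <- function(surface, x, y) {
  s <- surface$scaled
  ft <- surface$fast
  e <- cpp_surface_eval2(s$coef, ft$ei, ft$ej, ft$order, s$cx, s$cy,
                         s$sx, s$sy, x, y)
  list(f = e[1], fx = e[2], fy = e[3], fxx = e[4], fxy = e[5], fyy = e[6])
}

#' Closest point on a polynomial surface to a world point
#'
#' Multi-start damped Newton on the two-variable stationarity system of
#' `min_(x,y) ||(x, y, f(x,y)) - c||^2`, seeded from the vertical projection
#' of the query point plus a ring of 8 starts around it (guards against
#' multiple local minima near the groove ridges). If the minimizer leaves the
#' fit domain, the result is clamped to the domain boundary and flagged.
#'
#' @param surface `pf_poly_surface` (surface frame = its fitting frame).
#' @param c_world query point, world frame.
#' @param pose surface pose `list(x =, q =)` (default identity).
#' @param warm_start optional `(x, y)` seed from a previous query.
#' @param domain_margin fractional inflation of the fit domain accepted before
#'   clamping.
#' @return list: `p` (closest surface point, world), `distance` (signed,
#'   positive on the +z side of the surface), `normal` (world unit surface
#'   normal at p, +z side), `xy` (surface-frame footprint), `boundary`
#'   (TRUE if clamped), `residual` (stationarity residual, m).
#' @export
closest_point <- function(surface, c_world,
                          pose = list(x = c(0, 0, 0), q = c(1, 0, 0, 0)),
                          warm_start = NULL, domain_margin = 0.0) {
  stopifnot(inherits(surface, "pf_poly_surface"))
  R <- quat_to_mat(pose$q)
  cl <- drop(crossprod(R, c_world - pose$x))
  dom <- surface$fit_domain
  dx <- diff(dom$x); dy <- diff(dom$y)
  lox <- dom$x[1] - domain_margin * dx; hix <- dom$x[2] + domain_margin * dx
  loy <- dom$y[1] - domain_margin * dy; hiy <- dom$y[2] + domain_margin * dy
  sca <- surface$scaled; ft <- surface$fast
  damp_len <- 0.25 * max(dx, dy)
  run <- function(seeds)
    cpp_closest_multistart(sca$coef, ft$ei, ft$ej, ft$order, sca$cx, sca$cy,
                           sca$sx, sca$sy, cl, seeds, damp_len)
  best <- NULL
  if (!is.null(warm_start)) {
    best <- run(matrix(warm_start, 1, 2))
    # accept only an interior, converged stationary point from the warm seed
    if (!(best[3] < 1e-22 && best[1] > lox && best[1] < hix &&
          best[2] > loy && best[2] < hiy))
      best <- NULL
  }
  if (is.null(best)) {
    rad <- 0.18 * min(dx, dy)
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    seeds <- rbind(c(cl[1], cl[2]),
                   cbind(cl[1] + rad * cos(ang), cl[2] + rad * sin(ang)))
    seeds[, 1] <- pmin(pmax(seeds[, 1], lox), hix)
    seeds[, 2] <- pmin(pmax(seeds[, 2], loy), hiy)
    best <- run(seeds)
  }
  s <- best[1]; t <- best[2]
  boundary <- FALSE
  if (s < lox || s > hix || t < loy || t > hiy) {
    boundary <- TRUE
    s <- min(max(s, lox), hix)
    t <- min(max(t, loy), hiy)
    # refine along the clamped boundary (coordinate-wise 1-D golden search)
    obj <- function(ss, tt) {
      zz <- surface_height(surface, ss, tt)
      (ss - cl[1])^2 + (tt - cl[2])^2 + (zz - cl[3])^2
    }
    if (s %in% c(lox, hix)) {
      op <- stats::optimize(function(tt) obj(s, tt), c(loy, hiy))
      t <- op$minimum
    } else {
      op <- stats::optimize(function(ss) obj(ss, t), c(lox, hix))
      s <- op$minimum
    }
  }
  e <- surface_eval2(surface, s, t)
  nl <- c(-e$fx, -e$fy, 1) / sqrt(1 + e$fx^2 + e$fy^2)
  pl <- c(s, t, e$f)
  dvec <- cl - pl
  dist <- sqrt(sum(dvec * dvec)) * sign(sum(dvec * nl) + 1e-300)
  r <- e$f - cl[3]
  g <- c((s - cl[1]) + r * e$fx, (t - cl[2]) + r * e$fy)
  resid <- sqrt(sum(g * g)) / sqrt(1 + e$fx^2 + e$fy^2 + sum(g * g))
  list(p = drop(R %*% pl) + pose$x, distance = dist,
       normal = drop(R %*% nl), xy = c(s, t), boundary = boundary,
       residual = resid)
}

#' Sphere-versus-polynomial-surface contact
#'
#' Contact exists iff the distance from the sphere center to the surface is
#' smaller than the sphere radius; `delta = radius - distance`. A center
#' below the surface (sign flip) is treated as deep penetration with
#' `delta = radius + |distance|` and a warning. If the closest point clamps to
#' the fit-domain boundary the sphere has left the modeled surface: the
#' episode ends and the exit is logged as a candidate dislocation marker.
#'
#' @param sphere [sphere_primitive()].
#' @param sphere_pose pose of the patella body `list(x =, q =)`.
#' @param surface `pf_poly_surface`.
#' @param surface_pose pose of the femur surface frame.
#' @param twist_sphere,twist_surface optional twists `list(v =, w =)` (world
#'   linear velocity, body angular velocity) for `delta_dot`.
#' @param episodes optional [contact_episodes()] environment.
#' @param commit update episode state (accepted steps only).
#' @param warm_start optional footprint seed.
#' @return a `pf_contact_patch` (point, normal from surface toward sphere,
#'   delta, delta_dot, delta_dot0, xy footprint) or `NULL` if separated.
#' @export
sphere_surface_contact <- function(sphere, sphere_pose, surface, surface_pose,
                                   twist_sphere = NULL, twist_surface = NULL,
                                   episodes = NULL, commit = FALSE,
                                   warm_start = NULL) {
  stopifnot(inherits(sphere, "pf_sphere"))
  Rs <- quat_to_mat(sphere_pose$q)
  cw <- drop(Rs %*% sphere$center) + sphere_pose$x
  cp <- closest_point(surface, cw, surface_pose, warm_start = warm_start)
  # footprint cache: pure speed-up for the next query's Newton seed
  if (!is.null(episodes)) episodes$warm <- cp$xy
  if (cp$boundary) {
    if (!is.null(episodes) && commit) {
      if (length(episodes$active))
        episode_log(episodes, list(type = "domain_exit", xy = cp$xy))
      episodes_end_all(episodes)
    }
    return(NULL)
  }
  if (cp$distance >= sphere$radius) {
    if (!is.null(episodes) && commit) episodes_end_all(episodes)
    return(NULL)
  }
  if (cp$distance < 0) {
    # deep penetration is honored only as the continuation of an existing
    # episode (or a sub-radius overshoot); a center arriving from below the
    # surface is not a new contact
    active <- !is.null(episodes) && length(episodes$active) > 0
    if (!active && abs(cp$distance) >= 0.5 * sphere$radius) {
      if (!is.null(episodes) && commit) episodes_end_all(episodes)
      return(NULL)
    }
    if (commit) warning("sphere center below surface: deep penetration",
                        call. = FALSE)
    delta <- sphere$radius + min(abs(cp$distance), sphere$radius)
  } else {
    delta <- sphere$radius - cp$distance
  }
  # normal oriented from the surface toward the sphere center
  n <- cp$normal
  if (sum(n * (cw - cp$p)) < 0) n <- -n
  delta_dot <- 0
  if (!is.null(twist_sphere)) {
    vs <- twist_sphere$v +
      drop(Rs %*% cross3(twist_sphere$w, sphere$center))
    vf <- c(0, 0, 0)
    if (!is.null(twist_surface)) {
      Rf <- quat_to_mat(surface_pose$q)
      vf <- twist_surface$v +
        drop(Rf %*% cross3(twist_surface$w,
                           drop(crossprod(Rf, cp$p - surface_pose$x))))
    }
    delta_dot <- -sum((vs - vf) * n)
  }
  dd0 <- if (!is.null(episodes))
    episode_delta_dot0(episodes, 1L, delta, delta_dot, commit) else NA_real_
  if (!is.null(episodes) && commit) episodes_keep_active(episodes, 1L)
  structure(list(point = cp$p, normal = n, delta = delta,
                 delta_dot = delta_dot, delta_dot0 = dd0,
                 xy = cp$xy, closed = TRUE),
            class = "pf_contact_patch")
}
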