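# Synthetic test-bench geometry: the trochlear-groove height field with a
# known analytic ground truth (stand-in for the undeposited implant CAD) and
# the icosphere patellar button. All lengths in meters.

#' Construct a triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (m).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param outward logical flag recording whether face normals are consistently
#'   oriented outward / upward for this surface.
#' @return An object of class `pf_mesh` with fields `vertices`, `faces`,
#'   `face_normals` (unit row vectors) and `outward`.
#' @export
pf_mesh <- function(vertices, faces, outward = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) == 0L) stop("mesh has no faces")
  if (max(faces) > nrow(vertices) || min(faces) < 1L)
    stop("face indices out of range")
  fn <- face_normals_areas(vertices, faces)
  if (any(fn$area <= 0))
    stop("degenerate (zero-area) faces: ",
         paste(utils::head(which(fn$area <= 0), 5), collapse = ", "))
  structure(list(vertices = vertices, faces = faces,
                 face_normals = fn$normals, face_areas = fn$area,
                 outward = isTRUE(outward)),
            class = "pf_mesh")
}

# Per-face unit normals and areas (right-hand rule over vertex order).
face_normals_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n * n))
  list(normals = n / pmax(len, 1e-300), area = len / 2)
}

#' @export
print.pf_mesh <- function(x, ...) {
  cat("pf_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  bounds x [%.4f, %.4f]  y [%.4f, %.4f]  z [%.4f, %.4f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Trochlear-groove parameters of the synthetic femoral surface
#'
#' The synthetic implant surface is a smooth bivariate height field
#' `z = f(x, y)` in the femoral surface frame (x sagittal, positive proximal;
#' y medial-lateral, medial positive; z height off the groove floor):
#'
#' `f = x^2/(2 Rs) + d * [ gbar * (1 - s (x + X)/(2 X)) * (u^2 - u^4/2) + ((gm - gl)/2) u^3 ]`
#'
#' with `u = y / w`, `gbar = (gl + gm)/2`, `X = Rs * sin(arc/2)` the sagittal
#' half-extent. The cross-section has ridges near `u = +/-1`; the cubic term
#' makes the lateral ridge (negative y) higher when `lateral_ridge_gain` >
#' `medial_ridge_gain`; the taper `s` shallows the groove from its full depth
#' at the distal end (`x = -X`) down to a fraction `1 - s` at the proximal
#' entrance (`x = +X`), the dislocation-prone region. The form is a bivariate
#' polynomial of total order 5, so an order-5 polynomial fit of sampled
#' vertices is exact.
#'
#' @param sagittal_radius sagittal radius of curvature Rs (m).
#' @param groove_halfwidth transverse distance w from groove line to ridge (m).
#' @param groove_depth ridge height scale d (m).
#' @param lateral_ridge_gain,medial_ridge_gain dimensionless ridge-height
#'   gains; lateral >= medial mirrors the anatomy relevant to lateral
#'   dislocation.
#' @param arc_extent sagittal arc of the groove (rad), in (0, pi].
#' @param proximal_taper dimensionless shallowing of the groove toward the
#'   proximal end (+x), in [0, 1).
#' @param transverse_span half-width of the modeled surface in units of
#'   `groove_halfwidth` (covers the ridges and the drop beyond them).
#' @return Object of class `pf_groove_params`; field `analytic_form` holds the
#'   ground-truth height function `f(x, y)` and `analytic_grad` its gradient.
#' @export
groove_params <- function(sagittal_radius = 0.045,
                          groove_halfwidth = 0.019,
                          groove_depth = 0.015,
                          lateral_ridge_gain = 1.1,
                          medial_ridge_gain = 1.0,
                          arc_extent = 1.5,
                          proximal_taper = 0.68,
                          transverse_span = 1.10) {
  stopifnot(sagittal_radius > 0, groove_halfwidth > 0, groove_depth > 0,
            lateral_ridge_gain > 0, medial_ridge_gain > 0,
            arc_extent > 0, arc_extent <= pi,
            proximal_taper >= 0, proximal_taper < 1, transverse_span > 1)
  if (lateral_ridge_gain < medial_ridge_gain)
    stop("lateral_ridge_gain must be >= medial_ridge_gain")
  Rs <- sagittal_radius; w <- groove_halfwidth; d <- groove_depth
  gl <- lateral_ridge_gain; gm <- medial_ridge_gain
  X <- Rs * sin(arc_extent / 2)
  gbar <- (gl + gm) / 2
  sig <- (gm - gl) / 2
  s <- proximal_taper
  taper <- function(x) 1 - s * (x + X) / (2 * X)
  f <- function(x, y) {
    u <- y / w
    x^2 / (2 * Rs) + d * (gbar * taper(x) * (u^2 - 0.5 * u^4) + sig * u^3)
  }
  grad <- function(x, y) {
    u <- y / w
    fx <- x / Rs + d * gbar * (-s / (2 * X)) * (u^2 - 0.5 * u^4)
    fy <- (d / w) * (gbar * taper(x) * (2 * u - 2 * u^3) + 3 * sig * u^2)
    cbind(fx, fy)
  }
  structure(list(sagittal_radius = Rs, groove_halfwidth = w, groove_depth = d,
                 lateral_ridge_gain = gl, medial_ridge_gain = gm,
                 arc_extent = arc_extent, proximal_taper = s,
                 transverse_span = transverse_span,
                 half_extent_x = X, half_extent_y = w * transverse_span,
                 analytic_form = f, analytic_grad = grad),
            class = "pf_groove_params")
}

#' Mesh quality targets / measurements
#'
#' @param max_chordal_deviation largest distance from a face centroid to the
#'   reference surface (m).
#' @param max_normal_deviation largest angle between a face normal and the
#'   reference normal (degrees).
#' @export
mesh_quality_target <- function(max_chordal_deviation, max_normal_deviation) {
  stopifnot(max_chordal_deviation >= 0, max_normal_deviation >= 0)
  structure(list(max_chordal_deviation = max_chordal_deviation,
                 max_normal_deviation = max_normal_deviation),
            class = "pf_mesh_quality")
}

# Grid triangulation of a rectangular (x, y) lattice into a pf_mesh over a
# height function; optional y-density weight concentrates lines laterally.
triangulate_heightfield <- function(f, xs, ys) {
  nx <- length(xs); ny <- length(ys)
  g <- expand.grid(x = xs, y = ys)  # x varies fastest
  v <- cbind(g$x, g$y, f(g$x, g$y))
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  # two triangles per cell, counter-clockwise seen from +z
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  pf_mesh(v, rbind(f1, f2))
}

#' Generate the synthetic trochlear surface mesh
#'
#' Samples the analytic groove height field on a rectangular lattice and
#' triangulates it, refining the lattice until the measured mesh quality
#' (chordal deviation at face centroids, normal deviation) meets the requested
#' targets. Every emitted vertex lies exactly on the analytic surface.
#'
#' @param params a [groove_params()] object.
#' @param resolution a [mesh_quality_target()]; defaults to the coarse bench
#'   target (0.1 mm, 1 degree).
#' @param lateral_refine optional numeric > 0: grid-density weight
#'   concentrating transverse grid lines near the lateral ridge (the
#'   dislocation-critical region); 0 disables.
#' @param max_iter maximum refinement rounds before giving up.
#' @return `pf_mesh` with attributes `quality` (measured [mesh_quality_target()])
#'   and `params`.
#' @export
make_trochlear_surface <- function(params,
                                   resolution = mesh_quality_target(1e-4, 1.0),
                                   lateral_refine = 0,
                                   max_iter = 8L) {
  stopifnot(inherits(params, "pf_groove_params"),
            inherits(resolution, "pf_mesh_quality"),
            resolution$max_chordal_deviation > 0,
            resolution$max_normal_deviation > 0)
  X <- params$half_extent_x; Y <- params$half_extent_y
  # curvature-based initial spacing: e ~ kappa L^2 / 8, angle ~ kappa L / 2
  d <- params$groove_depth; w <- params$groove_halfwidth
  gbar <- (params$lateral_ridge_gain + params$medial_ridge_gain) / 2
  kap <- max(1 / params$sagittal_radius, 4 * d * gbar / w^2)
  L <- min(sqrt(8 * resolution$max_chordal_deviation / kap),
           4 * resolution$max_normal_deviation * pi / 180 / kap)
  ref <- list(type = "heightfield", f = params$analytic_form,
              grad = params$analytic_grad)
  max_nodes <- 4e6  # memory guard: beyond this the tolerance is unreachable
  for (it in seq_len(max_iter)) {
    nx <- max(8L, as.integer(ceiling(min(2 * X / L, 1e7))) + 1L)
    ny <- max(8L, as.integer(ceiling(min(2 * Y / L, 1e7))) + 1L)
    if (as.numeric(nx) * ny > max_nodes)
      stop("requested mesh quality unreachable (would need ",
           format(as.numeric(nx) * ny, digits = 3), " lattice nodes)")
    ys <- seq(-Y, Y, length.out = ny)
    if (lateral_refine > 0) {
      # concentrate transverse grid lines near the lateral ridge at y = -w by
      # equipartitioning the integral of a density bumped around it
      yy <- seq(-Y, Y, length.out = 512L)
      dens <- 1 + lateral_refine * exp(-((yy + w) / (0.5 * w))^2)
      cdf <- cumsum(dens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
      ys <- stats::approx(cdf, yy, xout = seq(0, 1, length.out = ny),
                          ties = "ordered")$y
      ys[1] <- -Y; ys[ny] <- Y
    }
    mesh <- triangulate_heightfield(params$analytic_form,
                                    seq(-X, X, length.out = nx), ys)
    q <- mesh_quality(mesh, ref)
    if (q$max_chordal_deviation <= resolution$max_chordal_deviation &&
        q$max_normal_deviation <= resolution$max_normal_deviation) {
      attr(mesh, "quality") <- q
      attr(mesh, "params") <- params
      attr(mesh, "grid") <- c(nx = nx, ny = ny)
      return(mesh)
    }
    # second-order chordal / first-order angle convergence, 10% safety
    L <- L * 0.9 * min(
      sqrt(resolution$max_chordal_deviation / q$max_chordal_deviation),
      resolution$max_normal_deviation / q$max_normal_deviation, 0.95)
  }
  stop("requested mesh quality unreachable within ", max_iter,
       " refinement rounds")
}

#' Generate an icosphere mesh
#'
#' Subdivided icosahedron with all vertices projected onto the sphere of the
#' requested radius; the regular triangulation avoids a pole vertex shared by
#' many triangles.
#'
#' @param radius sphere radius (m), > 0.
#' @param subdivisions subdivision level >= 0; faces = 20 * 4^subdivisions.
#' @param center sphere center (default origin).
#' @param max_subdivisions memory guard.
#' @return `pf_mesh`.
#' @export
make_icosphere <- function(radius, subdivisions = 2L, center = c(0, 0, 0),
                           max_subdivisions = 7L) {
  stopifnot(radius > 0, subdivisions >= 0)
  if (subdivisions > max_subdivisions)
    stop("subdivisions > ", max_subdivisions, " (memory guard)")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v * v))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m * m))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      edge_mid[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    k <- 0L
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[k + 1L, ] <- c(a, ab, ca)
      newf[k + 2L, ] <- c(b, bc, ab)
      newf[k + 3L, ] <- c(cc, ca, bc)
      newf[k + 4L, ] <- c(ab, bc, ca)
      k <- k + 4L
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  mesh <- pf_mesh(v, f)
  attr(mesh, "radius") <- radius
  attr(mesh, "center") <- center
  mesh
}

#' Measure mesh quality against an analytic reference surface
#'
#' Maximum over face centroids of the distance to the reference surface and of
#' the angle between the face normal and the reference normal at the
#' centroid's footprint.
#'
#' @param mesh a `pf_mesh` that projects one-to-one onto the reference domain.
#' @param reference either a [groove_params()] object, a list
#'   `list(type = "heightfield", f, grad)`, or
#'   `list(type = "sphere", center, radius)`.
#' @return a [mesh_quality_target()] with the measured values.
#' @export
mesh_quality <- function(mesh, reference) {
  stopifnot(inherits(mesh, "pf_mesh"))
  if (inherits(reference, "pf_groove_params"))
    reference <- list(type = "heightfield", f = reference$analytic_form,
                      grad = reference$analytic_grad)
  cen <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  if (identical(reference$type, "sphere")) {
    rel <- sweep(cen, 2, reference$center)
    rr <- sqrt(rowSums(rel * rel))
    dev <- abs(rr - reference$radius)
    nref <- rel / rr
  } else if (identical(reference$type, "heightfield")) {
    z <- reference$f(cen[, 1], cen[, 2])
    if (any(!is.finite(z)))
      stop("face centroids outside reference domain: faces ",
           paste(utils::head(which(!is.finite(z)), 5), collapse = ", "))
    g <- reference$grad(cen[, 1], cen[, 2])
    slope <- sqrt(1 + g[, 1]^2 + g[, 2]^2)
    # distance along the reference normal (first-order exact, exact for planes)
    dev <- abs(cen[, 3] - z) / slope
    nref <- cbind(-g[, 1], -g[, 2], 1) / slope
  } else stop("unknown reference type")
  ca <- rowSums(mesh$face_normals * nref)
  ang <- acos(pmax(-1, pmin(1, abs(ca)))) * 180 / pi
  mesh_quality_target(max(dev), max(ang))
}
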