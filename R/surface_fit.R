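# Bivariate polynomial approximation of the femoral contact surface.
# The fit is a weighted least-squares height field z = sum c_ij x^i y^j over
# all i + j <= order, solved by QR on a centered/scaled monomial basis (the
# centering keeps the order-5 design well conditioned; normal equations are
# never formed).

poly_exponents <- function(order) {
  e <- expand.grid(i = 0:order, j = 0:order)
  e <- e[e$i + e$j <= order, , drop = FALSE]
  e[order(e$i + e$j, e$i), , drop = FALSE]
}

poly_design <- function(x, y, expo) {
  m <- matrix(1, length(x), nrow(expo))
  for (k in seq_len(nrow(expo))) {
    if (expo$i[k] > 0) m[, k] <- m[, k] * x^expo$i[k]
    if (expo$j[k] > 0) m[, k] <- m[, k] * y^expo$j[k]
  }
  m
}

#' Fit a bivariate polynomial surface to a vertex cloud
#'
#' @param points n x 3 matrix (or `pf_mesh`, whose vertices are used) of
#'   surface samples in the surface frame.
#' @param order total polynomial order n; z = sum over i+j<=n of c_ij x^i y^j.
#' @param weights optional non-negative per-point weights (the analogue of
#'   locally refining the mesh near the dislocation-critical ridge).
#' @return Object of class `pf_poly_surface` with elements `order`,
#'   `coefficients` (named `c_i_j`, in the original x/y frame), `fit_domain`
#'   (x/y bounding rectangle), `r_squared` (clipped to [0, 1]; raw value in
#'   `r_squared_raw`), `rmse_fit` (m), plus the internal scaled-basis
#'   representation used for numerically stable evaluation.
#' @export
fit_polynomial <- function(points, order, weights = NULL) {
  if (inherits(points, "pf_mesh")) points <- points$vertices
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, order >= 0)
  n_coef <- (order + 1) * (order + 2) / 2
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (any(weights < 0)) stop("weights must be >= 0")
  keep <- weights > 0
  pts <- points[keep, , drop = FALSE]
  wts <- weights[keep]
  if (nrow(pts) < n_coef)
    stop("need at least ", n_coef, " weighted points for order ", order)
  cx <- (max(pts[, 1]) + min(pts[, 1])) / 2
  cy <- (max(pts[, 2]) + min(pts[, 2])) / 2
  sx <- max((max(pts[, 1]) - min(pts[, 1])) / 2, 1e-12)
  sy <- max((max(pts[, 2]) - min(pts[, 2])) / 2, 1e-12)
  expo <- poly_exponents(order)
  A <- poly_design((pts[, 1] - cx) / sx, (pts[, 2] - cy) / sy, expo)
  sw <- sqrt(wts)
  qr_fit <- qr(A * sw, LAPACK = FALSE)
  if (qr_fit$rank < n_coef)
    stop("rank-deficient design (rank ", qr_fit$rank, " < ", n_coef,
         "): points are collinear or under-sample the basis")
  coef_s <- qr.coef(qr_fit, pts[, 3] * sw)
  zhat <- drop(A %*% coef_s)
  res <- pts[, 3] - zhat
  ss_res <- sum(wts * res^2)
  wmean <- sum(wts * pts[, 3]) / sum(wts)
  ss_tot <- sum(wts * (pts[, 3] - wmean)^2)
  r2_raw <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res <= 0)
  coef_orig <- unscale_poly_coef(coef_s, expo, cx, cy, sx, sy)
  names(coef_orig) <- paste0("c_", expo$i, "_", expo$j)
  structure(list(order = order,
                 coefficients = coef_orig,
                 exponents = expo,
                 fit_domain = list(x = range(pts[, 1]), y = range(pts[, 2])),
                 r_squared = max(0, min(1, r2_raw)),
                 r_squared_raw = r2_raw,
                 rmse_fit = sqrt(ss_res / sum(wts)),
                 scaled = list(coef = coef_s, cx = cx, cy = cy,
                               sx = sx, sy = sy),
                 fast = poly_fast_tables(coef_s, expo, sx, sy, order)),
            class = "pf_poly_surface")
}

# Precomputed index/coefficient tables for fast scalar evaluation of the
# surface and its first and second derivatives (hot path of the analytic
# contact backend).
poly_fast_tables <- function(coef_s, expo, sx, sy, order) {
  i <- expo$i; j <- expo$j
  list(order = order,
       ei = as.integer(i), ej = as.integer(j),
       i1 = i + 1L, j1 = j + 1L,
       ix = pmax(i, 1L), jy = pmax(j, 1L),          # index of power i-1 is i
       ix2 = pmax(i - 1L, 1L), jy2 = pmax(j - 1L, 1L),
       c0 = coef_s,
       cx = coef_s * i / sx,
       cy = coef_s * j / sy,
       cxx = coef_s * i * (i - 1) / sx^2,
       cxy = coef_s * i * j / (sx * sy),
       cyy = coef_s * j * (j - 1) / sy^2)
}

# Expand coefficients of the centered/scaled basis ((x-cx)/sx)^i ((y-cy)/sy)^j
# into plain monomials x^a y^b via binomial expansion.
unscale_poly_coef <- function(coef_s, expo, cx, cy, sx, sy) {
  order <- max(expo$i + expo$j)
  out <- stats::setNames(numeric(nrow(expo)),
                         paste(expo$i, expo$j, sep = "_"))
  for (k in seq_len(nrow(expo))) {
    i <- expo$i[k]; j <- expo$j[k]
    for (a in 0:i) for (b in 0:j) {
      key <- paste(a, b, sep = "_")
      out[key] <- out[key] + coef_s[k] *
        choose(i, a) * (-cx)^(i - a) / sx^i *
        choose(j, b) * (-cy)^(j - b) / sy^j
    }
  }
  out
}

#' Evaluate a fitted polynomial surface
#'
#' @param surface `pf_poly_surface`.
#' @param x,y query coordinates (vectors).
#' @param gradient also return the height gradient and unit surface normal.
#' @return list with `z`, `extrapolated` (logical per point, TRUE outside the
#'   fit domain; extrapolation is flagged, not an error) and, if requested,
#'   `grad` (n x 2) and `normal` (n x 3 unit rows, proportional to
#'   `(-df/dx, -df/dy, 1)`).
#' @export
eval_surface <- function(surface, x, y, gradient = FALSE) {
  stopifnot(inherits(surface, "pf_poly_surface"))
  s <- surface$scaled
  xs <- (x - s$cx) / s$sx
  ys <- (y - s$cy) / s$sy
  expo <- surface$exponents
  z <- drop(poly_design(xs, ys, expo) %*% s$coef)
  dom <- surface$fit_domain
  extra <- x < dom$x[1] | x > dom$x[2] | y < dom$y[1] | y > dom$y[2]
  out <- list(z = z, extrapolated = extra)
  if (gradient) {
    dx_expo <- expo; dx_expo$i <- pmax(expo$i - 1L, 0L)
    cdx <- s$coef * expo$i / s$sx
    dy_expo <- expo; dy_expo$j <- pmax(expo$j - 1L, 0L)
    cdy <- s$coef * expo$j / s$sy
    fx <- drop(poly_design(xs, ys, dx_expo) %*% cdx)
    fy <- drop(poly_design(xs, ys, dy_expo) %*% cdy)
    nr <- cbind(-fx, -fy, 1)
    nr <- nr / sqrt(rowSums(nr * nr))
    out$grad <- cbind(fx, fy)
    out$normal <- nr
  }
  out
}

# Height-only shorthand used in hot loops.
surface_height <- function(surface, x, y) {
  s <- surface$scaled
  drop(poly_design((x - s$cx) / s$sx, (y - s$cy) / s$sy,
                   surface$exponents) %*% s$coef)
}

#' @export
print.pf_poly_surface <- function(x, ...) {
  cat(sprintf("pf_poly_surface: order %d, %d coefficients, R^2 = %.6f, RMSE = %.3g m\n",
              x$order, length(x$coefficients), x$r_squared, x$rmse_fit))
  invisible(x)
}

#' Fit several polynomial orders to the same cloud
#'
#' Convenience wrapper mirroring the bench comparison of order 2/4/5 implant
#' approximations.
#' @param points vertex cloud or `pf_mesh`.
#' @param orders integer vector.
#' @param weights optional per-point weights.
#' @return named list of `pf_poly_surface` (names `P2`, `P4`, ...).
#' @export
fit_polynomial_orders <- function(points, orders = c(2, 4, 5), weights = NULL) {
  out <- lapply(orders, function(n) fit_polynomial(points, n, weights))
  names(out) <- paste0("P", orders)
  out
}
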