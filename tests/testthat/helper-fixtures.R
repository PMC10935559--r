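# Shared fixtures, all generated in code.

# flat surface z = 0 as a fitted polynomial (plane fits are exact)
plane_surface <- function(half = 1, order = 1) {
  g <- expand.grid(x = seq(-half, half, length.out = 9),
                   y = seq(-half, half, length.out = 9))
  fit_polynomial(cbind(g$x, g$y, 0), order)
}

# paraboloid z = ax^2 + by^2 fitted exactly at order 2
paraboloid_surface <- function(a = 1, b = 1, half = 1) {
  g <- expand.grid(x = seq(-half, half, length.out = 11),
                   y = seq(-half, half, length.out = 11))
  fit_polynomial(cbind(g$x, g$y, a * g$x^2 + b * g$y^2), 2)
}

# random full-order bivariate polynomial surface (deterministic under seed)
random_poly_surface <- function(order = 5, seed = 1, scale = 0.2, half = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq(-half, half, length.out = 21),
                   y = seq(-half, half, length.out = 21))
  e <- pftwin:::poly_exponents(order)
  cf <- stats::rnorm(nrow(e)) * scale / (1 + e$i + e$j)^2
  z <- drop(pftwin:::poly_design(g$x, g$y, e) %*% cf)
  fit_polynomial(cbind(g$x, g$y, z), order)
}

id_pose <- function(x = c(0, 0, 0)) list(x = x, q = c(1, 0, 0, 0))

# small bench problem: one flexion-extension cycle, shared by several tests
test_scenario <- function(...) {
  scenario_config(cycles = 1, cycle_period = 1.6, ...)
}

# brute-force closest point on a fitted surface by dense grid + polish
grid_closest <- function(surface, cl, step = 1e-3) {
  dom <- surface$fit_domain
  g <- expand.grid(x = seq(dom$x[1], dom$x[2], by = step),
                   y = seq(dom$y[1], dom$y[2], by = step))
  z <- pftwin:::surface_height(surface, g$x, g$y)
  d2 <- (g$x - cl[1])^2 + (g$y - cl[2])^2 + (z - cl[3])^2
  i <- which.min(d2)
  op <- stats::optim(c(g$x[i], g$y[i]), function(p) {
    zz <- pftwin:::surface_height(surface, p[1], p[2])
    (p[1] - cl[1])^2 + (p[2] - cl[2])^2 + (zz - cl[3])^2
  }, method = "Nelder-Mead",
     control = list(reltol = 1e-14, maxit = 2000))
  list(xy = op$par, dist = sqrt(op$value))
}

# synthetic kinematic trajectory builder for event-detection tests: the
# patella follows a prescribed sphere-center path in the femur frame with a
# prescribed contact mask, under a prescribed knee-flexion profile.
kinematic_trajectory <- function(scenario, t, y_path, x_path, z_path,
                                 contact, knee_deg) {
  n <- length(t)
  femur <- cbind(matrix(0, n, 3), 1, matrix(0, n, 3))
  tibia <- t(vapply(seq_len(n), function(k)
    c(0, 0, 0, pftwin:::mat_to_quat(pftwin:::rot_axis(2,
                                                      -knee_deg[k] * pi / 180))),
    numeric(7)))
  patella <- cbind(x_path, y_path, z_path, 1, matrix(0, n, 3))
  structure(list(
    time = t,
    poses = list(femur = femur, tibia = tibia, patella = patella),
    springs = matrix(0, n, 2),
    contact = data.frame(t = t, Fmag = ifelse(contact, 1, 0),
                         px = NA, py = NA, pz = NA, nx = NA, ny = NA,
                         nz = NA, delta = 0, delta_dot = 0,
                         in_contact = as.numeric(contact)),
    stats = list(realtime_ratio = 1),
    events = list()),
    class = "pf_trajectory")
}

bounce_ratio <- function(eps, v0 = 0.3, k_n = 1e5, h = 1e-4) {
  pl <- plane_surface(half = 0.5)
  ball <- rigid_body("ball", 0.05, c(2e-6, 2e-6, 2e-6),
                     x = c(0, 0, 0.0201), v = c(0, 0, -v0))
  ground <- rigid_body("ground", 1, c(1, 1, 1), guided = TRUE)
  ct <- contact_pair_analytic(sphere_primitive(radius = 0.02), "ball", pl,
                              "ground", flores_params(k_n = k_n, eps = eps))
  mod <- assemble(list(ball, ground), contacts = list(ct),
                  guidance = list(ground = guidance_constant(c(0, 0, 0))),
                  gravity = c(0, 0, 0))
  tr <- simulate_model(mod, c(0, 0.12), sim_config(h = h), record_every = 1)
  vz <- tr$twists$ball[, 3]
  inc <- tr$contact$in_contact
  i1 <- which(inc > 0)[1]
  list(ratio = max(vz[inc == 0 & seq_along(inc) > i1]) / v0, traj = tr)
}


pendulum_period_error <- function(h, th0 = 0.02, n_periods = 5) {
  L <- 0.5; g <- 9.81
  b <- rigid_body("p", 0.2, c(1e-6, 1e-6, 1e-6),
                  x = c(L * sin(th0), 0, -L * cos(th0)))
  mod <- assemble(list(b), constraints = list(
    constraint_distance("p", c(0, 0, 0), c(0, 0, 0), L)))
  T0 <- 2 * pi * sqrt(L / g) * (1 + th0^2 / 16)
  tr <- simulate_model(mod, c(0, n_periods * T0), sim_config(h = h),
                       record_every = 1)
  x <- tr$poses$p[, 1]; t <- tr$time
  zc <- which(x[-1] > 0 & x[-length(x)] <= 0)
  tz <- t[zc] - x[zc] * (t[zc + 1] - t[zc]) / (x[zc + 1] - x[zc])
  list(err = abs(mean(diff(tz)) - T0), T0 = T0, traj = tr)
}

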