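test_that("closest point on a plane is the vertical projection", {
  pl <- plane_surface()
  cp <- closest_point(pl, c(0.3, -0.2, 0.5))
  expect_equal(cp$p, c(0.3, -0.2, 0), tolerance = 1e-10)
  expect_equal(cp$distance, 0.5, tolerance = 1e-10)
  expect_lt(cp$residual, 1e-10)
  expect_false(cp$boundary)
})

test_that("points on the axis of a paraboloid project to the apex", {
  pb <- paraboloid_surface(a = 1, b = 0)   # z = x^2
  for (h in c(0.1, 0.3, 0.45)) {
    cp <- closest_point(pb, c(0, 0, h))
    expect_equal(cp$p, c(0, 0, 0), tolerance = 1e-8)
    expect_equal(cp$distance, h, tolerance = 1e-10)
  }
})

test_that("closest point matches a grid + refine oracle on random quintics", {
  surf <- random_poly_surface(order = 5, seed = 5)
  set.seed(99)
  for (k in 1:50) {
    cl <- c(stats::runif(1, -0.7, 0.7), stats::runif(1, -0.7, 0.7),
            stats::runif(1, 0.1, 1.0))
    cp <- closest_point(surf, cl)
    oracle <- grid_closest(surf, cl, step = 5e-3)
    expect_equal(abs(cp$distance), oracle$dist, tolerance = 1e-6)
  }
})

test_that("sphere-plane contact follows the distance criterion exactly", {
  pl <- plane_surface()
  s <- sphere_primitive(radius = 0.015)
  expect_null(sphere_surface_contact(s, id_pose(c(0, 0, 0.016)), pl,
                                     id_pose()))
  p <- sphere_surface_contact(s, id_pose(c(0.2, 0.1, 0.013)), pl, id_pose())
  expect_equal(p$delta, 0.002, tolerance = 1e-10)
  expect_equal(p$normal, c(0, 0, 1), tolerance = 1e-10)
  expect_equal(p$point, c(0.2, 0.1, 0), tolerance = 1e-10)
})

test_that("a center below the surface is deep penetration with a warning", {
  pl <- plane_surface()
  s <- sphere_primitive(radius = 0.015)
  ep <- contact_episodes()
  expect_warning(
    p <- sphere_surface_contact(s, id_pose(c(0, 0, -0.002)), pl, id_pose(),
                                episodes = ep, commit = TRUE),
    "deep penetration")
  expect_equal(p$delta, 0.017, tolerance = 1e-10)
})

test_that("indentation is continuous while sweeping across the groove ridge", {
  gp <- groove_params()
  m <- make_trochlear_surface(gp, mesh_quality_target(5e-5, 1))
  surf <- fit_polynomial(m$vertices, 5)
  s <- sphere_primitive(radius = 0.014)
  ys <- seq(-0.012, 0.012, length.out = 120)
  deltas <- vapply(ys, function(y) {
    zc <- gp$analytic_form(0, y) + 0.012
    p <- sphere_surface_contact(s, id_pose(c(0, y, zc)), surf, id_pose())
    if (is.null(p)) 0 else p$delta
  }, numeric(1))
  expect_lt(max(abs(diff(deltas))), 5e-4)   # no jumps along the sweep
  # footprint agrees with the grid oracle at a ridge-adjacent probe
  zc <- gp$analytic_form(0, -0.013) + 0.011
  cp <- closest_point(surf, c(0, -0.013, zc))
  oracle <- grid_closest(surf, c(0, -0.013, zc), step = 2e-4)
  expect_equal(abs(cp$distance), oracle$dist, tolerance = 1e-6)
})

test_that("delta and the force magnitude are frame objective", {
  pb <- paraboloid_surface(a = 2, b = 1)
  s <- sphere_primitive(radius = 0.1)
  c0 <- c(0.05, -0.03, 0.11)
  p0 <- sphere_surface_contact(s, id_pose(c0), pb, id_pose())
  fl <- flores_params(k_n = 1e5, eps = 1)
  F0 <- flores_force(fl, p0)$Fmag
  # rigidly transform both bodies by the same pose
  R <- pftwin:::rot_axis(1, 0.7) %*% pftwin:::rot_axis(3, -0.4)
  tq <- pftwin:::mat_to_quat(R)
  tx <- c(0.3, -0.2, 0.5)
  pose_s <- list(x = drop(R %*% c0) + tx, q = tq)
  pose_f <- list(x = tx, q = tq)
  p1 <- sphere_surface_contact(s, pose_s, pb, pose_f)
  expect_equal(p1$delta, p0$delta, tolerance = 1e-10)
  expect_equal(flores_force(fl, p1)$Fmag, F0, tolerance = 1e-8)
})

test_that("leaving the fit domain ends the episode and logs the exit", {
  pl <- plane_surface(half = 0.05)
  s <- sphere_primitive(radius = 0.02)
  ep <- contact_episodes()
  p <- sphere_surface_contact(s, id_pose(c(0, 0, 0.015)), pl, id_pose(),
                              episodes = ep, commit = TRUE)
  expect_false(is.null(p))
  expect_length(ep$active, 1L)
  out <- sphere_surface_contact(s, id_pose(c(0.2, 0, 0.015)), pl, id_pose(),
                                episodes = ep, commit = TRUE)
  expect_null(out)
  expect_length(ep$active, 0L)
  expect_true(any(vapply(ep$log, function(e) e$type == "domain_exit",
                         logical(1))))
})
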