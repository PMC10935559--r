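test_that("degree-of-freedom bookkeeping matches the bench model", {
  free <- rigid_body("a", 1, c(1, 1, 1) * 1e-3)
  expect_equal(assemble(list(free))$n_unknowns, 6L)
  gd <- guidance_constant(c(0, 0, 0))
  femur <- rigid_body("femur", 1, c(1, 1, 1) * 1e-2, guided = TRUE)
  tibia <- rigid_body("tibia", 1, c(1, 1, 1) * 1e-2, guided = TRUE)
  patella <- rigid_body("patella", 0.05, c(1, 1, 1) * 1e-5)
  hip <- constraint_spherical("femur", c(0.3, 0, 0), c(0.3, 0, 0))
  m1 <- assemble(list(femur, tibia, patella), constraints = list(hip),
                 guidance = list(femur = gd, tibia = gd))
  expect_equal(m1$n_unknowns, 6L)
  tibia_free <- rigid_body("tibia", 1, c(1, 1, 1) * 1e-2)
  m2 <- assemble(list(femur, tibia_free, patella), constraints = list(hip),
                 guidance = list(femur = gd))
  expect_equal(m2$n_unknowns, 12L)
  expect_error(assemble(list(free, free)), "duplicate")
  expect_error(assemble(list(femur)), "no guidance")
})

test_that("free fall is integrated exactly (constant acceleration)", {
  mod <- assemble(list(rigid_body("m", 1, c(1e-3, 1e-3, 1e-3))))
  tr <- simulate_model(mod, c(0, 1), sim_config(h = 1e-3))
  expect_equal(tail(tr$poses$m[, 3], 1), -0.5 * 9.81, tolerance = 1e-6)
})

test_that("the small-angle pendulum period matches the closed form", {
  p <- pendulum_period_error(1e-3, n_periods = 10)
  expect_lt(p$err / p$T0, 0.005)
  # constraint health after every accepted step
  expect_lte(p$traj$stats$max_phi, 1e-8)
  expect_lte(p$traj$stats$max_vel_resid, 1e-8)
})

test_that("halving the step quarters the period error (second order)", {
  e1 <- pendulum_period_error(2e-3)$err
  e2 <- pendulum_period_error(1e-3)$err
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5.5)
})

test_that("guided bodies follow their prescription", {
  times <- seq(0, 1, 0.01)
  xs <- cbind(0.1 * sin(2 * pi * times), 0 * times, 0.05 * cos(2 * pi * times))
  qs <- t(vapply(times, function(t)
    mat_to_quat(rot_axis(2, 0.3 * sin(2 * pi * t))), numeric(4)))
  g <- guidance_spline(times, xs, qs)
  gb <- rigid_body("g", 1, c(1, 1, 1) * 1e-3, guided = TRUE)
  fb <- rigid_body("f", 1, c(1, 1, 1) * 1e-3)
  mod <- assemble(list(gb, fb), guidance = list(g = g))
  tr <- simulate_model(mod, c(0, 0.5), sim_config(h = 1e-3))
  for (k in c(11L, 101L, 401L)) {
    gt <- g(tr$time[k])
    expect_equal(tr$poses$g[k, 1:3], gt$x, tolerance = 1e-10)
    expect_equal(abs(sum(tr$poses$g[k, 4:7] * gt$q)), 1, tolerance = 1e-10)
  }
})

test_that("a resting state stays at rest without forces", {
  b <- rigid_body("b", 0.1, c(1e-5, 1e-5, 1e-5), x = c(0.1, 0.2, 0.3))
  mod <- assemble(list(b), gravity = c(0, 0, 0))
  tr <- simulate_model(mod, c(0, 0.5), sim_config(h = 1e-3))
  expect_lt(max(abs(sweep(tr$poses$b[, 1:3], 2, c(0.1, 0.2, 0.3)))), 1e-12)
})

test_that("identical runs are bitwise identical (determinism)", {
  sc <- test_scenario()
  geo <- build_bench_geometry(sc)
  mo <- synth_motion(sc)
  t1 <- simulate_scenario(sc, mo, geo, t_span = c(0, 0.3))
  t2 <- simulate_scenario(sc, mo, geo, t_span = c(0, 0.3))
  expect_identical(t1$poses$patella, t2$poses$patella)
  expect_identical(t1$contact$Fmag, t2$contact$Fmag)
})

test_that("static equilibrium solves the hanging-spring closed form", {
  b <- rigid_body("m", 1, c(1e-4, 1e-4, 1e-4), x = c(0, 0, -0.09))
  sp <- spring_damper_params(K = 100, L0 = 0.05,
                             attach_A = list(body = "world",
                                             point = c(0, 0, 0)),
                             attach_B = list(body = "m", point = c(0, 0, 0)))
  mod <- assemble(list(b), springs = list(sp))
  st <- static_equilibrium(mod, force_tol = 1e-9)
  # elongation mg/K below the natural length
  expect_equal(st$poses$m$x[3], -(0.05 + 9.81 / 100), tolerance = 1e-7)
})

test_that("static equilibrium on a contact solves k_n delta^p = mg", {
  pl <- plane_surface(half = 0.5)
  ball <- rigid_body("ball", 0.03, c(1e-6, 1e-6, 1e-6), x = c(0, 0, 0.0199))
  ground <- rigid_body("ground", 1, c(1, 1, 1), guided = TRUE)
  ct <- contact_pair_analytic(sphere_primitive(radius = 0.02), "ball", pl,
                              "ground", flores_params(k_n = 1e7, eps = 0.8))
  mod <- assemble(list(ball, ground), contacts = list(ct),
                  guidance = list(ground = guidance_constant(c(0, 0, 0))))
  st <- static_equilibrium(mod, force_tol = 1e-8)
  delta <- 0.02 - st$poses$ball$x[3]
  delta_ref <- (0.03 * 9.81 / 1e7)^(2 / 3)   # solves 1e7 delta^1.5 = mg
  expect_equal(delta, delta_ref, tolerance = 1e-4)
  expect_equal(delta_ref, 9.59e-7, tolerance = 1e-3)
})

test_that("the bench equilibrium restarts without drift under frozen guidance", {
  sc <- test_scenario()
  geo <- build_bench_geometry(sc)
  mo <- synth_motion(sc)
  guid <- list(
    femur = guidance_spline(mo$truth$femur$time, mo$truth$femur$x,
                            mo$truth$femur$q),
    tibia = guidance_spline(mo$truth$tibia$time, mo$truth$tibia$x,
                            mo$truth$tibia$q))
  model <- build_bench_model(sc, guid, geo,
                             patella_init = list(
                               x = mo$truth$patella$x[1, ],
                               q = mo$truth$patella$q[1, ]))
  st <- static_equilibrium(model, model_state(model, 0), force_tol = 1e-7)
  # freeze femur and tibia at their t = 0 poses and integrate 1 s
  frozen <- model
  frozen$guidance <- lapply(model$guidance, function(g) {
    g0 <- g(0)
    guidance_constant(g0$x, g0$q)
  })
  tr <- simulate_model(frozen, c(0, 1), sim_config(h = 1e-3), state = st)
  drift <- max(abs(sweep(tr$poses$patella[, 1:3], 2, st$poses$patella$x)))
  expect_lt(drift, 1e-4)
})

test_that("energy is conserved in the elastic contact oscillator", {
  pb <- paraboloid_surface(a = 5, b = 5, half = 0.3)
  ball <- rigid_body("ball", 0.05, c(2e-6, 2e-6, 2e-6),
                     x = c(0, 0, 0.0195))
  ground <- rigid_body("ground", 1, c(1, 1, 1), guided = TRUE)
  ct <- contact_pair_analytic(sphere_primitive(radius = 0.02), "ball", pb,
                              "ground", flores_params(k_n = 1e5, eps = 1))
  spr <- spring_damper_params(K = 50, L0 = 0.08, c = 0,
                              attach_A = list(body = "world",
                                              point = c(0, 0, 0.1)),
                              attach_B = list(body = "ball",
                                              point = c(0, 0, 0)))
  mod <- assemble(list(ball, ground), springs = list(spr),
                  contacts = list(ct),
                  guidance = list(ground = guidance_constant(c(0, 0, 0))))
  st <- static_equilibrium(mod)
  st$twists$ball$v <- c(0.05, 0, 0)
  KE0 <- 0.5 * 0.05 * 0.05^2
  tr <- simulate_model(mod, c(0, 2), sim_config(h = 1e-3), state = st,
                       record_every = 10)
  E <- vapply(seq_along(tr$time), function(k) {
    s <- list(poses = list(ball = list(x = tr$poses$ball[k, 1:3],
                                       q = tr$poses$ball[k, 4:7]),
                           ground = list(x = c(0, 0, 0),
                                         q = c(1, 0, 0, 0))),
              twists = list(ball = list(v = tr$twists$ball[k, 1:3],
                                        w = tr$twists$ball[k, 4:6])))
    total_energy(mod, s)
  }, numeric(1))
  expect_lt((max(E) - min(E)) / KE0, 1e-3)
})

test_that("the compiled bench stepper agrees with the generic stepper", {
  sc <- test_scenario()
  geo <- build_bench_geometry(sc)
  mo <- synth_motion(sc)
  tf <- simulate_scenario(sc, mo, geo, t_span = c(0, 0.25), fast = TRUE)
  ts <- simulate_scenario(sc, mo, geo, t_span = c(0, 0.25), fast = FALSE)
  n <- length(ts$time)
  expect_equal(tf$poses$patella[n, 1:3], unname(ts$poses$patella[n, 1:3]),
               tolerance = 1e-9)
  expect_equal(max(abs(tf$contact$Fmag - ts$contact$Fmag), na.rm = TRUE), 0,
               tolerance = 1e-6)
})
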