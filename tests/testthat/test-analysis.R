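test_that("patellar kinematics are constant for a constant relative pose", {
  n <- 25
  Rf <- rot_axis(2, 0.2)
  Rrel <- rot_axis(2, 0.5) %*% rot_axis(1, 0.1)
  fem <- t(vapply(seq_len(n), function(k)
    c(0.01 * k, 0, 0, mat_to_quat(Rf)), numeric(7)))
  pat <- t(vapply(seq_len(n), function(k)
    c(c(0.01 * k, 0, 0) + drop(Rf %*% c(0.05, 0.01, 0.04)),
      mat_to_quat(Rf %*% Rrel)), numeric(7)))
  kin <- patellar_kinematics(pat, fem)
  for (col in names(kin))
    expect_lt(diff(range(kin[[col]])), 1e-9)
  expect_equal(kin$x[1], 0.05, tolerance = 1e-10)
})

test_that("a pure rotation about Y reads as flexion only", {
  fem <- matrix(c(0, 0, 0, 1, 0, 0, 0), 1)
  pat <- matrix(c(0, 0, 0, mat_to_quat(rot_axis(2, 30 * pi / 180))), 1)
  kin <- patellar_kinematics(pat, fem)
  expect_equal(kin$flexion, 30, tolerance = 1e-10)
  expect_equal(kin$tilt, 0, tolerance = 1e-10)
  expect_equal(kin$rotation, 0, tolerance = 1e-10)
})

test_that("angle decomposition inverts the Y-X-Z composition", {
  set.seed(31)
  for (k in 1:200) {
    ang <- stats::runif(3, -1.2, 1.2)
    R <- rot_axis(2, ang[1]) %*% rot_axis(1, ang[2]) %*% rot_axis(3, ang[3])
    fem <- matrix(c(0, 0, 0, 1, 0, 0, 0), 1)
    pat <- matrix(c(0, 0, 0, mat_to_quat(R)), 1)
    kin <- patellar_kinematics(pat, fem)
    # independent oracle: recompose from the reported angles
    R2 <- rot_axis(2, kin$flexion * pi / 180) %*%
      rot_axis(1, kin$tilt * pi / 180) %*%
      rot_axis(3, kin$rotation * pi / 180)
    expect_lt(rotation_angle_between(R, R2), 1e-9 * pi / 180)
    expect_equal(kin$flexion, ang[1] * 180 / pi, tolerance = 1e-9)
    expect_equal(kin$tilt, ang[2] * 180 / pi, tolerance = 1e-9)
    expect_equal(kin$rotation, ang[3] * 180 / pi, tolerance = 1e-9)
  }
})

fake_traj <- function(t, pat_xyz, springs = NULL, Fmag = NULL) {
  n <- length(t)
  femur <- cbind(matrix(0, n, 3), 1, matrix(0, n, 3))
  structure(list(
    time = t,
    poses = list(femur = femur, tibia = femur,
                 patella = cbind(pat_xyz, 1, matrix(0, n, 3))),
    springs = springs %||% matrix(stats::rnorm(2 * n), n, 2),
    contact = data.frame(t = t, Fmag = Fmag %||% stats::runif(n, 0, 10),
                         px = 0, py = 0, pz = 0, nx = 0, ny = 0, nz = 1,
                         delta = 0, delta_dot = 0, in_contact = 1),
    stats = list(realtime_ratio = 1)), class = "pf_trajectory")
}

test_that("the validation report reduces to closed forms", {
  t <- seq(0, 1, 0.01)
  n <- length(t)
  base <- cbind(0.01 * sin(t), 0.002 * t, 0.03 + 0 * t)
  a <- fake_traj(t, base)
  self <- rmse_report(a, a)
  for (nm in setdiff(names(self), "runtime_ratio"))
    expect_equal(self[[nm]], 0, tolerance = 1e-12)
  # constant 2 mm offset in x
  shift <- base
  shift[, 1] <- shift[, 1] + 0.002
  b <- fake_traj(t, shift, springs = a$springs, Fmag = a$contact$Fmag)
  rep2 <- rmse_report(b, a)
  expect_equal(rep2$x_coord_mm, 2, tolerance = 1e-9)
  expect_equal(rep2$mean_distance_mm, 2, tolerance = 1e-9)
  expect_equal(rep2$y_coord_mm, 0, tolerance = 1e-9)
})

test_that("the report matches a naive recomputation and is symmetric", {
  set.seed(8)
  t <- seq(0, 1, 0.01)
  a <- fake_traj(t, cbind(rnorm(length(t), 0, 0.01), 0, 0.03))
  b <- fake_traj(t, cbind(rnorm(length(t), 0, 0.01), 0, 0.03))
  r_ab <- rmse_report(a, b)
  r_ba <- rmse_report(b, a)
  naive <- 1000 * sqrt(mean((a$poses$patella[, 1] - b$poses$patella[, 1])^2))
  expect_equal(r_ab$x_coord_mm, naive, tolerance = 1e-9)
  for (nm in setdiff(names(r_ab), "runtime_ratio"))
    expect_equal(r_ab[[nm]], r_ba[[nm]], tolerance = 1e-12)
})

test_that("event detection separates dislocation, high-riding and none", {
  sc <- scenario_config()
  t <- seq(0, 3, 0.01)
  n <- length(t)
  knee <- 45 + 40 * sin(2 * pi * t / 2)
  inside <- kinematic_trajectory(sc, t, y_path = rep(0, n),
                                 x_path = rep(0, n),
                                 z_path = rep(0.04, n),
                                 contact = rep(TRUE, n), knee_deg = knee)
  expect_length(detect_events(inside, sc), 0L)
  # dislocation: during extension the center crosses the lateral ridge and
  # contact is lost for good
  i0 <- which(t >= 1.2)[1]
  y <- rep(0, n); y[i0:n] <- -0.03
  contact <- rep(TRUE, n); contact[i0:n] <- FALSE
  disl <- kinematic_trajectory(sc, t, y, rep(0, n), rep(0.04, n), contact,
                               knee)
  ev <- detect_events(disl, sc)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "dislocation")
  # high-riding: stuck proximal with no engagement while flexing
  i1 <- which(t >= 0.05)[1]; i2 <- which(t >= 0.45)[1]
  contact2 <- rep(TRUE, n); contact2[i1:i2] <- FALSE
  x2 <- rep(0, n); x2[i1:i2] <- 0.025
  hr <- kinematic_trajectory(sc, t, rep(0, n), x2, rep(0.05, n), contact2,
                             knee)
  ev2 <- detect_events(hr, sc)
  expect_length(ev2, 1L)
  expect_equal(ev2[[1]]$type, "high_riding")
})

test_that("the genetic algorithm is deterministic and respects the box", {
  fn <- function(p) sum((p - c(1, -2))^2) + 3
  lower <- c(-5, -5); upper <- c(5, 5)
  r1 <- ga_optimize(fn, lower, upper, ga_config(pop_size = 20,
                                                generations = 15, seed = 4))
  r2 <- ga_optimize(fn, lower, upper, ga_config(pop_size = 20,
                                                generations = 15, seed = 4))
  expect_identical(r1$par, r2$par)
  expect_equal(r1$par, c(1, -2), tolerance = 0.05)
  expect_true(all(r1$evals[, 1] >= -5 & r1$evals[, 1] <= 5))
  expect_true(all(diff(r1$trace) <= 1e-12))  # monotone best-so-far
  expect_error(ga_optimize(function(p) stop("boom"), lower, upper,
                           ga_config(pop_size = 6, generations = 2)),
               "failed")
})

test_that("the calibration objective vanishes at the true parameters", {
  sc <- test_scenario(femur_attach = "medial", tibia_attach = "lateral")
  geo <- build_bench_geometry(sc)
  mo <- synth_motion(sc)
  obs <- simulate_scenario(sc, mo, geo, t_span = c(0, 0.8))
  cal_env <- calibrate_tendons(sc, obs, mo, geo,
                               ga = ga_config(pop_size = 4, generations = 0,
                                              seed = 1))
  truth <- cal_env$bounds$center
  expect_lt(cal_env$objective(unname(truth)), 1e-4)   # << 0.1 mm
})

test_that("an identity treatment edit reproduces the calibrated run bitwise", {
  sc <- test_scenario(femur_attach = "medial", tibia_attach = "lateral")
  geo <- build_bench_geometry(sc)
  mo <- synth_motion(sc)
  obs <- simulate_scenario(sc, mo, geo, t_span = c(0, 0.6))
  cal <- calibrate_tendons(sc, obs, mo, geo, t_span = c(0, 0.6),
                           ga = ga_config(pop_size = 6, generations = 1,
                                          seed = 2))
  p1 <- predict_treatment(cal, edit = list(), motion = mo, geometry = geo,
                          t_span = c(0, 0.6))
  p2 <- predict_treatment(cal, edit = list(), motion = mo, geometry = geo,
                          t_span = c(0, 0.6))
  expect_identical(p1$trajectory$poses$patella, p2$trajectory$poses$patella)
  expect_equal(names(coef(cal)), c("K1", "L1", "K2", "L2"))
  expect_true(all(coef(cal) >= cal$bounds$lower - 1e-12 &
                  coef(cal) <= cal$bounds$upper + 1e-12))
  # a report is included when a reference is supplied
  p3 <- predict_treatment(cal, edit = list(), motion = mo, geometry = geo,
                          reference = obs, t_span = c(0, 0.6))
  expect_s3_class(p3$report, "pf_validation")
})

test_that("the true parameters are the global minimum over the bounds grid", {
  # 5x5x5x5 grid spanning the +/-30% box, short calibration window
  sc <- test_scenario(femur_attach = "medial", tibia_attach = "lateral")
  geo <- build_bench_geometry(sc)
  mo <- synth_motion(sc)
  obs <- simulate_scenario(sc, mo, geo, t_span = c(0, 0.5))
  cal <- calibrate_tendons(sc, obs, mo, geo, t_span = c(0, 0.5),
                           ga = ga_config(pop_size = 4, generations = 0,
                                          seed = 1))
  truth <- unname(cal$bounds$center)
  f_truth <- cal$objective(truth)
  expect_lt(f_truth, 1e-4)
  fr <- seq(0.7, 1.3, length.out = 5)
  vals <- numeric(0)
  for (a in fr) for (b in fr) for (d in fr) for (e in fr)
    vals <- c(vals, cal$objective(truth * c(a, b, d, e)))
  # every grid point is the truth scaled by factors in {0.7..1.3}; the
  # unscaled center (all factors 1) is among them and is the minimum
  expect_equal(min(vals), f_truth, tolerance = 1e-9)
  expect_true(all(vals >= f_truth - 1e-12))
})
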