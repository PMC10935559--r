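# Validation metrics (patellar kinematics in the femur frame, channel-wise
# RMSE, dislocation / high-riding detection) and tendon-parameter
# identification by genetic algorithm for treatment prediction.

# decompose R = Ry(flexion) %*% Rx(tilt) %*% Rz(rotation); returns radians
decompose_yxz <- function(R) {
  tilt <- asin(max(-1, min(1, -R[2, 3])))
  flexion <- atan2(R[1, 3], R[3, 3])
  rotation <- atan2(R[2, 1], R[2, 2])
  c(flexion = flexion, tilt = tilt, rotation = rotation)
}

#' Patellar kinematics in the femoral reference frame
#'
#' Expresses the patellar sphere center in the femoral body frame (avoiding
#' world-frame error accumulation) and decomposes the relative orientation
#' with the fixed Y-X-Z Euler sequence: flexion about the medial-lateral
#' Y axis, tilt about the patellar long X axis, rotation about the
#' anterior-posterior Z axis.
#'
#' @param patella_poses,femur_poses n x 7 pose matrices (x, y, z, qw, qx, qy,
#'   qz), synchronized.
#' @param sphere_offset sphere-center offset in the patella frame (m).
#' @return data frame: `x`, `y`, `z` (m, femur frame), `tilt`, `flexion`,
#'   `rotation` (deg).
#' @export
patellar_kinematics <- function(patella_poses, femur_poses,
                                sphere_offset = c(0, 0, 0)) {
  if (nrow(patella_poses) != nrow(femur_poses))
    stop("pose series lengths differ")
  n <- nrow(patella_poses)
  out <- matrix(0, n, 6)
  for (k in seq_len(n)) {
    Rp <- quat_to_mat(patella_poses[k, 4:7])
    Rf <- quat_to_mat(femur_poses[k, 4:7])
    pw <- patella_poses[k, 1:3] + drop(Rp %*% sphere_offset)
    out[k, 1:3] <- drop(crossprod(Rf, pw - femur_poses[k, 1:3]))
    ang <- decompose_yxz(crossprod(Rf, Rp))
    out[k, 4:6] <- ang[c("tilt", "flexion", "rotation")] * 180 / pi
  }
  stats::setNames(as.data.frame(out),
                  c("x", "y", "z", "tilt", "flexion", "rotation"))
}

# knee flexion angle (deg) of tibia relative to femur (rotation about -Y)
knee_flexion <- function(tibia_poses, femur_poses) {
  n <- nrow(tibia_poses)
  vapply(seq_len(n), function(k) {
    R <- crossprod(quat_to_mat(femur_poses[k, 4:7]),
                   quat_to_mat(tibia_poses[k, 4:7]))
    -decompose_yxz(R)[["flexion"]] * 180 / pi
  }, numeric(1))
}

resample_cols <- function(t_from, X, t_to) {
  apply(as.matrix(X), 2, function(v)
    stats::approx(t_from, v, xout = t_to, rule = 2)$y)
}

#' Channel-wise RMSE validation report
#'
#' Root-mean-square errors between a simulated and a reference bench
#' trajectory: contact force, tibial and femoral spring forces, patellar
#' internal rotation / flexion / tilt, sphere-center coordinates in the femur
#' frame, plus the mean Euclidean distance error and the runtime ratio. The
#' simulated series is resampled onto the reference time base.
#'
#' @param sim,ref `pf_trajectory` objects with a common overlap window.
#' @param sphere_offset sphere-center offset in the patella frame.
#' @return object of class `pf_validation` (named list of non-negative
#'   numbers; RMSEs in N, deg and mm).
#' @export
rmse_report <- function(sim, ref, sphere_offset = c(0, 0, 0)) {
  t_ref <- ref$time
  t_ov <- t_ref[t_ref >= min(sim$time) & t_ref <= max(sim$time)]
  if (!length(t_ov)) stop("no overlapping time window")
  kin_s <- patellar_kinematics(sim$poses$patella, sim$poses$femur,
                               sphere_offset)
  kin_r <- patellar_kinematics(ref$poses$patella, ref$poses$femur,
                               sphere_offset)
  ks <- resample_cols(sim$time, kin_s, t_ov)
  kr <- resample_cols(t_ref, kin_r, t_ov)
  f_s <- ifelse(is.na(sim$contact$Fmag), 0, sim$contact$Fmag)
  f_r <- ifelse(is.na(ref$contact$Fmag), 0, ref$contact$Fmag)
  fs <- stats::approx(sim$time, f_s, t_ov, rule = 2)$y
  fr <- stats::approx(ref$time, f_r, t_ov, rule = 2)$y
  sp_s <- resample_cols(sim$time, sim$springs, t_ov)
  sp_r <- resample_cols(ref$time, ref$springs, t_ov)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  dist_err <- sqrt(rowSums((ks[, 1:3] - kr[, 1:3])^2))
  structure(list(
    contact_force_N = rmse(fs, fr),
    tibial_spring_force_N = rmse(sp_s[, 2], sp_r[, 2]),
    femoral_spring_force_N = rmse(sp_s[, 1], sp_r[, 1]),
    int_rotation_deg = rmse(ks[, 6], kr[, 6]),
    flexion_deg = rmse(ks[, 5], kr[, 5]),
    tilt_deg = rmse(ks[, 4], kr[, 4]),
    x_coord_mm = 1000 * rmse(ks[, 1], kr[, 1]),
    y_coord_mm = 1000 * rmse(ks[, 2], kr[, 2]),
    z_coord_mm = 1000 * rmse(ks[, 3], kr[, 3]),
    mean_distance_mm = 1000 * mean(dist_err),
    runtime_ratio = sim$stats$realtime_ratio %||% NA_real_),
    class = "pf_validation")
}

#' @export
print.pf_validation <- function(x, ...) {
  cat("Validation report (RMSE):\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %8.3f\n", nm, x[[nm]]))
  invisible(x)
}

#' Event detection: patellar dislocation and high-riding patella
#'
#' Dislocation: sustained (> `persistence` s) loss of groove contact with the
#' sphere center beyond the lateral ridge line while the knee keeps
#' extending. High-riding: during flexion above `flexion_threshold`, the
#' sphere center stays proximal to the groove entrance with no contact.
#'
#' @param traj `pf_trajectory` of a bench scenario (scenario attached as an
#'   attribute, or supplied via `scenario`).
#' @param scenario [scenario_config()] (defaults to `attr(traj, "scenario")`).
#' @param persistence minimum contact-loss duration (s), default 0.05.
#' @param ridge_margin lateral excursion threshold in units of the groove
#'   halfwidth (default 1: the ridge line).
#' @param flexion_threshold knee flexion (deg) above which a stuck,
#'   non-engaged patella counts as high-riding.
#' @param entrance_frac proximal entrance line as a fraction of the sagittal
#'   half-extent.
#' @return list of events, each `list(type, t_start, t_end)`; types
#'   `"dislocation"` and `"high_riding"`. Empty list if none. The thresholds
#'   used are attached as attribute `thresholds`.
#' @export
detect_events <- function(traj, scenario = attr(traj, "scenario"),
                          persistence = 0.05, ridge_margin = 1.0,
                          flexion_threshold = 25, entrance_frac = 0.55) {
  stopifnot(!is.null(scenario))
  lay <- scenario$layout
  gp <- scenario$groove
  kin <- patellar_kinematics(traj$poses$patella, traj$poses$femur,
                             lay$sphere_center)
  kf <- knee_flexion(traj$poses$tibia, traj$poses$femur)
  t <- traj$time
  contact <- traj$contact$in_contact > 0
  dkf <- c(0, diff(kf)) / c(1, diff(t))
  ridge_y <- -ridge_margin * gp$groove_halfwidth
  entrance_x <- entrance_frac * gp$half_extent_x
  events <- list()
  # runs of lost contact
  r <- rle(!contact)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    i0 <- starts[i]; i1 <- ends[i]
    if (t[i1] - t[i0] < persistence) next
    # classify from how the episode begins, not from the whole window (a
    # dislocated patella never re-engages, so the window spans later phases)
    win <- i0:(i0 + max(which(t[i0:i1] - t[i0] <= 3 * persistence)) - 1L)
    lateral <- any(kin$y[win] < ridge_y)
    extending <- mean(dkf[win]) < 0
    superior <- any(kin$x[win] > entrance_x)
    flexing <- mean(dkf[win]) > 0
    if (lateral && extending) {
      events[[length(events) + 1L]] <-
        list(type = "dislocation", t_start = t[i0], t_end = t[i1])
    } else if (superior && flexing && any(kf[win] > flexion_threshold)) {
      events[[length(events) + 1L]] <-
        list(type = "high_riding", t_start = t[i0], t_end = t[i1])
    }
  }
  attr(events, "thresholds") <- list(persistence = persistence,
                                     ridge_y = ridge_y,
                                     entrance_x = entrance_x,
                                     flexion_threshold = flexion_threshold)
  events
}

# Sphere-center kinematics of an observed trajectory, used as the
# calibration target.
observed_kinematics <- function(traj, scenario = attr(traj, "scenario")) {
  kin <- patellar_kinematics(traj$poses$patella, traj$poses$femur,
                             scenario$layout$sphere_center)
  data.frame(t = traj$time, x = kin$x, y = kin$y, z = kin$z)
}

#' Identify tendon spring parameters from observed patellar motion
#'
#' Genetic-algorithm estimation of (K1, L1, K2, L2) — quadriceps and patellar
#' tendon stiffness and natural length — within a box of +/- `bounds_frac`
#' around the scenario defaults. The objective is the RMS distance error
#' (mm) of the simulated sphere center relative to the observed kinematics in
#' the femur frame; forces are deliberately not part of the objective.
#'
#' @param scenario [scenario_config()] describing the pathological setup
#'   (its spring values are the box centers).
#' @param observed data frame `t, x, y, z` from [observed_kinematics()], or a
#'   `pf_trajectory`.
#' @param motion bench motion ([synth_motion()]) driving the simulation.
#' @param geometry [build_bench_geometry()] assets (rebuilt if NULL).
#' @param bounds_frac box half-width as a fraction of the defaults (0.3).
#' @param ga [ga_config()].
#' @param t_span calibration window (default: full observed span).
#' @return object of class `pf_calibration`: `par` (named estimates),
#'   `truth_center` (box centers), `value` (objective, mm), `trace`,
#'   `evals`, `bounds`.
#' @export
calibrate_tendons <- function(scenario, observed, motion, geometry = NULL,
                              bounds_frac = 0.3, ga = ga_config(),
                              t_span = NULL) {
  obs_init <- NULL
  if (inherits(observed, "pf_trajectory")) {
    # start every candidate simulation from the observed initial state: the
    # recorded patella replaces per-candidate equilibration (the observed
    # start is the true parameters' equilibrium)
    k0 <- 1L
    obs_init <- list(
      pose = list(x = observed$poses$patella[k0, 1:3],
                  q = observed$poses$patella[k0, 4:7]),
      twist = if (!is.null(observed$twists$patella))
        list(v = observed$twists$patella[k0, 1:3],
             w = observed$twists$patella[k0, 4:6])
      else list(v = c(0, 0, 0), w = c(0, 0, 0)))
    observed <- observed_kinematics(observed, scenario)
  }
  if (is.null(geometry)) geometry <- build_bench_geometry(scenario)
  t_span <- t_span %||% range(observed$t)
  obs <- observed[observed$t >= t_span[1] & observed$t <= t_span[2], ]
  center <- c(K1 = scenario$quad_K, L1 = scenario$quad_L0,
              K2 = scenario$pat_K, L2 = scenario$pat_L0)
  lower <- center * (1 - bounds_frac)
  upper <- center * (1 + bounds_frac)
  objective <- function(par) {
    sc <- scenario
    sc$quad_K <- par[1]; sc$quad_L0 <- par[2]
    sc$pat_K <- par[3]; sc$pat_L0 <- par[4]
    tr <- if (is.null(obs_init))
      simulate_scenario(sc, motion, geometry, t_span = t_span)
    else
      simulate_scenario(sc, motion, geometry, t_span = t_span,
                        equilibrate = FALSE, patella_init = obs_init$pose,
                        patella_twist = obs_init$twist)
    kin <- observed_kinematics(tr, sc)
    X <- resample_cols(kin$t, kin[, c("x", "y", "z")], obs$t)
    1000 * sqrt(mean(rowSums((X - as.matrix(obs[, c("x", "y", "z")]))^2)))
  }
  res <- ga_optimize(objective, lower, upper, ga)
  # local polish of the GA winner (box-clamped Nelder-Mead)
  pol <- tryCatch(
    stats::optim(res$par, function(p) {
      if (any(p < lower | p > upper)) return(res$value * 10 + 1)
      objective(p)
    }, method = "Nelder-Mead",
       control = list(maxit = 150, reltol = 1e-8)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < res$value) {
    res$par <- pol$par
    res$value <- pol$value
  }
  structure(list(par = stats::setNames(res$par, names(center)),
                 value = res$value, trace = res$trace, evals = res$evals,
                 n_failed = res$n_failed,
                 bounds = list(lower = lower, upper = upper,
                               center = center),
                 objective = objective, scenario = scenario,
                 ga = ga, t_span = t_span),
            class = "pf_calibration")
}

#' @export
print.pf_calibration <- function(x, ...) {
  cat("Tendon-parameter calibration (GA)\n")
  err <- 100 * (x$par - x$bounds$center) / x$bounds$center
  for (i in seq_along(x$par))
    cat(sprintf("  %-3s %10.4f  (box center %10.4f, %+.1f%%)\n",
                names(x$par)[i], x$par[i], x$bounds$center[i], err[i]))
  cat(sprintf("  objective %.4f mm after %d evaluations\n", x$value,
              nrow(x$evals)))
  invisible(x)
}

#' @export
coef.pf_calibration <- function(object, ...) object$par

#' Apply calibrated tendon parameters to a scenario
#' @param scenario [scenario_config()]; `calib` a [calibrate_tendons()] result.
#' @export
apply_calibration <- function(scenario, calib) {
  p <- calib$par
  scenario$quad_K <- unname(p["K1"]); scenario$quad_L0 <- unname(p["L1"])
  scenario$pat_K <- unname(p["K2"]); scenario$pat_L0 <- unname(p["L2"])
  scenario
}

#' Simulate a treatment edit with calibrated parameters
#'
#' Re-simulates the calibrated scenario after a treatment edit (default:
#' tibial-attachment medialization, the bench analogue of tibial tuberosity
#' transfer) and reports detected events; when a reference trajectory is
#' supplied a [rmse_report()] is included.
#'
#' @param calib [calibrate_tendons()] result.
#' @param edit named list of scenario fields to change (e.g.
#'   `list(tibia_attach = "medial")`); an empty list re-simulates the
#'   calibrated pathological scenario unchanged.
#' @param motion bench motion driving the simulation.
#' @param geometry bench geometry assets.
#' @param reference optional reference `pf_trajectory` for validation.
#' @param t_span simulated window.
#' @return list of class `pf_treatment`: `trajectory`, `events`,
#'   `scenario`, and `report` (NULL without a reference).
#' @export
predict_treatment <- function(calib, edit = list(tibia_attach = "medial"),
                              motion, geometry = NULL, reference = NULL,
                              t_span = NULL) {
  sc <- apply_calibration(calib$scenario, calib)
  for (nm in names(edit)) sc[[nm]] <- edit[[nm]]
  tr <- simulate_scenario(sc, motion, geometry, t_span = t_span)
  ev <- detect_events(tr, sc)
  rep <- if (!is.null(reference))
    rmse_report(tr, reference, sc$layout$sphere_center) else NULL
  structure(list(trajectory = tr, events = ev, scenario = sc,
                 report = rep),
            class = "pf_treatment")
}

#' @export
print.pf_treatment <- function(x, ...) {
  cat("Treatment prediction:", length(x$events), "event(s)\n")
  for (e in x$events)
    cat(sprintf("  %s [%.3f, %.3f] s\n", e$type, e$t_start, e$t_end))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
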