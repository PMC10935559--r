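# Bench scenarios: the synthetic sensorized knee rig. World frame = femur
# frame at rest (x proximal along the groove, y medial-lateral with medial
# positive, z height off the groove floor; gravity -z). The knee center is
# the origin; femur and tibia are guided, the patella is the free body.

#' Fixed geometric layout of the synthetic bench
#'
#' Positions are body-frame coordinates (m). Attachment supports offer a
#' medial and a lateral position on both femur and tibia, mirroring the
#' adjustable supports of a sensorized knee rig.
#' @param sphere_radius patellar button radius (m).
#' @export
bench_layout <- function(sphere_radius = 0.010) {
  list(
    hip = c(0.30, 0, 0),
    surface_z = 0.025,
    quad_anchor = c(0.19, 0, 0.070),
    quad_attach_y = c(medial = 0.02, lateral = -0.02),
    tubercle = c(-0.068, 0, 0.035),
    tubercle_y = c(medial = 0.010, lateral = -0.046),
    sphere_radius = sphere_radius,
    sphere_center = c(0, 0, 0),
    sup_pole = c(0.018, 0, 0.004),
    inf_pole = c(-0.018, 0, 0.004),
    strap_halfwidth = 0.008,
    patella_mass = 0.05,
    patella_inertia = c(1.2e-5, 1.5e-5, 1.5e-5),
    patella_rot_damping = 2e-4,
    femur_mass = 1.0, femur_inertia = c(0.01, 0.01, 0.01),
    tibia_mass = 1.0, tibia_inertia = c(0.01, 0.01, 0.01),
    markers = list(
      femur = list(f1 = c(0.25, 0.05, 0.05), f2 = c(0.25, -0.05, 0.02),
                   f3 = c(0.18, 0.03, 0.09), f4 = c(0.15, -0.06, 0.06)),
      tibia = list(t1 = c(-0.15, 0.04, 0.05), t2 = c(-0.15, -0.05, 0.02),
                   t3 = c(-0.22, 0.03, 0.08), t4 = c(-0.25, -0.04, 0.04)),
      patella = list(p1 = c(0, 0, 0.05), p2 = c(0.05, 0, 0.1),
                     p3 = c(-0.05, 0.02, 0.1), p4 = c(0, -0.05, 0.09))))
}

#' Scenario configuration
#'
#' Bundles the attachment configuration, tendon spring parameters (bench
#' defaults: quadriceps K1 = 156 N/m, L1 = 0.1432 m; patellar tendon
#' K2 = 629 N/m, L2 = 0.0714 m; damping 0.01 K), the optional rigid
#' extension of the quadriceps spring (0.0196 m models the lengthened
#' variant), the collision backend, contact-model parameters and integrator
#' settings.
#'
#' @param femur_attach,tibia_attach `"medial"` or `"lateral"`.
#' @param quad_K,quad_L0 quadriceps spring stiffness (N/m) / natural length (m).
#' @param pat_K,pat_L0 patellar tendon spring stiffness / natural length.
#' @param quad_rigid_extension rigid series element on the quadriceps spring
#'   (m); 0 by default, 0.0196 for the lengthened configuration.
#' @param backend `"analytic:2"`, `"analytic:4"`, `"analytic:5"`,
#'   `"mesh:coarse"` or `"mesh:fine"`.
#' @param flores [flores_params()]; default stiffness 3e6 N/m^1.5 keeps the
#'   indentation well below the button radius while integrable at 1 ms.
#' @param groove [groove_params()].
#' @param sim [sim_config()]; if NULL, the backend's default step is used
#'   (1 ms analytic, 0.1 ms coarse mesh, 0.05 ms fine mesh).
#' @param cycle_period flexion-extension cycle period (s).
#' @param cycles number of flexion-extension cycles.
#' @param start_flexion initial knee flexion (deg).
#' @param flexion_amplitude half-range of the flexion profile (deg).
#' @export
scenario_config <- function(femur_attach = c("medial", "lateral"),
                            tibia_attach = c("medial", "lateral"),
                            quad_K = 156, quad_L0 = 0.1432,
                            pat_K = 629, pat_L0 = 0.0714,
                            quad_rigid_extension = 0,
                            backend = "analytic:5",
                            flores = flores_params(k_n = 3e6, p = 1.5,
                                                   eps = 0.9),
                            groove = groove_params(),
                            sim = NULL,
                            layout = bench_layout(),
                            cycle_period = 2.0, cycles = 2,
                            start_flexion = 45, flexion_amplitude = 40) {
  femur_attach <- match.arg(femur_attach)
  tibia_attach <- match.arg(tibia_attach)
  stopifnot(quad_K > 0, quad_L0 > 0, pat_K > 0, pat_L0 > 0,
            quad_rigid_extension >= 0)
  bk <- parse_backend(backend)
  if (is.null(sim)) {
    # the fine mesh integrates cleanly at the default 1 ms; the coarse mesh
    # needs 0.1 ms to tame facet-induced force jumps
    h <- if (bk$type == "analytic" || identical(bk$level, "fine")) 1e-3
         else 1e-4
    sim <- sim_config(h = h)
  }
  structure(list(femur_attach = femur_attach, tibia_attach = tibia_attach,
                 quad_K = quad_K, quad_L0 = quad_L0,
                 pat_K = pat_K, pat_L0 = pat_L0,
                 quad_rigid_extension = quad_rigid_extension,
                 backend = backend, flores = flores, groove = groove,
                 sim = sim, layout = layout,
                 cycle_period = cycle_period, cycles = cycles,
                 start_flexion = start_flexion,
                 flexion_amplitude = flexion_amplitude),
            class = "pf_scenario")
}

parse_backend <- function(backend) {
  parts <- strsplit(backend, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 ||
      !(parts[1] %in% c("analytic", "mesh")) ||
      (parts[1] == "analytic" && !parts[2] %in% c("2", "4", "5")) ||
      (parts[1] == "mesh" && !parts[2] %in% c("coarse", "fine")))
    stop("invalid backend '", backend, "'; valid backends: analytic:2, ",
         "analytic:4, analytic:5, mesh:coarse, mesh:fine")
  list(type = parts[1],
       order = if (parts[1] == "analytic") as.integer(parts[2]) else NA,
       level = if (parts[1] == "mesh") parts[2] else NA)
}

#' Build the bench geometry assets for a scenario
#'
#' Generates the femoral trochlear meshes (coarse 0.1 mm / 1 deg and fine
#' 0.006 mm / 0.5 deg quality targets), the polynomial surface fits of the
#' fine vertex cloud (orders 2, 4, 5) and the icosphere patellar button.
#' Meshes and fits live in the femur body frame (groove floor raised to the
#' layout's `surface_z`).
#'
#' @param scenario [scenario_config()].
#' @param sphere_subdivisions icosphere subdivision level (default 3; the
#'   fine button uses 4).
#' @return list: `surface_coarse`, `surface_fine` (pf_mesh), `fits` (P2, P4,
#'   P5), `button` (pf_mesh, patella frame), `groove`, `layout`.
#' @export
build_bench_geometry <- function(scenario, sphere_subdivisions = NULL) {
  gp <- scenario$groove
  lay <- scenario$layout
  lift <- function(mesh) {
    v <- mesh$vertices
    v[, 3] <- v[, 3] + lay$surface_z
    out <- pf_mesh(v, mesh$faces)
    attr(out, "quality") <- attr(mesh, "quality")
    attr(out, "grid") <- attr(mesh, "grid")
    out
  }
  coarse <- make_trochlear_surface(gp, mesh_quality_target(1e-4, 1.0))
  fine <- make_trochlear_surface(gp, mesh_quality_target(6e-6, 0.5))
  coarse <- lift(coarse); fine <- lift(fine)
  fits <- fit_polynomial_orders(fine$vertices, orders = c(2, 4, 5))
  bk <- parse_backend(scenario$backend)
  subs <- sphere_subdivisions %||%
    (if (identical(bk$level, "coarse")) 3L else 4L)
  button <- make_icosphere(lay$sphere_radius, subs,
                           center = lay$sphere_center)
  list(surface_coarse = coarse, surface_fine = fine, fits = fits,
       button = button, groove = gp, layout = lay)
}

# world position of the tibial tubercle at knee flexion theta (rad)
tubercle_world <- function(layout, tibia_attach, theta) {
  p <- layout$tubercle
  p[2] <- layout$tubercle_y[[tibia_attach]]
  drop(rot_axis(2, -theta) %*% p)
}

#' Synthesize bench motion and virtual optical markers
#'
#' The femur stays fixed at the hip apart from a small prescribed rocking;
#' the tibia follows a smooth flexion-extension profile
#' `theta(t) = start + amplitude * sin(2 pi t / period)` (two cycles by
#' default, starting near 45 deg). Eight virtual markers (4 femur + 4 tibia)
#' provide the guided-body inputs; a 4-marker cluster on a patella post is
#' emitted for validation. Optional iid Gaussian marker noise.
#'
#' @param scenario [scenario_config()].
#' @param fs sampling frequency (Hz), default 100.
#' @param noise_sd marker noise standard deviation (m), default 0.
#' @param seed RNG seed for the noise.
#' @return list: `markers` (long data frame), `fs`, `truth` (per body:
#'   `time`, `x`, `q`), `knee_angle` (deg), `recipes` (per-body
#'   [vaughan_frames()] recipes), `duration`.
#' @export
synth_motion <- function(scenario, fs = 100, noise_sd = 0, seed = 1L) {
  lay <- scenario$layout
  Tc <- scenario$cycle_period
  dur <- scenario$cycles * Tc
  times <- seq(0, dur, by = 1 / fs)
  th <- (scenario$start_flexion +
         scenario$flexion_amplitude * sin(2 * pi * times / Tc)) * pi / 180
  rock <- 1.5 * pi / 180 * sin(2 * pi * times / (1.3 * Tc))
  nfr <- length(times)
  truth <- list()
  # femur: rotation about y through the hip point
  fx <- matrix(0, nfr, 3); fq <- matrix(0, nfr, 4)
  for (k in seq_len(nfr)) {
    R <- rot_axis(2, rock[k])
    fx[k, ] <- lay$hip - drop(R %*% lay$hip)
    fq[k, ] <- mat_to_quat(R)
  }
  truth$femur <- list(time = times, x = fx, q = fq)
  # tibia: rotation about y through the knee center (origin)
  tx <- matrix(0, nfr, 3); tq <- matrix(0, nfr, 4)
  for (k in seq_len(nfr)) tq[k, ] <- mat_to_quat(rot_axis(2, -th[k]))
  truth$tibia <- list(time = times, x = tx, q = tq)
  # patella: kinematic approximation gliding along the groove (used for
  # reconstruction closure and as the equilibrium initial guess)
  gp <- scenario$groove
  xp <- 0.012 - (th * 180 / pi - 5) / 80 * 0.034
  zp <- lay$surface_z + gp$analytic_form(xp, 0) + lay$sphere_radius
  px <- cbind(xp, 0, zp)
  pq <- matrix(0, nfr, 4)
  for (k in seq_len(nfr))
    pq[k, ] <- mat_to_quat(rot_axis(2, -(th[k] - pi / 4) * 0.3))
  truth$patella <- list(time = times, x = px, q = pq)
  # markers
  set.seed(seed)
  rows <- list()
  for (body in names(lay$markers)) {
    tr <- truth[[body]]
    for (mid in names(lay$markers[[body]])) {
      loc <- lay$markers[[body]][[mid]]
      pw <- t(vapply(seq_len(nfr), function(k)
        drop(quat_to_mat(tr$q[k, ]) %*% loc) + tr$x[k, ], numeric(3)))
      if (noise_sd > 0)
        pw <- pw + matrix(stats::rnorm(3 * nfr, 0, noise_sd), nfr, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = seq_len(nfr), time = times, id = mid,
        x = pw[, 1], y = pw[, 2], z = pw[, 3])
    }
  }
  markers <- do.call(rbind, rows)
  recipes <- lapply(lay$markers, function(locs) {
    ids <- names(locs)
    list(origin = ids[1], axis = ids[2], plane = ids[3], local = locs)
  })
  list(markers = markers, fs = fs, truth = truth,
       knee_angle = th * 180 / pi, recipes = recipes, duration = dur,
       noise_sd = noise_sd, seed = seed)
}

#' Assemble the bench multibody model
#'
#' @param scenario [scenario_config()].
#' @param guidance named list with `femur` and `tibia` guidance functions
#'   (e.g. from [guidance_spline()] over synthesized or reconstructed poses).
#' @param geometry from [build_bench_geometry()] (rebuilt if NULL).
#' @param patella_init optional initial patella pose `list(x, q)`.
#' @return `pf_model` with the patella as the single free body.
#' @export
build_bench_model <- function(scenario, guidance, geometry = NULL,
                              patella_init = NULL) {
  if (is.null(geometry)) geometry <- build_bench_geometry(scenario)
  lay <- scenario$layout
  bk <- parse_backend(scenario$backend)
  p0 <- patella_init %||% list(x = c(0, 0, lay$surface_z +
                                       scenario$groove$analytic_form(0, 0) +
                                       lay$sphere_radius),
                               q = c(1, 0, 0, 0))
  bodies <- list(
    rigid_body("femur", lay$femur_mass, lay$femur_inertia, guided = TRUE),
    rigid_body("tibia", lay$tibia_mass, lay$tibia_inertia, guided = TRUE),
    rigid_body("patella", lay$patella_mass, lay$patella_inertia,
               x = p0$x, q = p0$q,
               rot_damping = lay$patella_rot_damping))
  qa <- lay$quad_anchor
  qa[2] <- lay$quad_attach_y[[scenario$femur_attach]]
  tb <- lay$tubercle
  tb[2] <- lay$tubercle_y[[scenario$tibia_attach]]
  # each tendon is a two-strand strap (half stiffness per strand, strands
  # offset medially/laterally): the strap width gives the patella the roll
  # stiffness that a point attachment cannot transmit; strand tensions sum
  # to the load-cell channel
  ws <- c(0, lay$strap_halfwidth, 0)
  strand <- function(K, L0, ext, body_A, pA, pB, sgn)
    spring_damper_params(
      K = K / 2, L0 = L0, rigid_extension = ext,
      attach_A = list(body = body_A, point = pA + sgn * ws),
      attach_B = list(body = "patella", point = pB + sgn * ws))
  springs <- list(
    strand(scenario$quad_K, scenario$quad_L0,
           scenario$quad_rigid_extension, "femur", qa, lay$sup_pole, +1),
    strand(scenario$quad_K, scenario$quad_L0,
           scenario$quad_rigid_extension, "femur", qa, lay$sup_pole, -1),
    strand(scenario$pat_K, scenario$pat_L0, 0, "tibia", tb,
           lay$inf_pole, +1),
    strand(scenario$pat_K, scenario$pat_L0, 0, "tibia", tb,
           lay$inf_pole, -1))
  sphere <- sphere_primitive(lay$sphere_center, lay$sphere_radius)
  contact <- if (bk$type == "analytic") {
    contact_pair_analytic(sphere, "patella",
                          geometry$fits[[paste0("P", bk$order)]], "femur",
                          scenario$flores)
  } else {
    mesh <- if (bk$level == "coarse") geometry$surface_coarse
            else geometry$surface_fine
    contact_pair_mesh(build_aabb_tree(mesh), "femur", geometry$button,
                      "patella", scenario$flores)
  }
  model <- assemble(bodies, springs, list(contact),
                    constraints = list(constraint_spherical("femur", lay$hip,
                                                            lay$hip)),
                    guidance = guidance)
  model$spring_groups <- c(1L, 1L, 2L, 2L)   # 1 = quadriceps, 2 = tendon
  model
}

#' End-to-end bench simulation of a scenario
#'
#' Synthesizes (or accepts) the bench motion, builds guidance splines for
#' femur and tibia, initializes the patella at its static equilibrium near
#' the recorded pose, and runs the guided dynamic simulation.
#'
#' @param scenario [scenario_config()].
#' @param motion from [synth_motion()] (generated if NULL).
#' @param geometry from [build_bench_geometry()] (generated if NULL).
#' @param t_span simulated interval (default the full motion).
#' @param equilibrate run [static_equilibrium()] first (default TRUE).
#' @param record_every see [simulate_model()].
#' @return `pf_trajectory`, with the motion attached as attribute `motion`.
#' @export
simulate_scenario <- function(scenario, motion = NULL, geometry = NULL,
                              t_span = NULL, equilibrate = TRUE,
                              record_every = NULL, fast = TRUE,
                              patella_init = NULL, patella_twist = NULL) {
  if (is.null(motion)) motion <- synth_motion(scenario)
  if (is.null(geometry)) geometry <- build_bench_geometry(scenario)
  guid <- list(
    femur = guidance_spline(motion$truth$femur$time, motion$truth$femur$x,
                            motion$truth$femur$q),
    tibia = guidance_spline(motion$truth$tibia$time, motion$truth$tibia$x,
                            motion$truth$tibia$q))
  t_span <- t_span %||% c(0, motion$duration)
  k0 <- which.min(abs(motion$truth$patella$time - t_span[1]))
  p_init <- patella_init %||% list(x = motion$truth$patella$x[k0, ],
                                   q = motion$truth$patella$q[k0, ])
  model <- build_bench_model(scenario, guid, geometry,
                             patella_init = p_init)
  state <- model_state(model, t_span[1])
  if (!is.null(patella_twist))
    state$twists$patella <- patella_twist
  bk <- parse_backend(scenario$backend)
  if (equilibrate) {
    if (bk$type == "mesh") {
      # equilibrate on the exact analytic surface (identical geometry); the
      # faceted mesh force field is only piecewise smooth, which defeats a
      # Newton polish below the facet force granularity
      sc_eq <- scenario
      sc_eq$backend <- "analytic:5"
      model_eq <- build_bench_model(sc_eq, guid, geometry,
                                    patella_init = p_init)
      st_eq <- static_equilibrium(model_eq, model_state(model_eq, t_span[1]),
                                  t = t_span[1], force_tol = 1e-6)
      state$poses <- st_eq$poses
      state$twists <- st_eq$twists
    } else {
      state <- static_equilibrium(model, state, t = t_span[1],
                                  force_tol = 1e-6)
    }
  }
  traj <- if (fast && bk$type == "analytic") {
    wall0 <- proc.time()[3]
    tr <- simulate_bench_fast(model, scenario, t_span, scenario$sim, state,
                              record_every = record_every %||% 1L)
    tr$stats$wall_s <- proc.time()[3] - wall0
    tr$stats$realtime_ratio <- (t_span[2] - t_span[1]) / max(tr$stats$wall_s,
                                                             1e-9)
    tr
  } else {
    simulate_model(model, t_span, scenario$sim, state = state,
                   record_every = record_every)
  }
  traj <- freeze_after_dislocation(traj)
  attr(traj, "motion") <- motion
  attr(traj, "scenario") <- scenario
  traj
}

# Hold the trajectory constant shortly after a sustained loss of contact.
# A dislocated patella leaves the modeled implant surface; its subsequent
# free flight on point-attached springs is outside the model's scope (the
# physical trial also ends at dislocation), so the state is frozen a short
# hold time after separation.
freeze_after_dislocation <- function(traj, loss_window = 0.03, hold = 0.05) {
  lost <- traj$contact$in_contact == 0
  r <- rle(lost)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    if (traj$time[ends[i]] - traj$time[starts[i]] < loss_window) next
    if (ends[i] == length(lost) ||
        traj$time[ends[i]] - traj$time[starts[i]] >= loss_window) {
      t_freeze <- traj$time[starts[i]] + hold
      k <- which(traj$time >= t_freeze)
      if (length(k) > 1) {
        k0 <- k[1]
        idx <- k[-1]
        traj$poses$patella[idx, ] <- rep(traj$poses$patella[k0, ],
                                         each = length(idx))
        if (!is.null(traj$twists$patella))
          traj$twists$patella[idx, ] <- 0
        traj$contact$in_contact[idx] <- 0
        traj$contact$Fmag[idx] <- 0
        traj$springs[idx, ] <- rep(traj$springs[k0, ], each = length(idx))
        traj$frozen_from <- traj$time[k0]
      }
      break
    }
  }
  traj
}
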