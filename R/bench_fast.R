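# Compiled fast path for the standard bench model (free patella, two guided
# tendon anchors, analytic contact). Produces the same pf_trajectory shape as
# the generic stepper; agreement between the two paths is covered by tests.

# Evaluate guidance functions on the substep grid into plain arrays.
guided_arrays <- function(model, scenario, times) {
  n <- length(times)
  fem <- model$guidance$femur
  tib <- model$guidance$tibia
  fx <- matrix(0, n, 3); fq <- matrix(0, n, 4)
  fv <- matrix(0, n, 3); fw <- matrix(0, n, 3)
  gf <- lapply(times, fem)
  gt <- lapply(times, tib)
  for (k in seq_len(n)) {
    fx[k, ] <- gf[[k]]$x; fq[k, ] <- gf[[k]]$q
    fv[k, ] <- gf[[k]]$v; fw[k, ] <- gf[[k]]$w
  }
  anchors <- anchors_v <- vector("list", length(model$springs))
  for (si in seq_along(model$springs)) {
    at <- model$springs[[si]]$attach_A
    g <- if (at$body == "femur") gf else gt
    am <- matrix(0, n, 3); vm <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      R <- quat_to_mat(g[[k]]$q)
      am[k, ] <- drop(R %*% at$point) + g[[k]]$x
      vm[k, ] <- g[[k]]$v + drop(R %*% cross3(g[[k]]$w, at$point))
    }
    anchors[[si]] <- am
    anchors_v[[si]] <- vm
  }
  list(anchors = anchors, anchors_v = anchors_v,
       fem_x = fx, fem_q = fq, fem_v = fv, fem_w = fw)
}

# Fast bench simulation; state must come from model_state/static_equilibrium
# on the matching model. Returns a pf_trajectory.
simulate_bench_fast <- function(model, scenario, t_span, cfg,
                                state, record_every = 1L) {
  state <- init_accelerations(model, state)
  h <- cfg$h
  n_steps <- as.integer(round((t_span[2] - t_span[1]) / h))
  times <- t_span[1] + h * (0:n_steps)
  ga <- guided_arrays(model, scenario, times)
  surf <- model$contacts[[1]]$surface
  sph <- model$contacts[[1]]$sphere
  lay <- scenario$layout
  groups <- model$spring_groups %||% seq_along(model$springs)
  springs <- list(
    K = vapply(model$springs, `[[`, 0, "K"),
    L0 = vapply(model$springs, function(sp) sp$L0 + sp$rigid_extension, 0),
    c = vapply(model$springs, `[[`, 0, "c"),
    attach = t(vapply(model$springs, function(sp) sp$attach_B$point,
                      numeric(3))),
    group = as.integer(groups) - 1L)
  pat <- model$bodies$patella
  st0 <- c(state$poses$patella$x, state$poses$patella$q,
           state$twists$patella$v, state$twists$patella$w,
           state$acc$patella$a, state$acc$patella$al)
  dom <- surf$fit_domain
  out <- cpp_bench_simulate(
    body = list(mass = pat$mass, inertia = diag(pat$inertia),
                rot_damping = pat$rot_damping),
    springs = springs,
    sphere = list(center = sph$center, radius = sph$radius),
    surface = list(coef = surf$scaled$coef, ei = surf$fast$ei,
                   ej = surf$fast$ej, order = surf$fast$order,
                   cx = surf$scaled$cx, cy = surf$scaled$cy,
                   sx = surf$scaled$sx, sy = surf$scaled$sy,
                   domain = c(dom$x[1], dom$x[2], dom$y[1], dom$y[2])),
    flores = unclass(model$contacts[[1]]$flores),
    guided = ga, gravity = model$gravity, state0 = st0,
    h = h, gamma = cfg$gamma, beta = cfg$beta, n_steps = n_steps,
    record_every = as.integer(record_every),
    newton_tol = cfg$newton_tol * max(1, pat$mass * 9.81) ,
    newton_max = cfg$newton_max_iter, t0 = t_span[1])
  rec <- out$rec
  ridx <- seq(1L, n_steps + 1L, by = record_every)
  nr <- nrow(rec)
  poses <- list(femur = cbind(ga$fem_x, ga$fem_q)[ridx, , drop = FALSE],
                tibia = t(vapply(ridx, function(k) {
                  g <- model$guidance$tibia(times[k])
                  c(g$x, g$q)
                }, numeric(7))),
                patella = rec[, 2:8, drop = FALSE])
  contact <- data.frame(t = rec[, 1], Fmag = rec[, 17],
                        px = rec[, 20], py = rec[, 21], pz = rec[, 22],
                        nx = NA_real_, ny = NA_real_, nz = rec[, 24],
                        delta = rec[, 18], delta_dot = rec[, 19],
                        in_contact = rec[, 23])
  structure(list(
    time = rec[, 1],
    poses = poses,
    twists = list(patella = rec[, 9:14, drop = FALSE]),
    springs = rec[, 15:16, drop = FALSE],
    contact = contact,
    residuals = matrix(0, nr, 2, dimnames = list(NULL, c("phi", "vel"))),
    events = out$events,
    stats = list(n_steps = n_steps, wall_s = NA_real_,
                 realtime_ratio = NA_real_, max_phi = 0, max_vel_resid = 0),
    config = cfg,
    final_state = out$final),
    class = "pf_trajectory")
}
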