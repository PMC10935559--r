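# Constrained rigid-body dynamics: augmented-Lagrangian index-3 stepping with
# Newmark integration and velocity/acceleration projections onto the
# constraint subspace. Free-body unknowns are the accelerations
# (world-frame linear, body-frame angular); orientations are updated through
# the quaternion exponential of the Newmark rotation increment, so unit norm
# holds by construction.

#' Define a rigid body
#'
#' @param id character body id.
#' @param mass mass (kg), > 0.
#' @param inertia 3x3 symmetric positive-definite inertia tensor in the body
#'   frame (kg m^2), or a length-3 diagonal.
#' @param x initial position (m); `q` initial unit quaternion (w, x, y, z).
#' @param v initial world linear velocity (m/s); `w` initial body angular
#'   velocity (rad/s).
#' @param guided TRUE if the body's motion is prescribed (rheonomically
#'   guided); guided bodies contribute no unknowns.
#' @param rot_damping viscous rotational damping coefficient (N m s);
#'   models distributed resistance (e.g. tendon straps) that point
#'   attachments cannot transmit.
#' @param lin_damping viscous linear damping coefficient (N s/m); zero in
#'   dynamic runs, used by the static-equilibrium settle to kill slow
#'   translational modes.
#' @export
rigid_body <- function(id, mass, inertia, x = c(0, 0, 0),
                       q = c(1, 0, 0, 0), v = c(0, 0, 0), w = c(0, 0, 0),
                       guided = FALSE, rot_damping = 0, lin_damping = 0) {
  if (length(inertia) == 3) inertia <- diag(as.numeric(inertia))
  stopifnot(mass > 0, nrow(inertia) == 3,
            isTRUE(all.equal(inertia, t(inertia), tolerance = 1e-9)))
  if (any(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("inertia must be positive definite")
  structure(list(id = id, mass = mass, inertia = inertia,
                 x = as.numeric(x), q = quat_normalize(as.numeric(q)),
                 v = as.numeric(v), w = as.numeric(w),
                 guided = isTRUE(guided), rot_damping = rot_damping,
                 lin_damping = lin_damping),
            class = "pf_body")
}

#' Spherical-joint constraint (body point pinned to a world anchor)
#' @param body body id; `point` local attachment; `anchor` world point.
#' @export
constraint_spherical <- function(body, point, anchor) {
  structure(list(type = "spherical", body = body, point = as.numeric(point),
                 anchor = as.numeric(anchor), n_eq = 3L),
            class = "pf_constraint")
}

#' Distance constraint (body point at fixed distance from a world anchor)
#' @param body body id; `point` local point; `anchor` world point; `L`
#'   distance (m).
#' @export
constraint_distance <- function(body, point, anchor, L) {
  structure(list(type = "distance", body = body, point = as.numeric(point),
                 anchor = as.numeric(anchor), L = L, n_eq = 1L),
            class = "pf_constraint")
}

#' Simulation configuration
#'
#' @param h time step (s); 1 ms suits the analytic backend, 0.1 ms the coarse
#'   mesh backend (0.05 ms for its most demanding runs).
#' @param newmark_gamma,newmark_beta Newmark parameters; the default (1/2,
#'   1/4) is the unconditionally stable average-acceleration rule.
#' @param alpha augmented-Lagrangian penalty (scaled internally by the leading
#'   mass).
#' @param al_max_iter maximum multiplier updates per step.
#' @param newton_max_iter,newton_tol inner Newton settings.
#' @param pos_tol,vel_tol constraint residual tolerances (m, m/s).
#' @param jac_every steps between refreshes of the cached Newton Jacobian.
#' @param seed deterministic seed recorded with the run.
#' @export
sim_config <- function(h = 1e-3, newmark_gamma = 0.5, newmark_beta = 0.25,
                       alpha = 1e7, al_max_iter = 25L,
                       newton_max_iter = 50L, newton_tol = 1e-9,
                       pos_tol = 1e-8, vel_tol = 1e-8,
                       jac_every = 25L, seed = 1L) {
  stopifnot(h > 0, alpha > 0)
  if (newmark_gamma == 0.5 &&
      (newmark_beta < 0.25 || newmark_beta > 0.5))
    stop("with gamma = 0.5, beta must lie in [0.25, 0.5]")
  structure(list(h = h, gamma = newmark_gamma, beta = newmark_beta,
                 alpha = alpha, al_max_iter = al_max_iter,
                 newton_max_iter = newton_max_iter, newton_tol = newton_tol,
                 pos_tol = pos_tol, vel_tol = vel_tol,
                 jac_every = jac_every, seed = seed),
            class = "pf_sim_config")
}

#' Assemble a multibody model
#'
#' @param bodies list of [rigid_body()].
#' @param springs list of [spring_damper_params()] with attachments resolved
#'   to body ids (`"world"` allowed with world-frame points).
#' @param contacts list of contact definitions built by
#'   [contact_pair_analytic()] or [contact_pair_mesh()].
#' @param constraints list of constraint objects.
#' @param guidance named list (by body id) of guidance functions
#'   `function(t) -> list(x, q, v, w)`; required for every guided body.
#' @param gravity world gravity vector (m/s^2).
#' @return `pf_model`; element `n_unknowns` reports the net degrees of
#'   freedom (6 per free body minus constraint equations on free bodies).
#' @export
assemble <- function(bodies, springs = list(), contacts = list(),
                     constraints = list(), guidance = list(),
                     gravity = c(0, 0, -9.81)) {
  ids <- vapply(bodies, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate body ids: ",
                               ids[duplicated(ids)][1])
  names(bodies) <- ids
  for (b in bodies)
    if (b$guided && is.null(guidance[[b$id]]))
      stop("guided body '", b$id, "' has no guidance")
  free <- ids[!vapply(bodies, `[[`, TRUE, "guided")]
  n_con <- 0L
  for (cn in constraints)
    if (cn$body %in% free) n_con <- n_con + cn$n_eq
  structure(list(bodies = bodies, springs = springs, contacts = contacts,
                 constraints = constraints, guidance = guidance,
                 gravity = as.numeric(gravity), free = free,
                 n_unknowns = 6L * length(free) - n_con),
            class = "pf_model")
}

#' Analytic contact pair (sphere body vs polynomial surface body)
#' @param sphere [sphere_primitive()] attached to `sphere_body`.
#' @param surface `pf_poly_surface` attached to `surface_body` (surface frame
#'   = body frame).
#' @param flores [flores_params()].
#' @export
contact_pair_analytic <- function(sphere, sphere_body, surface, surface_body,
                                  flores) {
  structure(list(type = "analytic", sphere = sphere,
                 sphere_body = sphere_body, surface = surface,
                 surface_body = surface_body, flores = flores,
                 episodes = contact_episodes()),
            class = "pf_contact_pair")
}

#' Mesh contact pair (mesh body B vs mesh body A with AABB tree)
#' @param treeA [build_aabb_tree()] of body A's mesh (body frame).
#' @param body_A,body_B body ids (A carries the reference surface).
#' @param meshB `pf_mesh` of body B (body frame).
#' @param flores [flores_params()].
#' @export
contact_pair_mesh <- function(treeA, body_A, meshB, body_B, flores) {
  structure(list(type = "mesh", treeA = treeA, body_A = body_A,
                 meshB = meshB, body_B = body_B, flores = flores,
                 episodes = contact_episodes()),
            class = "pf_contact_pair")
}

#' Initial system state of a model
#' @param model `pf_model`.
#' @param t initial time.
#' @export
model_state <- function(model, t = 0) {
  poses <- lapply(model$bodies, function(b) list(x = b$x, q = b$q))
  twists <- lapply(model$bodies, function(b) list(v = b$v, w = b$w))
  for (id in names(model$guidance)) {
    g <- model$guidance[[id]](t)
    poses[[id]] <- list(x = g$x, q = g$q)
    twists[[id]] <- list(v = g$v, w = g$w)
  }
  acc <- stats::setNames(rep(list(list(a = c(0, 0, 0), al = c(0, 0, 0))),
                             length(model$free)), model$free)
  active <- Filter(function(cn) cn$body %in% model$free, model$constraints)
  lam <- rep(0, sum(vapply(active, `[[`, 0L, "n_eq")))
  list(t = t, poses = poses, twists = twists, acc = acc, lam = lam)
}

# ---- forces -------------------------------------------------------------

# Total applied force (world) and torque (body frame) on each free body.
# commit/record control contact-episode updates and logging.
model_forces <- function(model, poses, twists, t, commit = FALSE,
                         record = FALSE) {
  F <- stats::setNames(rep(list(c(0, 0, 0)), length(model$free)), model$free)
  Tq <- F
  for (id in model$free) {
    F[[id]] <- model$bodies[[id]]$mass * model$gravity
    if (model$bodies[[id]]$rot_damping > 0)
      Tq[[id]] <- Tq[[id]] - model$bodies[[id]]$rot_damping * twists[[id]]$w
    if ((model$bodies[[id]]$lin_damping %||% 0) > 0)
      F[[id]] <- F[[id]] - model$bodies[[id]]$lin_damping * twists[[id]]$v
  }
  spring_log <- numeric(length(model$springs))
  for (si in seq_along(model$springs)) {
    sp <- model$springs[[si]]
    wr <- spring_wrench(sp, poses, twists)
    spring_log[si] <- wr$tension
    for (side in c("A", "B")) {
      at <- sp[[paste0("attach_", side)]]
      if (!identical(at$body, "world") && at$body %in% model$free) {
        Fv <- if (side == "A") wr$F_on_A else wr$F_on_B
        pt <- if (side == "A") wr$A else wr$B
        F[[at$body]] <- F[[at$body]] + Fv
        R <- quat_to_mat(poses[[at$body]]$q)
        Tq[[at$body]] <- Tq[[at$body]] +
          drop(crossprod(R, cross3(pt - poses[[at$body]]$x, Fv)))
      }
    }
  }
  contact_log <- NULL
  for (cp in model$contacts) {
    if (cp$type == "analytic") {
      sb <- cp$sphere_body; fb <- cp$surface_body
      patch <- sphere_surface_contact(
        cp$sphere, poses[[sb]], cp$surface, poses[[fb]],
        twist_sphere = twists[[sb]], twist_surface = twists[[fb]],
        episodes = cp$episodes, commit = commit,
        warm_start = cp$episodes$warm)
    } else {
      sb <- cp$body_B; fb <- cp$body_A
      patches <- mesh_contacts(cp$treeA, poses[[fb]], cp$meshB, poses[[sb]],
                               twistA = twists[[fb]], twistB = twists[[sb]],
                               episodes = cp$episodes, commit = commit)
      patch <- if (length(patches)) patches else NULL
    }
    plist <- if (is.null(patch)) list()
             else if (inherits(patch, "pf_contact_patch")) list(patch)
             else patch
    Fm_tot <- 0; rec <- NULL
    for (pa in plist) {
      ff <- flores_force(cp$flores, pa)
      Fm_tot <- Fm_tot + ff$Fmag
      if (sb %in% model$free) {
        F[[sb]] <- F[[sb]] + ff$F
        Rb <- quat_to_mat(poses[[sb]]$q)
        Tq[[sb]] <- Tq[[sb]] +
          drop(crossprod(Rb, cross3(pa$point - poses[[sb]]$x, ff$F)))
      }
      if (fb %in% model$free) {
        F[[fb]] <- F[[fb]] - ff$F
        Rf <- quat_to_mat(poses[[fb]]$q)
        Tq[[fb]] <- Tq[[fb]] -
          drop(crossprod(Rf, cross3(pa$point - poses[[fb]]$x, ff$F)))
      }
      if (record && is.null(rec))
        rec <- c(pa$point, pa$normal, pa$delta, pa$delta_dot)
    }
    if (record)
      contact_log <- c(Fmag = Fm_tot,
                       if (is.null(rec)) rep(NA_real_, 8) else rec)
  }
  list(F = F, T = Tq, springs = spring_log, contact = contact_log)
}

# ---- constraints --------------------------------------------------------

# Values and Jacobian (w.r.t. stacked free-body generalized velocities
# [v; w_body]) of all constraints at the given poses.
constraint_eval <- function(model, poses, jac = TRUE) {
  # constraints on guided bodies are held by the guidance itself
  active <- Filter(function(cn) cn$body %in% model$free, model$constraints)
  n_eq <- sum(vapply(active, `[[`, 0L, "n_eq"))
  nf <- length(model$free)
  phi <- numeric(n_eq)
  J <- if (jac) matrix(0, n_eq, 6 * nf) else NULL
  row <- 0L
  for (cn in active) {
    bi <- match(cn$body, model$free)
    R <- quat_to_mat(poses[[cn$body]]$q)
    P <- drop(R %*% cn$point) + poses[[cn$body]]$x
    if (cn$type == "spherical") {
      phi[row + 1:3] <- P - cn$anchor
      if (jac && !is.na(bi)) {
        J[row + 1:3, 6 * bi - 5:3 + 0] <- diag(3)
        J[row + 1:3, 6 * bi - 2:0 + 0] <- -R %*% skew(cn$point)
      }
      row <- row + 3L
    } else if (cn$type == "distance") {
      d <- P - cn$anchor
      phi[row + 1] <- sum(d * d) - cn$L^2
      if (jac && !is.na(bi)) {
        J[row + 1, 6 * bi - 5:3 + 0] <- 2 * d
        J[row + 1, 6 * bi - 2:0 + 0] <- drop(-2 * d %*% R %*% skew(cn$point))
      }
      row <- row + 1L
    } else stop("unknown constraint type")
  }
  list(phi = phi, J = J)
}

# ---- Newmark-AL step ----------------------------------------------------

free_index <- function(model) {
  stats::setNames(seq_along(model$free), model$free)
}

# poses/twists of free bodies given stacked accelerations a (6 per body)
newmark_advance <- function(model, state, a_vec, cfg, guided1) {
  h <- cfg$h; beta <- cfg$beta; gamma <- cfg$gamma
  poses <- state$poses; twists <- state$twists
  for (k in seq_along(model$free)) {
    id <- model$free[k]
    a0 <- state$acc[[id]]$a; al0 <- state$acc[[id]]$al
    a1 <- a_vec[6 * k - 5:3 + 0]; al1 <- a_vec[6 * k - 2:0 + 0]
    x0 <- state$poses[[id]]$x; v0 <- state$twists[[id]]$v
    q0 <- state$poses[[id]]$q; w0 <- state$twists[[id]]$w
    x1 <- x0 + h * v0 + h^2 * ((0.5 - beta) * a0 + beta * a1)
    v1 <- v0 + h * ((1 - gamma) * a0 + gamma * a1)
    dth <- h * w0 + h^2 * ((0.5 - beta) * al0 + beta * al1)
    q1 <- quat_normalize(quat_mul(q0, quat_exp(dth)))
    w1 <- w0 + h * ((1 - gamma) * al0 + gamma * al1)
    poses[[id]] <- list(x = x1, q = q1)
    twists[[id]] <- list(v = v1, w = w1)
  }
  for (id in names(guided1)) {
    poses[[id]] <- list(x = guided1[[id]]$x, q = guided1[[id]]$q)
    twists[[id]] <- list(v = guided1[[id]]$v, w = guided1[[id]]$w)
  }
  list(poses = poses, twists = twists)
}

step_residual <- function(model, state, a_vec, lam, cfg, guided1, t1, alpha) {
  adv <- newmark_advance(model, state, a_vec, cfg, guided1)
  fr <- model_forces(model, adv$poses, adv$twists, t1)
  nf <- length(model$free)
  r <- numeric(6 * nf)
  for (k in seq_len(nf)) {
    id <- model$free[k]
    b <- model$bodies[[id]]
    a1 <- a_vec[6 * k - 5:3 + 0]; al1 <- a_vec[6 * k - 2:0 + 0]
    w1 <- adv$twists[[id]]$w
    r[6 * k - 5:3 + 0] <- b$mass * a1 - fr$F[[id]]
    r[6 * k - 2:0 + 0] <- drop(b$inertia %*% al1) +
      cross3(w1, drop(b$inertia %*% w1)) - fr$T[[id]]
  }
  if (n_active_constraints(model)) {
    ce <- constraint_eval(model, adv$poses)
    r <- r + drop(crossprod(ce$J, alpha * ce$phi + lam))
    attr(r, "phi") <- ce$phi
  }
  r
}

#' Advance a model one Newmark step
#'
#' Solves the Newmark-discretized equations of motion at `t + h` with
#' augmented-Lagrangian multiplier updates until the position-level
#' constraint residual satisfies `pos_tol`, then projects velocities and
#' accelerations onto the constraint subspace.
#'
#' @param model `pf_model`; `state` from [model_state()] or a previous step;
#'   `cfg` a [sim_config()].
#' @param cache optional environment reused across steps (Jacobian cache).
#' @return the state at `t + h`; attributes `phi_inf` and `vel_resid` report
#'   the constraint residuals after projection.
#' @export
step_model <- function(model, state, cfg, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  h <- cfg$h
  t1 <- state$t + h
  guided1 <- lapply(model$guidance, function(g) g(t1))
  nf <- length(model$free)
  n <- 6L * nf
  mass_scale <- max(vapply(model$bodies[model$free], `[[`, 0, "mass"))
  alpha <- cfg$alpha * mass_scale
  a_vec <- unlist(lapply(state$acc, function(z) c(z$a, z$al)), use.names = FALSE)
  lam <- state$lam
  resid <- function(a) step_residual(model, state, a, lam, cfg, guided1, t1,
                                     alpha)
  num_jac <- function(a, r0) {
    Jm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      da <- 1e-4 * max(1, abs(a[i]))
      ap <- a; ap[i] <- ap[i] + da
      Jm[, i] <- (resid(ap) - r0) / da
    }
    Jm
  }
  force_scale <- max(1, mass_scale * 9.81)
  tol <- cfg$newton_tol * force_scale
  # faceted (mesh) contact is only piecewise smooth: below the facet force
  # granularity the residual cannot be reduced further
  has_mesh <- any(vapply(model$contacts, function(cp)
    identical(cp$type, "mesh"), logical(1)))
  accept_tol <- if (has_mesh) 0.05 * force_scale else tol * 100
  converged_phi <- !n_active_constraints(model)
  for (al_it in seq_len(max(1L, cfg$al_max_iter))) {
    r <- resid(a_vec)
    it <- 0L
    stall <- 0L
    while (sqrt(sum(r^2)) > tol && it < cfg$newton_max_iter &&
           stall < 3L) {
      if (is.null(cache$J) || isTRUE(cache$refresh)) {
        cache$J <- num_jac(a_vec, r)
        cache$Jq <- qr(cache$J)
        cache$refresh <- FALSE
        cache$age <- 0L
      }
      da <- tryCatch(qr.solve(cache$Jq, r), error = function(e) NULL)
      if (is.null(da)) { cache$refresh <- TRUE; it <- it + 1L; next }
      a_new <- a_vec - da
      r_new <- resid(a_new)
      if (sqrt(sum(r_new^2)) > 0.9 * sqrt(sum(r^2)) && !isTRUE(cache$fresh_try)) {
        # stale Jacobian: refresh once before accepting a poor step
        cache$refresh <- TRUE
        cache$fresh_try <- TRUE
        it <- it + 1L
        next
      }
      cache$fresh_try <- FALSE
      stall <- if (sqrt(sum(r_new^2)) > 0.99 * sqrt(sum(r^2)))
        stall + 1L else 0L
      a_vec <- a_new; r <- r_new
      it <- it + 1L
    }
    if (sqrt(sum(r^2)) > accept_tol)
      stop("Newton divergence in step at t = ", t1,
           " (residual ", signif(sqrt(sum(r^2)), 3),
           "); consider a smaller time step h")
    if (!n_active_constraints(model)) break
    phi <- attr(r, "phi")
    if (is.null(phi)) {
      adv <- newmark_advance(model, state, a_vec, cfg, guided1)
      phi <- constraint_eval(model, adv$poses, jac = FALSE)$phi
    }
    if (max(abs(phi)) <= cfg$pos_tol) { converged_phi <- TRUE; break }
    lam <- lam + alpha * phi
  }
  if (!converged_phi && n_active_constraints(model))
    stop("augmented-Lagrangian iteration failed to reach pos_tol at t = ", t1)
  cache$age <- (cache$age %||% 0L) + 1L
  if (cache$age >= cfg$jac_every) cache$refresh <- TRUE
  adv <- newmark_advance(model, state, a_vec, cfg, guided1)
  # ---- velocity and acceleration projections ----
  phi_inf <- 0; vel_resid <- 0
  if (n_active_constraints(model)) {
    ce <- constraint_eval(model, adv$poses)
    phi_inf <- max(abs(ce$phi))
    Jc <- ce$J
    w_all <- numeric(n); a_all <- a_vec
    for (k in seq_len(nf)) {
      id <- model$free[k]
      w_all[6 * k - 5:3 + 0] <- adv$twists[[id]]$v
      w_all[6 * k - 2:0 + 0] <- adv$twists[[id]]$w
    }
    Mi <- matrix(0, n, n)
    for (k in seq_len(nf)) {
      id <- model$free[k]
      b <- model$bodies[[id]]
      Mi[6 * k - 5:3 + 0, 6 * k - 5:3 + 0] <- diag(3) / b$mass
      Mi[6 * k - 2:0 + 0, 6 * k - 2:0 + 0] <- solve(b$inertia)
    }
    S <- Jc %*% Mi %*% t(Jc)
    # velocity projection (rheonomic terms vanish: anchors are static)
    rhs_v <- drop(Jc %*% w_all)
    dw <- -drop(Mi %*% t(Jc) %*% solve(S, rhs_v))
    w_all <- w_all + dw
    # acceleration projection: J a + Jdot w = 0, Jdot w by finite difference
    epsd <- 1e-7
    poses_eps <- adv$poses
    for (k in seq_len(nf)) {
      id <- model$free[k]
      poses_eps[[id]] <- list(
        x = adv$poses[[id]]$x + epsd * w_all[6 * k - 5:3 + 0],
        q = quat_normalize(quat_mul(adv$poses[[id]]$q,
                                    quat_exp(epsd * w_all[6 * k - 2:0 + 0]))))
    }
    J2 <- constraint_eval(model, poses_eps)$J
    jdotw <- drop((J2 - Jc) %*% w_all) / epsd
    rhs_a <- drop(Jc %*% a_all) + jdotw
    da <- -drop(Mi %*% t(Jc) %*% solve(S, rhs_a))
    a_all <- a_all + da
    for (k in seq_len(nf)) {
      id <- model$free[k]
      adv$twists[[id]] <- list(v = w_all[6 * k - 5:3 + 0],
                               w = w_all[6 * k - 2:0 + 0])
    }
    a_vec <- a_all
    vel_resid <- max(abs(drop(Jc %*% w_all)))
  }
  # commit contact episodes and record logs at the accepted state
  fr <- model_forces(model, adv$poses, adv$twists, t1, commit = TRUE,
                     record = TRUE)
  acc <- state$acc
  for (k in seq_len(nf)) {
    id <- model$free[k]
    acc[[id]] <- list(a = a_vec[6 * k - 5:3 + 0], al = a_vec[6 * k - 2:0 + 0])
  }
  out <- list(t = t1, poses = adv$poses, twists = adv$twists, acc = acc,
              lam = lam)
  attr(out, "phi_inf") <- phi_inf
  attr(out, "vel_resid") <- vel_resid
  attr(out, "log") <- fr[c("springs", "contact")]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_active_constraints <- function(model) {
  sum(vapply(Filter(function(cn) cn$body %in% model$free, model$constraints),
             `[[`, 0L, "n_eq"))
}
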