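# Constitutive force laws: linear spring-damper tendons and the Flores
# dissipative normal contact model.

#' Spring-damper tendon parameters
#'
#' Linear spring-damper of stiffness `K`, natural length `L0` and damping
#' coefficient `c` (default `0.01 * K`, the bench convention). The tension is
#' `K (L - L0) + c * Ldot` in the dissipative sign convention (the damper
#' always resists length change); `damping_sign = "printed"` selects the
#' `- c * Ldot` variant instead.
#'
#' @param K stiffness (N/m), > 0.
#' @param L0 natural length (m), > 0.
#' @param c damping coefficient (N s/m), >= 0; default `0.01 * K`.
#' @param attach_A,attach_B attachments `list(body = <id>, point = <local xyz>)`.
#' @param rigid_extension rigid series element added to the natural length
#'   path (m); models the bench's added rigid component.
#' @param damping_sign `"dissipative"` (default) or `"printed"`.
#' @export
spring_damper_params <- function(K, L0, c = 0.01 * K,
                                 attach_A = NULL, attach_B = NULL,
                                 rigid_extension = 0,
                                 damping_sign = c("dissipative", "printed")) {
  stopifnot(K > 0, L0 > 0, c >= 0, rigid_extension >= 0)
  damping_sign <- match.arg(damping_sign)
  structure(list(K = K, L0 = L0, c = c, attach_A = attach_A,
                 attach_B = attach_B, rigid_extension = rigid_extension,
                 damping_sign = damping_sign),
            class = "pf_spring")
}

#' Scalar spring-damper tension
#'
#' @param params [spring_damper_params()].
#' @param L current end-to-end length (m), > 0.
#' @param Ldot length rate (m/s).
#' @return scalar tension (N); positive pulls the endpoints together.
#' @export
spring_damper_force <- function(params, L, Ldot = 0) {
  stopifnot(inherits(params, "pf_spring"), all(L > 0))
  el <- L - (params$L0 + params$rigid_extension)
  damp <- if (params$damping_sign == "dissipative") params$c * Ldot
          else -params$c * Ldot
  params$K * el + damp
}

# Force/torque contribution of a spring between two posed bodies.
# poses: named list of list(x, q); twists: named list of list(v, w) or NULL.
spring_wrench <- function(params, poses, twists = NULL) {
  pa <- params$attach_A; pb <- params$attach_B
  pose_of <- function(at) {
    if (identical(at$body, "world"))
      list(x = c(0, 0, 0), q = c(1, 0, 0, 0))
    else poses[[at$body]]
  }
  Ra <- quat_to_mat(pose_of(pa)$q); Rb <- quat_to_mat(pose_of(pb)$q)
  A <- drop(Ra %*% pa$point) + pose_of(pa)$x
  B <- drop(Rb %*% pb$point) + pose_of(pb)$x
  d <- B - A
  L <- norm3(d)
  u <- d / max(L, 1e-12)
  Ldot <- 0
  if (!is.null(twists)) {
    zero <- list(v = c(0, 0, 0), w = c(0, 0, 0))
    ta <- if (identical(pa$body, "world")) zero else twists[[pa$body]]
    tb <- if (identical(pb$body, "world")) zero else twists[[pb$body]]
    vA <- ta$v + drop(Ra %*% cross3(ta$w, pa$point))
    vB <- tb$v + drop(Rb %*% cross3(tb$w, pb$point))
    Ldot <- sum((vB - vA) * u)
  }
  Fmag <- spring_damper_force(params, L, Ldot)
  # tension pulls B toward A
  list(F_on_B = -Fmag * u, F_on_A = Fmag * u, A = A, B = B,
       L = L, Ldot = Ldot, tension = Fmag)
}

#' Flores contact-model parameters
#'
#' @param k_n generalized contact stiffness (N/m^p), > 0.
#' @param p Hertz exponent (default 1.5, the classical sphere contact value).
#' @param eps coefficient of restitution in (0, 1].
#' @export
flores_params <- function(k_n, p = 1.5, eps) {
  if (!(k_n > 0)) stop("k_n must be > 0")
  if (!(p > 0)) stop("p must be > 0")
  if (!(eps > 0 && eps <= 1)) stop("eps must be in (0, 1]")
  structure(list(k_n = k_n, p = p, eps = eps), class = "pf_flores")
}

#' Hertz sphere-on-plane contact stiffness
#'
#' `k = (4/3) E* sqrt(R)` for effective modulus `E*` and sphere radius `R`;
#' the default generalized stiffness when material moduli are configured.
#' @param E_star effective contact modulus (Pa).
#' @param R sphere radius (m).
#' @export
hertz_stiffness <- function(E_star, R) 4 / 3 * E_star * sqrt(R)

#' Flores dissipative normal contact force
#'
#' `F = k_n * delta^p * (1 + 8(1 - eps)/(5 eps) * delta_dot / delta_dot0)`
#' along the patch normal, clamped to be non-tensile (>= 0). `delta_dot0` is
#' the approach rate latched at episode start; if it is missing, zero, or
#' below `dd0_min` (initialization inside contact, or a grazing episode with
#' no meaningful approach speed) the dissipative term is disabled for the
#' episode. The compression ratio `delta_dot / delta_dot0` is clamped at 1,
#' its value at the start of a clean impact, so shallow episodes cannot
#' amplify the dissipative term without bound.
#'
#' @param params [flores_params()].
#' @param patch a `pf_contact_patch` (fields `delta`, `delta_dot`,
#'   `delta_dot0`, `normal`, `point`).
#' @param dd0_min smallest episode approach speed (m/s) for which the
#'   dissipative term is active.
#' @return list: `F` (force vector on the patella, world frame), `Fmag`
#'   (scalar along the normal), `point`.
#' @export
flores_force <- function(params, patch, dd0_min = 1e-4) {
  stopifnot(inherits(params, "pf_flores"))
  if (is.null(patch) || patch$delta <= 0)
    return(list(F = c(0, 0, 0), Fmag = 0, point = if (is.null(patch)) NULL
                else patch$point))
  bracket <- 1
  dd0 <- patch$delta_dot0
  if (!is.null(dd0) && is.finite(dd0) && dd0 > dd0_min) {
    bracket <- 1 + 8 * (1 - params$eps) / (5 * params$eps) *
      min(patch$delta_dot / dd0, 1)
  }
  Fmag <- max(0, params$k_n * patch$delta^params$p * bracket)
  list(F = Fmag * patch$normal, Fmag = Fmag, point = patch$point)
}

# Elastic potential of the Hertz backbone (energy bookkeeping in tests).
flores_potential <- function(params, delta) {
  params$k_n * pmax(delta, 0)^(params$p + 1) / (params$p + 1)
}
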