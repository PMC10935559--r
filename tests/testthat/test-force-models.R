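test_that("spring-damper tension follows the linear law", {
  sp <- spring_damper_params(K = 100, L0 = 0.2)
  expect_equal(spring_damper_force(sp, 0.2, 0), 0)
  # bench tendon stiffness: 1 cm stretch of the K2 = 629 N/m spring
  k2 <- spring_damper_params(K = 629, L0 = 0.0714)
  expect_equal(spring_damper_force(k2, 0.0714 + 0.01, 0), 6.29)
  # default damping coefficient c = 0.01 K
  expect_equal(sp$c, 1)
  # rigid series extension shifts the zero-tension length
  spx <- spring_damper_params(K = 156, L0 = 0.1432, rigid_extension = 0.0196)
  expect_equal(spring_damper_force(spx, 0.1432 + 0.0196, 0), 0)
})

test_that("damping dissipates over any closed length cycle", {
  for (sign in c("dissipative", "printed")) {
    sp <- spring_damper_params(K = 200, L0 = 0.1, c = 2, damping_sign = sign)
    t <- seq(0, 1, 1e-4)
    L <- 0.12 + 0.02 * sin(2 * pi * 3 * t)
    Ld <- 0.02 * 2 * pi * 3 * cos(2 * pi * 3 * t)
    Fel <- sp$K * (L - sp$L0)
    Fd <- spring_damper_force(sp, L, Ld) - Fel
    # work done on the spring by the damping term over the closed cycle
    W <- sum(Fd * Ld) * 1e-4
    if (sign == "dissipative") expect_gt(W, 0) else expect_lt(W, 0)
  }
})

test_that("parameter validation rejects unphysical values", {
  expect_error(flores_params(k_n = -1, eps = 0.5), "k_n")
  expect_error(flores_params(k_n = 1, p = 0, eps = 0.5), "p")
  expect_error(flores_params(k_n = 1, eps = 0), "eps")
  expect_error(flores_params(k_n = 1, eps = 1.2), "eps")
  expect_error(spring_damper_params(K = -5, L0 = 0.1))
})

test_that("the normal contact force reduces to its closed-form cases", {
  patch <- function(delta, ddot = 0, dd0 = NA)
    structure(list(delta = delta, delta_dot = ddot, delta_dot0 = dd0,
                   normal = c(0, 0, 1), point = c(0, 0, 0)),
              class = "pf_contact_patch")
  # no indentation, no force
  expect_equal(flores_force(flores_params(1e7, eps = 0.5),
                            patch(0))$Fmag, 0)
  # eps = 1: pure Hertz
  f <- flores_force(flores_params(1e7, p = 1.5, eps = 1),
                    patch(1e-3, 0.1, 0.1))
  expect_equal(f$Fmag, 1e7 * (1e-3)^1.5, tolerance = 1e-12)
  expect_equal(f$Fmag, 316.2278, tolerance = 1e-4)
  # eps = 0.5 at the episode-opening rate: bracket = 1 + 1.6 = 2.6
  f2 <- flores_force(flores_params(1e7, eps = 0.5), patch(1e-3, 0.2, 0.2))
  expect_equal(f2$Fmag / (1e7 * (1e-3)^1.5), 2.6, tolerance = 1e-12)
  # strong restitution rates clamp at zero force, never tensile
  f3 <- flores_force(flores_params(1e7, eps = 0.5), patch(1e-3, -0.5, 0.2))
  expect_equal(f3$Fmag, 0)
  # grazing episodes (negligible opening rate) fall back to pure Hertz
  f4 <- flores_force(flores_params(1e7, eps = 0.5), patch(1e-3, 0.3, 1e-6))
  expect_equal(f4$Fmag, 1e7 * (1e-3)^1.5, tolerance = 1e-12)
})

test_that("force is continuous in indentation and rate", {
  fl <- flores_params(1e6, eps = 0.6)
  mk <- function(d, dd) structure(
    list(delta = d, delta_dot = dd, delta_dot0 = 0.3,
         normal = c(0, 0, 1), point = c(0, 0, 0)),
    class = "pf_contact_patch")
  ds <- seq(1e-6, 2e-3, length.out = 200)
  Fd <- vapply(ds, function(d) flores_force(fl, mk(d, 0.1))$Fmag, numeric(1))
  expect_true(all(abs(diff(Fd)) < 2))
  dds <- seq(-0.6, 0.3, length.out = 200)
  Fr <- vapply(dds, function(v) flores_force(fl, mk(1e-3, v))$Fmag,
               numeric(1))
  expect_true(all(abs(diff(Fr)) < 1))
  expect_true(all(Fr >= 0))
})

test_that("a full bounce approximately restores the coefficient of restitution", {
  # the model is constructed to approximate eps; check a moderate value
  b <- bounce_ratio(0.7)
  expect_equal(b$ratio, 0.7, tolerance = 0.1)
  # eps = 1: elastic; net contact work over the episode is zero to 0.1%
  b1 <- bounce_ratio(1.0)
  expect_equal(b1$ratio, 1.0, tolerance = 1e-3)
  # and dissipative episodes never gain energy
  expect_lt(b$ratio, 1)
})
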