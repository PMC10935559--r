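test_that("a polynomial cloud is recovered exactly at its own order", {
  g <- expand.grid(x = seq(-1, 1, 0.2), y = seq(-1, 1, 0.2))
  z <- g$x^2 + 0.5 * g$y^2
  f <- fit_polynomial(cbind(g$x, g$y, z), 2)
  expect_equal(f$r_squared, 1)
  expect_lt(f$rmse_fit, 1e-10)
  expect_equal(unname(f$coefficients["c_2_0"]), 1, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["c_0_2"]), 0.5, tolerance = 1e-8)
  expect_lt(max(abs(f$coefficients[!names(f$coefficients) %in%
                                     c("c_2_0", "c_0_2")])), 1e-8)
})

test_that("a symmetric quadratic defeats a linear fit entirely", {
  x <- seq(-1, 1, 0.1)
  g <- expand.grid(x = x, y = x)
  f <- fit_polynomial(cbind(g$x, g$y, g$x^2), 1)
  # best linear fit is the constant mean: zero slopes, raw R^2 = 0
  expect_lt(abs(f$coefficients["c_1_0"]), 1e-10)
  expect_lt(abs(f$coefficients["c_0_1"]), 1e-10)
  expect_equal(f$r_squared_raw, 0, tolerance = 1e-10)
})

test_that("R^2 is non-decreasing in the order on the trochlear cloud", {
  gp <- groove_params()
  m <- make_trochlear_surface(gp, mesh_quality_target(5e-5, 1.0))
  fits <- fit_polynomial_orders(m$vertices, orders = c(2, 4, 5))
  r2 <- vapply(fits, function(f) f$r_squared_raw, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  expect_gt(r2["P4"], r2["P2"])
  expect_equal(unname(r2["P5"]), 1, tolerance = 1e-9)  # order-5 truth
})

test_that("evaluated gradients match central finite differences", {
  surf <- random_poly_surface(order = 5, seed = 42)
  set.seed(7)
  xs <- stats::runif(25, -0.8, 0.8)
  ys <- stats::runif(25, -0.8, 0.8)
  ev <- eval_surface(surf, xs, ys, gradient = TRUE)
  h <- 1e-6
  fx_fd <- (eval_surface(surf, xs + h, ys)$z -
            eval_surface(surf, xs - h, ys)$z) / (2 * h)
  fy_fd <- (eval_surface(surf, xs, ys + h)$z -
            eval_surface(surf, xs, ys - h)$z) / (2 * h)
  expect_equal(ev$grad[, 1], fx_fd, tolerance = 1e-6)
  expect_equal(ev$grad[, 2], fy_fd, tolerance = 1e-6)
  expect_equal(rowSums(ev$normal^2), rep(1, 25), tolerance = 1e-12)
  # normal proportional to (-fx, -fy, 1)
  expect_equal(ev$normal[, 1] / ev$normal[, 3], -ev$grad[, 1],
               tolerance = 1e-8)
})

test_that("plane normals come out in closed form", {
  g <- expand.grid(x = seq(-1, 1, 0.25), y = seq(-1, 1, 0.25))
  f <- fit_polynomial(cbind(g$x, g$y, 2 * g$x + 3 * g$y), 1)
  ev <- eval_surface(f, 0.3, -0.4, gradient = TRUE)
  expect_equal(drop(ev$normal), c(-2, -3, 1) / sqrt(14), tolerance = 1e-10)
})

test_that("duplicating a point equals doubling its weight", {
  set.seed(3)
  pts <- cbind(stats::runif(40, -1, 1), stats::runif(40, -1, 1),
               stats::rnorm(40))
  w <- rep(1, 40)
  dup <- rbind(pts, pts[7, ])
  f_dup <- fit_polynomial(dup, 2)
  w2 <- w; w2[7] <- 2
  f_w <- fit_polynomial(pts, 2, weights = w2)
  expect_equal(f_w$coefficients, f_dup$coefficients, tolerance = 1e-10)
})

test_that("degenerate designs fail loudly", {
  line <- cbind(seq(0, 1, 0.1), seq(0, 1, 0.1), 1)   # collinear in x = y
  expect_error(fit_polynomial(line, 2), "rank-deficient")
  expect_error(fit_polynomial(line[1:3, ], 2), "at least")
  expect_error(fit_polynomial(line, 1, weights = rep(-1, nrow(line))),
               "weights")
})

test_that("extrapolation is flagged, not refused", {
  f <- paraboloid_surface()
  ev <- eval_surface(f, c(0.5, 1.5), c(0, 0))
  expect_equal(ev$extrapolated, c(FALSE, TRUE))
  expect_equal(ev$z[2], 1.5^2, tolerance = 1e-8)
})
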