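test_that("icosphere has the exact combinatorics and radius at every level", {
  ico0 <- make_icosphere(0.015, 0)
  expect_equal(nrow(ico0$faces), 20L)
  expect_equal(nrow(ico0$vertices), 12L)
  devs <- vapply(0:3, function(s) {
    m <- make_icosphere(0.015, s)
    expect_equal(nrow(m$faces), 20L * 4L^s)
    expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 0.015)), 1e-12)
    mesh_quality(m, list(type = "sphere", center = c(0, 0, 0),
                         radius = 0.015))$max_chordal_deviation
  }, numeric(1))
  expect_true(all(diff(devs) < 0))   # strictly finer with each subdivision
  expect_error(make_icosphere(0.015, 9), "memory guard")
})

test_that("trochlear mesh vertices lie exactly on the analytic ground truth", {
  gp <- groove_params()
  m <- make_trochlear_surface(gp, mesh_quality_target(1e-4, 1.0))
  resid <- abs(m$vertices[, 3] -
               gp$analytic_form(m$vertices[, 1], m$vertices[, 2]))
  expect_lt(max(resid), 1e-12)
  q <- attr(m, "quality")
  expect_lte(q$max_chordal_deviation, 1e-4)
  expect_lte(q$max_normal_deviation, 1.0)
})

test_that("chordal deviation is second order in the edge length", {
  gp <- groove_params()
  X <- gp$half_extent_x; Y <- gp$half_extent_y
  mesh_at <- function(n) pftwin:::triangulate_heightfield(
    gp$analytic_form, seq(-X, X, length.out = n), seq(-Y, Y, length.out = n))
  ref <- list(type = "heightfield", f = gp$analytic_form,
              grad = gp$analytic_grad)
  d1 <- mesh_quality(mesh_at(41L), ref)$max_chordal_deviation
  d2 <- mesh_quality(mesh_at(81L), ref)$max_chordal_deviation
  expect_gt(d1 / d2, 3.0)
  expect_lt(d1 / d2, 5.5)
})

test_that("ridge gains control the medial-lateral asymmetry", {
  sym <- groove_params(lateral_ridge_gain = 1.0, medial_ridge_gain = 1.0)
  xs <- seq(-sym$half_extent_x, sym$half_extent_x, length.out = 21)
  ys <- seq(0.001, sym$half_extent_y, length.out = 40)
  for (x in xs[c(3, 11, 19)])
    expect_lt(max(abs(sym$analytic_form(x, ys) - sym$analytic_form(x, -ys))),
              1e-12)
  asym <- groove_params(lateral_ridge_gain = 1.2, medial_ridge_gain = 1.0)
  lat_max <- max(asym$analytic_form(0, -ys))   # lateral = negative y
  med_max <- max(asym$analytic_form(0, ys))
  expect_gt(lat_max, med_max)
  # groove line sits at the parametric center y = 0
  fy <- asym$analytic_grad(0.01, 0)[, 2]
  expect_lt(abs(fy), 1e-12)
  expect_lt(asym$analytic_form(0.01, 0), asym$analytic_form(0.01, 0.002))
})

test_that("mesh_quality matches a brute-force per-face oracle on a sphere", {
  m <- make_icosphere(0.02, 2)
  ref <- list(type = "sphere", center = c(0, 0, 0), radius = 0.02)
  q <- mesh_quality(m, ref)
  # oracle: explicit loop over faces
  worst_d <- 0; worst_a <- 0
  for (i in seq_len(nrow(m$faces))) {
    cen <- colMeans(m$vertices[m$faces[i, ], ])
    worst_d <- max(worst_d, abs(sqrt(sum(cen^2)) - 0.02))
    nref <- cen / sqrt(sum(cen^2))
    ca <- abs(sum(m$face_normals[i, ] * nref))
    worst_a <- max(worst_a, acos(min(1, ca)) * 180 / pi)
  }
  expect_equal(q$max_chordal_deviation, worst_d, tolerance = 1e-12)
  expect_equal(q$max_normal_deviation, worst_a, tolerance = 1e-12)
})

test_that("mesh_quality is exact-zero for a plane and errors off-domain", {
  g <- expand.grid(x = seq(-1, 1, 0.5), y = seq(-1, 1, 0.5))
  plane <- pf_mesh(cbind(g$x, g$y, 0),
                   pftwin:::triangulate_heightfield(function(x, y) 0 * x,
                                                    seq(-1, 1, 0.5),
                                                    seq(-1, 1, 0.5))$faces)
  ref <- list(type = "heightfield", f = function(x, y) 0 * x,
              grad = function(x, y) cbind(0 * x, 0 * y))
  q <- mesh_quality(plane, ref)
  expect_equal(q$max_chordal_deviation, 0)
  expect_equal(q$max_normal_deviation, 0)
  ref_bad <- ref
  ref_bad$f <- function(x, y) ifelse(abs(x) > 0.8, NaN, 0 * x)
  expect_error(mesh_quality(plane, ref_bad), "outside reference domain")
})

test_that("unreachable tolerance fails explicitly", {
  expect_error(
    make_trochlear_surface(groove_params(),
                           mesh_quality_target(1e-13, 1e-6), max_iter = 2L),
    "unreachable")
})

test_that("OBJ and STL files round-trip", {
  m <- make_icosphere(0.01, 1)
  fo <- file.path(tempdir(), "ico.obj")
  write_obj(m, fo)
  m2 <- read_obj(fo)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-14)  # order preserved
  expect_equal(m2$faces, m$faces)
  for (bin in c(FALSE, TRUE)) {
    fs <- file.path(tempdir(), paste0("ico", bin, ".stl"))
    write_stl(m, fs, binary = bin)
    m3 <- read_stl(fs)
    expect_equal(nrow(m3$faces), nrow(m$faces))
    # same surface: identical sorted vertex multiset up to float32 for binary
    tol <- if (bin) 1e-6 else 1e-12
    expect_equal(sort(m3$vertices[, 3]), sort(m$vertices[, 3]),
                 tolerance = tol)
  }
})
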