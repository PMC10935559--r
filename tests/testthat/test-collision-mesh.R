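test_that("a one-triangle mesh builds a single-leaf tree", {
  m <- pf_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  tree <- build_aabb_tree(m)
  nd <- aabb_nodes(tree)
  expect_equal(length(nd$tri), 1L)
  expect_equal(nd$tri[1], 1L)
  expect_equal(drop(nd$bmin), c(0, 0, 0))
  expect_equal(drop(nd$bmax), c(1, 1, 0))
  expect_equal(aabb_depth(tree), 0L)
})

test_that("tree structure invariants hold and depth is near log2(N)", {
  m <- make_icosphere(0.1, 2)   # 320 faces
  tree <- build_aabb_tree(m)
  nd <- aabb_nodes(tree)
  n <- length(nd$tri)
  leaves <- which(nd$tri > 0)
  # every triangle in exactly one leaf
  expect_equal(sort(nd$tri[leaves]), seq_len(nrow(m$faces)))
  for (i in seq_len(n)) {
    if (nd$tri[i] > 0) {
      v <- m$vertices[m$faces[nd$tri[i], ], , drop = FALSE]
      expect_true(all(sweep(v, 2, nd$bmin[i, ]) >= -1e-12))
      expect_true(all(sweep(v, 2, nd$bmax[i, ]) <= 1e-12))
    } else {
      for (ch in c(nd$left[i], nd$right[i])) {
        expect_true(all(nd$bmin[ch, ] >= nd$bmin[i, ] - 1e-12))
        expect_true(all(nd$bmax[ch, ] <= nd$bmax[i, ] + 1e-12))
      }
    }
  }
  expect_lte(aabb_depth(tree), ceiling(log2(320)) + 2L)
})

test_that("box queries match a brute-force scan on random probes", {
  m <- make_icosphere(0.1, 2)
  tree <- build_aabb_tree(m)
  tri_bounds <- function(i) {
    v <- m$vertices[m$faces[i, ], , drop = FALSE]
    list(lo = apply(v, 2, min), hi = apply(v, 2, max))
  }
  tb <- lapply(seq_len(nrow(m$faces)), tri_bounds)
  set.seed(11)
  for (k in 1:100) {
    c0 <- stats::runif(3, -0.12, 0.12)
    half <- stats::runif(3, 0.005, 0.08)
    lo <- c0 - half; hi <- c0 + half
    got <- query_candidates(tree, lo, hi)
    want <- which(vapply(tb, function(b)
      all(b$hi >= lo) && all(b$lo <= hi), logical(1)))
    expect_equal(got, want)
  }
  # degenerate probes
  expect_equal(query_candidates(tree, c(-1, -1, -1), c(1, 1, 1)),
               seq_len(nrow(m$faces)))
  expect_length(query_candidates(tree, c(2, 2, 2), c(3, 3, 3)), 0L)
})

test_that("two overlapping icospheres reproduce the analytic overlap", {
  r <- 0.1; d <- 0.19
  mA <- make_icosphere(r, 3)
  mB <- make_icosphere(r, 3)
  tree <- build_aabb_tree(mA)
  patches <- mesh_contacts(tree, id_pose(), mB, id_pose(c(d, 0, 0)))
  expect_length(patches, 1L)
  p <- patches[[1]]
  # combined chordal tolerance of two s=3 spheres
  tol <- 2 * mesh_quality(mA, list(type = "sphere", center = c(0, 0, 0),
                                   radius = r))$max_chordal_deviation
  expect_equal(p$delta, 2 * r - d, tolerance = 3 * tol / (2 * r - d))
  ang <- acos(min(1, sum(p$normal * c(1, 0, 0))))
  expect_lt(ang * 180 / pi, 2)
  expect_true(p$closed)
  # contact point near the mid-plane of the overlap lens
  expect_equal(p$point[1], d / 2, tolerance = 2e-3)
})

test_that("disjoint meshes yield no contact", {
  mA <- make_icosphere(0.1, 2)
  tree <- build_aabb_tree(mA)
  expect_length(mesh_contacts(tree, id_pose(), mA, id_pose(c(0.21, 0, 0))),
                0L)
})

test_that("sphere on a dense plane mesh recovers the closed-form depth", {
  g <- seq(-0.06, 0.06, length.out = 81)
  plane <- pftwin:::triangulate_heightfield(function(x, y) 0 * x, g, g)
  tree <- build_aabb_tree(plane)
  r <- 0.02
  sph <- make_icosphere(r, 3)
  patches <- mesh_contacts(tree, id_pose(), sph, id_pose(c(0, 0, r - 0.002)))
  expect_length(patches, 1L)
  p <- patches[[1]]
  expect_equal(p$delta, 0.002, tolerance = 0.05)
  expect_lt(acos(min(1, p$normal[3])) * 180 / pi, 1)
})

test_that("delta_dot is the projected relative approach rate and dd0 latches", {
  g <- seq(-0.06, 0.06, length.out = 41)
  plane <- pftwin:::triangulate_heightfield(function(x, y) 0 * x, g, g)
  tree <- build_aabb_tree(plane)
  sph <- make_icosphere(0.02, 2)
  ep <- contact_episodes()
  tw0 <- list(v = c(0, 0, 0), w = c(0, 0, 0))
  twd <- list(v = c(0, 0, -0.3), w = c(0, 0, 0))
  p1 <- mesh_contacts(tree, id_pose(), sph, id_pose(c(0, 0, 0.019)),
                      twistA = tw0, twistB = twd,
                      episodes = ep, commit = TRUE)[[1]]
  expect_equal(p1$delta_dot, 0.3, tolerance = 1e-6)
  expect_equal(p1$delta_dot0, 0.3, tolerance = 1e-6)
  # slower approach later in the same episode keeps the latched dd0
  tws <- list(v = c(0, 0, -0.1), w = c(0, 0, 0))
  p2 <- mesh_contacts(tree, id_pose(), sph, id_pose(c(0, 0, 0.0185)),
                      twistA = tw0, twistB = tws,
                      episodes = ep, commit = TRUE)[[1]]
  expect_equal(p2$delta_dot, 0.1, tolerance = 1e-6)
  expect_equal(p2$delta_dot0, 0.3, tolerance = 1e-6)
  # separation ends the episode
  mesh_contacts(tree, id_pose(), sph, id_pose(c(0, 0, 0.05)),
                episodes = ep, commit = TRUE)
  expect_length(ep$active, 0L)
})

test_that("contour debug dumps are valid OBJ polylines", {
  mA <- make_icosphere(0.1, 2)
  tree <- build_aabb_tree(mA)
  patches <- mesh_contacts(tree, id_pose(), mA, id_pose(c(0.19, 0, 0)))
  f <- file.path(tempdir(), "contours.obj")
  write_contours_obj(patches, f)
  ln <- readLines(f)
  expect_gt(sum(startsWith(ln, "v ")), 0)
  expect_gt(sum(startsWith(ln, "l ")), 0)
})
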