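test_that("the zero-phase low-pass filter has unit DC gain and the expected band", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  expect_lt(max(abs(butterworth_filter(rep(2.5, length(t)), fs) - 2.5)),
            1e-12)
  s2 <- sin(2 * pi * 2 * t)
  f2 <- butterworth_filter(s2, fs)
  mid <- seq(100, length(t) - 100)
  expect_equal(max(abs(f2[mid])), 1, tolerance = 0.01)   # 2 Hz preserved
  s40 <- sin(2 * pi * 40 * t)
  f40 <- butterworth_filter(s40, fs)
  expect_lt(max(abs(f40[mid])), 10^(-20 / 20))           # > 20 dB down
  expect_error(butterworth_filter(1:5, fs), "warm-up")
  expect_error(butterworth_filter(s2, fs = 20, cutoff = 12))
})

test_that("filtering an already band-limited signal is nearly idempotent", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  s <- sin(2 * pi * 1.5 * t) + 0.3 * cos(2 * pi * 4 * t)
  f1 <- butterworth_filter(s, fs)
  f2 <- butterworth_filter(f1, fs)
  mid <- seq(100, length(t) - 100)
  expect_lt(sqrt(mean((f2[mid] - f1[mid])^2)) / sqrt(mean(f1[mid]^2)), 0.01)
})

test_that("singular-spectrum analysis reconstructs structured signals", {
  expect_lt(max(abs(ssa_filter(rep(3, 200), window = 30) - 3)), 1e-10)
  t <- seq_len(400)
  s <- sin(2 * pi * t / 20)
  r <- ssa_filter(s, window = 30, components = 1:2)
  expect_lt(sqrt(mean((r - s)^2)), 0.01)   # a sinusoid spans 2 components
  set.seed(42)
  noise <- stats::rnorm(400, 0, sqrt(0.1 * stats::var(s)))  # SNR 10
  r2 <- ssa_filter(s + noise, window = 30, var_frac = 0.99)
  resid_power <- mean((r2 - s)^2)
  expect_lt(resid_power / mean(noise^2), 0.2)  # >= 80% noise power removed
  expect_error(ssa_filter(s, window = 1), "window")
  expect_error(ssa_filter(s[1:40], window = 30), "length")
})

test_that("pose reconstruction is exact for rigid marker clouds", {
  local <- list(a = c(0, 0, 0), b = c(0.12, 0, 0), c = c(0, 0.1, 0.02),
                d = c(0.05, 0.05, 0.09))
  recipe <- list(origin = "a", axis = "b", plane = "c", local = local)
  set.seed(5)
  n <- 20
  rows <- list()
  truth <- list()
  for (k in seq_len(n)) {
    R <- quat_to_mat(quat_normalize(stats::rnorm(4)))
    x0 <- stats::rnorm(3, 0, 0.5)
    truth[[k]] <- list(R = R, x = x0)
    for (id in names(local))
      rows[[length(rows) + 1]] <- data.frame(
        frame = k, time = k / 100, id = id,
        x = (R %*% local[[id]])[1] + x0[1],
        y = (R %*% local[[id]])[2] + x0[2],
        z = (R %*% local[[id]])[3] + x0[3])
  }
  mk <- do.call(rbind, rows)
  ps <- vaughan_frames(mk, recipe)
  for (k in seq_len(n)) {
    expect_equal(ps$x[k, ], truth[[k]]$x, tolerance = 1e-12)
    expect_lt(rotation_angle_between(quat_to_mat(ps$q[k, ]), truth[[k]]$R),
              1e-12)
  }
})

test_that("collinear marker triples are rejected", {
  local <- list(a = c(0, 0, 0), b = c(0.1, 0, 0), c = c(0.2, 0, 0))
  mk <- do.call(rbind, lapply(names(local), function(id)
    data.frame(frame = 1, time = 0, id = id, x = local[[id]][1],
               y = local[[id]][2], z = local[[id]][3])))
  expect_error(vaughan_frames(mk, list(origin = "a", axis = "b", plane = "c",
                                       local = local)),
               "collinear")
})

test_that("pose errors stay within 1 deg / 1 mm under 0.5 mm marker noise", {
  local <- list(a = c(0, 0, 0), b = c(0.15, 0, 0), c = c(0, 0.12, 0.02))
  recipe <- list(origin = "a", axis = "b", plane = "c", local = local)
  set.seed(12)
  n <- 100
  ang_err <- pos_err <- numeric(n)
  rows <- list()
  R <- rot_axis(2, 0.4) %*% rot_axis(1, -0.2)
  x0 <- c(0.3, -0.1, 0.2)
  for (k in seq_len(n)) {
    for (id in names(local)) {
      p <- drop(R %*% local[[id]]) + x0 + stats::rnorm(3, 0, 5e-4)
      rows[[length(rows) + 1]] <- data.frame(frame = k, time = k / 100,
                                             id = id, x = p[1], y = p[2],
                                             z = p[3])
    }
  }
  ps <- vaughan_frames(do.call(rbind, rows), recipe)
  for (k in seq_len(n)) {
    ang_err[k] <- rotation_angle_between(quat_to_mat(ps$q[k, ]), R) * 180 / pi
    pos_err[k] <- sqrt(sum((ps$x[k, ] - x0)^2))
  }
  expect_lt(mean(ang_err), 1)
  expect_lt(mean(pos_err), 1e-3)
})

test_that("synthetic motion closes through pose reconstruction", {
  sc <- test_scenario()
  mo <- synth_motion(sc, noise_sd = 0)
  # frame count: inclusive sampling of the full duration at 100 Hz
  expect_equal(length(unique(mo$markers$frame)), mo$duration * 100 + 1)
  # knee flexion has exactly one local maximum per cycle
  ka <- mo$knee_angle
  n_max <- sum(diff(sign(diff(ka))) == -2)
  expect_equal(n_max, sc$cycles)
  for (body in c("femur", "tibia", "patella")) {
    sub <- mo$markers[mo$markers$id %in% names(mo$recipes[[body]]$local), ]
    ps <- vaughan_frames(sub, mo$recipes[[body]])
    tr <- mo$truth[[body]]
    for (k in c(1L, 50L, 101L)) {
      expect_equal(ps$x[k, ], unname(tr$x[k, ]), tolerance = 1e-10)
      expect_lt(rotation_angle_between(quat_to_mat(ps$q[k, ]),
                                       quat_to_mat(tr$q[k, ])), 1e-10)
    }
  }
})

test_that("two flexion cycles appear with the default scenario", {
  mo <- synth_motion(scenario_config())
  ka <- mo$knee_angle
  expect_equal(sum(diff(sign(diff(ka))) == -2), 2L)
})

test_that("marker CSV round-trips with gaps, and short gaps interpolate", {
  mk <- data.frame(frame = rep(1:10, 2), time = rep(1:10, 2) / 100,
                   id = rep(c("m1", "m2"), each = 10),
                   x = rnorm(20), y = rnorm(20), z = rnorm(20))
  mk$x[3:4] <- NA                      # 2-frame gap -> fillable
  mk$y[14:19] <- NA                    # 6-frame gap -> kept missing
  f <- file.path(tempdir(), "markers.csv")
  write_markers_csv(mk, f)
  mk2 <- read_markers_csv(f)
  expect_equal(mk2$z, mk$z, tolerance = 1e-12)
  expect_true(all(is.na(mk2$x[3:4])))
  filled <- fill_marker_gaps(mk2, max_gap = 5)
  expect_false(anyNA(filled$x[3:4]))
  expect_equal(filled$x[3], mk$x[2] + (mk$x[5] - mk$x[2]) / 3,
               tolerance = 1e-9)
  expect_true(all(is.na(filled$y[14:19])))
})
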