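test_that("circle fitting is exact through 3 points and robust to noise", {
  th <- c(0.4, 1.3, 2.2)
  cx <- 310; cy <- -150; R <- 520
  f3 <- fullfield:::fit_circle(cx + R * cos(th), cy + R * sin(th))
  expect_equal(unname(c(f3$cx, f3$cy, f3$R)), c(cx, cy, R), tolerance = 1e-6)
  # 9 noisy points: least-squares residual stays near the noise floor
  set.seed(1)
  th9 <- seq(0.3, 2.3, length.out = 9)
  f9 <- fullfield:::fit_circle(cx + R * cos(th9) + rnorm(9, 0, 0.5),
                               cy + R * sin(th9) + rnorm(9, 0, 0.5))
  expect_lt(f9$rms, 0.6)
  expect_error(fullfield:::fit_circle(1:5, 2 * (1:5) + 3), "collinear")
})

test_that("calibration fitting reproduces its input points and validates edges", {
  model <- fix_model()
  for (edge in c("top", "bottom", "middle")) {
    pts <- model$points[[edge]]
    crv <- model$curves[[edge]]
    expect_lt(max(abs(crv$fx(pts$s_frac) - pts$px)), 1e-9)
    expect_lt(max(abs(crv$fy(pts$s_frac) - pts$py)), 1e-9)
  }
  # the near (top) edge appears wider on the raster than the far edge
  top_w <- diff(range(model$points$top$px))
  bot_w <- diff(range(model$points$bottom$px))
  expect_gt(top_w, bot_w)
  # degenerate calibrations are rejected
  expect_error(
    calibration_points(top = cbind(1:2, 1:2), bottom = cbind(1:3, 3:1)),
    "3 points")
  coll <- data.frame(px = c(0, 100, 200), py = c(5, 5, 5))
  arc <- data.frame(px = c(0, 100, 200), py = c(60, 90, 60))
  expect_error(fit_calibration(calibration_points(coll, arc)), "collinear")
  crossing <- calibration_points(
    top = data.frame(px = c(100, 500, 900), py = c(300, 200, 300)),
    bottom = data.frame(px = c(100, 500, 900), py = c(200, 320, 200)))
  expect_error(fit_calibration(crossing), "cross")
})

test_that("active region of the as-built calibration is 828 x 284 within 5%", {
  reg <- active_region(fix_model())
  expect_equal(unname(reg["width"]), 828, tolerance = 0.05)
  expect_equal(unname(reg["height"]), 284, tolerance = 0.05)
})

test_that("source corners map to arc endpoints and the map is orientation-true", {
  model <- fix_model()
  fwd <- fullfield:::warp_forward
  tp <- model$points$top; bp <- model$points$bottom
  expect_equal(unname(fwd(model, 0, 0)[1, ]),
               unname(c(tp$px[1], tp$py[1])), tolerance = 1e-6)
  expect_equal(unname(fwd(model, 1, 0)[1, ]),
               unname(c(tp$px[nrow(tp)], tp$py[nrow(tp)])), tolerance = 1e-6)
  expect_equal(unname(fwd(model, 0, 1)[1, ]),
               unname(c(bp$px[1], bp$py[1])), tolerance = 1e-6)
  expect_equal(unname(fwd(model, 1, 1)[1, ]),
               unname(c(bp$px[nrow(bp)], bp$py[nrow(bp)])), tolerance = 1e-6)
})

test_that("warp map matches the ray-traced ground truth to sub-pixel accuracy", {
  pose <- fix_pose(); scr <- fix_screen()
  map <- fix_map()
  set.seed(7)
  n <- 8000
  px <- cbind(runif(n, 0, 1024), runif(n, 0, 768))
  cell <- cbind(pmin(768, ceiling(px[, 2])), pmin(1024, ceiling(px[, 1])))
  centres <- cbind(cell[, 2] - 0.5, cell[, 1] - 0.5)
  truth <- trace_to_canvas(centres, pose, scr)
  on <- truth[, 3] == 1 & !is.na(map$map_x[cell])
  expect_gt(sum(on), 1000)
  err <- sqrt((map$map_x[cell][on] - truth[on, 1])^2 +
                (map$map_y[cell][on] - truth[on, 2])^2)
  expect_lt(max(err), 0.5)
  # and the map covers (nearly) every traced on-screen pixel
  expect_gt(mean(!is.na(map$map_x[cell][truth[, 3] == 1])), 0.995)
})

test_that("the calibrated forward map tracks ray tracing across random poses", {
  scr <- fix_screen()
  proj <- projection_geometry(screen = scr)
  set.seed(31)
  for (k in 1:10) {
    pose <- projector_pose(scr, proj,
                           throw_cm = runif(1, 60, 220),
                           tan_vhalf = tan(runif(1, 10, 35) * pi / 180))
    cal <- synth_calibration(pose, scr, n_per_edge = 9)
    model <- fit_calibration(cal)
    xi <- runif(300); eta <- runif(300)
    s <- (xi - 0.5) * scr$surface_width_cm
    h <- (eta - 0.5) * scr$surface_height_cm
    truth <- project_to_raster(fullfield:::surface_point(s, h, scr), pose)
    pred <- fullfield:::warp_forward(model, xi, eta)
    expect_lt(max(sqrt(rowSums((truth - pred)^2))), 1)
  }
})

test_that("warping preserves uniform fields, masks off-screen, round-trips > 30 dB", {
  map <- fix_map()
  flat <- canvas_blank(0.5)
  w <- warp_image(flat, map)
  expect_true(all(abs(w[map$mask] - 0.5) < 1e-9))
  expect_true(all(w[!map$mask] == 0))
  # warp then unwarp a structured scene: PSNR over the canvas interior
  scene <- synth_images("scene", 1, seed = 4)[[1]]
  u <- unwarp_image(warp_image(scene, map), map)
  rows <- 78:690; cols <- 103:921
  mse <- mean((u[rows, cols] - scene[rows, cols])^2)
  expect_gt(10 * log10(1 / mse), 30)
  # nearest-neighbour interpolation emits only source values (no halos)
  bw <- matrix(rep(c(0, 1), length.out = 768 * 1024), 768, 1024)
  wn <- warp_image(bw, map, interpolation = "nearest")
  expect_true(all(wn %in% c(0, 1)))
  expect_error(warp_image(matrix(0.5, 10, 10), map), "source canvas")
  expect_error(warp_image(array(0, c(768, 1024, 2)), map), "channels")
})

test_that("the forward map is orientation-preserving (bijective) on the region", {
  model <- fix_model()
  xi <- seq(0.005, 0.995, length.out = 60)
  eta <- seq(0.005, 0.995, length.out = 30)
  g <- expand.grid(xi = xi, eta = eta)
  h <- 1e-5
  f0 <- fullfield:::warp_forward(model, g$xi, g$eta)
  fx <- fullfield:::warp_forward(model, g$xi + h, g$eta)
  fe <- fullfield:::warp_forward(model, g$xi, g$eta + h)
  jac <- ((fx[, 1] - f0[, 1]) * (fe[, 2] - f0[, 2]) -
            (fx[, 2] - f0[, 2]) * (fe[, 1] - f0[, 1])) / h^2
  expect_true(all(jac > 0) || all(jac < 0))
})

test_that("display-surface aspect ratio is preserved by construction", {
  scr <- fix_screen()
  # wallpaper mapping: canvas pixels per cm match horizontally and vertically
  expect_equal(1024 / scr$surface_width_cm, 768 / scr$surface_height_cm,
               tolerance = 0.02)
  # and the mapped surface itself is 4:3
  expect_equal(scr$surface_width_cm / scr$surface_height_cm, 4 / 3,
               tolerance = 0.02)
})
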