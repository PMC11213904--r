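view_t <- viewing_geometry(15)

test_that("ring checkerboards fill exactly their eccentricity band", {
  rc <- make_ring_checkerboard(ring_spec(band = 3), view_t)
  pol <- fullfield:::canvas_polar(c(1024, 768))
  ecc <- radius_px_to_eccentricity(pol$r, view_t)
  inband <- ecc >= 6.3 & ecc <= 16.5
  expect_true(all(rc[inband] %in% c(0, 1)))
  expect_true(all(rc[!inband] == 0.5))
  # contrast inversion between the two flicker states
  rc2 <- make_ring_checkerboard(ring_spec(band = 3), view_t,
                                state = "white-black")
  expect_equal(rc2[inband], 1 - rc[inband])
  expect_equal(rc2[!inband], rc[!inband])
  # band pixel area matches the analytic annulus area within 2%
  r_in <- eccentricity_to_radius_px(6.3, view_t)
  r_out <- eccentricity_to_radius_px(16.5, view_t)
  expect_equal(sum(rc != 0.5), pi * (r_out^2 - r_in^2),
               tolerance = 0.02)
  # both check colours are substantially present
  expect_gt(mean(rc[inband] == 1), 0.3)
  expect_gt(mean(rc[inband] == 0), 0.3)
  expect_error(make_ring_checkerboard(
    ring_spec(inner_deg = 100, outer_deg = 120), view_t), "outside")
})

test_that("the five standard bands are non-overlapping and ordered", {
  bands <- lapply(1:5, ring_spec)
  inner <- vapply(bands, `[[`, 0, "inner_deg")
  outer <- vapply(bands, `[[`, 0, "outer_deg")
  expect_true(all(inner < outer))
  expect_true(all(utils::head(outer, -1) < utils::tail(inner, -1) + 1e-9 |
                    utils::head(outer, -1) <= utils::tail(inner, -1)))
  expect_equal(ring_spec(band = 1)$flicker_hz, 4)
})

test_that("meridian checkerboards cover complementary bowties", {
  h <- make_meridian_checkerboard("horizontal", view_t)
  v <- make_meridian_checkerboard("vertical", view_t)
  active_h <- h != 0.5; active_v <- v != 0.5
  expect_gt(sum(active_h), 1e4)
  expect_gt(sum(active_v), 1e4)
  expect_equal(sum(active_h & active_v), 0)
  states <- ring_frame_states(1.5, frame_rate_hz = 60, flicker_hz = 4)
  expect_equal(length(states), 90)
  expect_equal(length(rle(states)$lengths), 6)   # 4 state changes/s
})

test_that("phase scrambling preserves amplitude spectra and mean luminance", {
  scene <- synth_images("scene", 1, seed = 4, size = c(256, 192))[[1]]
  ps <- phase_scramble(scene, seed = 1)
  a0 <- Mod(stats::fft(scene)); a1 <- Mod(stats::fft(ps))
  expect_lt(max(abs(a1 - a0)) / max(a0), 1e-6)
  expect_lt(abs(mean(ps) - mean(scene)), 1e-6)
  # zero-strength scrambling is the identity
  expect_equal(phase_scramble(scene, seed = 1, amount = 0), scene,
               tolerance = 1e-12)
  # full-strength scrambling visibly rearranges the image
  expect_gt(max(abs(ps - scene)), 0.05)
  # colour images: shared phase field, per-channel amplitude preserved
  rgb <- array(runif(64 * 48 * 3), c(48, 64, 3))
  pr <- phase_scramble(rgb, seed = 2)
  for (ch in 1:3) {
    expect_lt(max(abs(Mod(stats::fft(pr[, , ch])) -
                        Mod(stats::fft(rgb[, , ch])))) /
                max(Mod(stats::fft(rgb[, , ch]))), 1e-6)
  }
})

test_that("postcard rescaling pads to the full canvas around a faithful miniature", {
  skip_if_not_installed("EBImage")
  scene <- synth_images("scene", 1, seed = 6)[[1]]
  pc <- make_postcard(scene)
  expect_equal(dim(pc), c(768, 1024))
  expect_equal(pc[1, 1], 0.5)
  expect_equal(pc[768, 1024], 0.5)
  # centre region equals an independently resampled miniature to ~1 gray level
  x0 <- floor((1024 - 205) / 2); y0 <- floor((768 - 154) / 2)
  centre <- pc[y0 + 1:154, x0 + 1:205]
  oracle <- EBImage::resize(t(scene), w = 205, h = 154)
  expect_lt(stats::median(abs(centre - t(oracle))), 1 / 255)
  expect_lt(mean(abs(centre - t(oracle))), 2 / 255)
  # bounding-box variant for faces/objects pads with white
  bb <- make_postcard(scene, target_px = c(171, 129), pad = 1)
  expect_equal(bb[1, 1], 1)
  expect_error(make_postcard(scene, target_px = c(2000, 100)), "larger")
})

test_that("scotomas mask exactly a central disc of the requested size", {
  scene <- synth_images("scene", 1, seed = 8)[[1]]
  expect_identical(apply_scotoma(scene, 0, view_t), scene)
  pol <- fullfield:::canvas_polar(c(1024, 768))
  for (d in c(29, 58, 88, 140)) {
    sc <- apply_scotoma(scene, d, view_t)
    expect_equal(sc[384, 512], 0.5)
    r_px <- eccentricity_to_radius_px(d / 2, view_t)
    disc <- pol$r <= r_px
    expect_true(all(sc[disc] == 0.5))
    expect_identical(sc[!disc], scene[!disc])
    # masked-pixel count matches the analytic disc area within 2%
    expect_equal(sum(disc), pi * r_px^2, tolerance = 0.02)
  }
  expect_error(apply_scotoma(scene, -3, view_t), "non-negative")
})

test_that("item arrays place 13 items without overlap across seeds", {
  items <- synth_images("face", 20, seed = 2, size = c(160, 160))
  for (s in 1:40) {
    arr <- layout_item_array(items, seed = s)
    p <- attr(arr, "placements")
    expect_equal(nrow(p), 13)
    expect_equal(as.vector(table(p$ring)), c(3, 6, 4))
    d <- as.matrix(stats::dist(p[, c("x", "y")]))
    need <- outer(p$radius_px, p$radius_px, "+")
    diag(need) <- 0
    expect_true(all(d >= need))
  }
  expect_error(layout_item_array(items[1:5]), "pool")
})

test_that("zero-jitter arrays respect the ring rotation symmetry", {
  spec0 <- array_layout_spec(jitter_px = 0)
  p <- fullfield:::array_positions(spec0)
  centre <- c(512, 384)
  for (ring in 1:2) {
    q <- p[p$ring == ring, ]
    ang <- sort(atan2(centre[2] - q$y, q$x - centre[1]) %% (2 * pi))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    expect_equal(gaps, rep(2 * pi / nrow(q), nrow(q)), tolerance = 1e-9)
    rad <- sqrt((q$x - centre[1])^2 + (q$y - centre[2])^2)
    expect_equal(rad, rep(spec0$radii_px[ring], nrow(q)), tolerance = 1e-9)
  }
  # outer items sit at the four corners
  q3 <- p[p$ring == 3, ]
  expect_equal(nrow(q3), 4)
  expect_true(all(q3$x %in% c(153, 1024 - 153) & q3$y %in% c(153, 768 - 153)))
})

test_that("luminance matching equates histograms while preserving rank order", {
  imgs <- synth_images("scene", 3, seed = 9, size = c(256, 192))
  out <- match_luminance(imgs)
  means <- vapply(out, mean, 0)
  expect_lt(diff(range(means)) * 255, 0.5)
  # rank order within each image is preserved
  for (k in 1:3) {
    o <- order(imgs[[k]]); expect_true(!is.unsorted(out[[k]][o]))
  }
  # two-image case: both share the average histogram (chi-squared distance)
  two <- match_luminance(imgs[1:2])
  h1 <- hist(two[[1]], breaks = seq(0, 1, by = 1 / 64), plot = FALSE)$counts
  h2 <- hist(two[[2]], breaks = seq(0, 1, by = 1 / 64), plot = FALSE)$counts
  chi2 <- sum((h1 - h2)^2 / pmax(h1 + h2, 1))
  expect_lt(chi2 / sum(h1), 0.01)
  # identical inputs come back unchanged
  same <- match_luminance(list(imgs[[1]], imgs[[1]]))
  expect_equal(same[[1]], imgs[[1]], tolerance = 1e-9)
  expect_warning(match_luminance(imgs[1]), "fewer than 2")
})

test_that("the factorial stimulus builder emits the full manifest", {
  td <- withr::local_tempdir()
  man <- build_exp3_stimuli(td, n_base = 2, pool_size = 13, seed = 5)
  expect_equal(nrow(man), 2 * 5 * 4)
  expect_equal(length(unique(man$filename)), nrow(man))
  expect_equal(sort(unique(man$content)),
               c("face_array", "object_array", "scene", "scrambled"))
  expect_true(all(file.exists(file.path(td, man$filename))))
  img <- read_image(file.path(td, man$filename[1]))
  expect_equal(dim(img)[1:2], c(768, 1024))
  man2 <- read_events(file.path(td, "manifest.tsv"))
  expect_equal(nrow(man2), nrow(man))
})
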