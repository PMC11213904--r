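## Stimulus generators. All stimuli are drawn on the canonical pre-warp
## canvas (1024 x 768 by default), values in [0, 1], grayscale matrices or
## H x W x 3 arrays, and pass through warp_image() unresized.

CANVAS_PX <- c(1024L, 768L)

#' Uniform canvas
#'
#' @param value Fill value in `[0, 1]`.
#' @param size Canvas `c(width, height)` in pixels.
#' @return A height x width matrix.
#' @export
canvas_blank <- function(value = 0.5, size = CANVAS_PX) {
  matrix(value, size[2], size[1])
}

# Pixel-centre polar coordinates about the canvas centre.
canvas_polar <- function(size = CANVAS_PX) {
  x <- (seq_len(size[1]) - 0.5) - size[1] / 2
  y <- (seq_len(size[2]) - 0.5) - size[2] / 2
  list(r = sqrt(outer(y^2, x^2, "+")),
       theta = atan2(matrix(y, size[2], size[1]),
                     matrix(x, size[2], size[1], byrow = TRUE)))
}

#' Eccentricity-band specification for ring checkerboards
#'
#' The five eccentricity conditions of the wide-field retinotopy protocol:
#' a centre disc of 1.8 degrees radius and rings spanning 2.0-5.6,
#' 6.3-16.5, 18.5-50.3 and 55.3+ degrees.
#'
#' @param band Integer 1-5 selecting a standard band, or `NULL` to use
#'   `inner_deg`/`outer_deg` directly.
#' @param inner_deg,outer_deg Band radii in visual degrees.
#' @param flicker_hz Flicker rate of the contrast states.
#' @return A list with class `ff_ring_spec`.
#' @export
ring_spec <- function(band = NULL, inner_deg = NULL, outer_deg = NULL,
                      flicker_hz = 4) {
  bands <- list(c(0, 1.8), c(2.0, 5.6), c(6.3, 16.5), c(18.5, 50.3),
                c(55.3, Inf))
  if (!is.null(band)) {
    stopifnot(band %in% 1:5)
    inner_deg <- bands[[band]][1]
    outer_deg <- bands[[band]][2]
  }
  if (is.null(inner_deg) || is.null(outer_deg) || inner_deg >= outer_deg)
    stop("need inner_deg < outer_deg")
  structure(list(inner_deg = inner_deg, outer_deg = outer_deg,
                 flicker_hz = flicker_hz),
            class = "ff_ring_spec")
}

#' Polar checkerboard confined to an eccentricity band
#'
#' Checks are defined in log-polar coordinates (fixed angular sectors and
#' radial rings that widen with eccentricity), so check size scales with
#' eccentricity as the cortical magnification of the stimulus does.
#' Contrast states alternate between `"black-white"`, its inversion
#' `"white-black"`, and `"random-color"` at the spec's flicker rate (see
#' [ring_frame_states()]).
#'
#' @param spec A [ring_spec()].
#' @param view A [viewing_geometry()] used to convert degrees to canvas px.
#' @param state One of `"black-white"`, `"white-black"`, `"random-color"`.
#' @param phase Integer check-phase offset (swaps the two check colours).
#' @param n_wedges Angular sectors per full circle.
#' @param ring_ratio Radial growth factor of successive check rings.
#' @param background Background gray value.
#' @param size Canvas size `c(width, height)`.
#' @param seed Seed for the random-colour state.
#' @return Grayscale matrix, or an H x W x 3 array for `"random-color"`.
#' @export
make_ring_checkerboard <- function(spec, view = viewing_geometry(),
                                   state = c("black-white", "white-black",
                                             "random-color"),
                                   phase = 0, n_wedges = 24,
                                   ring_ratio = 1.35, background = 0.5,
                                   size = CANVAS_PX, seed = NULL) {
  state <- match.arg(state)
  max_ecc <- cylinder_angular_width(view$screen, view) / 2
  if (spec$inner_deg >= max_ecc)
    stop("band lies entirely outside the screen")
  pol <- canvas_polar(size)
  ecc <- radius_px_to_eccentricity(pol$r, view, canvas_width_px = size[1])
  inband <- ecc >= spec$inner_deg & ecc <= spec$outer_deg
  wedge <- floor((pol$theta + pi) / (2 * pi / n_wedges))
  ring <- floor(log(pmax(ecc, 0.05) / 0.05) / log(ring_ratio))
  parity <- (wedge + ring + phase) %% 2
  if (state == "random-color") {
    if (!is.null(seed)) set.seed(seed)
    img <- array(background, c(size[2], size[1], 3))
    id <- (ring * n_wedges + wedge)[inband]
    uid <- sort(unique(id))
    cols <- matrix(stats::runif(3 * length(uid)), ncol = 3)
    ki <- match(id, uid)
    for (ch in 1:3) {
      plane <- matrix(background, size[2], size[1])
      plane[inband] <- cols[ki, ch]
      img[, , ch] <- plane
    }
    img
  } else {
    val <- ifelse(parity == 0, 1, 0)
    if (state == "white-black") val <- 1 - val
    img <- matrix(background, size[2], size[1])
    img[inband] <- val[inband]
    img
  }
}

#' Meridian-band checkerboard
#'
#' Bowtie-shaped checkerboard along the horizontal or vertical meridian,
#' used for delineating early visual areas.
#'
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param half_width_deg Angular half-width of the bowtie in polar angle.
#' @inheritParams make_ring_checkerboard
#' @return Grayscale matrix (or colour array, as for the rings).
#' @export
make_meridian_checkerboard <- function(orientation = c("horizontal", "vertical"),
                                       view = viewing_geometry(),
                                       state = "black-white", phase = 0,
                                       half_width_deg = 15, n_wedges = 24,
                                       ring_ratio = 1.35, background = 0.5,
                                       size = CANVAS_PX, seed = NULL) {
  orientation <- match.arg(orientation)
  full <- make_ring_checkerboard(ring_spec(inner_deg = 0.2, outer_deg = Inf),
                                 view, state, phase, n_wedges, ring_ratio,
                                 background, size, seed)
  pol <- canvas_polar(size)
  w <- deg2rad(half_width_deg)
  th <- pol$theta
  keep <- if (orientation == "horizontal") {
    abs(th) <= w | abs(abs(th) - pi) <= w
  } else {
    abs(th - pi / 2) <= w | abs(th + pi / 2) <= w
  }
  if (length(dim(full)) == 3) {
    for (ch in 1:3) {
      plane <- full[, , ch]; plane[!keep] <- background; full[, , ch] <- plane
    }
    full
  } else {
    full[!keep] <- background
    full
  }
}

#' Contrast states of a flickering checkerboard block
#'
#' @param duration_s Block duration in seconds.
#' @param frame_rate_hz Display frame rate.
#' @param flicker_hz State-change rate (default 4).
#' @return Character vector, one state per display frame, cycling
#'   black-white / white-black / random-color.
#' @export
ring_frame_states <- function(duration_s, frame_rate_hz = 60, flicker_hz = 4) {
  states <- c("black-white", "white-black", "random-color")
  t <- (seq_len(round(duration_s * frame_rate_hz)) - 1) / frame_rate_hz
  states[(floor(t * flicker_hz) %% length(states)) + 1]
}

#' Randomise the phase spectrum of an image
#'
#' Decomposes the image into amplitude and phase by FFT, adds a random
#' phase field, and inverts. The random phase is taken from the FFT of
#' white noise so it is conjugate-symmetric: the output is real, the
#' amplitude spectrum is preserved exactly, and the DC term (mean
#' luminance) is untouched. Colour images share one phase field across
#' channels by default, preserving inter-channel structure.
#'
#' @param img Grayscale matrix or H x W x 3 array.
#' @param seed Optional seed for the phase noise.
#' @param share_channels Use the same phase noise for all channels.
#' @param amount Scramble strength in `[0, 1]`: the added phase angles are
#'   scaled by this factor, so 0 returns the image unchanged and 1 (the
#'   default) fully randomises the phase.
#' @return Scrambled image, same dimensions, clipped to `[0, 1]`.
#' @export
phase_scramble <- function(img, seed = NULL, share_channels = TRUE,
                           amount = 1) {
  if (!is.null(seed)) set.seed(seed)
  dm <- dim(img)
  C <- if (length(dm) == 3) dm[3] else 1
  rand_phase <- function() {
    z <- stats::fft(matrix(stats::runif(dm[1] * dm[2]), dm[1], dm[2]))
    ph <- exp(1i * amount * Arg(z))
    ph[1, 1] <- 1          # DC untouched
    ph
  }
  ph <- rand_phase()
  # no clipping here: it would perturb the amplitude spectrum. Values can
  # exceed [0, 1] slightly; write_image() clips at 8-bit quantisation.
  scramble_plane <- function(plane, ph) {
    F <- stats::fft(plane)
    Re(stats::fft(F * ph, inverse = TRUE)) / length(plane)
  }
  if (C == 1) {
    scramble_plane(if (length(dm) == 2) img else img[, , 1], ph)
  } else {
    out <- array(0, dm)
    for (ch in seq_len(C)) {
      if (!share_channels && ch > 1) ph <- rand_phase()
      out[, , ch] <- scramble_plane(img[, , ch], ph)
    }
    out
  }
}

# Bilinear rescale of a whole image to a new width x height.
resize_image <- function(img, new_size) {
  dm <- dim(img)
  W <- new_size[1]; H <- new_size[2]
  gx <- (seq_len(W) - 0.5) * dm[2] / W
  gy <- (seq_len(H) - 0.5) * dm[1] / H
  g <- expand.grid(y = gy, x = gx)
  vals <- sample_image(img, g$x, g$y, "bilinear")
  if (length(dm) == 3) array(vals, c(H, W, dm[3])) else matrix(vals[, 1], H, W)
}

#' Rescale an image to "postcard" size on a padded canvas
#'
#' The whole image is rescaled (not cropped) to `target_px` and centred on
#' a canvas of the original size, padded with `pad`. The standard postcard
#' scene is 205 x 154 px (44 degrees wide at the nominal viewing
#' distance); faces and objects use a 171 x 129 px bounding box on white.
#'
#' @param img Canvas-sized image.
#' @param target_px Target `c(width, height)` of the rescaled image.
#' @param pad Padding value for the surround.
#' @param size Output canvas `c(width, height)`.
#' @return Canvas-sized image with the miniature at the centre.
#' @export
make_postcard <- function(img, target_px = c(205, 154), pad = 0.5,
                          size = CANVAS_PX) {
  if (any(target_px > size)) stop("target larger than the canvas")
  small <- resize_image(img, target_px)
  dmc <- if (length(dim(img)) == 3) 3L else 1L
  out <- if (dmc == 3) array(pad, c(size[2], size[1], 3)) else
    matrix(pad, size[2], size[1])
  x0 <- floor((size[1] - target_px[1]) / 2)
  y0 <- floor((size[2] - target_px[2]) / 2)
  rows <- y0 + seq_len(target_px[2]); cols <- x0 + seq_len(target_px[1])
  if (dmc == 3) out[rows, cols, ] <- small else out[rows, cols] <- small
  out
}

#' Mask the image centre with an artificial scotoma
#'
#' Replaces a central disc of the given diameter (in visual degrees,
#' converted through the viewing geometry) with the fill value. Diameter 0
#' is the identity. The standard levels are 0, 29, 58, 88 and 140 degrees.
#'
#' @param img Canvas-sized image.
#' @param diameter_deg Scotoma diameter in visual degrees (>= 0).
#' @param view A [viewing_geometry()].
#' @param fill Fill value for the masked disc.
#' @return Image with the central disc replaced.
#' @export
apply_scotoma <- function(img, diameter_deg, view = viewing_geometry(),
                          fill = 0.5) {
  if (diameter_deg < 0) stop("diameter must be non-negative")
  if (diameter_deg == 0) return(img)
  dm <- dim(img)
  size <- c(dm[2], dm[1])
  r_px <- eccentricity_to_radius_px(diameter_deg / 2, view,
                                    canvas_width_px = size[1])
  pol <- canvas_polar(size)
  disc <- pol$r <= r_px
  if (length(dm) == 3) {
    for (ch in seq_len(dm[3])) {
      plane <- img[, , ch]; plane[disc] <- fill; img[, , ch] <- plane
    }
  } else {
    img[disc] <- fill
  }
  img
}

#' Layout specification for eccentricity-scaled item arrays
#'
#' Item diameters grow with eccentricity to compensate cortical
#' magnification and avoid crowding: 3 items of 113 px on the inner
#' circle, 6 of 178 px on the middle circle, and 4 of 295 px at the image
#' corners.
#'
#' @param counts Items per ring (inner, middle, outer).
#' @param diameters_px Item diameters per ring.
#' @param radii_px Radii of the inner and middle eccentricity circles.
#' @param corner_inset_px Distance of the outer items' centres from the
#'   image corners, along both axes.
#' @param jitter_px Maximum absolute positional jitter per axis.
#' @param angle_offset_deg Angular offset of the first item on each circle.
#' @return A list with class `ff_array_spec`.
#' @export
array_layout_spec <- function(counts = c(3, 6, 4),
                              diameters_px = c(113, 178, 295),
                              radii_px = c(80, 225),
                              corner_inset_px = 153,
                              jitter_px = 5,
                              angle_offset_deg = c(90, 0)) {
  if (any(diff(diameters_px) <= 0))
    stop("diameters must increase with eccentricity")
  structure(list(counts = counts, diameters_px = diameters_px,
                 radii_px = radii_px, corner_inset_px = corner_inset_px,
                 jitter_px = jitter_px, angle_offset_deg = angle_offset_deg),
            class = "ff_array_spec")
}

# Nominal (jitter-free) item centres and radii for a layout.
array_positions <- function(spec, size = CANVAS_PX) {
  centre <- size / 2
  pos <- list()
  for (ring in 1:2) {
    k <- spec$counts[ring]
    ang <- deg2rad(spec$angle_offset_deg[ring]) +
      2 * pi * (seq_len(k) - 1) / k
    pos[[ring]] <- data.frame(
      x = centre[1] + spec$radii_px[ring] * cos(ang),
      y = centre[2] - spec$radii_px[ring] * sin(ang),
      ring = ring)
  }
  ci <- spec$corner_inset_px
  pos[[3]] <- data.frame(
    x = c(ci, size[1] - ci, ci, size[1] - ci),
    y = c(ci, ci, size[2] - ci, size[2] - ci),
    ring = 3)[seq_len(spec$counts[3]), ]
  out <- do.call(rbind, pos)
  out$radius_px <- spec$diameters_px[out$ring] / 2
  out
}

#' Arrange items along eccentricity circles with jitter
#'
#' Draws `sum(spec$counts)` items (by default 13) from the pool, rescales
#' each to its ring's diameter, and places them equally spaced on the
#' inner/middle circles and at the four corners, with uniform positional
#' jitter. Placements are rejected and re-jittered until no two item discs
#' overlap and all discs stay on the canvas; after `max_tries` failures an
#' error reports the seed.
#'
#' @param items List of square grayscale matrices (the item pool).
#' @param spec An [array_layout_spec()].
#' @param seed Seed for item draw and jitter.
#' @param background Canvas background value.
#' @param size Canvas `c(width, height)`.
#' @param max_tries Jitter retries before giving up.
#' @return Canvas-sized matrix with attribute `placements` (data frame of
#'   centres, radii and pool indices).
#' @export
layout_item_array <- function(items, spec = array_layout_spec(), seed = NULL,
                              background = 0.5, size = CANVAS_PX,
                              max_tries = 100) {
  if (!is.null(seed)) set.seed(seed)
  n_items <- sum(spec$counts)
  if (length(items) < n_items)
    stop(sprintf("item pool (%d) smaller than total count (%d)",
                 length(items), n_items))
  base <- array_positions(spec, size)
  draw <- sample(length(items), n_items)
  ok <- FALSE
  for (try in seq_len(max_tries)) {
    p <- base
    p$x <- p$x + stats::runif(n_items, -spec$jitter_px, spec$jitter_px)
    p$y <- p$y + stats::runif(n_items, -spec$jitter_px, spec$jitter_px)
    dmat <- as.matrix(stats::dist(p[, c("x", "y")]))
    need <- outer(p$radius_px, p$radius_px, "+")
    diag(need) <- 0
    on_canvas <- all(p$x - p$radius_px >= 0) && all(p$x + p$radius_px <= size[1]) &&
      all(p$y - p$radius_px >= 0) && all(p$y + p$radius_px <= size[2])
    if (all(dmat >= need) && on_canvas) { ok <- TRUE; break }
  }
  if (!ok)
    stop(sprintf("could not find a non-overlapping layout in %d tries (seed %s)",
                 max_tries, deparse(seed)))
  canvas <- canvas_blank(background, size)
  for (i in seq_len(n_items)) {
    d <- round(2 * p$radius_px[i])
    patch <- resize_image(items[[draw[i]]], c(d, d))
    rows <- round(p$y[i] - d / 2) + seq_len(d)
    cols <- round(p$x[i] - d / 2) + seq_len(d)
    canvas[rows, cols] <- patch
  }
  p$pool_index <- draw
  attr(canvas, "placements") <- p
  canvas
}

#' Equate luminance histograms across a stimulus set
#'
#' Rank-preserving histogram specification: each image's pixel values are
#' remapped to the average quantile function of the whole set, so all
#' outputs share (up to pixel-count granularity) one luminance histogram
#' while each image's spatial rank order is untouched.
#'
#' @param imgs List of grayscale matrices (equal sizes recommended).
#' @param n_quantiles Resolution of the common quantile profile.
#' @return List of matched matrices, same order.
#' @export
match_luminance <- function(imgs, n_quantiles = 2048) {
  if (length(imgs) < 2) {
    warning("fewer than 2 images: returning input unchanged")
    return(imgs)
  }
  sizes <- vapply(imgs, length, 0L)
  if (length(unique(sizes)) == 1) {
    # exact histogram specification: average the sorted pixel profiles
    target <- rowMeans(vapply(imgs, function(im) sort(as.vector(im)),
                              numeric(sizes[1])))
    lapply(imgs, function(im) {
      out <- im
      out[order(im)] <- target
      out
    })
  } else {
    # unequal sizes: interpolate the average quantile function
    p <- seq(0, 1, length.out = n_quantiles)
    qf <- rowMeans(vapply(imgs,
                          function(im) stats::quantile(im, p, names = FALSE),
                          numeric(n_quantiles)))
    lapply(imgs, function(im) {
      n <- length(im)
      out <- im
      out[] <- stats::approx(p, qf,
                             xout = (rank(im, ties.method = "first") - 0.5) / n)$y
      out
    })
  }
}

#' Build the full scenes/faces/objects x scotoma stimulus set
#'
#' Generates the complete factorial stimulus set: 4 content types
#' (procedural scenes, phase-scrambled scenes, face arrays, object arrays)
#' x `n_base` base images x `length(scotoma_deg)` scotoma levels -- with
#' the standard parameters, 4 x 20 x 5 = 400 unique stimuli. Scenes, faces
#' and objects are luminance-matched before scrambling and array layout.
#'
#' @param out_dir Output directory for PNG files (created if needed).
#' @param n_base Base images per content type.
#' @param scotoma_deg Scotoma diameters in visual degrees. The alternative
#'   published set `c(0, 30, 58, 88, 138)` may be supplied.
#' @param seed Master seed; every image is a pure function of it.
#' @param view Viewing geometry for degree-to-pixel conversion.
#' @param size Canvas size (reduce for quick tests).
#' @param pool_size Face/object pool size.
#' @param write Write PNGs (otherwise only the manifest is returned).
#' @return Invisibly, the manifest data frame (filename, content,
#'   base_id, scotoma_deg, seed), one row per stimulus.
#' @export
build_exp3_stimuli <- function(out_dir = NULL, n_base = 20,
                               scotoma_deg = c(0, 29, 58, 88, 140),
                               seed = 1, view = viewing_geometry(),
                               size = CANVAS_PX, pool_size = 58,
                               write = !is.null(out_dir)) {
  if (write && is.null(out_dir)) stop("out_dir required when write = TRUE")
  if (write) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenes <- synth_images("scene", n_base, seed = seed, size = size)
  faces <- synth_images("face", pool_size, seed = seed + 1,
                        size = c(305, 305))
  objects <- synth_images("object", pool_size, seed = seed + 2,
                          size = c(305, 305))
  matched <- match_luminance(c(scenes, faces, objects))
  scenes <- matched[seq_len(n_base)]
  faces <- matched[n_base + seq_len(pool_size)]
  objects <- matched[n_base + pool_size + seq_len(pool_size)]

  content_types <- c("scene", "scrambled", "face_array", "object_array")
  manifest <- expand.grid(base_id = seq_len(n_base),
                          scotoma_deg = scotoma_deg,
                          content = content_types,
                          stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$content, manifest$base_id,
                             manifest$scotoma_deg), ]
  manifest$seed <- seed
  manifest$filename <- sprintf("%s_base%02d_scot%03d.png", manifest$content,
                               manifest$base_id, round(manifest$scotoma_deg))
  base_cache <- new.env()
  base_image <- function(content, id) {
    key <- paste(content, id)
    if (!is.null(base_cache[[key]])) return(base_cache[[key]])
    img <- switch(content,
      scene = scenes[[id]],
      scrambled = phase_scramble(scenes[[id]], seed = seed + 100 + id),
      face_array = layout_item_array(faces, seed = seed + 200 + id,
                                     size = size),
      object_array = layout_item_array(objects, seed = seed + 300 + id,
                                       size = size))
    attr(img, "placements") <- NULL
    base_cache[[key]] <- img
    img
  }
  for (i in seq_len(nrow(manifest))) {
    img <- apply_scotoma(base_image(manifest$content[i], manifest$base_id[i]),
                         manifest$scotoma_deg[i], view)
    if (write) {
      png::writePNG(img, file.path(out_dir, manifest$filename[i]))
    }
  }
  if (write) {
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(manifest)
}
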