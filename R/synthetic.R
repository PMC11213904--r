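## Synthetic fixtures: simulated BOLD with planted structure, ground-truth
## optical calibrations, and procedural stimulus content. Everything is a
## pure function of its seed, so the whole pipeline is testable offline.

#' Simulation specification for synthetic BOLD data
#'
#' @param amplitudes Voxels x conditions matrix of response amplitudes in
#'   percent signal change.
#' @param baseline Baseline signal level (PSC-natural scale).
#' @param sigma Noise standard deviation (signal units).
#' @param phi AR(1) coefficient of the noise, |phi| < 1.
#' @param drift_order Order of the Legendre-polynomial drift (0 = none).
#' @param drift_amp Peak drift amplitude as a fraction of baseline.
#' @param seed Seed for noise and drift.
#' @return A list of class `ff_sim_spec`.
#' @export
sim_spec <- function(amplitudes, baseline = 100, sigma = 1, phi = 0,
                     drift_order = 2, drift_amp = 0.005, seed = 1) {
  amplitudes <- as.matrix(amplitudes)
  if (!all(is.finite(amplitudes))) stop("amplitudes must be finite")
  if (sigma < 0) stop("sigma must be non-negative")
  if (abs(phi) >= 1) stop("|phi| must be < 1")
  structure(list(amplitudes = amplitudes, baseline = baseline,
                 sigma = sigma, phi = phi, drift_order = drift_order,
                 drift_amp = drift_amp, seed = seed),
            class = "ff_sim_spec")
}

# Legendre polynomials on [-1, 1], orders 0..k, as columns.
legendre_basis <- function(n, k) {
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, k + 1)
  P[, 1] <- 1
  if (k >= 1) P[, 2] <- x
  if (k >= 2) for (j in 2:k) {
    P[, j + 1] <- ((2 * j - 1) * x * P[, j] - (j - 1) * P[, j - 1]) / j
  }
  P
}

#' Simulate BOLD time series for a run
#'
#' Generates `y = baseline * (1 + sum_c beta_vc x_c(t) / 100) + drift +
#' AR(1) noise` per voxel, where the `x_c` are the HRF-convolved condition
#' regressors of the run's design. Drift coefficients are drawn per voxel;
#' AR(1) innovations are scaled so the noise has marginal standard
#' deviation `sigma`.
#'
#' @param spec A [sim_spec()].
#' @param run An `ff_run` (from the protocol builders) or a design matrix
#'   from [build_design_matrix()].
#' @return A list of class `ff_bold`: `data` (voxels x time), `TR`,
#'   `design` (the condition regressors used), and the planted
#'   `amplitudes`.
#' @export
synth_bold <- function(spec, run) {
  X <- if (inherits(run, "ff_run")) {
    build_design_matrix(run$blocks, run$TR, run$timing$TRs)
  } else run
  conds <- attr(X, "conditions")
  Xc <- X[, conds, drop = FALSE]
  TR <- attr(X, "TR")
  n <- nrow(Xc)
  V <- nrow(spec$amplitudes)
  if (ncol(spec$amplitudes) != ncol(Xc))
    stop(sprintf("amplitudes have %d conditions but the design has %d",
                 ncol(spec$amplitudes), ncol(Xc)))
  set.seed(spec$seed)
  signal <- spec$baseline * (1 + (spec$amplitudes %*% t(Xc)) / 100)
  drift <- matrix(0, V, n)
  if (spec$drift_order > 0) {
    L <- legendre_basis(n, spec$drift_order)[, -1, drop = FALSE]
    cf <- matrix(stats::rnorm(V * ncol(L),
                              sd = spec$drift_amp * spec$baseline), V)
    drift <- cf %*% t(L)
  }
  noise <- matrix(0, V, n)
  if (spec$sigma > 0) {
    innov_sd <- spec$sigma * sqrt(1 - spec$phi^2)
    eps <- matrix(stats::rnorm(V * n, sd = innov_sd), V, n)
    if (abs(spec$phi) > 0) {
      noise[, 1] <- eps[, 1] / sqrt(1 - spec$phi^2)
      for (tt in 2:n) noise[, tt] <- spec$phi * noise[, tt - 1] + eps[, tt]
    } else {
      noise <- eps
    }
  }
  structure(list(data = signal + drift + noise, TR = TR,
                 design = Xc, amplitudes = spec$amplitudes,
                 conditions = conds, seed = spec$seed),
            class = "ff_bold")
}

#' @export
print.ff_bold <- function(x, ...) {
  cat(sprintf("Synthetic BOLD: %d voxels x %d TRs (TR %g s), %d conditions\n",
              nrow(x$data), ncol(x$data), x$TR, length(x$conditions)))
  invisible(x)
}

#' Plant an eccentricity-tuned voxel population
#'
#' Assigns each voxel one preferred eccentricity band whose response
#' amplitude exceeds all other bands by `margin` PSC, emulating the
#' centre-to-far-periphery progression of preferences along visual
#' cortex. Band membership cycles through the bands (configurable
#' proportions), and the ground-truth labels ride along.
#'
#' @param n_voxels Number of voxels.
#' @param n_bands Number of eccentricity conditions.
#' @param margin Amplitude margin (PSC) of the preferred band; scalar or
#'   one value per voxel.
#' @param base_amp Amplitude of non-preferred bands (PSC).
#' @param proportions Optional band membership proportions (length
#'   `n_bands`, summing to 1).
#' @param extra_conditions Number of additional zero-amplitude conditions
#'   appended after the bands (e.g. the two meridian conditions).
#' @return Voxels x conditions amplitude matrix with attribute
#'   `preferred` (integer band per voxel).
#' @export
synth_retinotopic_population <- function(n_voxels, n_bands = 5, margin = 0.5,
                                         base_amp = 0.3, proportions = NULL,
                                         extra_conditions = 0) {
  if (is.null(proportions)) proportions <- rep(1 / n_bands, n_bands)
  if (length(proportions) != n_bands || abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be length n_bands and sum to 1")
  counts <- diff(round(cumsum(c(0, proportions)) * n_voxels))
  preferred <- rep(seq_len(n_bands), counts)
  length(preferred) <- n_voxels
  preferred[is.na(preferred)] <- n_bands
  amp <- matrix(base_amp, n_voxels, n_bands)
  amp[cbind(seq_len(n_voxels), preferred)] <- base_amp + margin
  if (extra_conditions > 0)
    amp <- cbind(amp, matrix(0, n_voxels, extra_conditions))
  attr(amp, "preferred") <- preferred
  amp
}

#' Ground-truth calibration points from the ray-traced screen outline
#'
#' Projects labelled points along the screen's top, bottom and (optionally)
#' half-height outlines into the projector raster and adds Gaussian pixel
#' noise, emulating the manual on-screen calibration procedure. The "top"
#' calibration edge is the screen edge nearer the projector (wider on the
#' raster).
#'
#' @param pose A [projector_pose()].
#' @param screen A [screen_geometry()].
#' @param n_per_edge Points per edge (>= 3; endpoints always included).
#' @param noise_px Gaussian noise SD added to each coordinate.
#' @param middle Include the half-height middle outline (enables the
#'   projective vertical map).
#' @param seed Optional seed for the noise.
#' @return An [calibration_points()] object.
#' @export
synth_calibration <- function(pose, screen = screen_geometry(),
                              n_per_edge = 9, noise_px = 0, middle = TRUE,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_per_edge < 3) stop("need at least 3 points per edge")
  s_frac <- seq(0, 1, length.out = n_per_edge)
  s_cm <- (s_frac - 0.5) * screen$surface_width_cm
  half_h <- screen$surface_height_cm / 2
  edge_at <- function(h) {
    q <- project_to_raster(surface_point(s_cm, h, screen), pose)
    if (any(!is.finite(q))) stop("pose does not see the screen")
    data.frame(px = q[, 1] + stats::rnorm(n_per_edge, 0, noise_px),
               py = q[, 2] + stats::rnorm(n_per_edge, 0, noise_px),
               s_frac = s_frac)
  }
  calibration_points(top = edge_at(-half_h),
                     bottom = edge_at(half_h),
                     middle = if (middle) edge_at(0))
}

#' Procedural stimulus content
#'
#' Draws schematic stimulus images so the pipeline never depends on
#' photographs: `"scene"` produces a gradient-lit room view with furniture
#' blocks (non-flat, roughly power-law amplitude spectrum), `"face"` a
#' schematic face (head ellipse, eyes, brows, nose, mouth), `"object"` a
#' shaded geometric object on a plain ground. All are grayscale in
#' `[0, 1]` and deterministic given the seed.
#'
#' @param kind `"scene"`, `"face"` or `"object"`.
#' @param n Number of images.
#' @param seed Master seed (image i uses `seed + i`).
#' @param size Image `c(width, height)` in pixels.
#' @return List of `n` matrices.
#' @export
synth_images <- function(kind = c("scene", "face", "object"), n = 1,
                         seed = 1, size = CANVAS_PX) {
  kind <- match.arg(kind)
  lapply(seq_len(n), function(i) {
    set.seed(seed + i)
    switch(kind,
           scene = draw_scene(size),
           face = draw_face(size),
           object = draw_object(size))
  })
}

# normalised coordinate grids in [0,1]
coord_grid <- function(size) {
  list(x = matrix(seq(0, 1, length.out = size[1]), size[2], size[1],
                  byrow = TRUE),
       y = matrix(seq(0, 1, length.out = size[2]), size[2], size[1]))
}

draw_rect <- function(img, x0, y0, x1, y1, value) {
  W <- ncol(img); H <- nrow(img)
  cols <- max(1, round(x0 * W)):min(W, max(1, round(x1 * W)))
  rows <- max(1, round(y0 * H)):min(H, max(1, round(y1 * H)))
  img[rows, cols] <- value
  img
}

draw_scene <- function(size) {
  g <- coord_grid(size)
  horizon <- stats::runif(1, 0.45, 0.6)
  light <- stats::runif(1, 0.3, 0.7)
  img <- ifelse(g$y < horizon,
                0.75 - 0.35 * g$y / horizon * light,          # wall/ceiling
                0.35 + 0.45 * (g$y - horizon) / (1 - horizon)) # floor
  img <- img * (0.85 + 0.3 * abs(g$x - light))                # side lighting
  n_obj <- sample(4:7, 1)
  for (i in seq_len(n_obj)) {
    w <- stats::runif(1, 0.06, 0.2); h <- stats::runif(1, 0.08, 0.3)
    x0 <- stats::runif(1, 0, 1 - w)
    y0 <- horizon - stats::runif(1, 0, 0.1)
    img <- draw_rect(img, x0, y0, x0 + w, min(1, y0 + h),
                     stats::runif(1, 0.1, 0.9))
  }
  # central counter object
  img <- draw_rect(img, 0.47, horizon - 0.12, 0.53, horizon,
                   stats::runif(1, 0.05, 0.25))
  pmin(pmax(img, 0), 1)
}

draw_ellipse <- function(img, cx, cy, rx, ry, value, g) {
  sel <- ((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2 <= 1
  img[sel] <- value
  img
}

draw_face <- function(size) {
  g <- coord_grid(size)
  img <- matrix(stats::runif(1, 0.85, 0.95), size[2], size[1])
  skin <- stats::runif(1, 0.55, 0.75)
  img <- draw_ellipse(img, 0.5, 0.55, 0.33, 0.42, skin, g)           # head
  img <- draw_ellipse(img, 0.5, 0.22, 0.3, 0.14,
                      stats::runif(1, 0.05, 0.3), g)                 # hair
  ey <- stats::runif(1, 0.42, 0.48); ex <- stats::runif(1, 0.13, 0.17)
  for (sgn in c(-1, 1)) {
    img <- draw_ellipse(img, 0.5 + sgn * ex, ey, 0.06, 0.035, 0.95, g)
    img <- draw_ellipse(img, 0.5 + sgn * ex, ey, 0.025, 0.025, 0.05, g)
    img <- draw_ellipse(img, 0.5 + sgn * ex, ey - 0.07, 0.07, 0.012, 0.2, g)
  }
  img <- draw_ellipse(img, 0.5, 0.6, 0.025, 0.07, skin * 0.8, g)     # nose
  img <- draw_ellipse(img, 0.5, 0.76, stats::runif(1, 0.08, 0.14),
                      0.025, 0.15, g)                                # mouth
  img
}

draw_object <- function(size) {
  g <- coord_grid(size)
  img <- matrix(stats::runif(1, 0.85, 0.95), size[2], size[1])
  shape <- sample(c("disc", "box", "star"), 1)
  base <- stats::runif(1, 0.2, 0.6)
  if (shape == "disc") {
    r <- stats::runif(1, 0.2, 0.35)
    sel <- (g$x - 0.5)^2 + (g$y - 0.5)^2 <= r^2
    img[sel] <- base + 0.3 * (g$x[sel] - 0.5)                        # shading
  } else if (shape == "box") {
    w <- stats::runif(1, 0.2, 0.35); h <- stats::runif(1, 0.2, 0.35)
    img <- draw_rect(img, 0.5 - w, 0.5 - h, 0.5 + w, 0.5 + h, base)
    img <- draw_rect(img, 0.5 - w, 0.5 - h, 0.5, 0.5, base * 0.7)
  } else {
    th <- atan2(g$y - 0.5, g$x - 0.5)
    r <- sqrt((g$x - 0.5)^2 + (g$y - 0.5)^2)
    k <- sample(5:8, 1)
    sel <- r <= 0.18 + 0.12 * abs(cos(k * th / 2))
    img[sel] <- base
  }
  pmin(pmax(img, 0), 1)
}
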