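## Forward optical model: a pinhole projector looking up the bore at the
## tilted cylindrical screen. World frame: z along the bore axis, y up,
## x to the viewer's right; the screen centre is the origin.
##
## The screen is a 120 deg section of a cylinder whose axis is tilted by
## `tilt` in the y-z plane (the tilt increases the grazing angle of the
## projection rays from `incidence` on the bore wall to incidence + tilt on
## the screen). Surface coordinates: s = r * phi (arc length from the
## centre, positive to the right) and h (along the rulings, positive away
## from the projector).

v_cross <- function(u, w) {
  c(u[2] * w[3] - u[3] * w[2],
    u[3] * w[1] - u[1] * w[3],
    u[1] * w[2] - u[2] * w[1])
}

v_unit <- function(u) u / sqrt(sum(u^2))

screen_frame <- function(screen) {
  t <- deg2rad(screen$tilt_deg)
  a <- c(0, -sin(t), cos(t))  # cylinder axis (rulings)
  m <- c(0, cos(t), sin(t))   # axis -> screen-centre direction
  e <- c(1, 0, 0)             # completes the right-handed surface frame
  list(a = a, m = m, e = e, axis_point = -screen$radius_cm * m)
}

#' Point on the screen surface
#'
#' @param s_cm Arc-length coordinate (cm, 0 at the screen centre).
#' @param h_cm Height along the rulings (cm, 0 at the vertical centre).
#' @param screen A [screen_geometry()].
#' @return An n x 3 matrix of world coordinates (cm).
#' @keywords internal
surface_point <- function(s_cm, h_cm, screen) {
  fr <- screen_frame(screen)
  r <- screen$radius_cm
  phi <- s_cm / r
  n <- max(length(phi), length(h_cm))
  phi <- rep_len(phi, n); h <- rep_len(h_cm, n)
  out <- outer(h, fr$a) + r * (outer(cos(phi), fr$m) + outer(sin(phi), fr$e))
  sweep(out, 2, -fr$axis_point, "-")
}

#' Projector pose for the ray-traced optical model
#'
#' Builds a pinhole projector whose central ray climbs the bore at the
#' stated incidence angle and strikes the screen centre. The two quantities
#' the optical report does not state -- throw distance and lens field of
#' view -- are recovered numerically so that the screen's bounding extent on
#' the native raster matches `target_extent_px` (by default the measured
#' 828 x 284 on-screen pixels). The resulting pose is the package's
#' "as-built" projector (matching the measured on-screen extents).
#'
#' @param screen A [screen_geometry()].
#' @param proj A [projection_geometry()]; supplies the native raster, the
#'   incidence angle and the target on-screen extent.
#' @param throw_cm,tan_vhalf Optional explicit throw distance (cm) and
#'   tangent of the vertical half field of view. If either is `NULL` both
#'   are solved from `target_extent_px`.
#' @param target_extent_px Bounding `c(width, height)` of the screen on the
#'   raster used when solving the pose.
#' @return An object of class `ff_pose`: origin, camera basis, tangent
#'   half-FOVs and native raster.
#' @export
projector_pose <- function(screen = screen_geometry(),
                           proj = projection_geometry(screen = screen),
                           throw_cm = NULL, tan_vhalf = NULL,
                           target_extent_px = proj$usable_px) {
  alpha <- deg2rad(proj$incidence_deg)
  v <- c(0, sin(alpha), cos(alpha))
  fr <- screen_frame(screen)
  make_pose <- function(L, tanv) {
    right <- v_unit(v_cross(v, fr$m))
    up <- v_unit(v_cross(right, v))
    structure(
      list(origin = -L * v, forward = v, right = right, up = up,
           tan_vhalf = tanv,
           tan_hhalf = tanv * proj$native_px[1] / proj$native_px[2],
           native_px = proj$native_px,
           throw_cm = L),
      class = "ff_pose")
  }
  if (is.null(throw_cm) || is.null(tan_vhalf)) {
    bnd <- screen_boundary(screen, n = 121)
    objective <- function(p) {
      pose <- make_pose(exp(p[1]), exp(p[2]))
      q <- project_to_raster(bnd, pose)
      ext <- c(diff(range(q[, 1])), diff(range(q[, 2])))
      sum((ext - target_extent_px)^2)
    }
    fit <- stats::optim(c(log(100), log(tan(deg2rad(20)))), objective,
                        control = list(maxit = 5000, reltol = 1e-14))
    if (fit$value > 1) {
      fit <- stats::optim(fit$par, objective,
                          control = list(maxit = 5000, reltol = 1e-14))
    }
    if (fit$value > 1)
      stop("projector pose solve did not reach the target extents")
    throw_cm <- exp(fit$par[1]); tan_vhalf <- exp(fit$par[2])
  }
  make_pose(throw_cm, tan_vhalf)
}

#' @export
print.ff_pose <- function(x, ...) {
  cat(sprintf("Projector pose: throw %.1f cm, FOV %.1f x %.1f deg, raster %d x %d\n",
              x$throw_cm,
              2 * rad2deg(atan(x$tan_hhalf)), 2 * rad2deg(atan(x$tan_vhalf)),
              x$native_px[1], x$native_px[2]))
  invisible(x)
}

# Sample points along the four screen edges (world coords).
screen_boundary <- function(screen, n = 121) {
  half_s <- screen$surface_width_cm / 2
  half_h <- screen$surface_height_cm / 2
  s <- seq(-half_s, half_s, length.out = n)
  h <- seq(-half_h, half_h, length.out = n)
  rbind(surface_point(s, -half_h, screen),
        surface_point(s,  half_h, screen),
        surface_point(-half_s, h, screen),
        surface_point( half_s, h, screen))
}

#' Project world points into the projector raster
#'
#' Raster convention: x in [0, W] left-to-right, y in [0, H] top-to-bottom,
#' principal point at the raster centre.
#'
#' @param pts n x 3 matrix of world points (cm).
#' @param pose An [projector_pose()] object.
#' @return n x 2 matrix of raster coordinates (px).
#' @export
project_to_raster <- function(pts, pose) {
  pts <- rbind(pts)
  w <- sweep(pts, 2, pose$origin)
  z <- as.vector(w %*% pose$forward)
  x <- as.vector(w %*% pose$right)
  y <- as.vector(w %*% pose$up)
  W <- pose$native_px[1]; H <- pose$native_px[2]
  cbind(px = (x / z) / pose$tan_hhalf * (W / 2) + W / 2,
        py = H / 2 - (y / z) / pose$tan_vhalf * (H / 2))
}

#' Trace projector pixels onto the screen surface
#'
#' Casts the ray of each raster pixel from the projector and intersects it
#' with the tilted screen cylinder. Rays that miss the display surface (or
#' run parallel to it) are flagged off-screen; such pixels are set to black
#' at presentation time.
#'
#' @param pixel_xy n x 2 matrix (or length-2 vector) of raster coordinates.
#' @param pose A [projector_pose()].
#' @param screen A [screen_geometry()].
#' @return A data frame with columns `s_cm`, `h_cm` (surface coordinates,
#'   `NA` when off-screen) and logical `on_screen`.
#' @export
trace_projector_ray <- function(pixel_xy, pose, screen = screen_geometry()) {
  q <- rbind(pixel_xy)
  if (any(q[, 1] < 0 | q[, 1] > pose$native_px[1] |
          q[, 2] < 0 | q[, 2] > pose$native_px[2]))
    stop("pixel outside the native raster")
  W <- pose$native_px[1]; H <- pose$native_px[2]
  n <- nrow(q)
  dirs <- matrix(rep(pose$forward, each = n), n) +
    outer((q[, 1] - W / 2) / (W / 2) * pose$tan_hhalf, pose$right) +
    outer((H / 2 - q[, 2]) / (H / 2) * pose$tan_vhalf, pose$up)
  dirs <- dirs / sqrt(rowSums(dirs^2))

  fr <- screen_frame(screen)
  r <- screen$radius_cm
  half_phi <- deg2rad(screen$chord_angle_deg) / 2
  half_h <- screen$surface_height_cm / 2
  w0 <- pose$origin - fr$axis_point

  # quadratic for |perp component| = r along the ray
  d_a <- as.vector(dirs %*% fr$a)
  w_a <- sum(w0 * fr$a)
  dp <- dirs - outer(d_a, fr$a)
  wp <- w0 - w_a * fr$a
  A <- rowSums(dp^2)
  B <- 2 * as.vector(dp %*% wp)
  C <- sum(wp^2) - r^2
  disc <- B^2 - 4 * A * C

  s_cm <- rep(NA_real_, n); h_cm <- rep(NA_real_, n)
  ok <- disc > 0 & A > 1e-12
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    for (root in list((-B[ok] + sq) / (2 * A[ok]),    # far wall first
                      (-B[ok] - sq) / (2 * A[ok]))) {
      P <- sweep(dirs[ok, , drop = FALSE] * root, 2, -pose$origin, "-")
      rel <- sweep(P, 2, fr$axis_point)
      h <- as.vector(rel %*% fr$a)
      rad <- rel - outer(h, fr$a)
      phi <- atan2(as.vector(rad %*% fr$e), as.vector(rad %*% fr$m))
      hit <- root > 0 & abs(phi) <= half_phi + 1e-9 & abs(h) <= half_h + 1e-9
      idx <- which(ok)[hit]
      new <- idx[is.na(s_cm[idx])]
      if (length(new)) {
        sel <- match(new, which(ok))
        s_cm[new] <- r * phi[sel]
        h_cm[new] <- h[sel]
      }
    }
  }
  data.frame(s_cm = s_cm, h_cm = h_cm, on_screen = !is.na(s_cm))
}

#' Bounding on-screen extent of the raster
#'
#' Projects the screen boundary into the raster and returns the bounding
#' width and height in pixels -- the "usable" pixel extent of the display.
#'
#' @inheritParams trace_projector_ray
#' @return Named numeric `c(width, height)`.
#' @export
screen_raster_extent <- function(pose, screen = screen_geometry()) {
  q <- project_to_raster(screen_boundary(screen, n = 241), pose)
  c(width = diff(range(q[, 1])), height = diff(range(q[, 2])))
}

#' Fraction of projector pixels reaching the screen
#'
#' The usable fraction of the raster, computed (as in the optical report)
#' as the product of the marginal on-screen extents: columns reached times
#' rows reached over the native raster, e.g. 828 x 284 / (1024 x 768) ~ 30%.
#'
#' @inheritParams trace_projector_ray
#' @return A fraction in (0, 1].
#' @export
on_screen_fraction <- function(pose, screen = screen_geometry()) {
  ext <- screen_raster_extent(pose, screen)
  unname(prod(ext) / prod(pose$native_px))
}

## canvas <-> surface conventions, shared by the warp and the stimuli.
## Canvas row 0 (top) maps to the near, wider screen edge (h = -H/2);
## canvas x grows with the surface arc coordinate s.
surface_to_canvas <- function(s_cm, h_cm, screen, canvas_px = c(1024, 768)) {
  cbind(x = (s_cm / screen$surface_width_cm + 0.5) * canvas_px[1],
        y = (h_cm / screen$surface_height_cm + 0.5) * canvas_px[2])
}

canvas_to_surface <- function(x, y, screen, canvas_px = c(1024, 768)) {
  cbind(s_cm = (x / canvas_px[1] - 0.5) * screen$surface_width_cm,
        h_cm = (y / canvas_px[2] - 0.5) * screen$surface_height_cm)
}
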