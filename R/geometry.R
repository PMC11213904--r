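#' @keywords internal
"_PACKAGE"

CM_PER_INCH <- 2.54

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Physical geometry of the cylindrical projection screen
#'
#' Describes the custom curved screen mounted inside the scanner bore: a
#' section of a cylinder of radius `radius_cm` spanning `chord_angle_deg`
#' about the cylinder axis, tilted by `tilt_deg` relative to the bore axis.
#' The display surface measures `surface_width_cm` along the arc and
#' `surface_height_cm` along the (tilted) cylinder rulings.
#'
#' @param radius_cm Cylinder radius in cm. Default 11 inches.
#' @param chord_angle_deg Horizontal angular extent of the screen about the
#'   cylinder axis, in degrees.
#' @param tilt_deg Tilt of the screen relative to the bore axis, in degrees.
#' @param surface_width_cm Arc length of the display surface. Defaults to
#'   `radius_cm * chord_angle` (radians); if supplied it must agree with the
#'   arc length to within 1%.
#' @param surface_height_cm Linear height of the display surface in cm.
#' @return An object of class `ff_screen` (a list of the above fields).
#' @examples
#' scr <- screen_geometry()
#' scr$surface_width_cm  # 58.5 cm arc
#' @export
screen_geometry <- function(radius_cm = 11 * CM_PER_INCH,
                            chord_angle_deg = 120,
                            tilt_deg = 10,
                            surface_width_cm = NULL,
                            surface_height_cm = 44) {
  if (!is.numeric(radius_cm) || radius_cm <= 0)
    stop("radius_cm must be positive")
  if (chord_angle_deg <= 0 || chord_angle_deg >= 360)
    stop("chord_angle_deg must be in (0, 360)")
  arc <- arc_length(radius_cm, chord_angle_deg)
  if (is.null(surface_width_cm)) {
    surface_width_cm <- arc
  } else if (abs(surface_width_cm - arc) > 0.01 * arc) {
    stop(sprintf(
      "surface_width_cm (%.2f) inconsistent with arc length %.2f (>1%%)",
      surface_width_cm, arc))
  }
  if (surface_height_cm <= 0) stop("surface_height_cm must be positive")
  structure(
    list(radius_cm = radius_cm,
         chord_angle_deg = chord_angle_deg,
         tilt_deg = tilt_deg,
         surface_width_cm = surface_width_cm,
         surface_height_cm = surface_height_cm),
    class = "ff_screen")
}

#' @export
print.ff_screen <- function(x, ...) {
  cat("Cylindrical screen:\n")
  cat(sprintf("  radius        %.2f cm  (%.2f in)\n",
              x$radius_cm, x$radius_cm / CM_PER_INCH))
  cat(sprintf("  chord angle   %g deg, tilt %g deg\n",
              x$chord_angle_deg, x$tilt_deg))
  cat(sprintf("  surface       %.1f cm (arc) x %.1f cm (linear)\n",
              x$surface_width_cm, x$surface_height_cm))
  invisible(x)
}

#' Viewing geometry of the observer inside the bore
#'
#' The eye sits on the mid-sagittal plane at `eye_to_screen_cm` from the
#' screen centre, measured along the cylinder radius, so its distance from
#' the cylinder axis is `radius_cm - eye_to_screen_cm`. Visual angles are
#' computed monocularly from this single cyclopean point.
#'
#' @param eye_to_screen_cm Eye-to-screen distance in cm (head size and
#'   cushion dependent; typical range 13.5-16.5, nominal 15).
#' @param screen A [screen_geometry()] object.
#' @return An object of class `ff_view`.
#' @export
viewing_geometry <- function(eye_to_screen_cm = 15, screen = screen_geometry()) {
  if (eye_to_screen_cm <= 0 || eye_to_screen_cm >= screen$radius_cm)
    stop("eye_to_screen_cm must lie strictly between 0 and the cylinder radius")
  structure(
    list(eye_to_screen_cm = eye_to_screen_cm,
         eye_offset_cm = screen$radius_cm - eye_to_screen_cm,
         screen = screen),
    class = "ff_view")
}

#' @export
print.ff_view <- function(x, ...) {
  cat(sprintf("Viewing geometry: eye %.1f cm from screen centre (%.2f cm off-axis)\n",
              x$eye_to_screen_cm, x$eye_offset_cm))
  cat(sprintf("  angular extent %.1f deg (w) x %.1f deg (h)\n",
              cylinder_angular_width(x$screen, x),
              cylinder_angular_height(x$screen, x)))
  invisible(x)
}

#' Projector raster and incidence geometry
#'
#' @param native_px Native projector raster, `c(width, height)` in pixels.
#' @param incidence_deg Grazing angle of the projection rays onto the (untilted)
#'   bore wall, in degrees.
#' @param screen A [screen_geometry()] object; its tilt adds to the incidence
#'   to give the effective incidence on the tilted screen.
#' @param usable_px On-screen pixel extent `c(width, height)`: the bounding
#'   columns/rows of the projector raster that land on the display surface.
#' @return An object of class `ff_projection`.
#' @export
projection_geometry <- function(native_px = c(1024, 768),
                                incidence_deg = 18.5,
                                screen = screen_geometry(),
                                usable_px = c(828, 284)) {
  if (any(usable_px > native_px))
    stop("usable_px cannot exceed native_px")
  structure(
    list(native_px = as.integer(native_px),
         incidence_deg = incidence_deg,
         effective_incidence_deg = incidence_deg + screen$tilt_deg,
         usable_px = as.integer(usable_px),
         screen = screen),
    class = "ff_projection")
}

#' @export
print.ff_projection <- function(x, ...) {
  cat(sprintf("Projector: native %d x %d px, usable %d x %d px\n",
              x$native_px[1], x$native_px[2], x$usable_px[1], x$usable_px[2]))
  cat(sprintf("  incidence %.1f deg on bore wall, %.1f deg on tilted screen\n",
              x$incidence_deg, x$effective_incidence_deg))
  invisible(x)
}

#' Arc length of a circular section
#'
#' @param radius_cm Circle radius (cm).
#' @param chord_angle_deg Subtended angle at the centre, degrees.
#' @return Arc length in cm, `radius * angle` (radians).
#' @examples
#' arc_length(11 * 2.54, 120)  # 58.5 cm display surface
#' @export
arc_length <- function(radius_cm, chord_angle_deg) {
  if (any(radius_cm <= 0)) stop("radius_cm must be positive")
  if (any(chord_angle_deg < 0) || any(chord_angle_deg > 360))
    stop("chord_angle_deg must be in [0, 360]")
  radius_cm * deg2rad(chord_angle_deg)
}

#' Horizontal field of view of a perspective camera
#'
#' For a pinhole camera with vertical field of view `vfov_deg` and pixel
#' aspect ratio `aspect` (width / height), the horizontal field of view is
#' `2 * atan(aspect * tan(vfov/2))`. Used to pick the rendering camera for
#' full-field views: a 105 degree vertical FOV at 4:3 gives 120.2 degrees
#' horizontally, matching the 120 degree chord of the physical screen.
#'
#' @param vfov_deg Vertical field of view in degrees, in (0, 180).
#' @param aspect Width-to-height aspect ratio, > 0.
#' @return Horizontal field of view in degrees.
#' @examples
#' horizontal_fov_from_vertical(105, 4 / 3)  # 120.2
#' @export
horizontal_fov_from_vertical <- function(vfov_deg, aspect) {
  if (any(vfov_deg <= 0) || any(vfov_deg >= 180))
    stop("vfov_deg must be in (0, 180)")
  if (any(aspect <= 0)) stop("aspect must be positive")
  rad2deg(2 * atan(aspect * tan(deg2rad(vfov_deg) / 2)))
}

#' Horizontal visual angle of the cylindrical screen
#'
#' Angle subtended at the eye by the screen's horizontal extent. With the
#' eye displaced `radius - d` from the cylinder axis towards the screen
#' centre, the half-angle to the screen edge (at half the chord angle
#' `theta`) is `atan2(r sin(theta/2), r cos(theta/2) - (r - d))`. The width
#' grows as the eye approaches the screen; on the axis it equals the chord
#' angle itself.
#'
#' @param screen A [screen_geometry()].
#' @param view A [viewing_geometry()].
#' @return Visual angle in degrees.
#' @examples
#' cylinder_angular_width(screen_geometry(), viewing_geometry(15))  # ~175
#' @export
cylinder_angular_width <- function(screen = screen_geometry(),
                                   view = viewing_geometry(screen = screen)) {
  r <- screen$radius_cm
  half <- deg2rad(screen$chord_angle_deg) / 2
  k <- view$eye_offset_cm
  if (k < 0 || k >= r) stop("eye must lie inside the cylinder")
  rad2deg(2 * atan2(r * sin(half), r * cos(half) - k))
}

#' Vertical visual angle of the screen
#'
#' Treats the vertical section of the display as a chord of height
#' `surface_height_cm` centred on the line of sight. For a centred chord the
#' subtended angle is independent of the chord's tilt (both endpoints are
#' equidistant from the eye), giving `2 * atan((H/2) / d)`. This is an
#' approximation insofar as the true eye position may sit below the screen's
#' vertical midline; it reproduces the measured 106-117 degree range over
#' viewing distances 16.5-13.5 cm.
#'
#' @inheritParams cylinder_angular_width
#' @return Visual angle in degrees.
#' @export
cylinder_angular_height <- function(screen = screen_geometry(),
                                    view = viewing_geometry(screen = screen)) {
  d <- view$eye_to_screen_cm
  if (d <= 0) stop("eye_to_screen_cm must be positive")
  rad2deg(2 * atan((screen$surface_height_cm / 2) / d))
}

#' Pixel density
#'
#' @param pixels Extent in pixels.
#' @param degrees Corresponding visual angle in degrees (> 0).
#' @return Pixels per degree.
#' @examples
#' pixels_per_degree(284, 117)  # ~2.4 px/deg vertical
#' @export
pixels_per_degree <- function(pixels, degrees) {
  if (any(degrees <= 0)) stop("degrees must be positive")
  pixels / degrees
}

#' Resolution upgrade factor between projector generations
#'
#' Ratio of vertical rasters, e.g. 2400 / 768 = 3.125 when moving from an
#' XGA projector to a 4k projector at the same 4:3 aspect.
#'
#' @param new_vertical_px,old_vertical_px Vertical raster sizes in pixels.
#' @return Dimensionless scale factor.
#' @export
resolution_scale_factor <- function(new_vertical_px = 2400, old_vertical_px = 768) {
  if (any(old_vertical_px <= 0) || any(new_vertical_px <= 0))
    stop("raster sizes must be positive")
  new_vertical_px / old_vertical_px
}

## --- eccentricity <-> surface arc <-> canvas pixels ------------------------

# Surface arc-length coordinate s (cm from screen centre, along the
# circumference) of the point seen at eccentricity ecc (radians) from the
# line of sight, for an eye offset k from the axis:
#   tan(ecc) = r sin(phi) / (r cos(phi) - k),  s = r * phi
# which inverts in closed form as phi = ecc - asin((k/r) sin ecc).
ecc_to_arc_cm <- function(ecc_deg, view) {
  r <- view$screen$radius_cm
  k <- view$eye_offset_cm
  ecc <- deg2rad(ecc_deg)
  phi <- ecc - asin(pmin(1, pmax(-1, (k / r) * sin(ecc))))
  r * phi
}

arc_cm_to_ecc <- function(s_cm, view) {
  r <- view$screen$radius_cm
  k <- view$eye_offset_cm
  phi <- s_cm / r
  rad2deg(atan2(r * sin(phi), r * cos(phi) - k))
}

#' Convert visual eccentricity to canvas pixel radius
#'
#' The source canvas is "wallpapered" onto the display surface, so canvas
#' position is proportional to surface arc length. A given eccentricity is
#' first converted to arc length via the viewing geometry (closed form on
#' the horizontal meridian), then scaled by the canvas pixel pitch. The
#' canvas is isotropic: 1024 px / 58.5 cm horizontally matches
#' 768 px / 44 cm vertically to within 0.3%, so one radius serves all
#' directions.
#'
#' @param ecc_deg Eccentricity in visual degrees (0 at the centre of gaze).
#' @param view A [viewing_geometry()].
#' @param canvas_width_px Width in pixels of the raster the radius refers
#'   to: 1024 for the source canvas (default), 828 for the projector's
#'   active on-screen region.
#' @return Radius in pixels on the given canvas.
#' @seealso [radius_px_to_eccentricity()] for the inverse.
#' @export
eccentricity_to_radius_px <- function(ecc_deg, view = viewing_geometry(),
                                      canvas_width_px = 1024) {
  if (any(ecc_deg < 0)) stop("eccentricity must be non-negative")
  max_ecc <- cylinder_angular_width(view$screen, view) / 2
  if (any(ecc_deg > max_ecc + 1e-9))
    stop(sprintf("eccentricity beyond screen edge (%.1f deg)", max_ecc))
  s <- ecc_to_arc_cm(ecc_deg, view)
  s * canvas_width_px / view$screen$surface_width_cm
}

#' Convert canvas pixel radius to visual eccentricity
#'
#' Inverse of [eccentricity_to_radius_px()].
#'
#' @param radius_px Radius in pixels on the given canvas.
#' @inheritParams eccentricity_to_radius_px
#' @return Eccentricity in visual degrees.
#' @export
radius_px_to_eccentricity <- function(radius_px, view = viewing_geometry(),
                                      canvas_width_px = 1024) {
  if (any(radius_px < 0)) stop("radius must be non-negative")
  s <- radius_px * view$screen$surface_width_cm / canvas_width_px
  arc_cm_to_ecc(s, view)
}

#' Summarise the optical configuration
#'
#' Prints (and returns invisibly) the angular extents and pixel densities of
#' the display for a set of viewing distances, as used to report the
#' stimulus size: width 168-182 deg and height 106-117 deg over 16.5-13.5 cm,
#' with 4.6-4.9 px/deg horizontally and 2.4-2.7 px/deg vertically.
#'
#' @param screen A [screen_geometry()].
#' @param proj A [projection_geometry()].
#' @param distances_cm Viewing distances to tabulate.
#' @return Invisibly, a data frame with one row per distance.
#' @export
geometry_report <- function(screen = screen_geometry(),
                            proj = projection_geometry(screen = screen),
                            distances_cm = c(13.5, 15, 16.5)) {
  rows <- lapply(distances_cm, function(d) {
    v <- viewing_geometry(d, screen)
    w <- cylinder_angular_width(screen, v)
    h <- cylinder_angular_height(screen, v)
    data.frame(distance_cm = d,
               width_deg = w,
               height_deg = h,
               ppd_x = pixels_per_degree(proj$usable_px[1], w),
               ppd_y = pixels_per_degree(proj$usable_px[2], h))
  })
  out <- do.call(rbind, rows)
  cat(sprintf("Screen: %.1f cm arc x %.1f cm, radius %.2f cm, chord %g deg, tilt %g deg\n",
              screen$surface_width_cm, screen$surface_height_cm,
              screen$radius_cm, screen$chord_angle_deg, screen$tilt_deg))
  cat(sprintf("Projector: %d x %d native, %d x %d on screen (%.0f%% of pixels)\n",
              proj$native_px[1], proj$native_px[2],
              proj$usable_px[1], proj$usable_px[2],
              100 * prod(proj$usable_px) / prod(proj$native_px)))
  for (i in seq_len(nrow(out))) {
    cat(sprintf("  d = %4.1f cm: %5.1f x %5.1f deg, %.1f x %.1f px/deg\n",
                out$distance_cm[i], out$width_deg[i], out$height_deg[i],
                out$ppd_x[i], out$ppd_y[i]))
  }
  invisible(out)
}

#' Read or write a geometry configuration file
#'
#' Round-trips the screen / viewing / projection parameters through a YAML
#' (or JSON) file so a scanning site can keep its measured values under
#' version control.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or `.json`).
#' @param screen,view,proj Geometry objects to write.
#' @return `read_geometry_config` returns a list with elements `screen`,
#'   `view`, `proj`.
#' @export
write_geometry_config <- function(path, screen = screen_geometry(),
                                  view = viewing_geometry(screen = screen),
                                  proj = projection_geometry(screen = screen)) {
  cfg <- list(
    screen = screen[c("radius_cm", "chord_angle_deg", "tilt_deg",
                      "surface_width_cm", "surface_height_cm")],
    viewing = list(eye_to_screen_cm = view$eye_to_screen_cm),
    projection = list(native_px = proj$native_px,
                      incidence_deg = proj$incidence_deg,
                      usable_px = proj$usable_px))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @rdname write_geometry_config
#' @export
read_geometry_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  screen <- do.call(screen_geometry, cfg$screen)
  view <- viewing_geometry(cfg$viewing$eye_to_screen_cm, screen)
  proj <- projection_geometry(unlist(cfg$projection$native_px),
                              cfg$projection$incidence_deg,
                              screen,
                              unlist(cfg$projection$usable_px))
  list(screen = screen, view = view, proj = proj)
}
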