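## Calibration-driven warp between the rectangular source canvas and the
## curved on-screen region of the projector raster.
##
## Calibration: an operator marks raster coordinates of known positions
## along the screen outline -- at minimum the ends and midpoint of the top
## and bottom edges, optionally more points and a middle (half-height) arc.
## Each edge is summarised two ways: a fitted circle (the arc model used
## for validation and the active region) and an interpolating curve through
## the labelled points (used for the mapping itself). Vertically the screen
## is ruled by straight lines, so the exact map between surface height and
## raster position along a ruling is 1-D projective; with a middle arc the
## package fits that projective map per column, otherwise it falls back to
## linear interpolation between the two edges.

#' Labelled calibration points along the screen outline
#'
#' @param top,bottom,middle Data frames (or 2/3-column matrices) with
#'   columns `px`, `py` and optionally `s_frac`, the known normalised arc
#'   position of each point along its edge (0 = left end, 1 = right end).
#'   When `s_frac` is missing the points are assumed equally spaced. `top`
#'   is the screen edge nearer the projector (it appears wider on the
#'   raster and receives the top row of the source image); `middle`
#'   (half-height outline) is optional but enables the projective vertical
#'   map.
#' @return An object of class `ff_calibration`.
#' @export
calibration_points <- function(top, bottom, middle = NULL) {
  tidy <- function(p, name) {
    p <- as.data.frame(p)
    if (ncol(p) == 2) names(p) <- c("px", "py")
    if (is.null(p$s_frac)) p$s_frac <- seq(0, 1, length.out = nrow(p))
    if (nrow(p) < 3) stop(name, " edge needs at least 3 points")
    if (anyDuplicated(round(p[c("px", "py")], 9)))
      stop(name, " edge has duplicate points")
    if (min(p$s_frac) > 0 || max(p$s_frac) < 1)
      stop(name, " edge must include both endpoints (s_frac 0 and 1)")
    p[order(p$s_frac), c("px", "py", "s_frac")]
  }
  structure(list(top = tidy(top, "top"),
                 bottom = tidy(bottom, "bottom"),
                 middle = if (!is.null(middle)) tidy(middle, "middle")),
            class = "ff_calibration")
}

#' @export
print.ff_calibration <- function(x, ...) {
  cat(sprintf("Screen calibration: %d top + %d bottom%s points\n",
              nrow(x$top), nrow(x$bottom),
              if (!is.null(x$middle)) sprintf(" + %d middle", nrow(x$middle)) else ""))
  invisible(x)
}

# Least-squares circle (Kasa fit; exact through 3 points).
fit_circle <- function(px, py) {
  A <- cbind(2 * px, 2 * py, 1)
  if (qr(A)$rank < 3) stop("degenerate arc: calibration points are collinear")
  sol <- qr.solve(A, px^2 + py^2)
  R2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (R2 <= 0) stop("degenerate arc fit")
  list(cx = sol[1], cy = sol[2], R = sqrt(R2),
       rms = sqrt(mean((sqrt((px - sol[1])^2 + (py - sol[2])^2) - sqrt(R2))^2)))
}

# Interpolating curve through an edge's labelled points: raster position as
# a (componentwise) cubic spline in the arc fraction. Forsythe-Malcolm-Moler
# end conditions (exact cubics through the end quadruples) keep the
# endpoint error small on strongly curved projected edges; with ~9 points
# per edge the curve tracks the true projection to < 0.2 px.
edge_curve <- function(edge) {
  list(fx = stats::splinefun(edge$s_frac, edge$px, method = "fmm"),
       fy = stats::splinefun(edge$s_frac, edge$py, method = "fmm"))
}

#' Fit the warp model from calibration points
#'
#' Fits a circle through each measured edge (exactly for 3 points, least
#' squares beyond) and builds the interpolating edge curves that carry the
#' mapping. Fails on collinear points and on calibrations whose edges
#' cross inside the active span.
#'
#' @param points An [calibration_points()] object.
#' @param source_px Source canvas size `c(width, height)` in pixels.
#' @param native_px Projector raster size `c(width, height)` in pixels.
#' @return An object of class `ff_warp_model` with elements `arcs` (fitted
#'   circles with residuals), `curves`, `active_region`
#'   (`c(width, height)` plus offsets) and the raster sizes.
#' @export
fit_calibration <- function(points, source_px = c(1024, 768),
                            native_px = c(1024, 768)) {
  stopifnot(inherits(points, "ff_calibration"))
  arcs <- lapply(points[!vapply(points, is.null, TRUE)],
                 function(e) fit_circle(e$px, e$py))
  curves <- lapply(points[!vapply(points, is.null, TRUE)], edge_curve)
  model <- structure(
    list(points = points, arcs = arcs, curves = curves,
         has_middle = !is.null(points$middle),
         source_px = as.integer(source_px),
         native_px = as.integer(native_px)),
    class = "ff_warp_model")

  # edges must not cross: top curve strictly above bottom curve throughout
  xi <- seq(0, 1, length.out = 101)
  tq <- warp_forward(model, xi, rep(0, 101))
  bq <- warp_forward(model, xi, rep(1, 101))
  gap <- (bq[, 2] - tq[, 2])
  if (any(gap <= 0)) stop("invalid calibration: top and bottom arcs cross")
  bnd <- rbind(tq, bq,
               warp_forward(model, rep(0, 51), seq(0, 1, length.out = 51)),
               warp_forward(model, rep(1, 51), seq(0, 1, length.out = 51)))
  model$active_region <- c(width = diff(range(bnd[, 1])),
                           height = diff(range(bnd[, 2])),
                           x0 = min(bnd[, 1]), y0 = min(bnd[, 2]))
  model
}

#' @export
print.ff_warp_model <- function(x, ...) {
  cat(sprintf("Warp model: source %d x %d -> active region %.0f x %.0f px (raster %d x %d)\n",
              x$source_px[1], x$source_px[2],
              x$active_region["width"], x$active_region["height"],
              x$native_px[1], x$native_px[2]))
  cat(sprintf("  arc radii: top %.0f px, bottom %.0f px%s; fit RMS %.2g px\n",
              x$arcs$top$R, x$arcs$bottom$R,
              if (x$has_middle) sprintf(", middle %.0f px", x$arcs$middle$R) else "",
              max(vapply(x$arcs, `[[`, 0, "rms"))))
  cat(sprintf("  vertical interpolation: %s\n",
              if (x$has_middle) "projective (middle arc)" else "linear"))
  invisible(x)
}

# Forward map: normalised source coordinates (xi, eta) in [0,1]^2 -> raster
# position. xi follows the labelled arc fraction; eta moves from the top
# edge (eta = 0) to the bottom edge along the (straight) ruling, with a
# per-column projective parameter when a middle arc is available.
warp_forward <- function(model, xi, eta) {
  ct <- model$curves$top; cb <- model$curves$bottom
  Tx <- ct$fx(xi); Ty <- ct$fy(xi)
  Bx <- cb$fx(xi); By <- cb$fy(xi)
  if (model$has_middle) {
    cm <- model$curves$middle
    Mx <- cm$fx(xi); My <- cm$fy(xi)
    dx <- Bx - Tx; dy <- By - Ty
    tm <- ((Mx - Tx) * dx + (My - Ty) * dy) / (dx^2 + dy^2)
    tm <- pmin(0.95, pmax(0.05, tm))
    # 1-D projective map fixed by (0,0), (1/2, tm), (1,1)
    cc <- (2 * tm - 1) / (1 - tm)
    t <- (cc + 1) * eta / (cc * eta + 1)
  } else {
    t <- eta
  }
  cbind(x = Tx + t * (Bx - Tx), y = Ty + t * (By - Ty))
}

#' Build the per-pixel warp map
#'
#' Inverts the calibrated forward map over the projector raster: for every
#' output pixel inside the active region the map stores the continuous
#' source-canvas coordinate to sample, along with an on-screen mask.
#' Inversion seeds each pixel from a dense forward-evaluated grid and
#' polishes with two Newton steps, leaving sub-0.01 px inversion error.
#'
#' @param model An [fit_calibration()] model.
#' @param grid_n Forward seeding grid resolution `c(n_xi, n_eta)`.
#' @return An object of class `ff_warp_map`: matrices `map_x`, `map_y`
#'   (source px, `NA` off-screen) of raster size, logical `mask`, and the
#'   model.
#' @export
build_warp_map <- function(model, grid_n = c(1400, 500)) {
  W <- model$native_px[1]; H <- model$native_px[2]
  xi_g <- seq(0, 1, length.out = grid_n[1])
  eta_g <- seq(0, 1, length.out = grid_n[2])
  g <- expand.grid(xi = xi_g, eta = eta_g)
  q <- warp_forward(model, g$xi, g$eta)

  # seed: nearest forward sample per output pixel
  cx <- pmin(W, pmax(1, ceiling(q[, 1])))
  cy <- pmin(H, pmax(1, ceiling(q[, 2])))
  cell <- (cx - 1) * H + cy
  seed_xi <- rep(NA_real_, W * H); seed_eta <- rep(NA_real_, W * H)
  ord <- order(cell)                      # last write wins; any sample is fine
  seed_xi[cell[ord]] <- g$xi[ord]
  seed_eta[cell[ord]] <- g$eta[ord]
  filled <- which(!is.na(seed_xi))
  if (!length(filled)) stop("empty active region")

  # fill small gaps from the 4-neighbourhood (a few dilation passes)
  sx <- matrix(seed_xi, H, W); se <- matrix(seed_eta, H, W)
  for (pass in 1:3) {
    holes <- is.na(sx)
    if (!any(holes)) break
    for (shift in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb_x <- shift_matrix(sx, shift[1], shift[2])
      nb_e <- shift_matrix(se, shift[1], shift[2])
      take <- is.na(sx) & !is.na(nb_x)
      sx[take] <- nb_x[take]; se[take] <- nb_e[take]
    }
  }

  idx <- which(!is.na(sx))
  xi <- sx[idx]; eta <- se[idx]
  px <- ((idx - 1) %/% H) + 0.5           # pixel centres, raster coords
  py <- ((idx - 1) %% H) + 0.5
  hstep <- 1e-4
  for (iter in 1:3) {
    f0 <- warp_forward(model, xi, eta)
    rx <- f0[, 1] - px; ry <- f0[, 2] - py
    fx <- warp_forward(model, xi + hstep, eta)
    fe <- warp_forward(model, xi, eta + hstep)
    j11 <- (fx[, 1] - f0[, 1]) / hstep; j21 <- (fx[, 2] - f0[, 2]) / hstep
    j12 <- (fe[, 1] - f0[, 1]) / hstep; j22 <- (fe[, 2] - f0[, 2]) / hstep
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-12] <- NA
    xi <- xi - (j22 * rx - j12 * ry) / det
    eta <- eta - (-j21 * rx + j11 * ry) / det
    xi[is.na(xi)] <- NA; eta[is.na(eta)] <- NA
  }
  fin <- warp_forward(model, pmin(1, pmax(0, xi)), pmin(1, pmax(0, eta)))
  err <- sqrt((fin[, 1] - px)^2 + (fin[, 2] - py)^2)
  tol <- 1e-6
  inside <- !is.na(xi) & xi >= -tol & xi <= 1 + tol &
    !is.na(eta) & eta >= -tol & eta <= 1 + tol & err < 0.05

  map_x <- matrix(NA_real_, H, W); map_y <- matrix(NA_real_, H, W)
  map_x[idx[inside]] <- pmin(1, pmax(0, xi[inside])) * model$source_px[1]
  map_y[idx[inside]] <- pmin(1, pmax(0, eta[inside])) * model$source_px[2]
  structure(list(map_x = map_x, map_y = map_y,
                 mask = !is.na(map_x), model = model),
            class = "ff_warp_map")
}

shift_matrix <- function(m, dr, dc) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' @export
print.ff_warp_map <- function(x, ...) {
  cat(sprintf("Warp map: %d x %d raster, %d on-screen pixels (%.1f%%)\n",
              ncol(x$map_x), nrow(x$map_x), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

## --- image resampling -------------------------------------------------------

# Bilinear / nearest sampling of an image (matrix or H x W x C array) at
# continuous positions (x, y) in [0, W] x [0, H]; pixel centres at k - 0.5.
sample_image <- function(img, x, y, interpolation = "bilinear", background = 0) {
  dm <- dim(img)
  H <- dm[1]; W <- dm[2]; C <- if (length(dm) == 3) dm[3] else 1
  out <- matrix(background, length(x), C)
  ok <- !is.na(x) & !is.na(y)
  if (interpolation == "nearest") {
    cx <- pmin(W, pmax(1, ceiling(x[ok])))
    cy <- pmin(H, pmax(1, ceiling(y[ok])))
    for (ch in seq_len(C)) {
      plane <- if (C == 1 && length(dm) == 2) img else img[, , ch]
      out[ok, ch] <- plane[(cx - 1) * H + cy]
    }
  } else {
    gx <- pmin(W - 0.5, pmax(0.5, x[ok])) - 0.5
    gy <- pmin(H - 0.5, pmax(0.5, y[ok])) - 0.5
    x0 <- floor(gx); y0 <- floor(gy)
    fx <- gx - x0; fy <- gy - y0
    x0 <- pmin(W - 2, x0); y0 <- pmin(H - 2, y0)
    i00 <- x0 * H + y0 + 1
    for (ch in seq_len(C)) {
      plane <- if (C == 1 && length(dm) == 2) img else img[, , ch]
      v <- plane[i00] * (1 - fx) * (1 - fy) +
        plane[i00 + H] * fx * (1 - fy) +
        plane[i00 + 1] * (1 - fx) * fy +
        plane[i00 + H + 1] * fx * fy
      out[ok, ch] <- v
    }
  }
  out
}

#' Warp a source image into the projector raster
#'
#' Resamples the source canvas through the calibrated map so that, once
#' projected, the image drapes over the curved screen with its aspect ratio
#' preserved on the display surface. Raster pixels that do not reach the
#' screen are set to `background` (black).
#'
#' @param img Source image: numeric matrix (grayscale) or H x W x C array,
#'   values in `[0, 1]`, sized to the model's source canvas.
#' @param map An [build_warp_map()] map.
#' @param interpolation `"bilinear"` (default) or `"nearest"` (for masks
#'   and checkerboards, avoiding gray halos).
#' @param background Value for off-screen pixels.
#' @return Warped image at the native raster size, same channel count.
#' @export
warp_image <- function(img, map, interpolation = c("bilinear", "nearest"),
                       background = 0) {
  interpolation <- match.arg(interpolation)
  dm <- dim(img)
  if (is.null(dm) || length(dm) < 2) stop("img must be a matrix or array")
  if (length(dm) == 3 && !dm[3] %in% c(1, 3))
    stop("img must have 1 or 3 channels")
  src <- map$model$source_px
  if (dm[2] != src[1] || dm[1] != src[2])
    stop(sprintf("img is %d x %d but the model's source canvas is %d x %d",
                 dm[2], dm[1], src[1], src[2]))
  H <- nrow(map$map_x); W <- ncol(map$map_x)
  C <- if (length(dm) == 3) dm[3] else 1
  vals <- sample_image(img, as.vector(map$map_x), as.vector(map$map_y),
                       interpolation, background)
  vals[!as.vector(map$mask), ] <- background
  if (C == 1) matrix(vals[, 1], H, W) else array(vals, c(H, W, C))
}

#' Unwarp a projected image back onto the source canvas
#'
#' Approximate inverse of [warp_image()] for verification and preview:
#' samples the warped raster at the forward-mapped position of every source
#' pixel. Source pixels whose raster position fell off-screen keep the
#' `background` value.
#'
#' @param warped Image at the native raster size.
#' @param map An [build_warp_map()] map.
#' @inheritParams warp_image
#' @return Image at the source canvas size.
#' @export
unwarp_image <- function(warped, map, interpolation = c("bilinear", "nearest"),
                         background = 0) {
  interpolation <- match.arg(interpolation)
  model <- map$model
  dm <- dim(warped)
  if (dm[1] != model$native_px[2] || dm[2] != model$native_px[1])
    stop("warped image does not match the native raster")
  sw <- model$source_px[1]; sh <- model$source_px[2]
  g <- expand.grid(y = seq_len(sh) - 0.5, x = seq_len(sw) - 0.5)
  q <- warp_forward(model, g$x / sw, g$y / sh)
  C <- if (length(dm) == 3) dm[3] else 1
  vals <- sample_image(warped, q[, 1], q[, 2], interpolation, background)
  if (C == 1) matrix(vals[, 1], sh, sw) else array(vals, c(sh, sw, C))
}

#' Active on-screen region of a warp model
#'
#' @param model An [fit_calibration()] model.
#' @return Named numeric: bounding `width`/`height` in raster pixels and
#'   the region's top-left offset `x0`/`y0`.
#' @export
active_region <- function(model) model$active_region
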