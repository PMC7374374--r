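#' Synthetic segmentation fixtures
#'
#' Generators for the synthetic study shapes: ellipses (optionally partially
#' occluded or with a missing wedge), fish silhouettes varying in size and
#' bend, and banana-shaped blobs with adjustable atrophy and weak
#' (gradient-suppressed) boundary segments. Each fixture pairs a grayscale
#' image in `[0, 1]` with a strictly binary ground-truth mask on the same
#' canvas (default 100 x 100). Occlusion, missing parts and edge suppression
#' corrupt the image only: the truth mask always encodes the full shape.
#'
#' @name synthetic_fixtures
NULL

FG_INTENSITY <- 0.9
BG_INTENSITY <- 0.1

new_fixture <- function(image, truth, kind, params, seed) {
  structure(
    list(image = image, truth = truth, kind = kind,
         params = params, seed = seed),
    class = "lbseg_fixture"
  )
}

#' @export
print.lbseg_fixture <- function(x, ...) {
  cat(sprintf("<lbseg_fixture> kind=%s  %dx%d  foreground=%d px  seed=%s\n",
              x$kind, nrow(x$image), ncol(x$image), sum(x$truth),
              format(x$seed)))
  invisible(x)
}

finish_image <- function(img, noise_sd, seed) {
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img)))
  }
  pmin(pmax(img, 0), 1)
}

#' Ellipse fixture, optionally occluded or with a missing wedge
#'
#' Rasterizes an ellipse at pixel centers: a pixel belongs to the truth mask
#' iff its center `(x, y)` satisfies the ellipse inequality
#' `(x'/a)^2 + (y'/b)^2 <= 1` in the rotated frame. In `"occluded"` mode an
#' opaque gray bar crossing the upper boundary is painted over the image; in
#' `"missing"` mode a wedge of the ellipse is erased to background
#' intensity. The truth mask is the full ellipse in every mode.
#'
#' @param center ellipse center `(cx, cy)` in pixel coordinates.
#' @param axes semi-axes `(a, b)` in pixels, both positive.
#' @param angle ellipse orientation in degrees (counter-clockwise).
#' @param mode one of `"clean"`, `"occluded"`, `"missing"`.
#' @param noise_sd standard deviation of additive Gaussian noise, applied
#'   before clipping to `[0, 1]`.
#' @param seed integer RNG seed; identical arguments reproduce the fixture
#'   bit-exactly.
#' @param size canvas dimensions `(h, w)`.
#' @param occ_width,occ_value width (px) and intensity of the occluding bar.
#' @param wedge_deg angular span (degrees) of the erased wedge.
#' @return an object of class `lbseg_fixture` with elements `image`,
#'   `truth`, `kind`, `params`, `seed`.
#' @examples
#' fx <- make_ellipse(axes = c(20, 12), seed = 1)
#' sum(fx$truth)  # ~ pi * 20 * 12
#' @export
make_ellipse <- function(center = c(50, 50), axes = c(20, 12), angle = 0,
                         mode = c("clean", "occluded", "missing"),
                         noise_sd = 0.03, seed = 1, size = c(100, 100),
                         occ_width = 10, occ_value = 0.5, wedge_deg = 70) {
  mode <- match.arg(mode)
  stopifnot(length(axes) == 2, length(center) == 2)
  if (any(axes <= 0)) stop("ellipse semi-axes must be positive")
  h <- size[1]; w <- size[2]
  th <- angle * pi / 180
  # rotated bounding half-widths of the ellipse
  hx <- sqrt((axes[1] * cos(th))^2 + (axes[2] * sin(th))^2)
  hy <- sqrt((axes[1] * sin(th))^2 + (axes[2] * cos(th))^2)
  if (center[1] - hx < 0 || center[1] + hx > w - 1 ||
      center[2] - hy < 0 || center[2] + hy > h - 1)
    stop(sprintf(
      "ellipse exceeds the %dx%d canvas (x extent [%.1f, %.1f], y extent [%.1f, %.1f])",
      h, w, center[1] - hx, center[1] + hx, center[2] - hy, center[2] + hy))
  g <- pixel_grid(h, w)
  dx <- g$x - center[1]; dy <- g$y - center[2]
  # counter-clockwise in the y-up sense (matrix rows run down): see package docs
  u <- cos(th) * dx - sin(th) * dy
  v <- sin(th) * dx + cos(th) * dy
  truth <- matrix(as.numeric((u / axes[1])^2 + (v / axes[2])^2 <= 1), h, w)
  img <- BG_INTENSITY + (FG_INTENSITY - BG_INTENSITY) * truth
  if (mode == "occluded") {
    bar <- abs(g$x - center[1]) <= occ_width / 2 & g$y <= center[2]
    img[bar] <- occ_value
  } else if (mode == "missing") {
    ang <- atan2(dy, dx)
    wedge <- truth == 1 & abs(ang) <= (wedge_deg / 2) * pi / 180
    img[wedge] <- BG_INTENSITY
  }
  img <- finish_image(img, noise_sd, seed)
  new_fixture(img, truth, paste0("ellipse",
                                 if (mode != "clean") paste0("_", mode)),
              list(center = center, axes = axes, angle = angle, mode = mode,
                   noise_sd = noise_sd, occ_width = occ_width,
                   occ_value = occ_value, wedge_deg = wedge_deg), seed)
}

#' Fish-silhouette fixture
#'
#' A fish as the union of a body ellipse and a triangular tail, scaled by
#' `scale` and vertically sheared by `bend` (shear factor `dy/dx` applied
#' about the body center, so `bend = 0` gives a silhouette mirror-symmetric
#' about its horizontal axis up to rasterization).
#'
#' @param scale overall similarity scale, in `[0.5, 1.5]`.
#' @param bend vertical shear factor; `0` is a straight fish.
#' @param seed integer RNG seed.
#' @param noise_sd additive Gaussian noise sd.
#' @param size canvas dimensions `(h, w)`.
#' @return an `lbseg_fixture`.
#' @export
make_fish <- function(scale = 1, bend = 0, seed = 1, noise_sd = 0.03,
                      size = c(100, 100)) {
  if (scale < 0.5 || scale > 1.5)
    stop("`scale` must lie in [0.5, 1.5]")
  h <- size[1]; w <- size[2]
  bx <- 44; by <- 50
  a <- 20 * scale; b <- 11 * scale
  g <- pixel_grid(h, w)
  # undo the shear before testing set membership
  x <- g$x
  y <- g$y - bend * (g$x - bx)
  body <- ((x - bx) / a)^2 + ((y - by) / b)^2 <= 1
  x0 <- bx + 0.7 * a; x1 <- bx + 1.5 * a
  tail <- x >= x0 & x <= x1 &
    abs(y - by) <= 0.6 * b * (x - x0) / (0.8 * a)
  truth <- matrix(as.numeric(body | tail), h, w)
  idx <- which(truth == 1, arr.ind = TRUE)
  if (any(idx[, 1] %in% c(1, h)) || any(idx[, 2] %in% c(1, w)))
    stop("fish silhouette is clipped by the canvas; reduce `scale` or `bend`")
  img <- finish_image(BG_INTENSITY + (FG_INTENSITY - BG_INTENSITY) * truth,
                      noise_sd, seed)
  new_fixture(img, truth, "fish",
              list(scale = scale, bend = bend, noise_sd = noise_sd), seed)
}

#' Banana-shaped blob fixture with atrophy and weak edges
#'
#' A curved blob (a thickened circular arc, reminiscent of a hippocampus on
#' a sagittal slice) whose cross-sectional thickness shrinks monotonically
#' with `atrophy`. A fraction `edge_gap_fraction` of the boundary (one
#' contiguous angular run) has its intensity step suppressed by local
#' smoothing, emulating the discontinuous, low-contrast boundaries of real
#' data; the truth mask is unaffected.
#'
#' @param atrophy shrinkage level in `[0, 1]`; area decreases monotonically.
#' @param edge_gap_fraction fraction of boundary pixels (by angle around the
#'   arc center) whose edge gradient is suppressed, in `[0, 1]`.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer RNG seed.
#' @param size canvas dimensions `(h, w)`.
#' @return an `lbseg_fixture`.
#' @export
make_hc_blob <- function(atrophy = 0, edge_gap_fraction = 0,
                         noise_sd = 0.02, seed = 1, size = c(100, 100)) {
  if (atrophy < 0 || atrophy > 1) stop("`atrophy` must lie in [0, 1]")
  if (edge_gap_fraction < 0 || edge_gap_fraction > 1)
    stop("`edge_gap_fraction` must lie in [0, 1]")
  h <- size[1]; w <- size[2]
  cx <- 50; cy <- 66; R <- 26
  th0 <- 195 * pi / 180; th1 <- 345 * pi / 180; thm <- (th0 + th1) / 2
  tmax <- 10.5 * (1 - 0.45 * atrophy)
  g <- pixel_grid(h, w)
  dx <- g$x - cx; dy <- g$y - cy
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  inside_arc <- ang >= th0 & ang <= th1
  # thickness tapers toward the two ends of the arc
  tk <- tmax * (1 - 0.55 * ((ang - thm) / ((th1 - th0) / 2))^2)
  truth <- matrix(as.numeric(inside_arc & abs(r - R) <= tk), h, w)
  img <- BG_INTENSITY + (FG_INTENSITY - BG_INTENSITY) * truth
  if (edge_gap_fraction > 0) {
    bnd <- boundary_pixels(truth)
    bidx <- which(bnd == 1, arr.ind = TRUE)
    bang <- atan2(bidx[, 1] - 1 - cy, bidx[, 2] - 1 - cx) %% (2 * pi)
    ord <- order(bang)
    n_gap <- round(edge_gap_fraction * length(ord))
    weak <- matrix(0, h, w)
    if (n_gap > 0) weak[bidx[ord[seq_len(n_gap)], , drop = FALSE]] <- 1
    # contrast vanishes in the gap: the rim takes the background intensity,
    # feathered so no spurious sharp notch edge is introduced
    halo <- EBImage::dilate(weak, EBImage::makeBrush(7, "disc"))
    img[halo > 0] <- BG_INTENSITY
    fringe <- EBImage::dilate(halo, EBImage::makeBrush(9, "disc"))
    smooth <- EBImage::gblur(img, sigma = 2)
    img[fringe > 0] <- smooth[fringe > 0]
  }
  img <- finish_image(img, noise_sd, seed)
  new_fixture(img, truth, "hc_blob",
              list(atrophy = atrophy, edge_gap_fraction = edge_gap_fraction,
                   noise_sd = noise_sd), seed)
}

# Inner boundary: foreground pixels 4-adjacent to a background pixel.
boundary_pixels <- function(s) {
  h <- nrow(s); w <- ncol(s)
  up    <- rbind(s[1, , drop = FALSE], s[-h, , drop = FALSE])
  down  <- rbind(s[-1, , drop = FALSE], s[h, , drop = FALSE])
  left  <- cbind(s[, 1, drop = FALSE], s[, -w, drop = FALSE])
  right <- cbind(s[, -1, drop = FALSE], s[, w, drop = FALSE])
  bnd <- s == 1 & (up == 0 | down == 0 | left == 0 | right == 0)
  matrix(as.numeric(bnd), h, w)
}

#' Rotation augmentation of a fixture set
#'
#' Emits every base fixture at each rotation angle `0, step, ..., span`
#' degrees (counter-clockwise). Masks are rotated with nearest-neighbour
#' interpolation (stay binary), images with bilinear interpolation. A
#' rotation that would carry foreground off the canvas is rejected.
#'
#' @param base a list of `lbseg_fixture` objects (a single fixture is
#'   accepted and wrapped).
#' @param span_deg total rotation span in degrees; must be a nonnegative
#'   multiple of `step_deg`.
#' @param step_deg rotation increment in degrees.
#' @return an object of class `lbseg_augset`: a list with `items` (each a
#'   list with `image`, `truth`, `angle_deg`, `base_index`, `kind`),
#'   `rotations_deg`, and `base_count`;
#'   `length(items) == base_count * length(rotations_deg)`.
#' @examples
#' aug <- augment_rotations(list(make_ellipse(seed = 1)), 60, 10)
#' length(aug$items)  # 7
#' @export
augment_rotations <- function(base, span_deg = 60, step_deg = 10) {
  if (inherits(base, "lbseg_fixture")) base <- list(base)
  stopifnot(length(base) >= 1)
  if (span_deg < 0) stop("`span_deg` must be nonnegative")
  if (span_deg == 0) {
    angles <- 0
  } else {
    if (step_deg <= 0) stop("`step_deg` must be positive")
    if (abs(span_deg / step_deg - round(span_deg / step_deg)) > 1e-9)
      stop("`step_deg` must divide `span_deg`")
    angles <- seq(0, span_deg, by = step_deg)
  }
  items <- vector("list", length(base) * length(angles))
  k <- 0
  for (b in seq_along(base)) {
    fx <- base[[b]]
    h <- nrow(fx$truth); w <- ncol(fx$truth)
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    fg <- which(fx$truth == 1, arr.ind = TRUE)
    px <- fg[, 2] - 1 - cx; py <- cy - (fg[, 1] - 1)
    border <- c(fx$image[1, ], fx$image[h, ], fx$image[, 1], fx$image[, w])
    fill <- median(border)
    for (ang in angles) {
      th <- ang * pi / 180
      qx <- cos(th) * px - sin(th) * py + cx
      qy <- cy - (sin(th) * px + cos(th) * py)
      bad <- qx < 0 | qx > w - 1 | qy < 0 | qy > h - 1
      if (any(bad))
        stop(sprintf(
          "rotation by %g deg pushes foreground of base item %d off-canvas",
          ang, b))
      k <- k + 1
      items[[k]] <- list(
        image = rotate_grid(fx$image, ang, "bilinear", fill = fill),
        truth = rotate_grid(fx$truth, ang, "nearest", fill = 0),
        angle_deg = ang, base_index = b, kind = fx$kind)
    }
  }
  structure(list(items = items, rotations_deg = angles,
                 base_count = length(base)),
            class = "lbseg_augset")
}

#' @export
print.lbseg_augset <- function(x, ...) {
  cat(sprintf("<lbseg_augset> %d base x %d rotations = %d items\n",
              x$base_count, length(x$rotations_deg), length(x$items)))
  invisible(x)
}
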