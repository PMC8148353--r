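#' Union bounding box of a set of masks
#'
#' Kappa is computed only over the area surrounding the disc: the tight
#' inclusive box spanning the lowest/highest x and y of all foreground
#' pixels across the supplied masks, expanded by `margin` and clipped to the
#' image.
#'
#' @param masks a single mask or a list of binary masks of identical shape.
#' @param margin non-negative expansion in pixels.
#' @return list with 0-based inclusive `x_min, y_min, x_max, y_max`,
#'   class `bounding_box`.
#' @export
union_bounding_box <- function(masks, margin = 0) {
  if (is.matrix(masks)) masks <- list(masks)
  masks <- lapply(masks, .as_mask)
  shp <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == shp), logical(1))))
    stop("masks must share one shape")
  if (margin < 0) stop("margin must be non-negative")
  any_fg <- Reduce(`|`, masks)
  if (!any(any_fg)) stop("all masks are empty")
  rows <- range(which(rowSums(any_fg) > 0)) - 1
  cols <- range(which(colSums(any_fg) > 0)) - 1
  structure(list(
    x_min = max(0, cols[1] - margin),
    y_min = max(0, rows[1] - margin),
    x_max = min(shp[2] - 1, cols[2] + margin),
    y_max = min(shp[1] - 1, rows[2] + margin)), class = "bounding_box")
}

.crop_bbox <- function(mask, bbox) {
  mask[(bbox$y_min:bbox$y_max) + 1, (bbox$x_min:bbox$x_max) + 1, drop = FALSE]
}

.kappa_result <- function(kappa, po, pe, n) {
  structure(list(kappa = kappa, p_observed = po, p_expected = pe,
                 n_pixels = n), class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa %.4f (Po %.4f, Pe %.4f, n %d)>\n",
              x$kappa, x$p_observed, x$p_expected, x$n_pixels))
  invisible(x)
}

#' Cohen's kappa over a bounding box (disc region)
#'
#' Each pixel inside the box is a rated item, labelled disc/background by
#' each tracing; `kappa = (Po - Pe) / (1 - Pe)` where `Po` is the observed
#' proportion of identically-labelled pixels and
#' `Pe = p_a p_b + (1 - p_a)(1 - p_b)` is the chance agreement from each
#' tracing's foreground fraction in the box. The degenerate case `Pe = 1`
#' (both tracings constant and equal over the box) is defined as kappa 1.
#'
#' @param a,b binary masks of identical shape.
#' @param bbox a [union_bounding_box()]; defaults to the tight pairwise
#'   union box of `a` and `b`.
#' @return a `kappa_result` with elements `kappa`, `p_observed`,
#'   `p_expected`, `n_pixels`.
#' @export
region_kappa <- function(a, b, bbox = NULL) {
  a <- .as_mask(a, "a"); b <- .as_mask(b, "b")
  if (!all(dim(a) == dim(b))) stop("masks must share one shape")
  if (is.null(bbox)) bbox <- union_bounding_box(list(a, b))
  sa <- .crop_bbox(a, bbox); sb <- .crop_bbox(b, bbox)
  n <- length(sa)
  po <- mean(sa == sb)
  pa <- mean(sa); pb <- mean(sb)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  .kappa_result(kappa, po, pe, n)
}

#' Boundary band of a mask
#'
#' Outer contour pixels (foreground pixels with a background 8-neighbour
#' after hole filling) dilated by a disc of radius `tolerance`. This is the
#' raster each tracing is reduced to for the border-agreement kappa.
#'
#' @param mask binary mask.
#' @param tolerance band half-width in pixels (0 keeps the bare contour).
#' @return logical mask of the band.
#' @export
boundary_band <- function(mask, tolerance = 2) {
  mask <- .as_mask(mask)
  .assert_nonempty(mask)
  if (tolerance < 0) stop("tolerance must be non-negative")
  shp <- dim(mask)
  # work on a padded crop so morphology cost scales with the disc, not the image
  pad <- ceiling(tolerance) + 2
  rows <- range(which(rowSums(mask) > 0)); cols <- range(which(colSums(mask) > 0))
  r0 <- max(1, rows[1] - pad); r1 <- min(shp[1], rows[2] + pad)
  c0 <- max(1, cols[1] - pad); c1 <- min(shp[2], cols[2] + pad)
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  img <- EBImage::fillHull(EBImage::Image(sub * 1))
  inner <- EBImage::erode(img, EBImage::makeBrush(3, "box"))
  band <- EBImage::imageData(img) > 0.5 & EBImage::imageData(inner) < 0.5
  if (tolerance > 0) {
    brush <- EBImage::makeBrush(2 * ceiling(tolerance) + 1, "disc")
    band <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(band * 1), brush)) > 0.5
  }
  out <- matrix(FALSE, shp[1], shp[2])
  out[r0:r1, c0:c1] <- band
  out
}

#' Cohen's kappa on boundary bands (disc border)
#'
#' Region kappa saturates when two tracings overlap in bulk even though
#' their borders disagree; the border variant reduces each mask to its
#' [boundary_band()] first and applies the same bounding-box kappa to the
#' two bands.
#'
#' @inheritParams region_kappa
#' @param tolerance band half-width in pixels passed to [boundary_band()].
#' @return a `kappa_result`.
#' @export
border_kappa <- function(a, b, bbox = NULL, tolerance = 2) {
  a <- .as_mask(a, "a"); b <- .as_mask(b, "b")
  .assert_nonempty(a, "a"); .assert_nonempty(b, "b")
  if (is.null(bbox)) bbox <- union_bounding_box(list(a, b))
  region_kappa(boundary_band(a, tolerance), boundary_band(b, tolerance), bbox)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` counting foreground pixels; 1 means the
#' traced regions coincide exactly.
#'
#' @param a,b binary masks of identical shape, not both empty.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- .as_mask(a, "a"); b <- .as_mask(b, "b")
  if (!all(dim(a) == dim(b))) stop("masks must share one shape")
  denom <- sum(a) + sum(b)
  if (denom == 0) stop("both masks are empty (dice undefined)")
  2 * sum(a & b) / denom
}

#' Area centroid of a mask
#'
#' @param mask binary mask with at least one foreground pixel.
#' @return numeric `c(cx, cy)` in 0-based sub-pixel coordinates.
#' @export
mask_centroid <- function(mask) {
  mask <- .as_mask(mask)
  .assert_nonempty(mask)
  idx <- which(mask, arr.ind = TRUE)
  c(cx = mean(idx[, 2]) - 1, cy = mean(idx[, 1]) - 1)
}

# Vectorized ray casting: for each angle, the distance from `center` to the
# farthest foreground pixel along the ray, sampled every `step` px.
.radial_distances <- function(mask, center, angles, step = 0.25,
                              max_r = NULL) {
  h <- nrow(mask); w <- ncol(mask)
  cx <- center[1]; cy <- center[2]
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
    stop("center lies outside the image")
  if (is.null(max_r)) max_r <- sqrt(h^2 + w^2)
  s <- seq(0, max_r, by = step)
  dirs <- .ray_direction(angles)
  out <- rep(NA_real_, length(angles))
  for (i in seq_along(angles)) {
    px <- .px_round(cx + s * dirs[i, 1])
    py <- .px_round(cy + s * dirs[i, 2])
    ok <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
    fg <- ok
    fg[ok] <- mask[cbind(py[ok] + 1, px[ok] + 1)]
    if (any(fg)) out[i] <- s[max(which(fg))]
  }
  out
}

#' Distance from a point to a mask boundary along a ray
#'
#' Samples the ray from `center` at the given angle in 0.25 px steps up to
#' the image diagonal and returns the distance to the farthest sampled
#' foreground pixel — deterministic for filled masks, insensitive to
#' interior holes, and, for masks carrying a detached misaligned arc, the
#' arc wins (farthest-pixel rule). `NA` when no foreground lies on the ray.
#'
#' @param mask binary mask.
#' @param center numeric `c(cx, cy)` inside the image.
#' @param angle_deg angle(s) in degrees, counter-clockwise on screen from
#'   +x (90 = up).
#' @return numeric vector of distances in pixels (`NA` where undefined).
#' @export
radial_distance <- function(mask, center, angle_deg) {
  mask <- .as_mask(mask)
  .radial_distances(mask, center, angle_deg)
}

#' The uniform 12-direction angle set (30 degree spacing)
#' @return numeric vector 0, 30, ..., 330.
#' @export
angles_uniform12 <- function() seq(0, 330, by = 30)

#' The study's printed 12-direction list (irregular: includes 20 degrees)
#' @return numeric vector of 12 angles.
#' @export
angles_printed12 <- function() c(0, 20, 60, 90, 120, 150, 180, 210, 240,
                                 270, 300, 330)

#' Average radial boundary distance between two tracings
#'
#' From the centroid of the reference tracing, a ray is cast at each angle;
#' `d_ref` and `d_test` are the distances at which the ray leaves the
#' reference and test tracing respectively, and the average boundary
#' distance is `mu_d = mean(|d_ref - d_test|)` over the angles where both
#' are defined. Both distances are measured from the same (reference)
#' centroid. Angles where either tracing does not intersect the ray are
#' excluded; the result is flagged when more than half are excluded and it
#' is an error when all are.
#'
#' @param ref reference (ground-truth) mask; supplies the centroid.
#' @param test test mask.
#' @param angles direction set in degrees; default [angles_uniform12()].
#' @return object of class `radial_profile`: `center`, `angles`, `d_ref`,
#'   `d_test`, `mu_d`, `n_valid`, `flags`.
#' @export
average_boundary_distance <- function(ref, test, angles = angles_uniform12()) {
  ref <- .as_mask(ref, "ref"); test <- .as_mask(test, "test")
  .assert_nonempty(ref, "ref"); .assert_nonempty(test, "test")
  center <- mask_centroid(ref)
  d_ref <- .radial_distances(ref, center, angles)
  d_test <- .radial_distances(test, center, angles)
  valid <- is.finite(d_ref) & is.finite(d_test)
  if (!any(valid))
    stop("no angle intersects both tracings; boundary distance undefined")
  flags <- character(0)
  if (mean(valid) < 0.5) flags <- "majority_of_angles_undefined"
  structure(list(center = center, angles = angles, d_ref = d_ref,
                 d_test = d_test,
                 mu_d = mean(abs(d_ref[valid] - d_test[valid])),
                 n_valid = sum(valid), flags = flags),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial profile: mu_d %.2f px over %d/%d angles>\n",
              x$mu_d, x$n_valid, length(x$angles)))
  invisible(x)
}

#' Qualitative interpretation of a kappa value
#'
#' Maps kappa to the conventional agreement bands: less-than-chance
#' (below 0), poor (0.01–0.20), fair (0.21–0.40), moderate (0.41–0.60),
#' substantial (0.61–0.80) and almost-perfect (0.81–0.99). The two-decimal
#' cut-offs are realized with half-step boundaries (0.005, 0.205, ...) so
#' every real value up to 1 falls in exactly one band.
#'
#' @param kappa numeric vector, each value at most 1.
#' @return character vector of band labels.
#' @export
interpret_kappa <- function(kappa) {
  if (any(kappa > 1, na.rm = TRUE)) stop("kappa cannot exceed 1")
  as.character(cut(kappa,
    breaks = c(-Inf, 0.005, 0.205, 0.405, 0.605, 0.805, Inf),
    labels = c("less-than-chance", "poor", "fair", "moderate",
               "substantial", "almost-perfect"),
    right = FALSE))
}
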