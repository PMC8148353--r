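#' Geometric ellipse parameters
#'
#' @param cx,cy center, pixel coordinates.
#' @param semi_major,semi_minor semi-axis lengths in pixels,
#'   `semi_major >= semi_minor > 0` (swapped automatically if given in the
#'   other order, with the rotation adjusted).
#' @param rotation angle of the semi-major axis in radians; canonicalized
#'   to `[0, pi)`.
#' @return object of class `ellipse_params`.
#' @export
ellipse_params <- function(cx, cy, semi_major, semi_minor, rotation = 0) {
  if (semi_major <= 0 || semi_minor <= 0) stop("semi-axes must be positive")
  if (semi_minor > semi_major) {
    tmp <- semi_major; semi_major <- semi_minor; semi_minor <- tmp
    rotation <- rotation + pi / 2
  }
  rotation <- rotation %% pi
  structure(list(cx = cx, cy = cy, semi_major = semi_major,
                 semi_minor = semi_minor, rotation = rotation),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "<ellipse: center (%.2f, %.2f), semi-axes %.2f/%.2f, rotation %.1f deg>\n",
    x$cx, x$cy, x$semi_major, x$semi_minor, x$rotation * 180 / pi))
  invisible(x)
}

# normalize a conic vector: unit Euclidean norm, leading quadratic
# coefficient non-negative
.normalize_conic <- function(v) {
  v <- v / sqrt(sum(v^2))
  lead <- v[which(abs(v) > 1e-14)[1]]
  if (!is.na(lead) && lead < 0) v <- -v
  names(v) <- c("A", "B", "C", "D", "E", "F")
  class(v) <- "conic"
  v
}

.is_ellipse_conic <- function(v) v[2]^2 - 4 * v[1] * v[3] < 0

#' Direct least-squares ellipse fit (conic form)
#'
#' Fits the conic `A x^2 + B x y + C y^2 + D x + E y + F = 0` constrained to
#' be an ellipse (`B^2 - 4AC < 0`) by minimizing the algebraic distance of
#' the points to the conic, using the numerically stable block decomposition
#' of the constrained eigenproblem: the design matrix is split into a
#' quadratic block `D1` (rows `x^2, xy, y^2`) and a linear block `D2`
#' (rows `x, y, 1`); with scatter blocks `S1 = D1'D1`, `S2 = D1'D2`,
#' `S3 = D2'D2` the quadratic half `a1` of the coefficient vector is the
#' eigenvector of `M = C1^{-1} (S1 - S2 S3^{-1} S2')` satisfying the ellipse
#' constraint `4 a c - b^2 > 0`, where `C1 = [[0,0,2],[0,-1,0],[2,0,0]]`;
#' the linear half is `a2 = -S3^{-1} S2' a1`.
#'
#' For numerical conditioning the points are translated to their centroid
#' and isotropically scaled to RMS radius sqrt(2) before the fit; the conic
#' is mapped back to raw pixel coordinates afterwards. This is
#' mathematically equivalent to fitting in raw coordinates but keeps the
#' scatter blocks well-conditioned at fundus-image pixel scales.
#'
#' @param points a [polyline()] or two-column (x, y) matrix of at least 6
#'   non-collinear boundary points.
#' @return a `conic` vector (A..F), unit norm, with `A >= 0`.
#' @seealso [conic_to_geometric()], [refit_tracing()]
#' @export
fit_ellipse_conic <- function(points) {
  pts <- .as_points(points)
  n <- nrow(pts)
  if (n < 6) stop("need at least 6 points to fit an ellipse")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  ux <- pts[, 1] - mx; uy <- pts[, 2] - my
  rms <- sqrt(mean(ux^2 + uy^2))
  if (rms < .Machine$double.eps * 100)
    stop("degenerate point set (all points coincide)")
  s <- sqrt(2) / rms
  ux <- ux * s; uy <- uy * s

  D1 <- cbind(ux^2, ux * uy, uy^2)
  D2 <- cbind(ux, uy, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) stop("degenerate point set (collinear?)"))
  C1inv <- matrix(c(0, 0, 0.5, 0, -1, 0, 0.5, 0, 0), 3, 3)
  M <- C1inv %*% (S1 + S2 %*% T3)

  eig <- eigen(M)
  vec <- Re(eig$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  # exactly one eigenvector satisfies the ellipse constraint in exact
  # arithmetic; numerically take the largest positive constraint value
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no eigenvector satisfies the ellipse constraint")
  a1 <- vec[, ok[which.max(cond[ok])]]
  a2 <- T3 %*% a1

  # back-transform from conditioned coords u = s (x - m) to pixels
  A <- a1[1]; B <- a1[2]; C <- a1[3]
  D <- a2[1]; E <- a2[2]; F <- a2[3]
  v <- c(A * s^2,
         B * s^2,
         C * s^2,
         -2 * A * s^2 * mx - B * s^2 * my + D * s,
         -B * s^2 * mx - 2 * C * s^2 * my + E * s,
         A * s^2 * mx^2 + B * s^2 * mx * my + C * s^2 * my^2 -
           D * s * mx - E * s * my + F)
  v <- .normalize_conic(v)
  if (!.is_ellipse_conic(v)) stop("fitted conic is not an ellipse")
  v
}

#' Convert between conic and geometric ellipse forms
#'
#' `conic_to_geometric()` recovers center, semi-axes and rotation from the
#' conic coefficients: the center is the zero of the conic's gradient and
#' the axes/rotation come from the eigen-decomposition of the quadratic
#' form. `geometric_to_conic()` is its exact inverse.
#'
#' @param conic numeric A..F conic vector satisfying `B^2 - 4AC < 0`; any
#'   overall scaling is accepted.
#' @return `conic_to_geometric()`: an [ellipse_params()];
#'   `geometric_to_conic()`: a normalized `conic` vector.
#' @export
conic_to_geometric <- function(conic) {
  v <- as.numeric(conic)
  if (length(v) != 6) stop("conic must have 6 coefficients")
  if (!.is_ellipse_conic(v)) stop("conic does not describe an ellipse")
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]; E <- v[5]; F <- v[6]
  center <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2, byrow = TRUE),
                  -c(D, E))
  cx <- center[1]; cy <- center[2]
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eig <- eigen(Q, symmetric = TRUE)   # eigenvalues decreasing
  r2 <- -Fc / eig$values
  if (any(r2 <= 0)) stop("conic does not describe a real ellipse")
  # smaller eigenvalue -> longer axis
  vmaj <- eig$vectors[, 2]
  ellipse_params(cx, cy, sqrt(r2[2]), sqrt(r2[1]),
                 atan2(vmaj[2], vmaj[1]))
}

#' @rdname conic_to_geometric
#' @param params an [ellipse_params()].
#' @export
geometric_to_conic <- function(params) {
  a <- params$semi_major; b <- params$semi_minor
  ct <- cos(params$rotation); st <- sin(params$rotation)
  A <- ct^2 / a^2 + st^2 / b^2
  B <- 2 * ct * st * (1 / a^2 - 1 / b^2)
  C <- st^2 / a^2 + ct^2 / b^2
  cx <- params$cx; cy <- params$cy
  D <- -(2 * A * cx + B * cy)
  E <- -(B * cx + 2 * C * cy)
  F <- A * cx^2 + B * cx * cy + C * cy^2 - 1
  .normalize_conic(c(A, B, C, D, E, F))
}

#' Convenience: fit an ellipse and return geometric parameters
#'
#' @inheritParams fit_ellipse_conic
#' @return an [ellipse_params()].
#' @export
fit_ellipse <- function(points) conic_to_geometric(fit_ellipse_conic(points))

#' Rasterize an ellipse into a filled mask
#'
#' A pixel is foreground iff its center satisfies the ellipse interior
#' inequality (value of the normalized quadratic form at most 1); the
#' ellipse is clipped to the image bounds.
#'
#' @param params an [ellipse_params()].
#' @param shape integer `c(height, width)`.
#' @return logical matrix of dimension `shape`.
#' @export
ellipse_to_mask <- function(params, shape) {
  h <- shape[1]; w <- shape[2]
  mask <- matrix(FALSE, h, w)
  R <- params$semi_major
  x0 <- max(0, floor(params$cx - R)); x1 <- min(w - 1, ceiling(params$cx + R))
  y0 <- max(0, floor(params$cy - R)); y1 <- min(h - 1, ceiling(params$cy + R))
  if (x0 > x1 || y0 > y1) return(mask)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - params$cx)
  dy <- outer(ys - params$cy, rep(1, length(xs)))
  ct <- cos(params$rotation); st <- sin(params$rotation)
  u <- (dx * ct + dy * st) / params$semi_major
  v <- (-dx * st + dy * ct) / params$semi_minor
  mask[ys + 1, xs + 1] <- u^2 + v^2 <= 1
  mask
}

#' Replace a tracing by its best-fit ellipse
#'
#' Repairs misaligned tracing strokes: boundary points are extracted (mask
#' input: outer contour of the largest component; polyline input: the
#' vertices as given, misaligned segments included — the fit is what absorbs
#' them), an ellipse is fitted by [fit_ellipse_conic()], and the fitted
#' ellipse is rasterized as the replacement tracing.
#'
#' For mask input the fitted semi-axes are enlarged by half a pixel:
#' contour pixel centers lie up to one pixel inside the traced region, so a
#' fit through them systematically under-estimates the axes by about half a
#' pixel; the compensation makes the refit of a rasterized ellipse a fixed
#' point (dice >= 0.99). Polyline vertices are continuous coordinates and
#' need no compensation.
#'
#' Fit failures (degenerate point sets, non-elliptical solutions) raise an
#' error; [analyze_pair()] catches it, falls back to the raw tracing and
#' flags the record.
#'
#' @param tracing a binary mask or a [polyline()].
#' @param shape integer `c(height, width)` of the target grid.
#' @return logical mask of the fitted ellipse, with the fitted
#'   [ellipse_params()] attached as attribute `"params"`.
#' @export
refit_tracing <- function(tracing, shape) {
  from_mask <- !inherits(tracing, "polyline")
  pts <- if (from_mask) mask_to_boundary(.as_mask(tracing))$points
         else tracing$points
  params <- fit_ellipse(pts)
  if (from_mask)
    params <- ellipse_params(params$cx, params$cy, params$semi_major + 0.5,
                             params$semi_minor + 0.5, params$rotation)
  out <- ellipse_to_mask(params, shape)
  if (!any(out)) stop("fitted ellipse lies outside the image")
  attr(out, "params") <- params
  out
}
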