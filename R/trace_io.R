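#' Boundary polylines
#'
#' A polyline is an ordered sequence of (x, y) vertices, sub-pixel precision
#' allowed, optionally closed. Vertices use the package-wide convention:
#' 0-based pixel coordinates, x = column, y = row (downward).
#'
#' Normalization removes consecutive duplicate vertices and, for closed
#' polylines, a repeated final vertex equal to the first.
#'
#' @param points two-column numeric matrix (or data frame) of x, y vertices.
#' @param closed logical; is the path a closed boundary? Closed polylines
#'   need at least 3 distinct vertices.
#' @return an object of class `polyline` with elements `points` (matrix with
#'   columns `x`, `y`) and `closed`.
#' @export
polyline <- function(points, closed = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("`points` must have two columns (x, y)")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  if (nrow(points) >= 2) {
    dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
    points <- points[!dup, , drop = FALSE]
  }
  if (closed && nrow(points) >= 2 &&
      all(points[1, ] == points[nrow(points), ])) {
    points <- points[-nrow(points), , drop = FALSE]
  }
  if (closed && nrow(points) < 3)
    stop("a closed polyline needs at least 3 distinct vertices")
  if (nrow(points) < 1) stop("empty polyline")
  structure(list(points = points, closed = isTRUE(closed)),
            class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline: %d vertices, %s>\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

.as_points <- function(x) {
  if (inherits(x, "polyline")) x$points else {
    p <- as.matrix(x)
    storage.mode(p) <- "double"
    if (ncol(p) != 2) stop("points must be a two-column matrix")
    colnames(p) <- c("x", "y")
    p
  }
}

#' Read a binary tracing mask from a raster image
#'
#' Any pixel with a nonzero value in any channel is foreground; this is
#' deliberately tolerant of anti-aliased exports of hand tracings.
#'
#' @param path path to a PNG or TIFF file (single channel or RGB).
#' @return logical matrix (rows = image rows / y, cols = columns / x).
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format (expect png/tif/tiff): ", path)
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), max)
  mask <- img > 0
  if (!any(mask))
    warning("mask is entirely background: ", path)
  mask
}

#' Write a binary tracing mask as a raster image
#'
#' Lossless single-channel output: foreground 255, background 0.
#'
#' @param mask binary matrix (rows = y, cols = x).
#' @param path destination path; format chosen by extension (png/tif/tiff).
#' @export
save_mask <- function(mask, path) {
  mask <- .as_mask(mask)
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported mask format (expect png/tif/tiff): ", path)
  )
  invisible(path)
}

#' Rasterize a closed polyline into a filled mask
#'
#' The interior is filled under the nonzero winding rule evaluated at pixel
#' centers (integer coordinates); in addition, pixels whose center lies on
#' the path itself (within an eighth of a pixel) are set, so rasterization
#' is inclusive of the traced boundary without inflating the region's area:
#' an axis-aligned square with corners (10,10)..(20,20) yields an 11 x 11
#' block, and a rasterized circle's pixel count stays within a couple of
#' percent of its true area. Open polylines are closed automatically.
#' Vertices are clipped to the image bounds.
#'
#' @param poly a [polyline()] (or two-column matrix) with at least 3 vertices.
#' @param shape integer vector `c(height, width)` of the target grid.
#' @return logical matrix of dimension `shape`.
#' @export
polyline_to_mask <- function(poly, shape) {
  pts <- .as_points(poly)
  if (nrow(pts) < 3) stop("need at least 3 vertices to fill a polygon")
  h <- shape[1]; w <- shape[2]
  if (h < 1 || w < 1) stop("invalid shape")
  x <- pmin(pmax(pts[, 1], 0), w - 1)
  y <- pmin(pmax(pts[, 2], 0), h - 1)
  n <- length(x)
  # shoelace area; zero-area polygons cannot be filled
  area2 <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
  if (area2 < .Machine$double.eps * 100)
    stop("degenerate (zero-area) polygon")
  mask <- matrix(FALSE, h, w)

  # edges i -> i+1 (wrapping)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])

  # scanline fill, nonzero winding, at integer y rows
  for (yc in seq(max(0, ceiling(min(y))), min(h - 1, floor(max(y))))) {
    up <- y <= yc & y2 > yc      # edge crosses upward (in y-down sense)
    dn <- y2 <= yc & y > yc
    cross <- up | dn
    if (!any(cross)) next
    t <- (yc - y[cross]) / (y2[cross] - y[cross])
    xc <- x[cross] + t * (x2[cross] - x[cross])
    dir <- ifelse(up[cross], 1L, -1L)
    o <- order(xc)
    xc <- xc[o]; wind <- cumsum(dir[o])
    k <- length(xc)
    if (k < 2) next
    for (j in seq_len(k - 1)) {
      if (wind[j] != 0) {
        # half-open span [xc_j, xc_{j+1}): unbiased center-inside rule;
        # centers exactly on an edge are handled by the boundary pass
        x_from <- ceiling(xc[j]); x_to <- ceiling(xc[j + 1]) - 1
        if (x_from <= x_to)
          mask[yc + 1, (x_from:x_to) + 1] <- TRUE
      }
    }
  }

  # inclusive boundary: pixel centers lying on the path (within an eighth
  # of a pixel; path sampled every quarter pixel so no on-path center is
  # missed)
  seg_len <- sqrt((x2 - x)^2 + (y2 - y)^2)
  for (i in seq_len(n)) {
    m <- max(2L, ceiling(seg_len[i] / 0.25) + 1L)
    t <- seq(0, 1, length.out = m)
    sx <- x[i] + t * (x2[i] - x[i])
    sy <- y[i] + t * (y2[i] - y[i])
    px <- .px_round(sx); py <- .px_round(sy)
    on <- pmax(abs(sx - px), abs(sy - py)) <= 0.13
    if (any(on))
      mask[cbind(py[on] + 1, px[on] + 1)] <- TRUE
  }
  mask
}

# 8-connected labelling: EBImage's bwlabel is 4-connected, so merge labels
# that touch diagonally.
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  h <- nrow(lab); w <- ncol(lab)
  for (shift in list(c(1, 1), c(1, -1))) {
    di <- shift[1]; dj <- shift[2]
    ri <- seq_len(h - 1)
    cj <- if (dj > 0) seq_len(w - 1) else 2:w
    a <- lab[ri, cj, drop = FALSE]
    b <- lab[ri + di, cj + dj, drop = FALSE]
    touch <- which(a > 0 & b > 0 & a != b)
    for (k in touch) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0]]
  out
}

#' Extract the ordered outer boundary of a mask
#'
#' Traces the outer contour of the largest 8-connected foreground component;
#' interior holes are ignored. Contour pixels are returned in traversal
#' order as a closed polyline in (x, y) pixel coordinates.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @return a closed [polyline()] of 0-based integer pixel coordinates.
#' @export
mask_to_boundary <- function(mask) {
  mask <- .as_mask(mask)
  .assert_nonempty(mask)
  lab <- .label8(mask)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[which.max(sizes)])
  comp <- lab == keep
  oc <- EBImage::ocontour(EBImage::Image(comp * 1))[[1]]
  # ocontour on an untransposed matrix returns 0-based (row, col) = (y, x)
  polyline(cbind(oc[, 2], oc[, 1]), closed = TRUE)
}

#' Read / write a polyline
#'
#' CSV dialect: header `x,y`, one vertex per row, decimals allowed.
#' JSON dialect: a list of `[x, y]` pairs.
#'
#' @param path file path; dialect chosen by extension (csv or json).
#' @param closed logical; whether the stored path is a closed boundary.
#' @return [read_polyline()] returns a [polyline()].
#' @export
read_polyline <- function(path, closed = TRUE) {
  ext <- tolower(tools::file_ext(path))
  pts <- switch(ext,
    csv = {
      d <- utils::read.csv(path)
      if (!all(c("x", "y") %in% names(d)))
        stop("polyline CSV must have columns x,y: ", path)
      cbind(d$x, d$y)
    },
    json = {
      l <- jsonlite::fromJSON(path)
      as.matrix(l)
    },
    stop("unsupported polyline format (expect csv/json): ", path)
  )
  polyline(pts, closed = closed)
}

#' @rdname read_polyline
#' @param poly a [polyline()].
#' @export
write_polyline <- function(poly, path) {
  pts <- .as_points(poly)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = utils::write.csv(as.data.frame(pts), path, row.names = FALSE),
    json = jsonlite::write_json(unname(split(pts, row(pts))), path,
                                auto_unbox = FALSE, digits = NA),
    stop("unsupported polyline format (expect csv/json): ", path)
  )
  invisible(path)
}

#' One image's labelled tracings
#'
#' Bundles every tracing of one fundus image: a map from rater label to a
#' mask or polyline, which must include a `"ground_truth"` entry for the
#' precision metrics, plus the dataset and retinal-condition labels used for
#' stratification.
#'
#' @param image_id character id.
#' @param dataset dataset label, e.g. `"drishti"` or `"aria"`.
#' @param condition one of `"glaucoma"`, `"dr"`, `"normal"`.
#' @param shape integer `c(height, width)` shared by all tracings.
#' @param tracings named list of binary masks and/or [polyline()]s.
#' @return an object of class `image_record`.
#' @export
image_record <- function(image_id, dataset, condition, shape, tracings) {
  condition <- match.arg(condition, c("glaucoma", "dr", "normal"))
  if (length(shape) != 2 || any(shape < 1)) stop("invalid shape")
  if (is.null(names(tracings)) || any(names(tracings) == ""))
    stop("tracings must be a named list (rater label -> tracing)")
  for (nm in names(tracings)) {
    tr <- tracings[[nm]]
    if (is.matrix(tr)) {
      if (!all(dim(tr) == shape))
        stop(sprintf("tracing '%s' does not match the record shape", nm))
      tracings[[nm]] <- .as_mask(tr, nm)
    } else if (!inherits(tr, "polyline")) {
      stop(sprintf("tracing '%s' must be a mask matrix or a polyline", nm))
    }
  }
  structure(list(image_id = as.character(image_id), dataset = dataset,
                 condition = condition, shape = as.integer(shape),
                 tracings = tracings),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %s: %s/%s, %dx%d, tracings: %s>\n",
              x$image_id, x$dataset, x$condition, x$shape[1], x$shape[2],
              paste(names(x$tracings), collapse = ", ")))
  invisible(x)
}

# tracing (mask or polyline) -> mask on the record grid
.tracing_to_mask <- function(tr, shape) {
  if (inherits(tr, "polyline")) polyline_to_mask(tr, shape) else .as_mask(tr)
}

#' Read a study manifest and its tracings
#'
#' The manifest (CSV or JSON) has one row per tracing with columns
#' `image_id, dataset, condition, rater, path, kind` where `kind` is
#' `"mask"` or `"polyline"`. Paths are resolved relative to the manifest's
#' directory. Each image must contribute at least one mask (usually the
#' ground truth), from which the record's grid shape is taken.
#'
#' @param manifest path to a manifest file, or a data frame with the
#'   manifest columns (then `root` must be given for relative paths).
#' @param root directory against which relative `path` entries are resolved;
#'   defaults to the manifest's directory.
#' @return a list of [image_record()]s.
#' @export
read_study <- function(manifest, root = NULL) {
  if (is.character(manifest)) {
    if (is.null(root)) root <- dirname(manifest)
    ext <- tolower(tools::file_ext(manifest))
    manifest <- switch(ext,
      csv = utils::read.csv(manifest, stringsAsFactors = FALSE),
      json = jsonlite::fromJSON(manifest),
      stop("unsupported manifest format (expect csv/json)")
    )
  }
  need <- c("image_id", "dataset", "condition", "rater", "path", "kind")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.null(root)) root <- "."
  records <- list()
  for (id in unique(manifest$image_id)) {
    rows <- manifest[manifest$image_id == id, , drop = FALSE]
    tracings <- list()
    shape <- NULL
    for (i in seq_len(nrow(rows))) {
      p <- rows$path[i]
      if (!file.exists(p)) p <- file.path(root, rows$path[i])
      tr <- switch(rows$kind[i],
        mask = load_mask(p),
        polyline = read_polyline(p),
        stop("manifest kind must be 'mask' or 'polyline'")
      )
      if (is.matrix(tr) && is.null(shape)) shape <- dim(tr)
      tracings[[rows$rater[i]]] <- tr
    }
    if (is.null(shape))
      stop(sprintf("image %s has no mask tracing to define the grid shape", id))
    records[[length(records) + 1]] <- image_record(
      id, rows$dataset[1], rows$condition[1], shape, tracings)
  }
  records
}

#' Write a study to disk
#'
#' Masks are written as PNG, polylines as CSV, plus a `manifest.csv` in the
#' dialect read by [read_study()].
#'
#' @param records list of [image_record()]s.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_study <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (rec in records) {
    for (nm in names(rec$tracings)) {
      tr <- rec$tracings[[nm]]
      if (is.matrix(tr)) {
        fn <- sprintf("%s_%s.png", rec$image_id, nm)
        save_mask(tr, file.path(dir, fn))
        kind <- "mask"
      } else {
        fn <- sprintf("%s_%s.csv", rec$image_id, nm)
        write_polyline(tr, file.path(dir, fn))
        kind <- "polyline"
      }
      rows[[length(rows) + 1]] <- data.frame(
        image_id = rec$image_id, dataset = rec$dataset,
        condition = rec$condition, rater = nm, path = fn, kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
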