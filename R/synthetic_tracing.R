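#' Simulated observer (rater) model
#'
#' Describes how a simulated rater deviates from the true disc boundary.
#' The boundary is traced in polar form about the true disc center at one
#' degree steps; the observer then
#' \enumerate{
#'   \item adds zero-mean Gaussian radial jitter (`radial_jitter_sd`),
#'   \item adds the sector biases — signed radial offsets over fixed angular
#'     intervals, active only for retinal conditions that enable them; this
#'     models systematic outward confusion of the disc border with
#'     peripapillary atrophy (PPA) in glaucomatous images,
#'   \item with probability `misalignment_prob` displaces one contiguous
#'     random arc of width `misalignment_arc` degrees radially by
#'     `misalignment_offset` pixels — a tracing stroke deviating from its
#'     intended path (the calibration artifact ellipse fitting repairs),
#'   \item smooths the radius sequence with a circular moving average of
#'     width `smoothing_window` (hand strokes are smooth at 1 degree
#'     resolution).
#' }
#'
#' @param radial_jitter_sd standard deviation of the radial jitter, px.
#' @param misalignment_prob probability (per image) of one misaligned arc.
#' @param misalignment_arc arc width in degrees, in (0, 360).
#' @param misalignment_offset signed radial displacement of the arc, px.
#' @param sector_bias `NULL`, or a data frame / list of rows
#'   `(start, end, offset)`: signed radial offset (px) applied on angles in
#'   `[start, end)` degrees.
#' @param smoothing_window odd integer >= 1; number of neighbouring 1-degree
#'   samples averaged.
#' @return object of class `observer_model`.
#' @export
observer_model <- function(radial_jitter_sd = 1.5, misalignment_prob = 0,
                           misalignment_arc = 60, misalignment_offset = 8,
                           sector_bias = NULL, smoothing_window = 5) {
  if (radial_jitter_sd < 0) stop("radial_jitter_sd must be >= 0")
  if (misalignment_prob < 0 || misalignment_prob > 1)
    stop("misalignment_prob must be in [0, 1]")
  if (misalignment_arc <= 0 || misalignment_arc >= 360)
    stop("misalignment_arc must be in (0, 360)")
  if (smoothing_window < 1 || smoothing_window %% 2 != 1)
    stop("smoothing_window must be an odd integer >= 1")
  if (!is.null(sector_bias)) {
    sector_bias <- as.data.frame(do.call(rbind, lapply(
      if (is.data.frame(sector_bias)) split(sector_bias, seq_len(nrow(sector_bias)))
      else sector_bias,
      function(r) {
        r <- unlist(r)
        if (length(r) != 3) stop("each sector_bias entry is (start, end, offset)")
        setNames(as.numeric(r), c("start", "end", "offset"))
      })))
  }
  structure(list(radial_jitter_sd = radial_jitter_sd,
                 misalignment_prob = misalignment_prob,
                 misalignment_arc = misalignment_arc,
                 misalignment_offset = misalignment_offset,
                 sector_bias = sector_bias,
                 smoothing_window = as.integer(smoothing_window)),
            class = "observer_model")
}

# PPA-style outward bias in the superior (around 90 deg) and inferior
# (around 270 deg) sectors; the two default raters get different magnitudes
# and slightly different sectors so they also disagree with each other.
.default_observers <- function() {
  list(
    od1 = observer_model(radial_jitter_sd = 1.5, misalignment_prob = 0.15,
                         sector_bias = list(c(60, 120, 5), c(240, 300, 5))),
    od2 = observer_model(radial_jitter_sd = 2.5, misalignment_prob = 0.15,
                         sector_bias = list(c(70, 130, 8), c(250, 310, 8)))
  )
}

#' Configuration of a synthetic tracing study
#'
#' Defaults mirror the composition of the real study: 159 images — 69
#' glaucoma and 37 normal on a Drishti-like grid, 53 diabetic retinopathy
#' (DR) on an ARIA-like grid. The Drishti preset is 724 x 486 px
#' (quarter-scale of the source 2,896 x 1,944 px images, for tractable
#' simulation); ARIA is 768 x 576 px at full scale. True discs are ellipses
#' with semi-axes 8–14% of the image width, optionally modulated by a
#' smooth low-order angular perturbation (non-elliptic discs), centered
#' near the image middle with random rotation. Sector bias is enabled for
#' glaucomatous images only, emulating PPA confusion.
#'
#' @param n_images named counts per condition.
#' @param shapes named list of `c(height, width)` grids per dataset label.
#' @param dataset_by_condition named map condition -> dataset label.
#' @param axis_frac range of true semi-axes as a fraction of image width.
#' @param center_jitter_frac the true center is the image center plus a
#'   uniform offset of at most this fraction of each dimension.
#' @param perturbation named per-condition amplitude of the non-elliptic
#'   boundary perturbation (fraction of the local ellipse radius).
#' @param observers named list of [observer_model()]s, one per rater label.
#' @param ppa_bias_conditions condition labels for which observers'
#'   `sector_bias` is active.
#' @param seed integer seed; the whole study is reproducible from it.
#' @return object of class `study_config`.
#' @export
synthetic_study_config <- function(
    n_images = c(glaucoma = 69, dr = 53, normal = 37),
    shapes = list(drishti = c(486, 724), aria = c(576, 768)),
    dataset_by_condition = c(glaucoma = "drishti", normal = "drishti",
                             dr = "aria"),
    axis_frac = c(0.08, 0.14),
    center_jitter_frac = 0.05,
    perturbation = c(glaucoma = 0.05, dr = 0.03, normal = 0.03),
    observers = .default_observers(),
    ppa_bias_conditions = "glaucoma",
    seed = 1L) {
  if (any(n_images < 0)) stop("image counts must be >= 0")
  if (length(axis_frac) != 2 || any(axis_frac <= 0) ||
      axis_frac[1] > axis_frac[2])
    stop("axis_frac must be an increasing positive range")
  stopifnot(all(names(n_images) %in% names(dataset_by_condition)))
  stopifnot(all(dataset_by_condition[names(n_images)] %in% names(shapes)))
  if (is.null(names(observers)) || any(names(observers) == ""))
    stop("observers must be a named list")
  for (o in observers)
    if (!inherits(o, "observer_model")) stop("observers must be observer_model objects")
  structure(list(n_images = n_images, shapes = shapes,
                 dataset_by_condition = dataset_by_condition,
                 axis_frac = axis_frac,
                 center_jitter_frac = center_jitter_frac,
                 perturbation = perturbation, observers = observers,
                 ppa_bias_conditions = ppa_bias_conditions,
                 seed = as.integer(seed)),
            class = "study_config")
}

# boundary radius of a (perturbed) true disc at polar angle phi (radians,
# measured with .ray_direction's convention) about the ellipse center
.true_radius <- function(params, pert, phi) {
  a <- params$semi_major; b <- params$semi_minor
  # the ray direction is (cos phi, -sin phi); express in the ellipse frame
  th <- params$rotation
  du <- cos(phi) * cos(th) + (-sin(phi)) * sin(th)
  dv <- -cos(phi) * sin(th) + (-sin(phi)) * cos(th)
  r <- 1 / sqrt((du / a)^2 + (dv / b)^2)
  if (!is.null(pert)) r <- r * (1 + pert$amp * (
    pert$w2 * cos(2 * phi + pert$ph2) + pert$w3 * cos(3 * phi + pert$ph3)))
  r
}

#' Generate one true disc
#'
#' Samples the true disc's geometry for one image from the config's ranges
#' (using the current RNG state) and rasterizes it. With zero perturbation
#' amplitude the mask is exactly [ellipse_to_mask()] of the returned
#' parameters; otherwise the boundary radius is the ellipse radius
#' modulated by a smooth low-order angular perturbation and the returned
#' `params` record the base ellipse.
#'
#' @param condition retinal condition label.
#' @param shape integer `c(height, width)`.
#' @param config a [synthetic_study_config()].
#' @return list with `params` ([ellipse_params()]), `mask`, and the
#'   perturbation descriptor `pert` (`NULL` when amplitude is 0).
#' @export
generate_true_disc <- function(condition, shape, config) {
  h <- shape[1]; w <- shape[2]
  ax <- sort(runif(2, config$axis_frac[1] * w, config$axis_frac[2] * w))
  a <- ax[2]; b <- ax[1]
  cx <- (w - 1) / 2 + runif(1, -1, 1) * config$center_jitter_frac * w
  cy <- (h - 1) / 2 + runif(1, -1, 1) * config$center_jitter_frac * h
  th <- runif(1, 0, pi)
  amp <- config$perturbation[[condition]]
  if (is.null(amp)) amp <- 0
  margin <- a * (1 + amp) + 2
  if (cx - margin < 0 || cx + margin > w - 1 ||
      cy - margin < 0 || cy + margin > h - 1)
    stop("configured disc does not fit inside the image")
  params <- ellipse_params(cx, cy, a, b, th)
  pert <- NULL
  if (amp > 0) {
    w2 <- runif(1)
    pert <- list(amp = amp, w2 = w2, w3 = 1 - w2,
                 ph2 = runif(1, 0, 2 * pi), ph3 = runif(1, 0, 2 * pi))
    mask <- .rasterize_polar_disc(params, pert, shape)
  } else {
    mask <- ellipse_to_mask(params, shape)
  }
  list(params = params, mask = mask, pert = pert)
}

# pixel is foreground iff its distance from the center is <= the perturbed
# boundary radius at the pixel's polar angle
.rasterize_polar_disc <- function(params, pert, shape) {
  h <- shape[1]; w <- shape[2]
  R <- params$semi_major * (1 + abs(pert$amp)) + 1
  x0 <- max(0, floor(params$cx - R)); x1 <- min(w - 1, ceiling(params$cx + R))
  y0 <- max(0, floor(params$cy - R)); y1 <- min(h - 1, ceiling(params$cy + R))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - params$cx)
  dy <- outer(ys - params$cy, rep(1, length(xs)))
  # .ray_direction uses (cos phi, -sin phi), so phi = atan2(-dy, dx)
  phi <- atan2(-dy, dx)
  r <- sqrt(dx^2 + dy^2)
  mask <- matrix(FALSE, h, w)
  mask[ys + 1, xs + 1] <- r <= .true_radius(params, pert, phi)
  mask
}

.circular_smooth <- function(x, window) {
  if (window <= 1) return(x)
  k <- (window - 1) / 2
  n <- length(x)
  xp <- c(tail(x, k), x, head(x, k))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(k + 1):(k + n)]
}

#' Simulate one rater's tracing of a true disc
#'
#' Samples the true boundary at 1 degree steps by radial ray casting from
#' the true center, then applies the observer model (jitter, sector bias if
#' the condition enables it, at most one misaligned arc, smoothing; see
#' [observer_model()]). Uses the current RNG state.
#'
#' @param true_mask the true disc mask.
#' @param true_params the true disc's [ellipse_params()] (supplies the
#'   center and a ray-length bound).
#' @param observer an [observer_model()].
#' @param condition the image's retinal condition label.
#' @param bias_enabled logical: is this condition in the study's
#'   `ppa_bias_conditions`?
#' @return a closed [polyline()] with one vertex per degree.
#' @export
simulate_tracing <- function(true_mask, true_params, observer,
                             condition = "normal", bias_enabled = FALSE) {
  angles <- 0:359
  center <- c(true_params$cx, true_params$cy)
  max_r <- true_params$semi_major * 1.6 + 8
  r <- .radial_distances(.as_mask(true_mask), center, angles, max_r = max_r)
  if (anyNA(r)) stop("true mask is not star-shaped about its center")
  if (observer$radial_jitter_sd > 0)
    r <- r + rnorm(360, 0, observer$radial_jitter_sd)
  if (bias_enabled && !is.null(observer$sector_bias)) {
    for (i in seq_len(nrow(observer$sector_bias))) {
      sb <- observer$sector_bias[i, ]
      inarc <- if (sb$start <= sb$end) angles >= sb$start & angles < sb$end
               else angles >= sb$start | angles < sb$end
      r[inarc] <- r[inarc] + sb$offset
    }
  }
  if (observer$misalignment_prob > 0 &&
      runif(1) < observer$misalignment_prob) {
    start <- sample(0:359, 1)
    idx <- (start + seq_len(observer$misalignment_arc) - 1) %% 360 + 1
    r[idx] <- r[idx] + observer$misalignment_offset
  }
  r <- .circular_smooth(r, observer$smoothing_window)
  r <- pmax(r, 1)
  dirs <- .ray_direction(angles)
  polyline(cbind(center[1] + r * dirs[, 1], center[2] + r * dirs[, 2]),
           closed = TRUE)
}

#' Generate a full synthetic study
#'
#' One [image_record()] per image: the ground-truth disc mask plus one
#' simulated tracing (polyline) per configured rater. Fully reproducible
#' from `config$seed`; image ids encode dataset and condition.
#'
#' @param config a [synthetic_study_config()].
#' @return list of [image_record()]s, with each record's true
#'   [ellipse_params()] attached as attribute `"true_params"`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "study_config"))
    stop("config must come from synthetic_study_config()")
  set.seed(config$seed)
  records <- list()
  for (condition in names(config$n_images)) {
    n <- config$n_images[[condition]]
    if (n == 0) next
    dataset <- config$dataset_by_condition[[condition]]
    shape <- config$shapes[[dataset]]
    bias_on <- condition %in% config$ppa_bias_conditions
    for (i in seq_len(n)) {
      disc <- generate_true_disc(condition, shape, config)
      tracings <- list(ground_truth = disc$mask)
      for (rater in names(config$observers)) {
        tracings[[rater]] <- simulate_tracing(
          disc$mask, disc$params, config$observers[[rater]],
          condition, bias_enabled = bias_on)
      }
      rec <- image_record(sprintf("%s_%s_%03d", dataset, condition, i),
                          dataset, condition, shape, tracings)
      attr(rec, "true_params") <- disc$params
      records[[length(records) + 1]] <- rec
    }
  }
  records
}
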