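#' Analysis options for a tracing study
#'
#' @param apply_ellipse_fit replace each rater tracing by its best-fit
#'   ellipse ([refit_tracing()]) before computing metrics.
#' @param bbox_scope `"pair"` (union box of the two masks compared — the
#'   default, self-contained per comparison) or `"all"` (union box over
#'   every tracing of the record).
#' @param bbox_margin extra margin around the box, px.
#' @param border_tolerance boundary band half-width for [border_kappa()], px.
#' @param angle_set `"uniform30"` ([angles_uniform12()]), `"printed"`
#'   ([angles_printed12()], the irregular commonly-printed 12-direction
#'   list), or a numeric vector of angles in degrees.
#' @param refit_ground_truth also refit the ground-truth tracing (off by
#'   default: the reference is treated as fixed).
#' @param seed optional seed applied by [run_study()] before analysis (the
#'   pipeline itself is deterministic; this pins any user-supplied
#'   stochastic extensions).
#' @return object of class `analysis_options`.
#' @export
analysis_options <- function(apply_ellipse_fit = FALSE,
                             bbox_scope = c("pair", "all"),
                             bbox_margin = 0,
                             border_tolerance = 2,
                             angle_set = "uniform30",
                             refit_ground_truth = FALSE,
                             seed = NULL) {
  bbox_scope <- match.arg(bbox_scope)
  if (bbox_margin < 0 || border_tolerance < 0)
    stop("margins and tolerances must be non-negative")
  angles <- if (is.numeric(angle_set)) angle_set
            else switch(match.arg(angle_set, c("uniform30", "printed")),
                        uniform30 = angles_uniform12(),
                        printed = angles_printed12())
  structure(list(apply_ellipse_fit = isTRUE(apply_ellipse_fit),
                 bbox_scope = bbox_scope, bbox_margin = bbox_margin,
                 border_tolerance = border_tolerance, angles = angles,
                 refit_ground_truth = isTRUE(refit_ground_truth),
                 seed = seed),
            class = "analysis_options")
}

# metrics for a pair of prepared masks; radial_ref is NULL, "a" or "b"
.pair_metrics <- function(mask_a, mask_b, options, radial_ref = NULL,
                          flags = character(0), all_masks = NULL,
                          band_a = NULL, band_b = NULL) {
  masks_for_box <- if (options$bbox_scope == "all" && !is.null(all_masks))
    all_masks else list(mask_a, mask_b)
  bbox <- union_bounding_box(masks_for_box, options$bbox_margin)
  region <- region_kappa(mask_a, mask_b, bbox)
  if (is.null(band_a)) band_a <- boundary_band(mask_a, options$border_tolerance)
  if (is.null(band_b)) band_b <- boundary_band(mask_b, options$border_tolerance)
  border <- region_kappa(band_a, band_b, bbox)
  radial <- NULL
  if (!is.null(radial_ref)) {
    ref <- if (radial_ref == "a") mask_a else mask_b
    test <- if (radial_ref == "a") mask_b else mask_a
    radial <- tryCatch(average_boundary_distance(ref, test, options$angles),
                       error = function(e) NULL)
    if (is.null(radial)) flags <- c(flags, "radial_undefined")
    else flags <- c(flags, radial$flags)
  }
  structure(list(dice = dice_coefficient(mask_a, mask_b),
                 region = region, border = border, radial = radial,
                 flags = unique(flags)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement: dice %.4f, kappa region %.4f, border %.4f%s>\n",
              x$dice, x$region$kappa, x$border$kappa,
              if (!is.null(x$radial)) sprintf(", mu_d %.2f px", x$radial$mu_d)
              else ""))
  invisible(x)
}

# refit a rater tracing with fallback to the raw mask
.refit_or_fallback <- function(tracing, raw_mask, shape) {
  tryCatch(list(mask = refit_tracing(tracing, shape), flag = character(0)),
           error = function(e) list(mask = raw_mask, flag = "fit_fallback"))
}

#' Compare two tracings of one image
#'
#' Converts both tracings to masks, optionally replaces rater tracings by
#' their best-fit ellipse (the ground truth is exempt unless
#' `refit_ground_truth`), and computes dice, region and border kappa over
#' the configured bounding box. The radial profile (mu_d) is computed when
#' exactly one side is `"ground_truth"` (that side supplies the centroid);
#' with `radial_reference = "first"` it is also computed for rater-vs-rater
#' pairs using `rater_a` as reference, and the choice is flagged. On a refit
#' failure the raw tracing is used and the result flagged `fit_fallback`.
#'
#' @param record an [image_record()].
#' @param rater_a,rater_b tracing labels present in the record.
#' @param options an [analysis_options()].
#' @param radial_reference `"auto"` (ground truth only), `"first"`, or
#'   `"none"`.
#' @return an `agreement_result`: `dice`, `region`, `border`, `radial`
#'   (possibly `NULL`), `flags`.
#' @export
analyze_pair <- function(record, rater_a, rater_b,
                         options = analysis_options(),
                         radial_reference = c("auto", "first", "none")) {
  radial_reference <- match.arg(radial_reference)
  for (r in c(rater_a, rater_b))
    if (!r %in% names(record$tracings))
      stop(sprintf("rater '%s' not present in record %s", r, record$image_id))
  shape <- record$shape
  flags <- character(0)
  prep <- function(label) {
    raw <- .tracing_to_mask(record$tracings[[label]], shape)
    if (!any(raw)) stop(sprintf("tracing '%s' is empty in record %s",
                                label, record$image_id))
    refit <- options$apply_ellipse_fit &&
      (label != "ground_truth" || options$refit_ground_truth)
    if (refit) {
      res <- .refit_or_fallback(record$tracings[[label]], raw, shape)
      flags <<- c(flags, res$flag)
      res$mask
    } else raw
  }
  mask_a <- prep(rater_a)
  mask_b <- prep(rater_b)
  all_masks <- NULL
  if (options$bbox_scope == "all")
    all_masks <- lapply(names(record$tracings),
                        function(l) .tracing_to_mask(record$tracings[[l]], shape))
  is_gt <- c(rater_a, rater_b) == "ground_truth"
  radial_ref <- NULL
  if (radial_reference == "auto") {
    if (sum(is_gt) == 1) radial_ref <- if (is_gt[1]) "a" else "b"
  } else if (radial_reference == "first") {
    if (sum(is_gt) == 1) radial_ref <- if (is_gt[1]) "a" else "b"
    else { radial_ref <- "a"; flags <- c(flags, paste0("mu_d_reference=", rater_a)) }
  }
  .pair_metrics(mask_a, mask_b, options, radial_ref, flags, all_masks)
}

#' Run the full agreement study
#'
#' For every image, every rater pair (`od1-od2`, `od1-gt`, `od2-gt`) is
#' analyzed in each requested fitting state; aggregates are unweighted means
#' of the per-image metrics within each (pair, dataset, fitted) and
#' (pair, condition, fitted) stratum (per-image-then-mean, matching
#' box-plot-style summaries; pixel pooling is deliberately not offered),
#' with interpretation bands attached to the aggregate kappas. For the
#' rater-vs-rater pair, mu_d uses the first rater as reference and the row
#' is flagged accordingly.
#'
#' @param records list of [image_record()]s with consistent rater labels.
#' @param options an [analysis_options()]; its `apply_ellipse_fit` flag is
#'   ignored in favour of `fitted_states`.
#' @param fitted_states logical vector: which fitting states to run
#'   (default both `FALSE` and `TRUE`, the before/after comparison).
#' @return object of class `study_report`: `per_image` (one row per image,
#'   pair and fitting state), `by_dataset`, `by_condition`, `options`.
#' @export
run_study <- function(records, options = analysis_options(),
                      fitted_states = c(FALSE, TRUE)) {
  if (length(records) == 0) stop("no records to analyze")
  if (!is.null(options$seed)) set.seed(options$seed)
  raters <- setdiff(names(records[[1]]$tracings), "ground_truth")
  if (length(raters) < 2) stop("need at least two raters besides ground_truth")
  r1 <- raters[1]; r2 <- raters[2]
  pairs <- list(c(r1, r2), c(r1, "ground_truth"), c(r2, "ground_truth"))
  pair_label <- function(p) {
    lab <- function(x) if (x == "ground_truth") "gt" else x
    paste(lab(p[1]), lab(p[2]), sep = "-")
  }

  rows <- vector("list", length(records) * length(pairs) * length(fitted_states))
  k <- 0L
  for (rec in records) {
    shape <- rec$shape
    raw <- lapply(rec$tracings, .tracing_to_mask, shape = shape)
    for (nm in names(raw))
      if (!any(raw[[nm]]))
        stop(sprintf("tracing '%s' is empty in record %s", nm, rec$image_id))
    prepared <- list(`FALSE` = list(masks = raw, flags = character(0)))
    if (any(fitted_states)) {
      masks <- raw; fl <- character(0)
      for (nm in names(raw)) {
        if (nm == "ground_truth" && !options$refit_ground_truth) next
        res <- .refit_or_fallback(rec$tracings[[nm]], raw[[nm]], shape)
        masks[[nm]] <- res$mask
        fl <- c(fl, res$flag)
      }
      prepared$`TRUE` <- list(masks = masks, flags = fl)
    }
    for (fitted in fitted_states) {
      st <- prepared[[as.character(fitted)]]
      bands <- lapply(st$masks, boundary_band,
                      tolerance = options$border_tolerance)
      for (p in pairs) {
        is_gt <- p == "ground_truth"
        radial_ref <- if (sum(is_gt) == 1) { if (is_gt[1]) "a" else "b" } else "a"
        flags <- st$flags
        if (sum(is_gt) == 0) flags <- c(flags, paste0("mu_d_reference=", p[1]))
        res <- .pair_metrics(st$masks[[p[1]]], st$masks[[p[2]]], options,
                             radial_ref, flags,
                             all_masks = st$masks,
                             band_a = bands[[p[1]]], band_b = bands[[p[2]]])
        k <- k + 1L
        rows[[k]] <- data.frame(
          image_id = rec$image_id, dataset = rec$dataset,
          condition = rec$condition, pair = pair_label(p), fitted = fitted,
          dice = res$dice, kappa_region = res$region$kappa,
          kappa_border = res$border$kappa,
          mu_d = if (is.null(res$radial)) NA_real_ else res$radial$mu_d,
          n_valid_angles = if (is.null(res$radial)) NA_integer_
                           else res$radial$n_valid,
          flags = paste(res$flags, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  per_image <- do.call(rbind, rows[seq_len(k)])
  if (all(nzchar(per_image$flags) &
          grepl("fit_fallback", per_image$flags)))
    stop("all rows are flagged fit_fallback; study report would be vacuous")

  agg <- function(group) {
    out <- per_image |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c("pair", group, "fitted")))) |>
      dplyr::summarise(
        n_images = dplyr::n(),
        dice = mean(.data$dice),
        kappa_region = mean(.data$kappa_region),
        kappa_border = mean(.data$kappa_border),
        mu_d = mean(.data$mu_d, na.rm = TRUE),
        .groups = "drop") |>
      as.data.frame()
    out$region_band <- interpret_kappa(out$kappa_region)
    out$border_band <- interpret_kappa(out$kappa_border)
    out
  }
  structure(list(per_image = per_image,
                 by_dataset = agg("dataset"),
                 by_condition = agg("condition"),
                 options = options),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d rows over %d images>\n",
              nrow(x$per_image), length(unique(x$per_image$image_id))))
  print(x$by_dataset)
  invisible(x)
}

#' Serialize a study report
#'
#' `report_markdown()` renders the aggregate tables in the familiar
#' rows-are-pairs layout with before/after-fitting blocks; `write_report()`
#' writes the per-image table (CSV) plus aggregates in the requested
#' formats.
#'
#' @param report a [run_study()] report.
#' @return `report_markdown()`: a character scalar of markdown.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "study_report"))
  fmt_block <- function(df, group) {
    strata <- unique(df[[group]])
    metrics <- c(dice = "Dice", kappa_region = "Kappa (region)",
                 kappa_border = "Kappa (border)", mu_d = "Boundary (px)")
    lines <- character(0)
    for (fitted in sort(unique(df$fitted))) {
      sub <- df[df$fitted == fitted, ]
      lines <- c(lines, sprintf("### %s ellipse fitting (by %s)",
                                if (fitted) "After" else "Before", group))
      hdr <- paste0("| Pair | ", paste(
        unlist(lapply(names(metrics), function(m)
          paste(metrics[[m]], strata))), collapse = " | "), " |")
      sep <- paste0("|", paste(rep("---", 1 + length(metrics) * length(strata)),
                               collapse = "|"), "|")
      lines <- c(lines, hdr, sep)
      for (p in unique(sub$pair)) {
        cells <- unlist(lapply(names(metrics), function(m)
          vapply(strata, function(s) {
            v <- sub[sub$pair == p & sub[[group]] == s, m]
            if (length(v) == 0 || is.na(v)) "-" else sprintf("%.3f", v)
          }, character(1))))
        lines <- c(lines, paste0("| ", p, " | ",
                                 paste(cells, collapse = " | "), " |"))
      }
      lines <- c(lines, "")
    }
    lines
  }
  paste(c("# Disc tracing agreement report", "",
          fmt_block(report$by_dataset, "dataset"),
          fmt_block(report$by_condition, "condition")),
        collapse = "\n")
}

#' @rdname report_markdown
#' @param dir output directory.
#' @param formats subset of `c("csv", "json", "markdown")`.
#' @return `write_report()`: the output directory, invisibly.
#' @export
write_report <- function(report, dir,
                         formats = c("csv", "json", "markdown")) {
  stopifnot(inherits(report, "study_report"))
  if (nrow(report$by_dataset) == 0) stop("report has empty aggregates")
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if ("csv" %in% formats) {
    utils::write.csv(report$per_image, file.path(dir, "per_image.csv"),
                     row.names = FALSE)
    utils::write.csv(report$by_dataset, file.path(dir, "by_dataset.csv"),
                     row.names = FALSE)
    utils::write.csv(report$by_condition, file.path(dir, "by_condition.csv"),
                     row.names = FALSE)
  }
  if ("json" %in% formats)
    jsonlite::write_json(list(by_dataset = report$by_dataset,
                              by_condition = report$by_condition),
                         file.path(dir, "aggregates.json"),
                         dataframe = "rows", digits = NA)
  if ("markdown" %in% formats)
    writeLines(report_markdown(report), file.path(dir, "summary.md"))
  invisible(dir)
}
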