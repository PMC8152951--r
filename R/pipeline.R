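#' Default analysis configuration
#'
#' One nested list holding every tunable of the pipeline; serializable to
#' YAML via [write_config()] so a run can be reproduced from its resolved
#' configuration.
#'
#' @param pixel_size um per pixel for segmentation (ignored for
#'   coordinate-only inputs).
#' @export
default_config <- function(pixel_size = 1) {
  list(
    soma_radius = 6,                     # um; double-positive merge radius
    segmentation = list(pixel_size = pixel_size, projection_slices = 4,
                        dog_sigma1 = 4, clahe_tile = 128, clahe_clip = 3,
                        threshold_method = "isodata", min_area = 40,
                        max_area = 400, min_circularity = 0.5,
                        max_circularity = 1.05),
    spatial = list(correction = "translation", bandwidth = NULL,
                   r_max = NULL, n_r = 100, envelope = FALSE, n_sim = 99,
                   min_points = 10),
    seed = 1L)
}

#' @param config configuration list.
#' @param path YAML file path.
#' @rdname default_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Blind a study manifest
#'
#' Assigns each image file a random numeric code so the analyst never sees
#' group identity during quantification; deterministic under the seed and
#' losslessly reversible. Codes are digit strings, so no group label can
#' leak as a substring.
#'
#' @param manifest data frame with a unique `file` column (other columns,
#'   e.g. `mouse_id` and `group`, pass through into the map only).
#' @param seed integer seed.
#' @return list with `map` (data frame `original`, `code`) and `coded`
#'   (the manifest with files replaced by codes and group columns
#'   dropped).
#' @export
blind_manifest <- function(manifest, seed = 1L) {
  stopifnot(is.data.frame(manifest), "file" %in% names(manifest))
  if (anyDuplicated(manifest$file)) stop("file names must be unique")
  n <- nrow(manifest)
  codes <- with_seed(seed, {
    repeat {
      c0 <- sprintf("IMG%07d", sample.int(9999999L, n))
      if (!anyDuplicated(c0)) break
    }
    c0
  })
  coded <- data.frame(file = codes, stringsAsFactors = FALSE)
  list(map = data.frame(original = manifest$file, code = codes,
                        stringsAsFactors = FALSE),
       coded = coded)
}

#' @param coded a coded manifest (or any data frame with a `file` column
#'   of codes).
#' @param map the map returned by [blind_manifest()].
#' @rdname blind_manifest
#' @export
unblind_manifest <- function(coded, map) {
  i <- match(coded$file, map$code)
  if (anyNA(i)) stop("unknown code in manifest")
  coded$file <- map$original[i]
  coded
}

#' Analyze one region of interest
#'
#' The per-ROI unit of the study: from either image stacks (one per
#' marker channel; segmented first) or a typed coordinate pattern,
#' computes the double-positive merge, the layer assignment and laminar
#' summary per cell type, nearest-neighbor statistics for every ordered
#' type pair, and pair correlation estimates for every type pair.
#' Failures of individual statistics (e.g. too few cells of a type) are
#' recorded per statistic, not propagated.
#'
#' @param input a typed [point_pattern()], or a named list of
#'   [image_stack()]s keyed by channel/type.
#' @param annotation a [cortical_annotation()].
#' @param config configuration list, see [default_config()].
#' @param roi_id identifier stamped into the output tables.
#' @return list with `pattern`, `laminar` (per type x layer), `nnd`
#'   (per ordered type pair), `pcf` (named list of `pcf_estimate`s),
#'   `errors` (character).
#' @export
run_roi <- function(input, annotation, config = default_config(),
                    roi_id = "roi1") {
  errors <- character(0)
  w <- annotation_window(annotation)
  if (inherits(input, "point_pattern")) {
    pat <- input
  } else if (is.list(input) && all(vapply(input, inherits, logical(1),
                                          "image_stack"))) {
    segp <- do.call(segmentation_params, config$segmentation)
    dets <- lapply(names(input), function(ch) {
      s <- input[[ch]]; s$channel_name <- ch
      segment_cells(s, segp)
    })
    names(dets) <- names(input)
    pats <- lapply(names(dets), function(ch) {
      d <- dets[[ch]]
      keep <- in_window(d$x_um, d$y_um, w)
      if (any(!keep)) errors <<- c(errors, sprintf(
        "%s: %d detections outside ROI dropped", ch, sum(!keep)))
      point_pattern(d$x_um[keep], d$y_um[keep], w,
                    type = rep(ch, sum(keep)))
    })
    pat <- if (length(pats) == 2) {
      merge_double_positive(pats[[1]], pats[[2]], config$soma_radius,
                            labels = c(names(dets),
                                       paste(names(dets), collapse = "+")))
    } else if (length(pats) == 1) pats[[1]]
    else do.call(function(...) {
      xs <- unlist(lapply(list(...), `[[`, "x"))
      ys <- unlist(lapply(list(...), `[[`, "y"))
      tp <- unlist(lapply(list(...), `[[`, "type"))
      point_pattern(xs, ys, w, type = tp)
    }, pats)
  } else stop("input must be a point_pattern or a list of image_stacks")

  types <- if (is.null(pat$type)) "all" else sort(unique(pat$type))
  pat$layer <- assign_layers(pat, annotation)

  laminar <- do.call(rbind, lapply(types, function(tp) {
    sub <- if (identical(tp, "all")) pat else subset_pattern(pat, pat$type == tp)
    ls <- laminar_summary(sub, annotation)
    cbind(roi_id = roi_id, type = tp, ls, stringsAsFactors = FALSE)
  }))

  pairs <- expand.grid(from = types, to = types, stringsAsFactors = FALSE)
  nnd_rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    ft <- pairs$from[k]; tt <- pairs$to[k]
    res <- tryCatch(nnd(pat, ft, tt), error = function(e) e)
    if (inherits(res, "error")) {
      errors <<- c(errors, sprintf("nnd %s->%s: %s", ft, tt,
                                   conditionMessage(res)))
      data.frame(roi_id = roi_id, from_type = ft, to_type = tt,
                 n = 0L, mean_nnd_um = NA_real_, sd_nnd_um = NA_real_,
                 cv = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(roi_id = roi_id, from_type = ft, to_type = tt, n = res$n,
                 mean_nnd_um = res$mean, sd_nnd_um = res$sd, cv = res$cv,
                 stringsAsFactors = FALSE)
    }
  }))

  upairs <- pairs[as.integer(factor(pairs$from, types)) <=
                    as.integer(factor(pairs$to, types)), ]
  sp <- config$spatial
  pcfs <- list()
  for (k in seq_len(nrow(upairs))) {
    ft <- upairs$from[k]; tt <- upairs$to[k]
    nm <- paste(ft, tt, sep = "-")
    est <- tryCatch(
      withCallingHandlers(
        pcf(pat, ft, tt,
            r_grid = if (!is.null(sp$r_max))
              seq(1, sp$r_max, length.out = sp$n_r),
            bandwidth = sp$bandwidth, correction = sp$correction,
            min_points = sp$min_points),
        warning = function(wn) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(est, "error")) {
      errors <- c(errors, sprintf("pcf %s: %s", nm, conditionMessage(est)))
    } else {
      if (isTRUE(sp$envelope))
        est <- csr_envelope(pat, ft, tt, n_sim = sp$n_sim,
                            seed = split_seed(config$seed, k),
                            r_grid = est$r, bandwidth = est$bandwidth,
                            correction = sp$correction)
      pcfs[[nm]] <- est
    }
  }

  list(roi_id = roi_id, pattern = pat, laminar = laminar, nnd = nnd_rows,
       pcf = pcfs, errors = errors)
}

#' Tidy scalar metrics of one ROI result
#'
#' Flattens a [run_roi()] result into long rows `(roi_id, metric, value)`
#' — densities, laminar fractions, thicknesses, mean NND and CV per type
#' pair — the unit that feeds two-level replicate averaging.
#'
#' @param roi a [run_roi()] result.
#' @return long data frame.
#' @export
roi_metrics <- function(roi) {
  lam <- roi$laminar
  rows <- rbind(
    data.frame(roi_id = roi$roi_id,
               metric = paste0("density.", lam$type, ".", lam$layer),
               value = lam$density, stringsAsFactors = FALSE),
    data.frame(roi_id = roi$roi_id,
               metric = paste0("fraction.", lam$type, ".", lam$layer),
               value = lam$fraction, stringsAsFactors = FALSE),
    data.frame(roi_id = roi$roi_id,
               metric = paste0("nnd_mean.", roi$nnd$from_type, ".",
                               roi$nnd$to_type),
               value = roi$nnd$mean_nnd_um, stringsAsFactors = FALSE),
    data.frame(roi_id = roi$roi_id,
               metric = paste0("nnd_cv.", roi$nnd$from_type, ".",
                               roi$nnd$to_type),
               value = roi$nnd$cv, stringsAsFactors = FALSE))
  rows[!duplicated(rows[c("roi_id", "metric")]), ]
}

#' Two-level replicate averaging
#'
#' Technical replicates (ROIs) are first averaged within each animal, and
#' animal means are then averaged within each group — both unweighted —
#' so every animal carries equal weight regardless of its ROI count. ROIs
#' where a metric was incomputable contribute nothing to that metric's
#' mouse mean (available-case averaging); the number of contributing ROIs
#' is reported.
#'
#' @param metrics long data frame from [roi_metrics()] (rows
#'   `roi_id, metric, value`), possibly many ROIs.
#' @param manifest data frame mapping `roi_id` to `mouse_id` and `group`.
#' @return list with `per_mouse` and `per_group` tidy tables; the
#'   per-mouse table is the unit intended for external statistical tests.
#' @export
aggregate_study <- function(metrics, manifest) {
  stopifnot(all(c("roi_id", "mouse_id", "group") %in% names(manifest)))
  if (!all(metrics$roi_id %in% manifest$roi_id))
    stop("metrics contain ROIs absent from the manifest")
  m <- merge(metrics, manifest[c("roi_id", "mouse_id", "group")],
             by = "roi_id")
  per_mouse <- stats::aggregate(value ~ group + mouse_id + metric, data = m,
                                FUN = mean, na.action = stats::na.omit)
  navail <- stats::aggregate(cbind(n_rois = !is.na(m$value)),
                             by = m[c("group", "mouse_id", "metric")],
                             FUN = sum)
  per_mouse <- merge(per_mouse, navail,
                     by = c("group", "mouse_id", "metric"))
  per_group <- stats::aggregate(value ~ group + metric, data = per_mouse,
                                FUN = mean)
  n_mice <- stats::aggregate(cbind(n_mice = per_mouse$mouse_id),
                             by = per_mouse[c("group", "metric")],
                             FUN = function(x) length(unique(x)))
  per_group <- merge(per_group, n_mice, by = c("group", "metric"))
  list(per_mouse = per_mouse[order(per_mouse$metric, per_mouse$group,
                                   per_mouse$mouse_id), ],
       per_group = per_group[order(per_group$metric, per_group$group), ])
}

#' Two-level averaging of pair correlation estimates
#'
#' ROI estimates are averaged into one curve per animal, then animal
#' curves into one per group, with [average_pcf()] at each level.
#'
#' @param estimates named list of `pcf_estimate`s, names = roi_id.
#' @param manifest data frame mapping `roi_id` to `mouse_id` and `group`.
#' @return list of `pcf_estimate`s, one per group, plus `per_mouse`.
#' @export
aggregate_pcf <- function(estimates, manifest) {
  stopifnot(all(names(estimates) %in% manifest$roi_id))
  mi <- manifest[match(names(estimates), manifest$roi_id), ]
  per_mouse <- lapply(split(estimates, mi$mouse_id), average_pcf)
  mouse_group <- manifest$group[match(names(per_mouse), manifest$mouse_id)]
  per_group <- lapply(split(per_mouse, mouse_group), average_pcf)
  list(per_mouse = per_mouse, per_group = per_group)
}
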