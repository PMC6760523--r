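#' Snap set: one field of view, one image per channel
#'
#' @param images Named list of grayscale image matrices (identical
#'   dimensions and bit depth), names among blue/green/orange/red.
#' @param exposure_s Named per-channel exposure times in seconds.
#' @param snap_id Identifier used in reports.
#' @return An object of class `snap_set`.
#' @export
snap_set <- function(images, exposure_s = NULL, snap_id = "snap") {
  if (length(images) < 1) stop("at least one channel image is required")
  if (is.null(names(images)) || !all(names(images) %in% CHANNELS))
    stop("channel images must be named among: ",
         paste(CHANNELS, collapse = ", "))
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("all channel images must share the same dimensions")
  bd <- vapply(images, image_bit_depth, 0L)
  if (length(unique(bd)) != 1)
    stop("all channel images must share the same bit depth")
  structure(list(images = images, exposure_s = exposure_s,
                 snap_id = snap_id),
            class = "snap_set")
}

#' @export
print.snap_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<snap_set> '%s': %s | %d x %d px, %d bit\n", x$snap_id,
              paste(names(x$images), collapse = "+"), d[2], d[1],
              image_bit_depth(x$images[[1]])))
  invisible(x)
}

#' Phenotype classification rule
#'
#' A rule names the channels a cell class must express
#' (`required_channels`), the channels it must not (`excluded_channels`),
#' and its minimum diameter. Rules are applied in increasing `priority`
#' order; a component claimed by a higher-priority rule is withheld from
#' lower-priority rules.
#'
#' @param label Phenotype label.
#' @param required_channels Character vector of required channels
#'   (non-empty).
#' @param excluded_channels Character vector of excluded channels
#'   (disjoint from required).
#' @param min_diameter_um Minimum cell diameter in micrometres (> 0).
#' @param priority Integer; lower values are assigned first.
#' @return An object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(label, required_channels,
                           excluded_channels = character(),
                           min_diameter_um, priority = 1L) {
  if (length(required_channels) < 1) stop("'required_channels' is empty")
  if (!all(c(required_channels, excluded_channels) %in% CHANNELS))
    stop("unknown channel in rule '", label, "'")
  if (length(intersect(required_channels, excluded_channels)))
    stop("required and excluded channels overlap in rule '", label, "'")
  if (min_diameter_um <= 0) stop("'min_diameter_um' must be positive")
  structure(list(label = label,
                 required_channels = unique(required_channels),
                 excluded_channels = unique(excluded_channels),
                 min_diameter_um = min_diameter_um,
                 priority = as.integer(priority)),
            class = "phenotype_rule")
}

#' @export
print.phenotype_rule <- function(x, ...) {
  cat(sprintf("<phenotype_rule> %s: +[%s] -[%s] >= %.3g um (priority %d)\n",
              x$label, paste(x$required_channels, collapse = ","),
              paste(x$excluded_channels, collapse = ","),
              x$min_diameter_um, x$priority))
  invisible(x)
}

#' Default classification rule sets
#'
#' `"four_color"`: a CTC is a nucleated (blue) cell expressing cytokeratin
#' (green) and PSMA (orange) while CD45-negative (red), at least 7 um in
#' diameter; a WBC expresses blue and red, at least 2.5 um; remaining
#' blue-only objects at least 2.5 um are other nucleated cells.
#' `"two_color"`: a CTC is imaged in orange with a blue nucleus, at least
#' 7 um; remaining blue objects at least 2.5 um are nucleated cells.
#'
#' @param mode `"four_color"` or `"two_color"`.
#' @return A list of [phenotype_rule()] objects.
#' @export
default_rules <- function(mode = c("four_color", "two_color")) {
  mode <- match.arg(mode)
  if (mode == "four_color") {
    list(
      phenotype_rule("CTC", c("blue", "green", "orange"), "red", 7, 1L),
      phenotype_rule("WBC", c("blue", "red"), c("green", "orange"), 2.5, 2L),
      phenotype_rule("NUCLEATED_OTHER", "blue",
                     c("green", "orange", "red"), 2.5, 3L))
  } else {
    list(
      phenotype_rule("CTC", c("blue", "orange"), character(), 7, 1L),
      phenotype_rule("NUCLEATED", "blue", "orange", 2.5, 2L))
  }
}

#' Median filter
#'
#' Sliding-window median with edge replication; kernel 1 is the identity.
#'
#' @param image Grayscale image matrix.
#' @param kernel_px Odd window side length (>= 1).
#' @return Filtered image, same shape, dtype and bit depth.
#' @export
median_filter <- function(image, kernel_px = 3L) {
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 1 || kernel_px %% 2L == 0L)
    stop("'kernel_px' must be an odd integer >= 1")
  if (kernel_px == 1L) return(image)
  out <- .median_filter_cpp(image, kernel_px)
  new_image(out, image_bit_depth(image))
}

#' Window/level contrast stretch
#'
#' Linear intensity remapping for background reduction and contrast
#' enhancement: intensities at or below the low-percentile anchor map to
#' 0, at or above the high-percentile anchor map to the dtype maximum,
#' linearly in between. If the two anchors coincide on a non-constant
#' image, a full min/max stretch is used instead; a constant image is
#' returned unchanged. Both degenerate cases emit a warning.
#'
#' Automatic percentile anchors on an image with no real foreground would
#' place both anchors inside the background noise and amplify it to
#' foreground level; `min_span_frac` guards against this by never letting
#' the stretch window shrink below that fraction of the dtype range
#' (the high anchor is raised if needed). Set it to 0 for the pure
#' percentile mapping.
#'
#' @param image Grayscale image matrix.
#' @param low_percentile,high_percentile Anchor percentiles,
#'   `0 <= low < high <= 100`.
#' @param min_span_frac Minimum window width as a fraction of the dtype
#'   maximum (default 0.05).
#' @return Stretched image, same shape and bit depth.
#' @export
window_level <- function(image, low_percentile = 1, high_percentile = 99.5,
                         min_span_frac = 0.05) {
  if (!(low_percentile >= 0 && low_percentile < high_percentile &&
        high_percentile <= 100))
    stop("require 0 <= low_percentile < high_percentile <= 100")
  maxval <- image_max_value(image)
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: window/level left it unchanged")
    return(image)
  }
  lo <- as.numeric(quantile(image, low_percentile / 100, names = FALSE))
  hi <- as.numeric(quantile(image, high_percentile / 100, names = FALSE))
  hi <- max(hi, lo + min_span_frac * maxval)
  if (hi <= lo) {
    warning("degenerate percentile window: falling back to min/max stretch")
    lo <- rng[1]; hi <- rng[2]
  }
  out <- round((image - lo) / (hi - lo) * maxval)
  new_image(clamp(out, 0, maxval), image_bit_depth(image))
}

#' Compose a phenotype classification mask
#'
#' Pixel-to-pixel channel arithmetic according to the phenotype's
#' biological definition: the sum of the rule's required channels minus
#' the sum of its excluded channels, computed in floating point and
#' saturated to the image dtype range.
#'
#' @param snap A [snap_set()].
#' @param rule A [phenotype_rule()].
#' @return Grayscale mask image, same shape and bit depth as the inputs.
#' @export
compose_mask <- function(snap, rule) {
  chans <- c(rule$required_channels, rule$excluded_channels)
  missing <- setdiff(chans, names(snap$images))
  if (length(missing))
    stop("snap '", snap$snap_id, "' is missing channel(s): ",
         paste(missing, collapse = ", "))
  acc <- matrix(0, nrow(snap$images[[1]]), ncol(snap$images[[1]]))
  for (ch in rule$required_channels) acc <- acc + snap$images[[ch]]
  for (ch in rule$excluded_channels) acc <- acc - snap$images[[ch]]
  maxval <- image_max_value(snap$images[[1]])
  new_image(clamp(acc, 0, maxval), image_bit_depth(snap$images[[1]]))
}

#' Otsu threshold
#'
#' Histogram-based threshold selection maximising the between-class
#' variance \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}, with class 0 the
#' pixels at or below the threshold. Ties are broken by the smallest
#' threshold. A constant image yields that value with
#' `separable = FALSE` (there is no foreground to separate).
#'
#' @param image Integer-valued grayscale image matrix.
#' @return A list with elements `threshold` and `separable`.
#' @export
otsu_threshold <- function(image) {
  if (length(image) == 0) stop("empty image")
  v <- as.integer(image)
  lo <- min(v)
  if (lo == max(v))
    return(list(threshold = lo, separable = FALSE))
  counts <- as.numeric(tabulate(v - lo + 1L))
  levels <- as.numeric(seq_along(counts) - 1L + lo)
  n <- length(v)
  w0 <- cumsum(counts) / n
  m0 <- cumsum(counts * levels) / n
  mt <- m0[length(m0)]
  # candidates: thresholds below the max level (both classes non-empty)
  k <- seq_len(length(counts) - 1L)
  bcv <- (mt * w0[k] - m0[k])^2 / (w0[k] * (1 - w0[k]))
  bcv[!is.finite(bcv)] <- -Inf
  best <- which.max(bcv)  # first maximum = smallest threshold on ties
  list(threshold = levels[best], separable = TRUE)
}

#' Extract connected components from a binary mask
#'
#' 8-connected component labelling; components touching the border are
#' kept. Pixel-centre coordinates are 0-based, x = column, y = row.
#'
#' @param binary_mask Logical matrix (or 0/1 matrix) of foreground pixels.
#' @return A data frame of unlabeled detections: `centroid_x_px`,
#'   `centroid_y_px`, `area_px`, and half-open bounding box
#'   `x0, y0, x1, y1`. Zero rows for an empty mask.
#' @export
extract_components <- function(binary_mask) {
  m <- matrix(as.logical(binary_mask), nrow = nrow(binary_mask))
  lab <- .label_components_cpp(m)
  n <- attr(lab, "n")
  empty <- data.frame(centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                      area_px = integer(0), x0 = integer(0), y0 = integer(0),
                      x1 = integer(0), y1 = integer(0))
  if (n == 0) return(structure(empty, label_matrix = lab))
  idx <- which(lab > 0)
  lv <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab))        # 0-based y
  cols <- ((idx - 1L) %/% nrow(lab))       # 0-based x
  area <- tabulate(lv, n)
  df <- data.frame(
    centroid_x_px = as.numeric(rowsum(cols, lv)) / area,
    centroid_y_px = as.numeric(rowsum(rows, lv)) / area,
    area_px = as.integer(area),
    x0 = as.integer(tapply(cols, lv, min)),
    y0 = as.integer(tapply(rows, lv, min)),
    x1 = as.integer(tapply(cols, lv, max)) + 1L,
    y1 = as.integer(tapply(rows, lv, max)) + 1L)
  structure(df, label_matrix = lab)
}

#' Filter detections by pixel area
#'
#' Keeps components whose area is strictly greater than the gate
#' ("an area greater than N pixels"); order is preserved.
#'
#' @param cells Data frame of detections with an `area_px` column.
#' @param min_area_px Area gate in pixels (>= 0).
#' @return The filtered data frame.
#' @export
filter_by_area <- function(cells, min_area_px) {
  if (min_area_px < 0) stop("'min_area_px' must be >= 0")
  cells[cells$area_px > min_area_px, , drop = FALSE]
}

#' Pipeline configuration for classification
#'
#' @param median_kernel_px Median pre-filter window (odd; 1 disables).
#' @param window_low,window_high Window/level anchor percentiles.
#' @param window_min_span_frac Minimum window/level stretch window as a
#'   fraction of the dtype range (see [window_level()]).
#' @param coincidence_check Require each detection to be expressed in
#'   every required channel and dark in every excluded channel (see
#'   [classify_and_count()]).
#' @param coincidence_frac Where between the channel background (median)
#'   and the channel's Otsu threshold the required-channel expression
#'   criterion sits (0.5 = midpoint; 1 = the full Otsu threshold). A
#'   fraction below 1 keeps legitimately dim cells, whose mean can fall
#'   short of a global Otsu threshold dominated by brighter cells.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(median_kernel_px = 3L, window_low = 1,
                            window_high = 99.5, window_min_span_frac = 0.05,
                            coincidence_check = TRUE,
                            coincidence_frac = 0.5) {
  structure(list(median_kernel_px = as.integer(median_kernel_px),
                 window_low = window_low, window_high = window_high,
                 window_min_span_frac = window_min_span_frac,
                 coincidence_check = isTRUE(coincidence_check),
                 coincidence_frac = coincidence_frac),
            class = "pipeline_config")
}

#' Classify and count the cells of one snap
#'
#' The six-step recognition pipeline: (1) take the per-channel grayscale
#' images, (2) median-filter and window/level-stretch each channel,
#' (3) compose each phenotype's classification mask by channel
#' addition/subtraction, (4) Otsu-threshold the mask, (5) extract
#' 8-connected components and discriminate them by size (strictly greater
#' than the pixel area of the rule's minimum-diameter circle) and by
#' per-channel coincidence (mean intensity above the channel's Otsu
#' threshold in required channels, not above it in excluded channels),
#' and (6) label the detections. Rules are applied in priority order and
#' a component containing the centroid of a higher-priority detection is
#' withheld from lower-priority rules.
#'
#' @param snap A [snap_set()].
#' @param rules List of [phenotype_rule()] (distinct priorities).
#' @param optics An [optics_geometry()] for the um-to-pixel conversion.
#' @param config A [pipeline_config()].
#' @return A [count_report()] for this snap. The preprocessed channels,
#'   per-rule masks and thresholds are attached as attribute `"masks"`.
#' @export
classify_and_count <- function(snap, rules, optics = optics_geometry(),
                               config = pipeline_config()) {
  prio <- vapply(rules, function(r) r$priority, 0L)
  if (anyDuplicated(prio)) stop("rules must have distinct priorities")
  rules <- rules[order(prio)]
  log_params("classify_and_count", snap = snap$snap_id,
             rules = vapply(rules, function(r) r$label, ""),
             median_kernel_px = config$median_kernel_px,
             window = c(config$window_low, config$window_high))

  # (2) preprocess each channel once
  pre <- lapply(snap$images, function(img)
    window_level(median_filter(img, config$median_kernel_px),
                 config$window_low, config$window_high,
                 config$window_min_span_frac))
  pre_snap <- snap_set(pre, snap$exposure_s, snap$snap_id)
  chan_thr <- lapply(pre, otsu_threshold)

  claimed <- list()  # centroids of higher-priority detections (0-based px)
  cells <- list()
  masks <- list()
  for (rule in rules) {
    mask <- compose_mask(pre_snap, rule)                       # (3)
    ot <- otsu_threshold(mask)                                 # (4)
    masks[[rule$label]] <- list(mask = mask, threshold = ot$threshold,
                                separable = ot$separable)
    if (!ot$separable) next
    binary <- mask > ot$threshold
    comp <- extract_components(binary)                         # (5)
    lab <- attr(comp, "label_matrix")
    gate <- circle_area_px(rule$min_diameter_um, optics)
    comp <- filter_by_area(comp, gate)
    if (nrow(comp) == 0) next
    keep <- rep(TRUE, nrow(comp))
    # mean intensity per component in every channel (on preprocessed images)
    comp_ids <- which(lab > 0)
    comp_lab <- lab[comp_ids]
    means <- sapply(names(pre), function(ch)
      as.numeric(rowsum(pre[[ch]][comp_ids], comp_lab)) /
        tabulate(comp_lab, max(comp_lab)))
    if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                             dimnames = list(NULL, names(pre)))
    row_of <- as.integer(rownames(comp))
    if (config$coincidence_check) {
      for (ch in rule$required_channels) {
        bg <- stats::median(pre[[ch]])
        bound <- bg + config$coincidence_frac *
          (chan_thr[[ch]]$threshold - bg)
        keep <- keep & means[row_of, ch] > bound
      }
      for (ch in rule$excluded_channels)
        if (ch %in% colnames(means))
          keep <- keep & means[row_of, ch] <= chan_thr[[ch]]$threshold
    }
    # exclusion by centroid containment of higher-priority detections
    if (length(claimed)) {
      cl <- do.call(rbind, claimed)
      cl_lab <- lab[cbind(pmin(pmax(round(cl[, 2]), 0), nrow(lab) - 1) + 1,
                          pmin(pmax(round(cl[, 1]), 0), ncol(lab) - 1) + 1)]
      taken <- unique(cl_lab[cl_lab > 0])
      keep <- keep & !(row_of %in% taken)
    }
    comp <- comp[keep, , drop = FALSE]
    if (nrow(comp) == 0) next
    claimed <- c(claimed,
                 lapply(seq_len(nrow(comp)), function(i)
                   c(comp$centroid_x_px[i], comp$centroid_y_px[i])))
    det <- comp
    det$label <- rule$label
    det$snap_id <- snap$snap_id
    mrow <- as.integer(rownames(comp))
    for (ch in names(pre)) det[[paste0("mean_", ch)]] <- means[mrow, ch]
    rownames(det) <- NULL
    cells[[rule$label]] <- det
  }
  cells_df <- if (length(cells)) do.call(rbind, c(cells, make.row.names = FALSE))
              else NULL
  rep <- count_report(cells_df, snap_ids = snap$snap_id,
                      phenotypes = vapply(rules, function(r) r$label, ""))
  attr(rep, "masks") <- masks
  attr(rep, "preprocessed") <- pre_snap
  rep
}

#' Count report
#'
#' Aggregates detections into per-snap and total phenotype counts.
#'
#' @param cells Data frame of labeled detections (may be `NULL`/empty);
#'   needs columns `snap_id` and `label`.
#' @param snap_ids Snap identifiers covered (so empty snaps report zeros).
#' @param phenotypes Phenotype labels covered.
#' @return An object of class `count_report` with elements `per_snap`
#'   (data frame snap_id x phenotype x count), `totals` (named vector)
#'   and `cells`.
#' @export
count_report <- function(cells, snap_ids, phenotypes) {
  if (is.null(cells))
    cells <- data.frame(snap_id = character(0), label = character(0))
  per <- expand.grid(snap_id = snap_ids, phenotype = phenotypes,
                     stringsAsFactors = FALSE)
  per$count <- mapply(function(s, p)
    sum(cells$snap_id == s & cells$label == p), per$snap_id, per$phenotype)
  totals <- vapply(phenotypes, function(p) sum(per$count[per$phenotype == p]),
                   0)
  structure(list(per_snap = per, totals = totals, cells = cells),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat("<count_report>\n  totals:",
      paste(sprintf("%s=%d", names(x$totals), as.integer(x$totals)),
            collapse = "  "),
      sprintf("\n  %d snap(s), %d detections\n",
              length(unique(x$per_snap$snap_id)),
              nrow(x$cells)))
  invisible(x)
}

# Merge two count reports (concatenating snaps).
combine_reports <- function(a, b) {
  phen <- union(names(a$totals), names(b$totals))
  cells <- rbind(a$cells, b$cells)
  count_report(cells,
               snap_ids = c(unique(a$per_snap$snap_id),
                            unique(b$per_snap$snap_id)),
               phenotypes = phen)
}

#' Merged, colorized display image
#'
#' Additively blends the channel images tinted with their display colors
#' (saturating at white), and outlines each detection's bounding box in
#' its phenotype's color.
#'
#' @param snap A [snap_set()].
#' @param cells Optional data frame of labeled detections
#'   (from [classify_and_count()]'s `$cells`).
#' @param channel_colors Named list mapping channel to an RGB triplet in
#'   \[0, 1\].
#' @param phenotype_colors Named list mapping phenotype label to an RGB
#'   triplet for the outlines.
#' @return An H x W x 3 array in \[0, 1\].
#' @export
merge_colorize <- function(snap, cells = NULL,
                           channel_colors = list(
                             blue = c(0.25, 0.45, 1), green = c(0, 1, 0.2),
                             orange = c(1, 0.6, 0), red = c(1, 0.1, 0.1)),
                           phenotype_colors = list(
                             CTC = c(1, 1, 0), WBC = c(1, 0, 1),
                             NUCLEATED_OTHER = c(0, 1, 1),
                             NUCLEATED = c(0, 1, 1))) {
  d <- dim(snap$images[[1]])
  out <- array(0, c(d[1], d[2], 3))
  maxval <- image_max_value(snap$images[[1]])
  for (ch in names(snap$images)) {
    tint <- channel_colors[[ch]]
    if (is.null(tint)) stop("no display color for channel '", ch, "'")
    norm <- snap$images[[ch]] / maxval
    for (k in 1:3) out[, , k] <- out[, , k] + norm * tint[k]
  }
  out <- clamp(out, 0, 1)
  if (!is.null(cells) && nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      col <- phenotype_colors[[cells$label[i]]] %||% c(1, 1, 1)
      rr <- clamp(c(cells$y0[i], cells$y1[i] - 1) + 1, 1, d[1])
      cc <- clamp(c(cells$x0[i], cells$x1[i] - 1) + 1, 1, d[2])
      for (k in 1:3) {
        out[rr[1]:rr[2], cc, k] <- col[k]
        out[rr, cc[1]:cc[2], k] <- col[k]
      }
    }
  }
  out
}
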