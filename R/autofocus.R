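#' Brightness focus metric
#'
#' The score is the maximum pixel value after a median denoise: in-focus
#' cells concentrate their light, so brightness is maximal at the focal
#' plane (assuming the image is not over-exposed). A hot pixel is rejected
#' by the median; adding dark out-of-focus area does not change the score.
#' If the image saturates the digitiser the score is returned with
#' attribute `saturated = TRUE` and a warning, since saturation caps the
#' metric.
#'
#' @param image Grayscale image matrix.
#' @param denoise_kernel_px Odd median window (1 disables denoising).
#' @return Numeric score (with attribute `saturated`).
#' @export
brightness_metric <- function(image, denoise_kernel_px = 3L) {
  if (length(image) == 0) stop("empty image")
  den <- median_filter(image, denoise_kernel_px)
  score <- max(den)
  sat <- max(image) >= image_max_value(image)
  if (sat) warning("image saturates the digitiser; brightness metric capped")
  attr(score, "saturated") <- sat
  score
}

#' Contrast focus metric (normalised variance)
#'
#' The classical normalised-variance focus function:
#' `variance(pixels) / mean(pixels)` (population variance). Zero for a
#' constant image; a zero-mean image scores 0. Note the score scales
#' linearly under multiplication of all pixels by k > 0.
#'
#' @param image Grayscale image matrix.
#' @return Numeric score.
#' @export
contrast_metric <- function(image) {
  if (length(image) == 0) stop("empty image")
  m <- mean(image)
  if (m == 0) return(0)
  mean((image - m)^2) / m
}

#' Focus search configuration
#'
#' @param z_min_um,z_max_um Search range in micrometres (`z_min < z_max`).
#' @param n_coarse Coarse-pass acquisitions, equidistant over the full
#'   range including both endpoints (>= 2; default 15 sample pictures).
#' @param n_fine Fine-pass acquisitions around the coarse optimum
#'   (0 disables the fine pass).
#' @param fine_halfwidth_um Half-width of the fine pass; defaults to one
#'   coarse step.
#' @param metric `"brightness"` or `"contrast"`.
#' @param denoise_kernel_px Median window used by the brightness metric.
#' @return An object of class `focus_search_config`.
#' @export
focus_search_config <- function(z_min_um, z_max_um, n_coarse = 15L,
                                n_fine = 10L, fine_halfwidth_um = NULL,
                                metric = c("brightness", "contrast"),
                                denoise_kernel_px = 3L) {
  if (z_min_um >= z_max_um) stop("'z_min_um' must be < 'z_max_um'")
  if (n_coarse < 2) stop("'n_coarse' must be >= 2")
  if (n_fine < 0) stop("'n_fine' must be >= 0")
  metric <- match.arg(metric)
  step <- (z_max_um - z_min_um) / (n_coarse - 1)
  structure(list(z_min_um = z_min_um, z_max_um = z_max_um,
                 n_coarse = as.integer(n_coarse), n_fine = as.integer(n_fine),
                 fine_halfwidth_um = fine_halfwidth_um %||% step,
                 metric = metric,
                 denoise_kernel_px = as.integer(denoise_kernel_px)),
            class = "focus_search_config")
}

focus_score <- function(image, config) {
  if (config$metric == "brightness")
    as.numeric(suppressWarnings(
      brightness_metric(image, config$denoise_kernel_px)))
  else contrast_metric(image)
}

#' Two-pass brightness autofocus search
#'
#' Coarse pass: `n_coarse` equidistant acquisitions covering the full
#' predefined Z range (both endpoints included); the plane of maximum
#' score is selected. Fine pass (if `n_fine > 0`): a second equidistant
#' sweep over the coarse optimum plus/minus `fine_halfwidth_um`, clipped
#' to the range. Ties select the lowest z. Exactly `n_coarse + n_fine`
#' acquisitions are issued.
#'
#' @param acquire_fn Function `z_um -> image` (e.g. a closure over
#'   [virtual_acquire()] or a loaded stack).
#' @param config A [focus_search_config()].
#' @return An object of class `focus_result`: `best_z_um`, `metric_curve`
#'   (data frame z_um, score, stage) and `stage` (`"coarse"` or `"fine"`).
#' @export
autofocus_search <- function(acquire_fn, config) {
  log_params("autofocus_search", z_range = c(config$z_min_um, config$z_max_um),
             n_coarse = config$n_coarse, n_fine = config$n_fine,
             metric = config$metric)
  sweep <- function(zs, stage) {
    scores <- vapply(zs, function(z) {
      img <- tryCatch(acquire_fn(z), error = function(e)
        stop(sprintf("acquisition failed at z = %.4g um: %s", z,
                     conditionMessage(e))))
      focus_score(img, config)
    }, 0)
    data.frame(z_um = zs, score = scores, stage = stage)
  }
  coarse <- sweep(seq(config$z_min_um, config$z_max_um,
                      length.out = config$n_coarse), "coarse")
  best <- coarse$z_um[which.max(coarse$score)]  # first max = lowest z
  curve <- coarse
  stage <- "coarse"
  if (config$n_fine > 0) {
    lo <- max(config$z_min_um, best - config$fine_halfwidth_um)
    hi <- min(config$z_max_um, best + config$fine_halfwidth_um)
    fine <- sweep(seq(lo, hi, length.out = config$n_fine), "fine")
    curve <- rbind(curve, fine)
    cand <- rbind(coarse[which.max(coarse$score), ],
                  fine[which.max(fine$score), ])
    cand <- cand[order(-cand$score, cand$z_um), ]
    best <- cand$z_um[1]
    stage <- "fine"
  }
  structure(list(best_z_um = best, metric_curve = curve, stage = stage),
            class = "focus_result")
}

#' @export
print.focus_result <- function(x, ...) {
  cat(sprintf("<focus_result> best z = %.4g um (%s pass, %d acquisitions)\n",
              x$best_z_um, x$stage, nrow(x$metric_curve)))
  invisible(x)
}

#' Score a loaded focal stack
#'
#' Applies a focus metric to every image of a stack (as produced by
#' [render_focal_stack()] or loaded from disk) and selects the best plane;
#' ties select the lowest z.
#'
#' @param stack List of images with attribute `z_um` (or `z_um` given).
#' @param metric `"brightness"` or `"contrast"`.
#' @param z_um Optional vector of plane positions.
#' @param denoise_kernel_px Median window for the brightness metric.
#' @return A `focus_result`.
#' @export
score_stack <- function(stack, metric = c("brightness", "contrast"),
                        z_um = attr(stack, "z_um"), denoise_kernel_px = 3L) {
  metric <- match.arg(metric)
  if (is.null(z_um)) z_um <- seq_along(stack)
  cfg <- list(metric = metric, denoise_kernel_px = denoise_kernel_px)
  scores <- vapply(stack, function(img) focus_score(img, cfg), 0)
  curve <- data.frame(z_um = z_um, score = scores, stage = "stack")
  structure(list(best_z_um = z_um[which.max(scores)], metric_curve = curve,
                 stage = "stack"),
            class = "focus_result")
}
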