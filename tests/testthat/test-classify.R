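test_that("median filter matches a brute-force sliding-window oracle", {
  img <- new_image(matrix(100, 9, 9), 8L)
  expect_equal(strip_img(median_filter(img, 3)), strip_img(img))
  expect_identical(median_filter(img, 1), img)
  hot <- new_image(matrix(0, 9, 9), 8L); hot[5, 5] <- 200
  expect_true(all(median_filter(hot, 3) == 0))
  expect_error(median_filter(img, 4), "odd")
  set.seed(31)
  for (k in c(3, 5)) for (rep in 1:4) {
    r <- new_image(matrix(sample(0:255, 81, TRUE), 9, 9), 8L)
    expect_equal(strip_img(median_filter(r, k)), strip_img(oracle_median(r, k)))
  }
})

test_that("window/level maps percentile anchors to the dtype range", {
  ramp <- new_image(matrix(0:255, 16, 16), 8L)
  out <- window_level(ramp, 0, 100, min_span_frac = 0)
  expect_true(all(abs(out - ramp) <= 1))  # full-range image ~unchanged
  two <- new_image(matrix(c(10, 200), 10, 10), 8L)
  wl <- window_level(two, 0, 100, min_span_frac = 0)
  expect_setequal(unique(as.numeric(wl)), c(0, 255))
  # linear ramp with (25, 75): low quartile clipped to 0, top to 255
  mid <- window_level(ramp, 25, 75, min_span_frac = 0)
  expect_true(all(mid[ramp <= 63] == 0))
  expect_true(all(mid[ramp >= 192] == 255))
  expect_true(all(diff(mid[order(ramp)]) >= 0))  # monotone mapping
  v <- as.numeric(ramp[8, 8])
  lo <- quantile(ramp, 0.25); hi <- quantile(ramp, 0.75)
  expect_equal(as.numeric(mid[8, 8]),
               round((v - lo) / (hi - lo) * 255), ignore_attr = TRUE)
  expect_warning(window_level(new_image(matrix(7, 5, 5), 8L)), "constant")
})

test_that("window/level does not stretch pure background noise to full scale", {
  set.seed(32)
  noise <- new_image(matrix(pmax(0, round(rnorm(1e4, 9, 3))), 100, 100), 16L)
  out <- window_level(noise, 1, 99.5)  # default min_span_frac = 0.05
  expect_lt(max(out), 0.02 * 65535)
  # with the guard disabled the same image would span the full range
  out0 <- window_level(noise, 1, 99.5, min_span_frac = 0)
  expect_equal(max(out0), 65535)
})

test_that("classification masks follow saturated channel arithmetic", {
  ctc2 <- phenotype_rule("CTC", c("blue", "orange"), character(), 7)
  sn <- snap_set(list(blue = new_image(matrix(100, 2, 2), 8L),
                      orange = new_image(matrix(50, 2, 2), 8L)))
  expect_true(all(compose_mask(sn, ctc2) == 150))
  ctc4 <- phenotype_rule("CTC", c("blue", "green", "orange"), "red", 7)
  sn2 <- snap_set(list(blue = new_image(matrix(200, 2, 2), 8L),
                       green = new_image(matrix(200, 2, 2), 8L),
                       orange = new_image(matrix(200, 2, 2), 8L),
                       red = new_image(matrix(255, 2, 2), 8L)))
  expect_true(all(compose_mask(sn2, ctc4) == 255))  # saturates high
  wbc <- phenotype_rule("WBC", c("blue", "red"), c("green", "orange"), 2.5)
  px <- function(b, g, o, r)
    snap_set(list(blue = new_image(matrix(b, 1, 1), 8L),
                  green = new_image(matrix(g, 1, 1), 8L),
                  orange = new_image(matrix(o, 1, 1), 8L),
                  red = new_image(matrix(r, 1, 1), 8L)))
  expect_equal(as.numeric(compose_mask(px(100, 0, 0, 100), wbc)), 200)
  expect_equal(as.numeric(compose_mask(px(100, 200, 200, 100), wbc)), 0)
  # widened-arithmetic oracle on random 8-bit snaps
  set.seed(33)
  for (rep in 1:5) {
    imgs <- lapply(1:4, function(i)
      new_image(matrix(sample(0:255, 64, TRUE), 8, 8), 8L))
    names(imgs) <- c("blue", "green", "orange", "red")
    sn3 <- snap_set(imgs)
    want <- pmin(pmax(imgs$blue + imgs$red - imgs$green - imgs$orange,
                      0), 255)
    expect_equal(strip_img(compose_mask(sn3, wbc)), strip_img(want))
  }
  expect_error(compose_mask(sn, ctc4), "green")
})

test_that("Otsu threshold equals exhaustive between-class maximisation", {
  bi <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  res <- otsu_threshold(bi)
  expect_equal(res$threshold, 10)  # all splits tie; smallest wins
  expect_true(res$separable)
  const <- otsu_threshold(matrix(42, 5, 5))
  expect_false(const$separable)
  expect_equal(const$threshold, 42)
  expect_error(otsu_threshold(matrix(numeric(0), 0, 0)), "empty")
  set.seed(34)
  for (rep in 1:30) {
    img <- switch(1 + rep %% 3,
                  matrix(sample(0:255, 100, TRUE), 10, 10),
                  matrix(c(rpois(60, 20), rpois(40, 180)), 10, 10),
                  matrix(sample(0:15, 100, TRUE), 10, 10))
    got <- otsu_threshold(img)
    want <- oracle_otsu(img)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("component extraction matches a flood-fill oracle", {
  expect_equal(nrow(extract_components(matrix(FALSE, 5, 5))), 0)
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE; m[7:9, 6:8] <- TRUE
  comp <- extract_components(m)
  expect_equal(nrow(comp), 2)
  expect_true(all(comp$area_px == 9))
  expect_equal(comp$x1 - comp$x0, c(3, 3))
  # diagonal touching counts as one component (8-connectivity)
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_equal(nrow(extract_components(d)), 1)
  # border components are kept
  b <- matrix(FALSE, 5, 5); b[1, 1:3] <- TRUE
  expect_equal(extract_components(b)$area_px, 3L)
  # random blobs vs oracle: counts, areas and centroids
  set.seed(35)
  for (rep in 1:5) {
    r <- matrix(runif(400) < 0.35, 20, 20)
    comp <- extract_components(r)
    lab <- oracle_label(r)
    expect_equal(nrow(comp), max(lab))
    want_areas <- sort(as.numeric(table(lab[lab > 0])))
    expect_equal(sort(comp$area_px), want_areas)
    # centroid of each oracle component appears among the extracted ones
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l, arr.ind = TRUE)
      cx <- mean(idx[, 2]) - 1; cy <- mean(idx[, 1]) - 1
      expect_true(any(abs(comp$centroid_x_px - cx) < 1e-9 &
                        abs(comp$centroid_y_px - cy) < 1e-9))
    }
  }
})

test_that("area gate is strict and conservative", {
  cells <- data.frame(area_px = c(107L, 108L), id = 1:2)
  kept <- filter_by_area(cells, 107)
  expect_equal(kept$id, 2)
  expect_equal(filter_by_area(cells, 0), cells)
  expect_equal(nrow(filter_by_area(cells, Inf)), 0)
  expect_error(filter_by_area(cells, -1), "min_area_px")
  # conservation: gate 0 keeps every extracted component
  set.seed(36)
  m <- matrix(runif(400) < 0.3, 20, 20)
  comp <- extract_components(m)
  expect_equal(nrow(filter_by_area(comp, 0)), nrow(comp))
})

test_that("rule construction validates channel sets", {
  expect_error(phenotype_rule("X", character(), "red", 5), "empty")
  expect_error(phenotype_rule("X", "blue", "blue", 5), "overlap")
  expect_error(phenotype_rule("X", "blue", "red", 0), "min_diameter")
  expect_error(phenotype_rule("X", "cyan", character(), 5), "unknown")
})

test_that("the full pipeline recovers a small noise-free scene exactly", {
  opt <- optics_for(c(300, 250))
  cfg <- simulation_config(optics = opt)
  scene <- make_scene(3, 8, 12, c(300, 250), seed = 51, min_sep_um = 18)
  snap <- render_snap_set(scene, cfg, noise = FALSE, snap_id = "s1")
  rep <- suppressWarnings(classify_and_count(snap, default_rules(), opt))
  expect_equal(as.numeric(rep$totals[c("CTC", "WBC", "NUCLEATED_OTHER")]),
               c(3, 8, 12))
  expect_equal(sum(rep$per_snap$count), nrow(rep$cells))
  # every detection sits on a true cell of the same phenotype
  gt <- match_detections(rep, scene, opt)
  expect_true(all(gt$detected == gt$phenotype))
})

test_that("raising the CTC diameter gate removes CTCs without relabeling them", {
  opt <- optics_for(c(250, 200))
  cfg <- simulation_config(optics = opt)
  scene <- make_scene(3, 5, 5, c(250, 200), seed = 52, min_sep_um = 18)
  rules <- default_rules()
  rules[[1]]$min_diameter_um <- 30  # above the largest generated cell
  snap <- render_snap_set(scene, cfg, noise = FALSE)
  rep <- suppressWarnings(classify_and_count(snap, rules, opt))
  expect_equal(as.numeric(rep$totals["CTC"]), 0)
  # gated-out CTCs fail the WBC rule (green/orange exclusion): no migration
  expect_equal(as.numeric(rep$totals["WBC"]), 5)
})

test_that("counts are monotone non-increasing in the diameter gate", {
  opt <- optics_for(c(250, 200))
  cfg <- simulation_config(optics = opt)
  scene <- make_scene(0, 12, 0, c(250, 200), seed = 53, min_sep_um = 16)
  snap <- render_snap_set(scene, cfg, noise = FALSE)
  counts <- vapply(c(2.5, 6, 8, 10, 12, 14), function(d) {
    rules <- list(phenotype_rule("WBC", c("blue", "red"),
                                 c("green", "orange"), d, 1L))
    rep <- suppressWarnings(classify_and_count(snap, rules, opt))
    as.numeric(rep$totals["WBC"])
  }, 0)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 12)
})

test_that("a uniform offset below the low anchor leaves counts unchanged", {
  opt <- optics_for(c(250, 200))
  cfg <- simulation_config(optics = opt)
  scene <- make_scene(2, 6, 6, c(250, 200), seed = 54, min_sep_um = 18)
  snap <- render_snap_set(scene, cfg, noise = TRUE, seed = 54)
  rep1 <- suppressWarnings(classify_and_count(snap, default_rules(), opt))
  shifted <- snap
  shifted$images <- lapply(snap$images, function(img)
    new_image(pmin(unclass(img) + 40, 65535), 16L))
  rep2 <- suppressWarnings(classify_and_count(shifted, default_rules(), opt))
  expect_equal(rep1$totals, rep2$totals)
})

test_that("overlapping CTCs merge into a single contour", {
  opt <- optics_for(c(120, 120))
  cfg <- simulation_config(optics = opt)
  # centres closer than one cell radius: merged by the contour stage
  scene <- synthetic_scene(list(fixed_cell("CTC", 57, 60, 12),
                                fixed_cell("CTC", 62, 60, 12)), c(120, 120))
  snap <- render_snap_set(scene, cfg, noise = FALSE)
  rep <- suppressWarnings(classify_and_count(snap, default_rules(), opt))
  expect_equal(as.numeric(rep$totals["CTC"]), 1)
})

test_that("colorized merge tints, saturates and outlines deterministically", {
  img <- new_image(matrix(c(0, 128, 255, 64), 2, 2), 8L)
  sn <- snap_set(list(blue = img))
  rgb <- merge_colorize(sn, channel_colors = list(blue = c(0, 0, 1)))
  expect_equal(rgb[, , 3], unclass(img) / 255, ignore_attr = TRUE)
  expect_true(all(rgb[, , 1:2] == 0))
  zero <- snap_set(list(blue = new_image(matrix(0, 3, 3), 8L),
                        red = new_image(matrix(0, 3, 3), 8L)))
  expect_true(all(merge_colorize(zero) == 0))
  # swapping two channels permutes the corresponding color planes
  a <- new_image(matrix(sample(0:255, 16), 4, 4), 8L)
  b <- new_image(matrix(sample(0:255, 16), 4, 4), 8L)
  cols <- list(blue = c(0, 0, 1), red = c(1, 0, 0))
  r1 <- merge_colorize(snap_set(list(blue = a, red = b)),
                       channel_colors = cols)
  r2 <- merge_colorize(snap_set(list(blue = b, red = a)),
                       channel_colors = cols)
  expect_equal(r1[, , 3], r2[, , 1])
  expect_equal(r1[, , 1], r2[, , 3])
})
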