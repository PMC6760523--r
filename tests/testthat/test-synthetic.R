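test_that("scene generation is reproducible and respects requested structure", {
  expect_length(make_scene(0, 0, 0, c(100, 100), seed = 1)$cells, 0)
  s1 <- make_scene(5, 20, 30, c(500, 400), seed = 7)
  s2 <- make_scene(5, 20, 30, c(500, 400), seed = 7)
  expect_identical(ground_truth_table(s1), ground_truth_table(s2))
  gt <- ground_truth_table(s1)
  expect_equal(sum(gt$phenotype == "CTC"), 5)
  expect_equal(sum(gt$phenotype == "WBC"), 20)
  expect_equal(sum(gt$phenotype == "NUCLEATED_OTHER"), 30)
  # CTC emission pattern: blue/green/orange on, red off
  ctc <- gt[gt$phenotype == "CTC", ]
  expect_true(all(ctc$flux_blue > 0 & ctc$flux_green > 0 &
                    ctc$flux_orange > 0 & ctc$flux_red == 0))
  wbc <- gt[gt$phenotype == "WBC", ]
  expect_true(all(wbc$flux_blue > 0 & wbc$flux_red > 0 &
                    wbc$flux_green == 0 & wbc$flux_orange == 0))
  oth <- gt[gt$phenotype == "NUCLEATED_OTHER", ]
  expect_true(all(oth$flux_blue > 0 & oth$flux_green == 0 &
                    oth$flux_orange == 0 & oth$flux_red == 0))
  expect_true(all(ctc$diameter_um >= 8))
  expect_true(all(gt$x_um >= 0 & gt$x_um <= 500 &
                    gt$y_um >= 0 & gt$y_um <= 400))
  # minimum separation honoured
  s3 <- make_scene(0, 10, 10, c(300, 300), seed = 3, min_sep_um = 25)
  g3 <- ground_truth_table(s3)
  dmin <- min(dist(cbind(g3$x_um, g3$y_um)))
  expect_gt(dmin, 25)
})

test_that("infeasible packing fails with an explicit error", {
  expect_error(make_scene(0, 100, 100, c(60, 60), seed = 1,
                          min_sep_um = 30),
               "could not place")
})

test_that("phenotype-emission consistency is enforced at construction", {
  expect_error(ground_truth_cell("CTC", c(10, 10), 10,
                                 c(blue = 1, green = 1, orange = 1,
                                   red = 5)), "must not emit")
  expect_error(ground_truth_cell("WBC", c(10, 10), 8,
                                 c(blue = 1, red = 0)), "must emit")
  expect_error(ground_truth_cell("NUCLEATED_OTHER", c(10, 10), 5,
                                 c(blue = 1, green = 2, orange = 0,
                                   red = 0)), "must not emit")
})

test_that("renders obey the signal model in degenerate cases", {
  opt <- optics_for(c(60, 60))
  cam0 <- camera_spec(camera_noise_e = 0)
  cfg0 <- simulation_config(camera = cam0, optics = opt)
  empty <- synthetic_scene(list(), c(60, 60),
                           background_flux = c(blue = 0, green = 0,
                                               orange = 0, red = 0))
  img <- render_snap(empty, "blue", cfg0, noise = TRUE, seed = 5)
  expect_true(all(img == 0))
  # a WBC has zero green emission: its green render equals background-only
  wbc_scene <- synthetic_scene(list(fixed_cell("WBC", 30, 30, 9)), c(60, 60))
  cfg <- simulation_config(optics = opt)
  empty_like <- synthetic_scene(list(), c(60, 60), wbc_scene$background_flux)
  expect_equal(strip_img(render_snap(wbc_scene, "green", cfg, noise = FALSE)),
               strip_img(render_snap(empty_like, "green", cfg,
                                     noise = FALSE)))
  expect_error(render_snap(wbc_scene, "violet", cfg), "channel|arg")
  # determinism under a fixed seed
  a <- render_snap(wbc_scene, "blue", cfg, noise = TRUE, seed = 9)
  b <- render_snap(wbc_scene, "blue", cfg, noise = TRUE, seed = 9)
  expect_identical(a, b)
})

test_that("background pixel statistics match the signal and noise model", {
  opt <- optics_for(c(120, 120))  # 200 x 200 px
  cfg <- simulation_config(optics = opt)
  scene <- synthetic_scene(list(), c(120, 120),
                           background_flux = c(blue = 300, green = 0,
                                               orange = 0, red = 0))
  img <- render_snap(scene, "blue", cfg, noise = TRUE, seed = 21)
  n <- length(img)
  s <- expected_signal(300, cfg$camera, cfg$exposure_s[["blue"]])
  v <- total_noise(s, cfg$camera)^2
  expect_equal(mean(img), s, tolerance = 3 * sqrt(v / n) / s)
  expect_equal(var(as.numeric(img)), v,
               tolerance = 3 * sqrt(2 / n) + 0.1 / v)  # + quantisation
})

test_that("defocus redistributes but conserves a cell's flux", {
  opt <- optics_for(c(80, 80))
  cfg <- simulation_config(optics = opt)
  scene <- synthetic_scene(list(fixed_cell("NUCLEATED_OTHER", 40, 40, 8)),
                           c(80, 80),
                           background_flux = c(blue = 0, green = 0,
                                               orange = 0, red = 0))
  f0 <- sum(render_snap(scene, "blue", cfg, z_stage_um = 0, noise = FALSE))
  f8 <- sum(render_snap(scene, "blue", cfg, z_stage_um = 8, noise = FALSE))
  expect_equal(f8 / f0, 1, tolerance = 0.01)
  # peak amplitude strictly decreases away from focus
  peaks <- vapply(c(0, 3, 6, 12), function(z)
    max(render_snap(scene, "blue", cfg, z_stage_um = z, noise = FALSE)), 0)
  expect_true(all(diff(peaks) < 0))
})

test_that("focal stacks are equidistant, inclusive and reproducible", {
  opt <- optics_for(c(60, 60))
  cfg <- simulation_config(optics = opt)
  scene <- synthetic_scene(list(fixed_cell("CTC", 30, 30, 10)), c(60, 60))
  st <- render_focal_stack(scene, "blue", c(-10, 10), 2, cfg, noise = FALSE)
  expect_equal(attr(st, "z_um"), c(-10, 10))
  st21 <- render_focal_stack(scene, "blue", c(-10, 10), 21, cfg,
                             noise = FALSE)
  zs <- attr(st21, "z_um")
  expect_equal(diff(zs), rep(1, 20))
  peaks <- vapply(st21, max, 0)
  expect_equal(which.max(peaks), 11)  # middle image, cell at z = 0
  expect_error(render_focal_stack(scene, "blue", c(5, 5), 5, cfg), "range")
  expect_error(render_focal_stack(scene, "blue", c(-5, 5), 1, cfg),
               "n_steps")
  s1 <- render_focal_stack(scene, "blue", c(-5, 5), 3, cfg, seed = 4)
  s2 <- render_focal_stack(scene, "blue", c(-5, 5), 3, cfg, seed = 4)
  expect_identical(s1, s2)
})

test_that("virtual acquisition maps stage coordinates onto pixels", {
  ext <- c(200, 150)
  opt <- optics_for(c(48, 30))  # tile FOV 48 x 30 um, 80 x 50 px
  cfg <- simulation_config(optics = opt)
  scene <- synthetic_scene(list(fixed_cell("CTC", 100, 75, 10)), ext)
  # same position, same seed => identical tiles
  t1 <- virtual_acquire(scene, c(100, 75), 0, "blue", cfg, seed = 3)
  t2 <- virtual_acquire(scene, c(100, 75), 0, "blue", cfg, seed = 3)
  expect_identical(t1, t2)
  # a cell at the stage position appears at the image centre (within 1 px)
  tile <- virtual_acquire(scene, c(100, 75), 0, "blue", cfg, noise = FALSE)
  pk <- which(tile == max(tile), arr.ind = TRUE)
  centre <- (dim(tile) + 1) / 2
  expect_lte(abs(mean(pk[, 1]) - centre[1]), 1)
  expect_lte(abs(mean(pk[, 2]) - centre[2]), 1)
  # stepping the stage by one FOV gives abutting, non-overlapping tiles
  whole_opt <- optics_for(c(96, 30))
  whole_cfg <- simulation_config(optics = whole_opt)
  scene2 <- synthetic_scene(list(fixed_cell("WBC", 48, 15, 8)), c(96, 30))
  whole <- render_snap(scene2, "blue", whole_cfg, noise = FALSE)
  left <- virtual_acquire(scene2, c(24, 15), 0, "blue", cfg, noise = FALSE)
  right <- virtual_acquire(scene2, c(72, 15), 0, "blue", cfg, noise = FALSE)
  expect_equal(strip_img(cbind(left, right)), strip_img(whole))
  # tiles outside the extent are rejected unless explicitly allowed
  expect_error(virtual_acquire(scene, c(10, 10), 0, "blue", cfg), "outside")
  expect_silent(virtual_acquire(scene, c(10, 10), 0, "blue", cfg,
                                allow_outside = TRUE))
})
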