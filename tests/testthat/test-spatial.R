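test_that("label image container validates its rasters", {
  lab <- matrix(0L, 8, 8); lab[2:3, 2:3] <- 1L
  vm <- matrix(FALSE, 8, 8); vm[, 1] <- TRUE
  z <- matrix(0, 8, 8)
  expect_s3_class(label_image(lab, vm, list(NG2 = z), 0.5), "label_image")
  expect_error(label_image(lab, matrix(FALSE, 4, 4), list(NG2 = z), 0.5),
               "shape")
  expect_error(label_image(lab, vm, list(NG2 = matrix(0, 4, 4)), 0.5),
               "NG2")
  expect_error(label_image(lab, vm, list(NG2 = z), 0), "pixel_size_um")
  lab_gap <- lab; lab_gap[2, 2] <- 5L
  expect_error(label_image(lab_gap, vm, list(NG2 = z), 0.5), "contiguous")
})

test_that("vessel distance is the median pixel distance in micrometres", {
  img <- build_tiny_image(cells = list(cbind(5, 2:4)))
  expect_equal(vessel_distance(img, 1), 2)
  # even pixel count: mean of the central pair
  img2 <- build_tiny_image(cells = list(cbind(5, 2:5)))
  expect_equal(vessel_distance(img2, 1), 2.5)
  # cell entirely on the vessel
  img3 <- build_tiny_image(cells = list(cbind(3:4, 1)))
  expect_equal(vessel_distance(img3, 1), 0)
  # pixel size scales the answer
  img4 <- build_tiny_image(cells = list(cbind(5, 2:4)), pixel_size_um = 0.5)
  expect_equal(vessel_distance(img4, 1), 1)
  # translation invariance: shift cell and vessel together
  img5 <- build_tiny_image(cells = list(cbind(5, 5:7)), vessel_cols = 4)
  expect_equal(vessel_distance(img5, 1), 2)
  # shrinking the vessel can only increase distances
  img6 <- build_tiny_image(dim = c(12, 12), cells = list(cbind(5, 4)),
                           vessel_cols = c(1, 2))
  img7 <- build_tiny_image(dim = c(12, 12), cells = list(cbind(5, 4)),
                           vessel_cols = 1)
  expect_gte(vessel_distance(img7, 1), vessel_distance(img6, 1))
  expect_error(vessel_distance(img, 99), "label")
  no_vessel <- build_tiny_image(cells = list(cbind(5, 2:4)))
  no_vessel$vessel_mask[] <- FALSE
  expect_error(vessel_distance(no_vessel, 1), "empty")
})

test_that("state classification follows the marker/location rule", {
  z <- function() matrix(0, 20, 20)
  ng2 <- z(); asma <- z()
  lab <- matrix(0L, 20, 20)
  lab[9:11, 2:3] <- 1L    # adjacent to vessel (col 1)
  lab[9:11, 9:10] <- 2L   # far
  lab[2:4, 15:16] <- 3L   # far
  lab[15:17, 15:16] <- 4L # far, no markers -> unclassified
  ng2[lab == 1] <- 1; ng2[lab == 2] <- 1
  asma[lab == 2] <- 1; asma[lab == 3] <- 1
  vm <- matrix(FALSE, 20, 20); vm[, 1] <- TRUE
  img <- label_image(lab, vm, list(NG2 = ng2, aSMA = asma), pixel_size_um = 1)
  res <- classify_cell_states(img, thresholds = list(ng2 = 0.5, asma = 0.5))
  expect_equal(res$calls$state, c("pericyte", "intermediate", "myofibroblast",
                                  "unclassified"))
  # proportions use classified cells only and sum to one
  expect_equal(sum(res$proportions), 1)
  expect_equal(unname(res$proportions), rep(1 / 3, 3))
  img_no <- img; img_no$channels$aSMA <- NULL
  expect_error(classify_cell_states(img_no, list(ng2 = .5, asma = .5)), "aSMA")
})

test_that("noise-free synthetic tissue is classified perfectly with ordered distances", {
  sp <- generate_tissue_image(n_cells = 24,
                              intensity_params = noise_free_intensities(),
                              seed = 3)
  expect_setequal(unique(sp$truth$state),
                  c("pericyte", "intermediate", "myofibroblast"))
  res <- classify_cell_states(sp$image, thresholds = list(ng2 = 0.5, asma = 0.5))
  expect_equal(res$calls$state[sp$truth$cell_label], sp$truth$state)
  d <- tapply(res$calls$vessel_distance_um, res$calls$state, mean)
  expect_lt(d[["pericyte"]], d[["intermediate"]])
  expect_lt(d[["intermediate"]], d[["myofibroblast"]])
  # determinism
  sp2 <- generate_tissue_image(n_cells = 24,
                               intensity_params = noise_free_intensities(),
                               seed = 3)
  expect_identical(sp$image$cell_labels, sp2$image$cell_labels)
  expect_identical(sp$image$channels, sp2$image$channels)
  # degenerate mixture
  sp_all <- generate_tissue_image(n_cells = 10,
                                  state_mixture = c(pericyte = 1,
                                                    intermediate = 0,
                                                    myofibroblast = 0),
                                  seed = 4)
  expect_true(all(sp_all$truth$state == "pericyte"))
  expect_error(generate_tissue_image(n_cells = 4000, dim = c(60, 60),
                                     seed = 5, max_tries = 10), "fewer cells")
})

test_that("proximity fraction counts source pixels near the target", {
  fn <- matrix(0, 20, 20); asma <- matrix(0, 20, 20)
  asma[10, 10] <- 1
  fn[10, 11:17] <- 1  # 7 pixels at distances 1..7
  fn[1, 1:3] <- 1     # 3 pixels far away
  img <- build_tiny_image(dim = c(20, 20),
                          channels = list(FN = fn, aSMA = asma))
  thr <- list(FN = 0.5, aSMA = 0.5)
  expect_equal(proximity_fraction(img, radius_um = 7,
                                  channel_thresholds = thr), 0.7)
  # monotone non-decreasing in the radius
  fr <- vapply(c(1, 3, 5, 7, 30), function(r)
    proximity_fraction(img, radius_um = r, channel_thresholds = thr),
    numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[length(fr)], 1)
  # source entirely inside the target
  img_in <- build_tiny_image(dim = c(20, 20),
                             channels = list(FN = asma, aSMA = asma))
  expect_equal(proximity_fraction(img_in, radius_um = 2.5,
                                  channel_thresholds = thr), 1)
  # source farther than the radius from all target pixels
  expect_equal(proximity_fraction(img, radius_um = 0.5,
                                  channel_thresholds = thr), 0)
  img_none <- build_tiny_image(dim = c(20, 20),
                               channels = list(FN = matrix(0, 20, 20),
                                               aSMA = asma))
  expect_error(proximity_fraction(img_none, channel_thresholds = thr),
               "source")
})

test_that("trend test applies the linear contrast per sample", {
  states <- c("pericyte", "intermediate", "myofibroblast")
  flat <- expand.grid(sample = paste0("s", 1:4), state = states)
  flat$distance <- 5
  r <- state_trend_test(flat)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  inc <- expand.grid(sample = paste0("s", 1:5), state = states)
  inc$distance <- c(pericyte = 1, intermediate = 5,
                    myofibroblast = 20)[as.character(inc$state)] +
    rep(c(0, .1, -.1, .2, 0), 3)
  r2 <- state_trend_test(inc)
  expect_gt(r2$mean_contrast, 0)
  expect_lt(r2$p, 0.05)

  # incomplete samples are dropped with a warning
  part <- inc[!(inc$sample == "s5" & inc$state == "pericyte"), ]
  expect_warning(r3 <- state_trend_test(part), "s5")
  expect_equal(length(r3$contrasts), 4)
  expect_error(suppressWarnings(state_trend_test(inc[inc$sample %in%
    c("s1", "s2"), ])), "3")
})

test_that("fraction-vs-chance test matches the textbook t statistic", {
  x <- c(0.7, 0.75, 0.72, 0.74)
  r <- fraction_vs_chance_test(x)
  t_hand <- (mean(x) - 0.5) / (sd(x) / sqrt(length(x)))
  expect_equal(r$t, t_hand, tolerance = 1e-9)
  expect_equal(r$df, 3)

  expect_equal(fraction_vs_chance_test(c(0.5, 0.5, 0.5))$p, 1)
  deg <- fraction_vs_chance_test(c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  expect_error(fraction_vs_chance_test(0.7), "2 samples")
})
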