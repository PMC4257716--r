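test_that("alignment background is the minimum click value minus the image SD", {
  img <- matrix(c(rep(40, 98), 50, 120), 10, 10)
  pts <- point_set(c(8, 9), c(9, 9))  # pixels at values 50 and 120
  reg <- build_alignment_regions(img, pts)
  expect_equal(reg$background, 50 - sd(as.numeric(img)))
  expect_error(build_alignment_regions(img,
                                       point_set(numeric(), numeric())),
               "empty")
})

test_that("alignment regions find every maximum of a clean two-spot image", {
  # equal-amplitude spots: the alignment background (min click value
  # minus the image SD) keeps both maxima in the foreground
  sc <- generate_scene(scene_params(shape = c(64L, 64L), n_spots = 2,
                                    noise_sd = 0, min_separation = 20,
                                    amplitude_sigma = 0), seed = 3)
  # click only the global maximum; both spot maxima must still appear
  top <- truth_points(sc)[which.max(sc$truth$amplitude), , drop = FALSE]
  reg <- build_alignment_regions(sc$image, top)
  r <- match_points(point_set(reg$maxima$x, reg$maxima$y),
                    truth_points(sc), radius = 2)
  expect_equal(r$m, 2)
})

test_that("a constant image leaves every point unmoved", {
  img <- matrix(3, 12, 12)
  pts <- point_set(c(2, 7), c(2, 7))
  al <- align_points(img, pts, alignment_config("percentile", n = 0))
  expect_true(all(al$points$status == "unmoved"))
  expect_true(all(al$points$distance == 0))
})

test_that("height threshold methods follow their documented rules", {
  cfg_p <- alignment_config("percentile", n = 25)
  # linear interpolation between closest ranks
  expect_equal(compute_height_threshold(c(10, 20, 30, 40), numeric(),
                                        cfg_p), 17.5)
  cfg_iqr <- alignment_config("iqr_1_5")
  h <- c(10, 20, 30, 40)
  qs <- quantile(h, c(0.25, 0.75), names = FALSE)
  expect_equal(compute_height_threshold(h, numeric(), cfg_iqr),
               qs[1] - 1.5 * (qs[2] - qs[1]))
  cfg_sd <- alignment_config("mean_minus_k_sd", k = 2)
  expect_equal(compute_height_threshold(c(7, 7, 7), numeric(), cfg_sd), 7)
  expect_equal(compute_height_threshold(h, numeric(), cfg_sd),
               mean(h) - 2 * sd(h))
  expect_error(compute_height_threshold(numeric(), numeric(), cfg_p))
})

test_that("adaptive threshold stops before the missed fraction exceeds q", {
  maxima <- c(100, 90, 80, 70, 60)
  # top aligned, 90 missed: q = 0 must stay at the very top
  expect_equal(compute_height_threshold(c(100, 80), maxima,
                                        alignment_config("adaptive",
                                                         q = 0)), 100)
  # q = 0.5 tolerates one missed of two above 80
  expect_equal(compute_height_threshold(c(100, 80), maxima,
                                        alignment_config("adaptive",
                                                         q = 0.5)), 70)
  # everything aligned: the threshold descends to the lowest maximum
  expect_equal(compute_height_threshold(maxima, maxima,
                                        alignment_config("adaptive",
                                                         q = 0)), 60)
})

test_that("points snap to their maxima one-to-one with fallback search", {
  img <- matrix(0, 15, 15)
  img[5, 5] <- 100
  pts <- point_set(5, 4)  # one pixel off the lone maximum
  al <- align_points(img, pts, alignment_config("percentile", n = 0))
  expect_equal(al$points$status, "moved")
  expect_equal(al$points$distance, 1)
  expect_equal(c(al$points$aligned_x, al$points$aligned_y), c(4, 4))

  # two points in one region: the brighter click claims the maximum,
  # the second falls back to the next maximum within its search radius
  img2 <- matrix(0, 21, 9)
  img2[8, 5] <- 100
  img2[12, 5] <- 60
  pts2 <- point_set(c(7, 9), c(4, 4))
  al2 <- align_points(img2, pts2, alignment_config("percentile", n = 0))
  expect_equal(al2$points$status, c("moved", "moved"))
  expect_equal(al2$points$aligned_x, c(7, 11))
  # no two points share a maximum
  expect_equal(anyDuplicated(al2$points$maximum_id), 0)

  # a point already on an unassigned maximum: moved with distance 0
  al3 <- align_points(img, point_set(4, 4),
                      alignment_config("percentile", n = 0))
  expect_equal(al3$points$status, "moved")
  expect_equal(al3$points$distance, 0)
})

test_that("gating reverts assignments to maxima below the threshold", {
  img <- matrix(0, 30, 9)
  img[5, 5] <- 100
  img[15, 5] <- 90
  img[25, 5] <- 8   # insignificant bump
  pts <- point_set(c(4, 14, 24), c(4, 4, 4))
  al <- align_points(img, pts,
                     alignment_config("mean_minus_k_sd", k = 1))
  expect_equal(al$points$status, c("moved", "moved", "gated"))
  expect_equal(al$points$aligned_x[3], 24)  # reverted to the click
  expect_equal(al$points$distance[3], 0)
  expect_gt(al$threshold_used, 8)
})

test_that("jittered clicks on clean scenes recover their true maxima", {
  sc <- clean_scene(n_spots = 15, seed = 29, shape = c(96L, 96L),
                    min_separation = 12)
  truth <- truth_points(sc)
  clicks <- simulate_annotator(sc, annotator_style(jitter_sd = 1),
                               seed = 30)
  al <- align_points(sc$image, clicks,
                     alignment_config("percentile", n = 0))
  det <- find_foci(sc$image, permissive_params())
  r <- match_points(point_set(al$points$aligned_x,
                              al$points$aligned_y),
                    foci_points(det), radius = 1.5)
  expect_gte(r$m / nrow(clicks), 0.99)
  expect_lt(abs(al$mean_moved_distance - 1.25), 0.8)
})

test_that("alignment quality is scored against comparable maxima", {
  img <- matrix(0, 40, 9)
  xs <- c(5, 12, 19, 26, 33)
  img[cbind(xs, 5)] <- c(100, 95, 90, 85, 80)
  # click 4 of the 5 maxima exactly, skipping the 85 one; the lowest
  # aligned height (80) keeps all five maxima in the reference set
  pts <- point_set(xs[c(1, 2, 3, 5)] - 1, rep(4, 4))
  al <- align_points(img, pts, alignment_config("percentile", n = 0))
  expect_equal(sum(al$points$status == "moved"), 4)
  s <- assess_alignment(al)
  # 4 aligned vs 5 reference maxima, all 4 matched
  expect_equal(s$f1, 8 / 9)
  expect_output(print(al), "moved")
})
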