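test_that("a blank image yields no foci", {
  res <- find_foci(matrix(5, 20, 20), foci_params(background_spec("otsu")))
  expect_equal(nrow(res$peaks), 0)
  expect_true(all(res$labels == 0L))
})

test_that("well-separated clean spots are each recovered within a pixel", {
  sc <- clean_scene(n_spots = 10, seed = 5)
  res <- find_foci(sc$image, permissive_params())
  expect_equal(nrow(res$peaks), 10)
  r <- match_points(foci_points(res), truth_points(sc), radius = 8)
  expect_equal(r$m, 10)
  expect_true(all(r$pairs$distance <= 1))
})

test_that("peak statistics come from the unsmoothed image", {
  sc <- clean_scene(n_spots = 8, seed = 9, noise_sd = 40)
  p0 <- foci_params(background_spec("absolute", 900), min_size = 4,
                    min_height_above_saddle = 200)
  p2 <- foci_params(background_spec("absolute", 900), blur_sigma = 2,
                    min_size = 4, min_height_above_saddle = 200)
  r0 <- find_foci(sc$image, p0)
  r2 <- find_foci(sc$image, p2)
  m <- match_points(foci_points(r0), foci_points(r2), radius = 3)
  expect_gt(m$m, 5)
  # matched peaks report identical maxima from the original image
  expect_equal(r0$peaks$max_value[m$pairs$index_a],
               r2$peaks$max_value[m$pairs$index_b])
})

test_that("labelled pixels partition into the peak member sets above background", {
  sc <- clean_scene(n_spots = 8, seed = 21, noise_sd = 50)
  res <- find_foci(sc$image, permissive_params())
  lab <- res$labels
  expect_true(all(sc$image[lab > 0L] > res$background))
  areas <- tabulate(lab[lab > 0L], nbins = nrow(res$peaks))
  expect_equal(areas, res$peaks$area)
  expect_setequal(unique(as.integer(lab)), c(0L, res$peaks$id))
})

test_that("peaks are ordered by descending maximum with deterministic ties", {
  set.seed(3)
  img <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  res <- find_foci(img, foci_params())
  expect_true(all(diff(res$peaks$max_value) <= 0))
  res2 <- find_foci(img, foci_params())
  expect_identical(res$peaks, res2$peaks)
  expect_identical(res$labels, res2$labels)
})

test_that("a 2D image embedded as a single-slice 3D stack yields identical peaks", {
  sc <- clean_scene(n_spots = 6, seed = 13, noise_sd = 30)
  res2d <- find_foci(sc$image, permissive_params())
  img3 <- array(sc$image, c(dim(sc$image), 1L))
  res3d <- find_foci(img3, permissive_params())
  expect_equal(nrow(res3d$peaks), nrow(res2d$peaks))
  expect_equal(res3d$peaks$x, res2d$peaks$x)
  expect_equal(res3d$peaks$y, res2d$peaks$y)
  expect_equal(res3d$peaks$max_value, res2d$peaks$max_value)
  expect_equal(res3d$peaks$area, res2d$peaks$area)
  expect_equal(as.integer(res3d$labels), as.integer(res2d$labels))
})

test_that("the full pipeline matches the brute force on random small images", {
  set.seed(303)
  for (rep in 1:40) {
    img <- random_small_image(sample(5:12, 1), sample(5:12, 1),
                              levels = 4)
    B <- sample(c(0, 1), 1)
    f <- sample(c(0, 0.5), 1)
    min_size <- sample(c(1, 3), 1)
    mhas <- sample(c(0, 1.5), 1)
    p <- foci_params(background = B, search_fraction = f,
                     min_size = min_size,
                     min_height_above_saddle = mhas)
    res <- find_foci(img, p)
    oc <- o_find_foci(img, B = B, f = f, min_size = min_size,
                      mhas = mhas)
    expect_same_peaks(res, oc, info = paste("rep", rep))
  }
})

test_that("result accessors and methods behave", {
  sc <- clean_scene(n_spots = 5, seed = 17)
  res <- find_foci(sc$image, permissive_params())
  expect_s3_class(res, "foci_result")
  expect_identical(as.data.frame(res), res$peaks)
  pts <- foci_points(res)
  expect_s3_class(pts, "point_set")
  expect_equal(nrow(pts), 5)
  expect_output(print(res), "Foci detection result")
  expect_output(summary(res), "Area")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(res, sc$image))
})
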