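test_that("grid enumeration is the ordered cartesian product", {
  g <- foci_grid(background = list(100, 200),
                 min_size = c(1, 3, 5))
  combos <- enumerate_grid(g)
  expect_length(combos, 6)
  # singleton ranges give back exactly those values
  g1 <- foci_grid(background = list(background_spec("otsu")),
                  blur_sigma = 2, min_size = 4)
  p <- enumerate_grid(g1)[[1]]
  expect_equal(p$blur_sigma, 2)
  expect_equal(p$min_size, 4L)
  expect_equal(p$background$method, "otsu")
  # range sizes 4,5,9,10,11 multiply out to the scale used in practice
  g2 <- foci_grid(background = as.list(seq(0, 80, length.out = 4)),
                  blur_sigma = seq(0, 2, length.out = 5),
                  search_fraction = seq(0, 0.8, length.out = 9),
                  min_size = 1:10,
                  min_height_above_saddle = seq(0, 50, length.out = 11))
  expect_equal(findfoci:::grid_size(g2), 19800)
  expect_error(foci_grid(blur_sigma = numeric()), "non-empty")
})

test_that("self-consistent references are recovered with a perfect score", {
  sc <- clean_scene(n_spots = 8, seed = 19, noise_sd = 50)
  p_true <- foci_params(background_spec("otsu"), min_size = 3,
                        min_height_above_saddle = 200)
  ref <- foci_points(find_foci(sc$image, p_true))
  g <- foci_grid(background = list(background_spec("otsu")),
                 min_size = c(1, 3),
                 min_height_above_saddle = c(0, 200, 1e5))
  opt <- optimise_single(sc$image, ref, g)
  best <- opt$records[opt$records$rank == 1, ]
  expect_equal(best$jaccard, 1)
  expect_equal(best$f1, 1)
  expect_error(optimise_single(sc$image,
                               point_set(numeric(), numeric()), g),
               "empty")
})

test_that("staged caching reproduces the naive per-combination run exactly", {
  sc <- clean_scene(n_spots = 10, seed = 23, noise_sd = 80)
  ref <- truth_points(sc)
  g <- foci_grid(background = list(background_spec("otsu"),
                                   background_spec("percentile", 95)),
                 blur_sigma = c(0, 1),
                 min_size = c(1, 4),
                 min_height_above_saddle = c(0, 150))
  cached <- optimise_single(sc$image, ref, g, use_cache = TRUE)
  naive <- optimise_single(sc$image, ref, g, use_cache = FALSE)
  expect_identical(cached$records, naive$records)
  expect_identical(cached$boundary_flags, naive$boundary_flags)
})

test_that("a winner at a range edge raises that parameter's boundary flag", {
  sc <- clean_scene(n_spots = 6, seed = 37)
  ref <- truth_points(sc)
  # only huge saddle thresholds merge noise bumps away: winner sits at
  # the top of the blur range here
  g <- foci_grid(background = list(550),
                 blur_sigma = c(0, 0.5, 1),
                 min_size = c(3, 4))
  opt <- optimise_single(sc$image, ref, g)
  best <- opt$records[opt$records$rank == 1, ]
  for (p in c("blur_sigma", "min_size")) {
    at_edge <- best[[p]] %in% range(g$ranges[[p]])
    expect_equal(unname(opt$boundary_flags[p]), at_edge)
  }
})

test_that("count_combinations reproduces the binomial formula exactly", {
  expect_equal(count_combinations(21, 11), 352716)
  expect_equal(count_combinations(21, 3), 1330)
  expect_equal(count_combinations(21, 1), 21)
  expect_equal(count_combinations(21, 2), 210)
  expect_equal(count_combinations(7, 0), 1)
  expect_equal(count_combinations(50, 25), choose(50, 25))
  expect_error(count_combinations(3, 5), "exceed")
})

test_that("image subsets enumerate below the cap and sample above it", {
  all210 <- sample_image_subsets(21, 2)
  expect_length(all210, 210)
  expect_true(all(vapply(all210, length, integer(1)) == 2))
  s <- sample_image_subsets(21, 11, sample_count = 100, seed = 99)
  expect_length(s, 100)
  keys <- vapply(s, paste, "", collapse = ",")
  expect_equal(anyDuplicated(keys), 0)
  s2 <- sample_image_subsets(21, 11, sample_count = 100, seed = 99)
  expect_identical(s, s2)
  # clamping to the full enumeration
  expect_length(sample_image_subsets(5, 2, enumerate_cap = 1,
                                     sample_count = 100), 10)
})

test_that("score conversions aggregate as hand-computed", {
  sc <- clean_scene(n_spots = 5, seed = 41)
  ref <- truth_points(sc)
  g <- foci_grid(background = list(550), min_size = c(1, 3, 4),
                 metric = "f1")
  o1 <- optimise_single(sc$image, ref, g)
  # forge two per-image tables with known scores over 3 combinations
  o2 <- o1
  o1$records$f1 <- c(0.9, 0.5, 0.4)
  o2$records$f1 <- c(0.2, 0.8, 0.7)
  # raw means: 0.55, 0.65, 0.55 -> combo 2 wins
  agg_raw <- aggregate_scores(list(o1, o2), "raw")
  expect_equal(agg_raw$best_combo, 2)
  expect_equal(agg_raw$aggregated, c(0.55, 0.65, 0.55))
  # relative: (1,5/9,4/9) and (0.25,1,7/8); means favour combo 2
  agg_rel <- aggregate_scores(list(o1, o2), "relative")
  expect_equal(agg_rel$aggregated,
               c(mean(c(1, 0.25)), mean(c(5 / 9, 1)),
                 mean(c(4 / 9, 7 / 8))))
  # rank: image1 ranks (1,2,3), image2 (3,1,2) -> combo 2 wins
  agg_rank <- aggregate_scores(list(o1, o2), "rank")
  expect_equal(agg_rank$aggregated, c(2, 1.5, 2.5))
  expect_equal(agg_rank$best_combo, 2)
  # zscore agrees with direct computation
  agg_z <- aggregate_scores(list(o1, o2), "zscore")
  z <- function(s) (s - mean(s)) / sd(s)
  expect_equal(agg_z$aggregated,
               rowMeans(cbind(z(o1$records$f1), z(o2$records$f1))))
})

test_that("identical score vectors make every conversion agree", {
  sc <- clean_scene(n_spots = 5, seed = 43)
  ref <- truth_points(sc)
  g <- foci_grid(background = list(550), min_size = c(1, 4))
  o <- optimise_single(sc$image, ref, g)
  for (conv in c("raw", "relative", "zscore", "rank")) {
    agg <- aggregate_scores(list(o, o), conv)
    expect_equal(agg$best_combo,
                 aggregate_scores(list(o), "raw")$best_combo,
                 info = conv)
  }
})

test_that("multi-image training equals single-image training for one image", {
  sc <- clean_scene(n_spots = 6, seed = 47, noise_sd = 60)
  ref <- truth_points(sc)
  g <- foci_grid(background = list(background_spec("otsu")),
                 min_size = c(2, 4),
                 min_height_above_saddle = c(100, 300))
  tr <- train_multi(list(sc$image), list(ref), g)
  o <- optimise_single(sc$image, ref, g)
  expect_equal(tr$best_combo,
               o$records$combo[o$records$rank == 1])
  # image order does not matter
  sc2 <- clean_scene(n_spots = 6, seed = 48, noise_sd = 60)
  ref2 <- truth_points(sc2)
  t12 <- train_multi(list(sc$image, sc2$image), list(ref, ref2), g)
  t21 <- train_multi(list(sc2$image, sc$image), list(ref2, ref), g)
  expect_equal(t12$best_combo, t21$best_combo)
  expect_equal(t12$aggregated, t21$aggregated)
})
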