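test_that("greedy matching handles the elementary cases", {
  a <- point_set(c(1, 5, 9), c(2, 2, 2))
  r <- match_points(a, a, 8)
  expect_equal(r$m, 3)
  expect_length(r$unmatched_a, 0)
  expect_length(r$unmatched_b, 0)
  expect_true(all(r$pairs$distance == 0))

  r2 <- match_points(point_set(0, 0), point_set(20, 0), 8)
  expect_equal(r2$m, 0)

  # closest pair wins; the farther candidate stays unmatched
  r3 <- match_points(point_set(0, 0), point_set(c(3, 4), c(0, 0)), 8)
  expect_equal(r3$pairs$index_b, 1)
  expect_equal(r3$pairs$distance, 3)
  expect_equal(r3$unmatched_b, 2)

  expect_error(match_points(point_set(0, 0),
                            point_set(0, 0, 0), 8), "dimensionality")
  expect_error(match_points(a, a, 0))
})

test_that("match scores follow the Jaccard/Recall/F1 formulas", {
  mk <- function(m, na, nb) {
    structure(list(pairs = data.frame(index_a = seq_len(m),
                                      index_b = seq_len(m),
                                      distance = numeric(m)),
                   unmatched_a = seq_len(na)[-seq_len(m)],
                   unmatched_b = seq_len(nb)[-seq_len(m)],
                   n_a = na, n_b = nb, m = m, radius = 8),
              class = "match_result")
  }
  s <- match_scores(mk(1, 1, 2))
  expect_equal(s$jaccard, 0.5)
  expect_equal(s$recall_1, 1)
  expect_equal(s$recall_2, 0.5)
  expect_equal(s$f1, 2 / 3)
  expect_equal(match_scores(mk(3, 3, 3))$jaccard, 1)
  expect_equal(match_scores(mk(0, 4, 5))$f1, 0)
  # degenerate conventions
  expect_equal(match_scores(mk(0, 0, 0))$jaccard, 1)
  expect_equal(match_scores(mk(0, 0, 3))$f1, 0)
})

test_that("J = F1/(2 - F1) on randomly generated match results", {
  set.seed(404)
  for (rep in 1:50) {
    na <- sample(1:12, 1); nb <- sample(1:12, 1)
    a <- point_set(runif(na, 0, 30), runif(na, 0, 30))
    b <- point_set(runif(nb, 0, 30), runif(nb, 0, 30))
    s <- match_scores(match_points(a, b, 8))
    expect_equal(s$jaccard, s$f1 / (2 - s$f1), tolerance = 1e-12)
  }
})

test_that("greedy matching equals the sorted-edge-list oracle", {
  set.seed(505)
  for (rep in 1:60) {
    na <- sample(1:12, 1); nb <- sample(1:12, 1)
    a <- point_set(runif(na, 0, 25), runif(na, 0, 25))
    b <- point_set(runif(nb, 0, 25), runif(nb, 0, 25))
    r <- match_points(a, b, 8)
    o <- o_match(a, b, 8)
    expect_equal(r$m, nrow(o), info = paste("rep", rep))
    if (r$m) {
      p1 <- r$pairs[order(r$pairs$index_a), ]
      p2 <- o[order(o$i), ]
      expect_equal(p1$index_a, p2$i, info = paste("rep", rep))
      expect_equal(p1$index_b, p2$j, info = paste("rep", rep))
    }
    # symmetry up to swapping roles
    rs <- match_points(b, a, 8)
    expect_equal(rs$m, r$m)
    if (r$m) {
      sw <- data.frame(index_a = r$pairs$index_b,
                       index_b = r$pairs$index_a)
      sw <- sw[order(sw$index_a, sw$index_b), ]
      ps <- rs$pairs[order(rs$pairs$index_a, rs$pairs$index_b),
                     c("index_a", "index_b")]
      rownames(sw) <- rownames(ps) <- NULL
      expect_equal(ps, sw)
    }
  }
})

test_that("adding a shared point never decreases J or F1", {
  set.seed(606)
  for (rep in 1:20) {
    a <- point_set(runif(6, 0, 30), runif(6, 0, 30))
    b <- point_set(runif(8, 0, 30), runif(8, 0, 30))
    s0 <- match_scores(match_points(a, b, 8))
    p <- c(runif(1, 0, 30), runif(1, 0, 30))
    a2 <- point_set(c(a$x, p[1]), c(a$y, p[2]))
    b2 <- point_set(c(b$x, p[1]), c(b$y, p[2]))
    s1 <- match_scores(match_points(a2, b2, 8))
    expect_gte(s1$jaccard + 1e-12, s0$jaccard)
    expect_gte(s1$f1 + 1e-12, s0$f1)
  }
})

test_that("quartile scores partition a single global matching by intensity", {
  img <- matrix(0, 40, 3)
  # 8 items: 4 faint unmatched A-only points, 4 bright matched pairs
  img[cbind(seq(2, 16, by = 2), 2)] <- 10
  img[cbind(seq(22, 36, by = 2), 2)] <- 100
  a <- point_set(c(seq(1, 7, by = 2), seq(21, 27, by = 2)), rep(1, 8))
  b <- point_set(seq(21, 27, by = 2), rep(1, 4))
  qs <- quartile_scores(a, b, img, radius = 2)
  expect_equal(qs$quartiles$Q1$jaccard, 0)
  expect_equal(qs$quartiles$Q2$jaccard, 0)
  expect_equal(qs$quartiles$Q3$jaccard, 1)
  expect_equal(qs$quartiles$Q4$jaccard, 1)
  # identical sets: every quartile is perfect
  p8 <- point_set(seq(1, 36, by = 5), rep(1, 8))
  qi <- quartile_scores(p8, p8, img, radius = 2)
  for (q in qi$quartiles) expect_equal(q$jaccard, 1)
  # quartile sizes differ by at most 1
  set.seed(8)
  a2 <- point_set(runif(7, 0, 39), runif(7, 0, 2.9))
  b2 <- point_set(runif(6, 0, 39), runif(6, 0, 2.9))
  q2 <- quartile_scores(a2, b2, img, radius = 5)
  sizes <- table(q2$assignment$quartile)
  expect_lte(max(sizes) - min(sizes), 1)
  # tiny unions collapse to one group with a warning
  expect_warning(quartile_scores(point_set(1, 1), point_set(1, 1), img,
                                 radius = 2), "fewer than 4")
})

test_that("three-way greedy clustering conserves membership", {
  s <- point_set(c(2, 10, 20), c(2, 10, 20))
  cl <- greedy_cluster(list(s, s, s), radius = 8)
  expect_true(all(cl$size == 3))
  expect_equal(cl$x, s$x)

  a <- point_set(0, 0); b <- point_set(2, 0); c <- point_set(30, 0)
  cl2 <- greedy_cluster(list(a, b, c), radius = 8)
  expect_equal(sort(cl2$size), c(1, 2))
  expect_equal(cl2$x[cl2$size == 2], 1)
  expect_equal(cl2$y[cl2$size == 2], 0)
  expect_equal(sum(cl2$size), 3)

  set.seed(77)
  sets <- lapply(1:3, function(i)
    point_set(runif(5 + i, 0, 40), runif(5 + i, 0, 40)))
  cl3 <- greedy_cluster(sets, radius = 8)
  expect_equal(sum(cl3$size), sum(vapply(sets, nrow, integer(1))))
  # a different processing order still conserves membership
  cl4 <- greedy_cluster(sets, radius = 8, order = c(2, 3, 1))
  expect_equal(sum(cl4$size), sum(cl3$size))
})

test_that("cluster intensities are normalised by the image-wide median", {
  img <- matrix(0, 20, 3)
  img[5, 2] <- 10
  img[15, 2] <- 30
  a <- point_set(c(4, 14), c(1, 1))
  b <- point_set(c(4, 14), c(1, 1))
  c <- point_set(c(4, 14), c(1, 1))
  cl <- cluster_intensity(greedy_cluster(list(a, b, c), radius = 2), img)
  expect_equal(sort(cl$mean_intensity), c(10, 30))
  expect_equal(sort(cl$normalized_intensity), c(0.5, 1.5))
  # single-member clusters: median of normalised values is 1
  far <- point_set(c(2, 10, 18), c(1, 1, 1))
  img2 <- matrix(0, 20, 3)
  img2[cbind(c(3, 11, 19), 2)] <- c(5, 20, 80)
  cl2 <- cluster_intensity(
    greedy_cluster(list(far, point_set(numeric(), numeric()),
                        point_set(numeric(), numeric())), radius = 1),
    img2)
  expect_equal(median(cl2$normalized_intensity), 1)
})
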