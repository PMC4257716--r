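#' Greedy closest-pair matching of two point sets
#'
#' Iteratively assigns the closest cross-set pairs as matches, up to the
#' given radius: among all unmatched pairs within `radius`, the pair
#' with the smallest Euclidean distance is committed, repeatedly, until
#' none remain. Distance ties are broken by the smaller index in `a`,
#' then the smaller index in `b`, making the pairing deterministic.
#'
#' @param a,b point sets ([point_set()] or data frames with x, y\[, z\])
#'   of equal dimensionality.
#' @param radius maximum pairing distance in pixels (> 0); 8 px is the
#'   conventional comparison radius for ~5-px-wide foci.
#' @return object of class `match_result`: `pairs` (data.frame
#'   `index_a`, `index_b`, `distance`), `unmatched_a`, `unmatched_b`
#'   (index vectors), counts `n_a`, `n_b`, `m`, and `radius`.
#' @export
match_points <- function(a, b, radius = 8) {
  stopifnot(radius > 0)
  if (point_dims(a) != point_dims(b))
    stop("point sets have different dimensionality", call. = FALSE)
  na <- nrow(a); nb <- nrow(b)
  pairs <- data.frame(index_a = integer(), index_b = integer(),
                      distance = numeric())
  if (na > 0L && nb > 0L) {
    cols <- intersect(c("x", "y", "z"), names(a))
    ma <- as.matrix(a[, cols, drop = FALSE])
    mb <- as.matrix(b[, cols, drop = FALSE])
    d2 <- outer(rowSums(ma^2), rep(1, nb)) +
      outer(rep(1, na), rowSums(mb^2)) - 2 * ma %*% t(mb)
    D <- sqrt(pmax(d2, 0))
    D[D > radius] <- Inf
    repeat {
      mval <- min(D)
      if (!is.finite(mval)) break
      hit <- which(D == mval, arr.ind = TRUE)
      hit <- hit[order(hit[, 1L], hit[, 2L])[1L], , drop = FALSE]
      i <- hit[1L, 1L]; j <- hit[1L, 2L]
      pairs <- rbind(pairs, data.frame(index_a = i, index_b = j,
                                       distance = mval))
      D[i, ] <- Inf
      D[, j] <- Inf
    }
  }
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(na), pairs$index_a),
                 unmatched_b = setdiff(seq_len(nb), pairs$index_b),
                 n_a = na, n_b = nb, m = nrow(pairs), radius = radius),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Point match: ", x$m, " pairs within ", x$radius, " px (|A| = ",
      x$n_a, ", |B| = ", x$n_b, ")\n", sep = "")
  invisible(x)
}

scores_from_counts <- function(m, n_a, n_b) {
  if (n_a == 0L && n_b == 0L) {
    s <- list(jaccard = 1, recall_1 = 1, recall_2 = 1, f1 = 1)
  } else if (n_a == 0L || n_b == 0L) {
    s <- list(jaccard = 0, recall_1 = 0, recall_2 = 0, f1 = 0)
  } else {
    s <- list(jaccard = m / (n_a + n_b - m),
              recall_1 = m / n_a,
              recall_2 = m / n_b,
              f1 = 2 * m / (n_a + n_b))
  }
  structure(c(s, list(m = m, n_a = n_a, n_b = n_b)),
            class = "match_scores")
}

#' Concordance scores for a match
#'
#' For `m` matched pairs between sets of sizes `n_A` and `n_B`:
#' Jaccard `J = m / (n_A + n_B - m)`, `Recall_1 = m / n_A`,
#' `Recall_2 = m / n_B`, and `F1 = 2m / (n_A + n_B)` (the equal-weight
#' combination of the two recalls); `J = F1 / (2 - F1)` always holds.
#' Degenerate conventions: both sets empty scores 1 everywhere (vacuous
#' agreement); exactly one empty scores 0 everywhere.
#'
#' @param r a `match_result` from [match_points()].
#' @return object of class `match_scores` with elements `jaccard`,
#'   `recall_1`, `recall_2`, `f1` and the counts `m`, `n_a`, `n_b`.
#' @export
match_scores <- function(r) {
  stopifnot(inherits(r, "match_result"))
  scores_from_counts(r$m, r$n_a, r$n_b)
}

#' @export
print.match_scores <- function(x, ...) {
  cat(sprintf("J = %.4f  R1 = %.4f  R2 = %.4f  F1 = %.4f  (m = %d)\n",
              x$jaccard, x$recall_1, x$recall_2, x$f1, x$m))
  invisible(x)
}

#' Match concordance by intensity quartile
#'
#' Matches the two sets once on the full data, then partitions that
#' single global matching by intensity: the union of all points (each
#' matched pair counted once at the mean of its two endpoints' pixel
#' values, each unmatched point at its own pixel value) is ranked by
#' intensity (ties by insertion order: pairs in match order, then
#' unmatched a, then unmatched b) and cut into four groups of as equal
#' count as possible, Q1 (lowest) to Q4 (highest). Match statistics are
#' then recomputed within each group.
#'
#' @param a,b point sets within the image bounds.
#' @param image intensity image supplying pixel values.
#' @param radius matching radius in pixels.
#' @return list with `quartiles` (list of four `match_scores`),
#'   `overall` (the full-set `match_scores`) and `assignment`
#'   (data.frame of union items with intensity and quartile). When the
#'   union holds fewer than four items all items fall in one group, with
#'   a warning.
#' @export
quartile_scores <- function(a, b, image, radius = 8) {
  r <- match_points(a, b, radius)
  va <- point_values(a, image)
  vb <- point_values(b, image)
  items <- rbind(
    if (r$m) data.frame(type = "pair",
                        intensity = (va[r$pairs$index_a] +
                                     vb[r$pairs$index_b]) / 2)
    else NULL,
    if (length(r$unmatched_a))
      data.frame(type = "a", intensity = va[r$unmatched_a]) else NULL,
    if (length(r$unmatched_b))
      data.frame(type = "b", intensity = vb[r$unmatched_b]) else NULL)
  n <- nrow(items)
  if (n == 0L)
    return(list(quartiles = rep(list(scores_from_counts(0, 0, 0)), 4),
                overall = match_scores(r), assignment = items))
  ngroup <- if (n < 4L) 1L else 4L
  if (n < 4L)
    warning("fewer than 4 points in the union; single-group fallback")
  ord <- order(items$intensity, seq_len(n))
  q <- integer(n)
  q[ord] <- ceiling(ngroup * seq_len(n) / n)
  items$quartile <- q
  quart <- lapply(seq_len(4L), function(g) {
    sub <- items$quartile == (if (ngroup == 1L) 1L else g)
    if (ngroup == 1L && g > 1L) sub <- rep(FALSE, n)
    m <- sum(sub & items$type == "pair")
    n_a <- m + sum(sub & items$type == "a")
    n_b <- m + sum(sub & items$type == "b")
    scores_from_counts(m, n_a, n_b)
  })
  names(quart) <- paste0("Q", 1:4)
  list(quartiles = quart, overall = match_scores(r), assignment = items)
}

#' Greedy three-way clustering of annotations
#'
#' Clusters point annotations from three annotators: the first two sets
#' are matched within `radius`; matched pairs become size-2 clusters at
#' the mean coordinate and singletons size-1 clusters. The cluster
#' centroids are then matched against the third set; matched clusters
#' gain the third point and re-average their centroid, unmatched
#' third-set points become size-1 clusters. Total membership is
#' conserved: cluster sizes sum to `n_1 + n_2 + n_3`.
#'
#' @param sets list of three point sets.
#' @param radius matching radius in pixels.
#' @param order permutation of 1:3 giving the processing order.
#' @return data.frame with `size` and centroid coordinates `x`,
#'   `y`\[, `z`\]; the `"members"` attribute lists each cluster's member
#'   coordinate matrix.
#' @export
greedy_cluster <- function(sets, radius = 8, order = c(1, 2, 3)) {
  stopifnot(length(sets) == 3L, radius > 0,
            setequal(order, 1:3))
  sets <- sets[order]
  cols <- intersect(c("x", "y", "z"), names(sets[[1L]]))
  mt <- lapply(sets, function(s) as.matrix(s[, cols, drop = FALSE]))
  r12 <- match_points(sets[[1L]], sets[[2L]], radius)
  members <- list()
  for (i in seq_len(r12$m))
    members[[length(members) + 1L]] <-
      rbind(mt[[1L]][r12$pairs$index_a[i], ], mt[[2L]][r12$pairs$index_b[i], ])
  for (i in r12$unmatched_a)
    members[[length(members) + 1L]] <- mt[[1L]][i, , drop = FALSE]
  for (i in r12$unmatched_b)
    members[[length(members) + 1L]] <- mt[[2L]][i, , drop = FALSE]
  cent <- do.call(rbind, lapply(members, colMeans))
  cent_set <- if (length(cols) == 3L)
    point_set(cent[, 1L], cent[, 2L], cent[, 3L])
  else point_set(cent[, 1L], cent[, 2L])
  r3 <- match_points(cent_set, sets[[3L]], radius)
  for (i in seq_len(r3$m)) {
    ci <- r3$pairs$index_a[i]
    members[[ci]] <- rbind(members[[ci]], mt[[3L]][r3$pairs$index_b[i], ])
  }
  for (i in r3$unmatched_b)
    members[[length(members) + 1L]] <- mt[[3L]][i, , drop = FALSE]
  cent <- do.call(rbind, lapply(members, colMeans))
  out <- data.frame(size = vapply(members, nrow, integer(1)))
  for (k in seq_along(cols)) out[[cols[k]]] <- cent[, k]
  attr(out, "members") <- members
  out
}

#' Cluster intensity, raw and normalised
#'
#' The intensity of a cluster is the mean pixel value over its member
#' points; the normalised intensity divides that mean by the median
#' pixel value of all selected points (all cluster members) in the
#' image, so a value of 1 marks a focus of typical brightness for that
#' image.
#'
#' @param clusters result of [greedy_cluster()].
#' @param image intensity image the clusters were derived from.
#' @return `clusters` with columns `mean_intensity` and
#'   `normalized_intensity` added (empty input returns empty output).
#' @export
cluster_intensity <- function(clusters, image) {
  members <- attr(clusters, "members")
  if (is.null(members) || length(members) == 0L) {
    clusters$mean_intensity <- numeric(0)
    clusters$normalized_intensity <- numeric(0)
    return(clusters)
  }
  val_of <- function(mm) {
    cols <- colnames(mm)
    ps <- if ("z" %in% cols) point_set(mm[, 1L], mm[, 2L], mm[, 3L])
          else point_set(mm[, 1L], mm[, 2L])
    point_values(ps, image)
  }
  vals <- lapply(members, val_of)
  clusters$mean_intensity <- vapply(vals, mean, numeric(1))
  med <- median(unlist(vals))
  clusters$normalized_intensity <- clusters$mean_intensity / med
  clusters
}
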