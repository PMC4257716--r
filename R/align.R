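#' Alignment threshold configuration
#'
#' Alignment of clicks to local maxima is gated by a height threshold
#' derived from the aligned maxima, so that clicks cannot snap to
#' insignificant background maxima. Methods:
#' \describe{
#'   \item{percentile}{the `n`-th percentile of the aligned-maxima
#'     heights (linear interpolation between closest ranks).}
#'   \item{iqr_1_5}{`Q1 - 1.5 * (Q3 - Q1)` of the aligned-maxima
#'     heights.}
#'   \item{mean_minus_k_sd}{mean minus `k` standard deviations of the
#'     aligned-maxima heights.}
#'   \item{adaptive}{lower the threshold from the highest maximum
#'     through every distinct maximum height while the missed fraction
#'     (non-aligned maxima at or above the threshold over all maxima at
#'     or above it) stays at most `q`; the threshold stops just before
#'     the first violation. With `q = 0` and the second-highest maximum
#'     missed, this is the height of the highest maximum — the
#'     method relies on the annotations including the most intense
#'     maximum.}
#' }
#' The default is adaptive with `q = 0.15` (accept a new maximum only
#' where at least 85% of comparable maxima were clicked) — a
#' configurable default, not a universal optimum.
#'
#' @param method one of `"percentile"`, `"iqr_1_5"`,
#'   `"mean_minus_k_sd"`, `"adaptive"`.
#' @param n percentile in \[0, 100\] (percentile method).
#' @param k non-negative factor (mean_minus_k_sd method).
#' @param q missed fraction in \[0, 1) (adaptive method).
#' @return list of class `alignment_config`.
#' @export
alignment_config <- function(method = c("adaptive", "percentile",
                                        "iqr_1_5", "mean_minus_k_sd"),
                             n = 10, k = 3, q = 0.15) {
  method <- match.arg(method)
  stopifnot(n >= 0, n <= 100, k >= 0, q >= 0, q < 1)
  structure(list(method = method, n = n, k = k, q = q),
            class = "alignment_config")
}

#' Local-maximum regions for click alignment
#'
#' Detects every local maximum relevant to a set of selected points and
#' labels the image by maximum. The background level is set to the
#' minimum pixel value of the selected points minus the standard
#' deviation of all image pixels, so all maxima near the selections are
#' found; detection runs with a minimum size of 1 pixel, no merging and
#' unrestricted expansion.
#'
#' @param image 2D/3D intensity image.
#' @param points non-empty point set within the image.
#' @return list with `maxima` (candidate table from
#'   [find_candidate_maxima()]), `labels` (region label array) and
#'   `background` (the level used).
#' @export
build_alignment_regions <- function(image, points) {
  check_image(image)
  if (nrow(points) == 0L) stop("point set is empty", call. = FALSE)
  B <- min(point_values(points, image)) - sd(as.numeric(image))
  cand <- find_candidate_maxima(image, B)
  labels <- expand_peaks(image, cand, 0, B)
  list(maxima = cand, labels = labels, background = B)
}

#' Height threshold for gated alignment
#'
#' @param heights intensities of the maxima that received an aligned
#'   point (non-empty).
#' @param maxima_heights intensities of all detected maxima (used by the
#'   adaptive method).
#' @param config an [alignment_config()].
#' @return a single threshold intensity.
#' @export
compute_height_threshold <- function(heights, maxima_heights, config) {
  if (!inherits(config, "alignment_config"))
    stop("config must come from alignment_config()", call. = FALSE)
  if (length(heights) == 0L) stop("no aligned heights", call. = FALSE)
  switch(config$method,
    percentile = quantile(heights, config$n / 100, names = FALSE, type = 7),
    iqr_1_5 = {
      qs <- quantile(heights, c(0.25, 0.75), names = FALSE, type = 7)
      qs[1L] - 1.5 * (qs[2L] - qs[1L])
    },
    mean_minus_k_sd = {
      s <- if (length(heights) > 1L) sd(heights) else 0
      mean(heights) - config$k * s
    },
    adaptive = {
      cand <- sort(unique(maxima_heights), decreasing = TRUE)
      best <- cand[1L]
      for (t in cand) {
        total <- sum(maxima_heights >= t)
        missed <- total - sum(heights >= t)
        frac <- if (total == 0L) 0 else missed / total
        if (frac > config$q) break
        best <- t
      }
      best
    })
}

#' Align annotated points to their local maxima
#'
#' Snaps each annotated point to its true local maximum. Points are
#' processed in descending order of their own pixel intensity; each is
#' assigned the maximum of the region containing it. Only one point may
#' claim each maximum: if the maximum is already taken, the distance to
#' it becomes a search radius and the highest unassigned maximum within
#' that radius is used instead; if none is available the point is left
#' unmoved. A height threshold ([compute_height_threshold()], computed
#' from a first unconstrained alignment pass) then gates the result:
#' assignments to maxima below the threshold revert to the original
#' coordinate with status `"gated"`. A point already sitting on its
#' available maximum counts as moved with distance 0.
#'
#' @param image 2D/3D intensity image.
#' @param points non-empty point set.
#' @param config an [alignment_config()].
#' @param regions optionally a precomputed [build_alignment_regions()].
#' @return object of class `foci_alignment`: data.frame `points` (per
#'   point: original and aligned coordinates, `distance`, `status` in
#'   moved/unmoved/gated, `maximum_id`), plus `threshold_used`,
#'   `mean_moved_distance`, `maxima`, `background` and `config`.
#' @export
align_points <- function(image, points, config = alignment_config(),
                         regions = NULL) {
  if (is.null(regions)) regions <- build_alignment_regions(image, points)
  maxima <- regions$maxima
  nd <- point_dims(points)
  cols <- c("x", "y", "z")[seq_len(nd)]
  pts <- as.matrix(points[, cols, drop = FALSE])
  mx <- as.matrix(maxima[, cols, drop = FALSE])
  mval <- maxima$value
  n <- nrow(pts)
  ord <- order(-point_values(points, image), seq_len(n))
  px <- point_pixels(points, dim(image))
  assigned_to <- rep(NA_integer_, n)      # maximum id per point
  taken <- rep(FALSE, nrow(maxima))
  for (i in ord) {
    lab <- regions$labels[matrix(px[i, ], 1L)]
    if (lab == 0L) next
    if (!taken[lab]) {
      assigned_to[i] <- lab
      taken[lab] <- TRUE
      next
    }
    rad <- sqrt(sum((pts[i, ] - mx[lab, ])^2))
    free <- which(!taken)
    if (!length(free)) next
    d <- sqrt(rowSums((mx[free, , drop = FALSE] -
                         matrix(pts[i, ], length(free), nd,
                                byrow = TRUE))^2))
    inr <- free[d <= rad]
    if (!length(inr)) next
    pick <- inr[order(-mval[inr], inr)[1L]]
    assigned_to[i] <- pick
    taken[pick] <- TRUE
  }
  aligned_ids <- assigned_to[!is.na(assigned_to)]
  status <- ifelse(is.na(assigned_to), "unmoved", "moved")
  threshold <- NA_real_
  if (length(aligned_ids)) {
    threshold <- compute_height_threshold(mval[aligned_ids], mval, config)
    gate <- !is.na(assigned_to) & mval[pmax(assigned_to, 1L)] < threshold
    status[gate] <- "gated"
    assigned_to[gate] <- NA_integer_
  }
  out <- as.data.frame(pts)
  names(out) <- cols
  acoord <- pts
  dist <- numeric(n)
  mv <- which(status == "moved")
  if (length(mv)) {
    acoord[mv, ] <- mx[assigned_to[mv], , drop = FALSE]
    dist[mv] <- sqrt(rowSums((acoord[mv, , drop = FALSE] -
                                pts[mv, , drop = FALSE])^2))
  }
  for (k in seq_along(cols)) out[[paste0("aligned_", cols[k])]] <- acoord[, k]
  out$distance <- dist
  out$status <- status
  out$maximum_id <- assigned_to
  structure(list(points = out, threshold_used = threshold,
                 mean_moved_distance = if (length(mv)) mean(dist[mv])
                                       else NA_real_,
                 maxima = maxima, background = regions$background,
                 config = config),
            class = "foci_alignment")
}

#' @export
print.foci_alignment <- function(x, ...) {
  tab <- table(factor(x$points$status,
                      levels = c("moved", "unmoved", "gated")))
  cat("Focus alignment: ", nrow(x$points), " points (",
      tab[["moved"]], " moved, ", tab[["unmoved"]], " unmoved, ",
      tab[["gated"]], " gated)\n", sep = "")
  cat("  threshold: ", format(x$threshold_used, digits = 6),
      ", mean moved distance: ",
      format(x$mean_moved_distance, digits = 4), " px\n", sep = "")
  invisible(x)
}

#' Assess an alignment against the detectable maxima
#'
#' Compares the aligned points to all potential maxima at least as high
#' as the lowest aligned focus, by greedy matching; the F1 (and
#' companions) measure how completely the annotator covered the maxima
#' that the alignment deems significant.
#'
#' @param result a `foci_alignment` with at least one aligned point.
#' @param radius matching radius in pixels.
#' @return a `match_scores`.
#' @export
assess_alignment <- function(result, radius = 8) {
  pts <- result$points
  mv <- pts$status == "moved"
  if (!any(mv)) stop("no aligned points; scores undefined", call. = FALSE)
  mval <- result$maxima$value
  lowest <- min(mval[pts$maximum_id[mv]])
  ref_idx <- which(mval >= lowest)
  nd <- if ("z" %in% names(result$maxima)) 3L else 2L
  mk <- function(df, idx, pre = "") {
    cl <- paste0(pre, c("x", "y", "z")[seq_len(nd)])
    if (nd == 3L) point_set(df[[cl[1]]][idx], df[[cl[2]]][idx],
                            df[[cl[3]]][idx])
    else point_set(df[[cl[1]]][idx], df[[cl[2]]][idx])
  }
  aligned <- mk(pts, which(mv), pre = "aligned_")
  ref <- mk(result$maxima, ref_idx)
  match_scores(match_points(aligned, ref, radius))
}
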