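#' Detect foci in an image
#'
#' Runs the full detection pipeline: Gaussian blur, background
#' estimation, candidate maxima, uphill-gradient expansion, saddle
#' computation, three-stage merging and focus filtering. Detection
#' (candidates, expansion, saddles, merge decisions) operates on the
#' smoothed image when `blur_sigma > 0`; all reported peak intensity
#' statistics (`max_value`, `total_intensity`,
#' `height_above_background`) are computed from the original, unsmoothed
#' image. Peaks are ordered by descending `max_value`, ties by raster
#' order of the maximum pixel, and relabelled 1..k.
#'
#' @param image 2D matrix or 3D array of non-negative intensities.
#' @param params a [foci_params()].
#' @return object of class `foci_result`: a list with `peaks` (one row
#'   per focus: id, x/y/z and centroid coordinates (0-based), max_value,
#'   area, total_intensity, height_above_background, saddle_value,
#'   saddle_neighbour), `labels` (integer array, 0 = background),
#'   `background` (the level B used) and `params`.
#' @export
find_foci <- function(image, params = foci_params()) {
  check_image(image)
  if (!inherits(params, "foci_params"))
    stop("params must come from foci_params()", call. = FALSE)
  det <- gaussian_blur(image, params$blur_sigma)
  B <- estimate_background(det, params$background)
  cand <- find_candidate_maxima(det, B)
  if (nrow(cand) == 0L)
    return(empty_foci_result(image, B, params))
  labels <- expand_peaks(det, cand, params$search_fraction, B)
  sad <- compute_saddles(det, labels)
  mg <- merge_peaks(det, labels, cand, sad, params, B)
  res <- build_foci_result(image, mg$labels, mg$state, B, params)
  filter_foci(res, min_area = params$min_area,
              min_intensity = params$min_intensity,
              min_height = params$min_height)
}

empty_foci_result <- function(image, B, params) {
  peaks <- data.frame(id = integer(), x = integer(), y = integer(),
                      z = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), centroid_z = numeric(),
                      max_value = numeric(), area = integer(),
                      total_intensity = numeric(),
                      height_above_background = numeric(),
                      saddle_value = numeric(),
                      saddle_neighbour = integer())
  labels <- array(0L, dim(image))
  structure(list(peaks = peaks, labels = labels, background = B,
                 params = params, dim = dim(image)),
            class = "foci_result")
}

build_foci_result <- function(image, labels, st, B, params) {
  alive <- which(st$alive)
  if (!length(alive)) return(empty_foci_result(image, B, params))
  d3 <- img_dim3(image)
  rows <- lapply(alive, function(i) {
    mem <- st$members[[i]]
    v <- image[mem]
    top <- max(v)
    pos <- min(mem[v == top]) - 1L
    c(pos = pos, max_value = top, area = length(mem),
      total_intensity = sum(v))
  })
  m <- do.call(rbind, rows)
  pos <- as.integer(m[, "pos"])
  peaks <- data.frame(
    id = alive,
    x = pos %% d3[1L],
    y = (pos %/% d3[1L]) %% d3[2L],
    z = pos %/% (d3[1L] * d3[2L]),
    centroid_x = st$cent[alive, 1L],
    centroid_y = st$cent[alive, 2L],
    centroid_z = st$cent[alive, 3L],
    max_value = m[, "max_value"],
    area = as.integer(m[, "area"]),
    total_intensity = m[, "total_intensity"],
    height_above_background = m[, "max_value"] - B,
    saddle_value = st$hs[alive],
    saddle_neighbour = st$hn[alive])
  ord <- order(-peaks$max_value, pos)
  peaks <- peaks[ord, , drop = FALSE]
  remap <- integer(max(alive))
  remap[peaks$id] <- seq_len(nrow(peaks))
  new_labels <- labels
  nz <- labels > 0L
  new_labels[nz] <- remap[labels[nz]]
  peaks$saddle_neighbour <- ifelse(is.na(peaks$saddle_neighbour),
                                   NA_integer_,
                                   remap[peaks$saddle_neighbour])
  peaks$id <- seq_len(nrow(peaks))
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, labels = new_labels, background = B,
                 params = params, dim = dim(image)),
            class = "foci_result")
}

#' Filter detected foci
#'
#' Retains the peaks meeting every configured minimum; removed peaks'
#' pixels revert to label 0. Saddle statistics of the survivors are not
#' recomputed.
#'
#' @param result a `foci_result`.
#' @param min_area minimum area in pixels (0 disables).
#' @param min_intensity minimum total intensity (0 disables).
#' @param min_height minimum height above background (0 disables).
#' @return filtered `foci_result` with peaks renumbered 1..k.
#' @export
filter_foci <- function(result, min_area = 0, min_intensity = 0,
                        min_height = 0) {
  stopifnot(inherits(result, "foci_result"))
  p <- result$peaks
  keep <- p$area >= min_area & p$total_intensity >= min_intensity &
    p$height_above_background >= min_height
  subset_foci(result, keep)
}

# keep: logical over result$peaks rows; drops the rest, clears their
# labels and renumbers survivors 1..k
subset_foci <- function(result, keep) {
  p <- result$peaks
  if (all(keep)) return(result)
  dropped <- p$id[!keep]
  result$labels[result$labels %in% dropped] <- 0L
  p <- p[keep, , drop = FALSE]
  kept_ids <- p$id
  remap <- rep(NA_integer_, max(result$peaks$id))
  remap[kept_ids] <- seq_len(nrow(p))
  nz <- result$labels > 0L
  result$labels[nz] <- remap[result$labels[nz]]
  sn <- p$saddle_neighbour
  p$saddle_neighbour <- ifelse(!is.na(sn) & sn %in% kept_ids,
                               remap[pmax(sn, 1L)], NA_integer_)
  p$id <- seq_len(nrow(p))
  rownames(p) <- NULL
  result$peaks <- p
  result
}

#' @export
print.foci_result <- function(x, ...) {
  d <- paste(x$dim, collapse = " x ")
  cat("Foci detection result\n")
  cat("  image:      ", d, "\n", sep = "")
  cat("  background: ", format(x$background, digits = 6), "\n", sep = "")
  cat("  foci:       ", nrow(x$peaks), "\n", sep = "")
  if (nrow(x$peaks)) {
    cat("  top peaks:\n")
    print(head(x$peaks[, c("id", "x", "y", "z", "max_value", "area",
                           "total_intensity")], 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.foci_result <- function(object, ...) {
  p <- object$peaks
  cat("Foci: ", nrow(p), " (background ",
      format(object$background, digits = 6), ")\n", sep = "")
  if (nrow(p)) {
    cat("Area (px):       ")
    print(summary(p$area))
    cat("Max intensity:   ")
    print(summary(p$max_value))
    cat("Height above bg: ")
    print(summary(p$height_above_background))
  }
  invisible(object)
}

#' @export
as.data.frame.foci_result <- function(x, ...) x$peaks

#' Peak maxima as a point set
#'
#' @param result a `foci_result`.
#' @return a [point_set()] of the peak maximum pixels (2D sets for 2D
#'   images), source `"findfoci"`.
#' @export
foci_points <- function(result) {
  p <- result$peaks
  if (length(result$dim) == 3L)
    point_set(p$x, p$y, p$z, source = "findfoci")
  else point_set(p$x, p$y, source = "findfoci")
}

#' Plot detected foci over an image
#'
#' @param x a `foci_result`.
#' @param image optional intensity image to use as backdrop (2D, or a
#'   3D array of which the brightest slice projection is shown).
#' @param ... passed to [graphics::image()].
#' @export
plot.foci_result <- function(x, image = NULL, ...) {
  bg <- if (!is.null(image)) image else (x$labels > 0L) * 1
  if (length(dim(bg)) == 3L) bg <- apply(bg, c(1L, 2L), max)
  graphics::image(seq_len(nrow(bg)) - 1L, seq_len(ncol(bg)) - 1L, bg,
                  col = grDevices::gray.colors(256, 0, 1), xlab = "x",
                  ylab = "y", useRaster = TRUE, ...)
  if (nrow(x$peaks))
    graphics::points(x$peaks$x, x$peaks$y, col = "red", pch = 3)
  invisible(x)
}
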