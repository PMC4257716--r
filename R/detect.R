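#' Detection parameters
#'
#' Bundles every tunable of the detection pipeline. The pipeline is:
#' Gaussian blur (`blur_sigma`), background estimation (`background`),
#' candidate maxima, uphill expansion limited by `search_fraction`,
#' saddle computation, three-stage merging (`min_height_above_saddle`
#' with `saddle_mode`, `min_size`, and optionally size-above-saddle when
#' `merge_above_saddle` is on), then focus filters.
#'
#' @param background a [background_spec()] or a single absolute intensity.
#' @param blur_sigma Gaussian smoothing sigma in pixels (>= 0); 0 disables
#'   smoothing. Reported peak statistics always come from the original,
#'   unsmoothed image.
#' @param search_fraction f in \[0, 1\]: a peak only keeps pixels with
#'   intensity above `B + f * (max - B)` (its floor). `f = 0` expands to
#'   the background, `f = 1` keeps only the maximum/plateau pixels.
#' @param min_size minimum peak size in pixels (>= 1) used by merge
#'   stages 2 and 3.
#' @param min_height_above_saddle stage-1 threshold: a peak whose maximum
#'   rises less than this above its highest saddle is merged into the
#'   neighbour across that saddle. Interpreted as an absolute intensity
#'   (`saddle_mode = "absolute"`) or as a fraction of the peak's height
#'   above background (`"relative"`).
#' @param saddle_mode `"absolute"` or `"relative"`.
#' @param merge_above_saddle enable the optional third merge stage
#'   (pixel count above the highest saddle < `min_size`).
#' @param min_area,min_intensity,min_height optional focus filters:
#'   minimum area (pixels), minimum total intensity, and minimum height
#'   above background; 0 disables each.
#' @return list of class `foci_params`.
#' @export
foci_params <- function(background = 0, blur_sigma = 0,
                        search_fraction = 0, min_size = 1,
                        min_height_above_saddle = 0,
                        saddle_mode = c("absolute", "relative"),
                        merge_above_saddle = FALSE,
                        min_area = 0, min_intensity = 0, min_height = 0) {
  if (is.numeric(background) && length(background) == 1L)
    background <- background_spec("absolute", background)
  saddle_mode <- match.arg(saddle_mode)
  stopifnot(blur_sigma >= 0, search_fraction >= 0, search_fraction <= 1,
            min_size >= 1, min_height_above_saddle >= 0,
            min_area >= 0, min_intensity >= 0, min_height >= 0)
  structure(list(background = background, blur_sigma = blur_sigma,
                 search_fraction = search_fraction,
                 min_size = as.integer(min_size),
                 min_height_above_saddle = min_height_above_saddle,
                 saddle_mode = saddle_mode,
                 merge_above_saddle = isTRUE(merge_above_saddle),
                 min_area = min_area, min_intensity = min_intensity,
                 min_height = min_height),
            class = "foci_params")
}

img_dim3 <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) c(d, 1L) else d
}

#' Candidate maxima
#'
#' Identifies candidate foci: single pixels strictly above all of their
#' neighbours, or connected equal-intensity plateaus all of whose
#' adjacent pixels are lower, with value strictly above the background
#' level `B`. A plateau's position is its unweighted centre of mass; its
#' representative pixel is the member closest to that centroid.
#'
#' @param image 2D/3D intensity image.
#' @param B background intensity; only pixels with value > B qualify.
#' @return data.frame with one row per candidate: `id`, `value`,
#'   `x`, `y` (`z` for 3D; 0-based representative pixel) and
#'   `centroid_x/y(/z)`. The `"labels"` attribute holds the plateau
#'   label grid used by [expand_peaks()].
#' @export
find_candidate_maxima <- function(image, B) {
  check_image(image)
  stopifnot(is.finite(B))
  d3 <- img_dim3(image)
  res <- cpp_candidates(as.numeric(image), d3, B)
  labels <- res$labels
  dim(labels) <- dim(image)
  k <- length(res$value)
  mi <- res$max_idx
  out <- data.frame(id = seq_len(k),
                    value = res$value,
                    x = mi %% d3[1L],
                    y = (mi %/% d3[1L]) %% d3[2L],
                    centroid_x = res$cx, centroid_y = res$cy)
  if (length(dim(image)) == 3L) {
    out$z <- mi %/% (d3[1L] * d3[2L])
    out$centroid_z <- res$cz
  }
  attr(out, "labels") <- labels
  attr(out, "background") <- B
  out
}

#' Expand candidates into peak regions
#'
#' Assigns every foreground pixel to a candidate by following the uphill
#' gradient: pixels are processed in descending intensity and each takes
#' the label of its highest already-labelled neighbour (ties by lowest
#' label id, then raster order). A peak's expansion is limited by its
#' floor `B + f * (max - B)`: member pixels at or below the floor are
#' cleared back to background (the maximum/plateau pixels always remain).
#'
#' @param image the image the candidates were found on.
#' @param candidates result of [find_candidate_maxima()] on `image`.
#' @param f search fraction in \[0, 1\].
#' @param B background intensity (same value used for the candidates).
#' @return integer label array (0 = background) of the image's shape.
#' @export
expand_peaks <- function(image, candidates, f, B) {
  check_image(image)
  stopifnot(f >= 0, f <= 1, is.finite(B))
  labels0 <- attr(candidates, "labels")
  if (is.null(labels0))
    stop("candidates must come from find_candidate_maxima()", call. = FALSE)
  labels <- cpp_expand(as.numeric(image), img_dim3(image),
                       as.integer(labels0), B)
  dim(labels) <- dim(image)
  if (f > 0 && nrow(candidates) > 0L) {
    floors <- B + f * (candidates$value - B)
    idx <- which(labels > 0L & labels0 == 0L)
    drop <- idx[image[idx] <= floors[labels[idx]]]
    labels[drop] <- 0L
  }
  labels
}

#' Saddle points between touching peaks
#'
#' For every pair of adjacent pixels carrying different peak labels the
#' candidate saddle height is the lower of the two intensities; the
#' saddle of a pair of touching peaks is the highest such candidate.
#' The relation is symmetric; one row per unordered pair is returned.
#'
#' @param image the image the labels were derived from.
#' @param labels integer label array from [expand_peaks()].
#' @return data.frame with columns `peak_id`, `neighbour_id`
#'   (`peak_id < neighbour_id`) and `saddle_value`.
#' @export
compute_saddles <- function(image, labels) {
  check_image(image)
  stopifnot(identical(dim(image), dim(labels)))
  cpp_saddles(as.numeric(image), img_dim3(image), as.integer(labels))
}
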