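# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Detection-parameter grid
#'
#' An enumerable space of detection parameters for the optimiser. Every
#' range must be non-empty; the total combination count is the product
#' of the range sizes. Enumeration is lexicographic with `blur_sigma`
#' outermost, then `background`, `search_fraction`, `min_size`,
#' `min_height_above_saddle`, `merge_above_saddle`, `min_area`,
#' `min_intensity`, `min_height` (innermost) — the order the staged
#' caches exploit.
#'
#' @param background list of [background_spec()]s (bare numbers allowed).
#' @param blur_sigma,search_fraction,min_size,min_height_above_saddle,min_area,min_intensity,min_height
#'   numeric value ranges.
#' @param saddle_mode single mode for the whole grid.
#' @param merge_above_saddle logical values to try.
#' @param metric ranking metric, `"jaccard"` or `"f1"`.
#' @param match_radius pairing radius in pixels for scoring (default 8).
#' @return list of class `foci_grid`.
#' @export
foci_grid <- function(background = list(background_spec("otsu")),
                      blur_sigma = 0, search_fraction = 0, min_size = 1,
                      min_height_above_saddle = 0,
                      saddle_mode = c("absolute", "relative"),
                      merge_above_saddle = FALSE,
                      min_area = 0, min_intensity = 0, min_height = 0,
                      metric = c("jaccard", "f1"), match_radius = 8) {
  if (!is.list(background)) background <- list(background)
  background <- lapply(background, function(b)
    if (is.numeric(b)) background_spec("absolute", b) else b)
  ranges <- list(blur_sigma = blur_sigma, background = background,
                 search_fraction = search_fraction, min_size = min_size,
                 min_height_above_saddle = min_height_above_saddle,
                 merge_above_saddle = merge_above_saddle,
                 min_area = min_area, min_intensity = min_intensity,
                 min_height = min_height)
  if (any(lengths(ranges) == 0L))
    stop("every parameter range must be non-empty", call. = FALSE)
  structure(list(ranges = ranges, saddle_mode = match.arg(saddle_mode),
                 metric = match.arg(metric), match_radius = match_radius),
            class = "foci_grid")
}

grid_size <- function(grid) prod(lengths(grid$ranges))

# combination index table in enumeration order (blur outermost)
grid_index <- function(grid) {
  ln <- lengths(grid$ranges)
  idx <- expand.grid(rev(lapply(ln, seq_len)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(ln)), drop = FALSE]
  names(idx) <- names(ln)
  idx
}

params_from_index <- function(grid, row) {
  r <- grid$ranges
  foci_params(background = r$background[[row$background]],
              blur_sigma = r$blur_sigma[row$blur_sigma],
              search_fraction = r$search_fraction[row$search_fraction],
              min_size = r$min_size[row$min_size],
              min_height_above_saddle =
                r$min_height_above_saddle[row$min_height_above_saddle],
              saddle_mode = grid$saddle_mode,
              merge_above_saddle = r$merge_above_saddle[row$merge_above_saddle],
              min_area = r$min_area[row$min_area],
              min_intensity = r$min_intensity[row$min_intensity],
              min_height = r$min_height[row$min_height])
}

#' Enumerate every parameter combination of a grid
#'
#' @param grid a [foci_grid()].
#' @return list of [foci_params()] in deterministic enumeration order.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "foci_grid"))
  idx <- grid_index(grid)
  lapply(seq_len(nrow(idx)), function(i) params_from_index(grid, idx[i, ]))
}

combo_table <- function(grid) {
  idx <- grid_index(grid)
  bg <- grid$ranges$background
  data.frame(
    combo = seq_len(nrow(idx)),
    blur_sigma = grid$ranges$blur_sigma[idx$blur_sigma],
    background_method = vapply(bg[idx$background], `[[`, "", "method"),
    background_param = vapply(bg[idx$background], `[[`, 0, "param"),
    search_fraction = grid$ranges$search_fraction[idx$search_fraction],
    min_size = grid$ranges$min_size[idx$min_size],
    min_height_above_saddle =
      grid$ranges$min_height_above_saddle[idx$min_height_above_saddle],
    saddle_mode = grid$saddle_mode,
    merge_above_saddle =
      grid$ranges$merge_above_saddle[idx$merge_above_saddle],
    min_area = grid$ranges$min_area[idx$min_area],
    min_intensity = grid$ranges$min_intensity[idx$min_intensity],
    min_height = grid$ranges$min_height[idx$min_height])
}

#' Train detection parameters on one annotated image
#'
#' Runs the detection pipeline for every parameter combination of the
#' grid, matches the detected peak maxima against the reference points
#' within `match_radius`, and ranks the combinations by the chosen
#' metric (ties resolved by enumeration order). With `use_cache = TRUE`
#' intermediate results are staged — the blurred image per
#' `blur_sigma`, the background level per background spec, the
#' expansion and saddles per `search_fraction` — and only merging,
#' filtering and scoring are repeated per combination; results are
#' identical to naively re-running the full pipeline for every
#' combination.
#'
#' If any parameter of the top-ranked combination sits at the edge of a
#' multi-valued numeric range, that parameter is flagged so the range
#' can be widened.
#'
#' @param image 2D/3D intensity image.
#' @param reference non-empty point set of true/annotated foci.
#' @param grid a [foci_grid()].
#' @param use_cache stage intermediate results (default) or re-run the
#'   full pipeline per combination.
#' @return object of class `foci_opt`: `records` (one row per
#'   combination in enumeration order: parameters, peak count, scores
#'   and `rank`), `boundary_flags` (named logical), `grid`, `metric`.
#' @export
optimise_single <- function(image, reference, grid, use_cache = TRUE) {
  check_image(image)
  stopifnot(inherits(grid, "foci_grid"))
  if (nrow(reference) == 0L)
    stop("reference point set is empty", call. = FALSE)
  tab <- combo_table(grid)
  idx <- grid_index(grid)
  n <- nrow(tab)
  sc <- matrix(NA_real_, n, 5,
               dimnames = list(NULL, c("n_peaks", "jaccard", "recall_1",
                                       "recall_2", "f1")))
  score_one <- function(res) {
    pts <- foci_points(res)
    if (point_dims(reference) == 2L && "z" %in% names(pts))
      pts$z <- NULL
    s <- match_scores(match_points(pts, reference, grid$match_radius))
    c(nrow(res$peaks), s$jaccard, s$recall_1, s$recall_2, s$f1)
  }
  if (!use_cache) {
    for (i in seq_len(n))
      sc[i, ] <- score_one(find_foci(image, params_from_index(grid,
                                                              idx[i, ])))
  } else {
    for (ib in seq_along(grid$ranges$blur_sigma)) {
      det <- gaussian_blur(image, grid$ranges$blur_sigma[ib])
      for (ig in seq_along(grid$ranges$background)) {
        B <- estimate_background(det, grid$ranges$background[[ig]])
        cand <- find_candidate_maxima(det, B)
        for (if_ in seq_along(grid$ranges$search_fraction)) {
          rows <- which(idx$blur_sigma == ib & idx$background == ig &
                          idx$search_fraction == if_)
          if (nrow(cand) == 0L) {
            for (i in rows)
              sc[i, ] <- score_one(empty_foci_result(
                image, B, params_from_index(grid, idx[i, ])))
            next
          }
          labels <- expand_peaks(det, cand,
                                 grid$ranges$search_fraction[if_], B)
          sad <- compute_saddles(det, labels)
          for (i in rows) {
            p <- params_from_index(grid, idx[i, ])
            mg <- merge_peaks(det, labels, cand, sad, p, B)
            res <- build_foci_result(image, mg$labels, mg$state, B, p)
            res <- filter_foci(res, p$min_area, p$min_intensity,
                               p$min_height)
            sc[i, ] <- score_one(res)
          }
        }
      }
    }
  }
  records <- cbind(tab, as.data.frame(sc))
  metric_col <- records[[grid$metric]]
  ord <- order(-metric_col, records$combo)
  records$rank <- integer(n)
  records$rank[ord] <- seq_len(n)
  best <- records[records$rank == 1L, ]
  structure(list(records = records,
                 boundary_flags = boundary_flags(grid, best),
                 best_params = params_from_index(grid,
                                                 idx[best$combo, ]),
                 grid = grid, metric = grid$metric),
            class = "foci_opt")
}

boundary_flags <- function(grid, best) {
  numeric_pars <- c("blur_sigma", "search_fraction", "min_size",
                    "min_height_above_saddle", "min_area",
                    "min_intensity", "min_height")
  flags <- logical(length(numeric_pars))
  names(flags) <- numeric_pars
  for (p in numeric_pars) {
    rng <- grid$ranges[[p]]
    if (length(rng) > 1L)
      flags[p] <- best[[p]] %in% range(rng)
  }
  flags
}

#' @export
print.foci_opt <- function(x, ...) {
  n <- nrow(x$records)
  best <- x$records[x$records$rank == 1L, ]
  cat("Parameter optimisation over ", n, " combinations (metric: ",
      x$metric, ")\n", sep = "")
  cat("  best ", x$metric, ": ", format(best[[x$metric]], digits = 4),
      " (combination ", best$combo, ", ", best$n_peaks, " peaks)\n",
      sep = "")
  if (any(x$boundary_flags))
    cat("  boundary: ",
        paste(names(which(x$boundary_flags)), collapse = ", "),
        " at range edge — consider widening\n", sep = "")
  invisible(x)
}

#' @export
summary.foci_opt <- function(object, ...) {
  r <- object$records[order(object$records$rank), ]
  print(object)
  cat("Top combinations:\n")
  print(head(r[, c("rank", "combo", "blur_sigma", "background_method",
                   "search_fraction", "min_size",
                   "min_height_above_saddle", object$metric)], 5),
        row.names = FALSE)
  invisible(object)
}

#' Exact binomial coefficient n choose r
#'
#' Computed by the multiplicative algorithm with an exact integer value
#' at every step; results are exact for all values below 2^53 (which
#' covers every n <= 55, and far beyond for small r).
#'
#' @param n,r non-negative integers with `r <= n`.
#' @return the number of r-element subsets of n items.
#' @export
count_combinations <- function(n, r) {
  stopifnot(length(n) == 1L, length(r) == 1L, n >= 0, r >= 0)
  if (r > n) stop("r must not exceed n", call. = FALSE)
  r <- min(r, n - r)
  res <- 1
  for (i in seq_len(r)) res <- round(res * (n - r + i) / i)
  res
}

#' Enumerate or sample image subsets for multi-image training
#'
#' Returns all `r`-element subsets of `n` images when their count is at
#' most `enumerate_cap` (eliminating sub-sampling bias); otherwise draws
#' `sample_count` distinct subsets uniformly at random, reproducibly
#' under `seed`. A `sample_count` of at least the total count returns
#' the full enumeration.
#'
#' @param n number of images.
#' @param r subset size (1 <= r <= n).
#' @param enumerate_cap full-enumeration limit (default 210).
#' @param sample_count number of random subsets above the cap
#'   (default 100).
#' @param seed RNG seed for the sampling.
#' @return list of strictly increasing integer index vectors.
#' @export
sample_image_subsets <- function(n, r, enumerate_cap = 210,
                                 sample_count = 100, seed = NULL) {
  stopifnot(r >= 1, r <= n)
  total <- count_combinations(n, r)
  if (total <= enumerate_cap || sample_count >= total) {
    cc <- combn(n, r)
    return(lapply(seq_len(ncol(cc)), function(i) cc[, i]))
  }
  with_seed(seed, {
    out <- list()
    seen <- character()
    while (length(out) < sample_count) {
      s <- sort(sample.int(n, r))
      key <- paste(s, collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- s
      }
    }
    out
  })
}

#' Aggregate per-image optimisation scores
#'
#' Combines the ranked tables from several images (identical
#' combination lists required) into one choice of parameters. Before
#' aggregation each image's score vector may be converted: `raw`
#' (identity), `relative` (fraction of the image's top score, bottom
#' assumed zero), `zscore` (centred and scaled by the image's score SD;
#' zero SD yields all zeros), or `rank` (1 = best, ties share the
#' smallest rank). Scores are aggregated per combination by the mean
#' (or median) across images and the best combination maximises the
#' aggregate (minimises it for `rank`); ties go to the earliest
#' combination in enumeration order.
#'
#' @param tables list of `foci_opt` objects from [optimise_single()].
#' @param conversion `"raw"`, `"relative"`, `"zscore"` or `"rank"`.
#' @param stat aggregation statistic, `"mean"` (default) or `"median"`.
#' @return object of class `foci_train`: `aggregated` (per-combination
#'   aggregate), `best_combo`, `best_params`, `boundary_flags`,
#'   `per_image` (converted score matrix), `conversion`, `grid`.
#' @export
aggregate_scores <- function(tables, conversion = c("raw", "relative",
                                                    "zscore", "rank"),
                             stat = c("mean", "median")) {
  conversion <- match.arg(conversion)
  stat <- match.arg(stat)
  stopifnot(length(tables) >= 1L)
  metric <- tables[[1L]]$metric
  par_cols <- setdiff(names(tables[[1L]]$records),
                      c("n_peaks", "jaccard", "recall_1", "recall_2",
                        "f1", "rank"))
  base <- tables[[1L]]$records[, par_cols]
  for (t in tables[-1L])
    if (!identical(t$records[, par_cols], base))
      stop("combination lists differ between images", call. = FALSE)
  raw <- vapply(tables, function(t) t$records[[metric]],
                numeric(nrow(base)))
  raw <- matrix(raw, nrow = nrow(base))
  conv <- apply(raw, 2L, function(s) switch(conversion,
    raw = s,
    relative = if (max(s) > 0) s / max(s) else rep(0, length(s)),
    zscore = if (sd(s) > 0) (s - mean(s)) / sd(s)
             else rep(0, length(s)),
    rank = rank(-s, ties.method = "min")))
  conv <- matrix(conv, nrow = nrow(base))
  agg <- apply(conv, 1L, if (stat == "mean") mean else median)
  best <- if (conversion == "rank") which(agg == min(agg))[1L]
          else which(agg == max(agg))[1L]
  grid <- tables[[1L]]$grid
  best_row <- tables[[1L]]$records[best, ]
  structure(list(aggregated = agg, best_combo = best,
                 best_params = params_from_index(grid,
                                                 grid_index(grid)[best, ]),
                 boundary_flags = boundary_flags(grid, best_row),
                 per_image = conv, conversion = conversion, stat = stat,
                 grid = grid, metric = metric, combos = base),
            class = "foci_train")
}

#' Train detection parameters on multiple annotated images
#'
#' Runs [optimise_single()] on every image (results are independent of
#' image order) and aggregates the scores with [aggregate_scores()].
#'
#' @param images list of intensity images.
#' @param references list of point sets, one per image.
#' @param grid a [foci_grid()].
#' @param conversion,stat passed to [aggregate_scores()].
#' @param use_cache passed to [optimise_single()].
#' @return a `foci_train` (see [aggregate_scores()]); its `tables`
#'   element keeps the per-image `foci_opt` objects.
#' @export
train_multi <- function(images, references, grid,
                        conversion = "raw", stat = "mean",
                        use_cache = TRUE) {
  stopifnot(length(images) >= 1L, length(images) == length(references))
  tables <- mapply(function(im, ref)
    optimise_single(im, ref, grid, use_cache = use_cache),
    images, references, SIMPLIFY = FALSE)
  out <- aggregate_scores(tables, conversion, stat)
  out$tables <- tables
  out
}

#' @export
print.foci_train <- function(x, ...) {
  cat("Multi-image training over ", length(x$aggregated),
      " combinations x ", ncol(x$per_image), " image(s) (", x$conversion,
      " ", x$stat, " of ", x$metric, ")\n", sep = "")
  cat("  best combination: ", x$best_combo, " (aggregate ",
      format(x$aggregated[x$best_combo], digits = 4), ")\n", sep = "")
  if (any(x$boundary_flags))
    cat("  boundary: ",
        paste(names(which(x$boundary_flags)), collapse = ", "),
        " at range edge — consider widening\n", sep = "")
  invisible(x)
}
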