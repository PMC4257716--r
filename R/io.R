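# TIFF images are stored row-major with the first raster row on top;
# internally the first array index is x, so slices are transposed on
# the way in and out. Integer TIFFs round-trip exactly (8- and 16-bit);
# float TIFFs are written as 32-bit samples scaled to [0, 1] by
# `bit_range` and rescaled on read.

#' Read a grayscale TIFF image
#'
#' Single-slice images become matrices with `dim = c(nx, ny)`;
#' multi-slice files become 3D arrays (slices along the third axis).
#' Multi-channel data is reduced to the first channel.
#'
#' @param path TIFF file path.
#' @param bit_range intensity scale for float TIFFs (values stored in
#'   \[0, 1\] are multiplied by this on read).
#' @return numeric matrix or array with a `bit_origin` attribute
#'   (`"8-bit"`, `"16-bit"` or `"float"`).
#' @export
read_image <- function(path, bit_range = 65535) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  to_xy <- function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    t(m)
  }
  slices <- lapply(slices, to_xy)
  img <- if (length(slices) == 1L) slices[[1L]]
         else array(unlist(slices), c(dim(slices[[1L]]), length(slices)))
  if (is.integer(unlist(slices)) || all(img == round(img))) {
    attr(img, "bit_origin") <- if (max(img) <= 255) "8-bit" else "16-bit"
  } else {
    img <- img * bit_range
    attr(img, "bit_origin") <- "float"
  }
  img
}

#' Write a grayscale TIFF image
#'
#' @param image numeric matrix or 3D array; 3D arrays are written as
#'   multi-slice TIFFs.
#' @param path output path.
#' @param bit_origin `"8-bit"`, `"16-bit"` or `"float"`; defaults to the
#'   image's `bit_origin` attribute, else 16-bit.
#' @param bit_range full-scale intensity for scaling.
#' @export
write_image <- function(image, path, bit_origin = NULL,
                        bit_range = 65535) {
  if (is.null(bit_origin))
    bit_origin <- attr(image, "bit_origin") %||% "16-bit"
  scale <- switch(bit_origin, "8-bit" = 255, "16-bit" = 65535,
                  "float" = bit_range)
  bits <- switch(bit_origin, "8-bit" = 8L, "16-bit" = 16L,
                 "float" = 32L)
  to_rc <- function(m) t(pmin(pmax(m / scale, 0), 1))
  d <- dim(image)
  what <- if (length(d) == 3L)
    lapply(seq_len(d[3L]), function(k) to_rc(image[, , k]))
  else to_rc(image)
  tiff::writeTIFF(what, path, bits.per.sample = bits)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a binary mask as an 8-bit TIFF (0/255)
#' @param mask logical matrix/array.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  write_image(mask * 255, path, bit_origin = "8-bit")
}

#' Write a peak label image as a 16-bit TIFF
#' @param labels integer label array (0 = background).
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  write_image(labels, path, bit_origin = "16-bit")
}

#' Read a point list from CSV
#'
#' Expects a header `id,x,y` (optionally `,z`); coordinates are 0-based
#' unless `one_based` is set, in which case 1 is subtracted.
#'
#' @param path CSV path.
#' @param one_based input uses 1-based coordinates.
#' @return a [point_set()] (source = file name).
#' @export
read_points <- function(path, one_based = FALSE) {
  df <- read.csv(path, comment.char = "#")
  need <- c("x", "y")
  if (!all(need %in% names(df)))
    stop("point file must have columns id,x,y[,z]: ", path,
         call. = FALSE)
  for (col in intersect(c("x", "y", "z"), names(df))) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data line %d of %s",
                   col, bad[1L], path), call. = FALSE)
    df[[col]] <- as.numeric(df[[col]])
  }
  off <- if (one_based) 1 else 0
  z <- if ("z" %in% names(df)) df$z - off else NULL
  point_set(df$x - off, df$y - off, z,
            source = tools::file_path_sans_ext(basename(path)))
}

#' Write a point list to CSV
#'
#' @param points a [point_set()].
#' @param path output path.
#' @export
write_points <- function(points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# 0-based pixel coordinates (x, y[, z])", con)
  df <- cbind(id = seq_len(nrow(points)),
              as.data.frame(points)[, intersect(c("x", "y", "z"),
                                                names(points)),
                                    drop = FALSE])
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v) && v == round(v) && abs(v) < 2^31)
      return(format(as.integer(v)))
    sprintf("%.17g", as.numeric(v))
  }, "")
}

#' Write detection parameters to a flat key-value file
#'
#' The file round-trips exactly: [read_params()] on the output
#' reproduces the in-memory parameters bit for bit.
#'
#' @param params a [foci_params()].
#' @param path output path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "foci_params"))
  kv <- c(version = "1",
          background_method = params$background$method,
          background_param = fmt_num(params$background$param),
          blur_sigma = fmt_num(params$blur_sigma),
          search_fraction = fmt_num(params$search_fraction),
          min_size = fmt_num(params$min_size),
          min_height_above_saddle = fmt_num(params$min_height_above_saddle),
          saddle_mode = params$saddle_mode,
          merge_above_saddle = if (params$merge_above_saddle) "1" else "0",
          min_area = fmt_num(params$min_area),
          min_intensity = fmt_num(params$min_intensity),
          min_height = fmt_num(params$min_height))
  writeLines(paste(names(kv), kv, sep = "="), path)
  invisible(path)
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  setNames(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""),
           vapply(kv, `[[`, "", 1L))
}

#' Read detection parameters from a key-value file
#' @param path file written by [write_params()].
#' @return a [foci_params()].
#' @export
read_params <- function(path) {
  kv <- read_kv(path)
  foci_params(
    background = background_spec(kv[["background_method"]],
                                 as.numeric(kv[["background_param"]])),
    blur_sigma = as.numeric(kv[["blur_sigma"]]),
    search_fraction = as.numeric(kv[["search_fraction"]]),
    min_size = as.numeric(kv[["min_size"]]),
    min_height_above_saddle = as.numeric(kv[["min_height_above_saddle"]]),
    saddle_mode = kv[["saddle_mode"]],
    merge_above_saddle = kv[["merge_above_saddle"]] == "1",
    min_area = as.numeric(kv[["min_area"]]),
    min_intensity = as.numeric(kv[["min_intensity"]]),
    min_height = as.numeric(kv[["min_height"]]))
}

#' Write a parameter grid to a flat key-value file
#' @param grid a [foci_grid()]; ranges are comma-separated.
#' @param path output path.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "foci_grid"))
  join <- function(x) paste(fmt_num(x), collapse = ",")
  bg <- vapply(grid$ranges$background, function(b)
    paste0(b$method, ":", fmt_num(b$param)), "")
  kv <- c(version = "1",
          background = paste(bg, collapse = ","),
          blur_sigma = join(grid$ranges$blur_sigma),
          search_fraction = join(grid$ranges$search_fraction),
          min_size = join(grid$ranges$min_size),
          min_height_above_saddle =
            join(grid$ranges$min_height_above_saddle),
          saddle_mode = grid$saddle_mode,
          merge_above_saddle = paste(
            ifelse(grid$ranges$merge_above_saddle, "1", "0"),
            collapse = ","),
          min_area = join(grid$ranges$min_area),
          min_intensity = join(grid$ranges$min_intensity),
          min_height = join(grid$ranges$min_height),
          metric = grid$metric,
          match_radius = fmt_num(grid$match_radius))
  writeLines(paste(names(kv), kv, sep = "="), path)
  invisible(path)
}

#' Read a parameter grid from a key-value file
#' @param path file written by [write_grid()].
#' @return a [foci_grid()].
#' @export
read_grid <- function(path) {
  kv <- read_kv(path)
  nums <- function(key) as.numeric(strsplit(kv[[key]], ",")[[1L]])
  bg <- lapply(strsplit(kv[["background"]], ",")[[1L]], function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
    background_spec(parts[1L], as.numeric(parts[2L]))
  })
  foci_grid(background = bg, blur_sigma = nums("blur_sigma"),
            search_fraction = nums("search_fraction"),
            min_size = nums("min_size"),
            min_height_above_saddle = nums("min_height_above_saddle"),
            saddle_mode = kv[["saddle_mode"]],
            merge_above_saddle =
              strsplit(kv[["merge_above_saddle"]], ",")[[1L]] == "1",
            min_area = nums("min_area"),
            min_intensity = nums("min_intensity"),
            min_height = nums("min_height"), metric = kv[["metric"]],
            match_radius = as.numeric(kv[["match_radius"]]))
}

fmt_table <- function(df) {
  for (col in names(df))
    if (is.double(df[[col]])) df[[col]] <- signif(df[[col]], 6)
  df
}

#' Write a foci results table as TSV
#'
#' One row per peak (id, coordinates, centroid, intensity statistics,
#' saddle info); decimals are written with 6 significant digits.
#'
#' @param result a `foci_result` (or a plain data frame).
#' @param path output path.
#' @export
write_foci_table <- function(result, path) {
  df <- if (inherits(result, "foci_result")) result$peaks else result
  utils::write.table(fmt_table(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Batch-detect foci over a directory of images
#'
#' Processes every TIFF in the directory in deterministic alphabetical
#' order with one fixed parameter set, writing per-image results tables
#' (`<image>_foci.tsv`), label masks (`<image>_labels.tif`), a summary
#' TSV and a plain-text run log (inputs, parameter hash, per-image peak
#' counts). With `mask_mode = "otsu"` peaks whose maximum falls outside
#' the image's Otsu foreground mask are dropped. Unreadable images are
#' logged and skipped; their names are returned in `failed`.
#'
#' @param directory directory containing `.tif`/`.tiff` images.
#' @param params a [foci_params()] or the path of a parameter file.
#' @param mask_mode `"none"` or `"otsu"`.
#' @param out_dir output directory (default: `directory`).
#' @return invisibly, list with `summary` (data.frame image/n_foci),
#'   `failed` (character) and `log` (log file path).
#' @export
batch_run <- function(directory, params, mask_mode = c("none", "otsu"),
                      out_dir = directory) {
  mask_mode <- match.arg(mask_mode)
  param_hash <- NA_character_
  if (is.character(params)) {
    param_hash <- unname(tools::md5sum(params))
    params <- read_params(params)
  }
  files <- sort(list.files(directory, pattern = "\\.tiff?$",
                           ignore.case = TRUE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "findfoci_batch.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                            ..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("batch start: ", directory, " (", length(files), " images, mask=",
       mask_mode, ", params md5=", param_hash, ")")
  summary_df <- data.frame(image = character(), n_foci = integer())
  failed <- character()
  for (f in files) {
    img <- tryCatch(read_image(file.path(directory, f)),
                    error = function(e) e)
    if (inherits(img, "error")) {
      logf("SKIP ", f, ": ", conditionMessage(img))
      failed <- c(failed, f)
      next
    }
    res <- find_foci(img, params)
    if (mask_mode == "otsu" && nrow(res$peaks)) {
      m <- otsu_mask(img)
      keep <- m[point_pixels(foci_points(res), dim(img))]
      res <- subset_foci(res, keep)
    }
    stem <- tools::file_path_sans_ext(f)
    write_foci_table(res, file.path(out_dir, paste0(stem, "_foci.tsv")))
    write_labels(res$labels, file.path(out_dir,
                                       paste0(stem, "_labels.tif")))
    logf(f, ": ", nrow(res$peaks), " foci")
    summary_df <- rbind(summary_df,
                        data.frame(image = f, n_foci = nrow(res$peaks)))
  }
  utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("batch end: ", nrow(summary_df), " ok, ", length(failed),
       " failed")
  invisible(list(summary = summary_df, failed = failed, log = log_path))
}
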