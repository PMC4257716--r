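#' Synthetic nucleus scene parameters
#'
#' Describes a synthetic spread-nucleus scene: an elliptical DNA-like
#' region over background, containing heterogeneous diffraction-limited
#' spots (isotropic Gaussians) with log-normally distributed peak
#' amplitudes, plus additive noise. Defaults emulate a 16-bit
#' fluorescence micrograph crop with a few dozen foci of width around 5
#' pixels (sigma 1.6--2.6 px) whose brightness spans roughly an order
#' of magnitude over a visible background.
#'
#' @param shape image dimensions `c(nx, ny)` in pixels.
#' @param n_spots number of spots.
#' @param amplitude_median,amplitude_sigma log-normal peak-amplitude
#'   parameters: amplitudes are `amplitude_median * exp(amplitude_sigma
#'   * N(0,1))` intensity units above background.
#' @param spot_sigma range `c(lo, hi)` of Gaussian spot widths (px).
#' @param background_level background intensity inside and outside the
#'   nucleus.
#' @param noise_sd additive Gaussian read-noise SD (0 = noiseless).
#' @param min_separation minimum centre-to-centre distance (px).
#' @param mask_axes ellipse semi-axes of the nucleus region as fractions
#'   of the half-dimensions.
#' @param doublet_fraction fraction of spots laid down as close pairs
#'   (2--3 px apart, typically fusing into one diffraction-limited blob;
#'   the extra partner is appended to the ground truth).
#' @param bit_range clip ceiling (16-bit by default).
#' @return list of class `scene_params`.
#' @export
scene_params <- function(shape = c(128L, 128L), n_spots = 60,
                         amplitude_median = 2000, amplitude_sigma = 0.5,
                         spot_sigma = c(1.6, 2.6),
                         background_level = 500, noise_sd = 100,
                         min_separation = 6, mask_axes = c(0.85, 0.75),
                         doublet_fraction = 0, bit_range = 65535) {
  stopifnot(length(shape) == 2L, all(shape >= 8L), n_spots >= 0,
            min_separation >= 0, noise_sd >= 0, amplitude_median > 0,
            length(spot_sigma) == 2L, all(spot_sigma > 0),
            doublet_fraction >= 0, doublet_fraction <= 1)
  structure(as.list(environment()), class = "scene_params")
}

#' Generate a synthetic nucleus scene
#'
#' Renders the sum of isotropic Gaussian spots placed inside the
#' elliptical nucleus region over a constant background, adds Gaussian
#' read noise and clips to `[0, bit_range]`. Spot centres are drawn
#' uniformly inside the (slightly eroded) ellipse subject to
#' `min_separation`, by rejection sampling with a bounded number of
#' retries. Byte-identical under a fixed seed.
#'
#' @param params a [scene_params()].
#' @param seed RNG seed; the scene is reproducible given the seed.
#' @return list with `image` (matrix), `mask` (logical matrix of the
#'   nucleus ellipse) and `truth` (data.frame of sub-pixel 0-based
#'   centres `x`, `y` with `amplitude`, `sigma` and `doublet` flag).
#' @export
generate_scene <- function(params = scene_params(), seed = NULL) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(seed, {
    nx <- params$shape[1L]; ny <- params$shape[2L]
    cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
    ax <- params$mask_axes[1L] * nx / 2
    ay <- params$mask_axes[2L] * ny / 2
    xs <- seq_len(nx) - 1; ys <- seq_len(ny) - 1
    mask <- outer(((xs - cx) / ax)^2, rep(1, ny)) +
      outer(rep(1, nx), ((ys - cy) / ay)^2) <= 1
    n_primary <- params$n_spots
    centres <- matrix(numeric(), 0L, 2L)
    tries <- 0L
    inner <- 0.95            # keep spots off the mask rim
    while (nrow(centres) < n_primary) {
      if ((tries <- tries + 1L) > 200L * max(n_primary, 1L))
        stop("could not place spots at the requested separation",
             call. = FALSE)
      u <- runif(1); th <- runif(1, 0, 2 * pi)
      p <- c(cx + inner * ax * sqrt(u) * cos(th),
             cy + inner * ay * sqrt(u) * sin(th))
      if (nrow(centres) == 0L ||
          min(sqrt(rowSums((centres - matrix(p, nrow(centres), 2L,
                                             byrow = TRUE))^2))) >=
            params$min_separation)
        centres <- rbind(centres, p)
    }
    doublet <- logical(nrow(centres))
    n_dbl <- round(params$doublet_fraction * n_primary)
    if (n_dbl > 0L && n_primary > 0L) {
      for (i in sample.int(n_primary, n_dbl)) {
        th <- runif(1, 0, 2 * pi)
        sep <- runif(1, 2, 3)
        centres <- rbind(centres, centres[i, ] +
                           sep * c(cos(th), sin(th)))
        doublet[i] <- TRUE
        doublet <- c(doublet, TRUE)
      }
    }
    n_all <- nrow(centres)
    amp <- params$amplitude_median * exp(params$amplitude_sigma *
                                           rnorm(n_all))
    sig <- runif(n_all, params$spot_sigma[1L], params$spot_sigma[2L])
    img <- matrix(params$background_level, nx, ny)
    for (i in seq_len(n_all)) {
      r <- ceiling(4 * sig[i])
      x0 <- max(0, floor(centres[i, 1L] - r))
      x1 <- min(nx - 1, ceiling(centres[i, 1L] + r))
      y0 <- max(0, floor(centres[i, 2L] - r))
      y1 <- min(ny - 1, ceiling(centres[i, 2L] + r))
      gx <- exp(-((x0:x1) - centres[i, 1L])^2 / (2 * sig[i]^2))
      gy <- exp(-((y0:y1) - centres[i, 2L])^2 / (2 * sig[i]^2))
      img[(x0:x1) + 1L, (y0:y1) + 1L] <-
        img[(x0:x1) + 1L, (y0:y1) + 1L] + amp[i] * outer(gx, gy)
    }
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(nx * ny, 0, params$noise_sd), nx, ny)
    img <- pmin(pmax(img, 0), params$bit_range)
    dim(img) <- c(nx, ny)
    attr(img, "bit_origin") <- "16-bit"
    truth <- data.frame(x = centres[, 1L], y = centres[, 2L],
                        amplitude = amp, sigma = sig, doublet = doublet)
    list(image = img, mask = mask, truth = truth)
  })
}

#' Ground-truth centres as a point set
#'
#' @param scene result of [generate_scene()].
#' @return [point_set()] of the true spot centres, source `"truth"`.
#' @export
truth_points <- function(scene) {
  point_set(scene$truth$x, scene$truth$y, source = "truth")
}

#' Simulated annotator style
#'
#' Parameterises the error modes of a human annotator clicking foci:
#' positional jitter around the true maximum; a personal background
#' cutoff (spots whose rendered amplitude falls below the annotator's
#' intensity quantile are skipped); interpreting a diffraction-limited
#' blob as a doublet (clicking it twice a couple of pixels apart);
#' accidental double-clicks on one maximum; and spurious clicks on
#' empty background.
#'
#' @param jitter_sd click jitter SD in pixels.
#' @param intensity_cutoff_quantile fraction of the faintest spots
#'   skipped (0 = clicks everything).
#' @param doublet_prob probability a clicked spot is clicked twice,
#'   2--3 px apart.
#' @param double_click_prob probability of an exact duplicate click.
#' @param false_click_prob probability (per spot) of adding a spurious
#'   background click inside the nucleus.
#' @param source annotator label.
#' @return list of class `annotator_style`.
#' @export
annotator_style <- function(jitter_sd = 1, intensity_cutoff_quantile = 0,
                            doublet_prob = 0, double_click_prob = 0,
                            false_click_prob = 0, source = "annotator") {
  p <- c(intensity_cutoff_quantile, doublet_prob, double_click_prob,
         false_click_prob)
  stopifnot(jitter_sd >= 0, all(p >= 0), all(p <= 1))
  structure(list(jitter_sd = jitter_sd,
                 intensity_cutoff_quantile = intensity_cutoff_quantile,
                 doublet_prob = doublet_prob,
                 double_click_prob = double_click_prob,
                 false_click_prob = false_click_prob, source = source),
            class = "annotator_style")
}

#' Simulate an annotator clicking a scene
#'
#' Keeps the spots whose amplitude exceeds the annotator's intensity
#' cutoff quantile, jitters each click with isotropic Gaussian noise,
#' then injects doublet, duplicate and false clicks at the style's
#' rates. Clicks are rounded to whole pixels (annotators click pixels)
#' and clamped inside the image. Reproducible under seed.
#'
#' @param scene result of [generate_scene()].
#' @param style an [annotator_style()].
#' @param seed RNG seed.
#' @return a [point_set()] of clicks.
#' @export
simulate_annotator <- function(scene, style = annotator_style(),
                               seed = NULL) {
  stopifnot(inherits(style, "annotator_style"))
  with_seed(seed, {
    tr <- scene$truth
    nx <- nrow(scene$image); ny <- ncol(scene$image)
    keep <- rep(TRUE, nrow(tr))
    if (style$intensity_cutoff_quantile > 0 && nrow(tr) > 0L) {
      cut <- quantile(tr$amplitude, style$intensity_cutoff_quantile,
                      names = FALSE, type = 7)
      keep <- tr$amplitude > cut
    }
    cx <- tr$x[keep]; cy <- tr$y[keep]
    n <- length(cx)
    if (n > 0L && style$jitter_sd > 0) {
      cx <- cx + rnorm(n, 0, style$jitter_sd)
      cy <- cy + rnorm(n, 0, style$jitter_sd)
    }
    if (n > 0L && style$doublet_prob > 0) {
      dd <- which(runif(n) < style$doublet_prob)
      if (length(dd)) {
        th <- runif(length(dd), 0, 2 * pi)
        sep <- runif(length(dd), 2, 3)
        cx <- c(cx, cx[dd] + sep * cos(th))
        cy <- c(cy, cy[dd] + sep * sin(th))
      }
    }
    if (length(cx) > 0L && style$double_click_prob > 0) {
      dup <- which(runif(length(cx)) < style$double_click_prob)
      cx <- c(cx, cx[dup]); cy <- c(cy, cy[dup])
    }
    if (style$false_click_prob > 0 && nrow(tr) > 0L) {
      nf <- sum(runif(nrow(tr)) < style$false_click_prob)
      placed <- 0L
      while (placed < nf) {
        p <- c(runif(1, 0, nx - 1), runif(1, 0, ny - 1))
        if (scene$mask[floor(p[1L]) + 1L, floor(p[2L]) + 1L]) {
          cx <- c(cx, p[1L]); cy <- c(cy, p[2L])
          placed <- placed + 1L
        }
      }
    }
    cx <- pmin(pmax(round(cx), 0), nx - 1)
    cy <- pmin(pmax(round(cy), 0), ny - 1)
    point_set(cx, cy, source = style$source)
  })
}
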