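#' Grayscale time-lapse image stack
#'
#' Container for the microscope recording: a sequence of same-shape integer
#' grayscale frames with timestamps and a physical pixel pitch. Marker-dyed
#' regions are darker (lower levels) than the hydrogel background.
#'
#' @param frames list of integer matrices (grayscale levels).
#' @param bit_depth bits per pixel (default 8; levels in `[0, 2^bit_depth-1]`).
#' @param timestamps frame times, s (default `(0, 1, ...)/fps`).
#' @param fps acquisition rate used for default timestamps (default 1).
#' @param pixel_size physical pixel pitch, mm/px.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, bit_depth = 8, timestamps = NULL, fps = 1,
                        pixel_size = 0.01) {
  if (!length(frames)) stop("'frames' must be a non-empty list")
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all frames must have the same shape")
  lvl_max <- 2^bit_depth - 1
  rng <- range(vapply(frames, function(f) range(f), numeric(2)))
  if (rng[1] < 0 || rng[2] > lvl_max)
    stop(sprintf("pixel levels must lie within [0, %d]", lvl_max))
  if (is.null(timestamps)) timestamps <- (seq_along(frames) - 1) / fps
  if (length(timestamps) != length(frames) ||
      (length(timestamps) > 1 && any(diff(timestamps) <= 0)))
    stop("'timestamps' must be increasing, one per frame")
  structure(list(frames = frames, bit_depth = bit_depth,
                 timestamps = as.numeric(timestamps),
                 pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "Image stack: %d frames of %d x %d px (%d-bit), %g mm/px, t in [%g, %g] s\n",
    length(x$frames), d[1], d[2], x$bit_depth, x$pixel_size,
    min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

# pixel-center coordinates (mm) of rows/cols, origin at the frame center
frame_coords <- function(n, pixel_size) (seq_len(n) - (n + 1) / 2) * pixel_size

#' Estimate the background grayscale level
#'
#' Mean grayscale level over a region of the frame far from the marker spot:
#' either an annulus `r >= r_inner` about the frame center or square boxes in
#' the four corners.
#'
#' @param frame integer matrix of grayscale levels.
#' @param region list: `list(type = "annulus", r_inner = <px>)` or
#'   `list(type = "corners", frac = <fraction of frame side>)`.
#' @return Mean background level.
#' @export
estimate_background <- function(frame,
                                region = list(type = "corners", frac = 0.15)) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (identical(region$type, "annulus")) {
    rr <- sqrt(outer((seq_len(nr) - (nr + 1) / 2)^2,
                     (seq_len(nc) - (nc + 1) / 2)^2, `+`))
    sel <- rr >= region$r_inner
  } else if (identical(region$type, "corners")) {
    m <- max(1L, floor(region$frac * min(nr, nc)))
    sel <- matrix(FALSE, nr, nc)
    sel[c(seq_len(m), nr - seq_len(m) + 1L), c(seq_len(m), nc - seq_len(m) + 1L)] <- TRUE
  } else {
    stop("unknown background region type")
  }
  if (!any(sel)) stop("background region is empty")
  mean(frame[sel])
}

#' Background subtraction with inversion
#'
#' Converts grayscale levels to a non-negative concentration proxy:
#' `max(background - pixel, 0)`. Marker regions, being darker than the
#' background, map to higher values; pixels brighter than the background
#' (noise excursions) clip to zero so that no negative concentrations arise.
#'
#' @param frame integer matrix of grayscale levels.
#' @param background background level (within the frame's level range).
#' @return Numeric matrix of non-negative inverted intensities.
#' @export
subtract_invert <- function(frame, background) {
  pmax(background - frame, 0)
}

#' Intensity-weighted centroid of an inverted map
#'
#' @param map non-negative matrix (output of [subtract_invert()]).
#' @return Numeric `c(row, col)`, fractional pixel coordinates.
#' @export
find_center <- function(map) {
  tot <- sum(map)
  if (!length(map)) stop("empty map")
  if (tot <= 0) stop("all-zero map: no centroid")
  c(row = sum(rowSums(map) * seq_len(nrow(map))) / tot,
    col = sum(colSums(map) * seq_len(ncol(map))) / tot)
}

#' Diametral cross-section profile
#'
#' Extracts the horizontal line through the spot center (averaged over
#' `center row +/- w` rows against pixel noise) and converts column indices
#' to signed positions in mm about the center.
#'
#' @param map non-negative matrix (inverted intensities).
#' @param center `c(row, col)` center, fractional pixels.
#' @param pixel_size mm/px.
#' @param w half-width of the row-averaging band, px (default 1).
#' @return An object of class `radial_profile` with `positions` (mm, signed)
#'   and `values` (non-negative).
#' @export
extract_cross_section <- function(map, center, pixel_size, w = 1) {
  nr <- nrow(map); nc <- ncol(map)
  r0 <- round(center[[1]])
  if (r0 < 1 || r0 > nr || center[[2]] < 1 || center[[2]] > nc)
    stop("center lies outside the frame")
  rows <- max(1L, r0 - w):min(nr, r0 + w)
  vals <- colMeans(map[rows, , drop = FALSE])
  structure(list(positions = (seq_len(nc) - center[[2]]) * pixel_size,
                 values = vals),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile: %d samples over [%.3g, %.3g] mm, peak %.4g\n",
              length(x$positions), min(x$positions), max(x$positions),
              max(x$values)))
  invisible(x)
}

#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$positions, x$values, type = "l", xlab = "position (mm)",
                 ylab = "inverted intensity", ...)
  invisible(x)
}

# linear indices of the n pixels nearest `center`, disk-ordered by radius,
# ties broken by angle (atan2), then by linear index for exact ties
nearest_pixel_index <- function(dim_rc, center, n_pixels) {
  nr <- dim_rc[1]; nc <- dim_rc[2]
  if (n_pixels > nr * nc) stop("'n_pixels' exceeds the frame size")
  dr <- rep(seq_len(nr) - center[[1]], times = nc)
  dc <- rep(seq_len(nc) - center[[2]], each = nr)
  r2 <- dr^2 + dc^2
  ang <- atan2(dc, dr)
  ord <- order(r2, ang)
  ord[seq_len(n_pixels)]
}

#' Mean intensity over the pixels nearest the center
#'
#' Averages the `n_pixels` pixels closest to the spot center (a quantized
#' disk; ties at equal radius broken by angle). The default 238 pixels
#' matches the central-averaging region used when reducing the recordings to
#' a center trace.
#'
#' @param map numeric matrix.
#' @param center `c(row, col)`, fractional pixels.
#' @param n_pixels number of pixels to average (default 238).
#' @return Mean value over the selected pixels.
#' @export
center_mean <- function(map, center, n_pixels = 238) {
  if (n_pixels < 1) stop("'n_pixels' must be >= 1")
  idx <- nearest_pixel_index(dim(map), center, n_pixels)
  mean(map[idx])
}

#' Normalize maps and center values to unity at the initial center
#'
#' Divides inverted-intensity maps and their center means by the `t = 0`
#' center mean, so the normalized central value at the first frame is exactly
#' 1 — the convention used for the experimental profiles. Any common gain
#' applied to all frames cancels.
#'
#' @param maps list of inverted-intensity matrices.
#' @param center_values center mean per frame (same length as `maps`).
#' @param timestamps frame times, s.
#' @return List with `trace` (a [center_trace_obj()] of normalized center
#'   values) and `maps` (normalized matrices).
#' @export
normalize_stack <- function(maps, center_values, timestamps) {
  if (length(maps) != length(center_values))
    stop("'maps' and 'center_values' must have the same length")
  ref <- center_values[1]
  if (!(ref > 0)) stop("zero reference center value at t = 0")
  list(trace = center_trace_obj(timestamps, center_values / ref),
       maps = lapply(maps, function(m) m / ref))
}

#' Pseudocolor contrast enhancement
#'
#' Squares the background-normalized inverted intensity,
#' `((background - pixel)_+ / background)^2`, emphasizing the marker against
#' the phantom. Values lie in `[0, 1]` (a pixel at level 0 maps to 1);
#' rendering through a color map is left to the caller.
#'
#' @param frame integer matrix of grayscale levels.
#' @param background background level.
#' @return Numeric matrix in `[0, 1]`.
#' @export
pseudocolor_enhance <- function(frame, background) {
  e <- (subtract_invert(frame, background) / background)^2
  pmin(pmax(e, 0), 1)
}

#' Quantify an image stack into normalized profiles and a center trace
#'
#' Runs the full chain: estimate the background from the first frame, invert
#' and background-subtract every frame, locate the spot center on the first
#' frame, average the central disk of `n_center` pixels per frame, normalize
#' to unity at `t = 0`, and extract diametral cross-section profiles.
#'
#' @param stack an [image_stack()].
#' @param background_region region spec for [estimate_background()].
#' @param n_center pixels in the central averaging disk (default 238).
#' @param w cross-section row-averaging half-width, px.
#' @param profile_times times (s) at which to keep cross-section profiles
#'   (default: first and last frame).
#' @return An object of class `stack_quantification`: `trace` (normalized
#'   [center_trace_obj()]), `profiles` (named list of normalized
#'   `radial_profile`), `background`, `center`, `n_center`.
#' @export
quantify_stack <- function(stack,
                           background_region = list(type = "corners",
                                                    frac = 0.15),
                           n_center = 238, w = 1, profile_times = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  bg <- estimate_background(stack$frames[[1]], background_region)
  map0 <- subtract_invert(stack$frames[[1]], bg)
  center <- find_center(map0)
  idx <- nearest_pixel_index(dim(map0), center, n_center)
  cvals <- vapply(stack$frames, function(f) {
    mean(pmax(bg - f[idx], 0))
  }, numeric(1))
  ref <- cvals[1]
  if (!(ref > 0)) stop("zero reference center value at t = 0")
  trace <- center_trace_obj(stack$timestamps, cvals / ref,
                            averaging_radius =
                              sqrt(n_center / pi) * stack$pixel_size)
  if (is.null(profile_times))
    profile_times <- stack$timestamps[c(1L, length(stack$timestamps))]
  profiles <- list()
  for (tp in profile_times) {
    i <- which.min(abs(stack$timestamps - tp))
    pr <- extract_cross_section(subtract_invert(stack$frames[[i]], bg),
                                center, stack$pixel_size, w = w)
    pr$values <- pr$values / ref
    profiles[[sprintf("t=%gs", stack$timestamps[i])]] <- pr
  }
  structure(list(trace = trace, profiles = profiles, background = bg,
                 center = center, n_center = n_center),
            class = "stack_quantification")
}

#' @export
print.stack_quantification <- function(x, ...) {
  cat(sprintf(
    "Stack quantification: background %.2f, center (%.1f, %.1f) px, %d-px disk\n",
    x$background, x$center[1], x$center[2], x$n_center))
  print(x$trace)
  invisible(x)
}

#' Read a grayscale image stack from disk
#'
#' Accepts a multi-page TIFF file or a directory / vector of numbered PNG or
#' TIFF files (sorted lexicographically).
#'
#' @param path TIFF file, directory, or character vector of image files.
#' @param fps frames per second for default timestamps.
#' @param pixel_size mm/px.
#' @param bit_depth bits per pixel (default 8).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, fps = 1, pixel_size = 0.01, bit_depth = 8) {
  lvl_max <- 2^bit_depth - 1
  to_levels <- function(img) {
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel
    round(img * lvl_max)
  }
  if (length(path) == 1L && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                            ignore.case = TRUE, full.names = TRUE))
    if (!length(path)) stop("no PNG/TIFF files found in directory")
  }
  if (length(path) == 1L && grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, to_levels)
  } else {
    frames <- lapply(path, function(p) {
      if (grepl("\\.png$", p, ignore.case = TRUE)) {
        to_levels(png::readPNG(p))
      } else {
        to_levels(tiff::readTIFF(p))
      }
    })
  }
  image_stack(frames, bit_depth = bit_depth, fps = fps,
              pixel_size = pixel_size)
}

#' Write an image stack to disk
#'
#' @param stack an [image_stack()].
#' @param path output: a `.tif`/`.tiff` file (multi-page) or a directory
#'   (numbered PNG files `frame_0001.png`, ...).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  lvl_max <- 2^stack$bit_depth - 1
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(lapply(stack$frames, function(f) f / lvl_max), path,
                    bits.per.sample = 8L)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_along(stack$frames)) {
      png::writePNG(stack$frames[[i]] / lvl_max,
                    file.path(path, sprintf("frame_%04d.png", i)))
    }
  }
  invisible(path)
}
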