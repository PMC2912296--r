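# Synthetic fluorescence fiber images with known ground truth, for testing
# the skeleton morphometry chain. Fibers are straight, anti-aliased bright
# segments on a dark background (the analyzed images are inverted
# micrographs, fibers bright on dark).

# additively accumulate one anti-aliased segment onto `img` (numeric
# matrix); returns list(img, core) where core is the exact-coverage mask
# (distance to the segment spine <= half_width)
.draw_segment <- function(img, x0, y0, x1, y1, half_width, intensity) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- ceiling(half_width + 2)
  jmin <- max(1L, floor(min(x0, x1)) - pad); jmax <- min(nc, ceiling(max(x0, x1)) + pad)
  imin <- max(1L, floor(min(y0, y1)) - pad); imax <- min(nr, ceiling(max(y0, y1)) + pad)
  if (jmin > jmax || imin > imax) {
    return(list(img = img, core = matrix(FALSE, nr, nc)))
  }
  jj <- jmin:jmax; ii <- imin:imax
  px <- matrix(jj, length(ii), length(jj), byrow = TRUE)
  py <- matrix(ii, length(ii), length(jj))
  # distance from pixel centers to the segment [P0, P1]
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  tt <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  dist <- sqrt((px - (x0 + tt * vx))^2 + (py - (y0 + tt * vy))^2)
  cover <- pmin(1, pmax(0, half_width + 0.5 - dist))
  img[ii, jj] <- pmax(img[ii, jj], intensity * cover)
  core <- matrix(FALSE, nr, nc)
  core[ii, jj] <- dist <= half_width
  list(img = img, core = core)
}

#' Generate a synthetic fiber image with ground-truth lengths
#'
#' Draws `n_fibers` straight anti-aliased segments at uniformly random
#' positions and orientations on a constant background, returning the 8-bit
#' image together with the true per-fiber lengths in micrometres and the
#' exact fiber-core mask. With `overlap = FALSE`, candidate fibers are
#' rejection-sampled until their cores keep a 2-pixel clearance, so every
#' fiber is a separate particle.
#'
#' @param n_fibers Number of fibers (>= 0).
#' @param length_mean,length_sd Mean and s.d. of the fiber length
#'   distribution (um); lengths are truncated below at two pixels.
#' @param width_px Full fiber width in pixels.
#' @param img_size Image size in pixels, scalar or `c(rows, cols)`.
#' @param pixel_size Calibration (um per pixel).
#' @param background Background grey level (0-255).
#' @param intensity Peak fiber grey level (0-255).
#' @param overlap Allow fibers to overlap (default `FALSE`).
#' @param seed RNG seed; identical arguments give a bit-identical image.
#' @param max_attempts Placement attempts per fiber before failing.
#' @return List of class `"fiber_image"`: `image` (integer matrix, 0-255),
#'   `lengths_um` (ground truth), `mask` (logical fiber-core mask),
#'   `pixel_size`.
#' @export
generate_fiber_image <- function(n_fibers, length_mean = 15, length_sd = 2,
                                 width_px = 3, img_size = 256,
                                 pixel_size = 0.5, background = 10,
                                 intensity = 200, overlap = FALSE,
                                 seed = 1L, max_attempts = 200L) {
  if (length(img_size) == 1) img_size <- c(img_size, img_size)
  if (any(img_size < 8) || n_fibers < 0 || width_px <= 0) {
    stop("invalid image parameters")
  }
  if (pixel_size <= 0) stop("invalid calibration: pixel_size must be > 0")
  nr <- img_size[1]; nc <- img_size[2]
  img <- matrix(0, nr, nc)
  occupied <- matrix(FALSE, nr, nc)
  half_width <- width_px / 2
  lengths <- numeric(0)
  .with_seed(seed, {
    for (k in seq_len(n_fibers)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        L_um <- max(2 * pixel_size,
                    stats::rnorm(1, length_mean, length_sd))
        L_px <- L_um / pixel_size
        theta <- stats::runif(1, 0, pi)
        dx <- L_px / 2 * cos(theta); dy <- L_px / 2 * sin(theta)
        pad <- half_width + 2
        cx_lo <- 1 + pad + abs(dx); cx_hi <- nc - pad - abs(dx)
        cy_lo <- 1 + pad + abs(dy); cy_hi <- nr - pad - abs(dy)
        if (cx_lo >= cx_hi || cy_lo >= cy_hi) next
        cx <- stats::runif(1, cx_lo, cx_hi)
        cy <- stats::runif(1, cy_lo, cy_hi)
        drawn <- .draw_segment(img, cx - dx, cy - dy, cx + dx, cy + dy,
                               half_width, intensity)
        if (!overlap) {
          # demand 2 px clearance between fiber cores
          near <- .dilate_mask(drawn$core, 2L)
          if (any(near & occupied)) next
        }
        img <- drawn$img
        occupied <- occupied | drawn$core
        lengths <- c(lengths, L_um)
        placed <- TRUE
        break
      }
      if (!placed) stop("placement failure: could not place fiber ", k,
                        " without overlap")
    }
  })
  out <- background + img
  out[out < 0] <- 0
  out[out > 255] <- 255
  out <- round(out)
  storage.mode(out) <- "integer"
  structure(list(image = out, lengths_um = lengths, mask = occupied,
                 pixel_size = pixel_size),
            class = "fiber_image")
}

# binary dilation by a square structuring element of radius r (cheap,
# shift-based; used only for placement clearance checks)
.dilate_mask <- function(mask, r) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(nr, nr + di)
    ti <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 + dj):min(nc, nc + dj)
    tj <- max(1, 1 - dj):min(nc, nc - dj)
    out[ti, tj] <- out[ti, tj] | mask[si, sj]
  }
  out
}

#' @export
print.fiber_image <- function(x, ...) {
  cat(sprintf(
    "synthetic fiber image: %d x %d px, %d fibers, pixel size %.3g um/px\n",
    nrow(x$image), ncol(x$image), length(x$lengths_um), x$pixel_size))
  invisible(x)
}
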