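# Fiber morphometry: threshold -> watershed -> skeletonize -> particle
# analysis, producing per-fiber lengths (um) and image density (mean grey
# value). Images are 8-bit grayscale matrices, fibers bright on dark.

.check_gray <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("unsupported image: expected a numeric grayscale matrix")
  }
  if (length(image) == 0) stop("no pixels")
  if (any(!is.finite(image)) || any(image < 0) || any(image > 255)) {
    stop("unsupported image: values must be finite in [0, 255]")
  }
  invisible(image)
}

#' Binarize a grayscale image
#'
#' Foreground mask by either Otsu's method or a fixed threshold; in both
#' cases a pixel is foreground when strictly above the threshold.
#'
#' @param image Numeric matrix, 8-bit grayscale (0-255).
#' @param method `"otsu"` or `"fixed"`.
#' @param t Threshold for `method = "fixed"` (grey levels).
#' @return Logical mask with attribute `threshold` (the grey level used).
#' @export
binarize <- function(image, method = c("otsu", "fixed"), t = NULL) {
  .check_gray(image)
  method <- match.arg(method)
  thr <- if (method == "otsu") {
    255 * EBImage::otsu(EBImage::Image(image / 255), range = c(0, 1))
  } else {
    if (is.null(t)) stop("fixed threshold requires t")
    t
  }
  mask <- image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Split touching fibers and reduce them to labeled skeletons
#'
#' Watershed segmentation on the distance transform of the mask separates
#' touching blobs; morphological thinning (Zhang-Suen) then reduces each
#' blob to a one-pixel-wide skeleton. Skeleton pixels inherit the watershed
#' label of their blob, so fibers that touch remain distinct particles.
#'
#' @param mask Logical foreground mask, as from [binarize()].
#' @param tolerance,ext Watershed parameters (minimum object depth in
#'   distance-transform units, and neighborhood radius), passed to
#'   [EBImage::watershed()].
#' @return Integer label matrix: 0 background, `1..k` skeletonized fibers.
#'   An empty mask yields an all-zero matrix (no error).
#' @export
segment_and_skeletonize <- function(mask, tolerance = 1, ext = 1) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("unsupported image: expected a logical mask")
  }
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(labels)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance,
                                              ext = ext))
  skel <- .thin_mask(mask)
  keep <- skel & ws > 0
  labels[keep] <- as.integer(ws[keep])
  # compact label ids to 1..k
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) > 0) labels[labels > 0] <- match(labels[labels > 0], ids)
  labels
}

# shift a logical matrix by (di, dj), filling with FALSE
.shift_mask <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  si <- max(1, 1 + di):min(nr, nr + di)
  sj <- max(1, 1 + dj):min(nc, nc + dj)
  out[si - di, sj - dj] <- m[si, sj]
  out
}

# Zhang-Suen morphological thinning to a 1-px, 8-connected skeleton
.thin_mask <- function(mask) {
  p <- mask
  # neighbor order P2..P9 = N, NE, E, SE, S, SW, W, NW (row 1 at top)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- lapply(offs, function(o) .shift_mask(p, o[1], o[2]))
      B <- Reduce(`+`, nb)
      A <- matrix(0L, nrow(p), ncol(p))
      for (k in 1:8) {
        a <- nb[[k]]; b <- nb[[if (k == 8) 1 else k + 1]]
        A <- A + (!a & b)
      }
      if (sub == 1) {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[5]])  # P2*P4*P6 == 0
        c2 <- !(nb[[3]] & nb[[5]] & nb[[7]])  # P4*P6*P8 == 0
      } else {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[7]])  # P2*P4*P8 == 0
        c2 <- !(nb[[1]] & nb[[5]] & nb[[7]])  # P2*P6*P8 == 0
      }
      del <- p & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        p[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  .prune_staircase(p)
}

# Sequential simple-point pruning of thinning artifacts (staircase corners,
# doubled diagonals): a non-endpoint pixel whose foreground neighbors form a
# single 8-connected component can be removed without changing the skeleton
# topology. Removal is sequential, so neighboring candidates cannot
# disconnect each other.
.prune_staircase <- function(p) {
  # ring cells in order N, NE, E, SE, S, SW, W, NW; image adjacency between
  # ring cells (chebyshev distance 1) is fixed
  ring_off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                    c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  ring_adj <- outer(1:8, 1:8, Vectorize(function(a, b) {
    a != b && max(abs(ring_off[a, ] - ring_off[b, ])) <= 1
  }))
  n_ring_components <- function(fg) {
    comp <- integer(8); k <- 0L
    for (s in which(fg)) {
      if (comp[s] > 0L) next
      k <- k + 1L
      queue <- s
      while (length(queue) > 0) {
        q <- queue[1]; queue <- queue[-1]
        if (comp[q] > 0L) next
        comp[q] <- k
        queue <- c(queue, which(fg & ring_adj[q, ] & comp == 0L))
      }
    }
    k
  }
  nr <- nrow(p); nc <- ncol(p)
  repeat {
    removed <- FALSE
    for (q in which(p)) {
      i <- (q - 1L) %% nr + 1L
      j <- (q - 1L) %/% nr + 1L
      if (i <= 1 || i >= nr || j <= 1 || j >= nc) next
      fg <- logical(8)
      for (k in 1:8) fg[k] <- p[i + ring_off[k, 1], j + ring_off[k, 2]]
      if (sum(fg) >= 2 && n_ring_components(fg) == 1L) {
        p[i, j] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  p
}

#' Per-fiber skeleton lengths
#'
#' Chain-code length of each labeled skeleton: orthogonal neighbor steps
#' count 1 pixel, diagonal steps `sqrt(2)` pixels (a diagonal step is only
#' counted when it is not a shortcut across an existing orthogonal
#' connection). Lengths are returned in micrometres, sorted descending.
#'
#' @param skeletons Integer label matrix from [segment_and_skeletonize()].
#' @param pixel_size Calibration (um per pixel), > 0.
#' @return Numeric vector of fiber lengths (um), one per label, descending.
#' @export
fiber_sizes <- function(skeletons, pixel_size) {
  if (!is.matrix(skeletons)) stop("unsupported image: expected a label matrix")
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stop("invalid calibration: pixel_size must be > 0")
  }
  L <- skeletons
  ids <- sort(unique(L[L > 0]))
  if (length(ids) == 0) return(numeric(0))
  sh <- function(di, dj) .shift_mask2(L, di, dj)
  same <- function(s) L > 0 & s == L
  # orthogonal pairs: right and down neighbors
  orth <- list(same(sh(0, 1)), same(sh(1, 0)))
  # diagonal pairs: down-right and down-left, skipping bridged shortcuts
  dr <- same(sh(1, 1)) & !(same(sh(1, 0)) | same(sh(0, 1)))
  dl <- same(sh(1, -1)) & !(same(sh(1, 0)) | same(sh(0, -1)))
  count_by_label <- function(m) {
    v <- L[m]
    if (length(v) == 0) return(stats::setNames(numeric(length(ids)), ids))
    tab <- table(factor(v, levels = ids))
    as.numeric(tab)
  }
  n_orth <- count_by_label(orth[[1]]) + count_by_label(orth[[2]])
  n_diag <- count_by_label(dr) + count_by_label(dl)
  unname(sort((n_orth + sqrt(2) * n_diag) * pixel_size, decreasing = TRUE))
}

# integer-matrix shift, filling with 0 (background label)
.shift_mask2 <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  si <- max(1, 1 + di):min(nr, nr + di)
  sj <- max(1, 1 + dj):min(nc, nc + dj)
  out[si - di, sj - dj] <- m[si, sj]
  out
}

#' Fiber density of an image
#'
#' Mean grey value of the raw (unthresholded) image, the standard
#' fluorescence density proxy.
#'
#' @param image Numeric matrix, 8-bit grayscale (0-255).
#' @return Mean grey value (0-255).
#' @export
fiber_density <- function(image) {
  .check_gray(image)
  mean(image)
}

#' Full fiber morphometry of one image
#'
#' Convenience chain: [binarize()] -> [segment_and_skeletonize()] ->
#' [fiber_sizes()], plus [fiber_density()] on the raw image.
#'
#' @param image Numeric matrix, 8-bit grayscale (0-255).
#' @param pixel_size Calibration (um per pixel).
#' @param method,t Thresholding settings, see [binarize()].
#' @param tolerance,ext Watershed settings, see [segment_and_skeletonize()].
#' @return List of class `"fiber_stats"`: `sizes` (um, descending),
#'   `mean_size`, `sd_size`, `n_fibers`, `density` (mean grey value), and
#'   `threshold` used.
#' @export
fiber_stats <- function(image, pixel_size, method = "otsu", t = NULL,
                        tolerance = 1, ext = 1) {
  mask <- binarize(image, method = method, t = t)
  skel <- segment_and_skeletonize(mask, tolerance = tolerance, ext = ext)
  sizes <- fiber_sizes(skel, pixel_size)
  structure(list(sizes = sizes,
                 mean_size = if (length(sizes)) mean(sizes) else NA_real_,
                 sd_size = if (length(sizes) > 1) stats::sd(sizes) else NA_real_,
                 n_fibers = length(sizes),
                 density = fiber_density(image),
                 threshold = attr(mask, "threshold")),
            class = "fiber_stats")
}

#' @export
print.fiber_stats <- function(x, ...) {
  cat(sprintf(
    "fiber morphometry: %d fibers, mean size %.2f +/- %.2f um, density (m.g.v.) %.2f\n",
    x$n_fibers, x$mean_size, ifelse(is.na(x$sd_size), 0, x$sd_size),
    x$density))
  invisible(x)
}
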