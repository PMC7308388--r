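#' Render a stimulus point as a dot-array image
#'
#' Places `n` non-overlapping white discs of area ISA inside a circular
#' field of area FA centred on a square black canvas, then rasterizes them
#' without anti-aliasing (a pixel is white iff its centre falls inside a
#' disc). Placement is uniform rejection sampling with a minimum edge gap;
#' if a dot cannot be placed within `max_tries` proposals the whole image is
#' restarted, and after `max_restarts` failed restarts a placement error is
#' raised naming the stimulus point.
#'
#' Dot centres always lie inside the field disc; in addition each disc is
#' kept fully inside the canvas with a 1-px margin so rasterized area is not
#' clipped.
#'
#' @param point one-row `data.frame` (or list) with `n`, `size`, `spacing`.
#' @param canvas canvas side length in px (default 200).
#' @param min_gap minimum edge-to-edge gap between dots, px.
#' @param max_tries proposals per dot before restarting the image.
#' @param max_restarts image-level restarts before giving up.
#' @return Object of class `dot_array`: list with `pixels` (canvas x canvas
#'   0/1 matrix), `centers` (n x 2), `radius`, `field_radius`, `point`.
#' @export
render_dot_array <- function(point, canvas = 200, min_gap = 1,
                             max_tries = 10000, max_restarts = 20) {
  n <- as.integer(point$n)
  feat <- derive_features(data.frame(n = n, size = point$size,
                                     spacing = point$spacing))
  r <- sqrt(feat$isa / pi)
  field_r <- sqrt(feat$fa / pi)
  if (2 * field_r > canvas)
    stop("render_dot_array: field disc (diameter ", round(2 * field_r, 1),
         " px) does not fit in a ", canvas, " px canvas", call. = FALSE)
  cx <- canvas / 2
  # centres stay inside the field disc and dots fully on canvas
  place_r <- min(field_r, canvas / 2 - r - 1)
  if (place_r <= 0)
    stop("render_dot_array: dots too large for canvas", call. = FALSE)

  for (restart in seq_len(max_restarts)) {
    centers <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      tries <- 0
      while (tries < max_tries) {
        m <- min(64, max_tries - tries)
        tries <- tries + m
        # uniform proposals in the placement disc
        rr <- place_r * sqrt(stats::runif(m))
        th <- stats::runif(m, 0, 2 * pi)
        px <- cx + rr * cos(th)
        py <- cx + rr * sin(th)
        if (i == 1) {
          centers[1, ] <- c(px[1], py[1]); placed <- TRUE; break
        }
        prev <- centers[seq_len(i - 1), , drop = FALSE]
        d2min <- (2 * r + min_gap)^2
        for (j in seq_len(m)) {
          if (all((prev[, 1] - px[j])^2 + (prev[, 2] - py[j])^2 > d2min)) {
            centers[i, ] <- c(px[j], py[j]); placed <- TRUE; break
          }
        }
        if (placed) break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      pix <- rasterize_discs(centers, r, canvas)
      out <- list(pixels = pix, centers = centers, radius = r,
                  field_radius = field_r,
                  point = data.frame(n = n, size = point$size,
                                     spacing = point$spacing,
                                     instance_id =
                                       if (!is.null(point$instance_id))
                                         point$instance_id else NA))
      class(out) <- "dot_array"
      return(out)
    }
  }
  stop("render_dot_array: placement infeasible for point (n=", n,
       ", size=", signif(point$size, 4), ", spacing=",
       signif(point$spacing, 4), ")", call. = FALSE)
}

# binary rasterization: pixel centre (i-0.5, j-0.5) inside any disc
rasterize_discs <- function(centers, r, canvas) {
  pix <- matrix(0L, canvas, canvas)
  for (i in seq_len(nrow(centers))) {
    x0 <- centers[i, 1]; y0 <- centers[i, 2]
    xs <- max(1L, floor(x0 - r)):min(canvas, ceiling(x0 + r))
    ys <- max(1L, floor(y0 - r)):min(canvas, ceiling(y0 + r))
    dx2 <- (xs - 0.5 - x0)^2
    dy2 <- (ys - 0.5 - y0)^2
    inside <- outer(dx2, dy2, "+") <= r^2
    pix[xs, ys][inside] <- 1L
  }
  pix
}

#' Downscale an image by area-weighted averaging
#'
#' Each output pixel is the average of the source region it covers, so mean
#' intensity is preserved exactly; with an integer scale factor this is
#' plain block averaging. Output values lie in `[0, 1]`.
#'
#' @param img a `dot_array` or a numeric matrix.
#' @param target output side length (<= source side).
#' @return `target` x `target` numeric matrix in `[0, 1]`.
#' @export
downscale_image <- function(img, target) {
  x <- if (inherits(img, "dot_array")) img$pixels else img
  s <- nrow(x)
  if (target > s)
    stop("downscale_image: target larger than source", call. = FALSE)
  if (target == s) return(x * 1.0)
  A <- resample_weights(s, target)
  A %*% x %*% t(A)
}

# target x source matrix of interval-overlap weights, rows sum to 1
resample_weights <- function(s, target) {
  A <- matrix(0, target, s)
  scale <- s / target
  for (i in seq_len(target)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    js <- (floor(lo) + 1):ceiling(hi)
    w <- pmin(hi, js) - pmax(lo, js - 1)
    A[i, js] <- w / scale
  }
  A
}

#' Measure empirical features of a rendered dot array
#'
#' Recovers stimulus features from the rendered image: dot count from
#' 4-connected components of the binary image, total white area and mean
#' item area in px^2, convex hull area of the union of dot discs (hull of
#' the centres dilated by the dot radius: hull area + hull perimeter * r +
#' pi r^2), total perimeter assuming circular dots, and occupied field
#' extent (area of the smallest canvas-centred disc containing all dots).
#'
#' @param img a `dot_array`.
#' @return Named list: `count`, `total_area`, `mean_item_area`,
#'   `convex_hull_area`, `total_perimeter`, `field_extent`.
#' @export
measure_empirical_features <- function(img) {
  stopifnot(inherits(img, "dot_array"))
  pix <- img$pixels
  if (sum(pix) == 0)
    stop("measure_empirical_features: empty image", call. = FALSE)
  cnt <- count_components(pix)
  total <- sum(pix)
  r <- img$radius
  hull <- hull_area_discs(img$centers, r)
  cx <- nrow(pix) / 2
  dmax <- max(sqrt((img$centers[, 1] - cx)^2 + (img$centers[, 2] - cx)^2))
  list(
    count = cnt,
    total_area = total,
    mean_item_area = total / cnt,
    convex_hull_area = hull,
    total_perimeter = cnt * 2 * pi * r,
    field_extent = pi * (dmax + r)^2
  )
}

# exact area of the convex hull of a union of equal discs
hull_area_discs <- function(centers, r) {
  n <- nrow(centers)
  if (n == 1) return(pi * r^2)
  h <- grDevices::chull(centers[, 1], centers[, 2])
  hp <- centers[h, , drop = FALSE]
  k <- nrow(hp)
  if (k < 3) { # collinear centres: hull is a stadium over the extreme points
    d <- max(stats::dist(centers))
    return(pi * r^2 + 2 * r * d)
  }
  x <- hp[, 1]; y <- hp[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  area + per * r + pi * r^2
}

# 4-connected component count on a 0/1 matrix (iterative flood fill)
count_components <- function(pix) {
  nr <- nrow(pix); nc <- ncol(pix)
  lab <- matrix(0L, nr, nc)
  count <- 0L
  white <- which(pix == 1L)
  for (s in white) {
    if (lab[s] != 0L) next
    count <- count + 1L
    stack <- s
    lab[s] <- count
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      nb <- c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
              if (j > 1L) cur - nr, if (j < nc) cur + nr)
      nb <- nb[pix[nb] == 1L & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- count
        stack <- c(stack, nb)
      }
    }
  }
  count
}

#' Render a whole grid of stimulus points to a flattened image matrix
#'
#' Convenience batch renderer: renders every row of `grid`, optionally
#' downscales, and returns images as rows of a matrix (column-major pixel
#' flattening), the layout consumed by the deep-network trainer.
#'
#' @param grid a [build_full_grid()] result.
#' @param canvas render canvas side (px).
#' @param downscale_to optional output side; `NULL` keeps `canvas`.
#' @param measure_hull if `TRUE`, also return the empirical convex-hull
#'   area per image (used by categorical RSA models).
#' @return List: `images` (nrow(grid) x side^2 matrix), `side`, and
#'   optionally `hull_area` (numeric per image).
#' @export
render_grid_images <- function(grid, canvas = 200, downscale_to = NULL,
                               measure_hull = FALSE) {
  side <- if (is.null(downscale_to)) canvas else downscale_to
  imgs <- matrix(0, nrow(grid), side * side)
  hull <- if (measure_hull) numeric(nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    da <- render_dot_array(grid[i, , drop = FALSE], canvas = canvas)
    m <- if (is.null(downscale_to)) da$pixels else
      downscale_image(da, downscale_to)
    imgs[i, ] <- as.vector(m)
    if (measure_hull) hull[i] <- hull_area_discs(da$centers, da$radius)
  }
  out <- list(images = imgs, side = side)
  if (measure_hull) out$hull_area <- hull
  out
}

#' Write a dot array as ASCII PGM plus a centres CSV sidecar
#'
#' Plain-text image export (P2 portable graymap) used by the pipeline
#' stages; binary formats are deliberately avoided.
#'
#' @param img a `dot_array`.
#' @param path output path without extension; writes `path.pgm` and
#'   `path.csv`.
#' @return `path`, invisibly.
#' @export
write_dot_array <- function(img, path) {
  pix <- t(img$pixels) * 255L  # PGM is row-major, top row first
  con <- file(paste0(path, ".pgm"), "w")
  writeLines(c("P2", paste(ncol(pix), nrow(pix)), "255"), con)
  utils::write.table(pix, con, row.names = FALSE, col.names = FALSE)
  close(con)
  utils::write.csv(
    data.frame(x = img$centers[, 1], y = img$centers[, 2],
               radius = img$radius),
    paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
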