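#' Log-spaced level grid
#'
#' Levels evenly spaced on a logarithmic scale between `lo` and `hi`
#' (inclusive), as used for each dimension of the dot-array stimulus space.
#'
#' @param lo,hi positive range endpoints, `lo < hi`.
#' @param k number of levels (>= 2).
#' @return Numeric vector of `k` strictly increasing values with
#'   `level[i] = lo * (hi/lo)^((i-1)/(k-1))`.
#' @examples
#' log_grid_levels(7, 28, 13)
#' @export
log_grid_levels <- function(lo, hi, k) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= 0)
    stop("log_grid_levels: bounds must be positive", call. = FALSE)
  if (lo >= hi)
    stop("log_grid_levels: need lo < hi", call. = FALSE)
  if (!is.numeric(k) || k < 2 || k != round(k))
    stop("log_grid_levels: k must be an integer >= 2", call. = FALSE)
  i <- seq_len(k) - 1
  lo * (hi / lo)^(i / (k - 1))
}

#' Default stimulus-space level grids
#'
#' The canonical 13-level log grids: Numerosity 7--28 (rounded to integers),
#' Size 2.6e5--1.04e6 px^4, Spacing 0.8e7--3.2e7 px^4. Size is the product
#' of item surface area and total surface area; Spacing the product of field
#' area and sparsity, which makes the three dimensions orthogonal in log
#' space.
#'
#' @param n_range,size_range,spacing_range length-2 ranges per dimension.
#' @param k levels per dimension.
#' @return List with numeric vectors `numerosity`, `size`, `spacing`.
#' @export
default_space_levels <- function(n_range = c(7, 28),
                                 size_range = c(2.6e5, 10.4e5),
                                 spacing_range = c(0.8e7, 3.2e7),
                                 k = 13) {
  list(
    numerosity = round(log_grid_levels(n_range[1], n_range[2], k)),
    size       = log_grid_levels(size_range[1], size_range[2], k),
    spacing    = log_grid_levels(spacing_range[1], spacing_range[2], k)
  )
}

#' Build the full stimulus grid
#'
#' Cartesian product of the per-dimension levels, replicated `instances`
#' times with a unique instance index. Each row is one stimulus point
#' (one image to be rendered).
#'
#' @param num_levels integer dot counts (>= 1).
#' @param size_levels,spacing_levels positive Size / Spacing values (px^4).
#' @param instances replicate images per grid point (>= 1).
#' @return `data.frame` with columns `n`, `size`, `spacing`, `instance_id`.
#' @examples
#' lv <- default_space_levels()
#' nrow(build_full_grid(lv$numerosity, lv$size, lv$spacing, 10)) # 21970
#' @export
build_full_grid <- function(num_levels, size_levels, spacing_levels,
                            instances = 1) {
  if (length(num_levels) == 0 || length(size_levels) == 0 ||
      length(spacing_levels) == 0)
    stop("build_full_grid: empty level list", call. = FALSE)
  if (instances < 1)
    stop("build_full_grid: instances must be >= 1", call. = FALSE)
  if (any(num_levels < 1) || any(size_levels <= 0) || any(spacing_levels <= 0))
    stop("build_full_grid: invalid level values", call. = FALSE)
  g <- expand.grid(n = num_levels, size = size_levels,
                   spacing = spacing_levels, instance_id = seq_len(instances),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$n, g$size, g$spacing, g$instance_id), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("stimulus_grid", "data.frame")
  g
}

#' Derive continuous features from stimulus-space coordinates
#'
#' The Size and Spacing dimensions are defined as products of two areas
#' (Size = ISA x TSA, Spacing = FA x sparsity), so every individual feature
#' is an exact power-law combination of (n, Size, Spacing):
#' ISA = sqrt(Size/n), TSA = sqrt(Size*n), FA = sqrt(Spacing*n),
#' sparsity = sqrt(Spacing/n), coverage = sqrt(Size/Spacing), and for
#' circular dots total perimeter = n * 2*sqrt(pi*ISA).
#'
#' @param points `data.frame` with columns `n`, `size`, `spacing` (a
#'   [build_full_grid()] result or any subset of rows).
#' @return The input with appended columns `isa`, `tsa`, `fa`, `sparsity`,
#'   `coverage`, `total_perimeter` (areas in px^2, perimeter in px).
#' @export
derive_features <- function(points) {
  stopifnot(all(c("n", "size", "spacing") %in% names(points)))
  if (any(points$n < 1) || any(points$size <= 0) || any(points$spacing <= 0))
    stop("derive_features: invalid stimulus point", call. = FALSE)
  n <- points$n
  points$isa <- sqrt(points$size / n)
  points$tsa <- sqrt(points$size * n)
  points$fa <- sqrt(points$spacing * n)
  points$sparsity <- sqrt(points$spacing / n)
  points$coverage <- sqrt(points$size / points$spacing)
  points$total_perimeter <- n * 2 * sqrt(pi * points$isa)
  points
}

#' Names of the supported feature axes
#' @return Character vector of the ten feature names.
#' @export
feature_axis_names <- function() {
  c("numerosity", "size", "spacing", "isa", "tsa", "fa", "sparsity",
    "coverage", "total_perimeter", "convex_hull")
}

#' Feature axis in the orthonormal log-stimulus space
#'
#' Each feature's log-linear relation to (log2 n, log2 Size, log2 Spacing)
#' defines a direction in the 3-D space; e.g. log2 TSA =
#' (log2 n + log2 Size)/2 gives the unit direction (1,1,0)/sqrt(2).
#' Convex hull has no exact log-linear axis and is approximated by the
#' field-area direction, since at fixed n the hull scales with field area.
#'
#' @param name one of [feature_axis_names()].
#' @return Object of class `feature_axis`: list with `name` and unit
#'   3-vector `direction`.
#' @export
feature_axis <- function(name) {
  dirs <- list(
    numerosity      = c(1, 0, 0),
    size            = c(0, 1, 0),
    spacing         = c(0, 0, 1),
    isa             = c(-1, 1, 0),
    tsa             = c(1, 1, 0),
    fa              = c(1, 0, 1),
    sparsity        = c(-1, 0, 1),
    coverage        = c(0, 1, -1),
    total_perimeter = c(3, 1, 0),
    convex_hull     = c(1, 0, 1)
  )
  if (!name %in% names(dirs))
    stop("feature_axis: unknown feature '", name, "'", call. = FALSE)
  d <- dirs[[name]]
  structure(list(name = name, direction = d / sqrt(sum(d^2))),
            class = "feature_axis")
}

#' All (or a subset of) feature axes as a matrix
#' @param names feature names; defaults to all ten.
#' @return Matrix with one row per axis (unit vectors), rownames = features.
#' @export
feature_axes <- function(names = feature_axis_names()) {
  m <- t(vapply(names, function(nm) feature_axis(nm)$direction, numeric(3)))
  colnames(m) <- c("log2_num", "log2_size", "log2_spacing")
  m
}

#' Angle between two vectors, in degrees
#'
#' @param a,b nonzero numeric 3-vectors (a `feature_axis` is accepted).
#' @return Angle in `[0, 180]` degrees.
#' @export
angle_between <- function(a, b) {
  if (inherits(a, "feature_axis")) a <- a$direction
  if (inherits(b, "feature_axis")) b <- b$direction
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("angle_between: zero vector", call. = FALSE)
  cosang <- sum(a * b) / (na * nb)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Export a stimulus grid with derived features as CSV
#'
#' One row per stimulus point with columns n, size, spacing, instance_id,
#' isa, tsa, fa, sparsity, coverage, total_perimeter.
#'
#' @param grid a [build_full_grid()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stimulus_table <- function(grid, path) {
  utils::write.csv(derive_features(as.data.frame(grid)), path,
                   row.names = FALSE)
  invisible(path)
}
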