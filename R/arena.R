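#' Arena specification for a modified open-field system
#'
#' An `arena_spec` describes the rectangular open-field chamber, the
#' position of the floor-level water dispenser, the texturized patch that
#' signals it, and the duration for which each delivered drop of water
#' remains available. Coordinates use the arena's own frame: origin at one
#' corner, x rightward, y upward, units cm.
#'
#' @param width,height Arena dimensions in cm (default 100 x 100).
#' @param dispenser Numeric length-2, dispenser (x, y) in cm.
#' @param patch Numeric length-2, patch (x, y) in cm, or `NULL` to place it
#'   5.5 cm from the dispenser toward the arena centre (along +x when the
#'   dispenser already sits at the centre).
#' @param availability Seconds each water delivery remains available.
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec()                      # 100 x 100 cm, dispenser at the centre
#' make_arena("wall", wall_offset = 5)
#' @export
arena_spec <- function(width = 100, height = 100,
                       dispenser = c(width / 2, height / 2),
                       patch = NULL, availability = 3) {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width),
            is.numeric(height), length(height) == 1L, is.finite(height))
  if (width <= 0 || height <= 0)
    stop("arena width and height must be positive", call. = FALSE)
  dispenser <- as.numeric(dispenser)
  if (length(dispenser) != 2L || anyNA(dispenser))
    stop("dispenser must be a finite (x, y) pair", call. = FALSE)
  if (dispenser[1] < 0 || dispenser[1] > width ||
      dispenser[2] < 0 || dispenser[2] > height)
    stop("dispenser must lie inside the arena", call. = FALSE)
  if (is.null(patch)) {
    centre <- c(width / 2, height / 2)
    v <- centre - dispenser
    nv <- sqrt(sum(v^2))
    u <- if (nv < 1e-9) c(1, 0) else v / nv
    patch <- dispenser + 5.5 * u
  }
  patch <- as.numeric(patch)
  if (length(patch) != 2L || anyNA(patch) ||
      patch[1] < 0 || patch[1] > width || patch[2] < 0 || patch[2] > height)
    stop("patch must lie inside the arena", call. = FALSE)
  if (!is.numeric(availability) || length(availability) != 1L ||
      !is.finite(availability) || availability < 0)
    stop("availability must be a nonnegative duration in seconds", call. = FALSE)
  structure(
    list(width = width, height = height, dispenser = dispenser,
         patch = patch, availability = availability),
    class = "arena_spec"
  )
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g cm\n", x$width, x$height))
  cat(sprintf("  dispenser: (%g, %g) cm; patch: (%.1f, %.1f) cm\n",
              x$dispenser[1], x$dispenser[2], x$patch[1], x$patch[2]))
  cat(sprintf("  water availability: %g s\n", x$availability))
  invisible(x)
}

#' Build the arena for one experimental condition
#'
#' In the first condition the dispenser sits at the centre of the chamber;
#' in the second it sits next to a wall, `wall_offset` cm from the bottom
#' wall at mid-width. The signalling patch is placed 5.5 cm from the
#' dispenser toward the arena centre.
#'
#' @param condition `"center"` or `"wall"`.
#' @param wall_offset Distance (cm) from the wall to the dispenser in the
#'   wall condition; must lie in (0, height/2).
#' @param width,height,availability Passed to [arena_spec()].
#' @return An `arena_spec`.
#' @examples
#' make_arena("center")$dispenser   # (50, 50)
#' make_arena("wall", 5)$dispenser  # (50, 5)
#' @export
make_arena <- function(condition = c("center", "wall"), wall_offset = 5,
                       width = 100, height = 100, availability = 3) {
  condition <- match.arg(condition)
  if (!is.numeric(wall_offset) || length(wall_offset) != 1L ||
      !is.finite(wall_offset) || wall_offset <= 0 || wall_offset >= height / 2)
    stop("wall_offset must lie in (0, height/2)", call. = FALSE)
  dispenser <- switch(condition,
    center = c(width / 2, height / 2),
    wall   = c(width / 2, wall_offset)
  )
  arena_spec(width = width, height = height, dispenser = dispenser,
             availability = availability)
}

#' Maximum possible distance from a point to anywhere in the arena
#'
#' The farthest arena location from any interior point of a rectangle is a
#' corner, so this is the maximum of the four corner distances. Used as the
#' denominator of the relative distance-to-dispenser series.
#'
#' @param point Numeric (x, y) in cm, inside the arena.
#' @param arena An [arena_spec()].
#' @return Distance in cm.
#' @examples
#' max_distance_to(c(50, 50), arena_spec())  # 50 * sqrt(2)
#' @export
max_distance_to <- function(point, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  point <- as.numeric(point)
  if (length(point) != 2L || anyNA(point))
    stop("point must be a finite (x, y) pair", call. = FALSE)
  if (point[1] < 0 || point[1] > arena$width ||
      point[2] < 0 || point[2] > arena$height)
    stop("point lies outside the arena", call. = FALSE)
  corners_x <- c(0, arena$width, 0, arena$width)
  corners_y <- c(0, 0, arena$height, arena$height)
  max(sqrt((corners_x - point[1])^2 + (corners_y - point[2])^2))
}

#' Zone grid: the spatial partition of the arena
#'
#' Tiles the arena exactly into `n_rows` x `n_cols` rectangular regions.
#' Regions are indexed 0-based, row-major: region 0 is the cell containing
#' the origin corner, indices increase with x along a row and with y across
#' rows. Cells are half-open `[x0, x1) x [y0, y1)` except the last column
#' and row, which are closed so that every point of the closed arena maps
#' to exactly one region.
#'
#' @param arena An [arena_spec()].
#' @param n_rows,n_cols Number of grid rows/columns (default 10 x 10).
#' @return An object of class `zone_grid`.
#' @export
zone_grid <- function(arena, n_rows = 10, n_cols = 10) {
  stopifnot(inherits(arena, "arena_spec"))
  if (!is.numeric(n_rows) || n_rows < 1 || n_rows != round(n_rows) ||
      !is.numeric(n_cols) || n_cols < 1 || n_cols != round(n_cols))
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         arena = arena),
    class = "zone_grid"
  )
}

#' @export
print.zone_grid <- function(x, ...) {
  cat(sprintf("<zone_grid> %d x %d regions over a %g x %g cm arena\n",
              x$n_rows, x$n_cols, x$arena$width, x$arena$height))
  invisible(x)
}

n_regions <- function(grid) grid$n_rows * grid$n_cols

#' Region index of points on the zone grid
#'
#' Vectorised over points. Returns the 0-based row-major region index of
#' each point (see [zone_grid()] for the indexing convention).
#'
#' @param x,y Numeric vectors of coordinates in cm.
#' @param grid A [zone_grid()].
#' @return Integer vector of region indices in `[0, n_rows * n_cols)`.
#' @examples
#' g <- zone_grid(arena_spec())
#' region_of(0.1, 0.1, g)   # 0
#' region_of(100, 100, g)   # 99
#' @export
region_of <- function(x, y, grid) {
  stopifnot(inherits(grid, "zone_grid"))
  a <- grid$arena
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  bad <- which(!is.finite(x) | !is.finite(y) |
               x < 0 | x > a$width | y < 0 | y > a$height)
  if (length(bad))
    stop(sprintf("point %d (%.6g, %.6g) lies outside the arena",
                 bad[1], x[bad[1]], y[bad[1]]), call. = FALSE)
  col <- pmin(floor(x * grid$n_cols / a$width), grid$n_cols - 1L)
  row <- pmin(floor(y * grid$n_rows / a$height), grid$n_rows - 1L)
  as.integer(row * grid$n_cols + col)
}

#' Peripheral (outer-ring) regions of a zone grid
#'
#' The outer ring of grid cells operationalises the arena's peripheral
#' (thigmotaxis) zone; its complement is the central zone.
#'
#' @param grid A [zone_grid()] with at least 3 rows and 3 columns.
#' @return Sorted integer vector of 0-based region indices on the outer ring.
#' @examples
#' length(peripheral_mask(zone_grid(arena_spec())))  # 36
#' @export
peripheral_mask <- function(grid) {
  stopifnot(inherits(grid, "zone_grid"))
  if (grid$n_rows < 3 || grid$n_cols < 3)
    stop("peripheral_mask needs a grid of at least 3 x 3", call. = FALSE)
  idx <- 0:(n_regions(grid) - 1L)
  row <- idx %/% grid$n_cols
  col <- idx %% grid$n_cols
  sort(idx[row == 0L | row == grid$n_rows - 1L |
           col == 0L | col == grid$n_cols - 1L])
}
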