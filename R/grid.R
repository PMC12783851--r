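#' Create a uniform grid of search piles
#'
#' Defines the foraging terrain: `rows * cols` piles on a uniform lattice
#' with a physical pitch (centre-to-centre spacing) in meters. Pile ids are
#' the integers `0 .. rows*cols - 1`, mapped row-major to 0-based lattice
#' coordinates `(col, row)`; the physical position of a pile is its lattice
#' coordinate times the pitch, with the origin at one corner of the room.
#'
#' The default pitch of 0.3 m matches the pile-to-meter conversion used by
#' the kernel model (1 pile = 0.3 m); `pitch = 0.25` reproduces the
#' alternative arena spacing.
#'
#' @param rows,cols Number of lattice rows and columns (each >= 1).
#' @param pitch Lattice spacing in meters (> 0).
#' @return A `pile_grid` object.
#' @examples
#' make_grid(9, 12)            # 108 piles
#' make_grid(9, 9)             # 81 piles
#' pile_coords(make_grid(3, 3))
#' @export
make_grid <- function(rows, cols, pitch = 0.3) {
  if (length(rows) != 1 || length(cols) != 1 || length(pitch) != 1 ||
      !is.finite(rows) || !is.finite(cols) || !is.finite(pitch) ||
      rows < 1 || cols < 1 || pitch <= 0 ||
      rows != as.integer(rows) || cols != as.integer(cols)) {
    abort("`rows` and `cols` must be positive integers and `pitch` > 0.",
          class = "foragekernel_invalid_argument")
  }
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  n <- rows * cols
  pile <- 0:(n - 1L)
  col <- pile %% cols
  row <- pile %/% cols
  structure(
    list(
      rows = rows, cols = cols, pitch = pitch, n_piles = n,
      # lattice coordinates, one row per pile id (0-based ids)
      coords = cbind(col = col, row = row)
    ),
    class = "pile_grid"
  )
}

#' @export
print.pile_grid <- function(x, ...) {
  cat(sprintf("<pile_grid> %d x %d = %d piles, pitch %.3g m\n",
              x$rows, x$cols, x$n_piles, x$pitch))
  invisible(x)
}

#' Pile coordinates of a grid
#'
#' @param grid A [make_grid()] object.
#' @return A tibble with one row per pile: `pile` (0-based id), lattice
#'   `col` and `row`, and physical `x`, `y` in meters.
#' @export
pile_coords <- function(grid) {
  stopifnot(inherits(grid, "pile_grid"))
  tibble(
    pile = 0:(grid$n_piles - 1L),
    col = unname(grid$coords[, "col"]),
    row = unname(grid$coords[, "row"]),
    x = unname(grid$coords[, "col"]) * grid$pitch,
    y = unname(grid$coords[, "row"]) * grid$pitch
  )
}

# squared lattice distance matrix between all piles (unit = piles)
grid_dist2 <- function(grid) {
  cc <- grid$coords
  dx <- outer(cc[, "col"], cc[, "col"], "-")
  dy <- outer(cc[, "row"], cc[, "row"], "-")
  dx * dx + dy * dy
}

# Gaussian kernel matrix K[a, b] = exp(-d_ab^2 / (2 sigma^2)), lattice units.
# Cached per (grid, sigma) in `cache` (an environment) when supplied.
kernel_matrix <- function(grid, sigma, cache = NULL) {
  key <- sprintf("k%.12g", sigma)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  k <- exp(-grid_dist2(grid) / (2 * sigma^2))
  if (!is.null(cache)) cache[[key]] <- k
  k
}

check_pile_ids <- function(pile, grid, what = "pile id") {
  bad <- which(!is.finite(pile) | pile < 0 | pile >= grid$n_piles |
                 pile != floor(pile))
  if (length(bad)) {
    abort(sprintf("invalid %s %s for a %d-pile grid (row %d)",
                  what, format(pile[bad[1]]), grid$n_piles, bad[1]),
          class = "foragekernel_format_error")
  }
  invisible(as.integer(pile))
}
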