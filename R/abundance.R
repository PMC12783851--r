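#' Hidden abundance maps
#'
#' An abundance map assigns a hidden, non-negative reward count to every
#' pile of a grid. Two constructions are provided, mirroring the two
#' terrain conditions of the study:
#'
#' * **localized** ([generate_localized_map()]): a single circular disk of
#'   21 filled piles -- 3 items at the centre, 2 in each of the 8 piles of
#'   the Chebyshev ring around it, and 1 in each of the 12 adjacent piles
#'   forming the outer margin of the disk (the piles at squared lattice
#'   distance 4 or 5 from the centre), 31 items in total. The centre is
#'   drawn uniformly among piles whose whole disk fits inside the grid.
#' * **scattered** ([generate_scattered_map()]): four randomly placed,
#'   pairwise disjoint patches of three piles each, arranged as an
#'   L-shaped (corner) triomino with a uniformly random orientation.
#'
#' @param grid A [make_grid()] grid.
#' @param seed Optional integer seed; with a fixed seed generation is
#'   bit-reproducible.
#' @param center Optional pile id forced as disk centre (localized maps).
#' @param items_per_pile Reward items per filled pile (scattered maps).
#' @return An `abundance_map` object; see [map_counts()].
#' @name abundance_map
NULL

# lattice offsets of the 21-pile localized disk, by reward count
localized_offsets <- function() {
  ring0 <- cbind(0L, 0L)
  ring1 <- as.matrix(expand.grid(dc = -1:1, dr = -1:1))
  ring1 <- ring1[!(ring1[, 1] == 0 & ring1[, 2] == 0), , drop = FALSE]
  all2 <- as.matrix(expand.grid(dc = -2:2, dr = -2:2))
  d2 <- all2[, 1]^2 + all2[, 2]^2
  ring2 <- all2[d2 %in% c(4L, 5L), , drop = FALSE]
  list(ring0 = ring0, ring1 = unname(ring1), ring2 = unname(ring2))
}

new_abundance_map <- function(grid, counts, kind, params, seed) {
  structure(
    list(grid = grid, counts = as.integer(counts), kind = kind,
         params = params, seed = seed),
    class = "abundance_map"
  )
}

#' @rdname abundance_map
#' @examples
#' g <- make_grid(9, 12)
#' m <- generate_localized_map(g, seed = 1)
#' sum(map_counts(m) > 0)  # 21 filled piles
#' sum(map_counts(m))      # 31 hidden items
#' @export
generate_localized_map <- function(grid, seed = NULL, center = NULL) {
  stopifnot(inherits(grid, "pile_grid"))
  off <- localized_offsets()
  # the disk spans 2 lattice units in every direction
  ok_col <- grid$coords[, "col"] >= 2 & grid$coords[, "col"] <= grid$cols - 3L
  ok_row <- grid$coords[, "row"] >= 2 & grid$coords[, "row"] <= grid$rows - 3L
  eligible <- which(ok_col & ok_row) - 1L
  if (!length(eligible)) {
    abort("grid too small to contain the 21-pile localized disk (needs >= 5x5)",
          class = "foragekernel_invalid_argument")
  }
  if (is.null(center)) {
    center <- with_seed(seed, function() {
      eligible[sample.int(length(eligible), 1L)]
    })
  } else {
    center <- check_pile_ids(center, grid, "center pile id")
    if (!(center %in% eligible)) {
      abort("the 21-pile disk around `center` overflows the grid edge",
            class = "foragekernel_invalid_argument")
    }
  }
  counts <- integer(grid$n_piles)
  cc <- grid$coords[center + 1L, ]
  place <- function(offsets, k) {
    ids <- (cc["row"] + offsets[, 2]) * grid$cols + (cc["col"] + offsets[, 1])
    counts[ids + 1L] <<- k
  }
  place(off$ring2, 1L)
  place(off$ring1, 2L)
  place(off$ring0, 3L)
  new_abundance_map(grid, counts, "localized", list(center = center), seed)
}

# the four orientations of an L (corner) triomino, as lattice offsets
corner_triominoes <- function() {
  list(
    rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L)),
    rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L)),
    rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L)),
    rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
  )
}

#' @rdname abundance_map
#' @param max_attempts Rejection-sampling bound before a placement-failure
#'   error is raised.
#' @examples
#' s <- generate_scattered_map(g, seed = 1)
#' sum(map_counts(s) > 0)  # 12 filled piles, 4 disjoint corner patches
#' @export
generate_scattered_map <- function(grid, seed = NULL, items_per_pile = 1L,
                                   max_attempts = 1000L) {
  stopifnot(inherits(grid, "pile_grid"))
  if (items_per_pile < 1 || items_per_pile != floor(items_per_pile)) {
    abort("`items_per_pile` must be a positive integer",
          class = "foragekernel_invalid_argument")
  }
  if (grid$n_piles < 12L || grid$rows < 2L || grid$cols < 2L) {
    abort("grid cannot host 4 disjoint corner triominoes",
          class = "foragekernel_placement_failure")
  }
  shapes <- corner_triominoes()
  draw <- function() {
    occupied <- logical(grid$n_piles)
    patches <- vector("list", 4L)
    for (p in 1:4) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        sh <- shapes[[sample.int(4L, 1L)]]
        a_col <- sample.int(grid$cols - 1L, 1L) - 1L
        a_row <- sample.int(grid$rows - 1L, 1L) - 1L
        ids <- (a_row + sh[, 2]) * grid$cols + (a_col + sh[, 1])
        if (!any(occupied[ids + 1L])) {
          occupied[ids + 1L] <- TRUE
          patches[[p]] <- list(anchor = c(a_col, a_row), piles = ids)
          placed <- TRUE
          break
        }
      }
      if (!placed) return(NULL)
    }
    patches
  }
  patches <- with_seed(seed, draw)
  if (is.null(patches)) {
    abort("could not place 4 disjoint corner patches (placement failure)",
          class = "foragekernel_placement_failure")
  }
  counts <- integer(grid$n_piles)
  for (p in patches) counts[p$piles + 1L] <- as.integer(items_per_pile)
  new_abundance_map(grid, counts, "scattered", list(patches = patches), seed)
}

#' Reward counts of an abundance map
#'
#' @param map An `abundance_map`.
#' @return Integer vector of hidden reward counts, indexed by pile id + 1.
#' @export
map_counts <- function(map) {
  stopifnot(inherits(map, "abundance_map"))
  map$counts
}

#' @export
print.abundance_map <- function(x, ...) {
  cat(sprintf("<abundance_map> %s, %d filled piles, %d items on %d piles\n",
              x$kind, sum(x$counts > 0), sum(x$counts), x$grid$n_piles))
  invisible(x)
}
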