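#' Kernel sizes and mixing weights of the choice model
#'
#' The choice model combines three Gaussian kernel density fields over the
#' grid -- ambiguity, reward and proximity -- each with its own kernel size
#' (the standard deviation of the 2-D Gaussian). Kernel sizes may be given
#' in lattice pile units or in meters; one convention per run, converted
#' through the grid pitch where needed. The mixing weights are unitless,
#' non-negative, and sum to one.
#'
#' @param ambiguity,reward,proximity Kernel standard deviations (> 0).
#' @param units `"piles"` (lattice units, default) or `"m"`.
#' @return A `kernel_params` object.
#' @examples
#' kernel_params(3, 1, 2)                  # the generative-model defaults
#' kernel_params(0.9, 0.3, 0.6, units = "m")  # identical at pitch 0.3 m
#' @export
kernel_params <- function(ambiguity = 3, reward = 1, proximity = 2,
                          units = c("piles", "m")) {
  units <- match.arg(units)
  s <- c(ambiguity = ambiguity, reward = reward, proximity = proximity)
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("all kernel sizes must be positive",
          class = "foragekernel_invalid_argument")
  }
  structure(list(ambiguity = ambiguity, reward = reward,
                 proximity = proximity, units = units),
            class = "kernel_params")
}

# kernel sizes in lattice pile units
sigma_piles <- function(kernels, grid) {
  s <- c(kernels$ambiguity, kernels$reward, kernels$proximity)
  if (identical(kernels$units, "m")) s <- s / grid$pitch
  setNames(s, c("ambiguity", "reward", "proximity"))
}

#' @rdname kernel_params
#' @param info,rew,prox Mixing weights of the ambiguity (information),
#'   reward and proximity fields; non-negative, summing to 1 (within 1e-9).
#' @examples
#' weight_set(1 / 3, 1 / 3, 1 / 3)
#' @export
weight_set <- function(info, rew, prox = 1 - info - rew) {
  w <- c(info = info, rew = rew, prox = prox)
  if (any(!is.finite(w)) || any(w < -1e-9) || abs(sum(w) - 1) > 1e-9) {
    abort("weights must be non-negative and sum to 1",
          class = "foragekernel_invalid_argument")
  }
  structure(as.list(pmax(w, 0)), class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set> info %.3f, reward %.3f, proximity %.3f\n",
              x$info, x$rew, x$prox))
  invisible(x)
}

#' Evolving state of a foraging session
#'
#' Tracks which piles have been searched, the rewards discovered so far,
#' and the forager's current location. Before the first search the forager
#' sits at a (virtual) start pile -- by convention the gate-side corner,
#' pile 0 -- which centres the proximity kernel for the first choice
#' without removing that pile from the ambiguity field.
#'
#' @param grid A [make_grid()] grid.
#' @param start Pile id of the forager's starting location (default 0).
#' @return A `choice_state` object.
#' @export
choice_state <- function(grid, start = 0L) {
  stopifnot(inherits(grid, "pile_grid"))
  start <- check_pile_ids(start, grid, "start pile id")
  structure(
    list(
      grid = grid,
      searched = logical(grid$n_piles),
      rewards = integer(grid$n_piles),  # discovered items per pile
      current = start,
      n_searched = 0L,
      kcache = new.env(parent = emptyenv())
    ),
    class = "choice_state"
  )
}

#' @export
print.choice_state <- function(x, ...) {
  cat(sprintf("<choice_state> %d/%d piles searched, %d rewards found, at pile %d\n",
              x$n_searched, x$grid$n_piles, sum(x$rewards), x$current))
  invisible(x)
}

#' Component kernel density field
#'
#' Evaluates one of the three fields at every pile centre, as the mean of
#' unnormalised Gaussian kernels `exp(-d^2 / (2 sigma^2))` over the
#' component's centres: every unsearched pile (ambiguity), one centre per
#' discovered reward item at the pile where it was found (reward), or the
#' single current location (proximity). Kernels are truncated at the grid
#' boundary (no wraparound). An empty centre set yields an all-zero field.
#'
#' @param state A [choice_state()].
#' @param component `"ambiguity"`, `"reward"` or `"proximity"`.
#' @param sigma Kernel standard deviation in lattice pile units (> 0).
#' @return Numeric vector of field values, indexed by pile id + 1.
#' @export
component_field <- function(state, component = c("ambiguity", "reward", "proximity"),
                            sigma) {
  stopifnot(inherits(state, "choice_state"))
  component <- match.arg(component)
  if (!is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be positive", class = "foragekernel_invalid_argument")
  }
  k <- kernel_matrix(state$grid, sigma, state$kcache)
  mult <- switch(
    component,
    ambiguity = as.numeric(!state$searched),
    reward = as.numeric(state$rewards),
    proximity = {
      m <- numeric(state$grid$n_piles)
      m[state$current + 1L] <- 1
      m
    }
  )
  n_centers <- sum(mult)
  if (n_centers == 0) return(numeric(state$grid$n_piles))
  as.vector(k %*% mult) / n_centers
}

#' Per-pile choice probabilities
#'
#' The probability that each available (unsearched) pile is chosen as the
#' next pile to search: each component field is restricted to the
#' available piles and normalised to unit sum (an identically zero
#' component contributes nothing and its weight is absorbed by the final
#' renormalisation), the three are combined with the mixing weights, and
#' the weighted sum is renormalised to unit sum. Searched piles carry
#' probability exactly zero.
#'
#' @param state A [choice_state()].
#' @param weights A [weight_set()].
#' @param kernels A [kernel_params()].
#' @param normalize `"component"` (default): each field is normalised to
#'   unit sum over the available piles before weighting, so the weights
#'   stay comparable as maps fill and empty; `"final"`: the raw
#'   kernel-average fields are weighted directly and only the weighted
#'   sum is normalised.
#' @return Numeric vector of probabilities over all piles (zero on
#'   searched piles), with attribute `available` (logical vector).
#' @export
choice_distribution <- function(state, weights, kernels,
                                normalize = c("component", "final")) {
  stopifnot(inherits(state, "choice_state"), inherits(weights, "weight_set"),
            inherits(kernels, "kernel_params"))
  normalize <- match.arg(normalize)
  avail <- !state$searched
  if (!any(avail)) {
    abort("no available piles: the terrain is exhausted",
          class = "foragekernel_exhausted_terrain")
  }
  sig <- sigma_piles(kernels, state$grid)
  w <- c(weights$info, weights$rew, weights$prox)
  comps <- list(
    component_field(state, "ambiguity", sig[["ambiguity"]]),
    component_field(state, "reward", sig[["reward"]]),
    component_field(state, "proximity", sig[["proximity"]])
  )
  p <- numeric(state$grid$n_piles)
  for (i in 1:3) {
    f <- comps[[i]][avail]
    tot <- if (normalize == "component") sum(f) else 1
    if (sum(f) > 0) p[avail] <- p[avail] + w[i] * f / tot
  }
  tot <- sum(p)
  if (tot <= 0) {
    # all weighted components vanished (e.g. zero weight on the only
    # non-empty field): fall back to uniform over available piles
    p[avail] <- 1 / sum(avail)
  } else {
    p <- p / tot
  }
  attr(p, "available") <- avail
  p
}

#' Record a pile search and update the state
#'
#' Moves the forager to `pile`, marks it searched (its ambiguity kernel is
#' removed), and adds one reward kernel centre per item observed there.
#' The proximity kernel recentres on the searched pile.
#'
#' @param state A [choice_state()].
#' @param pile Pile id about to be searched; must be unsearched.
#' @param observed_rewards Number of reward items found there (>= 0).
#' @return The updated `choice_state`.
#' @export
advance_state <- function(state, pile, observed_rewards = 0L) {
  stopifnot(inherits(state, "choice_state"))
  pile <- check_pile_ids(pile, state$grid)
  if (state$searched[pile + 1L]) {
    abort(sprintf("pile %d was already searched (revisit)", pile),
          class = "foragekernel_revisit_error")
  }
  if (observed_rewards < 0 || observed_rewards != floor(observed_rewards)) {
    abort("`observed_rewards` must be a non-negative integer",
          class = "foragekernel_invalid_argument")
  }
  state$searched[pile + 1L] <- TRUE
  state$rewards[pile + 1L] <- state$rewards[pile + 1L] + as.integer(observed_rewards)
  state$current <- pile
  state$n_searched <- state$n_searched + 1L
  state
}

#' Dump a per-pile field as a grid-shaped CSV matrix
#'
#' Writes any per-pile vector (a component field or a choice
#' distribution) as a `rows x cols` CSV matrix laid out like the grid,
#' for inspection and debugging.
#'
#' @param field Numeric vector indexed by pile id + 1.
#' @param grid The [make_grid()] grid the field lives on.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, grid, path) {
  stopifnot(inherits(grid, "pile_grid"), length(field) == grid$n_piles)
  m <- matrix(as.numeric(field), nrow = grid$rows, ncol = grid$cols,
              byrow = TRUE)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
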