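#' Agent specifications
#'
#' Describes a simulated forager. The `generative` kind samples each next
#' pile from the kernel-based choice distribution sharpened by the
#' exponent `p`; the marginal kinds isolate a single drive:
#'
#' * `information_seeker`: moves to the peak of the ambiguity field (ties
#'   broken uniformly at random);
#' * `reward_seeker`: searches uniformly at random until the first
#'   success, then samples proportionally to the reward field (vicinity of
#'   the discovered rewards, radius set by the reward kernel);
#' * `energy_preserver`: chooses uniformly among the nearest available
#'   piles, i.e. only takes the shortest possible steps;
#' * `random`: uniform sampling without replacement (naive baseline);
#' * `informed`: knows the abundance map and always moves to the nearest
#'   filled unsearched pile (upper-bound baseline; falls back to the
#'   nearest unsearched pile once all rewards are found).
#'
#' @param kind Agent kind, see above.
#' @param weights A [weight_set()] (generative agents).
#' @param kernels A [kernel_params()].
#' @param p Sharpening exponent applied to the choice distribution
#'   (`p = 0` samples uniformly, large `p` approaches the argmax);
#'   the generative simulations use `p = 5`.
#' @param start Start pile id (gate-side corner, 0, by default).
#' @param stop_rule `"all_piles"`, `"all_rewards"`, or `"max_steps"`.
#' @param max_steps Step cap, applied for any stop rule when finite.
#' @param normalize Field normalisation convention passed to
#'   [choice_distribution()] (generative agents).
#' @return An `agent_spec` object.
#' @export
agent_spec <- function(kind = c("generative", "information_seeker", "reward_seeker",
                                "energy_preserver", "random", "informed"),
                       weights = weight_set(1 / 3, 1 / 3, 1 / 3),
                       kernels = kernel_params(3, 1, 2),
                       p = 5,
                       start = 0L,
                       stop_rule = c("all_piles", "all_rewards", "max_steps"),
                       max_steps = Inf,
                       normalize = c("component", "final")) {
  kind <- match.arg(kind)
  stop_rule <- match.arg(stop_rule)
  normalize <- match.arg(normalize)
  if (!is.finite(p) || p < 0) {
    abort("`p` must be >= 0", class = "foragekernel_invalid_argument")
  }
  if (stop_rule == "max_steps" && !is.finite(max_steps)) {
    abort("`max_steps` must be finite under the max_steps stop rule",
          class = "foragekernel_invalid_argument")
  }
  structure(list(kind = kind, weights = weights, kernels = kernels, p = p,
                 start = as.integer(start), stop_rule = stop_rule,
                 max_steps = max_steps, normalize = normalize),
            class = "agent_spec")
}

#' Sample the next pile from a choice distribution
#'
#' Draws one pile from `distribution` raised elementwise to the power `p`
#' and renormalised. `p = 0` gives a uniform draw over the available
#' piles; as `p` grows the draw concentrates on the argmax.
#'
#' @param distribution Per-pile probabilities (e.g. from
#'   [choice_distribution()]); zero entries stay zero for `p > 0`.
#' @param p Sharpening exponent (>= 0).
#' @return A pile id (0-based).
#' @export
sample_next_pile <- function(distribution, p = 1) {
  avail <- attr(distribution, "available")
  if (is.null(avail)) avail <- distribution > 0
  if (!any(avail)) {
    abort("cannot sample from an all-zero distribution",
          class = "foragekernel_degenerate_distribution")
  }
  n <- length(distribution)
  if (p == 0) {
    ids <- which(avail)
  } else {
    d <- distribution[avail]
    if (max(d) <= 0) {
      abort("cannot sample from an all-zero distribution",
            class = "foragekernel_degenerate_distribution")
    }
    # scale before exponentiating so large p does not underflow
    w <- (d / max(d))^p
    ids <- which(avail)
    keep <- w > 0
    ids <- ids[keep]
    w <- w[keep]
    return(ids[sample.int(length(ids), 1L, prob = w)] - 1L)
  }
  ids[sample.int(length(ids), 1L)] - 1L
}

stop_fired <- function(spec, state, map, steps_taken) {
  if (steps_taken >= spec$max_steps) return(TRUE)
  switch(spec$stop_rule,
         all_piles = state$n_searched >= state$grid$n_piles,
         all_rewards = sum(state$rewards) >= sum(map_counts(map)),
         max_steps = FALSE)
}

#' Simulate a foraging session
#'
#' Runs an agent on a grid with a hidden abundance map, iterating choice,
#' sampling and state update until the stop rule fires, and logging every
#' search with its true outcome.
#'
#' @param grid A [make_grid()] grid.
#' @param map An abundance map defined on `grid`.
#' @param spec An [agent_spec()].
#' @param seed Optional integer seed (fixed seed, identical log).
#' @param id Session id stored in the log metadata.
#' @return A [session_log()].
#' @examples
#' g <- make_grid(9, 12)
#' m <- generate_localized_map(g, seed = 1)
#' log <- simulate_session(g, m, agent_spec("generative"), seed = 1)
#' @export
simulate_session <- function(grid, map, spec = agent_spec(), seed = NULL,
                             id = NULL) {
  stopifnot(inherits(grid, "pile_grid"), inherits(map, "abundance_map"),
            inherits(spec, "agent_spec"))
  counts <- map_counts(map)
  run <- function() {
    state <- choice_state(grid, start = spec$start)
    piles <- integer(0)
    found <- integer(0)
    repeat {
      if (stop_fired(spec, state, map, length(piles))) break
      if (state$n_searched >= grid$n_piles) break
      pile <- next_pile_for(spec, state, map)
      got <- counts[pile + 1L]
      state <- advance_state(state, pile, got)
      piles <- c(piles, pile)
      found <- c(found, got)
    }
    list(piles = piles, found = found)
  }
  res <- with_seed(seed, run)
  session_log(
    tibble(step = seq_along(res$piles), pile_id = res$piles,
           reward_count = res$found),
    grid, map = map,
    meta = list(id = id, seed = seed, agent = spec)
  )
}

# one choice for any agent kind
next_pile_for <- function(spec, state, map) {
  grid <- state$grid
  avail <- which(!state$searched) - 1L
  sig <- sigma_piles(spec$kernels, grid)
  switch(
    spec$kind,
    generative = {
      d <- choice_distribution(state, spec$weights, spec$kernels,
                               normalize = spec$normalize)
      sample_next_pile(d, spec$p)
    },
    information_seeker = {
      f <- component_field(state, "ambiguity", sig[["ambiguity"]])[avail + 1L]
      top <- avail[f >= max(f) - 1e-12]
      top[sample.int(length(top), 1L)]
    },
    reward_seeker = {
      f <- component_field(state, "reward", sig[["reward"]])[avail + 1L]
      if (sum(f) <= 0) {
        avail[sample.int(length(avail), 1L)]
      } else {
        avail[sample.int(length(avail), 1L, prob = f)]
      }
    },
    energy_preserver = {
      cc <- grid$coords
      cur <- cc[state$current + 1L, ]
      d2 <- (cc[avail + 1L, "col"] - cur["col"])^2 +
        (cc[avail + 1L, "row"] - cur["row"])^2
      near <- avail[d2 <= min(d2) + 1e-12]
      near[sample.int(length(near), 1L)]
    },
    random = avail[sample.int(length(avail), 1L)],
    informed = {
      counts <- map_counts(map)
      filled <- avail[counts[avail + 1L] > 0]
      target <- if (length(filled)) filled else avail
      cc <- grid$coords
      cur <- cc[state$current + 1L, ]
      d2 <- (cc[target + 1L, "col"] - cur["col"])^2 +
        (cc[target + 1L, "row"] - cur["row"])^2
      near <- target[d2 <= min(d2) + 1e-12]
      near[sample.int(length(near), 1L)]
    },
    abort(paste0("unknown agent kind: ", spec$kind),
          class = "foragekernel_invalid_argument")
  )
}

#' @rdname simulate_session
#' @param kind Marginal/baseline strategy; see [agent_spec()].
#' @export
marginal_session <- function(grid, map, kind, spec = agent_spec(kind = kind),
                             seed = NULL, id = NULL) {
  if (!identical(spec$kind, kind)) spec$kind <- kind
  simulate_session(grid, map, spec, seed = seed, id = id)
}

#' Simulate a batch of sessions
#'
#' Each session gets a fresh abundance map (drawn by `map_fn`) and a
#' deterministic seed substream derived from `seed`.
#'
#' @param n Number of sessions.
#' @param grid A [make_grid()] grid.
#' @param spec An [agent_spec()].
#' @param map_fn Function `(grid, seed)` returning an abundance map;
#'   defaults to [generate_localized_map()].
#' @param seed Optional global seed.
#' @return A list of [session_log()]s.
#' @export
simulate_sessions <- function(n, grid, spec = agent_spec(),
                              map_fn = generate_localized_map, seed = NULL) {
  purrr::map(seq_len(n), function(i) {
    map_seed <- derive_seed(seed, "map", i)
    ses_seed <- derive_seed(seed, "session", i)
    m <- map_fn(grid, seed = map_seed)
    simulate_session(grid, m, spec, seed = ses_seed, id = i)
  })
}
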