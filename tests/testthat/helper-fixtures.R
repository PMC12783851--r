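# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

grid_9x12 <- function() cached("g912", function() make_grid(9, 12))
grid_5x5 <- function() cached("g55", function() make_grid(5, 5))

# a small generative corpus from the p = 1 model (the model the
# likelihood scores), used by the fitting tests
corpus_p1 <- function() {
  cached("corpus_p1", function() {
    simulate_sessions(
      50, grid_9x12(),
      agent_spec("generative", weights = weight_set(0.5, 0.2, 0.3), p = 1,
                 stop_rule = "all_rewards", max_steps = 60),
      seed = 421
    )
  })
}

# a random partially-searched state for property tests
random_state <- function(grid, n_searched, seed, rewards = TRUE) {
  withr::with_seed(seed, {
    st <- choice_state(grid, start = 0L)
    piles <- sample.int(grid$n_piles, n_searched) - 1L
    for (p in piles) {
      got <- if (rewards) stats::rbinom(1, 3, 0.2) else 0L
      st <- advance_state(st, p, got)
    }
    st
  })
}

# brute-force double-loop kernel field, independent of the engine
naive_field <- function(state, component, sigma) {
  grid <- state$grid
  centers <- switch(component,
    ambiguity = {
      ids <- which(!state$searched) - 1L
      cbind(ids %% grid$cols, ids %/% grid$cols, 1)
    },
    reward = {
      ids <- which(state$rewards > 0) - 1L
      if (!length(ids)) return(numeric(grid$n_piles))
      cbind(ids %% grid$cols, ids %/% grid$cols, state$rewards[ids + 1L])
    },
    proximity = cbind(state$current %% grid$cols, state$current %/% grid$cols, 1)
  )
  if (!nrow(centers)) return(numeric(grid$n_piles))
  out <- numeric(grid$n_piles)
  for (a in seq_len(grid$n_piles)) {
    ac <- (a - 1L) %% grid$cols
    ar <- (a - 1L) %/% grid$cols
    s <- 0
    for (i in seq_len(nrow(centers))) {
      d2 <- (ac - centers[i, 1])^2 + (ar - centers[i, 2])^2
      s <- s + centers[i, 3] * exp(-d2 / (2 * sigma^2))
    }
    out[a] <- s / sum(centers[, 3])
  }
  out
}
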