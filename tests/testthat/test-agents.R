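test_that("sharpened sampling follows the closed-form power weighting", {
  # uniform distribution: any exponent leaves it uniform
  d <- rep(0.25, 4)
  attr(d, "available") <- rep(TRUE, 4)
  draws <- withr::with_seed(1, vapply(1:4000, function(i) sample_next_pile(d, 3),
                                      integer(1)))
  counts <- as.numeric(table(factor(draws, levels = 0:3)))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-6)

  # (0.7, 0.3) at p = 20: closed form 0.7^20 / (0.7^20 + 0.3^20) ~ 1 - 4.5e-8
  d2 <- c(0.7, 0.3)
  attr(d2, "available") <- c(TRUE, TRUE)
  draws2 <- withr::with_seed(2, vapply(1:10000, function(i) sample_next_pile(d2, 20),
                                       integer(1)))
  expect_gte(mean(draws2 == 0L), 0.999)

  # p = 0: uniform over available, including zero-probability piles
  d3 <- c(0, 1, 0)
  attr(d3, "available") <- c(TRUE, TRUE, TRUE)
  draws3 <- withr::with_seed(3, vapply(1:300, function(i) sample_next_pile(d3, 0),
                                       integer(1)))
  expect_setequal(unique(draws3), 0:2)

  expect_error(sample_next_pile(c(0, 0), 1),
               class = "foragekernel_degenerate_distribution")

  # fixed seed, identical draw sequence
  s1 <- withr::with_seed(9, vapply(1:50, function(i) sample_next_pile(d2, 2), integer(1)))
  s2 <- withr::with_seed(9, vapply(1:50, function(i) sample_next_pile(d2, 2), integer(1)))
  expect_identical(s1, s2)
})

test_that("simulated sessions are deterministic, complete and revisit-free", {
  g <- grid_9x12()
  m <- generate_localized_map(g, seed = 1)
  spec <- agent_spec("generative", kernels = kernel_params(0.9, 0.3, 0.6, units = "m"),
                     p = 5, stop_rule = "all_piles")
  l1 <- simulate_session(g, m, spec, seed = 2)
  l2 <- simulate_session(g, m, spec, seed = 2)
  expect_identical(tibble::as_tibble(l1), tibble::as_tibble(l2))
  expect_lte(nrow(l1), 108)
  expect_false(any(duplicated(l1$pile_id)))
  expect_equal(sum(l1$reward_count), 31)  # full search finds every item

  # stop at all rewards on a single-pile map ends exactly at collection
  m1 <- generate_localized_map(g, seed = 3)
  counts <- map_counts(m1)
  single <- m1
  single$counts <- integer(g$n_piles)
  single$counts[which.max(counts)] <- 1L
  lr <- simulate_session(g, single, agent_spec("random", stop_rule = "all_rewards"),
                         seed = 4)
  expect_equal(lr$reward_count[nrow(lr)], 1L)
  expect_equal(sum(lr$reward_count), 1L)

  lm <- simulate_session(g, m, agent_spec("random", stop_rule = "max_steps",
                                          max_steps = 7), seed = 5)
  expect_equal(nrow(lm), 7)
})

test_that("the energy preserver always takes the shortest available step", {
  g <- grid_9x12()
  m <- generate_localized_map(g, seed = 6)
  log <- marginal_session(g, m, "energy_preserver", seed = 7)
  cc <- g$coords
  searched <- rep(FALSE, g$n_piles)
  cur <- 0L
  searched_first <- FALSE
  for (i in seq_len(nrow(log))) {
    pile <- log$pile_id[i]
    avail <- which(!searched) - 1L
    d2 <- (cc[avail + 1, "col"] - cc[cur + 1, "col"])^2 +
      (cc[avail + 1, "row"] - cc[cur + 1, "row"])^2
    expect_equal(unname((cc[pile + 1, "col"] - cc[cur + 1, "col"])^2 +
                          (cc[pile + 1, "row"] - cc[cur + 1, "row"])^2),
                 min(d2))
    searched[pile + 1] <- TRUE
    cur <- pile
  }
  # and on a short virgin interior path, every step size equals the pitch
  interior <- agent_spec("energy_preserver", start = 40L, stop_rule = "max_steps",
                         max_steps = 8)
  li <- simulate_session(g, m, interior, seed = 8)
  expect_true(all(abs(step_sizes(li)$distance - g$pitch) < 1e-12 |
                    step_sizes(li)$distance == 0))
})

test_that("baseline searchers bracket the first-success statistics", {
  g <- grid_9x12()
  # informed searcher: first success at step 1, by construction
  for (seed in 1:5) {
    m <- generate_localized_map(g, seed = seed)
    li <- marginal_session(g, m, "informed", seed = seed + 100,
                           spec = agent_spec("informed", stop_rule = "all_rewards"))
    expect_equal(which(li$reward_count > 0)[1], 1L)
  }
  # random searcher: mean first success ~ (N + 1) / (K + 1) = 109 / 22
  logs <- simulate_sessions(1500, g, agent_spec("random", stop_rule = "all_rewards"),
                            seed = 77)
  fs <- vapply(logs, function(l) which(l$reward_count > 0)[1], integer(1))
  expect_equal(mean(fs), 109 / 22, tolerance = 0.05)
})

test_that("marginal drives produce their characteristic exploration", {
  g <- grid_9x12()
  # near-uniform exploration for a pure information seeker with a huge kernel
  st <- random_state(g, 20, seed = 3)
  p <- choice_distribution(st, weight_set(1, 0, 0),
                           kernel_params(500, 1, 1, units = "piles"))
  avail <- p[p > 0]
  expect_lt(max(avail) / min(avail), 1.001)

  # pure proximity with a small kernel: almost all steps lattice-adjacent
  spec <- agent_spec("generative", weights = weight_set(0, 0, 1),
                     kernels = kernel_params(3, 1, 0.5), p = 1,
                     stop_rule = "max_steps", max_steps = 40)
  logs <- simulate_sessions(10, g, spec, seed = 31)
  steps <- dplyr::bind_rows(lapply(logs, step_sizes))
  expect_gte(mean(steps$distance <= g$pitch * sqrt(2) + 1e-9), 0.95)

  # reward seeker stays near discovered rewards once it has found some
  m <- generate_localized_map(g, seed = 40)
  rs <- marginal_session(g, m, "reward_seeker", seed = 41,
                         spec = agent_spec("reward_seeker", stop_rule = "all_rewards"))
  expect_gt(sum(rs$reward_count), 0)

  expect_error(agent_spec("psychic"))
})
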