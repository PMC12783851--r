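test_that("step sizes are Euclidean distances labelled by outcome", {
  g <- grid_5x5()
  log <- session_log(
    tibble::tibble(step = 1:5, pile_id = c(0L, 1L, 7L, 12L, 24L),
                   reward_count = c(0L, 2L, 0L, 1L, 0L)), g)
  ss <- step_sizes(log)
  expect_equal(nrow(ss), 4)  # fencepost
  expect_equal(ss$distance[1], 0.3)            # lattice-adjacent
  expect_equal(ss$distance[2], 0.3 * sqrt(2))  # diagonal
  expect_equal(as.character(ss$prev_outcome), c("failure", "success",
                                                "failure", "success"))
  single <- session_log(tibble::tibble(step = 1, pile_id = 0L, reward_count = 0L), g)
  expect_error(step_sizes(single), class = "foragekernel_empty_series")
})

test_that("binned densities conserve probability mass", {
  b <- bin_density(rep(0.3, 10), width = 0.2)
  expect_equal(b$density[2], 5)
  expect_equal(b$bin_center[2], 0.3)
  expect_equal(sum(b$count), 10)
  expect_equal(sum(b$density) * 0.2, 1, tolerance = 1e-12)
  for (seed in 1:5) {
    x <- withr::with_seed(seed, stats::rexp(200, 2) + 0.3)
    b <- bin_density(x, width = 0.2)
    expect_equal(sum(b$density) * 0.2, 1, tolerance = 1e-12)
  }
  expect_error(bin_density(numeric(0)), class = "foragekernel_empty_series")
  expect_error(bin_density(1, width = -1), class = "foragekernel_invalid_argument")
})

test_that("power-law fits recover the generating exponent", {
  # noiseless density ~ x^-2 on the bin centres
  centers <- (1:8 + 0.5) * 0.2
  binned <- tibble::tibble(bin_center = centers, count = 1,
                           density = centers^(-2))
  fit <- fit_power_law(binned)
  expect_equal(fit$slope, -2, tolerance = 1e-9)
  expect_true(fit$in_levy_band)

  flat <- tibble::tibble(bin_center = centers, count = 1, density = 1)
  expect_equal(fit_power_law(flat)$slope, 0, tolerance = 1e-12)

  # slope is invariant to the log base used
  pts <- fit$points
  slope10 <- unname(coef(lm(log10(density) ~ log10(bin_center), data = pts))[2])
  expect_equal(fit$slope, slope10, tolerance = 1e-12)

  # truncated Pareto sample with exponent mu = 2
  x <- withr::with_seed(42, {
    u <- stats::runif(10000)
    xmin <- 0.3; xmax <- 3
    xmin / (1 - u * (1 - xmin / xmax))  # inverse cdf for density ~ x^-2
  })
  sl <- fit_power_law(bin_density(x, 0.2))$slope
  expect_gte(sl, -2.4)
  expect_lte(sl, -1.6)

  expect_error(fit_power_law(binned[1:2, ]),
               class = "foragekernel_insufficient_data")
})

test_that("convolutedness reproduces the three printed anchors", {
  expect_equal(convolutedness(cbind(0:3, 0)), -1)
  expect_equal(convolutedness(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 0)
  expect_equal(convolutedness(rbind(c(0, 0), c(1, 0), c(0, 0), c(1, 0))), 1)
})

test_that("convolutedness is bounded, scale-invariant and mode-consistent", {
  for (seed in 1:50) {
    pos <- withr::with_seed(seed, {
      n <- sample(3:12, 1)
      cbind(cumsum(stats::rnorm(n)), cumsum(stats::rnorm(n)))
    })
    for (mode in c("anchor", "wrap")) {
      v <- convolutedness(pos, mode = mode)
      expect_gte(v, -1)
      expect_lte(v, 1)
      expect_equal(convolutedness(pos * 7.3, mode = mode), v, tolerance = 1e-12)
    }
  }
  # wrap mode treats the last step as the predecessor of the first
  expect_equal(convolutedness(cbind(0:3, 0), mode = "wrap"), -1)
  expect_error(convolutedness(cbind(0:1, 0)),
               class = "foragekernel_insufficient_data")
})

test_that("outcome contrasts report geometric means and adjusted p-values", {
  same <- tibble::tibble(distance = rep(c(0.3, 0.6, 0.9), 2),
                         prev_outcome = factor(rep(c("success", "failure"), each = 3),
                                               levels = c("failure", "success")))
  ct <- outcome_step_contrast(same)
  expect_equal(ct$ratio, 1)
  expect_gte(ct$p_value, 0.99)

  const <- tibble::tibble(distance = c(0.3, 0.3, 0.3, 0.9, 0.9, 0.9),
                          prev_outcome = factor(c(rep("success", 3), rep("failure", 3)),
                                                levels = c("failure", "success")))
  ct2 <- outcome_step_contrast(const)
  expect_equal(ct2$geomean_success, 0.3)
  expect_equal(ct2$geomean_failure, 0.9)

  grouped <- dplyr::bind_rows(
    dplyr::mutate(same, forager = "a"),
    dplyr::mutate(const, forager = "b")
  )
  ct3 <- outcome_step_contrast(grouped, group = "forager")
  expect_equal(nrow(ct3), 2)
  expect_equal(ct3$p_adjusted, stats::p.adjust(ct3$p_value, "BH"))

  expect_error(outcome_step_contrast(same[same$prev_outcome == "success", ]),
               class = "foragekernel_insufficient_data")
})

test_that("a reward-and-proximity-dominant forager switches from roaming to
           dwelling at the first food encounter", {
  g <- grid_9x12()
  spec <- agent_spec("generative", weights = weight_set(0.1, 0.45, 0.45),
                     kernels = kernel_params(0.9, 0.3, 0.6, units = "m"),
                     p = 5, stop_rule = "all_rewards", max_steps = 60)
  logs <- simulate_sessions(50, g, spec, seed = 304)
  pp <- pre_post_reward_convolutedness(logs)
  expect_gt(pp$paired_mean_diff, 0)
  expect_lt(pp$paired_p, 0.05)
})

test_that("pre/post-reward convolutedness applies the sub-path length filter", {
  g <- grid_9x12()
  mk <- function(piles, rewards) {
    session_log(tibble::tibble(step = seq_along(piles), pile_id = piles,
                               reward_count = rewards), g)
  }
  # first reward at search 3: only 2 pre searches, excluded at min_len 4
  short <- mk(c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L),
              c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
  expect_error(pre_post_reward_convolutedness(list(short)),
               class = "foragekernel_insufficient_data")

  # straight pre path, straight post path: both -1, paired difference 0
  straight <- mk(c(0L, 1L, 2L, 3L, 16L, 17L, 18L, 19L),
                 c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L))
  res <- pre_post_reward_convolutedness(list(straight, straight))
  expect_equal(res$per_session$pre, c(-1, -1))
  expect_equal(res$per_session$post, c(-1, -1))
  expect_equal(res$paired_mean_diff, 0)
  expect_equal(res$paired_p, 1)
})
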