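test_that("the replay table reproduces the engine's per-step probabilities", {
  g <- grid_9x12()
  logs <- corpus_p1()[1:3]
  w <- weight_set(0.45, 0.25, 0.3)
  for (sig in list(c(3, 1, 2), c(0.4, 0.1, 6))) {
    k <- kernel_params(sig[1], sig[2], sig[3], units = "piles")
    ll_fast <- session_log_likelihood(logs, w, k)
    ll_ref <- 0
    for (log in logs) {
      st <- choice_state(g, start = 0L)
      for (i in seq_len(nrow(log))) {
        p <- choice_distribution(st, w, k)
        if (i >= 2) ll_ref <- ll_ref + log(p[log$pile_id[i] + 1])
        st <- advance_state(st, log$pile_id[i], log$reward_count[i])
      }
    }
    expect_equal(as.numeric(ll_fast), ll_ref, tolerance = 1e-10)
  }
})

test_that("log-likelihood is invariant to session order and pooling", {
  logs <- corpus_p1()[1:4]
  w <- weight_set(0.4, 0.3, 0.3)
  k <- kernel_params(3, 1, 2)
  pooled <- as.numeric(session_log_likelihood(logs, w, k))
  shuffled <- as.numeric(session_log_likelihood(rev(logs), w, k))
  per_session <- sum(vapply(logs, function(l)
    as.numeric(session_log_likelihood(l, w, k)), numeric(1)))
  expect_equal(pooled, shuffled, tolerance = 1e-12)
  expect_equal(pooled, per_session, tolerance = 1e-10)
  expect_lte(pooled, 0)
})

test_that("a near-flat ambiguity kernel recovers the uniform-policy likelihood", {
  logs <- corpus_p1()[1:3]
  # w_info = 1 with a very large kernel makes every available pile equally
  # likely, so LL = -sum over steps of log(N_available)
  ll <- session_log_likelihood(logs, weight_set(1, 0, 0),
                               kernel_params(1e5, 1, 1, units = "piles"))
  n <- grid_9x12()$n_piles
  closed <- -sum(vapply(logs, function(l) sum(log(n - seq_len(nrow(l) - 1))),
                        numeric(1)))
  expect_equal(as.numeric(ll), closed, tolerance = 1e-6)
  expect_equal(attr(ll, "n_terms"), sum(vapply(logs, nrow, integer(1))) - 3)

  # single step among N available under the uniform model
  g <- grid_5x5()
  two <- session_log(tibble::tibble(step = 1:2, pile_id = c(0L, 7L),
                                    reward_count = 0L), g)
  ll2 <- session_log_likelihood(two, weight_set(1, 0, 0),
                                kernel_params(1e5, 1, 1, units = "piles"))
  expect_equal(as.numeric(ll2), log(1 / 24), tolerance = 1e-8)
})

test_that("scoring the first choice is optional and adds one term per session", {
  logs <- corpus_p1()[1:4]
  w <- weight_set(0.4, 0.3, 0.3)
  k <- kernel_params(3, 1, 2)
  excl <- session_log_likelihood(logs, w, k)
  incl <- session_log_likelihood(logs, w, k, include_first = TRUE, start = 0L)
  expect_equal(attr(incl, "n_terms"), attr(excl, "n_terms") + length(logs))
  expect_lt(as.numeric(incl), as.numeric(excl))  # extra terms only add penalty
})

test_that("fields can be dumped as grid-shaped CSV matrices", {
  g <- grid_5x5()
  st <- choice_state(g)
  f <- component_field(st, "ambiguity", 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, g, path)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  expect_equal(dim(m), c(5, 5))
  expect_equal(as.numeric(t(m)), unname(f), tolerance = 1e-12)
})

test_that("an impossible choice yields a flagged -Inf, not an error", {
  g <- grid_9x12()
  # a long jump scored under pure proximity with a tiny kernel underflows
  far <- session_log(tibble::tibble(step = 1:3, pile_id = c(0L, 1L, 107L),
                                    reward_count = 0L), g)
  ll <- session_log_likelihood(far, weight_set(0, 0, 1),
                               kernel_params(1, 1, 0.05, units = "piles"))
  expect_true(is.infinite(ll) && ll < 0)
  expect_true(attr(ll, "degenerate"))
})

test_that("sessions are scored under their own generating weights best", {
  logs <- corpus_p1()
  k <- kernel_params(3, 1, 2)
  truth <- weight_set(0.5, 0.2, 0.3)
  swapped <- weight_set(0.2, 0.5, 0.3)
  expect_gt(as.numeric(session_log_likelihood(logs, truth, k)),
            as.numeric(session_log_likelihood(logs, swapped, k)))
})

test_that("weight optimisation recovers generating weights at the true sigmas", {
  fit <- fit_weights_given_sigmas(corpus_p1(), kernel_params(3, 1, 2))
  expect_equal(fit$weights$info, 0.5, tolerance = 0.1)
  expect_equal(fit$weights$rew, 0.2, tolerance = 0.1)
  expect_equal(fit$weights$prox, 0.3, tolerance = 0.1)
  expect_lte(fit$loglik, 0)
  expect_equal(fit$weights$info + fit$weights$rew + fit$weights$prox, 1,
               tolerance = 1e-9)

  multi <- fit_weights_given_sigmas(corpus_p1(), kernel_params(3, 1, 2),
                                    multi_start = TRUE)
  expect_equal(multi$weights$info, fit$weights$info, tolerance = 1e-3)
  expect_equal(multi$weights$rew, fit$weights$rew, tolerance = 1e-3)
})

test_that("the grid fitter agrees with the reference optimiser per cell", {
  logs <- corpus_p1()[1:10]
  sig_grid <- c(1, 3)
  fit <- grid_search_fit(logs, sigma_grid = sig_grid)
  expect_equal(nrow(fit$grid_table), 8)
  for (row in c(1, 4, 8)) {
    cell <- fit$grid_table[row, ]
    ref <- fit_weights_given_sigmas(
      logs, kernel_params(cell$sigma_ambiguity, cell$sigma_reward,
                          cell$sigma_proximity, units = "piles"))
    expect_equal(cell$loglik, ref$loglik, tolerance = 1e-6)
    expect_equal(cell$w_info, ref$weights$info, tolerance = 1e-3)
    expect_equal(cell$w_rew, ref$weights$rew, tolerance = 1e-3)
  }
})

test_that("the full grid search spans the canonical 1331 cells and lands the
           kernel sizes near truth", {
  fit <- grid_search_fit(corpus_p1())
  gt <- fit$grid_table
  expect_equal(nrow(gt), 1331)
  expect_setequal(unique(gt$sigma_ambiguity), sigma_search_grid())
  expect_true(all(gt$w_info >= 0 & gt$w_rew >= 0 & gt$w_prox >= -1e-9))
  expect_equal(gt$w_info + gt$w_rew + gt$w_prox, rep(1, 1331), tolerance = 1e-9)
  expect_true(fit$kernels$ambiguity %in% sigma_search_grid())
  expect_true(fit$kernels$reward %in% sigma_search_grid())
  expect_true(fit$kernels$proximity %in% sigma_search_grid())
  # the corpus was generated at sigma = (3, 1, 2) pile units: the selected
  # sizes should land on truth or a grid neighbour
  expect_true(fit$kernels$ambiguity %in% c(1.9, 3, 4))
  expect_true(fit$kernels$reward %in% c(0.7, 1, 1.3))
  expect_true(fit$kernels$proximity %in% c(1.6, 1.9, 3))
})

test_that("bootstrap fits resample steps and are reproducible", {
  logs <- corpus_p1()[1:8]
  sig <- c(1, 3)
  boot <- bootstrap_fit(logs, n_subsets = 12, fraction = 0.8,
                        sigma_grid = sig, seed = 5)
  n_steps <- sum(vapply(logs, nrow, integer(1))) - length(logs)
  expect_equal(nrow(boot), 12)
  expect_true(all(boot$n_steps == floor(0.8 * n_steps)))
  expect_equal(boot$w_info + boot$w_rew + boot$w_prox, rep(1, 12),
               tolerance = 1e-9)
  boot2 <- bootstrap_fit(logs, n_subsets = 12, fraction = 0.8,
                         sigma_grid = sig, seed = 5)
  expect_identical(tibble::as_tibble(boot), tibble::as_tibble(boot2))

  # fraction 1: every subset sees all steps, so the spread collapses
  full <- bootstrap_fit(logs, n_subsets = 5, fraction = 1,
                        sigma_grid = sig, seed = 6)
  expect_lt(max(full$w_info) - min(full$w_info), 1e-9)
  expect_lt(max(full$loglik) - min(full$loglik), 1e-9)
})

test_that("weight decodability is a rank AUC", {
  expect_equal(weight_decodability(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(weight_decodability(c(1, 2), c(3, 4)), 1)
  expect_equal(weight_decodability(c(0.1, 0.2), c(0.15, 0.3)), 0.75)
  # equals brute-force pair counting
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- sample(1:20, sample(3:50, 1), replace = TRUE)
      b <- sample(1:20, sample(3:50, 1), replace = TRUE)
    })
    brute <- mean(outer(b, a, function(x, y) (x > y) + 0.5 * (x == y)))
    expect_equal(weight_decodability(a, b), brute, tolerance = 1e-12)
  }
  expect_error(weight_decodability(numeric(0), 1),
               class = "foragekernel_insufficient_data")
})

test_that("fit objects expose broom-style summaries", {
  fit <- fit_weights_given_sigmas(corpus_p1()[1:5], kernel_params(3, 1, 2))
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("w_info", "w_rew", "w_prox", "sigma_ambiguity",
                             "sigma_reward", "sigma_proximity"))
  gl <- generics::glance(fit)
  expect_lte(gl$loglik, 0)

  boot <- bootstrap_fit(corpus_p1()[1:8], n_subsets = 6, sigma_grid = c(1, 3),
                        seed = 2)
  tb <- generics::tidy(boot)
  expect_setequal(tb$term, c("w_info", "w_rew", "w_prox"))
  expect_true(all(tb$conf.low <= tb$estimate & tb$estimate <= tb$conf.high))
})
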