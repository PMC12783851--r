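#' Maximum-likelihood weights at fixed kernel sizes
#'
#' Maximises the session log-likelihood over the weight simplex
#' (`w_info + w_rew + w_prox = 1`, all positive) for one triple of kernel
#' sizes, by BFGS on a softmax parametrisation of the simplex interior
#' (margin 1e-6). The likelihood surface over `(w_info, w_rew)` has a
#' single local maximum in practice, so one default initialisation
#' suffices; `multi_start = TRUE` verifies this with four spread-out
#' initialisations.
#'
#' @param logs A [session_log()] or list of them.
#' @param kernels A [kernel_params()].
#' @param init Initial [weight_set()].
#' @param include_first,start See [session_log_likelihood()].
#' @param multi_start Run four extra initialisations and keep the best?
#' @return A `forage_fit` object: `weights`, `kernels`, `loglik`,
#'   `n_terms`, optimisation diagnostics. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
fit_weights_given_sigmas <- function(logs, kernels,
                                     init = weight_set(1 / 3, 1 / 3),
                                     include_first = FALSE, start = 0L,
                                     multi_start = FALSE) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  grid <- session_grid(logs[[1]])
  sig <- sigma_piles(kernels, grid)
  tab <- replay_choice_table(logs, sig[["ambiguity"]], sig[["reward"]],
                             sig[["proximity"]],
                             include_first = include_first, start = start)
  a <- tab$A[, 1]; r <- tab$R[, 1]; x <- tab$X[, 1]
  zr <- tab$Zr[, 1]; zp <- tab$Zp[, 1]
  eps <- 1e-6
  nll <- function(u) {
    e <- exp(c(u, 0))
    w <- pmax(e / sum(e), eps)
    w <- w / sum(w)
    num <- w[1] * a + w[2] * r + w[3] * x
    den <- w[1] + w[2] * zr + w[3] * zp
    -sum(log(pmax(num, 1e-300)) - log(den))
  }
  starts <- list(c(0, 0))
  if (multi_start) {
    starts <- c(starts, list(c(2, -1), c(-1, 2), c(-2, -2), c(1.5, 1.5)))
  }
  w0 <- c(init$info, init$rew, init$prox)
  starts[[1]] <- log(pmax(w0[1:2], eps) / pmax(w0[3], eps))
  fits <- lapply(starts, function(s) {
    optim(s, nll, method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  e <- exp(c(best$par, 0))
  w <- e / sum(e)
  new_forage_fit(
    weights = weight_set(w[1], w[2], w[3]),
    kernels = kernels,
    loglik = -best$value,
    n_terms = nrow(tab$steps),
    diagnostics = list(convergence = best$convergence,
                       counts = best$counts,
                       n_starts = length(starts))
  )
}

new_forage_fit <- function(weights, kernels, loglik, n_terms,
                           diagnostics = list(), grid_table = NULL) {
  structure(
    list(weights = weights, kernels = kernels, loglik = loglik,
         n_terms = n_terms, diagnostics = diagnostics,
         grid_table = grid_table),
    class = "forage_fit"
  )
}

#' @export
print.forage_fit <- function(x, ...) {
  cat(sprintf(
    "<forage_fit> w_info %.3f, w_rew %.3f, w_prox %.3f | sigma (%.2g, %.2g, %.2g) %s | LL %.2f (%d choices)\n",
    x$weights$info, x$weights$rew, x$weights$prox,
    x$kernels$ambiguity, x$kernels$reward, x$kernels$proximity,
    x$kernels$units, x$loglik, x$n_terms))
  invisible(x)
}

#' The canonical kernel-size search grid
#'
#' Eleven values per kernel, in lattice pile units, giving 11^3 = 1331
#' triples for [grid_search_fit()].
#' @return Numeric vector of length 11.
#' @export
sigma_search_grid <- function() c(0.1, 0.4, 0.7, 1, 1.3, 1.6, 1.9, 3, 4, 5, 6)

#' Joint grid search over kernel sizes and weights
#'
#' Replays the sessions once per component kernel size, then fits the
#' mixing weights for every triple from the sigma grid (all 1331
#' permutations of the canonical 11-value list) and returns the
#' likelihood-maximising combination with the full grid table retained.
#'
#' @param logs A [session_log()] or list of them.
#' @param sigma_grid Kernel sizes, in lattice pile units.
#' @param include_first,start See [session_log_likelihood()].
#' @return A `forage_fit` whose `grid_table` is a tibble with one row per
#'   sigma triple (`sigma_ambiguity`, `sigma_reward`, `sigma_proximity`,
#'   `w_info`, `w_rew`, `w_prox`, `loglik`, `iterations`).
#' @export
grid_search_fit <- function(logs, sigma_grid = sigma_search_grid(),
                            include_first = FALSE, start = 0L) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  tab <- replay_choice_table(logs, sigma_grid, sigma_grid, sigma_grid,
                             include_first = include_first, start = start)
  fit_grid_from_table(tab, sigma_grid, rows = seq_len(nrow(tab$steps)))
}

# weight fits for all sigma triples on a row subset of a replay table
fit_grid_from_table <- function(tab, sigma_grid, rows,
                                winit = c(1 / 3, 1 / 3)) {
  ns <- length(sigma_grid)
  triples <- as.matrix(expand.grid(ia = seq_len(ns), ir = seq_len(ns),
                                   ip = seq_len(ns))) - 1L
  res <- fit_weights_grid_cpp(tab$A, tab$R, tab$X, tab$Zr, tab$Zp,
                              triples, as.integer(rows - 1L),
                              as.numeric(winit))
  grid_table <- tibble(
    sigma_ambiguity = sigma_grid[triples[, 1] + 1L],
    sigma_reward = sigma_grid[triples[, 2] + 1L],
    sigma_proximity = sigma_grid[triples[, 3] + 1L],
    w_info = res[, 1],
    w_rew = res[, 2],
    w_prox = 1 - res[, 1] - res[, 2],
    loglik = res[, 3],
    iterations = res[, 4]
  )
  ok <- is.finite(grid_table$loglik)
  if (!any(ok)) {
    abort("every sigma cell failed to produce a finite likelihood",
          class = "foragekernel_optimizer_failure")
  }
  best <- which.max(ifelse(ok, grid_table$loglik, -Inf))
  new_forage_fit(
    weights = weight_set(grid_table$w_info[best], grid_table$w_rew[best]),
    kernels = kernel_params(grid_table$sigma_ambiguity[best],
                            grid_table$sigma_reward[best],
                            grid_table$sigma_proximity[best],
                            units = "piles"),
    loglik = grid_table$loglik[best],
    n_terms = length(rows),
    diagnostics = list(n_cells = nrow(grid_table),
                       n_failed = sum(!ok)),
    grid_table = grid_table
  )
}

#' Bootstrap distribution of fitted weights
#'
#' Repeats the full sigma-grid fit on random subsets of the pile
#' searches pooled across sessions: each subset draws
#' `fraction * n_steps` scoreable steps without replacement (steps keep
#' their session context -- excluded steps still update the replayed
#' state, so the field sequence matches the recorded session). The
#' resulting weight distribution quantifies fit uncertainty and feeds
#' [weight_decodability()].
#'
#' @param logs A [session_log()] or list of them.
#' @param n_subsets Number of subsets (default 100).
#' @param fraction Fraction of steps per subset (default 0.8).
#' @param sigma_grid Kernel sizes in pile units.
#' @param seed Optional integer seed.
#' @param include_first,start See [session_log_likelihood()].
#' @return A `forage_boot` tibble with one row per subset (`subset`,
#'   weights, sigmas, `loglik`, `n_steps`), with the full-data fit in
#'   attribute `full_fit`. Supports [generics::tidy()] and
#'   [ggplot2::autoplot()].
#' @export
bootstrap_fit <- function(logs, n_subsets = 100, fraction = 0.8,
                          sigma_grid = sigma_search_grid(), seed = NULL,
                          include_first = FALSE, start = 0L) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  if (n_subsets < 1 || fraction <= 0 || fraction > 1) {
    abort("need n_subsets >= 1 and fraction in (0, 1]",
          class = "foragekernel_invalid_argument")
  }
  tab <- replay_choice_table(logs, sigma_grid, sigma_grid, sigma_grid,
                             include_first = include_first, start = start)
  n <- nrow(tab$steps)
  if (n < 10) {
    abort("need at least 10 scoreable steps to bootstrap",
          class = "foragekernel_insufficient_data")
  }
  m <- max(1L, floor(fraction * n))
  full <- fit_grid_from_table(tab, sigma_grid, rows = seq_len(n))
  winit <- c(full$weights$info, full$weights$rew)
  subsets <- with_seed(seed, function() {
    lapply(seq_len(n_subsets), function(i) sort(sample.int(n, m)))
  })
  rows <- purrr::imap(subsets, function(rws, i) {
    fit <- tryCatch(
      fit_grid_from_table(tab, sigma_grid, rows = rws, winit = winit),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)  # degenerate subset: skipped
    tibble(
      subset = i,
      w_info = fit$weights$info, w_rew = fit$weights$rew,
      w_prox = fit$weights$prox,
      sigma_ambiguity = fit$kernels$ambiguity,
      sigma_reward = fit$kernels$reward,
      sigma_proximity = fit$kernels$proximity,
      loglik = fit$loglik, n_steps = length(rws)
    )
  })
  out <- bind_rows(rows)
  structure(
    out,
    fraction = fraction, n_subsets = n_subsets, seed = seed,
    full_fit = full,
    class = c("forage_boot", class(out))
  )
}

#' Decodability of two weight distributions
#'
#' Rank-based area under the ROC curve for discriminating sample `b`
#' from sample `a`: the probability that a random draw from `b` exceeds
#' a random draw from `a`, counting ties as one half. `0.5` means
#' indistinguishable, `1` perfectly separated (all of `b` above `a`).
#'
#' @param a,b Numeric vectors of fitted weight values (e.g. a weight
#'   column of two [bootstrap_fit()] tables).
#' @return The AUC, a number in `[0, 1]`.
#' @examples
#' weight_decodability(c(0.1, 0.2), c(0.15, 0.3))  # 0.75
#' @export
weight_decodability <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (!length(a) || !length(b)) {
    abort("both samples must be non-empty",
          class = "foragekernel_insufficient_data")
  }
  rk <- rank(c(a, b))
  rb <- sum(rk[(length(a) + 1):(length(a) + length(b))])
  (rb - length(b) * (length(b) + 1) / 2) / (length(a) * length(b))
}
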