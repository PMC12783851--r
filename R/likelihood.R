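#' Log-likelihood of session logs under the kernel choice model
#'
#' Replays each session through the choice model and sums the log of the
#' probability the model assigns to each pile that was actually chosen:
#' `LL = sum_j log p_model(chosen pile at step j)`. The sharpening
#' exponent `p` of the generative sampler is not applied when scoring.
#' By default the first search of each session is excluded, because a
#' recorded forager's pre-session location (which centres the proximity
#' kernel at step 1) is unknown; set `include_first = TRUE` to score it
#' with the proximity kernel at `start`.
#'
#' @param logs A [session_log()] or list of them (order does not matter).
#' @param weights A [weight_set()].
#' @param kernels A [kernel_params()].
#' @param include_first Score each session's first choice? Default FALSE.
#' @param start Pile id of the assumed pre-session location when
#'   `include_first = TRUE`.
#' @return The total log-likelihood in nats (<= 0), with attributes
#'   `n_terms` (number of scored choices) and `degenerate` (TRUE if any
#'   chosen pile had zero model probability, making the total -Inf).
#'   Revisit events are skipped with a warning.
#' @export
session_log_likelihood <- function(logs, weights, kernels,
                                   include_first = FALSE, start = 0L) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  sig <- sigma_piles(kernels, session_grid(logs[[1]]))
  tab <- replay_choice_table(logs, sigma_ambiguity = sig[["ambiguity"]],
                             sigma_reward = sig[["reward"]],
                             sigma_proximity = sig[["proximity"]],
                             include_first = include_first, start = start)
  w <- c(weights$info, weights$rew, weights$prox)
  num <- w[1] * tab$A[, 1] + w[2] * tab$R[, 1] + w[3] * tab$X[, 1]
  den <- w[1] + w[2] * tab$Zr[, 1] + w[3] * tab$Zp[, 1]
  terms <- ifelse(num > 0 & den > 0, log(num) - log(den), -Inf)
  ll <- sum(terms)
  attr(ll, "n_terms") <- length(terms)
  attr(ll, "degenerate") <- any(!is.finite(terms))
  ll
}

#' Replay sessions into per-step component choice probabilities
#'
#' For every scoreable step of every session, computes the normalised
#' probability that each component field (ambiguity, reward, proximity)
#' assigns to the pile that was chosen, for each kernel size in the
#' supplied lists. Because the three components are independent given
#' the replayed state, a full sigma grid factorises into one column per
#' component sigma; the weight optimisation then only combines columns.
#' This is the workhorse behind [session_log_likelihood()],
#' [grid_search_fit()] and [bootstrap_fit()].
#'
#' @param logs List of [session_log()]s.
#' @param sigma_ambiguity,sigma_reward,sigma_proximity Kernel sizes in
#'   lattice pile units (vectors allowed).
#' @param include_first,start See [session_log_likelihood()].
#' @return A list: matrices `A`, `R`, `X` (steps x length(sigma)) of
#'   normalised component probabilities of the chosen pile, 0/1 matrices
#'   `Zr`, `Zp` flagging a non-vanishing reward/proximity field, and a
#'   `steps` tibble (`session`, `step`, `n_available`).
#' @keywords internal
#' @export
replay_choice_table <- function(logs, sigma_ambiguity, sigma_reward,
                                sigma_proximity, include_first = FALSE,
                                start = 0L) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  grid <- session_grid(logs[[1]])
  np <- grid$n_piles
  # full kernel matrices, cached per sigma and shared across sessions
  kcache <- new.env(parent = emptyenv())
  kmat <- function(s) kernel_matrix(grid, s, kcache)

  out <- purrr::imap(logs, function(log, li) {
    if (session_has_revisits(log)) {
      warn(sprintf("session %s: revisit events skipped when scoring", li))
      log <- log[!duplicated(log$pile_id), , drop = FALSE]
    }
    cseq <- log$pile_id + 1L
    r <- as.numeric(log$reward_count)
    Tn <- length(cseq)
    t0 <- if (include_first) 1L else 2L
    if (Tn < t0) return(NULL)
    ts <- t0:Tn
    start_i <- as.integer(start) + 1L

    # Each component field is maintained as a vector over piles and the
    # normalising mass is summed directly over the available piles:
    # additions of positive kernel values only (the ambiguity field is a
    # decreasing superposition, but its value at any unsearched pile is
    # at least the pile's own kernel, 1), so tiny kernels cannot be lost
    # to cancellation.
    comp <- function(sig_list, kind) {
      m <- matrix(0, length(ts), length(sig_list))
      z <- matrix(0, length(ts), length(sig_list))
      for (si in seq_along(sig_list)) {
        K <- kmat(sig_list[si])
        avail <- rep(TRUE, np)
        f <- switch(kind,
                    ambiguity = rowSums(K),
                    reward = numeric(np),
                    proximity = NULL)
        for (t in seq_len(Tn)) {
          if (t >= t0) {
            j <- t - t0 + 1L
            if (kind == "proximity") {
              cur <- if (t == 1L) start_i else cseq[t - 1L]
              num <- K[cseq[t], cur]
              den <- sum(K[avail, cur])
            } else {
              num <- f[cseq[t]]
              den <- sum(f[avail])
            }
            if (den > 0) {
              m[j, si] <- num / den
              z[j, si] <- 1
            }
          }
          avail[cseq[t]] <- FALSE
          if (kind == "ambiguity") f <- f - K[, cseq[t]]
          if (kind == "reward" && r[t] > 0) f <- f + r[t] * K[, cseq[t]]
        }
      }
      list(m = m, z = z)
    }
    amb <- comp(sigma_ambiguity, "ambiguity")
    rew <- comp(sigma_reward, "reward")
    pro <- comp(sigma_proximity, "proximity")
    meta <- attr(log, "meta")
    list(
      A = amb$m, R = rew$m, X = pro$m, Zr = rew$z, Zp = pro$z,
      steps = tibble(
        session = if (!is.null(meta$id)) meta$id else li,
        step = log$step[ts],
        n_available = grid$n_piles - (ts - 1L)
      )
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    abort("no scoreable steps in the supplied logs",
          class = "foragekernel_insufficient_data")
  }
  list(
    A = do.call(rbind, lapply(out, `[[`, "A")),
    R = do.call(rbind, lapply(out, `[[`, "R")),
    X = do.call(rbind, lapply(out, `[[`, "X")),
    Zr = do.call(rbind, lapply(out, `[[`, "Zr")),
    Zp = do.call(rbind, lapply(out, `[[`, "Zp")),
    steps = bind_rows(lapply(out, `[[`, "steps"))
  )
}
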