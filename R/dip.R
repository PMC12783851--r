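#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical distribution function and any unimodal distribution function
#' (Hartigan & Hartigan 1985, Ann. Statist. 13:70-84). It is computed by
#' iteratively refining a candidate modal interval: within the current
#' interval the greatest convex minorant (gcm) and least concave majorant
#' (lcm) of the empirical cdf are built and their largest separation is
#' compared with the best unimodal fit error accumulated from the tails.
#'
#' The dip lies in `[0, 1/4]`; for a sample of `n` distinct values it is
#' at least `1/(2n)`, with equality e.g. for equally spaced points.
#'
#' @param x Numeric sample (length >= 2 after removing non-finite values).
#' @return The dip statistic (a single number).
#' @examples
#' dip_statistic(1:10)          # 1/20: as unimodal as a sample can be
#' dip_statistic(c(0, 0, 1, 1)) # 1/4: two point masses
#' @export
dip_statistic <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2) {
    abort("dip needs at least 2 finite values",
          class = "foragekernel_insufficient_data")
  }
  u <- unique(x)
  m <- length(u)
  if (m == 1) return(0)
  if (m < n) return(dip_statistic_ties(u, x, n, m))
  cnt <- cumsum(tabulate(match(x, u), nbins = m))  # counts <= u_k
  pre <- c(0, cnt[-m])                             # counts <  u_k

  # index k of the hull segment bracketing position j, given vertex list v
  bracket <- function(v, j) {
    i <- findInterval(j, v)
    c(v[i], v[min(i + 1L, length(v))])
  }
  # hull values at all positions in lo:hi by linear interpolation
  hull_eval <- function(v, y, lo, hi) {
    stats::approx(u[v], y[v], xout = u[lo:hi], rule = 2)$y
  }

  lo <- 1L
  hi <- m
  D <- 0
  repeat {
    ks <- lo:hi
    gv <- lower_hull_idx(u[ks], pre[ks]) + lo - 1L   # gcm vertices (abs index)
    lv <- upper_hull_idx(u[ks], cnt[ks]) + lo - 1L   # lcm vertices
    g_at <- hull_eval(gv, pre, lo, hi)
    l_at <- hull_eval(lv, cnt, lo, hi)

    # largest separation between the hulls, with the cdf's left/right
    # limits at the vertices of each
    gap_g <- l_at[gv - lo + 1L] - pre[gv]   # at gcm vertices
    gap_l <- cnt[lv] - g_at[lv - lo + 1L]   # at lcm vertices
    d <- max(gap_g, gap_l)
    if (d <= D) break

    if (max(gap_g) >= max(gap_l)) {
      k_star <- gv[which.max(gap_g)]
      new_lo <- k_star
      new_hi <- bracket(lv, k_star)[2]
    } else {
      k_star <- lv[which.max(gap_l)]
      new_lo <- bracket(gv, k_star)[1]
      new_hi <- k_star
    }
    if (new_lo == lo && new_hi == hi) {
      # the modal interval cannot shrink further: fall back on the exact
      # general (mode-enumeration) computation
      return(dip_statistic_ties(u, x, n, m))
    }
    # best convex / concave fit error in the discarded tails
    D_l <- max(cnt[lo:new_lo] - g_at[seq_len(new_lo - lo + 1L)])
    D_r <- max(l_at[(new_hi - lo + 1L):(hi - lo + 1L)] - pre[new_hi:hi])
    D <- max(D, D_l, D_r)
    lo <- new_lo
    hi <- new_hi
    if (lo >= hi) {
      return(dip_statistic_ties(u, x, n, m))
    }
  }
  D / (2 * n)
}

# Dip of a sample with tied values. The hull-iteration shortcut above is
# exact for distinct values; atoms require the general minimax: the best
# unimodal cdf may place a point mass only at its mode, so the dip is
# min over mode nodes k of the smallest sup-distance T such that a
# nondecreasing function exists that is convex through the left bands,
# concave through the right bands, and jumps (only) at u_k. Solved by
# bisection on T with an O(m^2) feasibility check per candidate, using
# the classical slope condition for convex interpolation of intervals.
dip_statistic_ties <- function(u, x, n, m) {
  cnt <- cumsum(tabulate(match(x, u), nbins = m))  # F * n at u_k
  pre <- c(0, cnt[-m])                             # left limits * n
  span <- u[m] - u[1]

  # For a convex chain through vertical bands [lo_j, hi_j] at positions
  # pos (a virtual node pinning the function at 0 comes first), returns
  # per-node feasibility of each prefix chain and, for each node k, the
  # smallest achievable value of the chain 1..k-1 extended to pos[k].
  # Uses the slope characterisation of convex interpolation through
  # intervals: prefix 1..K is feasible iff no triple i < j < l <= K has
  # the chord of (pos_i, hi_i), (pos_l, hi_l) passing below lo_j.
  convex_side <- function(pos, lo, hi) {
    mm <- length(lo)
    steep <- numeric(mm)    # steepest forced entering slope at j
    first_bad <- rep(Inf, mm)
    for (j in 2:mm) {
      i <- 1:(j - 1)
      steep[j] <- max((lo[j] - hi[i]) / (pos[j] - pos[i]))
      if (j < mm) {
        l <- (j + 1):mm
        bad <- l[(hi[l] - lo[j]) / (pos[l] - pos[j]) < steep[j] - 1e-12]
        if (length(bad)) first_bad[j] <- bad[1]
      }
    }
    cutoff <- cummin(c(Inf, first_bad))[-1]  # min first_bad over j <= K
    prefix_ok <- (cumsum(lo > hi + 1e-12) == 0) & (seq_len(mm) < cutoff)
    end_min <- numeric(mm)
    for (k in 2:mm) {
      j <- 1:(k - 1)
      end_min[k] <- max(0, lo[j] + steep[j] * (pos[k] - pos[j]))
    }
    list(prefix_ok = prefix_ok, end_min = end_min)
  }

  pos_l <- c(u[1] - 1e6 * span, u)
  pos_r <- c(-u[m] - 1e6 * span, -rev(u))
  feasible <- function(Tc) {
    lo <- pmax(c(0, cnt - Tc), 0)
    hi <- pmin(c(0, pre + Tc), n)
    left <- convex_side(pos_l, lo, hi)
    # mirror: the concave chain through the right bands becomes a convex
    # chain on the flipped axis with bands [n - hi, n - lo]
    lo_r <- pmax(c(0, rev(n - (pre + Tc))), 0)
    hi_r <- pmin(c(0, rev(n - (cnt - Tc))), n)
    right <- convex_side(pos_r, lo_r, hi_r)
    for (k in 1:m) {
      kl <- k + 1L          # index of node k in the padded left arrays
      kr <- m - k + 2L      # index of node k in the mirrored arrays
      if (!left$prefix_ok[kl - 1L]) next
      if (!right$prefix_ok[kr - 1L]) next
      a_min <- left$end_min[kl]
      b_max <- n - right$end_min[kr]
      a_hi <- min(pre[k] + Tc, b_max)
      b_lo <- max(cnt[k] - Tc, a_min, 0)
      b_hi <- min(cnt[k] + Tc, n, b_max)
      if (a_min <= a_hi + 1e-9 && b_lo <= b_hi + 1e-9) return(TRUE)
    }
    FALSE
  }

  lo_T <- 0
  hi_T <- n / 4 + 1
  for (it in 1:60) {
    mid <- (lo_T + hi_T) / 2
    if (feasible(mid)) hi_T <- mid else lo_T <- mid
  }
  hi_T / n
}

# vertex indices (1-based, relative) of the lower convex hull of (x, y)
lower_hull_idx <- function(x, y) {
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  h <- integer(n)
  h[1:2] <- 1:2
  top <- 2L
  for (k in 3:n) {
    while (top >= 2L &&
           (y[h[top]] - y[h[top - 1L]]) * (x[k] - x[h[top]]) >=
           (y[k] - y[h[top]]) * (x[h[top]] - x[h[top - 1L]])) {
      top <- top - 1L
    }
    top <- top + 1L
    h[top] <- k
  }
  h[seq_len(top)]
}

upper_hull_idx <- function(x, y) {
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  h <- integer(n)
  h[1:2] <- 1:2
  top <- 2L
  for (k in 3:n) {
    while (top >= 2L &&
           (y[h[top]] - y[h[top - 1L]]) * (x[k] - x[h[top]]) <=
           (y[k] - y[h[top]]) * (x[h[top]] - x[h[top - 1L]])) {
      top <- top - 1L
    }
    top <- top + 1L
    h[top] <- k
  }
  h[seq_len(top)]
}

#' Dip test of unimodality
#'
#' Screens a step-size series (or any numeric sample) for bimodality with
#' Hartigan's dip statistic. The null distribution is calibrated by a
#' seeded bootstrap of uniform samples of the same size -- the uniform
#' being the asymptotically least favourable unimodal null -- and the
#' p-value is the fraction of null dips at least as large as the observed
#' one.
#'
#' @param x Numeric sample or a [step_sizes()] tibble (its `distance`
#'   column is used); needs at least 4 values.
#' @param n_boot Number of null resamples (default 2000).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `htest` with the dip statistic and p-value.
#' @export
dip_bimodality <- function(x, n_boot = 2000, seed = NULL) {
  d <- if (is.data.frame(x)) x$distance else as.numeric(x)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 4) {
    abort("the dip test needs at least 4 values",
          class = "foragekernel_insufficient_data")
  }
  stat <- dip_statistic(d)
  null <- with_seed(seed, function() {
    vapply(seq_len(n_boot), function(i) dip_statistic(runif(n)), numeric(1))
  })
  p <- (sum(null >= stat) + 1) / (n_boot + 1)
  structure(
    list(
      statistic = c(dip = stat),
      p.value = p,
      parameter = c(n = n, n_boot = n_boot),
      method = "Hartigan's dip test of unimodality (uniform bootstrap null)",
      data.name = deparse(substitute(x)),
      alternative = "non-unimodal (at least bimodal)"
    ),
    class = "htest"
  )
}
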