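#' Step sizes of a session
#'
#' The step size is the Euclidean distance in meters between the centres
#' of two consecutively searched piles (the decision path, not the
#' locomotion path). Each step is labelled with the outcome of the search
#' it follows, so the series supports post-success versus post-failure
#' contrasts.
#'
#' @param log A [session_log()].
#' @param grid Grid the log belongs to; defaults to the log's own grid.
#' @return A tibble with one row per transition: `session`, `step` (index
#'   of the arriving search), `distance` (m), and `prev_outcome`
#'   (`"success"` if the preceding search hit a filled pile).
#' @export
step_sizes <- function(log, grid = session_grid(log)) {
  stopifnot(inherits(log, "session_log"), inherits(grid, "pile_grid"))
  if (nrow(log) < 2) {
    abort("step sizes need at least two searches",
          class = "foragekernel_empty_series")
  }
  cc <- grid$coords
  p <- log$pile_id + 1L
  dx <- diff(cc[p, "col"]) * grid$pitch
  dy <- diff(cc[p, "row"]) * grid$pitch
  meta <- attr(log, "meta")
  id <- if (!is.null(meta$id)) meta$id else NA_integer_
  tibble(
    session = id,
    step = log$step[-1],
    distance = sqrt(dx^2 + dy^2),
    prev_outcome = factor(
      ifelse(log$reward_count[-nrow(log)] > 0, "success", "failure"),
      levels = c("failure", "success")
    )
  )
}

#' Binned step-size density
#'
#' Counts steps into bins of `width` meters (`[k w, (k+1) w)`) and
#' normalises to a probability density (`count / (total * width)`), so
#' `sum(density) * width == 1`. Bin centres sit at `(k + 0.5) w`.
#'
#' @param steps A step-size tibble from [step_sizes()] (possibly pooled
#'   across sessions), or a numeric vector of distances.
#' @param width Bin width in meters (default 0.2, i.e. 20 cm bins).
#' @return A tibble `bin_center`, `count`, `density` including empty bins
#'   up to the largest occupied one.
#' @export
bin_density <- function(steps, width = 0.2) {
  d <- if (is.data.frame(steps)) steps$distance else as.numeric(steps)
  if (!length(d)) {
    abort("empty step series", class = "foragekernel_empty_series")
  }
  if (!is.finite(width) || width <= 0) {
    abort("`width` must be positive", class = "foragekernel_invalid_argument")
  }
  k <- floor(d / width)
  counts <- tabulate(k + 1L, nbins = max(k) + 1L)
  tibble(
    bin_center = (seq_along(counts) - 0.5) * width,
    count = counts,
    density = counts / (length(d) * width)
  )
}

#' Power-law fit to a binned step-size density
#'
#' Ordinary least-squares regression of log density on log bin centre,
#' using only occupied bins (no pseudocounts). A straight line on the
#' double-log scale with slope in `[-3, -1]` is the conventional
#' signature of a Levy-like walk; a Brownian walk instead produces an
#' inverse-bell profile. The slope is invariant to the logarithm base.
#'
#' @param binned Output of [bin_density()].
#' @return A `power_law_fit` object with `slope`, `intercept` (natural
#'   log), `r_squared`, `in_levy_band`, and the points used; supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_power_law <- function(binned) {
  pts <- binned[binned$density > 0, , drop = FALSE]
  if (nrow(pts) < 3) {
    abort("power-law fit needs at least 3 occupied bins",
          class = "foragekernel_insufficient_data")
  }
  fit <- lm(log(density) ~ log(bin_center), data = pts)
  slope <- unname(coef(fit)[2])
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      # a noiseless power law fits exactly; the perfect-fit warning from
      # summary.lm is expected there
      r_squared = suppressWarnings(summary(fit)$r.squared),
      in_levy_band = slope >= -3 && slope <= -1,
      points = tibble(bin_center = pts$bin_center, density = pts$density),
      lm_fit = fit
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> slope %.3f (R^2 %.3f), %s the Levy band [-3, -1]\n",
              x$slope, x$r_squared,
              if (x$in_levy_band) "inside" else "outside"))
  invisible(x)
}

#' Post-success versus post-failure step contrast
#'
#' Compares the geometric mean of step sizes taken after a success
#' (filled pile) against those taken after a failure (empty pile), with a
#' two-sided Wilcoxon rank-sum test. When several foragers are compared
#' in one call (a `group` column), p-values are Benjamini-Hochberg
#' adjusted across them.
#'
#' @param steps Pooled step tibble with `distance` and `prev_outcome`
#'   columns (see [step_sizes()]), optionally a grouping column.
#' @param group Optional column name identifying the forager.
#' @return A tibble with one row per group: group sizes, geometric means,
#'   their ratio (success / failure), `p_value` and `p_adjusted`.
#' @export
outcome_step_contrast <- function(steps, group = NULL) {
  one <- function(df) {
    s <- df$distance[df$prev_outcome == "success"]
    f <- df$distance[df$prev_outcome == "failure"]
    if (!length(s) || !length(f)) {
      abort("both outcome groups must be non-empty",
            class = "foragekernel_insufficient_data")
    }
    gm <- function(v) exp(mean(log(v)))
    p <- if (all(s %in% f) && all(f %in% s) && length(s) == length(f)) 1 else
      suppressWarnings(wilcox.test(s, f, exact = FALSE)$p.value)
    tibble(
      n_success = length(s), n_failure = length(f),
      geomean_success = gm(s), geomean_failure = gm(f),
      ratio = gm(s) / gm(f), p_value = p
    )
  }
  if (is.null(group)) {
    out <- one(steps)
  } else {
    out <- steps %>%
      group_by(.data[[group]]) %>%
      dplyr::group_modify(~ one(.x)) %>%
      ungroup()
  }
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Convolutedness of a sub-path
#'
#' The negated, length-normalised sum of each step's projection on the
#' previous step:
#' `C = -(sum d_i cos(theta_i)) / (sum d_i)`, where `d_i` is the length
#' of step `i` and `theta_i` the angle between steps `i` and `i - 1`.
#' `C = -1` for a straight (roaming) path, `0` for right-angle turning,
#' `+1` for repeated reversals between two sites (dwelling). In the
#' default `"anchor"` mode the sum runs over steps 2..n; `"wrap"` mode
#' adds the first step, taking the last step of the path as the step
#' before the first.
#'
#' @param positions A two-column matrix or data frame of consecutive
#'   positions (any consistent spatial unit; the index is scale
#'   invariant), at least 3 rows.
#' @param mode `"anchor"` (default) or `"wrap"`.
#' @return The convolutedness index, a number in `[-1, 1]`.
#' @examples
#' convolutedness(cbind(0:3, 0))                      # straight: -1
#' convolutedness(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # square: 0
#' convolutedness(rbind(c(0, 0), c(1, 0), c(0, 0), c(1, 0)))  # lapses: +1
#' @export
convolutedness <- function(positions, mode = c("anchor", "wrap")) {
  mode <- match.arg(mode)
  pos <- as.matrix(positions)
  if (ncol(pos) != 2 || nrow(pos) < 3) {
    abort("convolutedness needs >= 3 positions (>= 2 steps)",
          class = "foragekernel_insufficient_data")
  }
  v <- diff(pos)                      # steps
  d <- sqrt(rowSums(v^2))
  if (any(d == 0)) {
    abort("zero-length steps are not allowed",
          class = "foragekernel_invalid_argument")
  }
  nstep <- nrow(v)
  cur <- 2:nstep
  prev <- 1:(nstep - 1)
  if (mode == "wrap") {
    cur <- c(1, cur)
    prev <- c(nstep, prev)
  }
  # d_i * cos(theta_i) = (v_i . v_{i-1}) / d_{i-1}
  proj <- rowSums(v[cur, , drop = FALSE] * v[prev, , drop = FALSE]) / d[prev]
  -sum(proj) / sum(d[cur]) + 0  # + 0 normalises a signed zero
}

# positions (meters) of a session's searched piles
session_positions <- function(log, grid = session_grid(log)) {
  cc <- grid$coords[log$pile_id + 1L, , drop = FALSE] * grid$pitch
  unname(cc)
}

#' Roaming versus dwelling around the first reward
#'
#' Splits each session into the pre-reward sub-path (searches strictly
#' before the first success) and the during/post-reward sub-path
#' (including and after the first success), keeping sessions with at
#' least `min_len` searches in both, and compares convolutedness: a
#' one-sample signed-rank test of all sub-path values against 0, and a
#' paired signed-rank test of post versus pre.
#'
#' @param logs A list of [session_log()]s (or one log).
#' @param min_len Minimum searches per sub-path (default 4).
#' @param mode Convolutedness mode, see [convolutedness()].
#' @return A list with `per_session` (tibble of `session`, `pre`, `post`),
#'   `pooled_mean`, `pooled_p` and `paired_p`.
#' @export
pre_post_reward_convolutedness <- function(logs, min_len = 4, mode = "anchor") {
  if (inherits(logs, "session_log")) logs <- list(logs)
  rows <- purrr::imap(logs, function(log, i) {
    first <- which(log$reward_count > 0)[1]
    if (is.na(first)) return(NULL)
    n_pre <- first - 1L
    n_post <- nrow(log) - first + 1L
    if (n_pre < min_len || n_post < min_len) return(NULL)
    pos <- session_positions(log)
    meta <- attr(log, "meta")
    tibble(
      session = if (!is.null(meta$id)) meta$id else i,
      pre = convolutedness(pos[1:n_pre, , drop = FALSE], mode = mode),
      post = convolutedness(pos[first:nrow(log), , drop = FALSE], mode = mode)
    )
  })
  per_session <- bind_rows(rows)
  if (!nrow(per_session)) {
    abort(sprintf("no session has >= %d searches both before and after the first reward",
                  min_len),
          class = "foragekernel_insufficient_data")
  }
  pooled <- c(per_session$pre, per_session$post)
  diffs <- per_session$post - per_session$pre
  pooled_p <- if (all(pooled == 0)) 1 else
    suppressWarnings(wilcox.test(pooled, mu = 0, exact = FALSE)$p.value)
  paired_p <- if (all(diffs == 0)) 1 else
    suppressWarnings(wilcox.test(per_session$post, per_session$pre,
                                 paired = TRUE, exact = FALSE)$p.value)
  list(
    per_session = per_session,
    pooled_mean = mean(pooled),
    pooled_p = pooled_p,
    paired_mean_diff = mean(diffs),
    paired_p = paired_p
  )
}
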