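#' Session logs of pile searches
#'
#' A session log is the ordered record of one foraging session: at each
#' step the id of the searched pile and the number of reward items found
#' there. Logs are tibbles with columns `step` (1-based, strictly
#' increasing), `pile_id` and `reward_count`, carrying the grid (and, for
#' simulated sessions, the abundance map and agent metadata) as attributes.
#'
#' @param events A data frame with columns `step`, `pile_id`,
#'   `reward_count`.
#' @param grid The [make_grid()] grid the session was recorded on.
#' @param map Optional `abundance_map` (simulated sessions).
#' @param meta Optional named list of session metadata (id, seed, agent).
#' @return A `session_log` tibble.
#' @export
session_log <- function(events, grid, map = NULL, meta = list()) {
  stopifnot(inherits(grid, "pile_grid"))
  events <- as_tibble(events)
  required <- c("step", "pile_id", "reward_count")
  missing <- setdiff(required, names(events))
  if (length(missing)) {
    abort(paste0("session log lacks column(s): ", paste(missing, collapse = ", ")),
          class = "foragekernel_format_error")
  }
  events <- events[required]
  if (nrow(events) < 1) {
    abort("a session log needs at least one search event",
          class = "foragekernel_format_error")
  }
  if (any(diff(events$step) <= 0)) {
    bad <- which(diff(events$step) <= 0)[1] + 1L
    abort(sprintf("step indices must be strictly increasing (row %d)", bad),
          class = "foragekernel_format_error")
  }
  bad <- which(events$reward_count < 0 |
                 events$reward_count != floor(events$reward_count))
  if (length(bad)) {
    abort(sprintf("reward_count must be a non-negative integer (row %d)", bad[1]),
          class = "foragekernel_format_error")
  }
  check_pile_ids(events$pile_id, grid)
  events$step <- as.integer(events$step)
  events$pile_id <- as.integer(events$pile_id)
  events$reward_count <- as.integer(events$reward_count)
  structure(
    events,
    grid = grid, map = map, meta = meta,
    has_revisits = anyDuplicated(events$pile_id) > 0,
    class = c("session_log", class(events))
  )
}

#' @export
#' @rdname session_log
#' @param log A `session_log`.
session_grid <- function(log) attr(log, "grid")

#' @export
#' @rdname session_log
session_has_revisits <- function(log) isTRUE(attr(log, "has_revisits"))

#' Write / read a session log as CSV
#'
#' The single interchange format: a CSV with header
#' `step,pile_id,reward_count`. Reading validates pile ids against the
#' grid, strict step ordering and non-negative counts, and flags (without
#' rejecting) revisited piles; see [session_has_revisits()].
#'
#' @param log A [session_log()].
#' @param path File path.
#' @param grid Grid the log belongs to, for validation.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` returns a `session_log`.
#' @examples
#' # a simulated 9 x 12 session shipped with the package
#' path <- system.file("extdata", "example_session.csv",
#'                     package = "foragekernel")
#' log <- read_session_log(path, make_grid(9, 12))
#' head(step_sizes(log))
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  readr::write_csv(as_tibble(log)[c("step", "pile_id", "reward_count")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path, grid) {
  if (!file.exists(path)) {
    abort(paste0("session log file not found: ", path),
          class = "foragekernel_file_not_found")
  }
  events <- readr::read_csv(
    path,
    col_types = readr::cols(
      step = readr::col_integer(),
      pile_id = readr::col_integer(),
      reward_count = readr::col_integer()
    ),
    progress = FALSE
  )
  log <- session_log(events, grid)
  attr(log, "meta") <- list(source = path)
  log
}
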