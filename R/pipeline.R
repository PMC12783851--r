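#' Run the simulate / analyze / fit workflow from one configuration
#'
#' Drives the whole pipeline from a single flat configuration (a named
#' list or the path of a YAML file): simulate sessions of a configured
#' agent on fresh hidden maps, analyse their paths (step-size density and
#' power-law fit, dip test, outcome contrast, convolutedness), and fit
#' the kernel model with grid search and bootstrap. Every stochastic
#' stage draws its own substream deterministically from the global
#' `seed`, so rerunning an identical configuration reproduces the output
#' files byte for byte. A `manifest.yml` records the configuration, its
#' hash and the package version; a failing stage halts with an error
#' naming the stage, leaving earlier outputs in place.
#'
#' Recognised keys (defaults in parentheses): `stages`
#' (`c("simulate", "analyze", "fit")`), `rows` (9), `cols` (12), `pitch_m`
#' (0.3), `map_kind` ("localized"), `n_sessions` (20), `agent_kind`
#' ("generative"), `w_info`, `w_rew`, `w_prox` (1/3 each),
#' `sigma_ambiguity` (3), `sigma_reward` (1), `sigma_proximity` (2) in
#' pile units, `p` (5), `stop_rule` ("all_rewards"), `max_steps` (Inf),
#' `start` (0), `bin_width_m` (0.2), `convolutedness_mode` ("anchor"),
#' `min_subpath` (4), `dip_boots` (2000), `n_subsets` (100), `fraction`
#' (0.8), `include_first` (FALSE), `seed` (1), `out_dir`.
#'
#' @param config Named list or path to a flat YAML file.
#' @return Invisibly, a list with the per-stage results (`sessions`,
#'   `analysis`, `fit`) and the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "foragekernel_file_not_found")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    stages = c("simulate", "analyze", "fit"),
    rows = 9, cols = 12, pitch_m = 0.3, map_kind = "localized",
    n_sessions = 20, agent_kind = "generative",
    w_info = 1 / 3, w_rew = 1 / 3, w_prox = 1 / 3,
    sigma_ambiguity = 3, sigma_reward = 1, sigma_proximity = 2,
    p = 5, stop_rule = "all_rewards", max_steps = Inf, start = 0,
    bin_width_m = 0.2, convolutedness_mode = "anchor", min_subpath = 4,
    dip_boots = 2000, n_subsets = 100, fraction = 0.8,
    include_first = FALSE, seed = 1, out_dir = NULL
  )
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$out_dir)) {
    abort("config needs an `out_dir`", class = "foragekernel_invalid_argument")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "foragekernel_stage_error")
    })
  }

  grid <- make_grid(cfg$rows, cfg$cols, cfg$pitch_m)
  spec <- agent_spec(
    kind = cfg$agent_kind,
    weights = weight_set(cfg$w_info, cfg$w_rew, cfg$w_prox),
    kernels = kernel_params(cfg$sigma_ambiguity, cfg$sigma_reward,
                            cfg$sigma_proximity, units = "piles"),
    p = cfg$p, start = cfg$start, stop_rule = cfg$stop_rule,
    max_steps = cfg$max_steps
  )
  map_fn <- switch(cfg$map_kind,
                   localized = generate_localized_map,
                   scattered = generate_scattered_map,
                   abort(paste0("unknown map_kind: ", cfg$map_kind),
                         class = "foragekernel_invalid_argument"))

  manifest <- list(
    config = cfg[order(names(cfg))],
    config_hash = rlang::hash(cfg[order(names(cfg))]),
    package_version = as.character(utils::packageVersion("foragekernel"))
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yml"))

  sessions <- NULL
  analysis <- NULL
  fit <- NULL

  if ("simulate" %in% cfg$stages) {
    sessions <- stage("simulate", function() {
      logs <- simulate_sessions(cfg$n_sessions, grid, spec,
                                map_fn = map_fn, seed = cfg$seed)
      for (i in seq_along(logs)) {
        write_session_log(logs[[i]],
                          file.path(cfg$out_dir, sprintf("session_%03d.csv", i)))
      }
      logs
    })
  }
  if ("analyze" %in% cfg$stages) {
    analysis <- stage("analyze", function() {
      logs <- sessions
      if (is.null(logs)) {
        paths <- sort(Sys.glob(file.path(cfg$out_dir, "session_*.csv")))
        if (!length(paths)) {
          abort(paste0("no session CSVs found under ", cfg$out_dir),
                class = "foragekernel_file_not_found")
        }
        logs <- lapply(paths, read_session_log, grid = grid)
      }
      steps <- bind_rows(lapply(logs, step_sizes))
      binned <- bin_density(steps, width = cfg$bin_width_m)
      readr::write_csv(binned, file.path(cfg$out_dir, "step_density.csv"),
                       progress = FALSE)
      pl <- tryCatch(fit_power_law(binned), error = function(e) NULL)
      dip <- dip_bimodality(steps, n_boot = cfg$dip_boots,
                            seed = derive_seed(cfg$seed, "dip"))
      contrast <- tryCatch(outcome_step_contrast(steps), error = function(e) NULL)
      conv <- tryCatch(
        pre_post_reward_convolutedness(logs, min_len = cfg$min_subpath,
                                       mode = cfg$convolutedness_mode),
        error = function(e) NULL)
      report <- list(
        n_sessions = length(logs),
        n_steps = nrow(steps),
        mean_step_m = mean(steps$distance),
        power_law = if (!is.null(pl)) as.list(glance(pl)) else NULL,
        dip = list(statistic = unname(dip$statistic), p_value = dip$p.value),
        outcome_contrast = if (!is.null(contrast)) as.list(contrast) else NULL,
        convolutedness = if (!is.null(conv)) {
          list(pooled_mean = conv$pooled_mean, pooled_p = conv$pooled_p,
               paired_mean_diff = conv$paired_mean_diff,
               paired_p = conv$paired_p, n_sessions = nrow(conv$per_session))
        } else NULL
      )
      jsonlite::write_json(report, file.path(cfg$out_dir, "analysis.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      report
    })
  }
  if ("fit" %in% cfg$stages) {
    fit <- stage("fit", function() {
      logs <- sessions
      if (is.null(logs)) {
        paths <- sort(Sys.glob(file.path(cfg$out_dir, "session_*.csv")))
        if (!length(paths)) {
          abort(paste0("no session CSVs found under ", cfg$out_dir),
                class = "foragekernel_file_not_found")
        }
        logs <- lapply(paths, read_session_log, grid = grid)
      }
      boot <- bootstrap_fit(logs, n_subsets = cfg$n_subsets,
                            fraction = cfg$fraction,
                            seed = derive_seed(cfg$seed, "bootstrap"),
                            include_first = cfg$include_first,
                            start = cfg$start)
      readr::write_csv(as_tibble(boot),
                       file.path(cfg$out_dir, "bootstrap_fits.csv"),
                       progress = FALSE)
      full <- attr(boot, "full_fit")
      jsonlite::write_json(
        list(weights = list(info = full$weights$info, rew = full$weights$rew,
                            prox = full$weights$prox),
             sigma_piles = list(ambiguity = full$kernels$ambiguity,
                                reward = full$kernels$reward,
                                proximity = full$kernels$proximity),
             loglik = full$loglik, n_terms = full$n_terms,
             bootstrap_median = as.list(setNames(tidy(boot)$estimate,
                                                 tidy(boot)$term))),
        file.path(cfg$out_dir, "fit.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      boot
    })
  }
  invisible(list(sessions = sessions, analysis = analysis, fit = fit,
                 out_dir = cfg$out_dir))
}
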