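# Trial-table I/O and the synthetic-study generator. Trial tables are CSV
# with header subject_id,condition,trial,stimulus,response; trial is
# 1-based and stimulus/response are in linear units.

trial_table_cols <- c("subject_id", "condition", "trial", "stimulus",
                      "response")

#' Write trial sequences to a CSV trial table
#'
#' @param trials A [trial_sequence()] or list of them.
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "trial_sequence")) trials <- list(trials)
  stopifnot(all(vapply(trials, inherits, logical(1), "trial_sequence")))
  tab <- do.call(rbind, lapply(trials, as.data.frame))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV trial table into trial sequences
#'
#' Validates the table (required columns, positive magnitudes, unique
#' `(subject, condition, trial)` keys), reporting offending row numbers,
#' then groups by subject and condition and sorts by trial index.
#'
#' @param path CSV file with columns
#'   `subject_id,condition,trial,stimulus,response`.
#'
#' @return Named list of [trial_sequence()] objects
#'   (`"<subject>.<condition>"`).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_table_cols, names(tab))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  problems <- character()
  bad <- which(!is.finite(tab$stimulus) | tab$stimulus <= 0 |
               !is.finite(tab$response) | tab$response <= 0)
  if (length(bad)) {
    problems <- c(problems, paste0("nonpositive or missing magnitude in row(s) ",
                                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  key <- paste(tab$subject_id, tab$condition, tab$trial, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate (subject, condition, trial) key in row(s) ",
                                   paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (length(problems)) stop(paste(problems, collapse = "; "))
  groups <- split(tab, paste(tab$subject_id, tab$condition, sep = "."))
  lapply(groups, function(g) {
    g <- g[order(g$trial), ]
    trial_sequence(g$subject_id[1], g$condition[1],
                   stimulus_sequence(g$stimulus, "iid"),
                   g$response)
  })
}

#' Default configuration for a synthetic reproduction study
#'
#' The defaults emulate the duration-reproduction design: 14 subjects, two
#' blocked conditions of 400 trials each — a bounded random walk between 400
#' and 1900 ms and the same 400 values in scrambled order — with responses
#' generated by subject-specific two-state observers whose variance ratios
#' are drawn uniformly from `v/r` in `[0.20, 4.12]` and `q/r` in
#' `[0, 0.66]` (the empirically observed parameter ranges), a small shift
#' `delta_x` in `[-0.05, 0.05]`, and log-domain response noise of SD 0.1.
#'
#' @param ... Named overrides of the default entries.
#'
#' @return A named list (class `study_config`).
#' @export
default_study_config <- function(...) {
  cfg <- list(n_subjects = 14L, n_trials = 400L, bounds = c(400, 1900),
              step_sd = NULL, v_over_r_range = c(0.20, 4.12),
              q_over_r_range = c(0, 0.66), delta_x_range = c(-0.05, 0.05),
              model_kind = "two_state", response_noise_sd = 0.1, d0 = 1,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  structure(modifyList(cfg, over), class = "study_config")
}

validate_study_config <- function(config) {
  if (!inherits(config, "study_config")) {
    config <- do.call(default_study_config, as.list(config))
  }
  stopifnot(config$n_subjects >= 1, config$n_trials >= 10,
            length(config$bounds) == 2, config$bounds[1] > 0,
            config$bounds[1] < config$bounds[2], config$d0 > 0,
            config$response_noise_sd >= 0)
  config
}

#' Generate a synthetic two-condition reproduction study
#'
#' For each subject: one bounded random-walk stimulus sequence, a permuted
#' ("randomized") copy of the same values, and responses simulated by a
#' subject-specific observer with parameters drawn from the configured
#' ranges. The random-walk step SD is calibrated once per bounds via
#' [calibrate_step_sd()] unless supplied. All randomness derives from
#' `config$seed`.
#'
#' @param config A list from [default_study_config()] (or overrides).
#' @param out_dir Optional directory; when given, a `trials.csv` table and
#'   a `manifest.json` (files, seeds, true parameters) are written there.
#'
#' @return List with `trials` (list of [trial_sequence()], two per
#'   subject), `config`, `truth` (per-subject parameter data frame) and
#'   `step_sd`.
#' @export
make_synthetic_study <- function(config = default_study_config(),
                                 out_dir = NULL) {
  config <- validate_study_config(config)
  n_sub <- config$n_subjects
  seeds <- derive_seeds(config$seed, 4L * n_sub + 1L)
  step_sd <- config$step_sd
  if (is.null(step_sd)) {
    step_sd <- calibrate_step_sd(config$bounds, n = config$n_trials,
                                 seed = seeds[4L * n_sub + 1L])
  }
  draw_in <- function(range, u) range[1] + u * (range[2] - range[1])
  trials <- list()
  truth_rows <- list()
  for (i in seq_len(n_sub)) {
    sid <- sprintf("s%02d", i)
    s_par <- seeds[4L * (i - 1L) + 1L]
    s_walk <- seeds[4L * (i - 1L) + 2L]
    s_perm <- seeds[4L * (i - 1L) + 3L]
    s_resp <- seeds[4L * (i - 1L) + 4L]
    u <- with_seed_(s_par, runif(3))
    pars <- observer_params(config$model_kind,
                            v_over_r = if (config$model_kind == "iterative") 0
                                       else draw_in(config$v_over_r_range, u[1]),
                            q_over_r = if (config$model_kind == "static") 0
                                       else draw_in(config$q_over_r_range, u[2]),
                            delta_x = draw_in(config$delta_x_range, u[3]),
                            d0 = config$d0)
    walk <- gen_random_walk_sequence(config$n_trials, step_sd,
                                     config$bounds, seed = s_walk)
    perm <- permute_sequence(walk, seed = s_perm)
    resp_seeds <- derive_seeds(s_resp, 2L)
    trials[[paste0(sid, ".random_walk")]] <-
      simulate_observer(walk, pars, config$response_noise_sd,
                        seed = resp_seeds[1], subject_id = sid,
                        condition = "random_walk")
    trials[[paste0(sid, ".randomized")]] <-
      simulate_observer(perm, pars, config$response_noise_sd,
                        seed = resp_seeds[2], subject_id = sid,
                        condition = "randomized")
    truth_rows[[i]] <- data.frame(subject_id = sid,
                                  model_kind = pars$model_kind,
                                  v_over_r = pars$v_over_r,
                                  q_over_r = pars$q_over_r,
                                  delta_x = pars$delta_x, d0 = pars$d0,
                                  stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  study <- list(trials = trials, config = config, truth = truth,
                step_sd = step_sd)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    manifest <- list(files = "trials.csv",
                     seed = config$seed, step_sd = step_sd,
                     config = unclass(config), truth = truth)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  study
}

#' Load a synthetic study written by [make_synthetic_study()]
#'
#' Reads the trial table and re-attaches the true observer parameters from
#' the manifest.
#'
#' @param dir Directory containing `trials.csv` and `manifest.json`.
#'
#' @return List with `trials` (truth attached), `truth` and `manifest`.
#' @export
read_synthetic_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  trials <- read_trials(file.path(dir, "trials.csv"))
  truth <- manifest$truth
  for (nm in names(trials)) {
    sid <- trials[[nm]]$subject_id
    row <- truth[truth$subject_id == sid, ]
    if (nrow(row) == 1) {
      trials[[nm]]$truth <- observer_params(row$model_kind, row$v_over_r,
                                            row$q_over_r, row$delta_x,
                                            row$d0)
    }
  }
  list(trials = trials, truth = truth, manifest = manifest)
}
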