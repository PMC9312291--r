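# Block-design acquisition schedule and event tables.
#
# The default design is a two-run block paradigm with three task
# conditions: NA (action generation), NV (verb generation) and NR (noun
# reading). Each run holds 12 task blocks (4 per condition) alternating
# with 12 rest blocks; a task block is a 2 s cue followed by six trials of
# a 1 s fixation and a 1.5 s stimulus, i.e. a 15 s task epoch; a rest
# block lasts 10 s. At TR = 2 s this gives 162 volumes per run, 324 over
# the session.

#' Default acquisition design
#'
#' @return a list of class `acquisition_design` with fields `tr_seconds`,
#'   `n_runs`, `blocks_per_task_per_run`, `cue_seconds`, `trials_per_block`,
#'   `fixation_seconds`, `stimulus_seconds`, `rest_seconds`, `task_names`.
#' @export
default_design <- function() {
  structure(list(
    tr_seconds = 2,
    n_runs = 2L,
    blocks_per_task_per_run = 4L,
    cue_seconds = 2,
    trials_per_block = 6L,
    fixation_seconds = 1,
    stimulus_seconds = 1.5,
    rest_seconds = 10,
    task_names = c("NA", "NV", "NR")
  ), class = "acquisition_design")
}

#' Task-epoch duration of one block (s)
#' @param design an `acquisition_design`.
#' @return seconds from first fixation onset to last stimulus offset.
#' @export
block_task_seconds <- function(design) {
  design$trials_per_block * (design$fixation_seconds + design$stimulus_seconds)
}

#' Scheduled duration of one run (s)
#' @param design an `acquisition_design`.
#' @export
run_duration_seconds <- function(design) {
  n_task <- length(design$task_names) * design$blocks_per_task_per_run
  n_task * (design$cue_seconds + block_task_seconds(design)) +
    n_task * design$rest_seconds
}

#' Number of volumes acquired per run
#' @param design an `acquisition_design`.
#' @export
volumes_per_run <- function(design) {
  as.integer(round(run_duration_seconds(design) / design$tr_seconds))
}

#' Build the block design and its per-run event tables
#'
#' Task blocks alternate with rest blocks. The condition order is a
#' deterministic Latin-square rotation: within run `r`, the `k`-th triple
#' of task blocks presents the three conditions rotated by `r + k - 2`
#' positions, so every condition occupies every within-triple position
#' across the session and each condition has
#' `blocks_per_task_per_run` blocks per run.
#'
#' @param defaults_override named list overriding fields of
#'   [default_design()].
#' @return list with `design` (the resolved `acquisition_design`) and
#'   `events`, a data.frame with columns `run_id` (1-based), `onset` (s
#'   from run start), `duration` (s), `condition` (one of the task names,
#'   `"cue"` or `"rest"`) and `block_id` (unique across the session).
#' @export
build_design <- function(defaults_override = list()) {
  design <- default_design()
  unknown <- setdiff(names(defaults_override), names(design))
  if (length(unknown)) stopf("build_design: unknown design fields: %s",
                             paste(unknown, collapse = ", "))
  design[names(defaults_override)] <- defaults_override
  durs <- unlist(design[c("cue_seconds", "fixation_seconds",
                          "stimulus_seconds", "rest_seconds")])
  if (design$tr_seconds <= 0) stopf("build_design: tr_seconds must be > 0")
  if (any(durs < 0)) stopf("build_design: negative durations: %s",
                           paste(names(durs)[durs < 0], collapse = ", "))
  run_s <- run_duration_seconds(design)
  n_vol <- run_s / design$tr_seconds
  if (abs(n_vol - round(n_vol)) > 1e-9) {
    stopf(paste0("build_design: run duration %g s is not a multiple of TR %g s",
                 " (cue=%g, fixation=%g, stimulus=%g, rest=%g)"),
          run_s, design$tr_seconds, design$cue_seconds,
          design$fixation_seconds, design$stimulus_seconds, design$rest_seconds)
  }

  tasks <- design$task_names
  k <- length(tasks)
  n_blocks <- k * design$blocks_per_task_per_run
  task_len <- block_task_seconds(design)
  rows <- list()
  block_counter <- 0L
  for (run in seq_len(design$n_runs)) {
    # Latin-square rotation of condition triples
    order_run <- character(0)
    for (tri in seq_len(design$blocks_per_task_per_run)) {
      rot <- (run + tri - 2L) %% k
      order_run <- c(order_run, tasks[((seq_len(k) - 1L + rot) %% k) + 1L])
    }
    t0 <- 0
    for (b in seq_len(n_blocks)) {
      block_counter <- block_counter + 1L
      if (design$cue_seconds > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          run_id = run, onset = t0, duration = design$cue_seconds,
          condition = "cue", block_id = block_counter,
          stringsAsFactors = FALSE)
      }
      if (task_len > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          run_id = run, onset = t0 + design$cue_seconds, duration = task_len,
          condition = order_run[b], block_id = block_counter,
          stringsAsFactors = FALSE)
      }
      t0 <- t0 + design$cue_seconds + task_len
      if (design$rest_seconds > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          run_id = run, onset = t0, duration = design$rest_seconds,
          condition = "rest", block_id = block_counter,
          stringsAsFactors = FALSE)
      }
      t0 <- t0 + design$rest_seconds
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(run_id = integer(0), onset = numeric(0), duration = numeric(0),
               condition = character(0), block_id = integer(0),
               stringsAsFactors = FALSE)
  }
  list(design = design, events = events)
}

#' Write per-run events as BIDS-style TSV
#'
#' Columns `onset`, `duration`, `trial_type`, `block_id`. One file per run.
#' @param events events data.frame from [build_design()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of file paths.
#' @export
write_events_tsv <- function(events, dir, prefix = "events") {
  runs <- sort(unique(events$run_id))
  paths <- character(0)
  for (run in runs) {
    ev <- events[events$run_id == run,
                 c("onset", "duration", "condition", "block_id")]
    names(ev)[3] <- "trial_type"
    path <- file.path(dir, sprintf("%s_run-%02d.tsv", prefix, run))
    utils::write.table(ev, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  paths
}

#' Read one or more BIDS-style events TSVs
#'
#' Note: the condition label "NA" is a real label here, so missing-value
#' parsing is disabled for the `trial_type` column.
#'
#' @param paths TSV paths in run order.
#' @return events data.frame in the [build_design()] layout.
#' @export
read_events_tsv <- function(paths) {
  out <- list()
  for (i in seq_along(paths)) {
    ev <- utils::read.table(paths[i], sep = "\t", header = TRUE,
                            colClasses = c(onset = "numeric",
                                           duration = "numeric",
                                           trial_type = "character",
                                           block_id = "integer"),
                            na.strings = character(0))
    names(ev)[names(ev) == "trial_type"] <- "condition"
    ev$run_id <- i
    out[[i]] <- ev[, c("run_id", "onset", "duration", "condition", "block_id")]
  }
  do.call(rbind, out)
}
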