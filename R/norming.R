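# Stimulus norming: action-consistency ratios and familiarity-based
# stimulus selection.

#' Action consistency of a response count table
#'
#' The ratio of the most common to the second most common related action
#' count for a noun. Unanimous response sets (second count 0) return
#' `Inf`, a sentinel that sorts above every finite ratio so the selection
#' ordering is preserved.
#'
#' @param counts named numeric vector (or list) of action -> count.
#' @return ratio >= 1, or `Inf` when responses are unanimous.
#' @export
action_consistency <- function(counts) {
  counts <- unlist(counts)
  if (!length(counts) || all(counts == 0)) {
    stopf("action_consistency: empty or all-zero counts")
  }
  if (any(counts < 0)) stopf("action_consistency: negative counts")
  srt <- sort(as.numeric(counts), decreasing = TRUE)
  n2 <- if (length(srt) >= 2) srt[2] else 0
  if (n2 == 0) Inf else srt[1] / n2
}

#' Summarize per-rater norming responses into a per-noun table
#'
#' @param ratings data.frame with columns `rater`, `noun`,
#'   `action_response`, `familiarity` (0-7).
#' @return data.frame per noun: `noun`, `top_action` (modal response),
#'   `consistency`, `familiarity_mean`.
#' @export
norming_table <- function(ratings) {
  if (any(ratings$familiarity < 0 | ratings$familiarity > 7)) {
    stopf("norming_table: familiarity outside [0, 7]")
  }
  nouns <- sort(unique(ratings$noun))
  rows <- lapply(nouns, function(nn) {
    sub <- ratings[ratings$noun == nn, ]
    counts <- table(sub$action_response)
    data.frame(noun = nn,
               top_action = names(counts)[which.max(counts)],
               consistency = action_consistency(counts),
               familiarity_mean = mean(sub$familiarity),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select stimuli by consistency and familiarity under per-action quotas
#'
#' Nouns passing both thresholds are ranked by consistency (unanimous
#' first) then familiarity, and taken to fill each action's quota
#' (default: 8 each of holding, pinching, pressing -> 24 stimuli).
#'
#' @param table per-noun data.frame from [norming_table()].
#' @param balance_groups named integer vector action -> quota.
#' @param min_consistency minimum consistency ratio.
#' @param min_familiarity minimum mean familiarity.
#' @return the selected rows of `table`, ranked, with a `group` column.
#' @export
select_stimuli <- function(table,
                           balance_groups = c(holding = 8, pinching = 8,
                                              pressing = 8),
                           min_consistency = 2, min_familiarity = 4) {
  ok <- table[table$consistency >= min_consistency &
                table$familiarity_mean >= min_familiarity, , drop = FALSE]
  picked <- list()
  for (act in names(balance_groups)) {
    pool <- ok[ok$top_action == act, , drop = FALSE]
    pool <- pool[order(-pool$consistency, -pool$familiarity_mean, pool$noun), ,
                 drop = FALSE]
    quota <- balance_groups[[act]]
    if (nrow(pool) < quota) {
      stopf("select_stimuli: only %d qualifying nouns for action '%s' (need %d)",
            nrow(pool), act, quota)
    }
    sel <- pool[seq_len(quota), , drop = FALSE]
    sel$group <- act
    picked[[act]] <- sel
  }
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}
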