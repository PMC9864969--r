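#' Score the Stop-and-Go Switch task from trial-level data
#'
#' Implements the standard scoring rule for the web-administered
#' Stop-and-Go Switch task, a measure of task switching and inhibitory
#' control. For each person: (1) respondents with fewer than `min_correct`
#' correct trials are excluded as invalid; (2) median latencies are
#' computed over the *correct* switch and nonswitch trials of the mixed
#' condition (medians blunt the influence of outlying trials; incorrect
#' trials never contribute because latency is timed to the correct
#' response); (3) the two medians are averaged; (4) the average is reverse
#' scored by negation, so higher scores mean better functioning. Baseline
#' and reverse-baseline conditions measure simple choice reaction time and
#' are ignored.
#'
#' @param trials Data frame with columns `person_id`, `condition`
#'   (`"baseline"`, `"reverse_baseline"`, `"mixed"`), `trial_type`
#'   (`"switch"`, `"nonswitch"`), `latency_ms` (> 0), `correct` (0/1), and
#'   optionally `test_date`.
#' @param min_correct Minimum fraction of correct trials (default 0.70).
#' @param gate_scope Whether the correctness gate is computed over `"all"`
#'   trials (default) or the `"mixed"` condition only.
#' @return A list with `scores` (person_id, test_name = "stop_go", score =
#'   minus the average of the two median latencies in ms, test_date) and
#'   `excluded` (person_id, reason).
#' @export
score_stop_go <- function(trials, min_correct = 0.70,
                          gate_scope = c("all", "mixed")) {
  gate_scope <- match.arg(gate_scope)
  stopifnot(all(c("person_id", "condition", "trial_type", "latency_ms",
                  "correct") %in% names(trials)))
  if (any(trials$latency_ms <= 0))
    stop("latency_ms must be positive", call. = FALSE)
  persons <- unique(trials$person_id)
  scores <- list()
  excluded <- list()
  for (p in persons) {
    tp <- trials[trials$person_id == p, ]
    gate_trials <- if (gate_scope == "all") tp else
      tp[tp$condition == "mixed", ]
    if (nrow(gate_trials) == 0L) {
      excluded[[p]] <- "no scorable trials"
      next
    }
    if (mean(gate_trials$correct) < min_correct) {
      excluded[[p]] <- sprintf("correct fraction %.2f below %.2f gate",
                               mean(gate_trials$correct), min_correct)
      next
    }
    mx <- tp[tp$condition == "mixed" & tp$correct == 1, ]
    sw <- mx$latency_ms[mx$trial_type == "switch"]
    ns <- mx$latency_ms[mx$trial_type == "nonswitch"]
    if (!length(sw) || !length(ns)) {
      excluded[[p]] <- "no correct switch or nonswitch trials in mixed condition"
      next
    }
    scores[[p]] <- data.frame(
      person_id = p, test_name = "stop_go",
      score = -(median(sw) + median(ns)) / 2,
      test_date = if ("test_date" %in% names(tp))
        max(as.Date(tp$test_date)) else as.Date(NA))
  }
  list(
    scores = if (length(scores)) do.call(rbind, c(scores, make.row.names = FALSE))
    else data.frame(person_id = character(0), test_name = character(0),
                    score = numeric(0), test_date = as.Date(character(0))),
    excluded = if (length(excluded))
      data.frame(person_id = names(excluded),
                 reason = unlist(excluded), row.names = NULL)
    else data.frame(person_id = character(0), reason = character(0)))
}
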