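#' Filter survey items by eligibility rules
#'
#' Retains records only for items that (1) were shown individually on a page
#' (`single_page == 1`; grid/matrix items lack per-item timestamps),
#' (2) are not open-ended, and (3) were completed by at least
#' `min_completion` of that survey's respondents. The completion-rate
#' denominator is the number of distinct persons with any record in the
#' item's survey.
#'
#' @param records Data frame of RT records with columns `person_id`,
#'   `item_id`, `survey_id`, `rt_seconds`.
#' @param item_meta Data frame with columns `item_id`, `survey_id`,
#'   `single_page`, `open_ended`, covering every item in `records`.
#' @param min_completion Minimum completion rate (default 0.75).
#' @return The retained records, with attribute `"filter_counts"` giving the
#'   number of items and records dropped per rule (an item failing several
#'   rules is counted under the first: page layout, then open-ended, then
#'   completion).
#' @export
filter_items <- function(records, item_meta, min_completion = 0.75) {
  stopifnot(is.data.frame(records), is.data.frame(item_meta))
  unknown <- setdiff(unique(records$item_id), item_meta$item_id)
  if (length(unknown))
    stop("items missing from item_meta: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)

  meta <- item_meta[match(unique(records$item_id), item_meta$item_id), ]
  # completion rate: responders(item) / responders(item's survey)
  svy_resp <- tapply(records$person_id, records$survey_id,
                     function(p) length(unique(p)))
  item_resp <- tapply(records$person_id, records$item_id,
                      function(p) length(unique(p)))
  meta$completion <- as.numeric(item_resp[meta$item_id]) /
    as.numeric(svy_resp[meta$survey_id])

  fail_page <- meta$single_page != 1L
  fail_open <- !fail_page & meta$open_ended == 1L
  fail_comp <- !fail_page & !fail_open & meta$completion < min_completion
  keep_items <- meta$item_id[!(fail_page | fail_open | fail_comp)]

  keep <- records$item_id %in% keep_items
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- data.frame(
    rule = c("not_single_page", "open_ended", "low_completion", "kept"),
    items = c(sum(fail_page), sum(fail_open), sum(fail_comp),
              length(keep_items)),
    records = c(sum(records$item_id %in% meta$item_id[fail_page]),
                sum(records$item_id %in% meta$item_id[fail_open]),
                sum(records$item_id %in% meta$item_id[fail_comp]),
                sum(keep)))
  out
}

#' Drop persons with too few completed surveys
#'
#' Panel-inclusion rule: a person must have records in at least
#' `min_surveys` distinct surveys.
#'
#' @param records RT record data frame.
#' @param min_surveys Minimum distinct surveys per person (default 5).
#' @return Retained records, with attribute `"persons_dropped"`.
#' @export
filter_min_surveys <- function(records, min_surveys = 5) {
  n_svy <- tapply(records$survey_id, records$person_id,
                  function(s) length(unique(s)))
  ok <- names(n_svy)[n_svy >= min_surveys]
  out <- records[records$person_id %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "persons_dropped") <- length(n_svy) - length(ok)
  out
}

#' Trim extreme response times per item
#'
#' For each item, computes the empirical `percentile` quantile of
#' `rt_seconds` across respondents (inverse-CDF definition, type 1, so the
#' threshold is an attained order statistic) and removes records strictly
#' above it. Removal (rather than winsorizing) is used because the targeted
#' records — respondents stepping away from the screen — carry no usable
#' timing signal. Because the threshold is itself a retained data point,
#' the operation is idempotent: re-trimming at the same percentile removes
#' nothing (an interpolated quantile would keep shaving records on every
#' pass).
#'
#' @param records RT record data frame.
#' @param percentile Trim quantile in (0, 1), default 0.99.
#' @return Retained records, with attribute `"n_trimmed"`.
#' @export
trim_rts <- function(records, percentile = 0.99) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 1)
    stop("'percentile' must lie strictly between 0 and 1", call. = FALSE)
  thr <- tapply(records$rt_seconds, records$item_id, quantile,
                probs = percentile, type = 1, names = FALSE)
  keep <- records$rt_seconds <= as.numeric(thr[records$item_id])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_trimmed") <- sum(!keep)
  out
}

#' Log-transform response times
#'
#' Adds `log_rt = ln(rt_seconds)` after handling sub-second records: by
#' default they are floored to 1 second (so the minimum possible log RT is
#' 0.00 log seconds); alternatively they can be dropped.
#'
#' @param records RT record data frame (already trimmed).
#' @param sub_second Either `"floor"` (default) or `"drop"`.
#' @return The records with a `log_rt` column (natural log of seconds).
#' @export
log_transform <- function(records, sub_second = c("floor", "drop")) {
  sub_second <- match.arg(sub_second)
  if (any(!is.finite(records$rt_seconds)) || any(records$rt_seconds <= 0))
    stop("rt_seconds must be positive and finite", call. = FALSE)
  out <- records
  if (sub_second == "drop") {
    out <- out[out$rt_seconds >= 1, , drop = FALSE]
    rownames(out) <- NULL
  }
  out$log_rt <- log(pmax(out$rt_seconds, 1))
  out
}

#' Run the full RT preprocessing pipeline
#'
#' Applies, in order: item eligibility filters ([filter_items()]), the
#' minimum-surveys person filter ([filter_min_surveys()]), per-item
#' percentile trimming ([trim_rts()]), and the log transform
#' ([log_transform()]). Trim thresholds are therefore computed on the
#' post-filter population.
#'
#' @inheritParams filter_items
#' @inheritParams trim_rts
#' @inheritParams filter_min_surveys
#' @inheritParams log_transform
#' @return Clean records with `log_rt`, carrying a `"preprocess_counts"`
#'   attribute summarizing each step.
#' @export
preprocess_rt <- function(records, item_meta, min_completion = 0.75,
                          min_surveys = 5, percentile = 0.99,
                          sub_second = "floor") {
  f <- filter_items(records, item_meta, min_completion)
  s <- filter_min_surveys(f, min_surveys)
  t <- trim_rts(s, percentile)
  out <- log_transform(t, sub_second)
  attr(out, "preprocess_counts") <- list(
    input_records = nrow(records),
    item_filter = attr(f, "filter_counts"),
    persons_dropped = attr(s, "persons_dropped"),
    records_trimmed = attr(t, "n_trimmed"),
    output_records = nrow(out))
  out
}
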