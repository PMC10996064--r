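#' Relative change in depression severity
#'
#' Percent change in the HDRS-17 total score at follow-up relative to
#' baseline: `100 * (followup - baseline) / baseline`. A 24 -> 12 change is
#' -50%, the response boundary.
#'
#' @param baseline Baseline HDRS score(s), in (0, 52].
#' @param followup Follow-up HDRS score(s), in 0..52.
#' @return Percent change (same length as inputs).
#' @seealso [label_outcome()], [absolute_delta()]
#' @export
delta_hdrs <- function(baseline, followup) {
  stopifnot(is.numeric(baseline), is.numeric(followup))
  if (any(baseline <= 0)) {
    stop("baseline HDRS must be > 0 for a relative change")
  }
  if (any(baseline > 52) || any(followup < 0) || any(followup > 52)) {
    stop("HDRS scores must lie within [0, 52]")
  }
  100 * (followup - baseline) / baseline
}

#' Binary clinical outcome label
#'
#' Subjects whose severity declined by at least half (percent change
#' <= -50, boundary inclusive) are labelled `"positive"` (responders),
#' all others `"negative"`.
#'
#' @param delta_pct Percent change in HDRS (from [delta_hdrs()]).
#' @return Factor with levels `negative`, `positive`.
#' @export
label_outcome <- function(delta_pct) {
  stopifnot(all(is.finite(delta_pct)))
  factor(ifelse(delta_pct <= -50, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Absolute change in depression severity
#'
#' Score-point difference `followup - baseline`. Provided for the
#' sensitivity analysis that swaps the relative change for the absolute one;
#' note that it conflates e.g. 35 -> 25 with 15 -> 5.
#'
#' @inheritParams delta_hdrs
#' @return Score difference in HDRS points.
#' @export
absolute_delta <- function(baseline, followup) {
  stopifnot(is.numeric(baseline), is.numeric(followup))
  followup - baseline
}
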