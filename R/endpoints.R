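#' Knee-swelling difference score
#'
#' Swelling at each timepoint is expressed relative to the pre-injection
#' measurement: `post - baseline` (mm; may be negative).
#'
#' @param post Post-injection measurement(s), mm.
#' @param baseline Baseline (pre-injection) measurement, mm.
#' @return Difference score(s), mm.
#' @examples
#' swellingDifference(5.2, 4.0)  # 1.2
#' @export
swellingDifference <- function(post, baseline) {
  if (any(is.na(post)) || any(is.na(baseline)))
    stop("post and baseline must both be measured")
  post - baseline
}

#' Time-course area under the curve per subject
#'
#' Trapezoidal integral of each subject's measurements over the time axis,
#' including the baseline timepoint. By default raw values are integrated
#' (no baseline anchoring); `subtractBaseline = TRUE` first subtracts each
#' subject's first measurement.
#'
#' @param timecourse Tidy data.frame with columns `subject_id`, `group`,
#'   `time`, `value` (e.g. from [simulateTimeCourse()]).
#' @param subtractBaseline Subtract the first timepoint's value before
#'   integrating.
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `auc` (measurement x time units).
#' @examples
#' tc <- data.frame(subject_id = "s1", group = "WT",
#'                  time = 0:3, value = c(0, 1, 1, 0))
#' timecourseAuc(tc)$auc  # 2
#' @export
timecourseAuc <- function(timecourse, subtractBaseline = FALSE) {
  stopifnot(all(c("subject_id", "time", "value") %in% names(timecourse)))
  subs <- unique(timecourse$subject_id)
  out <- lapply(subs, function(s) {
    d <- timecourse[timecourse$subject_id == s, ]
    d <- d[order(d$time), ]
    if (nrow(d) < 2L) stop("subject ", s, " has fewer than 2 timepoints")
    if (anyDuplicated(d$time)) stop("duplicate timepoint for subject ", s)
    v <- d$value
    if (subtractBaseline) v <- v - v[1]
    data.frame(subject_id = s,
               group = if ("group" %in% names(d)) d$group[1] else NA,
               auc = pracma::trapz(d$time, v), row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Log-transform withdrawal thresholds
#'
#' Von Frey 50% withdrawal thresholds are log-transformed before analysis;
#' base 10 by default.
#'
#' @param thresholds Positive thresholds in grams.
#' @param base Logarithm base (default 10).
#' @return Transformed values.
#' @examples
#' logThresholds(c(1, 0.1))  # 0, -1
#' @export
logThresholds <- function(thresholds, base = 10) {
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("thresholds must be positive")
  log(thresholds, base = base)
}

#' Comparative-CT relative expression
#'
#' Per sample, `dCT = CT_target - CT_reference`; `ddCT` subtracts the mean
#' dCT of the control group; the fold change is `2^(-ddCT)`. A sample with
#' dCT equal to the control mean has fold 1; the control group has
#' geometric-mean fold 1 by construction.
#'
#' @param records data.frame with columns `sample_id`, `group`,
#'   `ct_target`, `ct_reference` (threshold cycles).
#' @param controlGroup Label of the control (calibrator) group.
#' @return The records with `dct`, `ddct` and `fold` columns appended.
#' @examples
#' rec <- data.frame(sample_id = 1:2, group = c("veh", "ngf"),
#'                   ct_target = c(25, 24), ct_reference = c(20, 20))
#' relativeExpression(rec, "veh")$fold  # 1, 2
#' @export
relativeExpression <- function(records, controlGroup) {
  stopifnot(all(c("sample_id", "group", "ct_target", "ct_reference") %in%
                names(records)))
  if (any(!is.finite(records$ct_target)) ||
      any(!is.finite(records$ct_reference)) ||
      any(records$ct_target <= 0) || any(records$ct_reference <= 0))
    stop("CT values must be finite and positive")
  if (!controlGroup %in% records$group)
    stop("control group '", controlGroup, "' has no samples")
  records$dct <- records$ct_target - records$ct_reference
  ctrl <- mean(records$dct[records$group == controlGroup])
  records$ddct <- records$dct - ctrl
  records$fold <- 2^(-records$ddct)
  records
}

#' Per-group mean and standard error
#'
#' Mean ± SEM per group, SEM being the sample SD over sqrt(n); missing for
#' a single observation (never reported as 0).
#'
#' @param values Numeric measurements.
#' @param groups Group label per measurement.
#' @return data.frame: `group`, `n`, `mean`, `sem`.
#' @examples
#' groupSummary(c(3, 5), c("a", "a"))  # mean 4, sem 1
#' @export
groupSummary <- function(values, groups) {
  stopifnot(length(values) == length(groups), length(values) >= 1L)
  gs <- unique(groups)
  do.call(rbind, c(lapply(gs, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sem = semOf(v),
               row.names = NULL)
  }), list(make.row.names = FALSE)))
}
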