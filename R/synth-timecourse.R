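#' Simulate behavioral time-course measurements
#'
#' Generates per-subject repeated measurements over a shared set of
#' timepoints: observation = group mean trajectory + a subject-level random
#' offset + i.i.d. Gaussian noise. Suitable for emulating knee-swelling
#' (mm), knee-hyperalgesia withdrawal force (g, assay capped at 450 g in the
#' real apparatus) or von Frey threshold (g) series.
#'
#' @param nSubjects Subjects per group: scalar or vector named by group.
#' @param timepoints Strictly increasing numeric timepoints (days or weeks);
#'   at least 2.
#' @param groupMeans Named list: one mean trajectory (same length as
#'   `timepoints`) per group.
#' @param subjectSD SD of the per-subject constant offset.
#' @param noiseSD SD of the per-observation noise.
#' @param seed Integer RNG seed.
#' @return A tidy data.frame: `subject_id`, `group`, `time`, `value`.
#' @examples
#' tc <- simulateTimeCourse(5, timepoints = c(0, 2, 4, 7),
#'                          groupMeans = list(WT = c(0, 1.2, 1.0, 0.5),
#'                                            KO = c(0, 0.2, 0.1, 0.0)),
#'                          subjectSD = 0.1, noiseSD = 0.2, seed = 1)
#' @export
simulateTimeCourse <- function(nSubjects,
                               timepoints,
                               groupMeans,
                               subjectSD = 0,
                               noiseSD = 0,
                               seed = 1L) {
  if (length(timepoints) < 2L) stop("at least 2 timepoints are required")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  groups <- names(groupMeans)
  if (is.null(groups)) stop("groupMeans must be a named list")
  if (any(vapply(groupMeans, length, 1L) != length(timepoints)))
    stop("each group mean trajectory must match the timepoints")
  ns <- if (length(nSubjects) == 1L)
    setNames(rep(nSubjects, length(groups)), groups) else nSubjects[groups]

  set.seed(as.integer(seed))
  rows <- list()
  for (g in groups) {
    for (s in seq_len(ns[[g]])) {
      off <- if (subjectSD > 0) rnorm(1, 0, subjectSD) else 0
      eps <- if (noiseSD > 0) rnorm(length(timepoints), 0, noiseSD) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("%s_s%02d", g, s), group = g,
        time = timepoints, value = groupMeans[[g]] + off + eps,
        row.names = NULL)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
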