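#' Density-extrapolated total neuron count
#'
#' The total number of neurons in the imaged field is estimated by counting
#' neurons within a sub-region of average density and extrapolating to the
#' full imaged area: `round(count * imagedArea / subregionArea)`, rounding
#' half away from zero to an integer neuron count.
#'
#' @param countInSubregion Neurons counted in the sub-region.
#' @param subregionArea Sub-region area (µm²), positive and at most
#'   `imagedArea`.
#' @param imagedArea Full imaged area (µm²); defaults to the standard
#'   981.36 x 981.36 µm² field.
#' @return Integer estimated total.
#' @examples
#' estimateTotalNeurons(30, 10, 100)   # 300
#' @export
estimateTotalNeurons <- function(countInSubregion, subregionArea,
                                 imagedArea = 981.36^2) {
  if (subregionArea <= 0) stop("subregion area must be positive")
  if (imagedArea <= 0) stop("imaged area must be positive")
  if (subregionArea > imagedArea)
    stop("subregion area cannot exceed the imaged area")
  if (countInSubregion < 0) stop("count must be non-negative")
  as.integer(roundHalfAway(countInSubregion * imagedArea / subregionArea))
}

#' Percentage of imaged neurons responding to a stimulus
#'
#' `100 * nResponses / totalNeurons`.
#'
#' @param nResponses Number of responders (0 <= nResponses <= totalNeurons).
#' @param totalNeurons Total neurons imaged (> 0), typically from
#'   [estimateTotalNeurons()].
#' @return Percentage in `[0, 100]`.
#' @export
percentResponders <- function(nResponses, totalNeurons) {
  if (any(totalNeurons <= 0)) stop("totalNeurons must be positive")
  if (any(nResponses < 0) || any(nResponses > totalNeurons))
    stop("nResponses must lie in [0, totalNeurons]")
  100 * nResponses / totalNeurons
}

#' Relative frequency distribution of responder soma areas
#'
#' Bins areas (µm²) into left-closed, right-open intervals defined by
#' `binEdges` and returns per-bin counts and relative frequencies (fractions
#' of all binned values, summing to 1). With `includeOutside = TRUE` (the
#' default) two open end-bins collect values below the first and at/above
#' the last edge; otherwise such values are dropped with a warning.
#'
#' @param areas Positive areas in µm².
#' @param binEdges Strictly increasing bin edges; default 100-µm²-wide bins
#'   from 0 to 2000.
#' @param includeOutside Keep out-of-range values in open end-bins.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`, `freq`. An empty
#'   input yields all-zero counts with `freq` NA and a warning.
#' @examples
#' areaHistogram(c(100, 300), binEdges = c(0, 200, 400))$freq  # 0.5 0.5
#' @export
areaHistogram <- function(areas, binEdges = seq(0, 2000, by = 100),
                          includeOutside = TRUE) {
  if (any(diff(binEdges) <= 0) || length(binEdges) < 2L)
    stop("bin edges must be strictly increasing")
  if (length(areas) && any(areas <= 0)) stop("areas must be positive")
  lo <- binEdges[-length(binEdges)]
  hi <- binEdges[-1]
  if (includeOutside) {
    lo <- c(-Inf, lo, binEdges[length(binEdges)])
    hi <- c(binEdges[1], hi, Inf)
  }
  if (length(areas) == 0L) {
    warning("empty area list: returning an empty distribution")
    return(data.frame(bin_lo = lo, bin_hi = hi, count = 0L, freq = NA_real_))
  }
  idx <- findInterval(areas, binEdges, rightmost.closed = FALSE)
  if (includeOutside) {
    idx <- idx + 1L  # shift so the underflow bin is 1
  } else {
    drop <- idx == 0L | idx == length(binEdges)
    if (any(drop)) {
      warning(sum(drop), " value(s) outside the bin edges dropped")
      idx <- idx[!drop]
    }
    if (length(idx) == 0L)
      return(data.frame(bin_lo = lo, bin_hi = hi, count = 0L, freq = NA_real_))
  }
  counts <- tabulate(idx, nbins = length(lo))
  data.frame(bin_lo = lo, bin_hi = hi, count = counts,
             freq = counts / sum(counts))
}

#' Per-stimulus summary of a called imaging session
#'
#' Aggregates per-neuron responder calls into the session-level quantities:
#' responder count per stimulus, percent responders against the total number
#' of neurons imaged (supplied directly, or estimated by density
#' extrapolation via [estimateTotalNeurons()] upstream), mean peak AUC over
#' responders (NA when there are none, never 0), and the relative frequency
#' distribution of responder soma areas per stimulus.
#'
#' @param calls data.frame from [callResponses()].
#' @param totalNeurons Total neurons imaged: a single number applied to all
#'   stimuli, or a named vector per stimulus. Defaults to the number of
#'   neurons with calls for each stimulus.
#' @param binEdges Area histogram bin edges (µm²); see [areaHistogram()].
#' @return A [SessionSummary-class].
#' @export
summarizeSession <- function(calls, totalNeurons = NULL,
                             binEdges = seq(0, 2000, by = 100)) {
  stopifnot(is.data.frame(calls),
            all(c("stimulus", "responder", "peak_auc", "area_um2") %in%
                names(calls)))
  stims <- unique(calls$stimulus)
  rows <- list()
  hist <- list()
  for (s in stims) {
    cs <- calls[calls$stimulus == s, ]
    nresp <- sum(cs$responder)
    tot <- if (is.null(totalNeurons)) nrow(cs)
           else if (length(totalNeurons) == 1L && is.null(names(totalNeurons)))
             as.numeric(totalNeurons)
           else as.numeric(totalNeurons[[s]])
    rows[[s]] <- data.frame(
      stimulus = s, n_responders = nresp, total_neurons = tot,
      percent_responders = percentResponders(nresp, tot),
      mean_peak_auc = if (nresp > 0) mean(cs$peak_auc[cs$responder])
                      else NA_real_,
      row.names = NULL)
    if (nresp > 0) {
      h <- areaHistogram(cs$area_um2[cs$responder], binEdges = binEdges)
      hist[[s]] <- cbind(stimulus = s, h)
    }
  }
  new("SessionSummary",
      stimulusSummary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      areaDistribution = if (length(hist))
        do.call(rbind, c(hist, list(make.row.names = FALSE)))
      else data.frame(stimulus = character(), bin_lo = numeric(),
                      bin_hi = numeric(), count = integer(), freq = numeric()),
      binEdges = binEdges)
}
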