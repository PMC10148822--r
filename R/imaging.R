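#' Extract per-neuron traces from an image stack and ROI label image
#'
#' The trace of a neuron is the mean pixel intensity within its ROI at each
#' frame; its soma area is the ROI pixel count times the squared pixel size.
#'
#' @param stack Numeric 3-D array (x, y, frame) or list of frame matrices.
#' @param rois Integer label matrix on the same pixel grid; 0 = background,
#'   positive integers label one ROI per neuron.
#' @param pixelSize Pixel pitch in µm/pixel (default 1.92).
#' @return A list with `traces` (neurons x frames matrix, rows named
#'   `n<label>`) and `areas` (µm² per neuron).
#' @examples
#' fr <- matrix(7, 4, 4)
#' stk <- array(c(fr, fr), dim = c(4, 4, 2))
#' lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L
#' extractTraces(stk, lab, pixelSize = 1.92)$traces
#' @export
extractTraces <- function(stack, rois, pixelSize = 1.92) {
  if (is.list(stack))
    stack <- array(unlist(stack), dim = c(dim(stack[[1]]), length(stack)))
  d <- dim(stack)
  if (length(d) != 3L) stop("stack must be a 3-D array or list of matrices")
  if (!identical(dim(rois), d[1:2]))
    stop("stack and ROI label image must share the pixel grid")
  labels <- sort(unique(as.integer(rois[rois > 0])))
  if (length(labels) == 0L) stop("ROI label image contains no ROIs")
  sel <- which(rois > 0)
  lab <- as.integer(rois[sel])
  counts <- tabulate(lab, nbins = max(labels))[labels]
  flat <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])
  sums <- rowsum(flat[sel, , drop = FALSE], group = lab)
  tr <- sums[match(labels, as.integer(rownames(sums))), , drop = FALSE] / counts
  rownames(tr) <- paste0("n", labels)
  list(traces = tr, areas = setNames(counts * pixelSize^2, rownames(tr)))
}

#' ΔF/F₀ normalization against a baseline period
#'
#' Normalizes raw fluorescence to the mean of a designated baseline period:
#' `f0 = mean(trace[baselineFrames])` and `dff_t = (trace_t - f0) / f0`.
#' The baseline SD — the yardstick of the responder criterion — is the SD of
#' ΔF/F₀ over `sdFrames` (by default the same baseline period), using the
#' sample (n-1) convention unless `sdType = "population"`.
#'
#' For an [ImagingSession-class], `baselineMode` selects the baseline period:
#' `"global"` (default) uses the force-free block at the start of the
#' recording for both F₀ and the SD; `"prestim"` renormalizes each stimulus
#' epoch against its own 10 pre-stimulus frames (per-stimulus F₀ and SD are
#' then stored in `metadata(x)$perStimulus`).
#'
#' Note the invariances this normalization buys: a gain change
#' `trace -> g * trace` (g > 0) leaves ΔF/F₀ unchanged, whereas adding a
#' constant offset does not.
#'
#' @param x Numeric fluorescence trace, or an [ImagingSession-class].
#' @param baselineFrames Integer frame indices of the baseline period
#'   (numeric method).
#' @param sdFrames Frames over which the baseline SD is taken; defaults to
#'   `baselineFrames`.
#' @param sdType `"sample"` (n-1, default) or `"population"` (n).
#' @param baselineMode `"global"` or `"prestim"` (session method).
#' @param ... Passed on to the numeric method.
#' @return Numeric method: a list with `f0`, `dff` and `baseline_sd`.
#'   Session method: a [DffTraces-class].
#' @examples
#' computeDff(c(100, 100, 150), baselineFrames = 1:2)
#' @export
#' @rdname computeDff
setMethod("computeDff", "numeric",
  function(x, baselineFrames, sdFrames = baselineFrames,
           sdType = c("sample", "population"), ...) {
    sdType <- match.arg(sdType)
    if (length(baselineFrames) < 1L) stop("baselineFrames must be non-empty")
    if (any(baselineFrames < 1L) || any(baselineFrames > length(x)) ||
        any(sdFrames < 1L) || any(sdFrames > length(x)))
      stop("baseline indices out of range")
    f0 <- mean(x[baselineFrames])
    if (!is.finite(f0) || f0 <= 0)
      stop("baseline mean must be positive (corrupt trace?)")
    dff <- (x - f0) / f0
    bsd <- sdOf(dff[sdFrames], type = sdType)
    list(f0 = f0, dff = dff, baseline_sd = bsd)
  })

#' @export
#' @rdname computeDff
setMethod("computeDff", "ImagingSession",
  function(x, baselineMode = c("global", "prestim"),
           sdType = c("sample", "population"), ...) {
    baselineMode <- match.arg(baselineMode)
    sdType <- match.arg(sdType)
    p <- imagingProtocol(x)
    f <- traces(x)
    gframes <- globalBaselineFrames(p)
    f0g <- rowMeans(f[, gframes, drop = FALSE])
    if (any(f0g <= 0)) stop("baseline mean must be positive for every neuron")
    dmat <- sweep(sweep(f, 1, f0g, "-"), 1, f0g, "/")
    perStim <- NULL
    if (baselineMode == "global") {
      bsd <- apply(dmat[, gframes, drop = FALSE], 1, sdOf, type = sdType)
    } else {
      bsd <- rep(NA_real_, nrow(f))
      rows <- list()
      for (s in stimulusLabels(p)) {
        ep <- epochIndices(p, s)
        f0s <- rowMeans(f[, ep$pre, drop = FALSE])
        if (any(f0s <= 0)) stop("pre-stimulus baseline mean must be positive")
        idx <- c(ep$pre, ep$stim, ep$post)
        dmat[, idx] <- sweep(sweep(f[, idx, drop = FALSE], 1, f0s, "-"),
                             1, f0s, "/")
        dpre <- sweep(sweep(f[, ep$pre, drop = FALSE], 1, f0s, "-"), 1, f0s, "/")
        rows[[s]] <- data.frame(
          neuron_id = rownames(f), stimulus = s, f0 = f0s,
          baseline_sd = apply(dpre, 1, sdOf, type = sdType),
          row.names = NULL)
      }
      perStim <- do.call(rbind, rows)
    }
    se <- SummarizedExperiment(
      assays = list(dff = dmat),
      rowData = DataFrame(f0 = f0g, baseline_sd = bsd,
                          area_um2 = unname(neuronAreas(x)),
                          row.names = rownames(f)),
      metadata = list(protocol = p, baselineMode = baselineMode,
                      sdType = sdType, perStimulus = perStim))
    new("DffTraces", se)
  })

# strict ">" at the k-sigma boundary, per the responder definition
.responderDecision <- function(peak, baselineSD, k = 4) {
  peak > k * baselineSD
}

#' Responder decision for a single trace and application window
#'
#' A neuron responds to a stimulus when its peak ΔF/F₀ during the
#' application window strictly exceeds `k` times the SD of the baseline
#' period (default `k = 4`).
#'
#' @param dffTrace Numeric per-frame ΔF/F₀.
#' @param window Integer frame indices of the stimulus-application window.
#' @param baselineSD SD of ΔF/F₀ over the baseline period.
#' @param k Threshold multiplier (default 4).
#' @return A list with `peak_dff`, `threshold` (`k * baselineSD`) and
#'   logical `responder`.
#' @examples
#' callResponse(c(0, 0.21, 0), window = 1:3, baselineSD = 0.05)$responder
#' @export
callResponse <- function(dffTrace, window, baselineSD, k = 4) {
  if (length(window) < 1L) stop("application window must be non-empty")
  if (any(window < 1L) || any(window > length(dffTrace)))
    stop("application window outside the trace")
  peak <- max(dffTrace[window])
  list(peak_dff = peak, threshold = k * baselineSD,
       responder = .responderDecision(peak, baselineSD, k))
}

#' Peak area under the ΔF/F₀ curve
#'
#' Locates the frame of peak ΔF/F₀ within the application window, expands to
#' the maximal contiguous run of frames with positive ΔF/F₀ containing that
#' frame (the run may extend beyond the window, e.g. into post-stimulus
#' frames), and integrates ΔF/F₀ over the run by the trapezoidal rule with
#' frame spacing `1/frameRate` seconds. Returns 0 (degenerate) when the peak
#' is not positive or the run is a single frame.
#'
#' @param dffTrace Numeric per-frame ΔF/F₀.
#' @param window Integer frame indices of the stimulus-application window.
#' @param frameRate Frames per second.
#' @return Peak AUC in ΔF/F₀ · seconds (non-negative).
#' @examples
#' tr <- c(rep(0, 3), rep(0.5, 7), rep(0, 3))
#' peakAuc(tr, window = 4:10, frameRate = 0.7)  # 6 * (1/0.7) * 0.5
#' @export
peakAuc <- function(dffTrace, window, frameRate) {
  if (length(window) < 1L) stop("application window must be non-empty")
  if (any(window < 1L) || any(window > length(dffTrace)))
    stop("application window outside the trace")
  pk <- window[which.max(dffTrace[window])]
  if (!(dffTrace[pk] > 0)) return(0)
  lo <- pk
  while (lo > 1L && dffTrace[lo - 1L] > 0) lo <- lo - 1L
  hi <- pk
  while (hi < length(dffTrace) && dffTrace[hi + 1L] > 0) hi <- hi + 1L
  if (hi == lo) return(0)  # single-frame run: no trapezoid support
  run <- lo:hi
  max(0, pracma::trapz(run / frameRate, dffTrace[run]))
}

#' Call responders for every neuron and stimulus of a session
#'
#' Applies the k-SD responder criterion ([callResponse()]) to each neuron's
#' ΔF/F₀ over each stimulus-application window, and attaches the peak AUC
#' ([peakAuc()]) for responders (0 for non-responders). The application
#' window is exactly the stimulus frames; post-stimulus frames enter only
#' through AUC run expansion.
#'
#' @param x A [DffTraces-class] (from [computeDff()]) or an
#'   [ImagingSession-class] (normalized internally with defaults or the
#'   supplied `baselineMode`/`sdType`).
#' @param k Threshold multiplier (default 4).
#' @param ... Passed to [computeDff()] when `x` is an `ImagingSession`.
#' @return A data.frame with one row per (neuron, stimulus): `neuron_id`,
#'   `stimulus`, `f0`, `baseline_sd`, `peak_dff`, `threshold`, `responder`,
#'   `peak_auc`, `area_um2`.
#' @export
callResponses <- function(x, k = 4, ...) {
  if (is(x, "ImagingSession")) x <- computeDff(x, ...)
  stopifnot(is(x, "DffTraces"))
  p <- imagingProtocol(x)
  d <- dff(x)
  areas <- unname(neuronAreas(x))
  perStim <- metadata(x)$perStimulus
  out <- list()
  for (s in stimulusLabels(p)) {
    ep <- epochIndices(p, s)
    if (is.null(perStim)) {
      f0 <- rowData(x)$f0
      bsd <- rowData(x)$baseline_sd
    } else {
      ps <- perStim[perStim$stimulus == s, ]
      ps <- ps[match(rownames(x), ps$neuron_id), ]
      f0 <- ps$f0
      bsd <- ps$baseline_sd
    }
    peak <- apply(d[, ep$stim, drop = FALSE], 1, max)
    resp <- .responderDecision(peak, bsd, k)
    auc <- vapply(seq_len(nrow(d)), function(i) {
      if (resp[i]) peakAuc(d[i, ], ep$stim, frameRate(p)) else 0
    }, numeric(1))
    out[[s]] <- data.frame(
      neuron_id = rownames(x), stimulus = s, f0 = f0, baseline_sd = bsd,
      peak_dff = unname(peak), threshold = k * bsd,
      responder = unname(resp), peak_auc = auc, area_um2 = areas,
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' False-positive rate of the k-SD rule on pure-noise windows
#'
#' Simulates application windows of i.i.d. Gaussian ΔF/F₀ noise with known
#' SD and applies the responder decision with the true SD supplied as the
#' baseline SD. For window length `m`, the analytic false-positive rate is
#' `1 - pnorm(k)^m` (about 3.17e-4 for k = 4, m = 10).
#'
#' @param nWindows Number of simulated windows.
#' @param windowLength Frames per application window (default 10).
#' @param k Threshold multiplier (default 4).
#' @param sigma True noise SD (default 1; the rate is scale-free).
#' @param seed Optional RNG seed.
#' @return A list with the empirical `rate`, the `analytic` rate and `n`.
#' @export
responderFalsePositiveRate <- function(nWindows, windowLength = 10L, k = 4,
                                       sigma = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nWindows)
  hits <- 0L
  chunk <- 200000L
  done <- 0L
  while (done < n) {
    m <- min(chunk, n - done)
    peaks <- .rowMax(matrix(rnorm(m * windowLength, 0, sigma), nrow = m))
    hits <- hits + sum(.responderDecision(peaks, sigma, k))
    done <- done + m
  }
  list(rate = hits / n, analytic = 1 - stats::pnorm(k)^windowLength, n = n)
}

# row maxima without the matrixStats dependency
.rowMax <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
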