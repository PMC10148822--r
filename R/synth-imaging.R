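#' Simulate a stimulus-locked DRG calcium-imaging session
#'
#' Generates a recording that follows the acquisition protocol frame for
#' frame: a force-free global baseline block, then one pre/stim/post epoch
#' per stimulus. Each neuron has a lognormal baseline fluorescence and soma
#' area; per stimulus it is a responder with probability `responderProb`,
#' and responders carry one calcium transient whose shape is a
#' difference-of-exponentials kernel (GCaMP6s-like rise/decay) starting at a
#' random onset within the application window. Amplitudes are expressed in
#' ΔF/F₀ units: the kernel is normalized over the sampled frame grid so the
#' realized noiseless peak ΔF/F₀ equals the drawn amplitude exactly.
#' Transients are confined to their own epoch, mirroring the recovery pause
#' between stimuli that lets fluorescence return to baseline. Additive
#' Gaussian noise has SD `noiseSD` times each neuron's baseline
#' fluorescence.
#'
#' In `outputMode = "stack"` the neurons are additionally rendered as 2-D
#' Gaussian blobs on the protocol's pixel grid, with a disk ROI mask per
#' neuron (label image). The blob profile is normalized to mean 1 over the
#' ROI, so mean-ROI extraction recovers the generating trace.
#'
#' The generator is a pure function of its arguments and `seed`: identical
#' calls reproduce identical output.
#'
#' @param nNeurons Number of neurons.
#' @param protocol An [ImagingProtocol-class].
#' @param responderProb Responder probability per stimulus: scalar or vector
#'   named by stimulus label.
#' @param amplitudeMeanlog,amplitudeSdlog Lognormal parameters of transient
#'   peak amplitude (ΔF/F₀ units).
#' @param noiseSD Acquisition noise SD as a fraction of each neuron's
#'   baseline fluorescence.
#' @param baselineMean Mean baseline fluorescence (arbitrary units).
#' @param baselineSdlog Lognormal spread of baseline fluorescence across
#'   neurons.
#' @param areaMeanlog,areaSdlog Lognormal parameters of soma area (µm²);
#'   defaults span roughly 80–1600 µm² (diameters ~10–45 µm).
#' @param riseTau,decayTau Transient rise and decay time constants (s).
#' @param outputMode `"traces"` (default) or `"stack"`.
#' @param forbidOverlap In stack mode, rejection-sample centroids so ROIs do
#'   not overlap.
#' @param seed Integer RNG seed.
#' @return A list with `session` (an [ImagingSession-class]) and `truth`
#'   (itself a list: `neurons` — per-neuron id, area, baseline fluorescence
#'   and, in stack mode, centroid; `responses` — per neuron x stimulus
#'   responder flag, amplitude and onset frame). In stack mode also `stack`
#'   (x, y, frame array) and `rois` (integer label matrix).
#' @examples
#' p <- ImagingProtocol(stimulusLabels = c("30g", "100g"))
#' sim <- simulateImagingSession(20, p, responderProb = 0.3, seed = 1)
#' table(sim$truth$responses$responder)
#' @export
simulateImagingSession <- function(nNeurons,
                                   protocol = ImagingProtocol(),
                                   responderProb = 0.1,
                                   amplitudeMeanlog = log(0.8),
                                   amplitudeSdlog = 0.5,
                                   noiseSD = 0.05,
                                   baselineMean = 100,
                                   baselineSdlog = 0.25,
                                   areaMeanlog = log(360),
                                   areaSdlog = 0.75,
                                   riseTau = 0.2,
                                   decayTau = 1.5,
                                   outputMode = c("traces", "stack"),
                                   forbidOverlap = FALSE,
                                   seed = 1L) {
  outputMode <- match.arg(outputMode)
  nNeurons <- as.integer(nNeurons)
  if (nNeurons < 1L) stop("nNeurons must be positive")
  if (noiseSD < 0) stop("noiseSD must be non-negative")
  stims <- stimulusLabels(protocol)
  probs <- if (length(responderProb) == 1L)
    setNames(rep(responderProb, length(stims)), stims)
  else responderProb[stims]
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("responderProb must give probabilities in [0, 1] per stimulus")

  set.seed(as.integer(seed))
  ids <- paste0("n", seq_len(nNeurons))
  areas <- rlnorm(nNeurons, areaMeanlog, areaSdlog)
  basef <- rlnorm(nNeurons, log(baselineMean) - baselineSdlog^2 / 2,
                  baselineSdlog)
  nT <- totalFrames(protocol)
  dt <- 1 / frameRate(protocol)
  lay <- epochLayout(protocol)

  signal <- matrix(0, nNeurons, nT)
  resp <- list()
  for (s in stims) {
    ep <- epochIndices(protocol, s)
    isResp <- runif(nNeurons) < probs[[s]]
    amp <- ifelse(isResp, rlnorm(nNeurons, amplitudeMeanlog, amplitudeSdlog), 0)
    # onset anywhere in the window but leaving >= 1 stimulus frame after it,
    # so the sampled kernel peak stays inside the application window
    onsetChoices <- ep$stim[seq_len(max(1L, lay[["stim"]] - 1L))]
    onset <- onsetChoices[sample.int(length(onsetChoices), nNeurons,
                                     replace = TRUE)]
    onset[!isResp] <- NA_integer_
    epochEnd <- ep$post[length(ep$post)]
    for (i in which(isResp)) {
      fr <- onset[i]:epochEnd
      tt <- (fr - onset[i]) * dt
      ker <- exp(-tt / decayTau) - exp(-tt / riseTau)
      ker <- ker / max(ker)  # sampled-grid normalization: peak == amplitude
      signal[i, fr] <- signal[i, fr] + amp[i] * ker
    }
    resp[[s]] <- data.frame(neuron_id = ids, stimulus = s,
                            responder = isResp, amplitude = amp,
                            onset_frame = onset, row.names = NULL)
  }

  fluor <- basef * (1 + signal)
  if (noiseSD > 0)
    fluor <- fluor + matrix(rnorm(nNeurons * nT), nNeurons, nT) *
      (noiseSD * basef)
  fluor <- pmax(fluor, 0)
  rownames(fluor) <- ids

  neurons <- data.frame(neuron_id = ids, area_um2 = areas,
                        baseline_f = basef, row.names = NULL)
  out <- list()
  if (outputMode == "stack") {
    grid <- pixelGrid(protocol)
    px <- pixelSize(protocol)
    r_px <- sqrt(areas / pi) / px
    if (any(2 * r_px + 2 > min(grid)))
      stop("neurons too large for the pixel grid; enlarge the field")
    cx <- numeric(nNeurons); cy <- numeric(nNeurons)
    for (i in seq_len(nNeurons)) {
      for (try in seq_len(2000L)) {
        x <- runif(1, r_px[i] + 1, grid[1] - r_px[i])
        y <- runif(1, r_px[i] + 1, grid[2] - r_px[i])
        if (!forbidOverlap || i == 1L ||
            all(sqrt((x - cx[seq_len(i - 1L)])^2 +
                     (y - cy[seq_len(i - 1L)])^2) >
                r_px[i] + r_px[seq_len(i - 1L)] + 1))
          break
        if (try == 2000L) stop("could not place non-overlapping ROIs; ",
                               "reduce nNeurons or enlarge the field")
      }
      cx[i] <- x; cy[i] <- y
    }
    rois <- matrix(0L, grid[1], grid[2])
    flat <- matrix(0, grid[1] * grid[2], nT)
    xs <- row(rois); ys <- col(rois)
    for (i in seq_len(nNeurons)) {
      d2 <- (xs - cx[i])^2 + (ys - cy[i])^2
      mask <- which(d2 <= r_px[i]^2)
      if (length(mask) == 0L)
        mask <- which.min(d2)  # degenerate sub-pixel soma
      w <- exp(-d2[mask] / (2 * (r_px[i] / 2)^2))
      w <- w / mean(w)
      rois[mask] <- i
      flat[mask, ] <- flat[mask, ] + outer(w, fluor[i, ])
    }
    stack <- array(flat, dim = c(grid[1], grid[2], nT))
    neurons$centroid_x_px <- cx
    neurons$centroid_y_px <- cy
    # areas consistent with the rendered masks so trace and stack agree
    counts <- tabulate(rois[rois > 0], nbins = nNeurons)
    neurons$area_um2 <- areas <- counts * px^2
    out$stack <- stack
    out$rois <- rois
  }

  out$session <- ImagingSession(fluor, protocol, areas)
  out$truth <- list(neurons = neurons,
                    responses = do.call(rbind, c(resp,
                                                 list(make.row.names = FALSE))))
  out
}
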