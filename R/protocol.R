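#' Acquisition protocol for stimulus-locked DRG calcium imaging
#'
#' Describes how a recording is framed in time and space: frames are acquired
#' at a fixed rate, an initial force-free block provides the global baseline,
#' and each stimulus contributes one epoch of pre-stimulus, stimulus-application
#' and post-stimulus frames. The spatial fields give the scanned region (µm)
#' and the pixel pitch (µm/pixel).
#'
#' The defaults reproduce a typical in vivo two-photon protocol for the L4
#' DRG: 0.7 Hz frames, a 30-frame force-free baseline, 10 pre / 10 stimulus /
#' 10 post frames per stimulus, a 981.36 x 981.36 µm² field at 1.92 µm/pixel,
#' and three stimuli (30 g and 100 g knee force, hind-paw brush).
#'
#' @param frameRate Acquisition rate in frames per second.
#' @param nGlobalBaseline Number of force-free baseline frames at the start
#'   of the recording.
#' @param epochLayout Integer vector of three frame counts, named
#'   `pre`, `stim`, `post`, giving the per-stimulus epoch layout.
#' @param stimulusLabels Ordered character vector of stimulus names.
#' @param fieldSize Scanned region in µm, length-2 (x, y).
#' @param pixelSize Pixel pitch in µm/pixel.
#'
#' @return An `ImagingProtocol` object.
#' @examples
#' p <- ImagingProtocol()
#' totalFrames(p)            # 30 + 3 stimuli x 30 frames = 120
#' epochIndices(p, "100g")$stim
#' @aliases ImagingProtocol
#' @export ImagingProtocol
#' @exportClass ImagingProtocol
setClass("ImagingProtocol",
  representation(
    frameRate       = "numeric",
    nGlobalBaseline = "integer",
    epochLayout     = "integer",
    stimulusLabels  = "character",
    fieldSize       = "numeric",
    pixelSize       = "numeric"
  )
)

setValidity("ImagingProtocol", function(object) {
  msg <- character()
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(object@nGlobalBaseline) != 1L || object@nGlobalBaseline < 1L)
    msg <- c(msg, "nGlobalBaseline must be >= 1")
  if (length(object@epochLayout) != 3L || any(object@epochLayout < 1L))
    msg <- c(msg, "epochLayout must be three frame counts, all >= 1")
  if (!identical(names(object@epochLayout), c("pre", "stim", "post")))
    msg <- c(msg, "epochLayout must be named pre, stim, post")
  if (length(object@stimulusLabels) < 1L ||
      anyDuplicated(object@stimulusLabels) ||
      any(!nzchar(object@stimulusLabels)))
    msg <- c(msg, "stimulusLabels must be non-empty and unique")
  if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
    msg <- c(msg, "fieldSize must be two positive lengths (µm)")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive µm/pixel value")
  # field must map onto an integer pixel grid within half-pixel rounding
  if (length(msg) == 0L) {
    grid <- object@fieldSize / object@pixelSize
    if (any(abs(grid - round(grid)) > 0.5) || any(round(grid) < 1))
      msg <- c(msg, "fieldSize must divide into an integer pixel grid")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ImagingProtocol-class
ImagingProtocol <- function(frameRate = 0.7,
                            nGlobalBaseline = 30L,
                            epochLayout = c(pre = 10L, stim = 10L, post = 10L),
                            stimulusLabels = c("30g", "100g", "brush"),
                            fieldSize = c(981.36, 981.36),
                            pixelSize = 1.92) {
  layout <- as.integer(epochLayout)
  names(layout) <- if (is.null(names(epochLayout)))
    c("pre", "stim", "post") else names(epochLayout)
  new("ImagingProtocol",
      frameRate = as.numeric(frameRate),
      nGlobalBaseline = as.integer(nGlobalBaseline),
      epochLayout = layout,
      stimulusLabels = as.character(stimulusLabels),
      fieldSize = as.numeric(fieldSize),
      pixelSize = as.numeric(pixelSize))
}

#' @rdname protocol-accessors
#' @export
setMethod("frameRate", "ImagingProtocol", function(x) x@frameRate)

#' @rdname protocol-accessors
#' @export
setMethod("stimulusLabels", "ImagingProtocol", function(x) x@stimulusLabels)

#' @rdname protocol-accessors
#' @export
setMethod("epochLayout", "ImagingProtocol", function(x) x@epochLayout)

#' @rdname protocol-accessors
#' @export
setMethod("pixelSize", "ImagingProtocol", function(x) x@pixelSize)

#' @rdname protocol-accessors
#' @export
setMethod("fieldSize", "ImagingProtocol", function(x) x@fieldSize)

#' Total number of frames in a recording
#'
#' The global baseline block plus one `pre + stim + post` epoch per stimulus.
#'
#' @param protocol An [ImagingProtocol-class].
#' @return Integer frame count.
#' @export
totalFrames <- function(protocol) {
  stopifnot(is(protocol, "ImagingProtocol"))
  protocol@nGlobalBaseline +
    length(protocol@stimulusLabels) * sum(protocol@epochLayout)
}

#' Frame indices of one stimulus epoch
#'
#' Returns the 1-based frame indices of the pre-stimulus, stimulus-application
#' and post-stimulus blocks for a given stimulus, in recording order (epochs
#' follow the global baseline, one per stimulus in `stimulusLabels` order).
#'
#' @param protocol An [ImagingProtocol-class].
#' @param stimulus Stimulus label or 1-based index.
#' @return A list with integer vectors `pre`, `stim`, `post`.
#' @export
epochIndices <- function(protocol, stimulus) {
  stopifnot(is(protocol, "ImagingProtocol"))
  if (is.character(stimulus)) {
    s <- match(stimulus, protocol@stimulusLabels)
    if (is.na(s)) stop("unknown stimulus label: ", stimulus)
  } else {
    s <- as.integer(stimulus)
    if (s < 1L || s > length(protocol@stimulusLabels))
      stop("stimulus index out of range")
  }
  lay <- protocol@epochLayout
  base <- protocol@nGlobalBaseline + (s - 1L) * sum(lay)
  list(pre  = base + seq_len(lay[["pre"]]),
       stim = base + lay[["pre"]] + seq_len(lay[["stim"]]),
       post = base + lay[["pre"]] + lay[["stim"]] + seq_len(lay[["post"]]))
}

#' Frame indices of the global force-free baseline block
#'
#' @param protocol An [ImagingProtocol-class].
#' @return Integer vector of frame indices.
#' @export
globalBaselineFrames <- function(protocol) {
  stopifnot(is(protocol, "ImagingProtocol"))
  seq_len(protocol@nGlobalBaseline)
}

#' Pixel grid implied by the protocol's field and pixel size
#'
#' @param protocol An [ImagingProtocol-class].
#' @return Integer length-2 vector of pixels (x, y).
#' @export
pixelGrid <- function(protocol) {
  stopifnot(is(protocol, "ImagingProtocol"))
  as.integer(round(protocol@fieldSize / protocol@pixelSize))
}

setMethod("show", "ImagingProtocol", function(object) {
  cat("ImagingProtocol\n")
  cat(sprintf("  frame rate       : %g Hz (%.3f s/frame)\n",
              object@frameRate, 1 / object@frameRate))
  cat(sprintf("  global baseline  : %d frames\n", object@nGlobalBaseline))
  cat(sprintf("  epoch layout     : %d pre / %d stim / %d post\n",
              object@epochLayout[["pre"]], object@epochLayout[["stim"]],
              object@epochLayout[["post"]]))
  cat(sprintf("  stimuli          : %s\n",
              paste(object@stimulusLabels, collapse = ", ")))
  cat(sprintf("  field            : %.2f x %.2f µm² @ %.2f µm/pixel\n",
              object@fieldSize[1], object@fieldSize[2], object@pixelSize))
  cat(sprintf("  total frames     : %d\n", totalFrames(object)))
})
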