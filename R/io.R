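#' Read and write imaging sessions as CSV + JSON sidecar
#'
#' `writeImagingSession()` writes `traces.csv` (one row per neuron:
#' `neuron_id`, `area_um2`, then one column per frame `f0001...`) and
#' `protocol.json` holding the acquisition protocol;
#' `readImagingSession()` reconstructs the [ImagingSession-class].
#'
#' @param session An [ImagingSession-class].
#' @param dir Directory to write to / read from (created if missing).
#' @return `readImagingSession()` returns an [ImagingSession-class];
#'   `writeImagingSession()` invisibly returns `dir`.
#' @export
writeImagingSession <- function(session, dir) {
  stopifnot(is(session, "ImagingSession"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- imagingProtocol(session)
  tr <- traces(session)
  df <- data.frame(neuron_id = rownames(tr),
                   area_um2 = unname(neuronAreas(session)),
                   tr, row.names = NULL, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("f%04d", seq_len(ncol(tr)))
  utils::write.csv(df, file.path(dir, "traces.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate = p@frameRate,
         n_global_baseline = p@nGlobalBaseline,
         epoch_layout = as.list(p@epochLayout),
         stimulus_labels = p@stimulusLabels,
         field_size = p@fieldSize,
         pixel_size = p@pixelSize),
    file.path(dir, "protocol.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeImagingSession
#' @export
readImagingSession <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "protocol.json"),
                           simplifyVector = TRUE)
  p <- ImagingProtocol(frameRate = j$frame_rate,
                       nGlobalBaseline = j$n_global_baseline,
                       epochLayout = unlist(j$epoch_layout),
                       stimulusLabels = j$stimulus_labels,
                       fieldSize = j$field_size,
                       pixelSize = j$pixel_size)
  df <- utils::read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  tr <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(tr) <- list(df$neuron_id, NULL)
  ImagingSession(tr, p, areas = df$area_um2)
}

#' Read and write marker tables as CSV
#'
#' Plain CSV with columns `animal_id`, `section_id`, `cell_id`,
#' `diameter_um` and one logical column per probe; the probe order is the
#' column order.
#'
#' @param table A [CellMarkerTable-class].
#' @param file Path to a CSV file.
#' @return `readMarkerTable()` returns a [CellMarkerTable-class].
#' @export
writeMarkerTable <- function(table, file) {
  stopifnot(is(table, "CellMarkerTable"))
  utils::write.csv(markerData(table), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMarkerTable
#' @export
readMarkerTable <- function(file) {
  d <- utils::read.csv(file)
  keys <- c("animal_id", "section_id", "cell_id", "diameter_um")
  probes <- setdiff(names(d), keys)
  for (p in probes) d[[p]] <- as.logical(d[[p]])
  CellMarkerTable(d, probes = probes)
}

#' Read and write count matrices as a MatrixMarket triplet
#'
#' Writes the 10x-style triplet `matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv`, plus `cellmeta.tsv` with the per-cell covariates from
#' the colData; `readCountMatrix()` reconstructs the
#' [SingleCellExperiment::SingleCellExperiment] losslessly.
#'
#' @param sce A [SingleCellExperiment::SingleCellExperiment] with a
#'   `counts` assay.
#' @param dir Directory to write to / read from.
#' @return `readCountMatrix()` returns a `SingleCellExperiment`.
#' @export
writeCountMatrix <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(colData(sce))
  cd <- cbind(barcode = colnames(m), cd)
  utils::write.table(cd, file.path(dir, "cellmeta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  metaPath <- file.path(dir, "cellmeta.tsv")
  cd <- if (file.exists(metaPath)) {
    md <- utils::read.table(metaPath, sep = "\t", header = TRUE)
    rownames(md) <- md$barcode
    S4Vectors::DataFrame(md[colnames(m), setdiff(names(md), "barcode"),
                            drop = FALSE])
  } else S4Vectors::DataFrame(row.names = colnames(m))
  SingleCellExperiment(assays = list(counts = m), colData = cd)
}

#' Read and write image stacks as multi-page TIFF
#'
#' `writeStack()` writes the stack as a 16-bit multi-page TIFF plus a JSON
#' sidecar recording the intensity scale (TIFF pages hold values in
#' `[0, 1]`); the ROI label image goes to a separate single-page TIFF.
#' `readStack()` reverses both. Quantization error is about 1.5e-5 of the
#' intensity range.
#'
#' @param stack Numeric 3-D array (x, y, frame).
#' @param rois Integer ROI label matrix (optional).
#' @param dir Directory to hold `stack.tif`, `rois.tif`, `stack.json`.
#' @return `readStack()` returns a list with `stack` and (if present)
#'   `rois`.
#' @export
writeStack <- function(stack, rois = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maxVal <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(t) stack[, , t] / maxVal)
  tiff::writeTIFF(pages, file.path(dir, "stack.tif"), bits.per.sample = 16)
  jsonlite::write_json(list(max_value = maxVal, n_frames = dim(stack)[3]),
                       file.path(dir, "stack.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(rois)) {
    if (max(rois) > 65535L) stop("too many ROI labels for 16-bit TIFF")
    tiff::writeTIFF(rois / 65535, file.path(dir, "rois.tif"),
                    bits.per.sample = 16)
  }
  invisible(dir)
}

#' @rdname writeStack
#' @export
readStack <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "stack.json"),
                           simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "stack.tif"), all = TRUE)
  stack <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) *
    j$max_value
  out <- list(stack = stack)
  roiPath <- file.path(dir, "rois.tif")
  if (file.exists(roiPath)) {
    r <- tiff::readTIFF(roiPath)
    out$rois <- matrix(as.integer(round(r * 65535)), nrow(r), ncol(r))
  }
  out
}
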