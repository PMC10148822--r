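#' Nested per-cell marker positivity table
#'
#' One row per outlined cell from a multiplexed in-situ hybridization
#' section: animal and section identifiers, the cell's diameter (µm) and a
#' logical positivity column per probe. The probe column order defines the
#' combination lattice used by [classifyCombinations()].
#'
#' @param data A data.frame with columns `animal_id`, `section_id`,
#'   `cell_id`, `diameter_um` and one logical column per probe.
#' @param probes Ordered character vector of probe column names; defaults to
#'   every logical column after the key columns.
#' @param x A `CellMarkerTable`.
#'
#' @return `CellMarkerTable()` returns the validated object; `markerData()`
#'   the underlying data.frame; `probeNames()` the ordered probe names.
#' @examples
#' df <- data.frame(animal_id = "m1", section_id = 1, cell_id = 1:3,
#'                  diameter_um = c(18, 25, 31),
#'                  Scn10a = c(TRUE, TRUE, FALSE),
#'                  Piezo2 = c(TRUE, FALSE, TRUE))
#' mt <- CellMarkerTable(df)
#' probeNames(mt)
#' @aliases CellMarkerTable
#' @export CellMarkerTable
#' @exportClass CellMarkerTable
setClass("CellMarkerTable",
  representation(cells = "data.frame", probeNames = "character"))

setValidity("CellMarkerTable", function(object) {
  msg <- character()
  d <- object@cells
  need <- c("animal_id", "section_id", "cell_id", "diameter_um")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (!all(object@probeNames %in% names(d)))
    msg <- c(msg, "probe columns missing from the table")
  else if (!all(vapply(d[object@probeNames], is.logical, logical(1))))
    msg <- c(msg, "probe columns must be logical")
  if (length(object@probeNames) < 1L)
    msg <- c(msg, "at least one probe is required")
  if (nrow(d)) {
    if (any(!is.finite(d$diameter_um)) || any(d$diameter_um <= 0))
      msg <- c(msg, "diameters must be positive")
    key <- paste(d$animal_id, d$section_id, d$cell_id, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "(animal, section, cell) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CellMarkerTable-class
CellMarkerTable <- function(data, probes = NULL) {
  data <- as.data.frame(data)
  if (is.null(probes)) {
    keys <- c("animal_id", "section_id", "cell_id", "diameter_um")
    probes <- names(data)[vapply(data, is.logical, logical(1)) &
                          !names(data) %in% keys]
  }
  new("CellMarkerTable", cells = data, probeNames = as.character(probes))
}

#' @rdname CellMarkerTable-class
#' @export
setMethod("markerData", "CellMarkerTable", function(x) x@cells)

#' @rdname CellMarkerTable-class
#' @export
setMethod("probeNames", "CellMarkerTable", function(x) x@probeNames)

setMethod("show", "CellMarkerTable", function(object) {
  d <- object@cells
  cat(sprintf("CellMarkerTable: %d cells, %d animals, probes: %s\n",
              nrow(d), length(unique(d$animal_id)),
              paste(object@probeNames, collapse = ", ")))
})
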