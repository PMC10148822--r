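#' Count marker-positivity combinations over the full lattice
#'
#' Assigns every cell to exactly one of the 2^k positivity combinations of
#' the ordered probe list (the all-negative combination included) and
#' reports raw counts and percent-of-whole over all counted cells. The
#' combinations partition the cell set, so counts sum to the number of
#' cells and percents to 100.
#'
#' @param table A [CellMarkerTable-class].
#' @param probes Ordered probe names; defaults to `probeNames(table)`.
#' @return data.frame with `combination`, `count`, `percent`, one row per
#'   lattice combination in [combinationLattice()] order.
#' @examples
#' df <- data.frame(animal_id = "m1", section_id = 1, cell_id = 1:4,
#'                  diameter_um = 20,
#'                  A = c(TRUE, TRUE, FALSE, TRUE),
#'                  B = c(TRUE, FALSE, FALSE, TRUE))
#' classifyCombinations(CellMarkerTable(df))
#' @export
classifyCombinations <- function(table, probes = probeNames(table)) {
  stopifnot(is(table, "CellMarkerTable"))
  d <- markerData(table)
  missing <- setdiff(probes, names(d))
  if (length(missing))
    stop("unknown probe name(s): ", paste(missing, collapse = ", "))
  labs <- names(combinationLattice(probes))
  lab <- combinationLabelsOf(d, probes)
  counts <- base::table(factor(lab, levels = labs))
  data.frame(combination = labs, count = as.integer(counts),
             percent = if (nrow(d)) 100 * as.integer(counts) / nrow(d)
                       else rep(NA_real_, length(labs)),
             row.names = NULL)
}

# combination label of each row of a marker data.frame
combinationLabelsOf <- function(d, probes) {
  pos <- as.matrix(d[probes])
  apply(pos, 1, function(r) paste0(probes, ifelse(r, "+", "-"), collapse = ""))
}

#' Nested aggregation of combination percentages
#'
#' Percent-of-whole per combination is computed within each unit, then
#' averaged up the nesting: with `level = "animal"` (the default design:
#' several sections per animal are quantified and averaged) percentages are
#' computed per section, averaged within animal, and the mean ± SEM is
#' taken across animals; with `level = "section"` sections are the units.
#' SEM uses the sample SD over sqrt(n units) and is missing (NA) for a
#' single unit, never 0.
#'
#' @param table A [CellMarkerTable-class].
#' @param probes Ordered probe names; defaults to `probeNames(table)`.
#' @param level `"animal"` (sections averaged within animal first) or
#'   `"section"`.
#' @return A list with `perUnit` (unit x combination percent matrix as a
#'   long data.frame) and `summary` (per combination: `mean_percent`,
#'   `sem_percent`, `n_units`).
#' @export
aggregateNested <- function(table, probes = probeNames(table),
                            level = c("animal", "section")) {
  level <- match.arg(level)
  stopifnot(is(table, "CellMarkerTable"))
  d <- markerData(table)
  if (nrow(d) == 0L) stop("marker table has no cells")
  labs <- names(combinationLattice(probes))
  lab <- combinationLabelsOf(d, probes)
  secKey <- paste(d$animal_id, d$section_id, sep = "||")

  pctBy <- function(key) {
    tab <- base::table(factor(key, levels = unique(key)),
                 factor(lab, levels = labs))
    sweep(unclass(tab), 1, rowSums(tab), "/") * 100
  }
  secPct <- pctBy(secKey)
  if (any(rowSums(is.nan(secPct)) > 0))
    stop("a section has zero counted cells")

  if (level == "animal") {
    animalOf <- sub("\\|\\|.*$", "", rownames(secPct))
    unitPct <- rowsum(secPct, animalOf) /
      as.vector(base::table(factor(animalOf, levels = unique(animalOf))))
  } else {
    unitPct <- secPct
  }
  perUnit <- data.frame(
    unit = rep(rownames(unitPct), times = ncol(unitPct)),
    combination = rep(colnames(unitPct), each = nrow(unitPct)),
    percent = as.vector(unitPct), row.names = NULL)
  summ <- data.frame(
    combination = colnames(unitPct),
    mean_percent = colMeans(unitPct),
    sem_percent = apply(unitPct, 2, semOf),
    n_units = nrow(unitPct), row.names = NULL)
  list(perUnit = perUnit, summary = summ)
}

#' Diameter distributions per cell subset with pairwise KS comparison
#'
#' Builds the relative frequency distribution of cell diameters for each
#' requested subset of the marker table and compares every pair of subsets
#' with the two-sample two-tailed Kolmogorov–Smirnov test (statistic
#' `D = sup |ECDF1 - ECDF2|`, asymptotic p-value).
#'
#' @param table A [CellMarkerTable-class].
#' @param subsets Named list of subset definitions; each is a named logical
#'   vector of required probe states, e.g.
#'   `list("Scn10a+Piezo2+" = c(Scn10a = TRUE, Piezo2 = TRUE))`. Probes not
#'   mentioned are unconstrained.
#' @param binEdges Histogram bin edges in µm (default 2.5-µm bins, 0–60).
#' @return A list with `histograms` (long data.frame: subset, bin bounds,
#'   count, freq), `diameters` (list of per-subset diameter vectors) and
#'   `ks` (data.frame: subset1, subset2, D, p_value).
#' @export
diameterDistributions <- function(table, subsets,
                                  binEdges = seq(0, 60, by = 2.5)) {
  stopifnot(is(table, "CellMarkerTable"), length(subsets) >= 1L,
            !is.null(names(subsets)))
  d <- markerData(table)
  diams <- lapply(subsets, function(req) {
    bad <- setdiff(names(req), probeNames(table))
    if (length(bad)) stop("unknown probe(s): ", paste(bad, collapse = ", "))
    keep <- rep(TRUE, nrow(d))
    for (p in names(req)) keep <- keep & (d[[p]] == req[[p]])
    d$diameter_um[keep]
  })
  empty <- names(diams)[vapply(diams, length, 1L) == 0L]
  if (length(empty))
    stop("empty subset(s): ", paste(empty, collapse = ", "))
  hist <- do.call(rbind, c(lapply(names(diams), function(nm)
    cbind(subset = nm,
          areaHistogram(diams[[nm]], binEdges = binEdges))),
    list(make.row.names = FALSE)))
  ks <- NULL
  nms <- names(diams)
  if (length(nms) >= 2L) {
    pairs <- utils::combn(nms, 2)
    ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- diams[[pairs[1, j]]]; b <- diams[[pairs[2, j]]]
      if (length(a) < 2L || length(b) < 2L)
        stop("subsets need >= 2 cells for the KS test")
      kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                            exact = FALSE))
      data.frame(subset1 = pairs[1, j], subset2 = pairs[2, j],
                 D = unname(kt$statistic), p_value = kt$p.value,
                 row.names = NULL)
    }))
  }
  list(histograms = hist, diameters = diams, ks = ks)
}
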