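#' Combination labels over a probe lattice
#'
#' Enumerates the full 2^k positivity lattice for k probes, in a fixed
#' order: the first probe toggles slowest. Labels look like
#' `"Scn10a+Piezo2+Ntrk1-"`; the all-negative combination is included.
#'
#' @param probes Ordered character vector of probe names.
#' @return Named list mapping each label to its logical positivity vector.
#' @examples
#' names(combinationLattice(c("Scn10a", "Piezo2")))
#' @export
combinationLattice <- function(probes) {
  k <- length(probes)
  if (k < 1L) stop("at least one probe is required")
  # expand.grid toggles its first column fastest; reverse so the first
  # probe toggles slowest and the all-positive combination comes first
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), k))[, k:1, drop = FALSE]
  names(grid) <- probes
  labs <- apply(grid, 1, function(r)
    paste0(probes, ifelse(r, "+", "-"), collapse = ""))
  out <- lapply(seq_len(nrow(grid)), function(i)
    setNames(as.logical(grid[i, ]), probes))
  names(out) <- labs
  out
}

#' Simulate a nested RNAscope-style per-cell marker table
#'
#' Draws cells for a nested animal → section → cell design: each animal
#' contributes a number of quantified sections (uniform over
#' `sectionsPerAnimal`, default 2–4 as in typical section-sampling designs),
#' each section `cellsPerSection` outlined cells. Every cell is assigned one
#' combination of the probe-positivity lattice with the configured
#' probabilities (which must sum to 1 over the full lattice, all-negative
#' included), and a lognormal diameter, optionally combination-specific.
#'
#' @param nAnimals Number of animals.
#' @param sectionsPerAnimal Integer range (length 1 or 2) of sections per
#'   animal; default `c(2, 4)`.
#' @param cellsPerSection Cells outlined per section.
#' @param probes Ordered probe names.
#' @param combinationProbs Named numeric vector of probabilities over the
#'   lattice labels of [combinationLattice()] (missing labels get 0); must
#'   sum to 1 within 1e-8.
#' @param diameterMeanlog,diameterSdlog Default lognormal diameter (µm)
#'   parameters; overridable per combination via `diameterParams`, a named
#'   list of `c(meanlog, sdlog)`.
#' @param diameterParams Optional per-combination overrides.
#' @param seed Integer RNG seed.
#' @return A [CellMarkerTable-class].
#' @examples
#' lat <- names(combinationLattice(c("Scn10a", "Piezo2")))
#' pr <- setNames(c(0.38, 0.12, 0.25, 0.25), lat)
#' mt <- simulateMarkerTable(3, cellsPerSection = 50,
#'                           probes = c("Scn10a", "Piezo2"),
#'                           combinationProbs = pr, seed = 1)
#' @export
simulateMarkerTable <- function(nAnimals,
                                sectionsPerAnimal = c(2, 4),
                                cellsPerSection = 200,
                                probes = c("Scn10a", "Piezo2", "Ntrk1"),
                                combinationProbs,
                                diameterMeanlog = log(22),
                                diameterSdlog = 0.30,
                                diameterParams = NULL,
                                seed = 1L) {
  lat <- combinationLattice(probes)
  labs <- names(lat)
  pr <- setNames(rep(0, length(labs)), labs)
  unknown <- setdiff(names(combinationProbs), labs)
  if (length(unknown))
    stop("unknown combination label(s): ", paste(unknown, collapse = ", "))
  pr[names(combinationProbs)] <- combinationProbs
  if (abs(sum(pr) - 1) > 1e-8)
    stop("combination probabilities must sum to 1 over the full lattice")
  if (any(pr < 0)) stop("probabilities must be non-negative")
  if (length(sectionsPerAnimal) == 1L)
    sectionsPerAnimal <- rep(sectionsPerAnimal, 2)

  set.seed(as.integer(seed))
  rows <- list()
  for (a in seq_len(nAnimals)) {
    secRange <- seq(sectionsPerAnimal[1], sectionsPerAnimal[2])
    nsec <- if (length(secRange) == 1L) secRange else sample(secRange, 1L)
    for (s in seq_len(nsec)) {
      combo <- sample(labs, cellsPerSection, replace = TRUE, prob = pr)
      pars <- vapply(combo, function(cl) {
        p <- diameterParams[[cl]]
        if (is.null(p)) c(diameterMeanlog, diameterSdlog) else p
      }, numeric(2))
      diam <- rlnorm(cellsPerSection, pars[1, ], pars[2, ])
      pos <- do.call(rbind, lapply(combo, function(cl) lat[[cl]]))
      df <- data.frame(animal_id = sprintf("animal%02d", a),
                       section_id = sprintf("sec%d", s),
                       cell_id = seq_len(cellsPerSection),
                       diameter_um = diam, row.names = NULL)
      rows[[length(rows) + 1L]] <- cbind(df, as.data.frame(pos))
    }
  }
  CellMarkerTable(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                  probes = probes)
}
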