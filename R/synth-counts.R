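#' Simulate a sparse gene x cell count matrix with QC structure
#'
#' Builds a 10x-style sparse integer count matrix whose cells are
#' constructed either to pass or to fail the standard single-cell QC filter
#' (more than `minFeatures` detected genes AND mitochondrial percentage
#' below `maxMitoPercent`). Failing cells are split between a low-feature
#' mode (20 to `minFeatures` detected genes) and a high-mitochondrial mode
#' (mito fraction 1.5x to 4x the limit); passing cells detect
#' `minFeatures+100` up to `maxFeaturesPass` genes with mito percentage
#' between 0 and two thirds of the limit. Ground truth (`qc_pass` and the
#' failure mode) is stored in the column metadata, so downstream filtering
#' can be checked cell for cell.
#'
#' Marker genes are spiked into passing cells: each configured gene gets a
#' positive count (2–20 UMIs) in an independent Bernoulli draw per cell with
#' the given probability, and is guaranteed zero otherwise — the realized
#' expressing-cell sets are exact ground truth for threshold co-expression.
#'
#' Mitochondrial genes are named with `mitoPrefix` (`mt-1`, `mt-2`, ...).
#'
#' @param nGenes Total genes (includes `nMitoGenes` mito genes and the
#'   marker genes).
#' @param nCells Total cells.
#' @param failFraction Fraction of cells constructed to fail QC.
#' @param markerProbs Named numeric vector: expression probability per
#'   marker gene among QC-passing cells (e.g.
#'   `c(Scn10a = 0.6, Piezo2 = 0.5, Ntrk1 = 0.4)`).
#' @param minFeatures,maxMitoPercent QC thresholds the construction targets.
#' @param maxFeaturesPass Upper bound on detected genes for passing cells.
#' @param meanCount Mean UMI count per detected gene.
#' @param nMitoGenes Number of mitochondrial genes.
#' @param mitoPrefix Gene-name prefix marking mitochondrial genes.
#' @param seed Integer RNG seed.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay and colData columns `qc_pass`, `fail_mode` and
#'   `marker_<gene>` ground-truth flags.
#' @examples
#' sce <- simulateCountMatrix(nGenes = 500, nCells = 100, failFraction = 0.2,
#'                            markerProbs = c(Scn10a = 0.5), seed = 1)
#' table(SummarizedExperiment::colData(sce)$qc_pass)
#' @export
#' @importFrom Matrix sparseMatrix colSums rowSums t readMM writeMM
#' @importFrom SingleCellExperiment SingleCellExperiment
simulateCountMatrix <- function(nGenes = 2000,
                                nCells = 500,
                                failFraction = 0.2,
                                markerProbs = c(Scn10a = 0.6, Piezo2 = 0.5,
                                                Ntrk1 = 0.4),
                                minFeatures = 200,
                                maxMitoPercent = 15,
                                maxFeaturesPass = 1000,
                                meanCount = 3,
                                nMitoGenes = 13,
                                mitoPrefix = "mt-",
                                seed = 1L) {
  nGenes <- as.integer(nGenes); nCells <- as.integer(nCells)
  if (nGenes <= 0L || nCells <= 0L) stop("nGenes and nCells must be positive")
  markers <- names(markerProbs)
  if (nGenes < nMitoGenes + length(markers) + maxFeaturesPass)
    stop("nGenes too small for the requested structure")
  genes <- c(paste0(mitoPrefix, seq_len(nMitoGenes)), markers,
             sprintf("gene%05d", seq_len(nGenes - nMitoGenes - length(markers))))
  mitoIdx <- seq_len(nMitoGenes)
  markerIdx <- setNames(nMitoGenes + seq_along(markers), markers)
  bodyIdx <- setdiff(seq_len(nGenes), c(mitoIdx, markerIdx))

  set.seed(as.integer(seed))
  nFail <- as.integer(round(failFraction * nCells))
  qcPass <- rep(TRUE, nCells)
  if (nFail > 0) qcPass[sample.int(nCells, nFail)] <- FALSE
  failMode <- rep(NA_character_, nCells)
  failMode[!qcPass] <- sample(c("low_features", "high_mito"),
                              sum(!qcPass), replace = TRUE)

  ii <- list(); jj <- list(); xx <- list()
  markerTruth <- matrix(FALSE, nCells, length(markers),
                        dimnames = list(NULL, markers))
  for (c in seq_len(nCells)) {
    if (qcPass[c]) {
      nf <- sample(seq(minFeatures + 100, maxFeaturesPass), 1L)
      mitoTarget <- runif(1, 0, maxMitoPercent * 2 / 3) / 100
    } else if (failMode[c] == "low_features") {
      # detected mito genes count toward n_features, so leave room for them;
      # total detected stays <= minFeatures and the strict > filter fails
      nf <- sample(seq(20, minFeatures - nMitoGenes), 1L)
      mitoTarget <- runif(1, 0, maxMitoPercent * 2 / 3) / 100
    } else {
      nf <- sample(seq(minFeatures + 100, maxFeaturesPass), 1L)
      mitoTarget <- runif(1, min(1.5 * maxMitoPercent, 90),
                          min(4 * maxMitoPercent, 95)) / 100
    }
    gsel <- sample(bodyIdx, nf)
    cnt <- rpois(nf, meanCount - 1) + 1L
    if (qcPass[c] && length(markers)) {
      on <- runif(length(markers)) < markerProbs
      markerTruth[c, ] <- on
      if (any(on)) {
        gsel <- c(gsel, markerIdx[on])
        cnt <- c(cnt, sample(2:20, sum(on), replace = TRUE))
      }
    }
    # allocate mito counts to hit the target fraction of the final total:
    # m / (m + body) = f  =>  m = f * body / (1 - f)
    mcnt <- as.integer(round(mitoTarget * sum(cnt) / (1 - mitoTarget)))
    if (mcnt > 0) {
      nm <- min(nMitoGenes, mcnt)
      alloc <- tabulate(sample.int(nm, mcnt, replace = TRUE), nbins = nm)
      gsel <- c(gsel, mitoIdx[seq_len(nm)][alloc > 0])
      cnt <- c(cnt, alloc[alloc > 0])
    }
    ii[[c]] <- gsel; jj[[c]] <- rep(c, length(gsel)); xx[[c]] <- cnt
  }
  m <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                    dims = c(nGenes, nCells),
                    dimnames = list(genes,
                                    sprintf("cell%05d", seq_len(nCells))))
  cd <- DataFrame(qc_pass = qcPass, fail_mode = failMode,
                  row.names = colnames(m))
  for (g in markers) cd[[paste0("marker_", g)]] <- markerTruth[, g]
  sce <- SingleCellExperiment(assays = list(counts = m), colData = cd)
  perCellQCMetrics(sce, mitoPrefix = mitoPrefix)
}
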