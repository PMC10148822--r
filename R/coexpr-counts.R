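#' Recompute per-cell QC covariates from a count matrix
#'
#' Stores (or refreshes) `n_features` — the number of genes with count > 0
#' per cell — and `percent_mito` — 100 x mitochondrial counts / total
#' counts, mitochondrial genes being those whose name starts with
#' `mitoPrefix` — in the colData. These are always derived from the matrix,
#' so stored values can never drift from the counts.
#'
#' @param sce A [SingleCellExperiment::SingleCellExperiment] with a
#'   `counts` assay.
#' @param mitoPrefix Gene-name prefix marking mitochondrial genes
#'   (default `"mt-"`).
#' @return The object with updated `colData` columns `n_features` and
#'   `percent_mito`.
#' @export
#' @importFrom SummarizedExperiment colData colData<-
perCellQCMetrics <- function(sce, mitoPrefix = "mt-") {
  m <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) warning("cell(s) with zero total counts")
  mito <- startsWith(rownames(m), mitoPrefix)
  colData(sce)$n_features <- Matrix::colSums(m > 0)
  colData(sce)$percent_mito <- ifelse(tot > 0,
                                      100 * Matrix::colSums(m[mito, ,
                                                              drop = FALSE]) / tot,
                                      NA_real_)
  sce
}

#' Filter cells on feature count and mitochondrial percentage
#'
#' Retains cells with strictly more than `minFeatures` detected genes AND a
#' mitochondrial percentage strictly below `maxMitoPercent` (defaults
#' 200 and 15). Both covariates are recomputed from the matrix before
#' filtering; the gene set and cell order are preserved. The operation is
#' idempotent. An empty result is permitted (with a warning).
#'
#' @inheritParams perCellQCMetrics
#' @param minFeatures Detected-gene threshold (strict `>`).
#' @param maxMitoPercent Mitochondrial percentage limit (strict `<`).
#' @return The column-subsetted object.
#' @examples
#' sce <- simulateCountMatrix(nGenes = 1300, nCells = 50, failFraction = 0.3,
#'                            seed = 1)
#' ncol(qcFilter(sce))
#' @export
qcFilter <- function(sce, minFeatures = 200, maxMitoPercent = 15,
                     mitoPrefix = "mt-") {
  sce <- perCellQCMetrics(sce, mitoPrefix = mitoPrefix)
  keep <- colData(sce)$n_features > minFeatures &
    !is.na(colData(sce)$percent_mito) &
    colData(sce)$percent_mito < maxMitoPercent
  if (!any(keep)) warning("QC filter removed every cell")
  sce[, keep]
}

#' Log-normalize a count matrix
#'
#' Per cell, counts are scaled to a common library size and log-transformed:
#' `value = ln(1 + scaleFactor * count / cellTotal)` (defaults: scale
#' 10,000, natural log — the convention of standard single-cell toolchains).
#' The result is stored as the `logcounts` assay.
#'
#' @inheritParams perCellQCMetrics
#' @param scaleFactor Library-size scale (default 1e4).
#' @return The object with a dense-or-sparse `logcounts` assay added.
#' @export
logNormalizeCounts <- function(sce, scaleFactor = 1e4) {
  m <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) stop("cell(s) with zero total counts cannot be normalized")
  if (is(m, "sparseMatrix")) {
    ln <- as(m, "CsparseMatrix")
    ln@x <- log1p(scaleFactor * ln@x / rep.int(tot, diff(ln@p)))
  } else {
    ln <- log1p(scaleFactor * sweep(as.matrix(m), 2, tot, "/"))
  }
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  sce
}

#' Threshold co-expression counts and fractions
#'
#' A cell "expresses" a gene when its (normalized) expression value is
#' strictly greater than `threshold` (default 0.1). Returns the count and
#' fraction of cells expressing every listed gene, optionally restricted to
#' the cells expressing a conditioning gene — e.g. the fraction of
#' Scn10a-positive cells co-expressing Piezo2 and Ntrk1.
#'
#' @inheritParams perCellQCMetrics
#' @param genes Character vector of genes that must all be expressed.
#' @param threshold Expression threshold (strict `>`).
#' @param conditionOn Optional conditioning gene: the denominator becomes
#'   the cells expressing it.
#' @param assayName Assay holding expression values; `"logcounts"`
#'   (default, from [logNormalizeCounts()]) or `"counts"` for raw-count
#'   thresholding.
#' @return A list: `n_expressing`, `n_total` (denominator), `fraction`,
#'   `percent`.
#' @export
thresholdCoexpression <- function(sce, genes, threshold = 0.1,
                                  conditionOn = NULL,
                                  assayName = "logcounts") {
  m <- SummarizedExperiment::assay(sce, assayName)
  missing <- setdiff(c(genes, conditionOn), rownames(m))
  if (length(missing))
    stop("gene(s) absent from the matrix: ", paste(missing, collapse = ", "))
  expr <- function(g) as.vector(m[g, ] > threshold)
  denom <- if (is.null(conditionOn)) rep(TRUE, ncol(m)) else expr(conditionOn)
  hit <- denom
  for (g in genes) hit <- hit & expr(g)
  nTot <- sum(denom)
  nExp <- sum(hit)
  list(n_expressing = nExp, n_total = nTot,
       fraction = if (nTot > 0) nExp / nTot else NA_real_,
       percent = if (nTot > 0) 100 * nExp / nTot else NA_real_)
}
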