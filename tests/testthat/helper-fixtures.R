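# shared fixtures and independent oracles, built in code

# small protocol: quick to simulate, same layout logic as the default
smallProtocol <- function(stimuli = c("30g", "100g"),
                          field = c(96, 96), px = 1.92) {
  ImagingProtocol(stimulusLabels = stimuli, fieldSize = field, pixelSize = px)
}

# hand-built marker table with known combination membership
toyMarkerTable <- function() {
  df <- data.frame(
    animal_id = rep(c("m1", "m2"), each = 6),
    section_id = rep(c("s1", "s2", "s1", "s2"), each = 3),
    cell_id = rep(1:3, 4),
    diameter_um = c(12, 18, 25, 30, 14, 22, 19, 27, 33, 11, 16, 40),
    Scn10a = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
               TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    Piezo2 = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
               TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    Ntrk1  = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
               TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  CellMarkerTable(df, probes = c("Scn10a", "Piezo2", "Ntrk1"))
}

# independent trapezoid: plain loop over segments
oracleTrapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  s
}

# independent two-sample KS statistic: scan every observed value
oracleKS <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(p) abs(mean(a <= p) - mean(b <= p)), numeric(1)))
}

# independent histogram: count per [lo, hi) with open end bins
oracleHist <- function(x, edges) {
  lo <- c(-Inf, edges[-length(edges)], edges[length(edges)])
  hi <- c(edges[1], edges[-1], Inf)
  counts <- vapply(seq_along(lo), function(i)
    sum(x >= lo[i] & x < hi[i]), integer(1))
  counts
}
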