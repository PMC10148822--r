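test_that("noiseless generation matches its own construction", {
  p <- smallProtocol()
  # no signal, no noise: constant traces at baseline fluorescence
  sim <- simulateImagingSession(10, p, responderProb = 0, noiseSD = 0,
                                seed = 1)
  f <- traces(sim$session)
  expect_equal(f, matrix(sim$truth$neurons$baseline_f, 10, totalFrames(p),
                         dimnames = dimnames(f)))
  # one responder with known amplitude: max = (1 + amplitude) * baseline
  sim <- simulateImagingSession(1, p, responderProb = c(`30g` = 1, `100g` = 0),
                                amplitudeMeanlog = log(0.5),
                                amplitudeSdlog = 0, noiseSD = 0, seed = 1)
  b <- sim$truth$neurons$baseline_f
  expect_equal(max(traces(sim$session)), 1.5 * b, tolerance = 1e-12)
  # transient confined to its own epoch
  w2 <- epochIndices(p, "100g")
  expect_equal(unique(as.vector(traces(sim$session)[, c(w2$pre, w2$stim)])), b)
})

test_that("generators are pure functions of (config, seed)", {
  p <- smallProtocol()
  a <- simulateImagingSession(30, p, responderProb = 0.3, seed = 7)
  b <- simulateImagingSession(30, p, responderProb = 0.3, seed = 7)
  expect_identical(traces(a$session), traces(b$session))
  expect_identical(a$truth, b$truth)
  c <- simulateImagingSession(30, p, responderProb = 0.3, seed = 8)
  expect_false(identical(traces(a$session), traces(c$session)))

  lat <- names(combinationLattice(c("Scn10a", "Piezo2")))
  pr <- setNames(c(0.3, 0.2, 0.1, 0.4), lat)
  m1 <- simulateMarkerTable(3, cellsPerSection = 40,
                            probes = c("Scn10a", "Piezo2"),
                            combinationProbs = pr, seed = 5)
  m2 <- simulateMarkerTable(3, cellsPerSection = 40,
                            probes = c("Scn10a", "Piezo2"),
                            combinationProbs = pr, seed = 5)
  expect_identical(markerData(m1), markerData(m2))

  s1 <- simulateCountMatrix(nGenes = 1300, nCells = 60, seed = 3)
  s2 <- simulateCountMatrix(nGenes = 1300, nCells = 60, seed = 3)
  expect_identical(SummarizedExperiment::assay(s1), SummarizedExperiment::assay(s2))

  t1 <- simulateTimeCourse(4, 0:3, list(g = c(0, 1, 2, 1)),
                           subjectSD = 1, noiseSD = 1, seed = 2)
  t2 <- simulateTimeCourse(4, 0:3, list(g = c(0, 1, 2, 1)),
                           subjectSD = 1, noiseSD = 1, seed = 2)
  expect_identical(t1, t2)
})

test_that("marker table sampling matches the configured lattice probabilities", {
  probes <- c("Scn10a", "Piezo2", "Ntrk1")
  lat <- names(combinationLattice(probes))
  pr <- setNames(rep(0, 8), lat)
  pr["Scn10a+Piezo2+Ntrk1+"] <- 0.16
  pr["Scn10a+Piezo2+Ntrk1-"] <- 0.22
  pr["Scn10a-Piezo2-Ntrk1-"] <- 0.62
  # degenerate: all mass on triple-positive
  mtAll <- simulateMarkerTable(2, cellsPerSection = 30, probes = probes,
                               combinationProbs = c("Scn10a+Piezo2+Ntrk1+" = 1),
                               seed = 1)
  expect_true(all(as.matrix(markerData(mtAll)[probes])))
  # degenerate: all mass on all-negative
  mtNone <- simulateMarkerTable(2, cellsPerSection = 30, probes = probes,
                                combinationProbs = c("Scn10a-Piezo2-Ntrk1-" = 1),
                                seed = 1)
  expect_false(any(as.matrix(markerData(mtNone)[probes])))
  # 10,000 cells: empirical triple fraction within 3 binomial SDs of 0.16
  mt <- simulateMarkerTable(5, sectionsPerAnimal = 2, cellsPerSection = 1000,
                            probes = probes, combinationProbs = pr, seed = 11)
  n <- nrow(markerData(mt))
  expect_equal(n, 10000L)
  triple <- classifyCombinations(mt)
  frac <- triple$count[triple$combination == "Scn10a+Piezo2+Ntrk1+"] / n
  expect_lt(abs(frac - 0.16), 3 * sqrt(0.16 * 0.84 / n))
  # probabilities must cover the lattice
  expect_error(simulateMarkerTable(1, combinationProbs = c("Scn10a+Piezo2+Ntrk1+" = 0.5)),
               "sum to 1")
  expect_error(simulateMarkerTable(1, combinationProbs = c(nonsense = 1)),
               "unknown combination")
})

test_that("count matrix construction controls the QC outcome cell by cell", {
  # no failures: the filter keeps everything
  sceAll <- simulateCountMatrix(nGenes = 1300, nCells = 50, failFraction = 0,
                                seed = 2)
  expect_equal(ncol(qcFilter(sceAll)), 50L)
  # all failures: nothing survives
  sceNone <- simulateCountMatrix(nGenes = 1300, nCells = 30, failFraction = 1,
                                 seed = 2)
  expect_warning(f0 <- qcFilter(sceNone), "every cell")
  expect_equal(ncol(f0), 0L)
  # 1000 cells with 200 built to fail: exactly the other 800 retained
  sce <- simulateCountMatrix(nGenes = 1300, nCells = 1000, failFraction = 0.2,
                             seed = 9)
  truthPass <- colnames(sce)[SummarizedExperiment::colData(sce)$qc_pass]
  expect_length(truthPass, 800L)
  expect_identical(colnames(qcFilter(sce)), truthPass)
  expect_error(simulateCountMatrix(nGenes = 0, nCells = 10), "positive")
})

test_that("time-course generator honours trajectories and noise settings", {
  flat <- simulateTimeCourse(3, c(0, 2, 4), list(ctl = c(450, 450, 450)),
                             seed = 1)
  expect_true(all(flat$value == 450))
  expect_equal(nrow(flat), 9L)
  expect_error(simulateTimeCourse(3, 5, list(g = 1)), "2 timepoints")
  # zero group effect: mean difference within 3 SEs of 0, across many seeds
  diffs <- vapply(1:50, function(s) {
    tc <- simulateTimeCourse(6, c(0, 1),
                             groupMeans = list(a = c(0, 0), b = c(0, 0)),
                             subjectSD = 0.5, noiseSD = 0.5, seed = s)
    last <- tc[tc$time == 1, ]
    mean(last$value[last$group == "a"]) - mean(last$value[last$group == "b"])
  }, numeric(1))
  se <- sqrt(2 * (0.5^2 + 0.5^2) / 6) / sqrt(50)
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("rendered stacks conserve the generating traces and areas", {
  p <- smallProtocol("30g", field = c(192, 192))
  sim <- simulateImagingSession(8, p, responderProb = 0.5, noiseSD = 0,
                                areaMeanlog = log(150), areaSdlog = 0.2,
                                outputMode = "stack", forbidOverlap = TRUE,
                                seed = 3)
  ex <- extractTraces(sim$stack, sim$rois, pixelSize = pixelSize(p))
  tr <- traces(sim$session)
  expect_lt(max(abs(ex$traces[rownames(tr), ] - tr) / tr), 0.01)
  expect_equal(ex$areas[rownames(tr)], neuronAreas(sim$session))
  # labels partition: every neuron has an ROI
  expect_setequal(unique(as.vector(sim$rois[sim$rois > 0])), 1:8)
})
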