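test_that("combination counts match manual enumeration on a toy table", {
  mt <- toyMarkerTable()
  cc <- classifyCombinations(mt)
  # hand enumeration of the 12 fixture cells
  want <- c("Scn10a+Piezo2+Ntrk1+" = 2L, "Scn10a+Piezo2+Ntrk1-" = 2L,
            "Scn10a+Piezo2-Ntrk1+" = 2L, "Scn10a+Piezo2-Ntrk1-" = 2L,
            "Scn10a-Piezo2+Ntrk1+" = 0L, "Scn10a-Piezo2+Ntrk1-" = 2L,
            "Scn10a-Piezo2-Ntrk1+" = 1L, "Scn10a-Piezo2-Ntrk1-" = 1L)
  expect_equal(setNames(cc$count, cc$combination), want)
  expect_equal(sum(cc$count), 12L)           # lattice partitions the cells
  expect_equal(sum(cc$percent), 100)
  expect_error(classifyCombinations(mt, probes = c("Scn10a", "Trpv1")),
               "unknown probe")
})

test_that("an all-negative probe empties every combination containing it", {
  d <- markerData(toyMarkerTable())
  d$Piezo2 <- FALSE
  cc <- classifyCombinations(CellMarkerTable(d))
  hasPiezo <- grepl("Piezo2\\+", cc$combination)
  expect_true(all(cc$count[hasPiezo] == 0L))
})

test_that("adding a required probe never increases a combination's support", {
  set.seed(3)
  lat <- names(combinationLattice(c("A", "B", "C")))
  for (i in 1:10) {
    pr <- runif(8); pr <- setNames(pr / sum(pr), lat)
    mt <- simulateMarkerTable(2, cellsPerSection = 100, probes = c("A", "B", "C"),
                              combinationProbs = pr, seed = i)
    d <- markerData(mt)
    nA <- sum(d$A)
    nAB <- sum(d$A & d$B)
    nABC <- sum(d$A & d$B & d$C)
    expect_true(nA >= nAB && nAB >= nABC)
    expect_equal(sum(classifyCombinations(mt)$count), nrow(d))
  }
})

test_that("nested aggregation averages sections within animal first", {
  # two animals, triple percents 30 and 40 -> mean 35, SEM 5
  mk <- function(animal, ntrip, ntot) {
    data.frame(animal_id = animal, section_id = "s1", cell_id = seq_len(ntot),
               diameter_um = 20,
               A = c(rep(TRUE, ntrip), rep(FALSE, ntot - ntrip)))
  }
  mt <- CellMarkerTable(rbind(mk("m1", 3, 10), mk("m2", 4, 10)), probes = "A")
  ag <- aggregateNested(mt, level = "animal")
  row <- ag$summary[ag$summary$combination == "A+", ]
  expect_equal(row$mean_percent, 35)
  expect_equal(row$sem_percent, 5)
  # one animal, one section: mean defined, SEM missing (not 0)
  ag1 <- aggregateNested(CellMarkerTable(mk("m1", 3, 10), probes = "A"))
  expect_equal(ag1$summary$mean_percent[1], 30)
  expect_true(is.na(ag1$summary$sem_percent[1]))
  # sections average within animal before the across-animal mean
  d <- rbind(cbind(mk("m1", 2, 10), sec = "a"), cbind(mk("m1", 8, 10), sec = "b"))
  d$section_id <- d$sec; d$sec <- NULL
  d$cell_id <- seq_len(nrow(d))
  mt2 <- CellMarkerTable(d, probes = "A")
  ag2 <- aggregateNested(mt2)
  expect_equal(ag2$summary$mean_percent[ag2$summary$combination == "A+"], 50)
})

test_that("recovered combination percents converge to the configured truth", {
  probes <- c("Scn10a", "Piezo2", "Ntrk1")
  lat <- names(combinationLattice(probes))
  pr <- setNames(rep(0.62 / 7, 8), lat)
  pr["Scn10a+Piezo2+Ntrk1+"] <- 0.38
  mt <- simulateMarkerTable(5, sectionsPerAnimal = 3, cellsPerSection = 500,
                            probes = probes, combinationProbs = pr, seed = 21)
  ag <- aggregateNested(mt)
  row <- ag$summary[ag$summary$combination == "Scn10a+Piezo2+Ntrk1+", ]
  # 3 binomial SDs of the percent estimate over all counted cells
  n <- nrow(markerData(mt))
  expect_lt(abs(row$mean_percent - 38), 3 * 100 * sqrt(0.38 * 0.62 / n))
})

test_that("KS statistics agree with a brute-force ECDF oracle", {
  mtWide <- function(a, b) {
    # wrap two diameter samples into a marker table with a split probe
    d <- data.frame(animal_id = "m", section_id = "s",
                    cell_id = seq_len(length(a) + length(b)),
                    diameter_um = c(a, b),
                    G = rep(c(TRUE, FALSE), c(length(a), length(b))))
    CellMarkerTable(d, probes = "G")
  }
  subs <- list(pos = c(G = TRUE), neg = c(G = FALSE))
  # identical subsets: D = 0
  r <- diameterDistributions(mtWide(c(1, 2, 3), c(1, 2, 3)), subs)
  expect_equal(r$ks$D, 0)
  # disjoint supports: D = 1
  r <- diameterDistributions(mtWide(c(1, 2), c(10, 11)), subs)
  expect_equal(r$ks$D, 1)
  # {1,2,3} vs {2,3,4}: D = 1/3 by ECDF enumeration
  r <- diameterDistributions(mtWide(c(1, 2, 3), c(2, 3, 4)), subs)
  expect_equal(r$ks$D, 1 / 3)
  # all pairs of small samples over a small alphabet match the oracle
  alphabet <- c(1, 2, 3)
  pool <- unlist(lapply(2:4, function(n)
    apply(expand.grid(rep(list(alphabet), n)), 1, list)), recursive = FALSE)
  set.seed(7)
  pick <- sample(length(pool), 40)
  for (i in pick[1:20]) for (j in pick[21:40]) {
    a <- unlist(pool[[i]]); b <- unlist(pool[[j]])
    r <- diameterDistributions(mtWide(a, b), subs)
    expect_equal(r$ks$D, oracleKS(a, b))
  }
  # histogram normalization and guards
  r <- diameterDistributions(mtWide(c(10, 20, 30), c(15, 25, 60)), subs,
                             binEdges = seq(0, 50, 10))
  byset <- split(r$histograms$freq, r$histograms$subset)
  expect_true(all(abs(vapply(byset, sum, 1) - 1) < 1e-9))
  expect_error(diameterDistributions(mtWide(1:3, 4:6),
                                     list(x = c(H = TRUE))),
               "unknown probe")
  expect_error(diameterDistributions(mtWide(numeric(0), 4:6), subs),
               "empty subset")
})
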