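test_that("dF/F0 normalization matches hand-computed values", {
  # constant trace: dff identically 0, baseline SD 0
  r <- computeDff(rep(100, 40), baselineFrames = 1:30)
  expect_equal(r$f0, 100)
  expect_true(all(r$dff == 0))
  expect_equal(r$baseline_sd, 0)
  # baseline mean 100, frame value 150 -> dff 0.5
  r <- computeDff(c(rep(100, 30), 150), baselineFrames = 1:30)
  expect_equal(r$dff[31], 0.5)
  # alternating 90/110 baseline: dff is ±0.1; sample SD = sqrt(0.3/29)
  tr <- c(rep(c(90, 110), 15), 120)
  r <- computeDff(tr, baselineFrames = 1:30)
  expect_equal(r$f0, 100)
  expect_equal(r$baseline_sd, 0.10170952554312156)
  rp <- computeDff(tr, baselineFrames = 1:30, sdType = "population")
  expect_equal(rp$baseline_sd, 0.1)
  # errors
  expect_error(computeDff(rep(0, 10), baselineFrames = 1:5), "positive")
  expect_error(computeDff(rep(1, 10), baselineFrames = 9:12), "out of range")
})

test_that("gain invariance holds and offsets break it", {
  tr <- c(rep(c(95, 105), 15), 130, 140, 90)
  r1 <- computeDff(tr, baselineFrames = 1:30)
  r2 <- computeDff(3.7 * tr, baselineFrames = 1:30)
  expect_equal(r1$dff, r2$dff)
  r3 <- computeDff(tr + 50, baselineFrames = 1:30)
  expect_false(isTRUE(all.equal(r1$dff, r3$dff)))
})

test_that("responder decision is strict at the 4-sigma boundary", {
  d <- c(0, 0.21, 0)
  expect_true(callResponse(d, 1:3, baselineSD = 0.05)$responder)
  d[2] <- 0.20
  expect_false(callResponse(d, 1:3, baselineSD = 0.05)$responder)
  expect_equal(callResponse(d, 1:3, baselineSD = 0.05)$threshold, 0.2)
  expect_error(callResponse(d, integer(0), 0.05), "non-empty")
})

test_that("peak AUC integrates the positive run around the window peak", {
  # identically zero: AUC 0
  expect_equal(peakAuc(rep(0, 20), 5:10, 0.7), 0)
  # 0.5 on 7 consecutive frames at 0.7 Hz: frozen trapezoid value
  tr <- c(rep(0, 3), rep(0.5, 7), rep(0, 3))
  expect_equal(peakAuc(tr, 4:10, 0.7), 4.285714285714286)
  # linearity
  expect_equal(peakAuc(2 * tr, 4:10, 0.7), 2 * peakAuc(tr, 4:10, 0.7))
  # run expansion beyond the window (decay into post frames)
  tr2 <- c(rep(0, 3), 0.2, 0.5, 0.3, 0.1, 0.05, 0, 0)
  full <- peakAuc(tr2, 4:6, 0.7)
  expect_equal(full, oracleTrapz((4:8) / 0.7, tr2[4:8]))
  # random traces agree with the independent oracle
  set.seed(42)
  for (i in 1:25) {
    tr3 <- round(rnorm(30, 0, 0.2), 3)
    win <- 11:20
    pk <- win[which.max(tr3[win])]
    got <- peakAuc(tr3, win, 0.7)
    if (tr3[pk] <= 0) {
      expect_equal(got, 0)
    } else {
      lo <- pk; while (lo > 1 && tr3[lo - 1] > 0) lo <- lo - 1
      hi <- pk; while (hi < 30 && tr3[hi + 1] > 0) hi <- hi + 1
      want <- if (hi == lo) 0 else oracleTrapz((lo:hi) / 0.7, tr3[lo:hi])
      expect_equal(got, max(0, want))
    }
  }
})

test_that("trace extraction means ROIs and converts pixel counts to areas", {
  fr <- matrix(7, 6, 6)
  stk <- array(c(fr, fr * 2), dim = c(6, 6, 2))
  lab <- matrix(0L, 6, 6)
  lab[1:10] <- 1L
  ex <- extractTraces(stk, lab, pixelSize = 1.92)
  expect_equal(unname(ex$traces[1, ]), c(7, 14))
  expect_equal(unname(ex$areas), 10 * 1.92^2)
  # 100 pixels at 1.92 µm/pixel -> 368.64 µm²
  lab2 <- matrix(0L, 20, 20)
  lab2[1:100] <- 2L
  ex2 <- extractTraces(array(1, c(20, 20, 1)), lab2)
  expect_equal(unname(ex2$areas), 368.64)
  expect_error(extractTraces(stk, matrix(0L, 3, 3)), "pixel grid")
  expect_error(extractTraces(stk, matrix(0L, 6, 6)), "no ROIs")
})

test_that("session-level calls recover noiseless ground truth exactly", {
  p <- smallProtocol()
  sim <- simulateImagingSession(120, p, responderProb = 0.25, noiseSD = 0,
                                seed = 4)
  calls <- callResponses(sim$session)
  m <- merge(calls, sim$truth$responses, by = c("neuron_id", "stimulus"))
  expect_equal(nrow(m), 240L)
  expect_identical(m$responder.x, m$responder.y)
  # realized peak equals the drawn amplitude for responders
  r <- m$responder.y
  expect_equal(m$peak_dff[r], m$amplitude[r], tolerance = 1e-10)
  # responders get positive AUC, non-responders 0
  expect_true(all(m$peak_auc[r] > 0))
  expect_true(all(m$peak_auc[!r] == 0))
})

test_that("pre-stimulus baseline mode renormalizes each epoch", {
  p <- smallProtocol("30g")
  nT <- totalFrames(p)
  tr <- matrix(100, 2, nT)
  ep <- epochIndices(p, "30g")
  tr[1, ep$pre] <- 200              # elevated pre-stimulus plateau
  tr[1, c(ep$stim, ep$post)] <- 260
  s <- ImagingSession(tr, p, areas = c(300, 300))
  gl <- callResponses(s, baselineMode = "global")
  ps <- callResponses(s, baselineMode = "prestim")
  # global f0 = 100 -> peak dff 1.6; prestim f0 = 200 -> peak dff 0.3
  expect_equal(gl$peak_dff[1], 1.6)
  expect_equal(ps$peak_dff[1], 0.3)
  expect_equal(ps$f0[1], 200)
})

test_that("end-to-end summaries are deterministic in the inputs", {
  p <- smallProtocol()
  sim <- simulateImagingSession(60, p, responderProb = 0.3, noiseSD = 0.03,
                                seed = 6)
  s1 <- summarizeSession(callResponses(sim$session))
  s2 <- summarizeSession(callResponses(sim$session))
  expect_identical(stimulusSummary(s1), stimulusSummary(s2))
  expect_identical(areaDistribution(s1), areaDistribution(s2))
})
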