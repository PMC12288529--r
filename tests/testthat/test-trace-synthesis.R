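test_that("state-path simulation: frozen schemes, determinism and
          macro-dwell agreement with first-passage theory", {
  frozen <- rateParameters(k_on = 0, k_off = 0, k_cat = 0, k_break0 = 0,
                           k_form_CC = 0, k_form_OC = 0, k_gate_open = 0,
                           k_gate_close = 0, k_gate_close0 = 0)
  path <- simulateStatePath(buildScheme(frozen, "custom"), 1, 50, seed = 1)
  expect_length(path@states, 1L)
  expect_equal(path@duration, 50)

  ref <- refParams()
  sch <- buildScheme(ref, "WT")
  p1 <- simulateStatePath(sch, 3, 100, seed = 7)
  p2 <- simulateStatePath(sch, 3, 100, seed = 7)
  expect_identical(p1@states, p2@states)
  expect_identical(p1@entryTime, p2@entryTime)

  ## mean open macro-dwell matches inverse MFPT closing rate
  long <- simulateStatePath(sch, 3, 1e4, seed = 8)
  g <- rle(gateLabels(long))
  starts <- long@entryTime[cumsum(c(1L, g$lengths[-length(g$lengths)]))]
  dur <- c(starts[-1L], long@duration) - starts
  open <- dur[g$values == "OPEN"]
  open <- open[-length(open)]   # last dwell may be censored
  k_close <- effectiveRates(sch, 3)$k_close_eff_s
  expect_lt(abs(mean(open) - 1 / k_close),
            3 * stats::sd(open) / sqrt(length(open)))
})

test_that("extension rendering: sample count, two-level structure and
          amplitude/noise fidelity", {
  alt <- alternatingPath(rep(0.5, 12))
  clean <- renderExtensionTrace(alt, amplitude = 6, noise_sd = 0, seed = 1)
  expect_setequal(unique(clean@extension), c(0, 6))

  ref <- refParams()
  path <- simulateStatePath(buildScheme(ref, "WT"), 3, 300, seed = 4)
  tr <- renderExtensionTrace(path, amplitude = 6, noise_sd = 2, seed = 4)
  expect_length(tr@extension, 60000L)
  truth <- truthLabels(path, tr)
  expect_gt(min(table(truth)), 1e4)
  diffs <- mean(tr@extension[truth == "OPEN"]) -
    mean(tr@extension[truth == "CLOSED"])
  expect_equal(diffs, 6, tolerance = 0.1 / 6)
  resid <- tr@extension - ifelse(truth == "OPEN", 6, 0)
  expect_equal(stats::sd(resid), 2, tolerance = 0.05)

  tiny <- alternatingPath(c(0.001, 0.001))
  expect_error(renderExtensionTrace(tiny, rate = 200), "too short")
})

test_that("dwell datasets have the requested per-condition event counts,
          positive durations and flagged boundaries", {
  ref <- refParams()
  dw <- generateDwellDataset(ref, "WT", mg = c(0.3, 1, 3, 10),
                             n = c(61, 274, 313, 58), seed = 1)
  counts <- table(dw$state[!dw$boundary], dw$mg_mM[!dw$boundary])
  expect_equal(unname(counts["OPEN", c("0.3", "1", "3", "10")]),
               c(61, 274, 313, 58))
  expect_equal(unname(counts["CLOSED", c("0.3", "1", "3", "10")]),
               c(61, 274, 313, 58))
  expect_true(all(dw$duration_s > 0))
  expect_true(any(dw$boundary))
  expect_identical(dw, generateDwellDataset(ref, "WT",
                                            mg = c(0.3, 1, 3, 10),
                                            n = c(61, 274, 313, 58),
                                            seed = 1))
  expect_error(generateDwellDataset(ref, "WT", mg = 3, n = 0))
})

test_that("R447G opens far less often than WT over equal simulated time", {
  ref <- refParams()
  pW <- simulateStatePath(buildScheme(ref, "WT"), 3, 1500, seed = 3)
  pR <- simulateStatePath(buildScheme(ref, "R447G"), 3, 1500, seed = 3)
  nOpen <- function(p) sum(rle(gateLabels(p))$values == "OPEN")
  expect_lt(nOpen(pR), nOpen(pW) / 5)
})

test_that("hairpin assay bookkeeping: exposed ssDNA, Mg requirement of WT,
          and Mg-independent opening of 2E2Q", {
  expect_equal(generateHairpinAssay(579, "WT", mg = 3,
                                    high_force_duration = 60,
                                    seed = 1)$exposed_ssDNA, 1158L)
  wt_edta <- generateHairpinAssay(579, "WT", edta = TRUE,
                                  high_force_duration = 600, seed = 1)
  expect_equal(wt_edta$dEx, 0)
  expect_false(wt_edta$opened)
  ## window much longer than 1/k_gate_open: opening probability -> 1
  opened <- vapply(1:10, function(s)
    generateHairpinAssay(579, "2E2Q", edta = TRUE,
                         high_force_duration = 600, seed = s)$opened,
    logical(1L))
  expect_true(all(opened))
  expect_equal(generateHairpinAssay(579, "2E2Q", edta = TRUE,
                                    high_force_duration = 600,
                                    seed = 1)$dEx, 6)
  expect_error(generateHairpinAssay(579, "WT", high_force_duration = 0),
               "positive")
})

test_that("synthetic trajectories realize the scheduled contact geometry,
          opening profile and jitter", {
  sched <- data.frame(label = "interdomain", n_frames = 10)
  tj <- generateSyntheticTrajectory(sched)
  expect_equal(nFrames(tj), 10L)
  fr <- frameCoords(tj, 1)
  ev <- detectSaltBridges(fr, pairs = list(c(457, 304), c(454, 408),
                                           c(457, 447)))
  expect_equal(ev$distance_A, c(2.8, 2.8, 8.0))
  expect_equal(ev$present, c(TRUE, TRUE, FALSE))

  tj2 <- generateSyntheticTrajectory(
    data.frame(label = "intradomain", n_frames = 5))
  ev2 <- detectSaltBridges(frameCoords(tj2, 3),
                           pairs = list(c(457, 304), c(457, 447)))
  expect_equal(ev2$distance_A, c(8.0, 2.8))

  ramp <- generateSyntheticTrajectory(
    data.frame(label = "intradomain", n_frames = 10),
    opening_profile = seq(0, 30, length.out = 10))
  gc <- gateCoordinates(ramp)
  expect_equal(gc$dx_A[10], 30)
  expect_equal(gc$dy_A, rep(0, 10))

  expect_error(generateSyntheticTrajectory(
    data.frame(label = "sideways", n_frames = 2)), "unknown configuration")

  jit <- generateSyntheticTrajectory(sched, jitter_sd = 0.1, seed = 2)
  expect_false(identical(jit@coords, tj@coords))
  expect_lt(max(abs(jit@coords - tj@coords)), 0.1 * 6)
})
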