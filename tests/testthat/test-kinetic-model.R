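test_that("generator carries only the allowed transitions, conserves
          probability and applies variant modifiers", {
  p <- rateParameters()
  sch <- buildScheme(p, "WT")
  Q1 <- generator(sch, 1)
  expect_equal(unname(rowSums(Q1)), rep(0, 8), tolerance = 1e-14)
  expect_true(all(Q1[upper.tri(Q1) | lower.tri(Q1)] >= 0))

  ## at mg = 0 the only exit from the latched closed state is spontaneous
  ## bridge disruption
  Q0 <- generator(sch, 0)
  exits <- Q0["CLOSED.B_CC", setdiff(colnames(Q0), "CLOSED.B_CC")]
  expect_equal(unname(exits[exits > 0]),
               rateVector(p)[["k_break0"]])
  expect_named(exits[exits > 0], "CLOSED.APO")

  ## 2E2Q removes every Mg-coupled rate: generator independent of mg
  e <- buildScheme(p, "2E2Q")
  expect_identical(generator(e, 0), generator(e, 10))

  ## R447G scales intradomain bridge formation
  r <- buildScheme(p, "R447G")
  expect_equal(generator(r, 1)["CLOSED.APO", "CLOSED.B_OC"],
               0.02 * rateVector(p)[["k_form_OC"]])

  expect_error(rateParameters(k_cat = -1), "negative")
  expect_error(new("RateParameters", kOn = 1, kOff = 1, kCat = 1,
                   kBreak0 = 1, kFormCC = 1, kFormOC = 1, kGateOpen = 1,
                   kGateClose = 1, kGateClose0 = 2), "kGateClose0")
  expect_error(buildScheme(p, "E454Q"))
})

test_that("effective rates: Mg latch, variant unreachability, biphasic
          optimum and cycle-rate bound", {
  ref <- refParams()
  ## strict latch: no spontaneous disruption, no Mg
  p0 <- ref
  p0@kBreak0 <- 0
  expect_identical(effectiveRates(buildScheme(p0, "WT"), 0)$k_open_eff_s, 0)
  ## open-competent bridge never forms
  r0 <- buildScheme(ref, "R447G", r447gScale = 0)
  expect_identical(effectiveRates(r0, 5)$k_open_eff_s, 0)

  sch <- buildScheme(ref, "WT")
  grid <- exp(seq(log(0.05), log(20), length.out = 50))
  er <- effectiveRates(sch, grid)
  signChanges <- function(v) sum(diff(sign(diff(v))) != 0)
  expect_equal(signChanges(er$k_open_eff_s), 1)
  expect_equal(signChanges(er$k_close_eff_s), 1)
  imax <- which.max(er$k_open_eff_s)
  expect_gt(imax, 1); expect_lt(imax, length(grid))
  expect_true(all(er$k_cycle_s <=
                    pmin(er$k_open_eff_s, er$k_close_eff_s) + 1e-12))
})

test_that("Monte-Carlo first-passage oracle agrees with the MFPT rate", {
  ref <- refParams()
  sch <- buildScheme(ref, "WT")
  Q <- generator(sch, 1)
  set.seed(11)
  fp <- gatekin:::.ssaFirstPassageC(Q, 1L, 5:8, 5000L, 1e6)
  expect_false(anyNA(fp))
  k_mc <- 1 / mean(fp)
  k <- effectiveRates(sch, 1)$k_open_eff_s
  expect_lt(abs(k_mc - k), 3 * rateSE(fp))
})

test_that("stationary distribution is the normalized generator null vector
          and EMG occupancy grows with Mg", {
  ref <- refParams()
  sch <- buildScheme(ref, "WT")
  pi3 <- stationaryDistribution(sch, 3)
  expect_equal(sum(pi3), 1, tolerance = 1e-10)
  expect_true(all(pi3 >= 0))
  expect_equal(max(abs(as.numeric(pi3 %*% generator(sch, 3)))), 0,
               tolerance = 1e-10)

  emg <- function(pi) sum(pi[grep("EMG", names(pi))])
  p03 <- stationaryDistribution(sch, 0.3)
  p10 <- stationaryDistribution(sch, 10)
  expect_gt(emg(p10), emg(p03))

  ## brute-force long-run time-fraction oracle
  tf <- function(mg, dur) {
    set.seed(21)
    ssa <- gatekin:::.ssaPathC(generator(sch, mg), 1L, dur)
    st <- schemeStates()[ssa$states]
    dt <- c(diff(ssa$entry), dur - ssa$entry[length(ssa$entry)])
    sum(dt[grepl("EMG", st)]) / dur
  }
  expect_gt(tf(10, 3000), tf(0.3, 3000))
  expect_equal(tf(10, 3000), emg(p10), tolerance = 0.05)
})

test_that("degenerate chains: absorbing start state has occupancy 1, and
          ambiguous classes raise a naming error", {
  frozen <- rateParameters(k_on = 0, k_cat = 0, k_break0 = 0,
                           k_form_CC = 0, k_form_OC = 0,
                           k_gate_open = 5, k_gate_close = 5,
                           k_gate_close0 = 1)
  sch <- buildScheme(frozen, "custom")
  pi <- stationaryDistribution(sch, 1, start = "CLOSED.B_CC")
  expect_equal(unname(pi[["CLOSED.B_CC"]]), 1)
  expect_error(stationaryDistribution(sch, 1), "communicating classes")
})

test_that("master-equation propagation conserves probability and relaxes
          to the stationary distribution", {
  ref <- refParams()
  sch <- buildScheme(ref, "WT")
  pr <- propagateMaster(sch, 3, "CLOSED.B_CC", c(1, 10, 100, 1000))
  expect_equal(unname(rowSums(pr)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(pr[4L, ]),
               unname(stationaryDistribution(sch, 3)), tolerance = 1e-8)
})

test_that("calibration places the opening-rate optimum at the target
          concentration and rate", {
  ref <- refParams()
  sch <- buildScheme(ref, "WT")
  grid <- exp(seq(log(0.2), log(5), length.out = 400))
  ko <- effectiveRates(sch, grid)$k_open_eff_s
  expect_equal(grid[which.max(ko)], 1.0, tolerance = 0.05)
  expect_equal(max(ko), 0.5, tolerance = 0.01)
  expect_error(calibrateReference(target_peak_mg = -1))
})

test_that("predicted macro-dwell rates match simulated dwell means", {
  ref <- refParams()
  sch <- buildScheme(ref, "WT")
  for (m in c(0.3, 3)) {
    dw <- generateDwellDataset(ref, "WT", mg = m, n = 250,
                               seed = 31L + as.integer(10 * m))
    pred <- expectedDwellRates(sch, m)
    cl <- dw$duration_s[dw$state == "CLOSED" & !dw$boundary]
    op <- dw$duration_s[dw$state == "OPEN" & !dw$boundary]
    expect_lt(abs(1 / mean(cl) - pred$k_open_obs_s), 3 * rateSE(cl))
    expect_lt(abs(1 / mean(op) - pred$k_close_obs_s), 3 * rateSE(op))
  }
})
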