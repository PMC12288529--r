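test_that("exponential dwell MLE: closed form, sampling distribution and
          small-sample guard", {
  expect_equal(fitDwellRate(rep(2, 10))$rate_s, 0.5)
  set.seed(3)
  x <- stats::rexp(300, rate = 1)
  est <- fitDwellRate(x, seed = 3)
  expect_lt(abs(est$rate_s - 1), 3 / sqrt(300))
  expect_true(est$ci_lo <= est$rate_s && est$rate_s <= est$ci_hi)
  expect_error(fitDwellRate(rep(1, 4)), "pool")
  expect_error(fitDwellRate(numeric(0)), "pool")
})

test_that("phenomenological biphasic fit recovers exact generating
          parameters", {
  mg <- c(0.1, 0.3, 1, 3, 10, 30)
  truth <- c(k_max = 1, K1 = 0.5, K2 = 2)
  rate <- truth[["k_max"]] * (mg / truth[["K1"]]) /
    ((1 + mg / truth[["K1"]]) * (1 + mg / truth[["K2"]]))
  est <- data.frame(state = rep(c("CLOSED", "OPEN"), each = length(mg)),
                    mg_mM = rep(mg, 2), rate_s = rep(rate, 2), n = 100)
  fit <- fitMgDependence(est, model = "phenomenological", seed = 1)
  expect_equal(unname(fit$par[c("open.k_max", "open.K1", "open.K2")]),
               unname(truth), tolerance = 1e-6)
  expect_equal(fit$argmax_mg, sqrt(0.5 * 2), tolerance = 1e-6)
  expect_error(fitMgDependence(est[est$mg_mM < 0.4, ], seed = 1),
               "3 distinct")
})

test_that("mechanistic dwell-likelihood fit recovers the generating rates
          and prefers the biphasic scheme", {
  ref <- refParams()
  dw <- generateDwellDataset(ref, "WT", mg = c(0.3, 1, 3, 10),
                             n = c(61, 274, 313, 58), seed = 5)
  fit <- fitMgDependence(dw, model = "mechanistic", reference = ref,
                         seed = 5)
  truth <- c(rateVector(ref)[c("k_cat", "k_off", "k_form_OC")], scale = 1)
  expect_true(all(abs(fit$par / truth - 1) < 1))
  expect_lt(fit$aic[["biphasic"]], fit$aic[["monotonic"]])
  expect_true(fit$argmax_mg >= 0.4 && fit$argmax_mg <= 2.5)
  expect_true(all(fit$par_ci$ci_lo <= fit$par_ci$estimate &
                    fit$par_ci$estimate <= fit$par_ci$ci_hi))
})

test_that("AIC prefers the monotonic-saturation model for data generated
          under it", {
  mg <- c(0.3, 1, 3, 10)
  set.seed(8)
  ## dwell-table route: exponential dwells with saturating Mg dependence
  ko <- 2 * mg / (1 + mg); kc <- 3 * mg / (0.5 + mg)
  dw <- do.call(rbind, lapply(seq_along(mg), function(i) {
    data.frame(state = rep(c("CLOSED", "OPEN"), each = 150),
               duration_s = c(stats::rexp(150, ko[i]),
                              stats::rexp(150, kc[i])),
               mg_mM = mg[i], trace_id = "null", boundary = FALSE)
  }))
  fit <- fitMgDependence(dw, model = "mechanistic", reference = refParams(),
                         seed = 8)
  expect_lt(fit$aic[["monotonic"]], fit$aic[["biphasic"]])

  ## estimate route: noisy saturation rates, biphasic law not rewarded
  est <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(state = rep(c("CLOSED", "OPEN"), each = length(mg)),
               mg_mM = rep(mg, 2),
               rate_s = exp(stats::rnorm(2 * length(mg), 0, 0.05)) *
                 rep(c(2 * mg / (1 + mg), 3 * mg / (0.5 + mg))),
               n = 150)
  }))
  fitp <- fitMgDependence(est, model = "phenomenological", seed = 8)
  expect_lt(fitp$aic[["monotonic"]], fitp$aic[["biphasic"]])
})

test_that("activity profiles: WT cycle rate drops from 3 to 10 mM, 2E2Q is
          Mg-independent, degenerate fits give zero curves", {
  ref <- refParams()
  dw <- generateDwellDataset(ref, "WT", mg = c(0.3, 1, 3, 10),
                             n = c(61, 274, 313, 58), seed = 5)
  fit <- fitMgDependence(dw, model = "mechanistic", reference = ref,
                         seed = 5)
  act <- predictActivityProfile(fit, c(3, 10))
  expect_gt(act$k_cycle_s[1L], act$k_cycle_s[2L])

  dw2 <- generateDwellDataset(ref, "2E2Q", mg = c(0.5, 1, 3, 10),
                              n = 80, seed = 6)
  fit2 <- fitMgDependence(dw2, model = "mechanistic", reference = ref,
                          variant = "2E2Q", seed = 6)
  act2 <- predictActivityProfile(fit2, c(0.3, 1, 3, 10))
  expect_lt(max(act2$k_cycle_s) / min(act2$k_cycle_s), 1.01)

  dead <- structure(list(model = "mechanistic",
                         curve = function(mg)
                           data.frame(mg_mM = mg, k_open_eff_s = 0,
                                      k_close_eff_s = 0)),
                    class = "MgFitResult")
  expect_equal(predictActivityProfile(dead, c(1, 3))$k_cycle_s, c(0, 0))
})
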