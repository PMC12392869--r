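test_that("the 1:1 forward model honours its limits", {
  # koff -> 0: flat dissociation
  tr <- simulate_1to1_trace(1e6, 1e-12, 1, 10)
  expect_lt(diff(range(tr$dissociation$response)), 1e-6)
  # t -> infinity: association plateau equals Req
  tr2 <- simulate_1to1_trace(1e6, 1e-3, 2, 10, association_time = 1e5)
  kd_nM <- 1e-3 / 1e6 * 1e9
  req <- 2 * 10 / (10 + kd_nM)
  expect_equal(tr2$association$response[length(tr2$association$response)], req,
               tolerance = 1e-6)
  # C = KD: plateau is Rmax / 2
  tr3 <- simulate_1to1_trace(1e6, 1e-3, 2, kd_nM, association_time = 1e6)
  expect_equal(max(tr3$association$response), 1, tolerance = 1e-4)
  expect_error(simulate_1to1_trace(-1, 1e-3, 1, 10), "invalid")
})

test_that("global 1:1 fit recovers subnanomolar kinetics from clean traces", {
  df <- simulate_binding_data("bli", params = list(kon = 1e6, koff = 3.1e-4))
  fit <- fit_1to1_global(binderforge:::curves_to_traces(df))
  expect_equal(fit$kd_nM, 0.31, tolerance = 0.01)
  expect_equal(fit$kon, 1e6, tolerance = 0.01)
  expect_equal(fit$koff, 3.1e-4, tolerance = 0.01)
  # KD is koff/kon by construction
  expect_identical(fit$kd_molar, fit$koff / fit$kon)
  expect_true(fit$identifiable)
})

test_that("1:1 fit tolerates measurement noise", {
  df <- simulate_binding_data("bli", params = list(kon = 2e6, koff = 1e-3),
                              noise = 0.01, seed = 3)
  fit <- fit_1to1_global(binderforge:::curves_to_traces(df))
  true_kd <- 1e-3 / 2e6 * 1e9
  expect_equal(fit$kd_nM, true_kd, tolerance = 0.05)
})

test_that("1:1 parameter recovery holds over a seeded rate grid", {
  for (kon in c(1e4, 1e6)) {
    for (koff in c(1e-4, 1e-2)) {
      kd_nM <- koff / kon * 1e9
      conc <- kd_nM * c(0.3, 1, 3)
      df <- simulate_binding_data("bli", params = list(
        kon = kon, koff = koff, concentrations_nM = conc,
        association_time = max(300, 3 / (kon * min(conc) * 1e-9 + koff)),
        dissociation_time = max(300, 2 / koff)))
      fit <- fit_1to1_global(binderforge:::curves_to_traces(df))
      expect_equal(fit$kd_nM, kd_nM, tolerance = 0.01)
    }
  }
})

test_that("three-parameter dose-response recovers the on-cell constants", {
  d1 <- simulate_binding_data("dose", params = list(kd_nM = 1.9))
  f1 <- fit_dose_response3(d1$conc_nM, d1$response)
  expect_equal(f1$kd_nM, 1.9, tolerance = 0.01)
  expect_equal(f1$background, 100, tolerance = 0.01)
  expect_equal(f1$maximum, 10000, tolerance = 0.01)
  d2 <- simulate_binding_data("dose", params = list(kd_nM = 124))
  f2 <- fit_dose_response3(d2$conc_nM, d2$response)
  expect_equal(f2$kd_nM, 124, tolerance = 0.01)
  # MFI at c = KD is (bg + max) / 2
  mid <- f1$background + (f1$maximum - f1$background) *
    f1$kd_nM / (f1$kd_nM + f1$kd_nM)
  expect_equal(mid, (f1$background + f1$maximum) / 2)
  # flat responses cannot be fit
  expect_error(fit_dose_response3(1:6, rep(5, 6)), "identifiability")
  expect_error(fit_dose_response3(1:3, 1:3), "4 dose")
})

test_that("EC50-to-KD conversion applies the tracer correction exactly", {
  expect_equal(ec50_to_kd(3.268, 5, 1.9), 0.9, tolerance = 1e-3)
  # C_L -> 0: KD equals the EC50
  expect_equal(ec50_to_kd(7, 1e-9, 1.9), 7, tolerance = 1e-6)
  # EC50 = C_L = KD_L: KD = EC50 / 2
  expect_equal(ec50_to_kd(5, 5, 5), 2.5)
  expect_error(ec50_to_kd(-1, 5, 1.9), "positive")
  # monotone in each argument
  expect_gt(ec50_to_kd(10, 5, 1.9), ec50_to_kd(5, 5, 1.9))
  expect_gt(ec50_to_kd(10, 5, 3.8), ec50_to_kd(10, 5, 1.9))
  expect_lt(ec50_to_kd(10, 10, 1.9), ec50_to_kd(10, 5, 1.9))
})

competition_curves <- function(df) {
  lapply(split(df, df$series_id), function(d)
    data.frame(conc_nM = d$conc_nM, mfi = d$response))
}

test_that("global competition fit recovers all three competitor affinities", {
  df <- simulate_binding_data("competition")
  fit <- fit_competition_global(competition_curves(df), c_l_nM = 5,
                                kd_l_nM = 1.9)
  pc <- fit$per_competitor
  expect_equal(pc$kd_nM[pc$competitor == "NN_C1"], 0.9, tolerance = 0.05)
  expect_equal(pc$kd_nM[pc$competitor == "FN"], 612, tolerance = 0.05)
  expect_equal(pc$kd_nM[pc$competitor == "RGD_peptide"], 150000,
               tolerance = 0.05)
  # shared plateaus are single numbers by construction
  expect_length(fit$maximum, 1)
  expect_length(fit$minimum, 1)
  # permuting competitor order leaves the estimates unchanged
  fit2 <- fit_competition_global(rev(competition_curves(df)), 5, 1.9)
  pc2 <- fit2$per_competitor
  expect_equal(pc2$kd_nM[match(pc$competitor, pc2$competitor)], pc$kd_nM,
               tolerance = 1e-6)
})

test_that("single-competitor competition collapses to the descending dose fit", {
  df <- simulate_binding_data("competition",
                              params = list(kds_nM = c(only = 40)))
  curves <- competition_curves(df)
  fit_c <- fit_competition_global(curves, c_l_nM = 5, kd_l_nM = 1.9)
  fit_d <- fit_dose_response3(curves[[1]]$conc_nM, curves[[1]]$mfi,
                              direction = "descending")
  expect_equal(fit_c$per_competitor$ec50_nM[1], fit_d$kd_nM,
               tolerance = 1e-6)
  expect_equal(fit_c$maximum, fit_d$maximum, tolerance = 1e-6)
  expect_equal(fit_c$minimum, fit_d$background, tolerance = 1e-6)
})

test_that("a non-decreasing competitor is flagged as a bound, not a value", {
  df <- simulate_binding_data("competition",
                              params = list(kds_nM = c(weak = 1e9, ok = 10),
                                            concentrations_nM = 10^seq(-2, 4, length.out = 10)))
  fit <- fit_competition_global(competition_curves(df), 5, 1.9)
  pc <- fit$per_competitor
  expect_true(pc$ec50_is_lower_bound[pc$competitor == "weak"])
  expect_false(pc$ec50_is_lower_bound[pc$competitor == "ok"])
})
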