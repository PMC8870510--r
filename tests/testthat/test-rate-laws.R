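test_that("saturating rate has the Michaelis-Menten limits", {
  expect_equal(saturating_rate(1, 1, 1), 0.5)
  expect_equal(saturating_rate(2, 1, 0), 0)
  # near-saturation: within 1e-3 of vmax at s = 1000 * km
  expect_equal(saturating_rate(1, 0.5, 1000), 1, tolerance = 1e-3)
  expect_error(saturating_rate(1, 1, -0.1), "negative")
  expect_error(saturating_rate(1, 0, 1), "km")
})

test_that("Hill inhibition is 1 at zero, 1/2 at ki, and decreasing", {
  expect_equal(inhibition_factor(0, 2, 4), 1)
  expect_equal(inhibition_factor(2, 2, 4), 0.5)
  expect_equal(inhibition_factor(2, 2, 7), 0.5)  # half-point independent of n
  expect_equal(inhibition_factor(4, 2, 4), 1 / 17)
  x <- seq(0, 10, by = 0.25)
  expect_true(all(diff(inhibition_factor(x, 1.5, 4)) < 0))
  expect_error(inhibition_factor(1, 2, 0.5), "n must be")
})

test_that("Hill activation runs from 1 to amp through the midpoint", {
  expect_equal(activation_factor(0, 0.3, 2, 5), 1)
  expect_equal(activation_factor(0.3, 0.3, 2, 5), 3)  # 1 + (amp - 1)/2
  expect_equal(activation_factor(1000 * 0.3, 0.3, 2, 5), 5, tolerance = 1e-3)
  x <- seq(0, 2, by = 0.05)
  expect_true(all(diff(activation_factor(x, 0.25, 2, 8)) > 0))
})

test_that("PFK rate is monotone in each regulator", {
  p <- default_parameters()
  km <- p$km$R3[["F6P"]]
  # ATP = 0, FBP = 0, F6P = km: regulation factors reduce to 1, rate = vmax/2
  expect_equal(pfk_rate(km, 0, 0, p), p$vmax[["R3"]] / 2)
  atp <- seq(0.2, 3, by = 0.2)
  expect_true(all(diff(vapply(atp, function(a) pfk_rate(0.5, a, 0.1, p),
                              numeric(1))) < 0))
  fbp <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(vapply(fbp, function(f) pfk_rate(0.5, 1.5, f, p),
                              numeric(1))) > 0))
  f6p <- seq(0, 2, by = 0.1)
  expect_true(all(diff(vapply(f6p, function(s) pfk_rate(s, 1.5, 0.1, p),
                              numeric(1))) > 0))
})

test_that("reversible MDH changes sign at its mass-action equilibrium", {
  p <- default_parameters()
  kk <- p$km$R13
  expect_gt(reversible_mdh_rate(0.5, 0, 0, 0.5, p), 0)
  expect_lte(reversible_mdh_rate(0, 0.5, 0.5, 0, p), 0)
  # zero when (mal * nad) / (oaa * nadh) = k_r / k_f
  mal <- 0.4; nad <- 0.6; nadh <- 0.3
  oaa <- kk[["k_f"]] * mal * nad / (kk[["k_r"]] * nadh)
  expect_equal(reversible_mdh_rate(mal, oaa, nadh, nad, p), 0, tolerance = 1e-12)
  expect_error(reversible_mdh_rate(-1, 0, 0, 0, p), "negative")
})

test_that("ETC rate is gated by oxygen and ADP and rises with carrier", {
  expect_equal(etc_rate(0.5, 0, 1, 10, 0.2, 0.05, 0.1), 0)
  expect_equal(etc_rate(0.5, 1, 0, 10, 0.2, 0.05, 0.1), 0)
  carriers <- seq(0.05, 1, by = 0.05)
  v <- vapply(carriers, function(cc) etc_rate(cc, 0.8, 0.5, 10, 0.2, 0.05, 0.1),
              numeric(1))
  expect_true(all(diff(v) > 0))
  expect_error(etc_rate(0.5, 1.2, 1, 10, 0.2, 0.05, 0.1), "0, 1")
})
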