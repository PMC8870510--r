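test_that("the extended model keeps the cytosolic NAD pool closed", {
  m <- build_extended_network()
  p <- default_parameters(m)
  res <- suppressWarnings(integrate_to_steady_state(m, p))
  expect_true(res$converged)
  expect_lte(res$state[["NADH_c"]], p$pools$N_tot_c + 1e-9)
  expect_gte(res$state[["NADH_c"]], -1e-9)
  # readouts expose the ratio and use flux
  ro <- nad_readouts(res)
  nadh <- res$state[["NADH_c"]]
  expect_equal(ro$nad_ratio_c, (p$pools$N_tot_c - nadh) / nadh)
  expect_equal(ro$nad_use_flux, res$fluxes[["R24"]])
})

test_that("redox readouts refuse baseline-model results", {
  res <- default_steady_state()
  expect_error(nad_readouts(res), "extended model")
})

test_that("a half-reduced cytosolic pool gives a unit NAD ratio", {
  m <- build_extended_network()
  p <- default_parameters(m)
  res <- suppressWarnings(integrate_to_steady_state(m, p))
  res$state[["NADH_c"]] <- p$pools$N_tot_c / 2
  res$readouts <- derived_readouts(res)
  expect_equal(res$readouts$nad_ratio_c, 1)
})

test_that("a fast shuttle with no NAD+ demand recovers baseline behaviour", {
  # with the NAD+-use flux off and the shuttle far from limiting, the
  # cytosolic ratio is pinned and the extended model's lipid flux matches the
  # baseline fixed-ratio treatment
  mb <- build_default_network()
  pb <- default_parameters(mb)
  pb$regulation$amp_FBP <- 1
  rb <- suppressWarnings(integrate_to_steady_state(mb, pb))

  me <- build_extended_network()
  pe <- default_parameters(me)
  pe$regulation$amp_FBP <- 1
  pe$vmax[["R24"]] <- 0
  pe$vmax[["R23"]] <- 500
  re <- suppressWarnings(integrate_to_steady_state(me, pe))
  expect_true(rb$converged && re$converged)
  expect_equal(re$readouts$lipid_flux, rb$readouts$lipid_flux,
               tolerance = 0.05)
})
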