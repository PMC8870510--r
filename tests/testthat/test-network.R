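test_that("the default network matches the published catalogue shape", {
  m <- build_default_network()
  expect_s3_class(m, "ccm_model")
  expect_length(m$reactions, 22)
  expect_length(dynamic_species <- m$species$species_id[
    m$species$compartment %in% c("cytosol", "mitochondrion")], 14)
  expect_true(all(paste0("R", 1:22) %in% names(m$reactions)))
  # the extended variant adds cytosolic NADH and the two redox reactions
  me <- build_extended_network()
  expect_length(me$reactions, 24)
  expect_true("NADH_c" %in% me$species$species_id)
})

test_that("every reaction is carbon balanced, including the extension", {
  expect_true(all(reaction_carbon_residuals(build_default_network()) == 0))
  resid_ext <- reaction_carbon_residuals(build_extended_network())
  expect_true(all(resid_ext == 0))
  # the shuttle moves electrons, not carbon
  expect_identical(unname(resid_ext[["R23"]]), 0)
})

test_that("a corrupted stoichiometry is caught by the carbon audit", {
  m <- build_default_network()
  # drop the CO2 product from pyruvate dehydrogenase: 3 carbons in, 2 out
  m$reactions$R8$stoich <- m$reactions$R8$stoich[
    names(m$reactions$R8$stoich) != "CO2"]
  resid <- reaction_carbon_residuals(m)
  expect_equal(unname(resid[["R8"]]), -1)
  expect_true(all(resid[names(resid) != "R8"] == 0))
})

test_that("unknown species in stoichiometry raise an error", {
  m <- build_default_network()
  m$reactions$R8$stoich <- c(m$reactions$R8$stoich, FOO = 1)
  expect_error(reaction_carbon_residuals(m), "unknown species")
})

test_that("the lumped TCA span carries the full ATP and redox ledger", {
  m <- build_default_network()
  r12 <- m$reactions$R12
  expect_equal(r12$atp_stoich, 1)
  expect_equal(unname(r12$redox_stoich[c("NADH_m", "FADH2_m")]), c(1, 1))
  # lower glycolysis credits 2 ATP per triose so a glucose nets exactly 2
  expect_equal(m$reactions$R6$atp_stoich, 2)
  expect_equal(m$reactions$R1$atp_stoich + m$reactions$R3$atp_stoich, -2)
})

test_that("activity scaling is multiplicative and validated", {
  p <- default_parameters()
  p2 <- scale_activity(p, "LDH", 2)
  expect_equal(p2$activity[["LDH"]], 2 * p$activity[["LDH"]])
  expect_equal(scale_activity(p, "LDH", 1)$activity, p$activity)
  expect_error(scale_activity(p, "PHD", 2), "unknown activity key")
  expect_error(scale_activity(p, "LDH", -1), "factor")
})

test_that("model definitions round-trip through YAML losslessly", {
  for (m in list(build_default_network(), build_extended_network())) {
    path <- tempfile(fileext = ".yaml")
    model_to_yaml(m, path)
    m2 <- model_from_yaml(path)
    expect_equal(m2$variant, m$variant)
    expect_equal(m2$species, m$species)
    expect_equal(length(m2$reactions), length(m$reactions))
    for (rid in names(m$reactions)) {
      expect_equal(m2$reactions[[rid]]$stoich, m$reactions[[rid]]$stoich,
                   info = rid)
      expect_equal(m2$reactions[[rid]]$redox_stoich,
                   m$reactions[[rid]]$redox_stoich, info = rid)
      expect_equal(m2$reactions[[rid]]$modifiers, m$reactions[[rid]]$modifiers,
                   info = rid)
      expect_equal(m2$reactions[[rid]]$rate_template,
                   m$reactions[[rid]]$rate_template, info = rid)
    }
    # the restored model evaluates identically
    p <- default_parameters(m)
    st <- reference_state(m)
    expect_equal(compute_fluxes(st, p, m2), compute_fluxes(st, p, m))
    unlink(path)
  }
})
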