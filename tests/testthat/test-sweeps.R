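test_that("a single-value sweep reproduces a plain steady-state solve", {
  mp <- default_baseline()
  p <- mp$p
  p$regulation$amp_FBP <- 1
  sw <- suppressWarnings(run_sweep(mp$m, p, sweep_spec("activity.LDH", 1, "up")))
  direct <- suppressWarnings(integrate_to_steady_state(mp$m, p))
  expect_equal(nrow(sw$table), 1)
  expect_equal(sw$results$up[[1]]$state, direct$state, tolerance = 1e-8)
  expect_equal(sw$table$lipid_flux, direct$readouts$lipid_flux,
               tolerance = 1e-8)
})

test_that("sweep specifications are validated", {
  expect_error(sweep_spec("foo", 1:3), "param_path")
  expect_error(sweep_spec("activity.LDH", c(1, NA)), "finite")
  sp <- sweep_spec("environment.k_use", c(3, 1, 2), "up")
  expect_equal(sp$values, c(1, 2, 3))
})

test_that("bistability detection recovers a constructed hysteresis window", {
  # synthetic two-branch data: up sweep jumps after x = 4, down sweep after
  # x = 2, so the coexistence window is (2, 4]
  x <- 1:8
  up <- data.frame(swept_value = x, lipid_flux = c(1, 1, 1, 1, 10, 10, 10, 10),
                   converged = TRUE)
  down <- data.frame(swept_value = x, lipid_flux = c(1, 1, 10, 10, 10, 10, 10, 10),
                     converged = TRUE)
  rep <- detect_bistability(up, down, readout = "lipid_flux")
  expect_true(rep$bistable)
  expect_equal(rep$up_transition, 5)
  expect_equal(rep$down_transition, 3)
  expect_equal(rep$window, c(3, 5))
})

test_that("identical branches are reported monostable", {
  x <- 1:8
  b <- data.frame(swept_value = x, lipid_flux = seq(1, 8), converged = TRUE)
  rep <- detect_bistability(b, b, readout = "lipid_flux")
  expect_false(rep$bistable)
})

test_that("unconverged points are excluded from jump detection", {
  x <- 1:8
  up <- data.frame(swept_value = x, lipid_flux = c(1, 1, 1, 1, 1, 10, 10, 10),
                   converged = TRUE)
  down <- data.frame(swept_value = x,
                     lipid_flux = c(1, NA, NA, 10, 10, 10, 10, 10),
                     converged = c(TRUE, FALSE, FALSE, rep(TRUE, 5)))
  rep <- detect_bistability(up, down, readout = "lipid_flux")
  expect_true(rep$bistable)
  expect_equal(rep$down_transition, 4)
})

test_that("mismatched grids are rejected", {
  a <- data.frame(swept_value = 1:5, lipid_flux = 1:5, converged = TRUE)
  b <- data.frame(swept_value = 2:6, lipid_flux = 1:5, converged = TRUE)
  expect_error(detect_bistability(a, b, readout = "lipid_flux"), "same grid")
})

test_that("sweeps and phenotype maps are reproducible run to run", {
  mp <- default_baseline()
  p <- mp$p
  p$regulation$amp_FBP <- 1
  spec <- sweep_spec("environment.k_use", c(2, 4, 6), "up")
  sw1 <- suppressWarnings(run_sweep(mp$m, p, spec))
  sw2 <- suppressWarnings(run_sweep(mp$m, p, spec))
  expect_identical(sw1$table, sw2$table)
})

test_that("phenotype maps record winners and crossovers", {
  mp <- default_baseline()
  p <- mp$p
  p$regulation$amp_FBP <- 1
  pm <- suppressWarnings(optimal_phenotype_map(
    mp$m, p, c(10, 50), readout = "lipid_flux"))
  expect_setequal(unique(pm$table$phenotype), c("Warburg", "OXPHOS"))
  expect_equal(nrow(pm$winner), 2)
  # identical phenotypes cannot produce a crossover
  same <- list(A = c(LDH = 1, PDH = 1), B = c(LDH = 1, PDH = 1))
  pm2 <- suppressWarnings(optimal_phenotype_map(
    mp$m, p, c(10, 50), phenotypes = same, readout = "lipid_flux"))
  expect_null(pm2$crossovers)
  expect_error(optimal_phenotype_map(mp$m, p, c(1, 2),
                                     phenotypes = same[1]), "two phenotypes")
})
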