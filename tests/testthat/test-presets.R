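test_that("the preset catalogue is enumerable and validated", {
  ids <- list_presets()
  expect_gte(length(ids), 19)
  expect_true(all(c("ldh-hysteresis", "atp-demand-crossover", "yield-regimes",
                    "redox-crossover") %in% ids))
  expect_error(run_preset("no-such-scenario"), "unknown preset")
})

test_that("a preset returns tables, assertions and its parameters", {
  res <- suppressWarnings(run_preset("pc-rescue"))
  expect_s3_class(res, "ccm_preset_result")
  expect_true(length(res$tables) >= 1)
  expect_true(all(vapply(res$tables, is.data.frame, logical(1))))
  expect_true(all(vapply(res$assertions, function(a)
    is.logical(a$pass) && nzchar(a$detail), logical(1))))
  expect_s3_class(res$parameters, "ccm_parameters")
  # preset results serialize like any other result object
  out <- tempfile()
  files <- write_results(res, out)
  expect_true(any(grepl("comparison", files)))
  unlink(out, recursive = TRUE)
})

test_that("rerunning a preset reproduces identical tables", {
  r1 <- suppressWarnings(run_preset("glc-deprivation-oxygen"))
  r2 <- suppressWarnings(run_preset("glc-deprivation-oxygen"))
  expect_identical(r1$tables, r2$tables)
})
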