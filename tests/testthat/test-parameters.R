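test_that("shipped defaults encode the base case and pass validation", {
  p <- default_parameters("medicare")
  expect_true(is_valid(validate_parameters(p)))
  expect_equal(p$cost_purevu_device, 750)
  expect_equal(p$p_compliance_screening, 0.60)
  expect_equal(p$p_inadequate_prep_soc, 0.25)
  expect_equal(p$p_inadequate_prep_purevu, 0.05)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$screening_interval_years, 10L)
  expect_equal(p$horizon_years, 24L)
  expect_equal(p$payer_multiplier, 1.0)

  priv <- default_parameters("private")
  expect_true(is_valid(validate_parameters(priv)))
  # midpoint of the published 1.63-2.48 reimbursement range
  expect_equal(priv$payer_multiplier, (1.63 + 2.48) / 2)
})

test_that("validation reports every violation, not only the first", {
  p <- default_parameters()
  p$discount_rate <- -0.01
  p$utility_by_state$EARLY_CRC <- 1.2
  p$cost_complication <- -5
  rep <- validate_parameters(p)
  expect_false(is_valid(rep))
  expect_setequal(
    rep$errors$field,
    c("discount_rate", "utility_by_state", "cost_complication"))
})

test_that("write/load round-trips a parameter set identically", {
  p <- default_parameters("private")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  for (nm in setdiff(names(p), "psa_distributions")) {
    expect_equal(p2[[nm]], p[[nm]], tolerance = 1e-12, label = nm)
  }
  expect_equal(names(p2$psa_distributions), names(p$psa_distributions))
  expect_equal(p2$psa_distributions$p_compliance_screening$params,
               p$psa_distributions$p_compliance_screening$params,
               tolerance = 1e-12)
})

test_that("partial configuration files inherit defaults and are validated", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("p_inadequate_prep_soc: 0.25",
               "p_inadequate_prep_purevu: 0.05",
               "cost_purevu_device: 900"), f)
  p <- load_parameters(f)
  expect_equal(p$p_inadequate_prep_soc, 0.25)
  expect_equal(p$cost_purevu_device, 900)
  expect_equal(p$p_compliance_screening, 0.60)  # inherited default

  writeLines("discount_rate: -0.01", f)
  expect_error(load_parameters(f), "discount_rate")
  writeLines("no_such_field: 1", f)
  expect_error(load_parameters(f), "no_such_field")
  expect_error(load_parameters(file.path(tempdir(), "absent.yaml")),
               "not found")
})

test_that("shipped extdata configurations load and match the defaults", {
  f <- system.file("extdata", "base_case_medicare.yaml", package = "prepcea")
  expect_true(nzchar(f))
  p <- load_parameters(f)
  expect_equal(p$cost_purevu_device, default_parameters()$cost_purevu_device)
  expect_equal(p$p_progression_adenoma_to_early,
               default_parameters()$p_progression_adenoma_to_early)
})

test_that("distribution specs enforce their family invariants", {
  expect_error(dist_spec("beta", list(shape1 = -1, shape2 = 2)), "positive")
  expect_error(dist_spec("uniform", list(min = 2, max = 1)), "min < max")
  expect_error(dist_spec("triangular",
                         list(min = 0, mode = 2, max = 1)), "triangular")
  expect_error(dist_spec("point", list(value = 5), support = c(0, 1)),
               "outside")
  expect_s3_class(dist_spec("gamma", list(shape = 2, scale = 10)),
                  "dist_spec")
  p <- default_parameters()
  p$psa_distributions$p_compliance_screening$params$shape1 <- -3
  expect_false(is_valid(validate_parameters(p)))
})

test_that("parameter table flattens every scalar field", {
  tab <- as.data.frame(default_parameters())
  expect_true(all(c("p_compliance_screening", "cost_purevu_device",
                    "utility_by_state.EARLY_CRC") %in% tab$field))
  expect_true(all(is.finite(tab$value)))
})
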