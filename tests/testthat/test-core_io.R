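test_that("sample tables round-trip through delimited text exactly", {
  tab <- make_water_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(tab, path)
  back <- read_samples(path, "surface_water")
  expect_identical(back$values, tab$values)
  expect_identical(back$bdl_flags, tab$bdl_flags)
  expect_identical(back$sites, tab$sites)
  # a table with BDL-substituted cells round-trips values and flags too
  dl <- c(Pb = 0.05)
  lines <- c(paste(c("site", pte_elements), collapse = ","),
             paste(c("A", "<0.05", rep("1", 9)), collapse = ","),
             paste(c("B", rep("2", 10)), collapse = ","))
  tab2 <- read_samples(write_temp_csv(lines), "surface_water",
                       detection_limits = dl)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_samples(tab2, path2)
  back2 <- read_samples(path2, "surface_water", detection_limits = dl)
  expect_identical(back2$values, tab2$values)
  expect_identical(back2$bdl_flags, tab2$bdl_flags)
})

test_that("below-detection cells are substituted at DL/2, idempotently", {
  lines <- c(paste(c("site", pte_elements), collapse = ","),
             paste(c("A", "<0.05", rep("1", 9)), collapse = ","),
             paste(c("B", "0.01", rep("1", 9)), collapse = ","))
  tab <- read_samples(write_temp_csv(lines), "surface_water",
                      detection_limits = c(Pb = 0.05))
  expect_equal(tab$values["A", "Pb"], 0.025)
  expect_true(tab$bdl_flags["A", "Pb"])
  # a numeric value below the configured DL is flagged and substituted too
  expect_equal(tab$values["B", "Pb"], 0.025)
  expect_true(tab$bdl_flags["B", "Pb"])
  # substitution never exceeds the detection limit, and substituted values
  # are not re-substituted on a second pass
  expect_true(all(tab$values[tab$bdl_flags] <= 0.05))
  tab3 <- read_samples(write_temp_csv(lines), "surface_water",
                       detection_limits = c(Pb = 0.05), bdl_action = "zero")
  expect_equal(tab3$values["A", "Pb"], 0)
})

test_that("malformed sample files fail with informative errors", {
  no_sb <- c(paste(c("site", setdiff(pte_elements, "Sb")), collapse = ","),
             paste(c("A", rep("1", 9)), collapse = ","))
  expect_error(read_samples(write_temp_csv(no_sb), "surface_water",
                            elements = pte_elements), "Sb")
  neg <- c(paste(c("site", pte_elements), collapse = ","),
           paste(c("A", "-3", rep("1", 9)), collapse = ","))
  expect_error(read_samples(write_temp_csv(neg), "surface_water"),
               "negative")
  junk <- c(paste(c("site", pte_elements), collapse = ","),
            paste(c("A", "oops", rep("1", 9)), collapse = ","))
  expect_error(read_samples(write_temp_csv(junk), "surface_water"),
               "row 1.*Pb|Pb.*row 1")
})

test_that("the shipped default bundle covers all elements, media, populations", {
  refs <- default_reference_bundle()
  for (m in c("surface_water", "soil"))
    expect_true(all(pte_elements %in% names(refs$screening[[m]])))
  # crops deliberately lack Mo and V screening values
  expect_setequal(setdiff(pte_elements, names(refs$screening$crop)),
                  c("Mo", "V"))
  expect_true(all(pte_elements %in% names(refs$toxicity)))
  expect_true(all(refs$toxicity >= 1))
  expect_true(all(pte_elements %in% names(refs$rfd)))
  expect_setequal(names(refs$exposure), c("child", "adult"))
  # Zn carries no slope factor: it must be absent, not zero
  expect_false("Zn" %in% names(refs$slope))
})

test_that("reference bundle construction enforces its invariants", {
  expect_error(reference_bundle(
    screening = list(soil = list(Pb = 0)), toxicity = list(Pb = 5),
    rfd = list(Pb = list(ingestion = 1e-3)),
    exposure = list(child = list(bw = 15))), "positive")
  expect_warning(reference_bundle(
    screening = list(soil = list(Pb = 10)), toxicity = list(Pb = 0.5),
    rfd = list(Pb = list(ingestion = 1e-3)),
    exposure = list(child = list(bw = 15))), "toxicity")
})

test_that("distribution specs validate parameters and report central values", {
  expect_equal(dist_central(dist_spec("point", value = 3)), 3)
  expect_equal(dist_central(dist_spec("uniform", min = 335, max = 365)), 350)
  expect_equal(dist_central(dist_spec("normal", mean = 15, sd = 2.3)), 15)
  ln <- dist_spec("lognormal", meanlog = log(200) - 0.5 * log(1.25),
                  sdlog = sqrt(log(1.25)))
  expect_equal(dist_central(ln), 200)
  expect_error(dist_spec("normal", mean = 1, sd = -1), "non-negative")
  expect_error(dist_spec("uniform", min = 2, max = 1), "min <= max")
  expect_error(dist_spec("point", value = 1, lower = 5, upper = 2),
               "lower < upper")
  expect_error(dist_spec("triangular", min = 0, mode = 3, max = 2),
               "mode")
})

test_that("validation cross-checks coverage and units without mutating input", {
  refs <- default_reference_bundle()
  tab <- make_soil_table()
  rep1 <- validate_inputs(tab, refs)
  expect_true(rep1$passed)
  expect_equal(nrow(rep1$errors), 0)
  # an element with no screening value is reported by name
  vals <- cbind(tab$values, Hg = rep(0.1, nrow(tab$values)))
  tab_hg <- sample_table(vals, "soil")
  rep2 <- validate_inputs(tab_hg, refs)
  expect_false(rep2$passed)
  expect_match(paste(rep2$errors$message, collapse = " "), "Hg")
  # unit inconsistent with medium
  tab_bad <- tab
  tab_bad$unit <- "mg/kg"
  tab_bad$medium <- "surface_water"
  rep3 <- validate_inputs(tab_bad, refs)
  expect_false(rep3$passed)
  expect_match(paste(rep3$errors$message, collapse = " "), "unit")
})
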