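# Hand-computed reference values use the default child parameter set:
# R_ing 200 mg/d, EF 350 d/y, ED 6 y, BW 15 kg, AT 2190 d, SA 2800 cm2,
# AF 0.2 mg/cm2/d, ABS 0.001, R_inh 7.5 m3/d, PEF 1.36e9 m3/kg.

test_that("intake equations reproduce hand-calculated values", {
  expect_equal(adi_ingestion(100, 200, 350, 6, 15, 2190, 1e-6),
               100 * 200 * 350 * 6 / (15 * 2190) * 1e-6)
  expect_equal(adi_ingestion(100, 200, 350, 6, 15, 2190, 1e-6),
               1.27854e-3, tolerance = 1e-5)
  expect_equal(adi_dermal(100, 2800, 0.2, 0.001, 350, 6, 15, 2190, 1e-6),
               3.580e-6, tolerance = 1e-4)
  expect_equal(adi_inhalation(100, 7.5, 350, 6, 1.36e9, 15, 2190),
               3.525e-8, tolerance = 1e-4)
  expect_equal(adi_ingestion(0, 200, 350, 6, 15, 2190, 1e-6), 0)
  expect_equal(adi_dermal(0, 2800, 0.2, 0.001, 350, 6, 15, 2190, 1e-6), 0)
  expect_equal(adi_inhalation(0, 7.5, 350, 6, 1.36e9, 15, 2190), 0)
})

test_that("intakes are linear in concentration and inverse in PEF and BW", {
  a1 <- adi_ingestion(50, 200, 350, 6, 15, 2190, 1e-6)
  expect_equal(adi_ingestion(100, 200, 350, 6, 15, 2190, 1e-6), 2 * a1)
  i1 <- adi_inhalation(100, 7.5, 350, 6, 1.36e9, 15, 2190)
  expect_equal(adi_inhalation(100, 7.5, 350, 6, 1.36e9 / 2, 15, 2190), 2 * i1)
  expect_error(adi_ingestion(1, 200, 350, 6, 0, 2190, 1e-6), "body weight")
  expect_error(adi_ingestion(1, 200, 350, 6, 15, 0, 1e-6), "averaging time")
  expect_error(adi_dermal(1, 2800, 0.2, 0, 350, 6, 15, 2190, 1e-6),
               "absorption")
})

test_that("risk indices divide by RfD, multiply by SF, and sum exactly", {
  refs <- default_reference_bundle()
  adi <- matrix(0, 2, 3,
                dimnames = list(c("Ni", "Zn"),
                                c("ingestion", "dermal", "inhalation")))
  adi["Ni", "ingestion"] <- 1.27854e-3
  ri <- risk_indices(adi, refs)
  expect_equal(ri$nri_by["Ni", "ingestion"], 1.27854e-3 / 0.02)
  expect_equal(ri$nri_by["Ni", "ingestion"], 0.063927, tolerance = 1e-6)
  # CRI = ADI * SF (Ni ingestion SF 1.7 in the default bundle)
  expect_equal(ri$cri_by["Ni", "ingestion"], 1.27854e-3 * 1.7)
  # Zn has no slope factor: absent, not zero
  expect_true(all(is.na(ri$cri_by["Zn", ])))
  expect_equal(ri$nri_total, sum(ri$nri_by, na.rm = TRUE))
  expect_equal(ri$cri_total, sum(ri$cri_by, na.rm = TRUE))
  # ADI equal to RfD gives an NRI contribution of exactly 1
  adi2 <- adi; adi2["Ni", "ingestion"] <- 0.02
  expect_equal(risk_indices(adi2, refs)$nri_by["Ni", "ingestion"], 1)
  # missing RfD is a named error
  adi3 <- matrix(1e-3, 1, 3, dimnames = list("Xx",
                 c("ingestion", "dermal", "inhalation")))
  expect_error(risk_indices(adi3, refs), "Xx")
})

test_that("site assessment composes pathways and respects additivity", {
  refs <- default_reference_bundle()
  zero <- sample_table(matrix(0, 2, 10, dimnames = list(c("a", "b"),
                                                        pte_elements)),
                       "soil")
  r <- assess_risk(zero, refs, "child")
  expect_true(all(r$nri == 0))
  tot <- risk_totals(r)
  expect_true(all(tot$nri_total == 0))
  expect_false(any(tot$nri_exceeds))
  expect_false(any(tot$cri_exceeds))
  # single element, single nonzero pathway: the total equals that cell
  tab <- make_soil_table()
  r1 <- assess_risk(tab, refs, "child", elements = "Ni")
  t1 <- risk_totals(r1)
  by_hand <- tapply(r1$nri, r1$site, sum)
  expect_equal(unname(t1$nri_total), as.numeric(by_hand[t1$site]))
})

test_that("risk totals are invariant to element ordering", {
  refs <- default_reference_bundle()
  tab <- make_soil_table()
  r1 <- risk_totals(assess_risk(tab, refs, "child", elements = pte_elements))
  r2 <- risk_totals(assess_risk(tab, refs, "child",
                                elements = rev(pte_elements)))
  expect_equal(r1$nri_total, r2$nri_total)
  expect_equal(r1$cri_total, r2$cri_total)
})

test_that("with default parameters children bear higher risk than adults and
          ingestion dominates", {
  refs <- default_reference_bundle()
  tab <- make_soil_table()
  child <- risk_totals(assess_risk(tab, refs, "child"))
  adult <- risk_totals(assess_risk(tab, refs, "adult"))
  expect_true(all(child$nri_total >= adult$nri_total))
  expect_true(all(child$cri_total >= adult$cri_total))
  r <- assess_risk(tab, refs, "child")
  by_path <- tapply(r$nri, r$pathway, sum)
  expect_true(by_path["ingestion"] > by_path["dermal"])
  expect_true(by_path["dermal"] > by_path["inhalation"])
  # the same ordering holds for surface water (inhalation disabled, 0)
  wat <- make_water_table()
  rw <- assess_risk(wat, refs, "child")
  by_path_w <- tapply(rw$nri, rw$pathway, sum)
  expect_true(by_path_w["ingestion"] > by_path_w["dermal"])
  expect_equal(unname(by_path_w["inhalation"]), 0)
})

test_that("risk scales linearly with concentration", {
  refs <- default_reference_bundle()
  tab <- make_soil_table()
  tab2 <- sample_table(3 * tab$values, "soil")
  t1 <- risk_totals(assess_risk(tab, refs, "child"))
  t2 <- risk_totals(assess_risk(tab2, refs, "child"))
  expect_equal(t2$nri_total, 3 * t1$nri_total)
  expect_equal(t2$cri_total, 3 * t1$cri_total)
})
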