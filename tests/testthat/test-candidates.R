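test_that("the packaged library holds the 15 candidates and 6 standards", {
  lib <- saponin_library()
  expect_s3_class(lib, "candidate_set")
  expect_length(lib, 15L)
  expect_identical(names(lib), table2$identification)
  expect_setequal(standard_names(lib), authentic_standards)
})

test_that("molecular formulas equal the reference table formulas", {
  lib <- saponin_library()
  for (i in seq_along(lib)) {
    expect_equal(formula_string(molecular_formula(lib[[i]])),
                 table2$formula[i], info = names(lib)[i])
  }
})

test_that("aglycone formulas are consistent with glycoside arithmetic", {
  lib <- saponin_library()
  hex3 <- Reduce(formula_add, rep(list(parse_formula("C6H10O5")), 3))
  # subtracting the sugars from the reported molecular formula recovers
  # the stored aglycone (independent subtraction oracle)
  expect_identical(formula_subtract("C45H76O19", hex3),
                   lib[["Timosaponin BII"]]$aglycone_formula)
  hex2 <- formula_add("C6H10O5", "C6H10O5")
  expect_identical(formula_subtract("C39H64O13", hex2),
                   lib[["Timosaponin AIII"]]$aglycone_formula)
  # n_hexose = 0 leaves the aglycone untouched
  bare <- saponin_candidate("aglycone-only", "C27H44O3", 0, "spirostanol")
  expect_identical(molecular_formula(bare), parse_formula("C27H44O3"))
})

test_that("isomer groups collect candidates sharing a formula, in order", {
  lib <- saponin_library()
  g <- isomer_group(lib, "C45H76O19")
  expect_identical(names(g), c("Timosaponin BII", "25R-Timosaponin BII",
                               "25S-Officinalisnin-I"))
  expect_length(isomer_group(lib, "C39H64O14"), 4L)
  expect_length(isomer_group(lib, "C10H8O4"), 0L)
})

test_that("candidate invariants are enforced", {
  expect_error(saponin_candidate("x", "C27H44O3", 2, "spirostanol",
                                 c22_hydroxyl = TRUE), "furostanol")
  expect_error(saponin_candidate("x", "C27H44O3", 2, "furostanol",
                                 extra_aglycone_oh = 2L), "0 or 1")
  expect_error(saponin_candidate("x", "C27H44O3", 2, "furostanol",
                                 c25_config = "Z"), "c25_config")
})

test_that("a library round-trips through its TSV serialization", {
  lib <- saponin_library()
  path <- system.file("extdata", "saponin_library.tsv",
                      package = "saponinscreen")
  again <- saponin_library(path)
  expect_identical(lib, again)
})
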