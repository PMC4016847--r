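test_that("skeleton classification follows the in-source dehydration rule", {
  expect_equal(classify_skeleton(c("[M+Na]+", "[M+H-H2O]+")),
               "furostanol+C22-OH")
  expect_equal(classify_skeleton(c("[M+H]+", "[M+Na]+")), "spirostanol-type")
  expect_equal(classify_skeleton("[M+Na]+"), "undetermined")
  expect_error(classify_skeleton(character()), "no precursor")
})

test_that("hexose-loss counting finds the longest consecutive chain", {
  expect_equal(count_hexose_losses(c(741, 579, 417, 273, 255), 903), 3L)
  expect_equal(count_hexose_losses(c(579, 417, 273, 255), 741), 2L)
  expect_equal(count_hexose_losses(numeric(), 903), 0L)
  # a gap breaks the chain
  expect_equal(count_hexose_losses(c(741, 417), 903), 1L)
})

test_that("aglycone hydroxylation state reads the diagnostic series", {
  expect_equal(aglycone_hydroxylation_state(c(417, 273, 255)), 0L)
  expect_equal(aglycone_hydroxylation_state(c(433, 415, 271, 253)), 1L)
  expect_true(is.na(aglycone_hydroxylation_state(c(500))))
  expect_error(aglycone_hydroxylation_state(c(417, 273, 255, 433, 415)),
               "ambiguous")
})

test_that("C25 epimers are resolved by elution order within a pair", {
  lib <- saponin_library()
  grp <- isomer_group(lib, "C39H64O13")[c("Timosaponin AIII",
                                          "25R-Timosaponin AIII")]
  class(grp) <- "candidate_set"
  # records arrive with the R epimer first: the rule must swap them
  recs <- data.frame(rt_min = c(64.4, 63.9),
                     identification = c("Timosaponin AIII",
                                        "25R-Timosaponin AIII"),
                     stringsAsFactors = FALSE)
  out <- assign_c25_configuration(recs, grp)
  expect_equal(out$identification[out$rt_min == 64.4], "25R-Timosaponin AIII")
  expect_equal(out$identification[out$rt_min == 63.9], "Timosaponin AIII")
  # singleton untouched
  single <- data.frame(rt_min = 63.9, identification = "Timosaponin AIII",
                       stringsAsFactors = FALSE)
  expect_equal(assign_c25_configuration(single, grp)$identification,
               "Timosaponin AIII")
  # more records than candidates: extras flagged unresolved
  over <- data.frame(rt_min = c(63.9, 64.4, 65.0),
                     identification = NA_character_, stringsAsFactors = FALSE)
  out <- assign_c25_configuration(over, grp)
  expect_equal(sum(out$identification == "unassigned"), 1L)
  expect_equal(out$flag[out$rt_min == 65.0], "unresolved")
})

test_that("annotating the packaged peak table reproduces the reference", {
  peaks <- read_peak_table(table2_peaks_path())
  ann <- annotate_spectra(peaks, saponin_library())
  expect_equal(nrow(ann), 15L)
  expect_identical(ann$identification, table2$identification)
  expect_identical(ann$formula, table2$formula)
  expect_equal(round(ann$theoretical_mz, 4), table2$theoretical_mz)
  expect_equal(round(ann$error_ppm, 1), table2$error_ppm)
  expect_true(all(ann$confidence[ann$identification %in% authentic_standards]
                  == "standard-confirmed"))
  expect_true(all(ann$confidence[!ann$identification %in% authentic_standards]
                  == "tentative"))
})

test_that("annotation is insensitive to spectrum input order", {
  peaks <- read_peak_table(table2_peaks_path())
  ann <- annotate_spectra(peaks, saponin_library())
  set.seed(7)
  perm <- sample(seq_along(peaks))
  ann2 <- annotate_spectra(peaks[perm], saponin_library())
  expect_identical(ann2$identification[order(perm)], ann$identification)
  expect_equal(ann2$error_ppm[order(perm)], ann$error_ppm)
})

test_that("a precursor far from every library formula stays unassigned", {
  s <- qtof_spectrum("x", 10, 500.0, c("[M+Na]+", "[M+H]+"), c(417, 273, 255))
  ann <- annotate_spectra(list(s), saponin_library())
  expect_equal(ann$identification, "unassigned")
  expect_equal(ann$confidence, "class-only")
  expect_equal(ann$skeleton_call, "spirostanol-type")
})

test_that("contradicting skeleton evidence vetoes a candidate", {
  lib <- saponin_library()
  # correct precursor and ladder for the 3-hexose furostanol, but the ion
  # species claim a spirostanol: no assignment survives
  s <- qtof_spectrum("x", 37.6, 943.4886, c("[M+Na]+", "[M+H]+"),
                     c(903, 741, 579, 417, 273, 255))
  ann <- annotate_spectra(list(s), lib)
  expect_equal(ann$identification, "unassigned")
})
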