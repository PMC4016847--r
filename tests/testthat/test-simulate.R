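test_that("a fixed seed reproduces generators byte-identically", {
  lib <- saponin_library()
  s1 <- simulate_spectrum("Timosaponin BII", lib, n_decoy = 3, seed = 99)
  s2 <- simulate_spectrum("Timosaponin BII", lib, n_decoy = 3, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_spectrum("Timosaponin BII", lib, n_decoy = 3, seed = 100)
  expect_false(identical(s1$precursor_mz, s3$precursor_mz))
  p1 <- simulate_plate(40, seed = 7)
  p2 <- simulate_plate(40, seed = 7)
  expect_identical(p1, p2)
})

test_that("noiseless spectra are exactly the theoretical spectra", {
  lib <- saponin_library()
  s <- simulate_spectrum("Timosaponin BII", lib, ppm_sigma = 0,
                         frag_sigma = 0, n_decoy = 0, rt_jitter_min = 0,
                         seed = 1)
  expect_equal(round(s$precursor_mz, 4), 943.4873)
  tree <- predict_fragments(lib[["Timosaponin BII"]])
  expect_equal(s$fragments, sort(unique(tree$mz[tree$reported]),
                                 decreasing = TRUE))
  expect_setequal(s$ions_seen, c("[M+Na]+", "[M+H-H2O]+"))
  expect_equal(s$rt_min, 37.6)
})

test_that("noiseless generation round-trips through annotation", {
  lib <- saponin_library()
  for (nm in c("Timosaponin BII", "Timosaponin AIII", "Timosaponin AI",
               "Timosaponin N")) {
    s <- simulate_spectrum(nm, lib, ppm_sigma = 0, frag_sigma = 0,
                           n_decoy = 0, rt_jitter_min = 0, seed = 1)
    ann <- annotate_spectra(list(s), lib)
    truth_group <- names(isomer_group(lib, molecular_formula(lib[[nm]])))
    expect_true(ann$identification %in% truth_group, info = nm)
  }
})

test_that("simulated precursor ppm errors have the configured spread", {
  lib <- saponin_library()
  theo <- ion_mz(molecular_formula(lib[["Timosaponin BII"]]), "[M+Na]+")
  errs <- vapply(1:200, function(seed) {
    s <- simulate_spectrum("Timosaponin BII", lib, ppm_sigma = 5,
                           frag_sigma = 0, seed = seed)
    ppm_error(theo, s$precursor_mz)
  }, 0)
  # Normal tail oracle: ~95% of draws within 2 sigma
  expect_gte(mean(abs(errs) <= 10), 0.90)
  expect_gt(stats::sd(errs), 3) # genuinely at the requested scale
})

test_that("decoy peaks stay away from true ladder ions", {
  lib <- saponin_library()
  tree <- predict_fragments(lib[["Timosaponin G"]])
  ladder <- tree$mz[tree$reported]
  for (seed in 1:20) {
    s <- simulate_spectrum("Timosaponin G", lib, ppm_sigma = 0,
                           frag_sigma = 0, n_decoy = 3, seed = seed)
    expect_length(s$fragments, length(unique(round(ladder))) + 3L)
    decoys <- s$fragments[!s$fragments %in% ladder]
    expect_true(all(vapply(decoys, function(d) all(abs(d - ladder) > 1), TRUE)))
  }
})

test_that("noiseless plates recover the simulated truth exactly", {
  p <- simulate_plate(75.8, od_sigma = 0, seed = 3)
  expect_equal(plate_inhibition(p), rep(75.8, 6))
  p0 <- simulate_plate(0, od_sigma = 0, seed = 3)
  expect_equal(unique(p0$readings[p0$roles == "sample"]), 1.0)
})

test_that("plate inhibition recovery is unbiased at assay noise levels", {
  recovered <- vapply(1:100, function(seed) {
    p <- simulate_plate(75.8, od_sigma = 0.02, n = 6, seed = seed)
    mean(plate_inhibition(p))
  }, 0)
  expect_lt(abs(mean(recovered) - 75.8), 1)
})

test_that("a simulated screen ranks the dominant agent on top", {
  eff <- screen_effects_preset("fractions")
  plates <- simulate_screen(eff, n_rep = 3, od_sigma = 0.02, seed = 17)
  res <- analyze_screen(plates)
  rk <- rank_agents(res)
  expect_equal(rk$agent_id[1], "60% ethanol")
  expect_true(all(res$n == 3))
  # the extract preset reproduces the screening outcome as simulated truth
  eff2 <- screen_effects_preset("extracts")
  plates2 <- simulate_screen(eff2, n_rep = 3, od_sigma = 0, seed = 1)
  rk2 <- rank_agents(analyze_screen(plates2))
  expect_equal(rk2$agent_id[1], "Ethyl acetate/ultrasonic")
  expect_equal(rk2$mean_inhibition[1], 44.1)
})

test_that("empty effects give an empty screen", {
  eff <- data.frame(agent_id = character(), enzyme = character(),
                    inhibition = numeric())
  expect_length(simulate_screen(eff, seed = 1), 0L)
})
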