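test_that("nominal ladders reproduce the printed fragment lists for all peaks", {
  lib <- saponin_library()
  for (i in seq_along(lib)) {
    tree <- predict_fragments(lib[[i]])
    expect_identical(nominal_ladder(tree), as.integer(table2_ladders[[i]]),
                     info = names(lib)[i])
  }
})

test_that("every tree edge is one in-scope neutral loss and m/z decreases", {
  lib <- saponin_library()
  in_scope <- c("H2O", "C6H10O5", "C8H16O2", "C8H14O2", "C8H18O2")
  for (cand in lib) {
    tree <- predict_fragments(cand)
    kids <- which(!is.na(tree$parent))
    expect_gt(length(kids), 0)
    for (k in kids) {
      p <- match(tree$parent[k], tree$label)
      expect_true(tree$loss[k] %in% in_scope)
      # child composition = parent minus the stated loss
      expect_identical(
        formula_string(formula_subtract(tree$formula[p], tree$loss[k])),
        tree$formula[k])
      expect_lt(tree$mz[k], tree$mz[p])
    }
    # steps count generations from the precursor adducts
    expect_true(all(tree$step >= 0L))
    expect_false(anyDuplicated(tree$label) > 0)
  }
})

test_that("accurate fragment values of the glycoside standard match at 50 ppm", {
  lib <- saponin_library()
  tree <- predict_fragments(lib[["Timosaponin BII"]])
  observed <- c(903.4982, 741.4468, 579.3934, 417.3251, 273.2139, 255.2030)
  m <- match_fragments(tree, observed, tol_ppm = 50)
  expect_equal(nrow(m$matches), 6L)
  expect_equal(m$coverage, 1.0)
})

test_that("matching is exact on the nominal ladder and empty on nothing", {
  lib <- saponin_library()
  tree <- predict_fragments(lib[["Timosaponin BII"]])
  m <- match_fragments(tree, c(903, 741, 579, 417, 273, 255), tol_da = 0.5)
  expect_equal(m$coverage, 1.0)
  expect_equal(match_fragments(tree, numeric())$coverage, 0)
})

test_that("coverage is monotone nondecreasing in tolerance width", {
  lib <- saponin_library()
  set.seed(42)
  for (nm in sample(names(lib), 5)) {
    tree <- predict_fragments(lib[[nm]])
    obs <- nominal_ladder(tree) + rnorm(length(nominal_ladder(tree)), 0, 0.3)
    covs <- vapply(c(0.05, 0.2, 0.5, 1.0), function(tol) {
      match_fragments(tree, obs, tol_da = tol)$coverage
    }, 0)
    expect_true(all(diff(covs) >= 0), info = nm)
  }
})

test_that("each observed peak is matched at most once", {
  lib <- saponin_library()
  tree <- predict_fragments(lib[["Timosaponin AI"]])
  # one observed peak cannot satisfy two predicted ions
  m <- match_fragments(tree, c(417.3), tol_da = 200)
  expect_equal(nrow(m$matches), 1L)
})

test_that("a tree with no reported ions is flagged unusable", {
  lib <- saponin_library()
  tree <- predict_fragments(lib[["Timosaponin AI"]])
  tree$reported <- FALSE
  expect_error(match_fragments(tree, c(417)), "unusable")
})

test_that("expected precursor species follow the C22-hydroxyl rule", {
  lib <- saponin_library()
  expect_setequal(expected_precursor_ions(lib[["Timosaponin BII"]]),
                  c("[M+Na]+", "[M+H-H2O]+"))
  expect_setequal(expected_precursor_ions(lib[["Timosaponin AIII"]]),
                  c("[M+Na]+", "[M+H]+"))
})
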