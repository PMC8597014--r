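test_that("rate constants validate non-negativity and finiteness", {
  expect_error(rate_constants(-0.1, 1, 1, 0.01, 0.01), ">= 0")
  expect_error(rate_constants(Inf, 1, 1, 0.01, 0.01), "finite")
  k <- tri_constants()
  expect_named(unclass(k), c("k_O2_O6", "k_O3_O2", "k_O2_O3",
                             "k_prim_hydr", "k_sec_hydr"))
})

test_that("every rate-matrix column sums to zero (mass conservation)", {
  set.seed(2)
  for (i in 1:20) {
    kk <- random_constants()
    for (mk in c("trisaccharide", "ggm")) {
      K <- build_rate_matrix(kk, mk)
      expect_lt(max(abs(colSums(K))), 1e-14)
      offdiag <- K - diag(diag(K))
      expect_true(all(offdiag >= 0))
    }
  }
})

test_that("trisaccharide matrix entries reproduce the printed rate laws", {
  # hand evaluation with the published trisaccharide constants
  K <- build_rate_matrix(tri_constants(), "trisaccharide")
  expect_equal(K["c_1b", "c_1a"], 2.06e-3)
  expect_equal(K["c_1a", "c_1a"], -(2.06e-3 + 2 * 1.56e-3))
  expect_equal(K["c_1c", "c_1b"], 1.88)           # O3 -> O2 exchange
  expect_equal(K["c_1b", "c_1c"], 1.01)           # back migration
  expect_equal(K["c_1d", "c_1b"], 1.93e-3)        # primary hydrolysis
  expect_equal(K["c_1f", "c_1e"], 2.06e-3)        # 1e -> 1f at k_O2_O6
  expect_equal(K["c_1g", "c_1f"], 1.93e-3)        # 1f -> 1g primary
  expect_equal(K["c_1g", "c_1d"], 1.56e-3)
  expect_equal(K["c_1a", "c_1b"], 0)              # no back-migration 1b->1a
  # optional sensitivity channel restores the back-migration
  Kb <- build_rate_matrix(tri_constants(), "trisaccharide",
                          k_back_1b_1a = 0.01)
  expect_equal(Kb["c_1a", "c_1b"], 0.01)
  expect_lt(max(abs(colSums(Kb))), 1e-14)
})

test_that("GGM matrix entries reproduce the printed rate laws", {
  K <- build_rate_matrix(ggm2_constants(), "ggm")
  expect_equal(K["c_B", "c_A"], 1.60)
  expect_equal(K["c_A", "c_B"], 1.00)
  expect_equal(K["c_C", "c_B"], 1.50e-3)
  expect_equal(K["c_D", "c_C"], 3.72e-3)
  expect_equal(K["c_D", "c_A"], 2.60e-4)
})

test_that("species derivatives match hand-evaluated mass balances", {
  d <- species_rates(pure_state("c_1a", "trisaccharide"), tri_constants(),
                     1, "trisaccharide")
  expect_equal(unname(d["c_1a"]), -5.18e-3)
  expect_equal(unname(d["c_1b"]), 2.06e-3)
  expect_equal(unname(d["c_1d"]), 1.56e-3)
  expect_equal(unname(d["c_1e"]), 1.56e-3)
  expect_equal(unname(d[c("c_1c", "c_1f", "c_1g")]), c(0, 0, 0))

  dg <- species_rates(c(0.39, 0.61, 0, 0), ggm2_constants(), 1, "ggm")
  expect_equal(unname(dg["c_A"]), -0.0141014, tolerance = 1e-6)
  expect_equal(unname(dg["c_B"]), 0.0129264, tolerance = 1e-6)
  expect_equal(unname(dg["c_C"]), 9.15e-4, tolerance = 1e-6)
  expect_equal(unname(dg["c_D"]), 2.60e-4, tolerance = 1e-6)

  # the hydroxide factor scales every derivative linearly
  expect_equal(species_rates(c(0.39, 0.61, 0, 0), ggm2_constants(),
                             0.5, "ggm"), dg / 2)
})

test_that("derivatives sum to zero for arbitrary states", {
  set.seed(3)
  for (i in 1:10) {
    kk <- random_constants()
    expect_lt(abs(sum(species_rates(random_simplex_state("trisaccharide"),
                                    kk, runif(1, 0, 2), "trisaccharide"))),
              1e-14)
    expect_lt(abs(sum(species_rates(random_simplex_state("ggm"),
                                    kk, runif(1, 0, 2), "ggm"))), 1e-14)
  }
})

test_that("state dimension and domain errors are caught", {
  expect_error(species_rates(c(1, 0, 0), tri_constants(), 1,
                             "trisaccharide"), "length 7")
  expect_error(species_rates(c(2, 0, 0, 0), ggm2_constants(), 1, "ggm"),
               "\\[0, 1\\]")
  expect_error(species_rates(c(1, 0, 0, 0), ggm2_constants(), -1, "ggm"),
               "non-negative")
})

test_that("O2/O3 equilibrium fraction follows the migration constants", {
  sym <- rate_constants(0, 1.3, 1.3, 0, 0)
  expect_equal(equilibrium_O2_fraction(sym), 0.5)
  expect_equal(equilibrium_O2_fraction(tri_constants()),
               1.88 / (1.88 + 1.01))
  expect_equal(equilibrium_O2_fraction(ggm2_constants()), 1.60 / 2.60)
  none <- rate_constants(1e-3, 0, 0, 1e-3, 1e-3)
  expect_error(equilibrium_O2_fraction(none), "undefined")
})
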