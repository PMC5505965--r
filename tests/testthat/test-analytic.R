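# frozen oracle values computed with 40-digit arithmetic (mpmath):
#   (1 - exp(-0.125)) / (1 - exp(-125))    = 0.11750309741540459714
#   1 - 0.9 ^ (1 / (1 - exp(-0.0625)))     = 0.8243035036915354198

test_that("balance frequency solves the selection-mutation fixed point", {
  # no phenotypic mutation: the fitter phenotype takes over the lineage
  expect_equal(balance_frequency(0, 0.75, 0.85), 1)
  # fixed-point oracle at mu = 0.1
  expect_equal(balance_frequency(0.1, 0.75, 0.85),
               balance_fixed_point(0.1, 0.75, 0.85), tolerance = 1e-9)
  # maximal switching equilibrates the two phenotypes exactly
  f_half <- balance_frequency(0.5, 0.75, 0.85)
  expect_equal(f_half, 0.5)
  expect_lt(f_half, balance_frequency(0.1, 0.75, 0.85))
  # strict monotone decrease in mu, values within [1/2, 1]
  mus <- seq(0, 0.5, by = 0.05)
  fs <- balance_frequency(mus, 0.75, 0.85)
  expect_true(all(diff(fs) < 0))
  expect_true(all(fs >= 0.5 & fs <= 1))
  expect_error(balance_frequency(0.1, 0.8, 0.8), "degenerate")
})

test_that("the two balance parameterizations agree to machine precision", {
  for (mu in seq(0.025, 0.5, length.out = 8)) {
    for (sigma in c(0.01, 0.05, 0.1, 0.15)) {
      for (e_phi in c(0.5, 0.8, 1.2)) {
        expect_equal(balance_frequency(mu, e_phi - sigma, e_phi + sigma),
                     balance_frequency_ms(mu, e_phi, sigma),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("effective selection is the lineage mean fitness relative to the wild type", {
  expect_equal(effective_selection(1, 0.75, 0.85, 0.8), 0.0625)
  expect_equal(effective_selection(0.5, 0.75, 0.85, 0.8), 0)
  expect_equal(effective_selection(0, 0.75, 0.85, 0.8), -0.0625)
  expect_error(effective_selection(0.5, 0.75, 0.85, 0), "positive")
})

test_that("Kimura formula: neutral limit, frozen value, deleterious tail, monotone", {
  expect_identical(kimura_fixation(0, 1000), 1 / 1000)
  expect_identical(kimura_fixation(1e-12, 200), 1 / 200)
  expect_equal(kimura_fixation(0.0625, 1000), 0.11750309741540459714,
               tolerance = 1e-14)
  expect_lt(kimura_fixation(-0.05, 1000), 1e-20)
  s_grid <- seq(-0.1, 0.2, by = 0.01)
  expect_true(all(diff(kimura_fixation(s_grid, 500)) > 0))
})

test_that("rescue probability before loss follows the geometric-decay sum", {
  expect_equal(loss_mutation_probability(0, 0.1), 0)
  expect_equal(loss_mutation_probability(0.1, 0.0625), 0.8243035036915354198,
               tolerance = 1e-14)
  # as s grows the cumulative copy count approaches 1: P -> mu
  expect_equal(loss_mutation_probability(0.4999, 50), 1 - 0.5001^(1 / (1 - exp(-50))),
               tolerance = 1e-12)
  expect_lt(abs(loss_mutation_probability(0.4999, 50) - 0.4999), 1e-3)
  expect_error(loss_mutation_probability(0.1, 0), "non-decaying")
  expect_error(loss_mutation_probability(0.1, -0.2), "non-decaying")
})

test_that("the composed fixation chain satisfies its own identity and limits", {
  d <- phenotype_distribution("two_point", mean = 0.8, sd = 0.05)
  # full memory: no phenotypic mutation, so half the introductions fix as a_max
  r1 <- plastic_fixation_probability(1, d, phi_A = 0.8, N = 1000)
  expect_equal(r1$mu, 0)
  expect_equal(r1$p_eta, 0)
  expect_equal(r1$p_fix, 0.5 * kimura_fixation(0.0625, 1000))
  # the decomposition P_f(a) = 1/2 P_max + 1/2 P(eta) P_max holds exactly
  for (p in c(0.1, 0.5, 0.9)) {
    r <- plastic_fixation_probability(p, d, 0.8, 1000)
    expect_identical(r$p_fix, 0.5 * r$p_fix_max + 0.5 * r$p_eta * r$p_fix_max)
    expect_identical(r$p_fix_min, r$p_eta * r$p_fix_max)
  }
  expect_error(plastic_fixation_probability(
    0.5, phenotype_distribution("uniform", 0.8, 0.05), 0.8, 1000), "two_point")
})

test_that("predicted fixation is monotone in memory and in phenotypic variance", {
  ps <- seq(0.1, 0.99, length.out = 12)
  for (sd in c(0.02, 0.05, 0.1)) {
    d <- phenotype_distribution("two_point", 0.8, sd)
    curve <- vapply(ps, function(p)
      plastic_fixation_probability(p, d, 0.8, 1000)$p_fix, numeric(1))
    expect_true(all(diff(curve) > 0))
  }
  for (p in c(0.3, 0.6, 0.9)) {
    by_sd <- vapply(c(0.02, 0.05, 0.1), function(sd)
      plastic_fixation_probability(p, phenotype_distribution("two_point", 0.8, sd),
                                   0.8, 1000)$p_fix, numeric(1))
    expect_true(all(diff(by_sd) > 0))
  }
})

test_that("vanishing variance recovers the neutral fixation probability", {
  d <- phenotype_distribution("two_point", 0.8, 1e-10)
  r <- plastic_fixation_probability(0.9, d, 0.8, 1000)
  expect_lt(abs(r$s_a), 1e-8)
  expect_equal(r$p_fix_max, 1 / 1000)
})

test_that("the alternative decay coefficient |s_a| is available", {
  d <- phenotype_distribution("two_point", 0.8, 0.05)
  r1 <- plastic_fixation_probability(0.8, d, 0.8, 1000, s_loss = "phi_min")
  r2 <- plastic_fixation_probability(0.8, d, 0.8, 1000, s_loss = "abs_s_a")
  expect_equal(r1$s_loss, 1 - 0.75 / 0.8)
  expect_equal(r2$s_loss, abs(r2$s_a))
  expect_false(isTRUE(all.equal(r1$p_fix, r2$p_fix)))
})

test_that("the analytic curve export carries the whole chain", {
  curve <- analytic_fixation_curve(c(0.2, 0.5, 0.8), mean = 0.8, sd = 0.1,
                                   phi_A = 0.8, N = 1000)
  expect_equal(names(curve), c("p", "mu", "f_a_max", "s_a", "p_eta", "p_fix"))
  expect_equal(curve$mu, (1 - curve$p) / 2)
})
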