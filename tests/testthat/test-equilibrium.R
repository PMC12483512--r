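test_that("enhancement factor follows exp(E_B) V1 f(d, l0)", {
  # E_B = 10, V1 = 1, d = l0 = sqrt(50): oracle e^10 * 2.082e-4 = 4.586
  expect_equal(enhancement_factor(10, ref_d, ref_d, 1), 4.586, tolerance = 1e-3)
  # vanishes at large spacing
  expect_lt(enhancement_factor(10, 100, ref_d, 1), 1e-100)
  # definitional consistency with the threshold energy, any phi
  for (phi in c(0.05, sqrt(0.02), 0.5, 1)) {
    d <- 3
    V1 <- (phi * d)^3
    expect_equal(enhancement_factor(threshold_energy(phi), d, d, V1), 1,
                 tolerance = 1e-9)
  }
})

test_that("threshold energy matches the closed form and is decreasing", {
  expect_equal(threshold_energy(sqrt(0.02)), 8.48, tolerance = 5e-3)
  expect_equal(threshold_energy(1), 1.5 * (log(2 * pi / 3) + 1), tolerance = 1e-12)
  # root-finding cross-check: E with P(E, d, d) = 1
  phi <- 0.3
  d <- 5
  root <- stats::uniroot(function(E) enhancement_factor(E, d, d, (phi * d)^3) - 1,
                         c(0.1, 30), tol = 1e-10)$root
  expect_equal(threshold_energy(phi), root, tolerance = 1e-8)
  grid <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(threshold_energy(grid)) < 0))
  expect_error(threshold_energy(0), "positive")
})

test_that("configuration enumeration counts injective matchings", {
  # 1 site, 1 target: the four-state system
  expect_equal(nrow(enumerate_configurations(tf_architecture(1, 5),
                                             target_layout(1, 5))), 4)
  # 2 sites, 2 targets: 1 + 4 + 2 IDR matchings, doubled by the DBD state
  cfg22 <- enumerate_configurations(tf_architecture(2, 5), target_layout(2, 5))
  expect_equal(nrow(cfg22), 14)
  expect_equal(sum(cfg22$n_bound == 2), 2 * 2)  # both crossings, both DBD states
  # no IDR sites: free and DBD-bound only
  expect_equal(nrow(enumerate_configurations(tf_architecture(0, 5),
                                             target_layout(3, 5))), 2)
  # closed-form count agrees for larger systems
  expect_equal(configuration_count(4, 3),
               2 * sum(choose(4, 0:3) * choose(3, 0:3) * factorial(0:3)))
  expect_error(enumerate_configurations(tf_architecture(8, 5),
                                        target_layout(8, 5), cap = 100),
               "cap")
})

test_that("configuration weights follow the contact-product convention", {
  arch <- tf_architecture(1, ref_d)
  lay <- target_layout(1, ref_d)
  en <- ref_energy()
  # free state carries the translational volume
  expect_equal(configuration_weight(FALSE, NA_integer_, arch, lay, en), en$V)
  # bare DBD: single Boltzmann factor e^15 * V1
  expect_equal(configuration_weight(TRUE, NA_integer_, arch, lay, en), exp(15))
  # both bound: e^{E_DBD + E_B} V1^2 f(d, l0)
  expect_equal(configuration_weight(TRUE, 1L, arch, lay, en),
               exp(25) * gaussian_propagator(ref_d, 1, ref_d))
})

test_that("full configuration sum reproduces Q = 1 + P for one site and target", {
  arch <- tf_architecture(1, ref_d)
  lay <- target_layout(1, ref_d)
  # V-dominated regime: push the volume up so the bound weights are negligible
  en <- energy_model(10, 15, V1 = 1, V = 1e16)
  res <- binding_probability(arch, lay, en)
  P <- enhancement_factor(10, ref_d, ref_d, 1)
  expect_equal(res$Q, 1 + P, tolerance = 1e-6)
  # at the published nuclear volume the ratio is about 5.6
  res2 <- binding_probability(arch, lay, ref_energy())
  expect_equal(res2$Q, 1 + P, tolerance = 1e-3)
})

test_that("probability closure holds to 1e-12 across parameter sets", {
  for (pars in list(list(1, 1, 10, 15), list(2, 3, 8, 12),
                    list(4, 4, 12, 15), list(3, 2, 14, 20))) {
    arch <- tf_architecture(pars[[1]], ref_d)
    lay <- target_layout(pars[[2]], ref_d)
    en <- ref_energy(pars[[3]], pars[[4]])
    r <- binding_probability(arch, lay, en)
    expect_equal(r$P_free + r$P_IDR_only + r$P_TF, 1, tolerance = 1e-12)
    expect_true(all(c(r$P_free, r$P_IDR_only, r$P_TF) >= 0))
    expect_true(all(c(r$P_free, r$P_IDR_only, r$P_TF) <= 1))
  }
})

test_that("log-space sum agrees with direct R enumeration", {
  for (pars in list(c(1, 1), c(2, 2), c(3, 2), c(2, 4))) {
    arch <- tf_architecture(pars[1], 6)
    lay <- target_layout(pars[2], 8)
    en <- ref_energy(9, 13)
    s <- enum_weight_sums(arch, lay, en)
    r <- binding_probability(arch, lay, en)
    expect_equal(r$P_TF, s$tf / s$total, tolerance = 1e-10)
    expect_equal(r$n_configs, s$n)
  }
})

test_that("the IDR never lowers the DBD occupancy in the dilute regime", {
  # Q >= 1 whenever the volume term dominates
  for (EB in c(2, 6, 10)) {
    r <- binding_probability(tf_architecture(2, ref_d), target_layout(2, ref_d),
                             energy_model(EB, 15, 1, 1e16))
    expect_gte(r$Q, 1)
  }
})

test_that("weak-binding approximation matches the full ratio when P_TF is small", {
  arch <- tf_architecture(1, ref_d)
  lay <- target_layout(1, ref_d)
  en <- ref_energy()
  expect_equal(approximate_q(arch, lay, en),
               1 + enhancement_factor(10, ref_d, ref_d, 1), tolerance = 1e-12)
  # across an energy grid below threshold, within 10% of the full sum
  for (EB in seq(4, 8, by = 1)) {
    for (nb in c(2, 4)) {
      en2 <- ref_energy(EB)
      qa <- approximate_q(tf_architecture(nb, ref_d), target_layout(nb, ref_d), en2)
      qf <- binding_probability(tf_architecture(nb, ref_d), target_layout(nb, ref_d), en2)$Q
      expect_lt(abs(qa - qf) / qf, 0.1)
      expect_gte(qa, 1)
    }
  }
})

test_that("binding probability vanishes into the simple-TF limit as E_B -> 0", {
  arch <- tf_architecture(1, ref_d)
  lay <- target_layout(1, ref_d)
  en <- energy_model(1e-9, 15, 1, nm3_to_bp3(1e9))
  r <- binding_probability(arch, lay, en)
  expect_equal(r$Q, 1 + gaussian_propagator(ref_d, 1, ref_d), tolerance = 1e-6)
})

test_that("uniform-measure Monte Carlo limit recovers V1 / V", {
  # near-zero well depths: occupancy is the volume fraction
  en <- energy_model(1e-6, 1e-6, V1 = 4 / 3 * pi * 27, V = 64000)
  mc <- metropolis_binding(tf_architecture(1, 6), target_layout(1, 6), en,
                           n_sweeps = 4e5, seed = 5)
  expect_lt(abs(mc$P_TF - en$V1 / en$V), 3 * max(mc$se, 2e-4))
})
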