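test_that("two-term search time evaluates and scales correctly", {
  th <- t_total_theory(300, 4, 500, 1, 5, alpha = 0.5, beta = 14.5)
  # hand evaluation: 0.5 * 4 * 500^3 / 300 * log(300 / sqrt(4/6) / 5) and
  # 14.5 * 300^2
  expect_equal(th$t_3d, 0.5 * 4 * 500^3 / 300 * log(300 / (sqrt(4 / 6) * 5)),
               tolerance = 1e-12)
  expect_equal(th$t_3d, 3.58e6, tolerance = 1e-2)
  expect_equal(th$t_1d, 1.305e6, tolerance = 1e-12)
  expect_equal(th$t_total, th$t_3d + th$t_1d)
  # 1/D scaling: doubling D halves every term
  th2 <- t_total_theory(300, 4, 500, 2, 5, alpha = 0.5, beta = 14.5)
  expect_equal(th2$t_total, th$t_total / 2, tolerance = 1e-12)
  # beta = 0: strictly decreasing in L beyond e * r_p
  L <- seq(40, 900, by = 20)
  t3 <- t_total_theory(L, 4, 500, 1, 5, alpha = 0.5, beta = 0)$t_total
  expect_true(all(diff(t3[L > exp(1) * sqrt(4 / 6) * 5]) < 0))
  expect_error(t_total_theory(3, 4, 500, 1, 5), "r_p")
})

test_that("prefactor fitting recovers known alpha and beta from noisy data", {
  set.seed(8)
  L <- c(100, 150, 220, 330, 500)
  th <- t_total_theory(L, 4, 500, 1, 5, alpha = 0.5, beta = 14.5)
  for (rep in 1:5) {
    dat <- data.frame(
      L = L,
      t_3d = th$t_3d * (1 + rnorm(5, sd = 0.05)),
      t_1d = th$t_1d * (1 + rnorm(5, sd = 0.05)),
      se_3d = th$t_3d * 0.05, se_1d = th$t_1d * 0.05
    )
    fit <- fit_alpha_beta(dat, 4, 500, 1, 5)
    expect_lt(abs(fit$alpha - 0.5), 2.5 * fit$alpha_se + 0.02)
    expect_lt(abs(fit$beta - 14.5), 2.5 * fit$beta_se + 0.5)
  }
  expect_error(fit_alpha_beta(data.frame(L = c(1, 1, 2), t_3d = 1:3,
                                         t_1d = 1:3), 4, 500),
               "distinct")
})

test_that("optimal antenna length solves the stationarity condition", {
  # oracle: alpha n R^3 (log(L / r_p) - 1) = 2 beta L^3, solved by bisection
  for (R in c(500, 1500, 2941)) {
    opt <- optimal_antenna(4, R, 1, 5, alpha = 0.5, beta = 14.5)
    r_p <- sqrt(4 / 6) * 5
    g <- function(L) 0.5 * 4 * R^3 * (log(L / r_p) - 1) - 2 * 14.5 * L^3
    L_root <- stats::uniroot(g, c(r_p * 3, 20 * R), tol = 1e-8)$root
    expect_equal(opt$L_star, L_root, tolerance = 1e-4)
  }
  # published-scale check: R = 500 bp gives L* near 300 bp
  opt500 <- optimal_antenna(4, 500, 1, 5)
  expect_equal(opt500$L_star, 300, tolerance = 0.05)
})

test_that("optimal length scales linearly with R and t_min quadratically", {
  Rs <- c(500, 1000, 2000, 4000)
  opts <- lapply(Rs, function(R) optimal_antenna(4, R, 1, 5))
  Ls <- vapply(opts, `[[`, 0, "L_star")
  ts <- vapply(opts, `[[`, 0, "t_min")
  expect_true(all(diff(Ls) > 0))
  expect_true(all(diff(ts) > 0))
  for (i in 1:3) {
    expect_gt(Ls[i + 1] / Ls[i], 1.8)
    expect_lt(Ls[i + 1] / Ls[i], 2.2)
  }
  slope <- stats::coef(stats::lm(log(ts) ~ log(Rs)))[2]
  expect_gt(slope, 1.9)
  expect_lt(slope, 2.2)
})

test_that("simple-TF baseline follows R^3 / (3 D a)", {
  expect_equal(simple_tf_time(500, 1, 0.5), 500^3 / 1.5, tolerance = 1e-12)
  expect_equal(simple_tf_time(500, 1, 0.5), 8.33e7, tolerance = 1e-2)
  # continuity as the absorber fills the sphere
  expect_equal(simple_tf_time(100, 1, 100 * (1 - 1e-9)), 100^2 / 3,
               tolerance = 1e-6)
  expect_error(simple_tf_time(100, 1, 200))
})

test_that("rate conversion is dimensionally consistent", {
  r <- binding_rates(1e6, P_TF = 0.5, D_SI = 1e-13, copy_number = 100,
                     nucleus_volume = 4 / 3 * pi * 1e-18)
  # P_TF = 1/2 makes the off-rate the inverse effective search time
  expect_equal(r$k_off, 1 / r$t_eff_s, tolerance = 1e-12)
  expect_equal(r$k_D, r$k_off / r$k_on, tolerance = 1e-12)
  # k_on doubles with copy number, k_D is copy-number independent
  r2 <- binding_rates(1e6, P_TF = 0.5, D_SI = 1e-13, copy_number = 200,
                      nucleus_volume = 4 / 3 * pi * 1e-18)
  expect_equal(r2$k_on, 2 * r$k_on, tolerance = 1e-12)
  expect_equal(r2$k_D, r$k_D, tolerance = 1e-12)  # k_off doubles too
  expect_error(binding_rates(1e6, P_TF = 1))
})

test_that("rates are pure functions of their inputs", {
  a <- binding_rates(2.5e8, 0.9)
  b <- binding_rates(2.5e8, 0.9)
  expect_identical(a, b)
  o1 <- optimal_antenna(4, 2941, 1, 5)
  o2 <- optimal_antenna(4, 2941, 1, 5)
  expect_identical(o1, o2)
})

test_that("dissociation-constant variation is dominated by the off-rate", {
  # across an IDR-length sweep at fixed search time, k_on is constant and
  # all k_D variation comes from k_off
  en <- energy_model(11, 22, 1, nm3_to_bp3(1e9))
  tt <- optimal_antenna(4, nm_to_bp(1000), 1, 5)$t_min
  rates <- lapply(1:6, function(nb) {
    p <- binding_probability(tf_architecture(nb, sqrt(50)),
                             target_layout(6, sqrt(50)), en)$P_TF
    binding_rates(tt, p)
  })
  kon <- vapply(rates, `[[`, 0, "k_on")
  koff <- vapply(rates, `[[`, 0, "k_off")
  expect_gt(diff(range(log(koff))), 10 * diff(range(log(kon))))
})
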